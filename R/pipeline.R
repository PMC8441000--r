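# End-to-end orchestration: config validation, stage sequencing,
# machine-readable report, file writers and a CLI entry point.

#' Write a genotype matrix as VCF
#'
#' Emits a minimal VCF 4.2 with the counted allele as ALT and GT hard
#' calls (dosages rounded); missing dosages become `./.`. Round-trips
#' through [load_genotypes()].
#'
#' @param geno a [genotype_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(geno, path) {
  meta <- geno$snp_meta
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$sample_ids), collapse = "\t")
  ), con)
  gt_codes <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(meta))) {
    d <- round(geno$dosages[, j])
    gt <- ifelse(is.na(d), "./.", gt_codes[d + 1L])
    writeLines(paste(c(meta$chrom[j], meta$pos[j], meta$snp_id[j],
                       meta$other_allele[j], meta$counted_allele[j],
                       ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a genotype matrix as a dosage TSV
#'
#' Header is `sample_id` then snp_ids; one row per sample.
#'
#' @param geno a [genotype_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(geno, path) {
  df <- data.frame(sample_id = geno$sample_ids,
                   geno$dosages, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write GWAS summary statistics as TSV
#'
#' @param gwas a [gwas_summary].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gwas_summary <- function(gwas, path) {
  utils::write.table(as.data.frame(gwas), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Default (demo) pipeline configuration
#'
#' A fully simulated run at desk scale, mirroring the analysis plan:
#' MAVAN-preset QC, 50 kb / 5 SNP / r2 0.2 pruning for PCs, 250 kb / r2
#' 0.2 clumping, the 100-point threshold grid, per-SNP refinement at
#' alpha 0.05, model-3 GxE with simple slopes at +/- 1 SD, regions of
#' significance, PoI/PA, a 200-replicate bootstrap and 30 hot-deck
#' imputations.
#'
#' @param seed integer master seed.
#' @return A nested configuration list.
#' @export
default_pipeline_config <- function(seed = 42) {
  list(
    seed = as.integer(seed),
    simulate = list(),  # sim_config() overrides; empty = defaults
    qc = list(preset = "mavan"),
    prune = list(window_kb = 50, step_snps = 5, r2_max = 0.2),
    clump = list(window_kb = 250, r2_max = 0.2),
    scan = list(grid_size = 100, covariates = "pcs10", n_pcs = 10),
    alpha_refine = 0.05,
    gxe = list(probe_sd = 1, alpha = 0.05),
    bootstrap = list(enabled = TRUE, n_boot = 200),
    imputation = list(enabled = TRUE, m = 30)
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml/.yml or .json")
  }
}

#' Validate a pipeline configuration
#'
#' Checks that exactly one input mode is declared (a `simulate` block or
#' an `inputs` block of file paths), that required keys are present, and
#' that referenced files exist. Errors name the offending key.
#'
#' @param config configuration list.
#' @return The config, invisibly, on success.
#' @export
validate_pipeline_config <- function(config) {
  has_sim <- !is.null(config$simulate)
  has_inputs <- !is.null(config$inputs)
  if (has_sim == has_inputs) {
    stop("config must declare exactly one of 'simulate' or 'inputs'")
  }
  for (key in c("seed", "qc", "prune", "clump", "scan", "alpha_refine",
                "gxe")) {
    if (is.null(config[[key]])) stop("config is missing the key '", key, "'")
  }
  if (has_inputs) {
    for (key in c("gwas", "discovery_genotypes", "test_genotypes",
                  "phenotype", "adversity", "outcome")) {
      f <- config$inputs[[key]]
      if (is.null(f)) stop("config$inputs is missing the key '", key, "'")
      if (!file.exists(f)) stop("config$inputs$", key, " not found: ", f)
    }
  }
  invisible(config)
}

#' Run the full refined-PRS / GxE pipeline
#'
#' Sequence: simulate (or read) inputs -> QC -> population-structure PCs
#' -> allele alignment -> LD clumping -> 100-threshold scan -> per-SNP
#' refinement -> refined score in the test cohort -> adversity scoring
#' -> outcome assembly -> three GxE models with simple slopes, regions
#' of significance and PoI/PA, plus optional bootstrap and hot-deck
#' imputation with Rubin pooling. Stage messages go to `message()`; a
#' JSON report and TSV artifacts are written when `out_dir` is given.
#'
#' @param config configuration list (see [default_pipeline_config()]).
#' @param out_dir optional output directory for `report.json`,
#'   `refined_snp_set.tsv` (+ JSON sidecar) and `threshold_scan.tsv`.
#' @return The report list, invisibly.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = NULL) {
  validate_pipeline_config(config)
  report <- list(seed = config$seed)
  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  world <- stage("data", {
    if (!is.null(config$simulate)) {
      cfg <- do.call(sim_config, c(config$simulate,
                                   list(seed = config$seed)))
      simulate_cohorts(cfg)
    } else {
      read_world(config$inputs)
    }
  })
  report$data <- list(
    n_discovery = length(world$discovery$geno$sample_ids),
    n_test = length(world$test$geno$sample_ids),
    n_snps = nrow(world$gwas)
  )

  thr <- do.call(qc_thresholds, config$qc)
  disc <- stage("qc", qc_filter(world$discovery$geno, thr))
  test <- stage("qc", qc_filter(world$test$geno, thr))
  report$qc <- list(n_snps_discovery = nrow(disc$snp_meta),
                    n_snps_test = nrow(test$snp_meta))

  pcfg <- do.call(prune_config, config$prune)
  n_pcs <- config$scan$n_pcs %||% 10
  pcs_disc <- stage("pca", compute_pcs(disc, k = n_pcs, cfg = pcfg))
  pcs_test <- stage("pca", compute_pcs(test, k = 3, cfg = pcfg))
  report$pca <- list(k_discovery = ncol(pcs_disc), k_test = ncol(pcs_test))

  disc <- stage("align", align_alleles(disc, world$gwas))
  test <- stage("align", align_alleles(test, world$gwas))

  clump <- stage("clump", ld_clump(world$gwas, disc,
                                   r2_max = config$clump$r2_max,
                                   window_kb = config$clump$window_kb))
  gwas_clumped <- world$gwas[world$gwas$snp_id %in% clump$retained, ,
                             drop = FALSE]
  class(gwas_clumped) <- class(world$gwas)
  report$clump <- list(n_retained = length(clump$retained),
                       n_removed = length(clump$removed_by))

  covs <- if (identical(config$scan$covariates, "none")) NULL else pcs_disc
  grid <- seq(1 / config$scan$grid_size, 1,
              length.out = config$scan$grid_size)
  scan <- stage("scan", threshold_scan(disc, gwas_clumped,
                                       world$discovery$insulin,
                                       covariates = covs, grid = grid))
  report$scan <- list(best_threshold = scan$best_threshold,
                      n_thresholds = nrow(scan$scan),
                      table = scan$scan)

  refined <- stage("refine", refine_snps(
    disc, gwas_clumped, world$discovery$insulin, covariates = covs,
    source_threshold = scan$best_threshold,
    alpha_refine = config$alpha_refine))
  report$refine <- list(n_snps = nrow(refined$snps),
                        alpha_refine = refined$alpha_refine,
                        source_threshold = refined$source_threshold,
                        sha = refined_set_hash(refined))

  rprs <- stage("rprs", compute_rprs(test, refined))
  report$rprs <- list(n_snps_used = rprs$n_snps_used,
                      mean = mean(rprs$standardized),
                      sd = stats::sd(rprs$standardized))

  adv <- stage("adversity", adversity_score(world$test$adversity,
                                            complete_case = TRUE))
  report$adversity <- list(
    n_components = adv$n_components,
    n_complete = sum(adv$complete_case),
    score_table = as.list(table(adv$score, useNA = "no"))
  )

  analysis <- stage("outcome", data.frame(
    sample_id = test$sample_ids,
    outcome = world$test$outcome,
    adversity = as.numeric(adv$score),
    rprs = rprs$standardized,
    sex = world$test$sex,
    pc1 = pcs_test[, 1], pc2 = pcs_test[, 2], pc3 = pcs_test[, 3]
  ))

  gxe <- stage("gxe", {
    fits <- fit_gxe_models(analysis)
    fit3 <- fits$model3
    slopes <- simple_slopes(fit3,
                            m_points = c(-1, 1) * (config$gxe$probe_sd %||% 1),
                            alpha = config$gxe$alpha %||% 0.05)
    x_obs <- analysis$adversity[stats::complete.cases(analysis[-1])]
    ros <- jn_regions(fit3, range = c(min(x_obs), max(x_obs)),
                      alpha = config$gxe$alpha %||% 0.05)
    indices <- poi_pa(fit3, x_obs)
    out <- list(
      models = lapply(fits, function(f) f$coefficients),
      r_squared = vapply(fits, function(f) f$r_squared, numeric(1)),
      interaction = slopes$bXM,
      slopes = slopes$slopes,
      ros = list(boundaries = ros$boundaries, regions = ros$regions),
      poi = indices$poi, pa = indices$pa, crossover = indices$crossover
    )
    if (isTRUE(config$bootstrap$enabled)) {
      bt <- bootstrap_interaction(analysis,
                                  n_boot = config$bootstrap$n_boot %||% 1000,
                                  seed = config$seed + 100L)
      out$bootstrap <- list(estimate = bt$estimate, se = bt$se,
                            ci = c(bt$ci_low, bt$ci_high),
                            n_boot = bt$n_boot)
    }
    out
  })
  report$gxe <- gxe

  if (isTRUE(config$imputation$enabled)) {
    report$imputation <- stage("imputation", {
      m <- config$imputation$m %||% 30
      sets <- hot_deck_impute(world$test$adversity, m = m,
                              seed = config$seed + 200L)
      fits <- lapply(sets, function(comps) {
        sc <- adversity_score(comps, complete_case = TRUE)
        tab <- analysis
        tab$adversity <- as.numeric(sc$score)
        fit_gxe_models(tab)$model3
      })
      pooled <- pool_estimates(fits)
      list(m = m, pooled = pooled$pooled)
    })
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_refined_snp_set(refined, file.path(out_dir, "refined_snp_set.tsv"))
    utils::write.table(scan$scan, file.path(out_dir, "threshold_scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report_out <- c(report, list(timestamp = format(Sys.time(), tz = "UTC")))
    jsonlite::write_json(report_out, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  message("[done]")
  invisible(report)
}

# Assemble a cohort world from declared input files (the non-simulated
# path; formats as documented in the readers).
read_world <- function(inputs) {
  gwas <- read_gwas_summary(inputs$gwas)
  fmt <- function(p) if (grepl("\\.vcf$", p)) "vcf" else "dosage_tsv"
  disc <- load_genotypes(inputs$discovery_genotypes,
                         fmt(inputs$discovery_genotypes))
  test <- load_genotypes(inputs$test_genotypes, fmt(inputs$test_genotypes))
  phen <- utils::read.delim(inputs$phenotype, stringsAsFactors = FALSE)
  adv_tab <- utils::read.delim(inputs$adversity, stringsAsFactors = FALSE)
  out_tab <- utils::read.delim(inputs$outcome, stringsAsFactors = FALSE)
  # component kinds are declared in the config (inputs$adversity_kinds,
  # a named list); undeclared columns default to binary
  adversity <- lapply(setdiff(names(adv_tab), "sample_id"), function(nm) {
    kind <- inputs$adversity_kinds[[nm]] %||% "binary"
    adversity_component(nm, adv_tab[[nm]], kind)
  })
  list(
    gwas = gwas,
    discovery = list(geno = disc,
                     insulin = phen$insulin[match(disc$sample_ids,
                                                  phen$sample_id)],
                     sex = phen$sex[match(disc$sample_ids, phen$sample_id)]),
    test = list(geno = test, adversity = adversity,
                sex = out_tab$sex[match(test$sample_ids, out_tab$sample_id)],
                outcome = out_tab$outcome[match(test$sample_ids,
                                                out_tab$sample_id)])
  )
}

#' Command-line entry point
#'
#' Subcommands: `run` (full pipeline; flags `--config PATH`,
#' `--seed INT`, `--out DIR`) and `simulate` (write the synthetic
#' cohort files to `--out`). Intended to be called from
#' `inst/cli/rprsgxe.R`.
#'
#' @param args character vector of command-line arguments
#'   (`commandArgs(trailingOnly = TRUE)`).
#' @return Exit status (0 on success), invisibly.
#' @export
pipeline_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    message("usage: rprsgxe <run|simulate> [--config PATH] [--seed INT] [--out DIR]")
    return(invisible(1L))
  }
  sub <- args[1]
  opts <- optparse::parse_args(
    optparse::OptionParser(option_list = list(
      optparse::make_option("--config", type = "character", default = NULL),
      optparse::make_option("--seed", type = "integer", default = NULL),
      optparse::make_option("--out", type = "character", default = NULL)
    )), args = args[-1])
  config <- if (!is.null(opts$config)) read_pipeline_config(opts$config) else {
    default_pipeline_config()
  }
  if (!is.null(opts$seed)) config$seed <- opts$seed
  if (sub == "run") {
    run_pipeline(config, out_dir = opts$out)
  } else if (sub == "simulate") {
    if (is.null(opts$out)) stop("simulate requires --out DIR")
    dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
    cfg <- do.call(sim_config, c(config$simulate %||% list(),
                                 list(seed = config$seed)))
    world <- simulate_cohorts(cfg)
    write_genotypes_vcf(world$discovery$geno,
                        file.path(opts$out, "discovery.vcf"))
    write_genotypes_vcf(world$test$geno, file.path(opts$out, "test.vcf"))
    write_gwas_summary(world$gwas, file.path(opts$out, "gwas.tsv"))
    utils::write.table(
      data.frame(sample_id = world$discovery$geno$sample_ids,
                 insulin = world$discovery$insulin,
                 sex = world$discovery$sex),
      file.path(opts$out, "discovery_phenotypes.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(sample_id = world$test$geno$sample_ids,
                 outcome = world$test$outcome, sex = world$test$sex),
      file.path(opts$out, "test_outcome.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    message("simulate: wrote cohort files to ", opts$out)
  } else {
    stop("unknown subcommand '", sub, "'")
  }
  invisible(0L)
}
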