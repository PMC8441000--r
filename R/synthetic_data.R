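# Synthetic two-cohort generator: shared allele frequencies, block LD,
# a heritable "insulin" training phenotype, GWAS summary statistics,
# adversity components with missing-at-random gaps, and an outcome with
# a planted score-by-adversity interaction.

#' Simulation configuration
#'
#' Defaults describe the desk-scale world the test suite runs in: a
#' discovery cohort of 2,000 and a test cohort of 600 samples, 500 SNPs
#' in LD blocks of 10 with within-block latent correlation 0.4, 20
#' causal SNPs, training-phenotype heritability 0.3, a reference GWAS of
#' 100,000 samples, a seven-component adversity battery with
#' Table-5-like missingness, and a planted standardized interaction of
#' -0.33 on the outcome with residual SD 1 and no main effects.
#'
#' @param n_discovery,n_test cohort sample sizes.
#' @param n_snps,n_causal SNP counts (causal subset drawn at random).
#' @param beta_sd SD of causal effect sizes (phenotype units per allele).
#' @param beta_min minimum causal |effect|; draws are pushed away from
#'   zero so every causal SNP is detectable in principle.
#' @param maf_range allele-frequency interval, inside (0, 0.5].
#' @param ld_block_size,ld_rho SNPs per LD block and within-block latent
#'   correlation.
#' @param h2 heritability of the training (insulin) phenotype in [0, 1].
#' @param gwas_ref_n reference-GWAS sample size used to synthesize
#'   summary-statistic noise and p-values.
#' @param geno_missing_rate fraction of dosage cells set missing.
#' @param adversity_spec data frame describing adversity components
#'   (columns `name`, `kind`, `prevalence`, `missing_rate`); see
#'   [default_adversity_spec()].
#' @param gxe list with `intercept`, `bX`, `bM`, `bXM`, `noise_sd` and
#'   optional `cov_beta` for the outcome generator.
#' @param seed integer master seed; stage generators derive fixed
#'   offsets from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_discovery = 2000, n_test = 600, n_snps = 500,
                       n_causal = 20, beta_sd = 0.25, beta_min = 0.15,
                       maf_range = c(0.05, 0.5), ld_block_size = 10,
                       ld_rho = 0.4, h2 = 0.3, gwas_ref_n = 1e5,
                       geno_missing_rate = 0,
                       adversity_spec = default_adversity_spec(),
                       gxe = list(intercept = 5.5, bX = 0, bM = 0,
                                  bXM = -0.33, noise_sd = 1),
                       seed = 42) {
  stopifnot(n_discovery >= 1, n_test >= 1, n_snps >= 1,
            n_causal >= 1, n_causal <= n_snps,
            beta_sd > 0, beta_min >= 0,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            ld_block_size >= 1, ld_rho >= 0, ld_rho < 1,
            h2 >= 0, h2 <= 1, gwas_ref_n > 1,
            geno_missing_rate >= 0, geno_missing_rate < 1,
            nrow(adversity_spec) >= 1)
  for (k in c("intercept", "bX", "bM", "bXM", "noise_sd")) {
    if (is.null(gxe[[k]])) stop("gxe spec lacks '", k, "'")
  }
  structure(
    list(n_discovery = n_discovery, n_test = n_test, n_snps = n_snps,
         n_causal = n_causal, beta_sd = beta_sd, beta_min = beta_min,
         maf_range = maf_range, ld_block_size = ld_block_size,
         ld_rho = ld_rho, h2 = h2, gwas_ref_n = gwas_ref_n,
         geno_missing_rate = geno_missing_rate,
         adversity_spec = adversity_spec, gxe = gxe,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Default adversity-component battery
#'
#' Seven components loosely shaped like the published battery: three
#' binary exposures with realistic prevalences and four continuous
#' instrument summaries dichotomized at the 85th (high-risk tail) or
#' 15th (low tail, e.g. birth-size percentile) percentile. Missing
#' rates echo the published per-instrument missingness (0 to ~32%).
#'
#' @return Data frame with columns `name`, `kind`, `prevalence`,
#'   `missing_rate`.
#' @export
default_adversity_spec <- function() {
  data.frame(
    name = c("smoking_pregnancy", "low_income", "child_hospitalization",
             "maternal_depression", "maternal_anxiety",
             "family_dysfunction", "birthweight_percentile"),
    kind = c("binary", "binary", "binary",
             "continuous_high_tail", "continuous_high_tail",
             "continuous_high_tail", "continuous_low_tail"),
    prevalence = c(0.12, 0.11, 0.10, NA, NA, NA, NA),
    missing_rate = c(0.135, 0, 0, 0.145, 0.02, 0.32, 0),
    stringsAsFactors = FALSE
  )
}

# Shared per-SNP world (frequencies, map, alleles) derived from the
# master seed only, so both cohorts draw from identical frequencies.
snp_world <- function(cfg) {
  with_seed(cfg$seed, {
    n <- cfg$n_snps
    pairs <- list(c("A", "C"), c("A", "G"), c("T", "C"), c("T", "G"))
    pick <- sample(seq_along(pairs), n, replace = TRUE)
    swap <- sample(c(TRUE, FALSE), n, replace = TRUE)
    counted <- vapply(seq_len(n), function(i) {
      pairs[[pick[i]]][1 + swap[i]]
    }, character(1))
    other <- vapply(seq_len(n), function(i) {
      pairs[[pick[i]]][2 - swap[i]]
    }, character(1))
    list(
      meta = data.frame(
        snp_id = sprintf("snp%04d", seq_len(n)),
        chrom = "1",
        pos = seq_len(n) * 5000L,
        counted_allele = counted,
        other_allele = other,
        stringsAsFactors = FALSE
      ),
      freq = stats::runif(n, cfg$maf_range[1], cfg$maf_range[2]),
      causal_ids = sprintf("snp%04d", sort(sample.int(n, cfg$n_causal)))
    )
  })
}

#' Simulate genotypes for one cohort
#'
#' Allele frequencies, SNP map and the causal subset are drawn once from
#' the master seed and shared by both cohorts; genotype draws use a
#' cohort-specific offset. Each haplotype's alleles come from
#' thresholded latent Gaussians with exchangeable within-block
#' correlation `ld_rho`, so single-SNP genotype frequencies satisfy
#' Hardy-Weinberg while nearby SNPs are correlated.
#'
#' @param cfg a [sim_config].
#' @param cohort `"discovery"` or `"test"`.
#' @return A [genotype_matrix]; the generating frequencies and causal
#'   ids are attached as attributes `freq` and `causal_ids`.
#' @export
simulate_genotypes <- function(cfg, cohort = c("discovery", "test")) {
  cohort <- match.arg(cohort)
  world <- snp_world(cfg)
  n <- if (cohort == "discovery") cfg$n_discovery else cfg$n_test
  offset <- if (cohort == "discovery") 1L else 2L
  dos <- with_seed(cfg$seed + offset, {
    thr <- stats::qnorm(world$freq)
    out <- matrix(0, nrow = n, ncol = cfg$n_snps)
    blocks <- split(seq_len(cfg$n_snps),
                    ceiling(seq_len(cfg$n_snps) / cfg$ld_block_size))
    for (hap in 1:2) {
      for (idx in blocks) {
        shared <- stats::rnorm(n)
        z <- sqrt(cfg$ld_rho) * shared +
          sqrt(1 - cfg$ld_rho) * matrix(stats::rnorm(n * length(idx)), n)
        out[, idx] <- out[, idx] + (z < rep(thr[idx], each = n))
      }
    }
    if (cfg$geno_missing_rate > 0) {
      out[stats::runif(length(out)) < cfg$geno_missing_rate] <- NA
    }
    out
  })
  g <- genotype_matrix(dos, world$meta,
                       sprintf("%s%04d", substr(cohort, 1, 4), seq_len(n)))
  attr(g, "freq") <- world$freq
  attr(g, "causal_ids") <- world$causal_ids
  g
}

#' Synthesize GWAS summary statistics
#'
#' Causal SNPs receive true effects drawn from `Normal(0, beta_sd^2)`
#' pushed to at least `beta_min` in magnitude; null SNPs have true
#' effect zero. Reported effects add estimation noise at the standard
#' error implied by the allele frequency and `gwas_ref_n`, and p-values
#' come from the implied z statistics -- null p-values are uniform and
#' large effects yield very small p.
#'
#' @param snp_meta SNP metadata as in a [genotype_matrix]; needs a
#'   `freq` attribute or column (supplied by [simulate_genotypes()]).
#' @param causal_ids character vector of causal snp_ids.
#' @param cfg a [sim_config].
#' @param freq optional per-SNP allele frequencies (overrides metadata).
#' @return A [gwas_summary] with attribute `beta_true`.
#' @export
simulate_gwas <- function(snp_meta, causal_ids, cfg, freq = NULL) {
  freq <- freq %||% snp_meta$freq
  if (is.null(freq)) stop("allele frequencies required (freq)")
  if (!all(causal_ids %in% snp_meta$snp_id)) {
    stop("causal_ids must be a subset of snp_meta$snp_id")
  }
  with_seed(cfg$seed + 3L, {
    n <- nrow(snp_meta)
    beta_true <- numeric(n)
    causal <- snp_meta$snp_id %in% causal_ids
    raw <- stats::rnorm(sum(causal), 0, cfg$beta_sd)
    beta_true[causal] <- sign(raw) * pmax(abs(raw), cfg$beta_min)
    se <- 1 / sqrt(2 * freq * (1 - freq) * cfg$gwas_ref_n)
    beta_hat <- beta_true + stats::rnorm(n, 0, se)
    z <- beta_hat / se
    p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
    p[p == 0] <- .Machine$double.xmin
    g <- gwas_summary(data.frame(
      snp_id = snp_meta$snp_id, chrom = snp_meta$chrom, pos = snp_meta$pos,
      effect_allele = snp_meta$counted_allele,
      other_allele = snp_meta$other_allele,
      beta = beta_hat, p_value = p, stringsAsFactors = FALSE))
    attr(g, "beta_true") <- stats::setNames(beta_true, snp_meta$snp_id)
    g
  })
}

#' Simulate the heritable training ("insulin") phenotype
#'
#' Phenotype = genetic value (dosages weighted by the true effects) plus
#' Gaussian noise scaled so the genetic variance fraction equals `h2`.
#' With `h2 = 0` the phenotype is pure standard-normal noise.
#'
#' @param geno a [genotype_matrix].
#' @param gwas a [simulate_gwas()] result (carries `beta_true`).
#' @param causal_ids causal snp_ids present in `geno`.
#' @param cfg a [sim_config].
#' @param seed RNG seed; defaults to `cfg$seed + 4`.
#' @return Numeric phenotype vector, with attribute `genetic_value`.
#' @export
simulate_insulin <- function(geno, gwas, causal_ids, cfg,
                             seed = cfg$seed + 4L) {
  beta_true <- attr(gwas, "beta_true")
  if (is.null(beta_true)) stop("gwas lacks the beta_true attribute")
  if (!all(causal_ids %in% geno$snp_meta$snp_id)) {
    stop("causal SNPs missing from the genotype matrix")
  }
  d <- impute_dosage_means(
    geno$dosages[, match(causal_ids, geno$snp_meta$snp_id), drop = FALSE])
  gv <- as.numeric(d %*% beta_true[causal_ids])
  var_g <- stats::var(gv)
  with_seed(seed, {
    n <- length(gv)
    y <- if (cfg$h2 == 0) {
      stats::rnorm(n)
    } else {
      if (var_g == 0) stop("zero genetic variance with h2 > 0")
      noise_sd <- sqrt(var_g * (1 - cfg$h2) / cfg$h2)
      gv + stats::rnorm(n, 0, noise_sd)
    }
    attr(y, "genetic_value") <- gv
    y
  })
}

#' Simulate adversity components with missing-at-random gaps
#'
#' Binary components are Bernoulli draws at their configured
#' prevalences; continuous components are standard normal. Cells are
#' then masked missing-completely-at-random at each component's
#' configured rate.
#'
#' @param cfg a [sim_config] (uses `cfg$adversity_spec`).
#' @param n number of samples.
#' @param seed RNG seed; defaults to `cfg$seed + 5`.
#' @return List of [adversity_component] objects.
#' @export
simulate_adversity <- function(cfg, n, seed = cfg$seed + 5L) {
  spec <- cfg$adversity_spec
  if (any(spec$missing_rate >= 1)) stop("missing_rate must be < 1")
  with_seed(seed, {
    lapply(seq_len(nrow(spec)), function(i) {
      v <- if (spec$kind[i] == "binary") {
        stats::rbinom(n, 1, spec$prevalence[i])
      } else {
        stats::rnorm(n)
      }
      # the mask uniforms are always drawn so that configs differing
      # only in missing rates share identical underlying values
      u <- stats::runif(n)
      if (spec$missing_rate[i] > 0) v[u < spec$missing_rate[i]] <- NA
      adversity_component(spec$name[i], v, spec$kind[i])
    })
  })
}

#' Simulate the behavioral outcome with a planted interaction
#'
#' Outcome = intercept + bX x + bM m + bXM x m + covariate effects +
#' Normal(0, noise_sd^2). Optionally discretized onto the 2-9 per-trial
#' task scale (rounded and clamped).
#'
#' @param x adversity scores.
#' @param m true standardized genetic score (moderator).
#' @param covariates optional numeric matrix; effects come from
#'   `cfg$gxe$cov_beta` (recycled; default 0.1 per column).
#' @param cfg a [sim_config].
#' @param seed RNG seed; defaults to `cfg$seed + 6`.
#' @param discretize clamp/round onto the 2-9 scale (default FALSE).
#' @return Numeric outcome vector.
#' @export
simulate_outcome <- function(x, m, covariates = NULL, cfg,
                             seed = cfg$seed + 6L, discretize = FALSE) {
  if (length(x) != length(m)) stop("x and m lengths differ")
  gxe <- cfg$gxe
  lp <- gxe$intercept + gxe$bX * x + gxe$bM * m + gxe$bXM * x * m
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    cb <- rep(gxe$cov_beta %||% 0.1, length.out = ncol(covariates))
    lp <- lp + as.numeric(covariates %*% cb)
  }
  with_seed(seed, {
    y <- lp + stats::rnorm(length(x), 0, gxe$noise_sd)
    if (discretize) y <- pmin(pmax(round(y), 2), 9)
    y
  })
}

#' Generate the full linked two-cohort world
#'
#' Convenience wrapper running every stage generator with consistent
#' seeds: shared SNP world, discovery and test genotypes, synthetic
#' GWAS, discovery insulin phenotype, test-cohort adversity components,
#' sex covariates, and the test outcome driven by the true standardized
#' genetic score.
#'
#' @param cfg a [sim_config].
#' @return List with elements `gwas`, `causal_ids`, `discovery`
#'   (`geno`, `insulin`, `sex`) and `test` (`geno`, `adversity`,
#'   `genetic_score`, `sex`, `outcome`).
#' @export
simulate_cohorts <- function(cfg) {
  disc <- simulate_genotypes(cfg, "discovery")
  test <- simulate_genotypes(cfg, "test")
  causal_ids <- attr(disc, "causal_ids")
  gwas <- simulate_gwas(disc$snp_meta, causal_ids, cfg,
                        freq = attr(disc, "freq"))
  insulin <- simulate_insulin(disc, gwas, causal_ids, cfg)
  adversity <- simulate_adversity(cfg, cfg$n_test)
  adv_score <- adversity_score(adversity, complete_case = TRUE)
  # the outcome is driven by the complete battery (same draws, no
  # masking), so missing-adversity samples still carry the planted
  # signal and the imputation sub-analysis has something to recover
  cfg_full <- cfg
  cfg_full$adversity_spec$missing_rate[] <- 0
  adversity_full <- simulate_adversity(cfg_full, cfg$n_test)
  score_full <- adversity_score(adversity_full, complete_case = TRUE)

  gv_test <- simulate_insulin(test, gwas, causal_ids, cfg,
                              seed = cfg$seed + 7L)
  gv <- attr(gv_test, "genetic_value")
  m <- (gv - mean(gv)) / stats::sd(gv)

  sex_disc <- with_seed(cfg$seed + 8L,
                        stats::rbinom(cfg$n_discovery, 1, 0.5))
  sex_test <- with_seed(cfg$seed + 9L, stats::rbinom(cfg$n_test, 1, 0.5))
  outcome <- simulate_outcome(score_full$score, m,
                              covariates = cbind(sex = sex_test),
                              cfg = cfg)

  list(
    gwas = gwas, causal_ids = causal_ids,
    discovery = list(geno = disc, insulin = insulin, sex = sex_disc),
    test = list(geno = test, adversity = adversity,
                adversity_score = adv_score,
                genetic_score = m, sex = sex_test, outcome = outcome)
  )
}
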