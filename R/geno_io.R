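# Genotype and GWAS-summary input, allele alignment, QC, LD and PCA.

#' Construct a GWAS summary-statistics table
#'
#' A `gwas_summary` is a data frame with one row per SNP and columns
#' `snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `beta`,
#' `p_value`. The effect size `beta` is expressed per copy of the effect
#' allele, in phenotype units; `p_value` is the association p-value from
#' the source GWAS and must lie in (0, 1].
#'
#' @param df data frame carrying the seven required columns.
#' @return An object of class `gwas_summary`.
#' @export
gwas_summary <- function(df) {
  required <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                "beta", "p_value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("missing GWAS summary column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[required]
  df$snp_id <- as.character(df$snp_id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  df$beta <- as.numeric(df$beta)
  df$p_value <- as.numeric(df$p_value)
  validate_gwas_rows(df)
  rownames(df) <- NULL
  class(df) <- c("gwas_summary", "data.frame")
  df
}

# Row-level invariant checks; `lines` maps rows to source-file lines so
# parse errors can name the offending line.
validate_gwas_rows <- function(df, lines = NULL) {
  where <- function(i) {
    if (is.null(lines)) paste0("row ", i) else paste0("line ", lines[i])
  }
  bad <- which(is.na(df$p_value) | df$p_value <= 0 | df$p_value > 1)
  if (length(bad) > 0) {
    stop("p_value outside (0, 1] at ", where(bad[1]),
         " (snp ", df$snp_id[bad[1]], ")")
  }
  bad <- which(!is.finite(df$beta))
  if (length(bad) > 0) {
    stop("non-finite beta at ", where(bad[1]), " (snp ", df$snp_id[bad[1]], ")")
  }
  ok_allele <- c("A", "C", "G", "T")
  bad <- which(!(df$effect_allele %in% ok_allele) |
                 !(df$other_allele %in% ok_allele))
  if (length(bad) > 0) {
    stop("allele not one of A/C/G/T at ", where(bad[1]),
         " (snp ", df$snp_id[bad[1]], ")")
  }
  bad <- which(df$effect_allele == df$other_allele)
  if (length(bad) > 0) {
    stop("effect_allele equals other_allele at ", where(bad[1]),
         " (snp ", df$snp_id[bad[1]], ")")
  }
  dup <- which(duplicated(df$snp_id))
  if (length(dup) > 0) {
    stop("duplicate snp_id '", df$snp_id[dup[1]], "' at ", where(dup[1]))
  }
  invisible(df)
}

#' Read GWAS summary statistics from a tab-separated file
#'
#' The file must have a header naming the columns `snp_id`, `chrom`,
#' `pos`, `effect_allele`, `other_allele`, `beta`, `p_value` (order
#' free). Malformed rows raise an error naming the offending line.
#'
#' @param path path to a TSV file.
#' @return A [gwas_summary] with one validated record per input row.
#' @export
read_gwas_summary <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "",
                          colClasses = "character")
  required <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                "beta", "p_value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("header of ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[required]
  n <- nrow(df)
  lines <- seq_len(n) + 1L  # header occupies line 1
  suppressWarnings({
    df$pos <- as.integer(df$pos)
    df$beta <- as.numeric(df$beta)
    df$p_value <- as.numeric(df$p_value)
  })
  bad <- which(is.na(df$pos))
  if (length(bad) > 0) stop("malformed pos at line ", lines[bad[1]])
  df$effect_allele <- toupper(df$effect_allele)
  df$other_allele <- toupper(df$other_allele)
  validate_gwas_rows(df, lines = lines)
  rownames(df) <- NULL
  class(df) <- c("gwas_summary", "data.frame")
  df
}

#' Load the packaged 57-SNP refined-score fixture
#'
#' Returns the 57 rsIDs and their source-GWAS p-values that survive the
#' fasting-insulin score refinement, as a [gwas_summary]. The rsIDs and
#' p-values are the published values; the remaining columns (chromosome,
#' position, alleles, effect sizes) are synthetic placeholders generated
#' for testing, as the source GWAS weights are not redistributable --
#' see `inst/extdata/README.md`.
#'
#' @return A [gwas_summary] with 57 records.
#' @export
rprs_table1 <- function() {
  path <- system.file("extdata", "table1_rprs57_synthetic_meta.tsv",
                      package = "rprsgxe", mustWork = TRUE)
  read_gwas_summary(path)
}

#' Construct a genotype dosage matrix
#'
#' A `genotype_matrix` couples an `n_samples x n_snps` dosage matrix
#' (expected counts of the counted allele, in `[0, 2]`, `NA` for missing)
#' with per-SNP metadata (`snp_id`, `chrom`, `pos`, `counted_allele`,
#' `other_allele`) and unique sample identifiers.
#'
#' @param dosages numeric matrix, samples in rows, SNPs in columns.
#' @param snp_meta data frame with one row per SNP column.
#' @param sample_ids character vector of unique sample identifiers.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, snp_meta, sample_ids) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  snp_meta <- as.data.frame(snp_meta, stringsAsFactors = FALSE)
  required <- c("snp_id", "chrom", "pos", "counted_allele", "other_allele")
  missing_cols <- setdiff(required, names(snp_meta))
  if (length(missing_cols) > 0) {
    stop("snp_meta lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(dosages)) {
    stop("sample_ids length does not match dosage rows")
  }
  if (nrow(snp_meta) != ncol(dosages)) {
    stop("snp_meta rows do not match dosage columns")
  }
  if (anyDuplicated(sample_ids)) stop("sample_ids are not unique")
  if (anyDuplicated(snp_meta$snp_id)) stop("snp_meta snp_id are not unique")
  rng <- range(dosages, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2)) {
    stop("dosage outside [0, 2]: range ", rng[1], "..", rng[2])
  }
  dimnames(dosages) <- list(sample_ids, snp_meta$snp_id)
  rownames(snp_meta) <- NULL
  structure(
    list(sample_ids = sample_ids, snp_meta = snp_meta, dosages = dosages),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$sample_ids), "samples x",
      nrow(x$snp_meta), "SNPs;",
      sum(is.na(x$dosages)), "missing dosage cells\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

# Subset a genotype matrix to SNP ids (keeping their order in `ids`).
subset_snps <- function(geno, ids) {
  idx <- match(ids, geno$snp_meta$snp_id)
  if (anyNA(idx)) stop("unknown snp_id: ", ids[which(is.na(idx))[1]])
  genotype_matrix(geno$dosages[, idx, drop = FALSE],
                  geno$snp_meta[idx, , drop = FALSE],
                  geno$sample_ids)
}

#' Load genotypes from VCF or a dosage TSV
#'
#' For VCF input (parsed with \pkg{VariantAnnotation}), hard calls in the
#' `GT` field are converted to counts of the ALT allele (`0/0` -> 0,
#' `0/1` -> 1, `1/1` -> 2, `./.` -> missing); when a `DS` (dosage) format
#' field is present it takes precedence. Only biallelic SNVs are kept.
#' The counted allele is ALT, the other allele REF.
#'
#' For dosage TSV input, the header is `sample_id` followed by SNP ids
#' and each subsequent row is one sample; cells outside `[0, 2]` are an
#' error. SNP metadata (chromosome, position, alleles) may be supplied
#' via `snp_meta`; otherwise it is `NA` and the matrix is treated as
#' already aligned to the effect allele.
#'
#' @param path input file path.
#' @param format `"vcf"` or `"dosage_tsv"`.
#' @param snp_meta optional SNP metadata for `dosage_tsv` input.
#' @return A [genotype_matrix].
#' @export
load_genotypes <- function(path, format = c("vcf", "dosage_tsv"),
                           snp_meta = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") load_genotypes_vcf(path) else {
    load_genotypes_dosage_tsv(path, snp_meta)
  }
}

load_genotypes_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("VCF input requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  n_alt <- lengths(altl)
  alt <- rep(NA_character_, length(ref))
  alt[n_alt == 1L] <- as.character(unlist(altl[n_alt == 1L]))
  keep <- n_alt == 1L & ref %in% c("A", "C", "G", "T") &
    alt %in% c("A", "C", "G", "T")
  if (!all(keep)) {
    message("load_genotypes: dropping ", sum(!keep),
            " non-biallelic/non-SNV record(s)")
  }
  vcf <- vcf[keep, ]
  geno_fields <- VariantAnnotation::geno(vcf)
  if ("DS" %in% names(geno_fields)) {
    dos <- geno_fields$DS
    storage.mode(dos) <- "double"
  } else if ("GT" %in% names(geno_fields)) {
    gt <- geno_fields$GT
    dos <- gt_to_dosage(gt)
  } else {
    stop("VCF has neither DS nor GT genotype field")
  }
  rng <- range(dos, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2)) {
    stop("VCF dosage outside [0, 2]")
  }
  gr <- SummarizedExperiment::rowRanges(vcf)
  ids <- names(gr)
  rr <- as.data.frame(gr)
  meta <- data.frame(
    snp_id = ids,
    chrom = as.character(rr$seqnames),
    pos = as.integer(rr$start),
    counted_allele = alt[keep],
    other_allele = ref[keep],
    stringsAsFactors = FALSE
  )
  genotype_matrix(t(dos), meta, colnames(dos))
}

# "0/0"->0, "0/1"/"1|0"->1, "1/1"->2, "./." or "."->NA
gt_to_dosage <- function(gt) {
  map <- c("0/0" = 0, "0|0" = 0, "0/1" = 1, "1/0" = 1, "0|1" = 1,
           "1|0" = 1, "1/1" = 2, "1|1" = 2, "./." = NA, ".|." = NA,
           "." = NA)
  out <- map[gt]
  unknown <- is.na(out) & !(gt %in% names(map))
  if (any(unknown)) stop("unsupported GT code: ", gt[which(unknown)[1]])
  matrix(unname(out), nrow = nrow(gt), dimnames = dimnames(gt))
}

load_genotypes_dosage_tsv <- function(path, snp_meta = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "sample_id") {
    stop("dosage TSV must start with a sample_id column")
  }
  sample_ids <- as.character(df$sample_id)
  dos <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(dos) <- "double"
  bad <- which(!is.na(dos) & (dos < 0 | dos > 2), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("dosage outside [0, 2] at sample ", sample_ids[bad[1, 1]],
         ", snp ", colnames(dos)[bad[1, 2]])
  }
  if (is.null(snp_meta)) {
    snp_meta <- data.frame(
      snp_id = colnames(dos),
      chrom = NA_character_, pos = NA_integer_,
      counted_allele = NA_character_, other_allele = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  genotype_matrix(dos, snp_meta, sample_ids)
}

#' Align genotype dosages to the GWAS effect allele
#'
#' Restricts to SNPs present in both inputs and re-expresses each dosage
#' as the count of the GWAS effect allele: matrices counting the other
#' allele are flipped (`d -> 2 - d`). Strand-ambiguous SNPs (A/T or C/G
#' allele pairs) and SNPs whose allele pairs cannot be reconciled are
#' dropped with a message. SNPs with missing allele metadata are assumed
#' already aligned.
#'
#' @param geno a [genotype_matrix].
#' @param gwas a [gwas_summary].
#' @return A [genotype_matrix] whose counted allele equals the GWAS
#'   effect allele for every retained SNP.
#' @export
align_alleles <- function(geno, gwas) {
  meta <- geno$snp_meta
  idx <- match(meta$snp_id, gwas$snp_id)
  overlap <- which(!is.na(idx))
  if (length(overlap) == 0) stop("no overlapping SNPs between genotypes and GWAS")
  meta <- meta[overlap, , drop = FALSE]
  g <- gwas[idx[overlap], , drop = FALSE]
  dos <- geno$dosages[, overlap, drop = FALSE]

  ambiguous <- paste0(pmin(g$effect_allele, g$other_allele),
                      pmax(g$effect_allele, g$other_allele)) %in% c("AT", "CG")
  no_meta <- is.na(meta$counted_allele)
  same <- !no_meta & meta$counted_allele == g$effect_allele &
    meta$other_allele == g$other_allele
  flipped <- !no_meta & meta$counted_allele == g$other_allele &
    meta$other_allele == g$effect_allele
  keep <- !ambiguous & (no_meta | same | flipped)
  dropped <- meta$snp_id[!keep]
  if (length(dropped) > 0) {
    reason <- ifelse(ambiguous[!keep], "strand-ambiguous", "irreconcilable alleles")
    message("align_alleles: dropped ", length(dropped), " SNP(s): ",
            paste(paste0(dropped, " (", reason, ")"), collapse = ", "))
  }
  if (!any(keep)) stop("no SNPs remain after allele alignment")

  dos <- dos[, keep, drop = FALSE]
  flip <- flipped[keep]
  if (any(flip)) dos[, flip] <- 2 - dos[, flip]
  meta <- meta[keep, , drop = FALSE]
  meta$counted_allele <- g$effect_allele[keep]
  meta$other_allele <- g$other_allele[keep]
  genotype_matrix(dos, meta, geno$sample_ids)
}

#' Quality-control thresholds for SNP filtering
#'
#' Presets mirror the two cohorts' published filters: `"mavan"` removes
#' SNPs with call rate < 95%, MAF < 5% or HWE p < 1e-30; `"alspac"`
#' uses MAF < 1% and HWE p < 5e-7.
#'
#' @param call_rate_min minimum per-SNP call rate (fraction in `[0,1]`).
#' @param maf_min minimum minor-allele frequency.
#' @param hwe_p_min minimum Hardy-Weinberg equilibrium p-value.
#' @param preset optional preset name, `"mavan"` or `"alspac"`.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(call_rate_min = 0.95, maf_min = 0.05,
                          hwe_p_min = 1e-30, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("mavan", "alspac"))
    if (preset == "mavan") {
      call_rate_min <- 0.95; maf_min <- 0.05; hwe_p_min <- 1e-30
    } else {
      call_rate_min <- 0.95; maf_min <- 0.01; hwe_p_min <- 5e-7
    }
  }
  vals <- c(call_rate_min, maf_min, hwe_p_min)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1)) {
    stop("qc thresholds must lie in [0, 1]")
  }
  structure(list(call_rate_min = call_rate_min, maf_min = maf_min,
                 hwe_p_min = hwe_p_min),
            class = "qc_thresholds")
}

#' SNP-level quality control
#'
#' Removes SNPs failing any of three criteria: call rate below
#' `thr$call_rate_min`, minor-allele frequency below `thr$maf_min`
#' (computed from mean dosage, folded to the minor allele), or
#' Hardy-Weinberg equilibrium test p-value below `thr$hwe_p_min`
#' (chi-square goodness of fit on hard calls, see [hwe_test]). Removal
#' counts per criterion are reported via `message()`.
#'
#' @param geno a [genotype_matrix].
#' @param thr a [qc_thresholds] object.
#' @return The filtered [genotype_matrix].
#' @export
qc_filter <- function(geno, thr = qc_thresholds()) {
  stopifnot(inherits(thr, "qc_thresholds"))
  d <- geno$dosages
  n <- nrow(d)
  call_rate <- 1 - colSums(is.na(d)) / n
  af <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  maf[!is.finite(maf)] <- 0
  hwe_p <- apply(d, 2, function(col) {
    hc <- round(col[!is.na(col)])
    counts <- tabulate(hc + 1L, nbins = 3L)
    if (sum(counts) == 0) return(0)
    hwe_test(counts[1], counts[2], counts[3])
  })
  fail_cr <- call_rate < thr$call_rate_min
  fail_maf <- maf < thr$maf_min
  fail_hwe <- hwe_p < thr$hwe_p_min
  keep <- !(fail_cr | fail_maf | fail_hwe)
  message(sprintf(
    "qc_filter: removed %d/%d SNPs (call rate %d, MAF %d, HWE %d)",
    sum(!keep), length(keep), sum(fail_cr), sum(fail_maf), sum(fail_hwe)))
  if (!any(keep)) stop("qc_filter removed every SNP")
  genotype_matrix(d[, keep, drop = FALSE],
                  geno$snp_meta[keep, , drop = FALSE],
                  geno$sample_ids)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom chi-square goodness of fit of observed genotype
#' counts against the expectations implied by the sample allele
#' frequency. Expected-zero cells (fixed alleles) contribute nothing.
#'
#' @param n_aa,n_ab,n_bb genotype counts (reference homozygote,
#'   heterozygote, alternate homozygote).
#' @return The p-value.
#' @export
hwe_test <- function(n_aa, n_ab, n_bb) {
  counts <- c(n_aa, n_ab, n_bb)
  if (any(is.na(counts)) || any(counts < 0)) stop("genotype counts must be non-negative")
  n <- sum(counts)
  if (n < 1) stop("hwe_test: zero genotype total")
  p <- (2 * n_aa + n_ab) / (2 * n)
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  nz <- expected > 0
  stat <- sum((counts[nz] - expected[nz])^2 / expected[nz])
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Squared Pearson correlation between two dosage vectors
#'
#' Computed on pairwise-complete samples. A vector that is constant after
#' missing-data filtering makes r-squared undefined; this is signalled as
#' an error of class `rprsgxe_constant_error`.
#'
#' @param d_a,d_b numeric dosage vectors of equal length.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(d_a, d_b) {
  if (length(d_a) != length(d_b)) stop("dosage vectors differ in length")
  ok <- !is.na(d_a) & !is.na(d_b)
  if (sum(ok) < 2) stop("fewer than 2 pairwise-complete samples")
  a <- d_a[ok]; b <- d_b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    stop_named("rprsgxe_constant_error",
               "ld_r2 undefined: constant dosage vector")
  }
  unname(stats::cor(a, b)^2)
}

#' LD pruning configuration
#'
#' @param window_kb window size in kilobases (positions are 1-based and
#'   windows inclusive on both ends).
#' @param step_snps number of SNPs by which the window start advances.
#' @param r2_max maximum tolerated squared correlation between retained
#'   SNPs within a window.
#' @return An object of class `prune_config`.
#' @export
prune_config <- function(window_kb = 50, step_snps = 5, r2_max = 0.2) {
  if (!is.finite(window_kb) || window_kb <= 0) stop("window_kb must be > 0")
  if (!is.finite(step_snps) || step_snps < 1) stop("step_snps must be >= 1")
  if (!is.finite(r2_max) || r2_max < 0 || r2_max > 1) {
    stop("r2_max must lie in [0, 1]")
  }
  structure(list(window_kb = window_kb, step_snps = as.integer(step_snps),
                 r2_max = r2_max),
            class = "prune_config")
}

# Sort order used everywhere positions matter: chrom, pos, then snp_id
# lexicographically so equal positions break ties deterministically.
snp_sort_order <- function(meta) order(meta$chrom, meta$pos, meta$snp_id)

#' Sliding-window LD pruning
#'
#' SNPs are sorted by (chromosome, position, id). Windows start at every
#' `step_snps`-th SNP and span all downstream SNPs within `window_kb`
#' kilobases on the same chromosome. Within each window, every pair of
#' still-retained SNPs with pairwise r-squared above `cfg$r2_max` loses
#' its later member. The result is deterministic and independent of
#' sample order; undefined r-squared (constant SNPs) never triggers
#' removal.
#'
#' @param geno a [genotype_matrix].
#' @param cfg a [prune_config].
#' @return Character vector of retained snp_ids in genome order.
#' @export
prune_ld <- function(geno, cfg = prune_config()) {
  stopifnot(inherits(cfg, "prune_config"))
  ord <- snp_sort_order(geno$snp_meta)
  meta <- geno$snp_meta[ord, , drop = FALSE]
  dos <- geno$dosages[, ord, drop = FALSE]
  n <- nrow(meta)
  keep <- rep(TRUE, n)
  win_bp <- cfg$window_kb * 1000
  starts <- seq(1L, n, by = cfg$step_snps)
  for (s in starts) {
    members <- which(
      seq_len(n) >= s & keep &
        meta$chrom == meta$chrom[s] &
        meta$pos - meta$pos[s] <= win_bp & meta$pos >= meta$pos[s]
    )
    if (length(members) < 2) next
    for (ii in seq_along(members)) {
      i <- members[ii]
      if (!keep[i]) next
      for (jj in seq_along(members)[-seq_len(ii)]) {
        j <- members[jj]
        if (!keep[j]) next
        r2 <- tryCatch(ld_r2(dos[, i], dos[, j]),
                       rprsgxe_constant_error = function(e) 0)
        if (r2 > cfg$r2_max) keep[j] <- FALSE
      }
    }
  }
  meta$snp_id[keep]
}

#' Principal components of population structure
#'
#' Computes sample-level principal components from the column-standardized
#' dosage matrix (missing dosages mean-imputed per SNP, constant SNPs
#' excluded), optionally after LD pruning. Components are ordered by
#' decreasing explained variance and mutually orthogonal.
#'
#' @param geno a [genotype_matrix].
#' @param k number of components to return.
#' @param cfg optional [prune_config]; when supplied, PCA runs on the
#'   pruned SNP set.
#' @return `n_samples x k` matrix with columns `PC1..PCk`.
#' @export
compute_pcs <- function(geno, k = 10, cfg = NULL) {
  if (!is.null(cfg)) geno <- subset_snps(geno, prune_ld(geno, cfg))
  d <- impute_dosage_means(geno$dosages)
  sds <- apply(d, 2, stats::sd)
  nonconst <- sds > 0
  if (sum(nonconst) < k) {
    stop("compute_pcs: only ", sum(nonconst),
         " non-constant SNPs available for k = ", k)
  }
  d <- d[, nonconst, drop = FALSE]
  pc <- stats::prcomp(d, center = TRUE, scale. = TRUE)
  if (ncol(pc$x) < k) stop("compute_pcs: k exceeds available rank")
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rownames(scores) <- geno$sample_ids
  scores
}
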