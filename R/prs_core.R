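# Polygenic score construction: clumping, threshold scan, refinement,
# and transfer of the refined score to a test cohort.

#' Greedy LD clumping of a GWAS against a reference panel
#'
#' SNPs are visited in order of ascending GWAS p-value (ties broken by
#' snp_id). Each visited SNP not already removed becomes an index SNP
#' and removes every not-yet-retained SNP on the same chromosome within
#' `window_kb` kilobases whose squared dosage correlation with it (in
#' the reference panel, pairwise-complete samples) exceeds `r2_max`.
#'
#' @param gwas a [gwas_summary], allele-aligned to `ref`.
#' @param ref a [genotype_matrix] providing reference LD.
#' @param r2_max clumping r-squared threshold.
#' @param window_kb clumping window in kilobases.
#' @return An object of class `clump_result` with elements `retained`
#'   (snp_ids ordered by ascending p) and `removed_by` (named character
#'   vector mapping each removed SNP to its index SNP).
#' @export
ld_clump <- function(gwas, ref, r2_max = 0.2, window_kb = 250) {
  common <- intersect(gwas$snp_id, ref$snp_meta$snp_id)
  if (length(common) == 0) stop("no overlap between GWAS and reference panel")
  g <- gwas[match(common, gwas$snp_id), , drop = FALSE]
  ridx <- match(common, ref$snp_meta$snp_id)
  dos <- ref$dosages[, ridx, drop = FALSE]
  pos <- ref$snp_meta$pos[ridx]
  chrom <- ref$snp_meta$chrom[ridx]
  # fall back to GWAS coordinates when the panel has none (dosage TSVs)
  pos[is.na(pos)] <- g$pos[is.na(pos)]
  chrom[is.na(chrom)] <- g$chrom[is.na(chrom)]

  ord <- order(g$p_value, g$snp_id)
  win_bp <- window_kb * 1000
  n <- length(common)
  state <- rep(0L, n)  # 0 undecided, 1 retained, -1 removed
  removed_by <- character(0)
  retained <- character(0)
  for (i in ord) {
    if (state[i] != 0L) next
    state[i] <- 1L
    retained <- c(retained, common[i])
    cand <- which(state == 0L & chrom == chrom[i] &
                    abs(pos - pos[i]) <= win_bp)
    if (length(cand) == 0) next
    x <- dos[, i]
    r2 <- vapply(cand, function(j) {
      r <- suppressWarnings(stats::cor(x, dos[, j],
                                       use = "pairwise.complete.obs"))
      if (is.na(r)) 0 else r^2
    }, numeric(1))
    hit <- cand[r2 > r2_max]
    if (length(hit) > 0) {
      state[hit] <- -1L
      removed_by[common[hit]] <- common[i]
    }
  }
  structure(list(retained = retained, removed_by = removed_by),
            class = "clump_result")
}

#' @export
print.clump_result <- function(x, ...) {
  cat("clump_result:", length(x$retained), "index SNPs retained,",
      length(x$removed_by), "removed\n")
  invisible(x)
}

#' Compute a polygenic risk score at a GWAS p-value threshold
#'
#' The raw score of sample *i* is `sum_j dosage_ij * beta_j` over SNPs
#' whose GWAS p-value is at or below `threshold` and that are present in
#' the genotype matrix. Missing dosages are mean-imputed per SNP. The
#' standardized score has mean 0 and SD 1 in the scored cohort.
#'
#' @param geno an allele-aligned [genotype_matrix].
#' @param gwas a [gwas_summary].
#' @param threshold GWAS p-value cutoff (inclusive).
#' @return An object of class `prs_profile` with per-sample `raw` and
#'   `standardized` scores, `n_snps_used` and the contributing `snp_ids`.
#' @export
compute_prs <- function(geno, gwas, threshold) {
  sel <- gwas$snp_id[gwas$p_value <= threshold]
  sel <- sel[sel %in% geno$snp_meta$snp_id]
  if (length(sel) == 0) {
    stop("no SNP passes the p-value threshold ", threshold)
  }
  weights <- gwas$beta[match(sel, gwas$snp_id)]
  prs_profile_from_weights(geno, sel, weights, threshold = threshold)
}

# Shared scorer for PRS and rPRS.
prs_profile_from_weights <- function(geno, snp_ids, weights,
                                     threshold = NA_real_) {
  d <- impute_dosage_means(
    geno$dosages[, match(snp_ids, geno$snp_meta$snp_id), drop = FALSE])
  raw <- as.numeric(d %*% weights)
  sdv <- stats::sd(raw)
  if (is.na(sdv) || sdv == 0) {
    stop("score is constant across samples; cannot standardize")
  }
  structure(
    list(sample_id = geno$sample_ids, raw = raw,
         standardized = (raw - mean(raw)) / sdv,
         n_snps_used = length(snp_ids), snp_ids = snp_ids,
         threshold = threshold),
    class = "prs_profile"
  )
}

#' @export
print.prs_profile <- function(x, ...) {
  cat("prs_profile:", length(x$sample_id), "samples scored over",
      x$n_snps_used, "SNPs\n")
  invisible(x)
}

#' Scan PRS predictive performance over a p-value threshold grid
#'
#' For every cutoff in `grid`, the PRS is computed and the training
#' phenotype regressed on the covariates plus the PRS. The scan records
#' the SNP count, the incremental R-squared of the PRS term (R-squared
#' of the full model minus the covariates-only model) and the p-value of
#' the PRS coefficient. The selected `best_threshold` minimizes that
#' p-value; ties prefer larger incremental R-squared, then the smaller
#' cutoff. Cutoffs admitting zero SNPs are recorded with `n_snps = 0`
#' and `NA` statistics.
#'
#' @param geno clumped, allele-aligned training [genotype_matrix].
#' @param gwas a [gwas_summary] (typically restricted to clumped SNPs).
#' @param phenotype numeric training phenotype, one value per sample.
#' @param covariates optional numeric covariate matrix (no intercept).
#' @param grid ascending vector of cutoffs; the default is the 100-point
#'   grid 0.01, 0.02, ..., 1.00.
#' @return An object of class `threshold_scan`: a data frame with
#'   columns `threshold`, `n_snps`, `r2_incremental`, `p_prs`, plus the
#'   attribute-like element `best_threshold`.
#' @export
threshold_scan <- function(geno, gwas, phenotype, covariates = NULL,
                           grid = seq(0.01, 1, by = 0.01)) {
  if (length(grid) == 0) stop("threshold grid is empty")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  if (length(phenotype) != length(geno$sample_ids)) {
    stop("phenotype length does not match sample count")
  }
  present <- gwas$snp_id %in% geno$snp_meta$snp_id
  g <- gwas[present, , drop = FALSE]
  ord <- order(g$p_value, g$snp_id)
  g <- g[ord, , drop = FALSE]
  d <- impute_dosage_means(
    geno$dosages[, match(g$snp_id, geno$snp_meta$snp_id), drop = FALSE])
  wd <- sweep(d, 2, g$beta, `*`)

  n_snps <- vapply(grid, function(t) sum(g$p_value <= t), integer(1))
  # scores are cumulative sums over SNPs ordered by p; evaluate each
  # distinct non-zero SNP count once
  counts <- sort(unique(n_snps[n_snps > 0]))
  cum <- matrix(0, nrow = nrow(wd), ncol = length(counts))
  if (length(counts) > 0) {
    acc <- rep(0, nrow(wd))
    k0 <- 0L
    for (ci in seq_along(counts)) {
      k1 <- counts[ci]
      acc <- acc + rowSums(wd[, seq.int(k0 + 1L, k1), drop = FALSE])
      cum[, ci] <- acc
      k0 <- k1
    }
    colnames(cum) <- as.character(counts)
    assoc <- marginal_assoc(phenotype, cum, covariates)
  }
  res <- data.frame(threshold = grid, n_snps = n_snps,
                    r2_incremental = NA_real_, p_prs = NA_real_)
  if (length(counts) > 0) {
    m <- match(as.character(n_snps), rownames(assoc))
    res$r2_incremental <- assoc$r2_incremental[m]
    res$p_prs <- assoc$p[m]
  }
  usable <- which(!is.na(res$p_prs))
  if (length(usable) == 0) stop("no grid cutoff admits any SNP")
  best <- usable[order(res$p_prs[usable], -res$r2_incremental[usable],
                       res$threshold[usable])][1]
  structure(list(scan = res, best_threshold = res$threshold[best]),
            class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  b <- x$scan[x$scan$threshold == x$best_threshold, ]
  cat(sprintf(
    "threshold_scan over %d cutoffs; best p_t = %.3g (%d SNPs, incremental R2 = %.4f, p = %.3g)\n",
    nrow(x$scan), x$best_threshold, b$n_snps, b$r2_incremental, b$p_prs))
  invisible(x)
}

#' Refine a threshold SNP set by per-SNP association
#'
#' Every SNP with GWAS p-value at or below `source_threshold` is tested
#' individually: the training phenotype is regressed on the covariates
#' plus that SNP's dosage (mean-imputed), and SNPs whose dosage
#' coefficient achieves `p < alpha_refine` are retained. Weights remain
#' the original GWAS effect sizes. No multiple-testing correction is
#' applied, matching the two-stage refinement procedure this package
#' implements.
#'
#' @param geno training [genotype_matrix], allele-aligned.
#' @param gwas a [gwas_summary].
#' @param phenotype numeric training phenotype.
#' @param covariates optional covariate matrix.
#' @param source_threshold the selected scan cutoff (p_t-initial).
#' @param alpha_refine per-SNP retention cutoff (p_t-refined), default
#'   0.05.
#' @return An object of class `refined_snp_set`: data frame `snps` with
#'   columns `snp_id`, `weight`, `refine_p`, plus `alpha_refine` and
#'   `source_threshold`.
#' @export
refine_snps <- function(geno, gwas, phenotype, covariates = NULL,
                        source_threshold, alpha_refine = 0.05) {
  sel <- gwas$snp_id[gwas$p_value <= source_threshold]
  sel <- sel[sel %in% geno$snp_meta$snp_id]
  if (length(sel) == 0) {
    stop("no SNP passes source_threshold ", source_threshold)
  }
  sel <- sel[order(match(sel, geno$snp_meta$snp_id))]
  d <- impute_dosage_means(
    geno$dosages[, match(sel, geno$snp_meta$snp_id), drop = FALSE])
  const <- apply(d, 2, stats::sd) == 0
  assoc <- marginal_assoc(phenotype, d[, !const, drop = FALSE], covariates)
  keep_ids <- rownames(assoc)[!is.na(assoc$p) & assoc$p < alpha_refine]
  if (length(keep_ids) == 0) {
    stop("refinement retained zero SNPs at alpha_refine = ", alpha_refine,
         "; consider a larger alpha or a different source threshold")
  }
  structure(
    list(snps = data.frame(
           snp_id = keep_ids,
           weight = gwas$beta[match(keep_ids, gwas$snp_id)],
           refine_p = assoc$p[match(keep_ids, rownames(assoc))],
           stringsAsFactors = FALSE),
         alpha_refine = alpha_refine,
         source_threshold = source_threshold),
    class = "refined_snp_set"
  )
}

#' @export
print.refined_snp_set <- function(x, ...) {
  cat(sprintf(
    "refined_snp_set: %d SNPs (source threshold %.3g, refinement alpha %.3g)\n",
    nrow(x$snps), x$source_threshold, x$alpha_refine))
  invisible(x)
}

#' Score a test cohort with a refined SNP set
#'
#' The refined PRS is the weighted dosage sum over the refined SNPs,
#' standardized to mean 0 and SD 1 within the test cohort. Refined SNPs
#' absent from the test genotypes are dropped with a warning listing
#' them.
#'
#' @param test_geno test-cohort [genotype_matrix], aligned to the same
#'   GWAS effect alleles as the training data.
#' @param refined a [refined_snp_set].
#' @return A [compute_prs()]-style `prs_profile`.
#' @export
compute_rprs <- function(test_geno, refined) {
  stopifnot(inherits(refined, "refined_snp_set"))
  present <- refined$snps$snp_id %in% test_geno$snp_meta$snp_id
  if (!any(present)) stop("no refined SNP present in the test cohort")
  if (any(!present)) {
    warning("compute_rprs: ", sum(!present),
            " refined SNP(s) absent from test cohort: ",
            paste(refined$snps$snp_id[!present], collapse = ", "))
  }
  snps <- refined$snps[present, , drop = FALSE]
  prs_profile_from_weights(test_geno, snps$snp_id, snps$weight,
                           threshold = refined$source_threshold)
}

#' Serialize a refined SNP set
#'
#' Writes a TSV (`snp_id`, `weight`, `refine_p`) plus a JSON sidecar
#' recording `source_threshold`, `alpha_refine` and a content hash of
#' the TSV body, so downstream reports can prove they used the same set.
#'
#' @param refined a [refined_snp_set].
#' @param path output TSV path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_refined_snp_set <- function(refined, path) {
  utils::write.table(refined$snps, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sidecar <- list(source_threshold = refined$source_threshold,
                  alpha_refine = refined$alpha_refine,
                  n_snps = nrow(refined$snps),
                  sha = refined_set_hash(refined))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

# Stable content hash (no external digest dependency): polynomial
# rolling hash of the serialized, rounded table, modulo a Mersenne prime.
refined_set_hash <- function(refined) {
  txt <- paste(
    refined$snps$snp_id,
    sprintf("%.10g", refined$snps$weight),
    sprintf("%.10g", refined$snps$refine_p),
    sep = "\t", collapse = "\n")
  bytes <- as.integer(charToRaw(txt))
  h <- 0
  for (b in bytes) h <- (h * 257 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Read back a serialized refined SNP set
#'
#' @param path TSV path produced by [write_refined_snp_set()].
#' @return A [refined_snp_set].
#' @export
read_refined_snp_set <- function(path) {
  snps <- utils::read.delim(path, stringsAsFactors = FALSE)
  sidecar <- jsonlite::read_json(paste0(path, ".json"))
  structure(list(snps = snps,
                 alpha_refine = sidecar$alpha_refine,
                 source_threshold = sidecar$source_threshold),
            class = "refined_snp_set")
}
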