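# Independent oracles and tiny fixture builders. Oracles are written
# naively (explicit loops, textbook formulas) on purpose: they must not
# share code paths with the implementation they check.

# --- fixture builders ------------------------------------------------

# Genotype matrix from a dosage matrix; metadata defaults to chromosome
# 1, evenly spaced positions and a non-ambiguous A/G allele pair.
make_geno <- function(dosages, pos = NULL, chrom = NULL,
                      counted = NULL, other = NULL, snp_ids = NULL) {
  dosages <- as.matrix(dosages)
  p <- ncol(dosages)
  snp_ids <- snp_ids %||% sprintf("s%03d", seq_len(p))
  meta <- data.frame(
    snp_id = snp_ids,
    chrom = chrom %||% rep("1", p),
    pos = pos %||% (seq_len(p) * 1000L),
    counted_allele = counted %||% rep("A", p),
    other_allele = other %||% rep("G", p),
    stringsAsFactors = FALSE
  )
  genotype_matrix(dosages, meta, sprintf("ind%03d", seq_len(nrow(dosages))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# GWAS summary matching a genotype matrix's SNPs.
make_gwas <- function(geno, beta, p_value) {
  m <- geno$snp_meta
  gwas_summary(data.frame(
    snp_id = m$snp_id, chrom = m$chrom, pos = m$pos,
    effect_allele = m$counted_allele, other_allele = m$other_allele,
    beta = beta, p_value = p_value, stringsAsFactors = FALSE))
}

# Hand-built model-3 fit with chosen coefficients and covariance, for
# geometry tests of the interaction probes.
make_fit3 <- function(bX, bM, bXM, vX = 0.01, vM = 0.01, vXM = 0.01,
                      cXXM = 0, cMXM = 0, df = 100) {
  terms <- c("(Intercept)", "sex", "pc1", "pc2", "pc3",
             "adversity", "rprs", "adversity:rprs")
  est <- c(0, 0, 0, 0, 0, bX, bM, bXM)
  vcov <- diag(0.01, 8)
  dimnames(vcov) <- list(terms, terms)
  vcov["adversity", "adversity"] <- vX
  vcov["rprs", "rprs"] <- vM
  vcov["adversity:rprs", "adversity:rprs"] <- vXM
  vcov["adversity", "adversity:rprs"] <- cXXM
  vcov["adversity:rprs", "adversity"] <- cXXM
  vcov["rprs", "adversity:rprs"] <- cMXM
  vcov["adversity:rprs", "rprs"] <- cMXM
  structure(
    list(coefficients = data.frame(term = terms, estimate = est,
                                   se = sqrt(diag(vcov)),
                                   t = NA_real_, p = NA_real_,
                                   stringsAsFactors = FALSE),
         vcov = vcov, df_residual = df, sigma2 = 1,
         r_squared = NA_real_, n = df + 8),
    class = "linear_model_fit")
}

# Simulated GxE analysis table with known coefficients (no genotypes).
make_gxe_data <- function(n, bX = 0, bM = 0, bXM = 0, noise_sd = 1) {
  x <- sample(0:6, n, replace = TRUE)
  m <- rnorm(n)
  sex <- rbinom(n, 1, 0.5)
  pcs <- matrix(rnorm(n * 3), n)
  y <- 5 + 0.1 * sex + bX * x + bM * m + bXM * x * m +
    rnorm(n, 0, noise_sd)
  data.frame(outcome = y, adversity = x, rprs = m, sex = sex,
             pc1 = pcs[, 1], pc2 = pcs[, 2], pc3 = pcs[, 3])
}

# --- oracles ---------------------------------------------------------

# PRS by per-sample, per-SNP double loop.
oracle_prs <- function(geno, gwas, threshold) {
  sel <- gwas$snp_id[gwas$p_value <= threshold]
  sel <- sel[sel %in% geno$snp_meta$snp_id]
  n <- length(geno$sample_ids)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (s in sel) {
      j <- which(geno$snp_meta$snp_id == s)
      d <- geno$dosages[i, j]
      if (is.na(d)) d <- mean(geno$dosages[, j], na.rm = TRUE)
      acc <- acc + d * gwas$beta[gwas$snp_id == s]
    }
    out[i] <- acc
  }
  out
}

# Exhaustive greedy clumping, re-derived with explicit loops.
oracle_clump <- function(gwas, ref, r2_max, window_kb) {
  ids <- intersect(gwas$snp_id, ref$snp_meta$snp_id)
  g <- gwas[match(ids, gwas$snp_id), ]
  pos <- ref$snp_meta$pos[match(ids, ref$snp_meta$snp_id)]
  chrom <- ref$snp_meta$chrom[match(ids, ref$snp_meta$snp_id)]
  pos[is.na(pos)] <- g$pos[is.na(pos)]
  chrom[is.na(chrom)] <- g$chrom[is.na(chrom)]
  remaining <- ids[order(g$p_value, ids)]
  retained <- character(0)
  removed <- character(0)
  while (length(remaining) > 0) {
    idx <- remaining[1]
    retained <- c(retained, idx)
    remaining <- remaining[-1]
    i <- match(idx, ids)
    drop <- character(0)
    for (cand in remaining) {
      j <- match(cand, ids)
      if (chrom[j] != chrom[i]) next
      if (abs(pos[j] - pos[i]) > window_kb * 1000) next
      a <- ref$dosages[, match(idx, ref$snp_meta$snp_id)]
      b <- ref$dosages[, match(cand, ref$snp_meta$snp_id)]
      r <- suppressWarnings(cor(a, b, use = "pairwise.complete.obs"))
      if (!is.na(r) && r^2 > r2_max) drop <- c(drop, cand)
    }
    remaining <- setdiff(remaining, drop)
    removed <- c(removed, drop)
  }
  list(retained = retained, removed = removed)
}

# Sliding-window pruning, re-derived naively with the same window
# semantics (starts every step_snps SNPs, kb-bounded, drop the later
# member of an offending pair).
oracle_prune <- function(geno, window_kb, step_snps, r2_max) {
  ord <- order(geno$snp_meta$chrom, geno$snp_meta$pos, geno$snp_meta$snp_id)
  meta <- geno$snp_meta[ord, ]
  dos <- geno$dosages[, ord, drop = FALSE]
  n <- nrow(meta)
  keep <- rep(TRUE, n)
  for (s in seq(1, n, by = step_snps)) {
    win <- c()
    for (i in s:n) {
      if (meta$chrom[i] == meta$chrom[s] &&
          meta$pos[i] >= meta$pos[s] &&
          meta$pos[i] - meta$pos[s] <= window_kb * 1000) {
        win <- c(win, i)
      }
    }
    for (i in win) {
      if (!keep[i]) next
      for (j in win[win > i]) {
        if (!keep[j]) next
        ok <- complete.cases(dos[, i], dos[, j])
        a <- dos[ok, i]; b <- dos[ok, j]
        if (var(a) == 0 || var(b) == 0) next
        if (cor(a, b)^2 > r2_max) keep[j] <- FALSE
      }
    }
  }
  meta$snp_id[keep]
}

# OLS through the normal equations.
oracle_ols <- function(y, X) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  vcov <- sigma2 * solve(XtX)
  se <- sqrt(diag(vcov))
  list(beta = drop(beta), se = se, vcov = vcov, sigma2 = sigma2, df = df)
}

# Johnson-Neyman boundaries by brute-force scan of the moderator-effect
# t statistic over a dense grid.
oracle_jn_grid <- function(fit, range, alpha = 0.05, n_grid = 10000) {
  bM <- fit$coefficients$estimate[fit$coefficients$term == "rprs"]
  bXM <- fit$coefficients$estimate[fit$coefficients$term == "adversity:rprs"]
  vM <- fit$vcov["rprs", "rprs"]
  vXM <- fit$vcov["adversity:rprs", "adversity:rprs"]
  cv <- fit$vcov["rprs", "adversity:rprs"]
  tc <- qt(1 - alpha / 2, fit$df_residual)
  xs <- seq(range[1], range[2], length.out = n_grid)
  tv <- (bM + bXM * xs) / sqrt(vM + 2 * xs * cv + xs^2 * vXM)
  sig <- abs(tv) > tc
  flips <- which(diff(sig) != 0)
  (xs[flips] + xs[flips + 1]) / 2
}
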