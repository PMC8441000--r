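# Clumping, PRS, threshold scan, refinement, rPRS.

test_that("ld_clump follows the greedy rule and matches the oracle", {
  set.seed(5)
  n <- 150
  a <- rbinom(n, 2, 0.4)
  b <- ifelse(rbinom(n, 1, 0.2) == 1, 2 - a, a)   # r2 well above 0.2
  geno <- make_geno(cbind(a, b), pos = c(1000L, 3000L))
  gwas <- make_gwas(geno, beta = c(0.2, 0.3), p_value = c(1e-4, 1e-2))
  res <- ld_clump(gwas, geno, r2_max = 0.2, window_kb = 50)
  expect_equal(res$retained, "s001")
  expect_equal(res$removed_by, c(s002 = "s001"))

  # mutually uncorrelated SNPs are all retained
  set.seed(6)
  u <- sapply(runif(5, 0.2, 0.5), function(p) rbinom(n, 2, p))
  gu <- make_geno(u, pos = as.integer(1:5 * 1000))
  gg <- make_gwas(gu, beta = rep(0.1, 5), p_value = runif(5, 0.2, 0.9))
  resu <- ld_clump(gg, gu, r2_max = 0.2, window_kb = 50)
  expect_setequal(resu$retained, gu$snp_meta$snp_id)

  # every input SNP lands in exactly one of retained / removed_by
  expect_setequal(c(res$retained, names(res$removed_by)),
                  geno$snp_meta$snp_id)
})

test_that("ld_clump agrees with an exhaustive greedy oracle on random instances", {
  for (seed in c(101, 202, 303)) {
    set.seed(seed)
    n <- 120; p <- 30
    base <- matrix(rbinom(n * p, 2, 0.35), n)
    for (j in 2:p) {             # random LD with the previous SNP
      if (runif(1) < 0.5) {
        copy <- rbinom(n, 1, 0.8)
        base[, j] <- ifelse(copy == 1, base[, j - 1], base[, j])
      }
    }
    geno <- make_geno(base, pos = as.integer(seq_len(p) * 2000))
    gwas <- make_gwas(geno, beta = rnorm(p, 0, 0.1),
                      p_value = runif(p))
    res <- ld_clump(gwas, geno, r2_max = 0.2, window_kb = 10)
    orc <- oracle_clump(gwas, geno, 0.2, 10)
    expect_equal(res$retained, orc$retained)
    expect_setequal(names(res$removed_by), orc$removed)
  }
})

test_that("compute_prs sums weighted dosages and standardizes", {
  geno <- make_geno(matrix(c(0, 1, 2), ncol = 1))
  gwas <- make_gwas(geno, beta = 0.5, p_value = 0.01)
  prs <- compute_prs(geno, gwas, threshold = 0.05)
  expect_equal(prs$raw, c(0, 0.5, 1.0))
  expect_equal(mean(prs$standardized), 0, tolerance = 1e-9)
  expect_equal(sd(prs$standardized), 1, tolerance = 1e-9)
  expect_error(compute_prs(geno, gwas, threshold = 0.001), "0.001")
})

test_that("compute_prs equals the double-loop oracle, with missing dosages", {
  set.seed(9)
  d <- matrix(rbinom(200, 2, 0.4), nrow = 20)
  d[sample(length(d), 15)] <- NA
  geno <- make_geno(d)
  gwas <- make_gwas(geno, beta = rnorm(10, 0, 0.3), p_value = runif(10))
  thr <- 0.6
  prs <- compute_prs(geno, gwas, thr)
  expect_equal(prs$raw, oracle_prs(geno, gwas, thr), tolerance = 1e-12)
})

test_that("threshold_scan evaluates the full grid with nested SNP counts", {
  set.seed(21)
  n <- 300; p <- 40
  d <- matrix(rbinom(n * p, 2, 0.3), n)
  geno <- make_geno(d)
  beta <- c(rnorm(8, 0, 0.4), rep(0, p - 8))
  pheno <- as.numeric(d[, 1:8] %*% beta[1:8]) + rnorm(n, 0, 1.5)
  gwas <- make_gwas(geno, beta = beta,
                    p_value = c(runif(8, 0.001, 0.08), runif(p - 8, 0.2, 1)))
  scan <- threshold_scan(geno, gwas, pheno)
  expect_equal(nrow(scan$scan), 100)              # default grid size
  expect_true(all(diff(scan$scan$n_snps) >= 0))   # nested thresholds
  expect_true(scan$best_threshold %in% scan$scan$threshold)
  # cutoffs below the smallest p are recorded, not skipped
  gwas_hi <- make_gwas(geno, beta = beta, p_value = runif(p, 0.5, 1))
  scan_hi <- threshold_scan(geno, gwas_hi, pheno)
  expect_equal(nrow(scan_hi$scan), 100)
  expect_true(any(scan_hi$scan$n_snps == 0))
  expect_true(all(is.na(scan_hi$scan$p_prs[scan_hi$scan$n_snps == 0])))
  # scan statistics match a direct lm() refit at a few cutoffs
  for (t in c(0.05, 0.5, 1)) {
    row <- scan$scan[scan$scan$threshold == t, ]
    prs <- compute_prs(geno, gwas, t)
    fit <- lm(pheno ~ prs$raw)
    expect_equal(row$p_prs, summary(fit)$coefficients[2, 4],
                 tolerance = 1e-8)
    expect_equal(row$r2_incremental, summary(fit)$r.squared,
                 tolerance = 1e-8)
  }
})

test_that("threshold_scan prefers thresholds capturing the causal set", {
  hits <- 0L
  for (seed in 1:20) {
    cfg <- sim_config(n_discovery = 500, n_snps = 150, n_causal = 10,
                      seed = 1000 + seed)
    geno <- simulate_genotypes(cfg, "discovery")
    gwas <- simulate_gwas(geno$snp_meta, attr(geno, "causal_ids"), cfg,
                          freq = attr(geno, "freq"))
    pheno <- simulate_insulin(geno, gwas, attr(geno, "causal_ids"), cfg)
    scan <- threshold_scan(geno, gwas, pheno)
    causal_p <- gwas$p_value[gwas$snp_id %in% attr(geno, "causal_ids")]
    if (all(causal_p <= 0.1)) {
      # r2 at best threshold >= r2 at the smallest cutoff excluding
      # some causal SNP
      excl <- scan$scan$threshold[scan$scan$threshold < max(causal_p)]
      if (length(excl) == 0) {
        hits <- hits + 1L   # no grid cutoff excludes any causal SNP
        next
      }
      r2_best <- scan$scan$r2_incremental[
        scan$scan$threshold == scan$best_threshold]
      r2_excl <- scan$scan$r2_incremental[
        scan$scan$threshold == min(excl)]
      if (is.na(r2_excl) || r2_best >= r2_excl) hits <- hits + 1L
    } else {
      hits <- hits + 1L  # premise not met for this seed; not a failure
    }
  }
  expect_gte(hits, 11)  # majority of 20 seeds
})

test_that("refine_snps keeps sub-alpha SNPs with GWAS weights", {
  set.seed(31)
  n <- 400
  d <- matrix(rbinom(n * 6, 2, 0.4), n)
  geno <- make_geno(d)
  beta_true <- c(0.5, 0.45, 0, 0, 0, 0)
  pheno <- as.numeric(d %*% beta_true) + rnorm(n)
  gwas <- make_gwas(geno, beta = rnorm(6, 0, 0.2), p_value = runif(6, 0, 0.2))
  ref <- refine_snps(geno, gwas, pheno, source_threshold = 0.24,
                     alpha_refine = 0.05)
  expect_true(all(ref$snps$refine_p < 0.05))
  expect_true(all(ref$snps$snp_id %in% gwas$snp_id[gwas$p_value <= 0.24]))
  expect_true(all(c("s001", "s002") %in% ref$snps$snp_id))
  # weights are the GWAS betas, untouched by refinement
  expect_equal(ref$snps$weight,
               gwas$beta[match(ref$snps$snp_id, gwas$snp_id)])
  # per-SNP p matches a direct lm() refit
  for (k in seq_len(nrow(ref$snps))) {
    j <- match(ref$snps$snp_id[k], geno$snp_meta$snp_id)
    expect_equal(ref$snps$refine_p[k],
                 summary(lm(pheno ~ d[, j]))$coefficients[2, 4],
                 tolerance = 1e-8)
  }
  expect_error(
    refine_snps(geno, gwas, rnorm(n), source_threshold = 0.24,
                alpha_refine = 1e-12),
    "larger alpha")
})

test_that("refinement retains ~alpha of purely null SNPs", {
  # 200 null SNPs x 20 seeds; retained fraction within the binomial
  # 99% band around alpha = 0.05
  alpha <- 0.05
  total <- 0L; kept <- 0L
  for (seed in 1:20) {
    set.seed(2000 + seed)
    n <- 150; p <- 200
    d <- matrix(rbinom(n * p, 2, 0.4), n)
    geno <- make_geno(d, pos = as.integer(seq_len(p) * 1e6))
    gwas <- make_gwas(geno, beta = rnorm(p, 0, 0.1), p_value = runif(p))
    pheno <- rnorm(n)
    ref <- tryCatch(
      refine_snps(geno, gwas, pheno, source_threshold = 1,
                  alpha_refine = alpha),
      error = function(e) list(snps = data.frame()))
    kept <- kept + nrow(ref$snps)
    total <- total + p
  }
  band <- qbinom(c(0.005, 0.995), total, alpha) / total
  frac <- kept / total
  expect_gte(frac, band[1])
  expect_lte(frac, band[2])
})

test_that("refined sets are enriched for causal SNPs vs the threshold set", {
  wins <- 0L
  for (seed in 1:20) {
    cfg <- sim_config(seed = 3000 + seed)   # 2000 x 500, 20 causal, h2 0.3
    geno <- simulate_genotypes(cfg, "discovery")
    causal <- attr(geno, "causal_ids")
    gwas <- simulate_gwas(geno$snp_meta, causal, cfg,
                          freq = attr(geno, "freq"))
    pheno <- simulate_insulin(geno, gwas, causal, cfg)
    scan <- threshold_scan(geno, gwas, pheno)
    ref <- tryCatch(
      refine_snps(geno, gwas, pheno,
                  source_threshold = scan$best_threshold),
      error = function(e) NULL)
    if (is.null(ref)) next
    full_set <- gwas$snp_id[gwas$p_value <= scan$best_threshold]
    frac_ref <- mean(ref$snps$snp_id %in% causal)
    frac_full <- mean(full_set %in% causal)
    if (frac_ref > frac_full) wins <- wins + 1L
  }
  expect_gte(wins, 16)  # >= 80% of 20 seeds
})

test_that("refinement is byte-identical across repeated runs", {
  cfg <- sim_config(n_discovery = 300, n_snps = 100, seed = 77)
  run_once <- function() {
    geno <- simulate_genotypes(cfg, "discovery")
    causal <- attr(geno, "causal_ids")
    gwas <- simulate_gwas(geno$snp_meta, causal, cfg,
                          freq = attr(geno, "freq"))
    pheno <- simulate_insulin(geno, gwas, causal, cfg)
    refine_snps(geno, gwas, pheno, source_threshold = 0.5)
  }
  expect_identical(run_once(), run_once())
})

test_that("compute_rprs standardizes, drops absent SNPs with a warning", {
  geno <- make_geno(matrix(c(0, 2), ncol = 1), snp_ids = "s001")
  refined <- structure(
    list(snps = data.frame(snp_id = "s001", weight = 0.3, refine_p = 0.01),
         alpha_refine = 0.05, source_threshold = 0.24),
    class = "refined_snp_set")
  prof <- compute_rprs(geno, refined)
  expect_equal(prof$raw, c(0, 0.6))
  expect_equal(prof$standardized, (c(0, 0.6) - 0.3) / sd(c(0, 0.6)))
  expect_equal(mean(prof$standardized), 0, tolerance = 1e-9)
  expect_equal(sd(prof$standardized), 1, tolerance = 1e-9)

  refined2 <- refined
  refined2$snps <- rbind(refined2$snps,
                         data.frame(snp_id = "absent", weight = 1,
                                    refine_p = 0.01))
  expect_warning(prof2 <- compute_rprs(geno, refined2), "absent")
  expect_equal(prof2$n_snps_used, 1)
  refined3 <- refined
  refined3$snps$snp_id <- "nowhere"
  expect_error(compute_rprs(geno, refined3), "no refined SNP")
})

test_that("PRS threshold nesting holds and threshold 1 uses every SNP", {
  set.seed(41)
  d <- matrix(rbinom(600, 2, 0.3), nrow = 30)
  geno <- make_geno(d)
  gwas <- make_gwas(geno, beta = rnorm(20, 0, 0.2), p_value = runif(20))
  s1 <- compute_prs(geno, gwas, 0.3)$snp_ids
  s2 <- compute_prs(geno, gwas, 0.7)$snp_ids
  expect_true(all(s1 %in% s2))
  expect_equal(sort(compute_prs(geno, gwas, 1)$snp_ids),
               sort(gwas$snp_id))
})

test_that("refined sets roundtrip through TSV + sidecar", {
  refined <- structure(
    list(snps = data.frame(snp_id = c("a", "b"), weight = c(0.1, -0.2),
                           refine_p = c(0.01, 0.04),
                           stringsAsFactors = FALSE),
         alpha_refine = 0.05, source_threshold = 0.24),
    class = "refined_snp_set")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_refined_snp_set(refined, path)
  back <- read_refined_snp_set(path)
  expect_equal(back$snps$snp_id, refined$snps$snp_id)
  expect_equal(back$snps$weight, refined$snps$weight)
  expect_equal(back$alpha_refine, 0.05)
  expect_equal(back$source_threshold, 0.24)
})
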