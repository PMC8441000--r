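# OLS, GxE models, simple slopes, Johnson-Neyman, PoI/PA, bootstrap,
# Rubin pooling.

test_that("fit_ols matches the normal-equations oracle", {
  set.seed(3)
  n <- 30
  X <- cbind(`(Intercept)` = 1, a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- 1 + 0.5 * X[, "a"] - 0.3 * X[, "b"] + rnorm(n)
  fit <- fit_ols(y, X)
  orc <- oracle_ols(y, X)
  expect_equal(fit$coefficients$estimate, unname(orc$beta),
               tolerance = 1e-8)
  expect_equal(fit$coefficients$se, unname(orc$se), tolerance = 1e-8)
  expect_equal(unname(fit$vcov), unname(orc$vcov), tolerance = 1e-8)
  expect_equal(fit$df_residual, orc$df)
  # exact fit: y = 2x
  x <- 1:10
  fit2 <- fit_ols(2 * x, cbind(`(Intercept)` = 1, x = x))
  expect_equal(fit2$coefficients$estimate, c(0, 2), tolerance = 1e-10)
  expect_equal(fit2$r_squared, 1, tolerance = 1e-10)
  # duplicate column names the collinear culprit
  expect_error(fit_ols(y, cbind(X, dup = X[, "a"])), "dup")
})

test_that("fit_gxe_models builds the three pre-registered designs", {
  set.seed(8)
  dat <- make_gxe_data(120, bX = -0.1, bM = 0.05, bXM = -0.3)
  fits <- fit_gxe_models(dat)
  expect_named(fits, c("model1", "model2", "model3"))
  expect_equal(nrow(fits$model3$coefficients), 8)   # intercept+sex+3PC+X+M+XM
  expect_equal(fits$model3$coefficients$term,
               c("(Intercept)", "sex", "pc1", "pc2", "pc3",
                 "adversity", "rprs", "adversity:rprs"))
  # model 3 agrees with lm()
  lmfit <- lm(outcome ~ sex + pc1 + pc2 + pc3 + adversity * rprs, dat)
  expect_equal(sort(fits$model3$coefficients$estimate),
               sort(unname(coef(lmfit))), tolerance = 1e-10)
  # incomplete rows are dropped
  dat2 <- dat; dat2$adversity[1:5] <- NA
  expect_message(fits2 <- fit_gxe_models(dat2), "5 incomplete")
  expect_equal(fits2$model3$n, 115)
  expect_error(fit_gxe_models(dat[, -2]), "adversity")
})

test_that("interaction estimate recovers a planted effect at large n", {
  set.seed(14)
  dat <- make_gxe_data(10000, bXM = -0.33, noise_sd = 1)
  fit <- fit_gxe_models(dat)$model3
  est <- fit$coefficients$estimate[fit$coefficients$term == "adversity:rprs"]
  expect_equal(est, -0.33, tolerance = 0.05 / 0.33)  # within +/- 0.05
})

test_that("interaction test holds its type-I error under the null", {
  # 400 seeds at n = 5000; rejections should fall in the binomial 99%
  # band around alpha = 0.05
  set.seed(424242)
  rejections <- 0L
  n_seeds <- 400
  for (i in seq_len(n_seeds)) {
    dat <- make_gxe_data(5000, bX = 0.1, bM = 0.1, bXM = 0)
    fit <- fit_gxe_models(dat)$model3
    p <- fit$coefficients$p[fit$coefficients$term == "adversity:rprs"]
    if (p < 0.05) rejections <- rejections + 1L
  }
  band <- qbinom(c(0.005, 0.995), n_seeds, 0.05)
  expect_gte(rejections, band[1])
  expect_lte(rejections, band[2])
})

test_that("simple slopes follow the algebra and match a bootstrap oracle", {
  fit <- make_fit3(bX = 0.2, bM = -0.1, bXM = -0.4, cXXM = 0.002)
  sl <- simple_slopes(fit, m_points = c(-1, 0, 1))
  expect_equal(sl$slopes$slope, 0.2 + -0.4 * c(-1, 0, 1))
  # slope at m = 0 is bX with SE(bX)
  expect_equal(sl$slopes$se[2], sqrt(fit$vcov["adversity", "adversity"]))
  # bXM = 0 -> both probes equal bX
  fit0 <- make_fit3(bX = 0.2, bM = -0.1, bXM = 0)
  sl0 <- simple_slopes(fit0)
  expect_equal(sl0$slopes$slope, c(0.2, 0.2))
  # SEs within 15% of a 2000-rep case-resampling bootstrap at n = 500
  set.seed(55)
  dat <- make_gxe_data(500, bX = 0.1, bXM = -0.3)
  fit3 <- fit_gxe_models(dat)$model3
  sl3 <- simple_slopes(fit3, m_points = c(-1, 1))
  boots <- replicate(2000, {
    idx <- sample.int(500, replace = TRUE)
    f <- lm(outcome ~ sex + pc1 + pc2 + pc3 + adversity * rprs,
            dat[idx, ])
    b <- coef(f)
    b["adversity"] + b["adversity:rprs"] * c(-1, 1)
  })
  expect_equal(sl3$slopes$se[1], sd(boots[1, ]), tolerance = 0.15)
  expect_equal(sl3$slopes$se[2], sd(boots[2, ]), tolerance = 0.15)
  expect_error(simple_slopes(fit_ols(dat$outcome,
                                     cbind(`(Intercept)` = 1,
                                           adversity = dat$adversity))),
               "rprs")
})

test_that("jn_regions boundaries satisfy |t| = t_crit and match the grid scan", {
  set.seed(65)
  # fuzz over random fits; boundaries must self-reproduce t_crit and
  # agree with a 10,000-point scan
  for (rep in 1:100) {
    fit <- make_fit3(bX = rnorm(1, 0, 0.3), bM = rnorm(1, 0, 0.3),
                     bXM = rnorm(1, 0, 0.3),
                     vM = runif(1, 0.001, 0.05),
                     vXM = runif(1, 0.001, 0.05),
                     cMXM = runif(1, -0.002, 0.002),
                     df = sample(30:200, 1))
    range <- c(0, 8)
    ros <- jn_regions(fit, range)
    ib_vM <- fit$vcov["rprs", "rprs"]
    ib_vXM <- fit$vcov["adversity:rprs", "adversity:rprs"]
    ib_c <- fit$vcov["rprs", "adversity:rprs"]
    bM <- 0; bXM <- 0
    bM <- fit$coefficients$estimate[7]; bXM <- fit$coefficients$estimate[8]
    for (x in ros$boundaries) {
      tval <- (bM + bXM * x) / sqrt(ib_vM + 2 * x * ib_c + x^2 * ib_vXM)
      expect_equal(abs(tval), ros$t_crit, tolerance = 1e-6)
    }
    grid_bounds <- oracle_jn_grid(fit, range)
    in_range <- ros$boundaries[ros$boundaries > range[1] &
                                 ros$boundaries < range[2]]
    expect_equal(length(in_range), length(grid_bounds))
    if (length(grid_bounds) > 0) {
      # absolute comparison at the grid's own resolution (8e-4)
      expect_lt(max(abs(sort(in_range) - sort(grid_bounds))), 2e-3)
    }
  }
  # bXM = 0 with significant bM: significant everywhere, no boundaries
  fit_const <- make_fit3(bX = 0, bM = 0.5, bXM = 0, vM = 0.001,
                         vXM = 0)
  ros0 <- jn_regions(fit_const, c(0, 5))
  expect_length(ros0$boundaries, 0)
  expect_true(all(ros0$regions$significant))
})

test_that("poi_pa geometry: crossover placement drives PoI and PA", {
  # crossover at the range midpoint -> equal triangles -> PoI = 0.5
  fit <- make_fit3(bX = 0, bM = 2, bXM = -1)     # crossover at x = 2
  res <- poi_pa(fit, x_values = c(0, 1, 3, 4), range = c(0, 4))
  expect_equal(res$crossover, 2)
  expect_equal(res$poi, 0.5)
  expect_equal(res$pa, 0.5)   # two of four observations beyond x = 2
  # crossover below the range: all area on the adverse side -> PoI = 1
  fit2 <- make_fit3(bX = 0, bM = 1, bXM = -1)    # crossover at x = 1
  res2 <- poi_pa(fit2, x_values = c(2, 3, 4), range = c(2, 4))
  expect_equal(res2$poi, 1)
  expect_equal(res2$pa, 1)
  # crossover above the range on the benign side -> PoI = 0
  res3 <- poi_pa(fit2, x_values = c(-3, -2), range = c(-3, 0))
  expect_equal(res3$poi, 0)
  expect_equal(res3$pa, 0)
  # complementarity when the crossover is inside the range
  fit4 <- make_fit3(bX = 0, bM = 1.5, bXM = -1)  # crossover at 1.5
  r4 <- poi_pa(fit4, x_values = 0:4, range = c(0, 4))
  expect_equal(r4$poi + (1.5 - 0)^2 / ((1.5)^2 + (4 - 1.5)^2), 1)
  # zero interaction -> degenerate flag
  fit0 <- make_fit3(bX = 0.2, bM = 0.3, bXM = 0)
  expect_true(poi_pa(fit0, x_values = 1:5)$degenerate)
  expect_error(poi_pa(fit, x_values = numeric(0)), "empty")
})

test_that("bootstrap_interaction is reproducible with percentile CI", {
  set.seed(19)
  dat <- make_gxe_data(300, bXM = -0.3)
  b1 <- bootstrap_interaction(dat, n_boot = 200, seed = 7)
  b2 <- bootstrap_interaction(dat, n_boot = 200, seed = 7)
  expect_identical(b1, b2)
  expect_lte(b1$ci_low, b1$ci_high)
  expect_error(bootstrap_interaction(dat, n_boot = 50), "at least 100")
  # bootstrap SE within 20% of the classical SE in a well-specified model
  set.seed(23)
  dat2 <- make_gxe_data(500, bXM = -0.2)
  fit <- fit_gxe_models(dat2)$model3
  se_classical <- fit$coefficients$se[
    fit$coefficients$term == "adversity:rprs"]
  bt <- bootstrap_interaction(dat2, n_boot = 1000, seed = 11)
  expect_equal(bt$se, se_classical, tolerance = 0.2)
})

test_that("pool_estimates implements Rubin's rules", {
  set.seed(27)
  dat <- make_gxe_data(100)
  fit <- fit_gxe_models(dat)$model3
  # identical fits: pooled equals the single fit, B = 0
  pooled_same <- pool_estimates(list(fit, fit, fit))
  expect_equal(pooled_same$pooled$estimate, fit$coefficients$estimate)
  expect_equal(pooled_same$pooled$B, rep(0, 8))
  expect_equal(pooled_same$pooled$se, fit$coefficients$se)
  # hand-arithmetic check: estimates (1.0, 1.2, 1.4), within-var 0.04
  mk_toy <- function(est) {
    structure(list(coefficients = data.frame(
      term = "b", estimate = est, se = 0.2, t = NA, p = NA)),
      class = "linear_model_fit")
  }
  fits <- lapply(c(1.0, 1.2, 1.4), mk_toy)
  pooled <- pool_estimates(fits)
  expect_equal(pooled$pooled$estimate, 1.2)  # arithmetic mean
  B_hand <- var(c(1.0, 1.2, 1.4))
  expect_equal(pooled$pooled$se^2, 0.04 + (1 + 1 / 3) * B_hand)
  # mismatched names error
  bad <- mk_toy(1); bad$coefficients$term <- "other"
  expect_error(pool_estimates(list(fits[[1]], bad)), "mismatched")
})

test_that("constraining the interaction to zero reproduces the additive fit", {
  set.seed(31)
  dat <- make_gxe_data(200, bX = 0.2, bM = -0.1, bXM = 0.25)
  covs <- cbind(`(Intercept)` = 1, sex = dat$sex, pc1 = dat$pc1,
                pc2 = dat$pc2, pc3 = dat$pc3, adversity = dat$adversity,
                rprs = dat$rprs)
  additive <- fit_ols(dat$outcome, covs)
  lm_add <- lm(outcome ~ sex + pc1 + pc2 + pc3 + adversity + rprs, dat)
  expect_equal(sort(additive$coefficients$estimate),
               sort(unname(coef(lm_add))), tolerance = 1e-10)
})
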