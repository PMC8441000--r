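# Moderated regression: model fitting, simple slopes, Johnson-Neyman
# regions of significance, interaction-form indices (PoI/PA),
# non-parametric bootstrap, and Rubin pooling.

#' Ordinary least squares with classical standard errors
#'
#' Fits `y` on an explicit design matrix (caller supplies the intercept
#' column) and returns estimates, classical SEs, t and p statistics, the
#' full coefficient covariance matrix, residual degrees of freedom and
#' R-squared (centered when the design contains an intercept column).
#' A rank-deficient design is an error naming the collinear columns.
#'
#' @param y numeric outcome vector.
#' @param design numeric matrix with named columns, including the
#'   intercept if one is wanted.
#' @return An object of class `linear_model_fit`.
#' @export
fit_ols <- function(y, design) {
  design <- as.matrix(design)
  n <- length(y)
  p <- ncol(design)
  if (is.null(colnames(design))) {
    colnames(design) <- paste0("x", seq_len(p))
  }
  if (n != nrow(design)) stop("y and design have different lengths")
  if (n <= p) stop("need more observations than design columns")
  qx <- qr(design)
  if (qx$rank < p) {
    bad <- colnames(design)[qx$pivot[seq.int(qx$rank + 1L, p)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  coef <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  df <- n - p
  sigma2 <- sum(res^2) / df
  R <- qr.R(qx)
  unscaled <- chol2inv(R)
  # undo column pivoting, if any
  piv <- qx$pivot
  vcov <- matrix(NA_real_, p, p)
  vcov[piv, piv] <- unscaled
  vcov <- vcov * sigma2
  dimnames(vcov) <- list(colnames(design), colnames(design))
  se <- sqrt(diag(vcov))
  tstat <- coef / se
  pval <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  has_intercept <- any(apply(design, 2, function(col) all(col == col[1]) &&
                               col[1] != 0))
  tss <- if (has_intercept) sum((y - mean(y))^2) else sum(y^2)
  r2 <- 1 - sum(res^2) / tss
  structure(
    list(coefficients = data.frame(
           term = colnames(design), estimate = unname(coef),
           se = unname(se), t = unname(tstat), p = unname(pval),
           stringsAsFactors = FALSE),
         vcov = vcov, df_residual = df, sigma2 = sigma2,
         r_squared = r2, n = n),
    class = "linear_model_fit"
  )
}

#' @export
print.linear_model_fit <- function(x, ...) {
  cat("linear_model_fit: n =", x$n, ", residual df =", x$df_residual,
      ", R2 =", format(x$r_squared, digits = 4), "\n")
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

coef_value <- function(fit, term) {
  i <- match(term, fit$coefficients$term)
  if (is.na(i)) stop("model fit lacks the term '", term, "'")
  fit$coefficients$estimate[i]
}

#' Fit the three pre-registered GxE regression models
#'
#' Model 1: outcome ~ sex + PC1-3 + adversity. Model 2: outcome ~ sex +
#' PC1-3 + rPRS. Model 3: outcome ~ sex + PC1-3 + adversity + rPRS +
#' adversity x rPRS. Rows with any missing value among the used columns
#' are dropped (complete-case analysis).
#'
#' @param data data frame with columns `outcome`, `adversity`, `rprs`,
#'   `sex`, `pc1`, `pc2`, `pc3` (numeric).
#' @return Named list of three [fit_ols()] fits (`model1`, `model2`,
#'   `model3`), class `gxe_models`.
#' @export
fit_gxe_models <- function(data) {
  required <- c("outcome", "adversity", "rprs", "sex", "pc1", "pc2", "pc3")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  data <- data[required]
  cc <- stats::complete.cases(data)
  if (sum(!cc) > 0) {
    message("fit_gxe_models: dropping ", sum(!cc), " incomplete row(s)")
  }
  data <- data[cc, , drop = FALSE]
  covs <- as.matrix(data[c("sex", "pc1", "pc2", "pc3")])
  base <- cbind(`(Intercept)` = 1, covs)
  y <- data$outcome
  x <- data$adversity
  m <- data$rprs
  list_out <- list(
    model1 = fit_ols(y, cbind(base, adversity = x)),
    model2 = fit_ols(y, cbind(base, rprs = m)),
    model3 = fit_ols(y, cbind(base, adversity = x, rprs = m,
                              `adversity:rprs` = x * m))
  )
  structure(list_out, class = "gxe_models")
}

# Pull the interaction block (coefficients + vcov entries) out of a
# model-3 fit; shared by the probing functions.
interaction_block <- function(fit, predictor = "adversity",
                              moderator = "rprs") {
  int <- paste0(predictor, ":", moderator)
  terms <- fit$coefficients$term
  for (t in c(predictor, moderator, int)) {
    if (!t %in% terms) stop("fit lacks the term '", t, "'")
  }
  list(
    bX = coef_value(fit, predictor),
    bM = coef_value(fit, moderator),
    bXM = coef_value(fit, int),
    vX = fit$vcov[predictor, predictor],
    vM = fit$vcov[moderator, moderator],
    vXM = fit$vcov[int, int],
    cXXM = fit$vcov[predictor, int],
    cMXM = fit$vcov[moderator, int],
    df = fit$df_residual
  )
}

#' Simple slopes of the predictor at chosen moderator values
#'
#' The conditional slope of the outcome on the predictor at moderator
#' value m is `bX + bXM * m`, with variance `Var(bX) + m^2 Var(bXM) +
#' 2 m Cov(bX, bXM)`; t and p are computed on the residual degrees of
#' freedom. The default probes are the moderator mean +/- 1 SD, i.e.
#' `c(-1, 1)` for a standardized score.
#'
#' @param fit a model-3 [fit_ols()] fit containing predictor, moderator
#'   and interaction terms.
#' @param m_points moderator values at which to probe.
#' @param predictor,moderator term names in the fit.
#' @param alpha two-sided significance level for the critical t.
#' @return An object of class `interaction_analysis` carrying the three
#'   focal coefficients, the probe table (`slopes`), and `t_crit`.
#' @export
simple_slopes <- function(fit, m_points = c(-1, 1),
                          predictor = "adversity", moderator = "rprs",
                          alpha = 0.05) {
  ib <- interaction_block(fit, predictor, moderator)
  slope <- ib$bX + ib$bXM * m_points
  vars <- ib$vX + m_points^2 * ib$vXM + 2 * m_points * ib$cXXM
  se <- sqrt(vars)
  tstat <- slope / se
  p <- 2 * stats::pt(abs(tstat), ib$df, lower.tail = FALSE)
  structure(
    list(bX = ib$bX, bM = ib$bM, bXM = ib$bXM,
         m_low = min(m_points), m_high = max(m_points),
         slopes = data.frame(m = m_points, slope = slope, se = se,
                             t = tstat, p = p),
         t_crit = stats::qt(1 - alpha / 2, ib$df),
         df = ib$df, predictor = predictor, moderator = moderator),
    class = "interaction_analysis"
  )
}

#' @export
print.interaction_analysis <- function(x, ...) {
  cat(sprintf("interaction_analysis: bX = %.4f, bM = %.4f, bXM = %.4f\n",
              x$bX, x$bM, x$bXM))
  print(x$slopes, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Johnson-Neyman regions of significance
#'
#' Finds the predictor values x at which the conditional effect of the
#' moderator, `bM + bXM * x`, is exactly borderline-significant, i.e.
#' solves `(bM + bXM x)^2 = t_crit^2 [Var(bM) + 2 x Cov(bM, bXM) +
#' x^2 Var(bXM)]`, and classifies significance over the evaluation
#' range. A degenerate quadratic yields zero boundaries with the
#' pattern flagged as significant everywhere or nowhere.
#'
#' @param fit a model-3 [fit_ols()] fit.
#' @param range numeric length-2 evaluation interval on the predictor
#'   axis.
#' @param predictor,moderator term names in the fit.
#' @param alpha two-sided significance level.
#' @return An object of class `ros_result` with sorted `boundaries`,
#'   a `regions` table (sub-intervals of `range` with a `significant`
#'   flag), and `t_crit`.
#' @export
jn_regions <- function(fit, range, predictor = "adversity",
                       moderator = "rprs", alpha = 0.05) {
  stopifnot(length(range) == 2, range[1] < range[2])
  ib <- interaction_block(fit, predictor, moderator)
  tc <- stats::qt(1 - alpha / 2, ib$df)
  a <- ib$bXM^2 - tc^2 * ib$vXM
  b <- 2 * (ib$bM * ib$bXM - tc^2 * ib$cMXM)
  c0 <- ib$bM^2 - tc^2 * ib$vM
  roots <- numeric(0)
  if (abs(a) > 1e-12) {
    disc <- b^2 - 4 * a * c0
    if (disc > 0) roots <- sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
    else if (disc == 0) roots <- -b / (2 * a)
  } else if (abs(b) > 1e-12) {
    roots <- -c0 / b
  }
  cuts <- sort(unique(c(range, roots[roots > range[1] & roots < range[2]])))
  lo <- cuts[-length(cuts)]
  hi <- cuts[-1]
  mids <- (lo + hi) / 2
  tmid <- vapply(mids, function(x) {
    (ib$bM + ib$bXM * x) /
      sqrt(ib$vM + 2 * x * ib$cMXM + x^2 * ib$vXM)
  }, numeric(1))
  regions <- data.frame(lower = lo, upper = hi,
                        significant = abs(tmid) > tc)
  structure(list(boundaries = roots, regions = regions, range = range,
                 t_crit = tc, alpha = alpha),
            class = "ros_result")
}

#' @export
print.ros_result <- function(x, ...) {
  if (length(x$boundaries) == 0) {
    state <- if (all(x$regions$significant)) "everywhere" else {
      if (any(x$regions$significant)) "mixed" else "nowhere"
    }
    cat("ros_result: no finite boundaries; moderator effect significant ",
        state, " on [", x$range[1], ", ", x$range[2], "]\n", sep = "")
  } else {
    cat("ros_result: boundaries at",
        paste(format(x$boundaries, digits = 4), collapse = ", "), "\n")
    print(x$regions, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Interaction-form indices: crossover, PoI and PA
#'
#' Draws the two outcome-on-predictor lines at moderator values +/- 1 SD
#' (for a standardized moderator, m = +1 and m = -1). Their vertical gap
#' is `delta(x) = 2 (bM + bXM x)`, which changes sign at the crossover
#' `x0 = -bM / bXM`. PoI is the proportion of the total area between the
#' lines (over the evaluation range) lying on the side of the crossover
#' where the high-moderator group fares worse (lower outcome); values
#' near 0.5 suggest differential susceptibility, values near 0 or 1 a
#' diathesis-stress / vantage-sensitivity form. PA is the fraction of
#' observed predictor values on that same adverse side. With a zero
#' interaction the indices are degenerate and flagged.
#'
#' @param fit a model-3 [fit_ols()] fit.
#' @param x_values observed predictor (adversity) values.
#' @param range evaluation interval; defaults to the observed min-max of
#'   `x_values`.
#' @param moderator_sd SD step for the two lines (1 for a standardized
#'   moderator).
#' @param predictor,moderator term names in the fit.
#' @return An object of class `susceptibility_indices` with `crossover`,
#'   `poi`, `pa`, `range` and a `degenerate` flag.
#' @export
poi_pa <- function(fit, x_values, range = NULL, moderator_sd = 1,
                   predictor = "adversity", moderator = "rprs") {
  x_values <- x_values[!is.na(x_values)]
  if (length(x_values) == 0) stop("x_values is empty")
  range <- range %||% c(min(x_values), max(x_values))
  stopifnot(length(range) == 2, range[1] < range[2])
  ib <- interaction_block(fit, predictor, moderator)
  if (ib$bXM == 0) {
    return(structure(list(crossover = NA_real_, poi = NA_real_,
                          pa = NA_real_, range = range, degenerate = TRUE),
                     class = "susceptibility_indices"))
  }
  x0 <- -ib$bM / ib$bXM
  # gap between the +1 SD and -1 SD moderator lines
  delta <- function(x) 2 * moderator_sd * (ib$bM + ib$bXM * x)
  # adverse side: where the high-moderator line is lower (delta < 0);
  # |delta| is linear in x, so areas are triangles/trapezoids
  tri_area <- function(lo, hi) {
    if (hi <= lo) return(0)
    (abs(delta(lo)) + abs(delta(hi))) / 2 * (hi - lo)
  }
  L <- range[1]; U <- range[2]
  if (x0 <= L || x0 >= U) {
    mid_sign <- sign(delta((L + U) / 2))
    adverse_area <- if (mid_sign < 0) tri_area(L, U) else 0
    total_area <- tri_area(L, U)
  } else {
    left <- tri_area(L, x0)
    right <- tri_area(x0, U)
    left_sign <- sign(delta((L + x0) / 2))
    adverse_area <- if (left_sign < 0) left else right
    total_area <- left + right
  }
  poi <- if (total_area > 0) adverse_area / total_area else NA_real_
  pa <- mean(delta(x_values) < 0)
  structure(list(crossover = x0, poi = poi, pa = pa, range = range,
                 degenerate = FALSE),
            class = "susceptibility_indices")
}

#' @export
print.susceptibility_indices <- function(x, ...) {
  if (x$degenerate) {
    cat("susceptibility_indices: degenerate (zero interaction)\n")
  } else {
    cat(sprintf(
      "susceptibility_indices: crossover = %.4f, PoI = %.4f, PA = %.4f on [%g, %g]\n",
      x$crossover, x$poi, x$pa, x$range[1], x$range[2]))
  }
  invisible(x)
}

#' Non-parametric bootstrap of the interaction coefficient
#'
#' Case resampling with replacement at the individual level: each
#' replicate refits model 3 on a resampled dataset and records the
#' interaction coefficient. The SE is the SD of the replicate estimates
#' and the 95% CI their 2.5/97.5 percentiles. Replicates with a
#' rank-deficient design are skipped and counted; more than 10% skipped
#' is an error.
#'
#' @param data model-3 analysis table as for [fit_gxe_models()].
#' @param n_boot number of replicates (>= 100; default 1000).
#' @param seed integer seed.
#' @return An object of class `bootstrap_result`.
#' @export
bootstrap_interaction <- function(data, n_boot = 1000, seed = NULL) {
  if (n_boot < 100) stop("n_boot must be at least 100")
  required <- c("outcome", "adversity", "rprs", "sex", "pc1", "pc2", "pc3")
  data <- data[required]
  data <- data[stats::complete.cases(data), , drop = FALSE]
  n <- nrow(data)
  design <- with(data, cbind(
    `(Intercept)` = 1, sex = sex, pc1 = pc1, pc2 = pc2, pc3 = pc3,
    adversity = adversity, rprs = rprs, `adversity:rprs` = adversity * rprs))
  y <- data$outcome
  point <- fit_ols(y, design)
  est0 <- coef_value(point, "adversity:rprs")
  with_seed(seed, {
    reps <- rep(NA_real_, n_boot)
    skipped <- 0L
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      Xb <- design[idx, , drop = FALSE]
      qb <- qr(Xb)
      if (qb$rank < ncol(Xb)) {
        skipped <- skipped + 1L
        next
      }
      reps[b] <- qr.coef(qb, y[idx])["adversity:rprs"]
    }
    if (skipped > 0.1 * n_boot) {
      stop("bootstrap: ", skipped, " of ", n_boot,
           " replicates were rank deficient")
    }
    reps <- reps[!is.na(reps)]
    ci <- unname(stats::quantile(reps, c(0.025, 0.975), type = 7))
    structure(
      list(estimate = est0, se = stats::sd(reps),
           ci_low = ci[1], ci_high = ci[2],
           n_boot = n_boot, n_used = length(reps), n_skipped = skipped,
           seed = seed),
      class = "bootstrap_result"
    )
  })
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "bootstrap_result: estimate = %.4f, SE = %.4f, 95%% CI (%.4f, %.4f), %d replicates\n",
    x$estimate, x$se, x$ci_low, x$ci_high, x$n_used))
  invisible(x)
}

#' Pool fits across multiply-imputed datasets (Rubin's rules)
#'
#' Pooled estimate = mean of the per-imputation estimates; total
#' variance = W + (1 + 1/m) B with W the mean squared SE (within) and B
#' the between-imputation variance of the estimates; degrees of freedom
#' follow Rubin's small-sample formula, with B = 0 treated as infinite
#' df.
#'
#' @param fits list of `m >= 2` [fit_ols()] fits with identical
#'   coefficient sets.
#' @return An object of class `pooled_estimates`: a data frame with one
#'   row per coefficient (`estimate`, `W`, `B`, `se`, `df`, `p`).
#' @export
pool_estimates <- function(fits) {
  m <- length(fits)
  if (m < 2) stop("pooling needs at least 2 imputed fits")
  terms <- fits[[1]]$coefficients$term
  for (f in fits) {
    if (!identical(f$coefficients$term, terms)) {
      stop("fits have mismatched coefficient names")
    }
  }
  est <- sapply(fits, function(f) f$coefficients$estimate)
  ses <- sapply(fits, function(f) f$coefficients$se)
  if (is.null(dim(est))) {
    est <- matrix(est, nrow = 1); ses <- matrix(ses, nrow = 1)
  }
  qbar <- rowMeans(est)
  W <- rowMeans(ses^2)
  B <- apply(est, 1, stats::var)
  total <- W + (1 + 1 / m) * B
  df <- ifelse(B > 0, (m - 1) * (1 + W / ((1 + 1 / m) * B))^2, Inf)
  tstat <- qbar / sqrt(total)
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  out <- data.frame(term = terms, estimate = qbar, W = W, B = B,
                    se = sqrt(total), df = df, p = p,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(list(pooled = out, m = m), class = "pooled_estimates")
}

#' @export
print.pooled_estimates <- function(x, ...) {
  cat("pooled_estimates over", x$m, "imputed sets\n")
  print(x$pooled, row.names = FALSE, digits = 4)
  invisible(x)
}
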