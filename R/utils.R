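# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG state
#'
#' Restores the caller's `.Random.seed` on exit so seeded generators are
#' pure functions of their inputs and never perturb user code.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Mean-impute missing dosages column-wise; all-missing columns become 0.
impute_dosage_means <- function(d) {
  if (!anyNA(d)) return(d)
  mu <- colMeans(d, na.rm = TRUE)
  mu[!is.finite(mu)] <- 0
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- mu[idx[, 2L]]
  d
}

#' Marginal association of each column of X with y, adjusting covariates
#'
#' Frisch-Waugh residualization: y and every column of X are regressed on
#' the covariate design (with intercept); the per-column slope, classical
#' SE, t, p and incremental R-squared equal those from the full OLS fit
#' `y ~ covariates + x_j`. Used by the threshold scan and SNP refinement,
#' and cross-checked against `lm()` in the test suite.
#' @noRd
marginal_assoc <- function(y, X, covariates = NULL) {
  X <- as.matrix(X)
  n <- length(y)
  C <- cbind(`(Intercept)` = rep(1, n), covariates)
  qc <- qr(C)
  if (qc$rank < ncol(C)) stop("covariate design is rank deficient")
  ry <- qr.resid(qc, y)
  RX <- qr.resid(qc, X)
  sxx <- colSums(RX^2)
  sxy <- colSums(RX * ry)
  df <- n - ncol(C) - 1L
  if (df < 1L) stop("not enough observations for marginal regression")
  beta <- ifelse(sxx > 0, sxy / sxx, NA_real_)
  rss_cov <- sum(ry^2)
  rss_full <- rss_cov - ifelse(sxx > 0, sxy^2 / sxx, 0)
  sigma2 <- rss_full / df
  se <- sqrt(sigma2 / sxx)
  tstat <- beta / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  tss <- sum((y - mean(y))^2)
  data.frame(
    beta = beta, se = se, t = tstat, p = p,
    r2_incremental = ifelse(sxx > 0, (sxy^2 / sxx) / tss, NA_real_),
    row.names = colnames(X)
  )
}

stop_named <- function(class, ...) {
  stop(structure(
    class = c(class, "rprsgxe_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
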