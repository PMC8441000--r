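# Cumulative adversity scoring, hot-deck multiple imputation, and
# delay-of-gratification (Snack Delay) outcome scoring.

#' Define one component of the cumulative adversity score
#'
#' Components are either already binary (0/1 indicators such as smoking
#' during pregnancy) or continuous instrument summaries that are
#' dichotomized at an extreme percentile: `continuous_high_tail`
#' components (e.g. depression scores) score a point above the 85th
#' percentile, `continuous_low_tail` components (e.g. birth-size
#' percentile) below the 15th.
#'
#' @param name component label.
#' @param values per-sample numeric values; `NA` allowed.
#' @param kind `"binary"`, `"continuous_low_tail"` or
#'   `"continuous_high_tail"`.
#' @param cutoff_percentile optional override; defaults to 15 for the
#'   low tail and 85 for the high tail, and must match the kind.
#' @return An object of class `adversity_component`.
#' @export
adversity_component <- function(name, values,
                                kind = c("binary", "continuous_low_tail",
                                         "continuous_high_tail"),
                                cutoff_percentile = NULL) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (kind == "binary") {
    bad <- values[!is.na(values)]
    if (any(!bad %in% c(0, 1))) {
      stop("binary component '", name, "' has values outside {0, 1}")
    }
    if (!is.null(cutoff_percentile)) {
      stop("binary components take no cutoff_percentile")
    }
  } else {
    default_cut <- if (kind == "continuous_low_tail") 15 else 85
    cutoff_percentile <- cutoff_percentile %||% default_cut
    if (cutoff_percentile != default_cut) {
      stop("cutoff_percentile must be ", default_cut, " for kind ", kind)
    }
  }
  structure(list(name = name, values = values, kind = kind,
                 cutoff_percentile = cutoff_percentile),
            class = "adversity_component")
}

#' Dichotomize an adversity component into 0/1 points
#'
#' Binary components pass through. Continuous components score a point
#' strictly beyond their empirical percentile cutoff (linear
#' interpolation, `stats::quantile()` type 7): below the 15th percentile
#' for low-tail kinds, above the 85th for high-tail kinds. Values tied
#' exactly with the cutoff score 0. Missing values propagate.
#'
#' @param comp an [adversity_component].
#' @return Integer vector of 0/1 points with `NA` for missing.
#' @export
dichotomize_component <- function(comp) {
  stopifnot(inherits(comp, "adversity_component"))
  v <- comp$values
  if (all(is.na(v))) stop("component '", comp$name, "' is entirely missing")
  if (comp$kind == "binary") return(as.integer(v))
  obs <- v[!is.na(v)]
  if (length(obs) < 10) {
    stop("component '", comp$name,
         "' needs >= 10 non-missing values for percentile dichotomization")
  }
  cut <- stats::quantile(obs, comp$cutoff_percentile / 100, names = FALSE,
                         type = 7)
  pts <- if (comp$kind == "continuous_low_tail") v < cut else v > cut
  as.integer(pts)
}

#' Cumulative adversity score
#'
#' Sums the dichotomized points over all components. In complete-case
#' mode (the primary analysis), any sample missing any component gets a
#' missing composite score and is flagged `complete_case = FALSE`.
#' With `complete_case = FALSE` the sum runs over observed components.
#'
#' @param components non-empty list of [adversity_component] objects
#'   sharing one sample index.
#' @param complete_case logical; propagate missingness (default) or sum
#'   available points.
#' @return An object of class `adversity_score` with per-sample `score`,
#'   `complete_case` flags and `n_components`.
#' @export
adversity_score <- function(components, complete_case = TRUE) {
  if (length(components) == 0) stop("empty component list")
  pts <- vapply(components, dichotomize_component,
                integer(length(components[[1]]$values)))
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1)
  cc <- rowSums(is.na(pts)) == 0
  score <- if (complete_case) {
    ifelse(cc, rowSums(pts), NA_integer_)
  } else {
    rowSums(pts, na.rm = TRUE)
  }
  structure(list(score = as.integer(score), complete_case = cc,
                 n_components = length(components)),
            class = "adversity_score")
}

#' Hot-deck multiple imputation of adversity components
#'
#' Each missing cell is replaced by a value drawn uniformly (with
#' replacement) from the observed values of the same component; draws
#' are independent across cells and across the `m` imputed sets.
#' Observed cells are never altered. Reproducible under `seed`.
#'
#' @param components list of [adversity_component] objects.
#' @param m number of completed datasets (default 30).
#' @param seed integer seed.
#' @return List of `m` completed component lists.
#' @export
hot_deck_impute <- function(components, m = 30, seed = NULL) {
  if (length(components) == 0) stop("empty component list")
  for (comp in components) {
    if (all(is.na(comp$values))) {
      stop("component '", comp$name, "' has no observed donor values")
    }
  }
  with_seed(seed, {
    lapply(seq_len(m), function(set) {
      lapply(components, function(comp) {
        v <- comp$values
        miss <- is.na(v)
        if (any(miss)) {
          v[miss] <- sample(v[!miss], sum(miss), replace = TRUE)
          comp$values <- v
        }
        comp
      })
    })
  })
}

#' Score one Snack Delay trial
#'
#' The per-trial total is the behavior code (1-7; 7 = waits for the bell
#' before touching cup or candy) plus the latency code (1 = hands stay
#' on the table before OR after the bell is lifted, 2 = before AND
#' after), giving a total in 2-9. Higher totals indicate better delay
#' ability (less impulsivity). Vectorized over trials.
#'
#' @param behavior_code integer(s) in 1-7.
#' @param latency_code integer(s) in 1-2.
#' @return Integer trial total(s) in 2-9.
#' @export
score_snack_trial <- function(behavior_code, latency_code) {
  if (any(is.na(behavior_code)) || any(behavior_code < 1 | behavior_code > 7) ||
      any(behavior_code != round(behavior_code))) {
    stop("behavior_code must be an integer in 1..7")
  }
  if (any(is.na(latency_code)) || any(latency_code < 1 | latency_code > 2) ||
      any(latency_code != round(latency_code))) {
    stop("latency_code must be an integer in 1..2")
  }
  as.integer(behavior_code + latency_code)
}

#' Assemble a Snack Delay task record
#'
#' @param behavior_codes integer vector of 4 per-trial behavior codes
#'   (1-7).
#' @param latency_codes integer vector of 4 per-trial latency codes
#'   (1-2).
#' @param global_cooperation global cooperation rating 0-3.
#' @param delay_s the four trial delays in seconds; the task protocol
#'   fixes these at 10, 20, 15 and 30.
#' @return An object of class `snack_delay_record`.
#' @export
snack_delay_record <- function(behavior_codes, latency_codes,
                               global_cooperation,
                               delay_s = c(10, 20, 15, 30)) {
  if (length(behavior_codes) != 4 || length(latency_codes) != 4) {
    stop("a Snack Delay record has exactly 4 trials")
  }
  if (!identical(as.numeric(delay_s), c(10, 20, 15, 30))) {
    stop("trial delays must be 10, 20, 15, 30 seconds")
  }
  if (length(global_cooperation) != 1 || is.na(global_cooperation) ||
      !global_cooperation %in% 0:3) {
    stop("global_cooperation must be a single integer in 0..3")
  }
  totals <- score_snack_trial(behavior_codes, latency_codes)
  structure(list(behavior_codes = as.integer(behavior_codes),
                 latency_codes = as.integer(latency_codes),
                 trial_totals = totals,
                 delay_s = as.numeric(delay_s),
                 global_cooperation = as.integer(global_cooperation)),
            class = "snack_delay_record")
}

#' Snack Delay outcome with the global-cooperation filter
#'
#' Children with a global cooperation score other than 3 (full
#' engagement) are excluded: the function returns `NA` with attribute
#' `excluded = TRUE`. Otherwise the outcome aggregates the four trial
#' totals, by mean (default) or sum.
#'
#' @param rec a [snack_delay_record].
#' @param aggregate `"mean"` or `"sum"`.
#' @return Numeric outcome, or `NA` (attribute `excluded = TRUE`) for
#'   excluded children.
#' @export
snack_delay_outcome <- function(rec, aggregate = c("mean", "sum")) {
  stopifnot(inherits(rec, "snack_delay_record"))
  aggregate <- match.arg(aggregate)
  if (rec$global_cooperation != 3L) {
    return(structure(NA_real_, excluded = TRUE))
  }
  if (aggregate == "mean") mean(rec$trial_totals) else sum(rec$trial_totals)
}
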