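# Non-compartmental summary metrics and the profile-level Log2 error metrics.

#' Construct a concentration-time profile
#'
#' @param times Strictly increasing times (h).
#' @param concentrations Finite, non-negative concentrations (mg/L).
#' @param compound_id,study_id Optional labels.
#' @param compartment Sampled compartment label (venous plasma).
#' @return An `htpbk_profile` data.frame with columns `time_h`,
#'   `conc_mg_per_L` and label attributes.
#' @export
profile <- function(times, concentrations, compound_id = NA_character_,
                    study_id = NA_character_, compartment = "venous_plasma") {
  if (length(times) != length(concentrations))
    stop("times and concentrations must have equal length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(concentrations)) || any(concentrations < 0))
    stop("concentrations must be finite and >= 0")
  structure(data.frame(time_h = as.numeric(times),
                       conc_mg_per_L = as.numeric(concentrations)),
            compound_id = compound_id, study_id = study_id,
            compartment = compartment,
            class = c("htpbk_profile", "data.frame"))
}

#' Non-compartmental summary of a profile
#'
#' Cmax is the maximum concentration, Tmax the time of its first occurrence
#' (ties broken by earliest time), and AUC(0-last) uses the linear-up /
#' log-down trapezoid: the linear rule on non-decreasing segments, the
#' logarithmic rule `(C1 - C2) / ln(C1/C2) * dt` on decreasing segments with
#' both endpoints positive, and the linear rule as fallback when either
#' endpoint is zero.
#'
#' @param prof An `htpbk_profile` (or data.frame with `time_h`,
#'   `conc_mg_per_L`), at least 2 points.
#' @return List with `cmax` (mg/L), `tmax` (h), `auc_0_last` (mg*h/L).
#' @export
nca <- function(prof) {
  t <- prof$time_h; c <- prof$conc_mg_per_L
  if (length(t) < 2) stop("nca requires at least 2 points")
  auc <- 0
  for (i in seq_len(length(t) - 1)) {
    dt <- t[i + 1] - t[i]
    c1 <- c[i]; c2 <- c[i + 1]
    auc <- auc + if (c2 < c1 && c1 > 0 && c2 > 0)
      (c1 - c2) / log(c1 / c2) * dt else (c1 + c2) / 2 * dt
  }
  imax <- which.max(c)  # which.max returns the first maximum
  list(cmax = c[imax], tmax = t[imax], auc_0_last = auc)
}

#' Relative and absolute Log2 errors of a predicted profile
#'
#' Over the N usable datapoints of one profile:
#' relative = mean of log2(pred/obs) (systematic bias), absolute = mean of
#' |log2(pred/obs)| (overall closeness). Predictions must be evaluated at
#' exactly the observed timepoints. Observed values at or below `loq` are
#' excluded from N (count reported); non-positive predictions at usable
#' points are floored at 1e-12 mg/L with a warning.
#'
#' @param pred,obs `htpbk_profile`s on identical time grids.
#' @param loq Lower limit of quantification for the observations (default 0:
#'   exclude only non-positive values).
#' @return List with `relative_log2`, `absolute_log2`, `n_points`,
#'   `n_excluded`.
#' @export
profile_log2_errors <- function(pred, obs, loq = 0) {
  if (nrow(pred) != nrow(obs) ||
      any(abs(pred$time_h - obs$time_h) > 1e-9 * pmax(1, abs(obs$time_h))))
    stop("pred must be evaluated at the observed timepoints")
  usable <- obs$conc_mg_per_L > loq
  n_excluded <- sum(!usable)
  if (!any(usable)) stop("no usable (positive) observed datapoints")
  p <- pred$conc_mg_per_L[usable]
  o <- obs$conc_mg_per_L[usable]
  if (any(p <= 0)) {
    warning(sum(p <= 0), " non-positive predicted value(s) floored at 1e-12")
    p <- pmax(p, 1e-12)
  }
  r <- log2(p / o)
  list(relative_log2 = mean(r), absolute_log2 = mean(abs(r)),
       n_points = sum(usable), n_excluded = n_excluded)
}

#' Fold-range summary of predicted/observed pairs
#'
#' Percentage of pairs whose ratio lies within k-fold, i.e.
#' `|log2(pred/obs)| <= log2(k)`, for each k. Non-decreasing in k.
#'
#' @param pred,obs Positive paired scalars.
#' @param k_set Fold thresholds (default 1.5, 2, 3, 5, 10).
#' @return Named numeric vector of percentages, one per k.
#' @export
fold_summaries <- function(pred, obs, k_set = c(1.5, 2, 3, 5, 10)) {
  if (length(pred) == 0 || length(pred) != length(obs))
    stop("pred and obs must be non-empty and paired")
  if (any(pred <= 0) || any(obs <= 0)) stop("pairs must be positive")
  a <- abs(log2(pred / obs))
  setNames(vapply(k_set, function(k) 100 * mean(a <= log2(k)), numeric(1)),
           paste0("within_", k_set, "x"))
}
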