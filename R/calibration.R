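# Calibration diagnostics: binned observed-vs-predicted table and the
# logistic recalibration intercept (slope fixed at 1) and slope.

clip_risks <- function(risks, eps = 1e-8) {
  n_clip <- sum(risks < eps | risks > 1 - eps)
  if (n_clip > 0)
    message(n_clip, " risk(s) clipped to [", eps, ", 1 - ", eps,
            "] before logit")
  pmin(pmax(risks, eps), 1 - eps)
}

check_calibration_inputs <- function(risks, outcomes) {
  outcomes <- as.integer(as.logical(outcomes))
  if (length(risks) != length(outcomes))
    stop("risks and outcomes must have equal length")
  if (any(is.na(risks)) || any(is.na(outcomes)))
    stop("risks and outcomes must not contain missing values")
  if (all(outcomes == 0) || all(outcomes == 1))
    stop("complete separation: need at least one event and one non-event")
  outcomes
}

#' Binned calibration table
#'
#' Sorts pregnancies by predicted risk (stable in input order for ties) and
#' splits them into `n_bins` near-equal-count bins; reports the mean
#' predicted risk and the observed incidence per bin.
#'
#' @param risks Predicted probabilities.
#' @param outcomes Binary outcomes (logical or 0/1).
#' @param n_bins Number of bins (default 10).
#' @return Data frame with `bin`, `n`, `mean_predicted`,
#'   `observed_incidence`.
#' @export
calibration_bins <- function(risks, outcomes, n_bins = 10) {
  outcomes <- as.integer(as.logical(outcomes))
  stopifnot(length(risks) == length(outcomes))
  if (n_bins < 2) stop("n_bins must be >= 2")
  if (n_bins > length(risks)) stop("n_bins exceeds the number of rows")
  ord <- order(risks)                      # stable for ties
  bin <- rep(seq_len(n_bins),
             diff(floor(seq(0, length(risks), length.out = n_bins + 1))))
  bin <- bin[order(ord)]                   # back to input order
  data.frame(
    bin = seq_len(n_bins),
    n = as.vector(table(bin)),
    mean_predicted = as.vector(tapply(risks, bin, mean)),
    observed_incidence = as.vector(tapply(outcomes, bin, mean))
  )
}

#' Calibration intercept (calibration-in-the-large)
#'
#' Maximum-likelihood intercept of a logistic regression of outcomes on the
#' logit of the predicted risk with the slope fixed at 1, i.e. an
#' intercept-only Bernoulli fit with `qlogis(risk)` as offset. Zero indicates
#' risks that are correct on average.
#'
#' @inheritParams calibration_bins
#' @return List with `estimate` (log-odds) and `se`.
#' @export
calibration_intercept <- function(risks, outcomes) {
  outcomes <- check_calibration_inputs(risks, outcomes)
  lp <- qlogis(clip_risks(risks))
  fit <- glm(outcomes ~ 1, offset = lp, family = binomial(),
             control = list(epsilon = 1e-10, maxit = 100))
  list(estimate = unname(coef(fit)[1]),
       se = unname(sqrt(diag(vcov(fit)))[1]))
}

#' Calibration slope
#'
#' Slope of the two-parameter logistic regression of outcomes on the logit of
#' the predicted risk. One indicates correctly spread risks; below one,
#' over-dispersed (too extreme) predictions.
#'
#' @inheritParams calibration_bins
#' @return List with `estimate`, `se` and `intercept` (the companion
#'   two-parameter intercept).
#' @export
calibration_slope <- function(risks, outcomes) {
  outcomes <- check_calibration_inputs(risks, outcomes)
  lp <- qlogis(clip_risks(risks))
  if (stats::var(lp) == 0)
    stop("risks have zero variance; slope is not identifiable")
  fit <- glm(outcomes ~ lp, family = binomial(),
             control = list(epsilon = 1e-10, maxit = 100))
  list(estimate = unname(coef(fit)[2]),
       se = unname(sqrt(diag(vcov(fit)))[2]),
       intercept = unname(coef(fit)[1]))
}

#' Full calibration summary for a scored cohort
#'
#' @param risks Predicted probabilities (e.g. the `r_all` column of
#'   [score_cohort()]).
#' @param outcomes Binary outcomes.
#' @param n_bins Bins for the calibration table.
#' @return Object of class `pe_calibration`: `intercept`, `slope` (each with
#'   estimate and standard error) and the bin table.
#' @export
calibrate_risks <- function(risks, outcomes, n_bins = 10) {
  structure(list(
    intercept = calibration_intercept(risks, outcomes),
    slope = calibration_slope(risks, outcomes),
    bins = calibration_bins(risks, outcomes, n_bins)
  ), class = "pe_calibration")
}

#' @export
print.pe_calibration <- function(x, ...) {
  cat(sprintf("Calibration intercept: %+.4f (se %.4f)   [0 = perfect]\n",
              x$intercept$estimate, x$intercept$se))
  cat(sprintf("Calibration slope:     %.4f (se %.4f)   [1 = perfect]\n",
              x$slope$estimate, x$slope$se))
  cat(sprintf("Bins: %d (equal-count)\n", nrow(x$bins)))
  invisible(x)
}
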