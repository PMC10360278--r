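#' Ordinal outcome-model coefficients
#'
#' Cumulative-logit (proportional-odds) model of the 7-level modified Rankin
#' Scale at 90 days.  The linear predictor enters as `alpha_j - x*beta`, i.e.
#' `P(mRS <= j) = plogis(alpha_{j+1} - x*beta)`, so a *positive* slope means
#' the covariate is harmful (shifts mass toward worse outcomes).  In
#' particular `beta_otg > 0` encodes harm from treatment delay.
#'
#' @param cutpoints Six strictly increasing cut points `alpha_1..alpha_6` on
#'   the logit scale, one per cumulative split of the 7 mRS levels.
#' @param beta_otg Log-odds per minute of onset-to-groin time.
#' @param beta_age Log-odds per year of age.
#' @param beta_nihss Log-odds per NIHSS point.
#' @param beta_collateral Length-3 contrasts for collateral grades 1-3
#'   relative to grade 0 (absent collaterals); better collaterals should be
#'   protective, i.e. negative.
#' @param otg_scale Multiplier applied to OTG before the linear predictor
#'   (use 1/60 for coefficients fitted on hours).
#' @return An object of class `outcome_coefficients`.
#' @export
outcome_coefficients <- function(cutpoints, beta_otg, beta_age, beta_nihss,
                                 beta_collateral, otg_scale = 1) {
  assert_that(length(cutpoints) == 6 && all(diff(cutpoints) > 0),
              "outcome_coefficients: cutpoints must be 6 strictly increasing values")
  assert_that(length(beta_collateral) == 3,
              "outcome_coefficients: beta_collateral must have length 3")
  for (b in list(beta_otg, beta_age, beta_nihss))
    assert_that(is_scalar_number(b),
                "outcome_coefficients: slopes must be finite scalars")
  structure(list(cutpoints = as.numeric(cutpoints), beta_otg = beta_otg,
                 beta_age = beta_age, beta_nihss = beta_nihss,
                 beta_collateral = as.numeric(beta_collateral),
                 otg_scale = otg_scale),
            class = "outcome_coefficients")
}

#' Default (non-fitted) outcome coefficients
#'
#' A declared fixture with plausible magnitudes — NOT coefficients estimated
#' from any patient registry: 0.004 per-minute harm from delay, mild age and
#' NIHSS harm, protective collateral contrasts, and cut points placed so a
#' typical LVO cohort sits near 50% favorable outcome.  Replace via
#' [read_config()] when fitted coefficients are available.
#'
#' @return An [outcome_coefficients()] object.
#' @export
default_coefficients <- function() {
  outcome_coefficients(
    cutpoints = c(0.8, 2.1, 3.3, 4.3, 5.3, 6.5),
    beta_otg = 0.004, beta_age = 0.03, beta_nihss = 0.08,
    beta_collateral = c(-0.6, -1.2, -1.8))
}

.linear_predictor <- function(coeffs, otg, age, nihss, collateral) {
  assert_that(all(collateral %in% 0:3),
              "outcome model: collateral grade must be in 0..3")
  contrast <- c(0, coeffs$beta_collateral)[collateral + 1]
  coeffs$beta_otg * coeffs$otg_scale * otg + coeffs$beta_age * age +
    coeffs$beta_nihss * nihss + contrast
}

#' Predicted mRS probability distribution
#'
#' Evaluates the cumulative-logit model for one or more patients and returns
#' the 7 category probabilities (mRS 0-6) as successive differences of the
#' cumulative terms; each row is non-negative and sums to 1.
#'
#' @param coeffs An [outcome_coefficients()].
#' @param otg Onset-to-groin time in minutes (vectorized).
#' @param age Age in years.
#' @param nihss NIHSS score.
#' @param collateral Collateral grade 0-3.
#' @return An `n x 7` matrix of probabilities with columns `mrs0..mrs6`.
#' @export
mrs_distribution <- function(coeffs, otg, age, nihss, collateral) {
  xb <- .linear_predictor(coeffs, otg, age, nihss, collateral)
  cum <- vapply(coeffs$cutpoints, function(a) stats::plogis(a - xb),
                numeric(length(xb)))
  cum <- matrix(cum, nrow = length(xb))
  cum <- cbind(cum, 1)
  probs <- cbind(cum[, 1, drop = FALSE],
                 cum[, -1, drop = FALSE] - cum[, -7, drop = FALSE])
  colnames(probs) <- paste0("mrs", 0:6)
  probs
}

#' Predicted probability of favorable outcome
#'
#' `P(mRS <= 2)`, the third cumulative term of the model; strictly decreasing
#' in OTG whenever `beta_otg > 0`.
#'
#' @inheritParams mrs_distribution
#' @return Numeric vector of probabilities.
#' @export
ppfo <- function(coeffs, otg, age, nihss, collateral) {
  xb <- .linear_predictor(coeffs, otg, age, nihss, collateral)
  stats::plogis(coeffs$cutpoints[3] - xb)
}

#' Fit the ordinal outcome model
#'
#' Maximum-likelihood cumulative-logit fit via [MASS::polr()], which uses the
#' same `alpha_j - x*beta` sign convention as [mrs_distribution()], so the
#' returned slopes read directly as per-unit harm.  Collateral grade is
#' treated as a factor with grade 0 as reference.
#'
#' @param cohort A `data.frame` with columns `mrs` (0-6), `otg`, `age`,
#'   `nihss`, `collateral`; at least 50 rows.
#' @return An [outcome_coefficients()] with attributes `se` (slope standard
#'   errors) and `converged`.
#' @export
fit_ordinal <- function(cohort) {
  assert_that(nrow(cohort) >= 50, "fit_ordinal: need at least 50 cases")
  need <- c("mrs", "otg", "age", "nihss", "collateral")
  missing <- setdiff(need, names(cohort))
  assert_that(length(missing) == 0, "fit_ordinal: missing column(s): %s",
              paste(missing, collapse = ", "))
  d <- data.frame(mrs = factor(cohort$mrs, levels = 0:6),
                  otg = cohort$otg, age = cohort$age, nihss = cohort$nihss,
                  collateral = factor(cohort$collateral, levels = 0:3))
  empty <- names(which(table(d$mrs) == 0))
  if (length(empty) > 0)
    stop_config(paste0("fit_ordinal: did not converge: mRS level(s) %s have ",
                       "no observations (degenerate or separated data)"),
                paste(empty, collapse = ", "))
  if (length(unique(cohort$collateral)) < 2)
    stop_config("fit_ordinal: collateral grade is constant; contrasts are not identifiable")
  fit <- tryCatch(
    suppressWarnings(MASS::polr(mrs ~ otg + age + nihss + collateral,
                                data = d, Hess = TRUE)),
    error = function(e) stop_config("fit_ordinal: did not converge (%s)",
                                    conditionMessage(e)))
  if (fit$convergence != 0 || any(abs(stats::coef(fit)) > 20))
    stop_config(paste0("fit_ordinal: optimizer did not converge cleanly ",
                       "(code %d, max |slope| %.1f); data may be separated"),
                fit$convergence, max(abs(stats::coef(fit))))
  co <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit)))[names(co)],
                 error = function(e) stop_config(
                   "fit_ordinal: singular Hessian; data may be separated"))
  bc <- co[c("collateral1", "collateral2", "collateral3")]
  if (any(is.na(bc)))
    stop_config("fit_ordinal: not all collateral grades observed; contrasts are not identifiable")
  out <- outcome_coefficients(
    cutpoints = as.numeric(fit$zeta),
    beta_otg = co[["otg"]], beta_age = co[["age"]],
    beta_nihss = co[["nihss"]],
    beta_collateral = as.numeric(bc))
  attr(out, "se") <- se
  attr(out, "converged") <- TRUE
  attr(out, "loglik") <- as.numeric(stats::logLik(fit))
  out
}

#' Simulate mRS outcomes from known coefficients
#'
#' Inverse-CDF draws from the per-patient mRS distribution; the recovery
#' oracle for [fit_ordinal()] tests and calibration checks.
#'
#' @inheritParams mrs_distribution
#' @return Integer vector of mRS levels 0-6.
#' @export
simulate_mrs <- function(coeffs, otg, age, nihss, collateral) {
  probs <- mrs_distribution(coeffs, otg, age, nihss, collateral)
  u <- stats::runif(nrow(probs))
  cum <- t(apply(probs, 1, cumsum))
  as.integer(rowSums(u > cum))
}
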