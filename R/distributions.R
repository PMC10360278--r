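#' Interval-time distribution specifications
#'
#' A `dist_spec` describes how one pathway interval (in minutes) is sampled:
#' a parametric family, an optional location shift and an optional truncation
#' range.  All pathway steps are right-skewed positive service times, so the
#' default family set is lognormal / gamma / Weibull / exponential, with
#' triangular, uniform, point mass and empirical specs available for expert
#' estimates and degenerate test inputs.
#'
#' Family parameters follow base R conventions:
#' \describe{
#'   \item{lognormal}{`meanlog`, `sdlog`}
#'   \item{gamma}{`shape`, `rate`}
#'   \item{weibull}{`shape`, `scale`}
#'   \item{exponential}{`rate`}
#'   \item{triangular}{`min`, `mode`, `max`}
#'   \item{uniform}{`min`, `max`}
#'   \item{point_mass}{`value`}
#'   \item{empirical}{`values` (resampled with replacement)}
#' }
#'
#' @param family Distribution family name, one of the set above.
#' @param ... Named family parameters.
#' @param shift Non-negative location offset in minutes added to every draw.
#' @param truncation Optional `c(low, high)` in minutes (on the shifted
#'   scale); sampling is restricted to this range by inverse-CDF.
#' @return An object of class `dist_spec`.
#' @examples
#' spec <- dist_spec("lognormal", meanlog = log(6), sdlog = 0.5, shift = 3)
#' spec_mean(spec)
#' @export
dist_spec <- function(family, ..., shift = 0, truncation = NULL) {
  family <- match.arg(family, spec_families())
  params <- list(...)
  assert_that(is_scalar_number(shift) && shift >= 0,
              "dist_spec: 'shift' must be a single non-negative number")
  spec <- structure(list(family = family, params = params,
                         shift = shift, truncation = truncation),
                    class = "dist_spec")
  validate_spec(spec)
  spec
}

#' Supported distribution families
#' @return Character vector of family names accepted by [dist_spec()].
#' @export
spec_families <- function() {
  c("lognormal", "gamma", "weibull", "exponential",
    "triangular", "uniform", "point_mass", "empirical")
}

.spec_required_params <- list(
  lognormal = c("meanlog", "sdlog"), gamma = c("shape", "rate"),
  weibull = c("shape", "scale"), exponential = "rate",
  triangular = c("min", "mode", "max"), uniform = c("min", "max"),
  point_mass = "value", empirical = "values")

validate_spec <- function(spec) {
  p <- spec$params
  need <- .spec_required_params[[spec$family]]
  missing <- setdiff(need, names(p))
  assert_that(length(missing) == 0,
              "dist_spec(%s): missing parameter(s) %s",
              spec$family, paste(missing, collapse = ", "))
  ok <- switch(spec$family,
    lognormal   = is.finite(p$meanlog) && p$sdlog >= 0,
    gamma       = p$shape > 0 && p$rate > 0,
    weibull     = p$shape > 0 && p$scale > 0,
    exponential = p$rate > 0,
    triangular  = p$min <= p$mode && p$mode <= p$max && p$min >= 0,
    uniform     = p$min <= p$max && p$min >= 0,
    point_mass  = is_scalar_number(p$value) && p$value >= 0,
    empirical   = length(p$values) >= 1 && all(is.finite(p$values)) &&
                  all(p$values >= 0))
  assert_that(isTRUE(ok), "dist_spec(%s): invalid parameters", spec$family)
  if (!is.null(spec$truncation)) {
    tr <- spec$truncation
    assert_that(length(tr) == 2 && tr[1] < tr[2],
                "dist_spec(%s): truncation must be c(low, high) with low < high",
                spec$family)
    mass <- spec_cdf(spec, tr[2]) - spec_cdf(spec, tr[1])
    assert_that(mass > 0,
      "dist_spec(%s): truncation range [%g, %g] carries no probability mass",
      spec$family, tr[1], tr[2])
  }
  invisible(spec)
}

#' @export
print.dist_spec <- function(x, ...) {
  pstr <- paste(names(x$params),
                vapply(x$params, function(v) paste(signif(v, 4), collapse = ","),
                       character(1)),
                sep = "=", collapse = ", ")
  cat(sprintf("<dist_spec> %s(%s)", x$family, pstr))
  if (x$shift > 0) cat(sprintf(" + shift %g", x$shift))
  if (!is.null(x$truncation))
    cat(sprintf(" | [%g, %g]", x$truncation[1], x$truncation[2]))
  cat("\n")
  invisible(x)
}

# CDF / quantile of the *shifted* (untruncated) distribution --------------

ptri <- function(q, min, mode, max) {
  q <- pmin(pmax(q, min), max)
  ifelse(q < mode,
         (q - min)^2 / ((max - min) * (mode - min + (mode == min))),
         1 - (max - q)^2 / ((max - min) * (max - mode + (max == mode))))
}

qtri <- function(p, min, mode, max) {
  fc <- if (max > min) (mode - min) / (max - min) else 0
  ifelse(p < fc,
         min + sqrt(p * (max - min) * (mode - min)),
         max - sqrt((1 - p) * (max - min) * (max - mode)))
}

spec_cdf <- function(spec, q) {
  x <- q - spec$shift
  p <- spec$params
  switch(spec$family,
    lognormal   = stats::plnorm(x, p$meanlog, p$sdlog),
    gamma       = stats::pgamma(x, p$shape, p$rate),
    weibull     = stats::pweibull(x, p$shape, p$scale),
    exponential = stats::pexp(x, p$rate),
    triangular  = ptri(x, p$min, p$mode, p$max),
    uniform     = stats::punif(x, p$min, p$max),
    point_mass  = as.numeric(x >= p$value),
    empirical   = stats::ecdf(p$values)(x))
}

#' Quantile of a distribution specification
#'
#' @param spec A [dist_spec()].
#' @param prob Vector of probabilities.
#' @return Quantiles in minutes (shift included; truncation ignored).
#' @export
spec_quantile <- function(spec, prob) {
  p <- spec$params
  q <- switch(spec$family,
    lognormal   = stats::qlnorm(prob, p$meanlog, p$sdlog),
    gamma       = stats::qgamma(prob, p$shape, p$rate),
    weibull     = stats::qweibull(prob, p$shape, p$scale),
    exponential = stats::qexp(prob, p$rate),
    triangular  = qtri(prob, p$min, p$mode, p$max),
    uniform     = stats::qunif(prob, p$min, p$max),
    point_mass  = rep(p$value, length(prob)),
    empirical   = stats::quantile(p$values, prob, names = FALSE, type = 7))
  q + spec$shift
}

#' Closed-form mean of a distribution specification
#'
#' Used as the independent oracle for linearity-of-expectation checks on the
#' simulated pathway.  Truncated specs are refused (no general closed form).
#'
#' @param spec A [dist_spec()].
#' @return Mean in minutes.
#' @export
spec_mean <- function(spec) {
  assert_that(is.null(spec$truncation),
              "spec_mean: no closed form for truncated specs")
  p <- spec$params
  m <- switch(spec$family,
    lognormal   = exp(p$meanlog + p$sdlog^2 / 2),
    gamma       = p$shape / p$rate,
    weibull     = p$scale * gamma(1 + 1 / p$shape),
    exponential = 1 / p$rate,
    triangular  = (p$min + p$mode + p$max) / 3,
    uniform     = (p$min + p$max) / 2,
    point_mass  = p$value,
    empirical   = mean(p$values))
  m + spec$shift
}

#' Closed-form variance of a distribution specification
#' @inheritParams spec_mean
#' @return Variance in minutes squared.
#' @export
spec_var <- function(spec) {
  assert_that(is.null(spec$truncation),
              "spec_var: no closed form for truncated specs")
  p <- spec$params
  switch(spec$family,
    lognormal   = (exp(p$sdlog^2) - 1) * exp(2 * p$meanlog + p$sdlog^2),
    gamma       = p$shape / p$rate^2,
    weibull     = p$scale^2 * (gamma(1 + 2 / p$shape) - gamma(1 + 1 / p$shape)^2),
    exponential = 1 / p$rate^2,
    triangular  = (p$min^2 + p$mode^2 + p$max^2 - p$min * p$mode -
                   p$min * p$max - p$mode * p$max) / 18,
    uniform     = (p$max - p$min)^2 / 12,
    point_mass  = 0,
    empirical   = stats::var(p$values) * (length(p$values) - 1) /
                  length(p$values))
}

#' Sample from a distribution specification
#'
#' Draws use the current R random stream, so `set.seed()` before calling makes
#' the sequence reproducible.  Truncation is honoured by inverse-CDF sampling
#' on the truncated probability range (never rejection), so draws always fall
#' inside `[low, high]`.
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws.
#' @return Numeric vector of `n` draws in minutes.
#' @examples
#' set.seed(1)
#' spec_sample(dist_spec("uniform", min = 5, max = 10), 3)
#' @export
spec_sample <- function(spec, n = 1) {
  validate_spec(spec)
  if (is.null(spec$truncation)) {
    p <- spec$params
    x <- switch(spec$family,
      lognormal   = stats::rlnorm(n, p$meanlog, p$sdlog),
      gamma       = stats::rgamma(n, p$shape, p$rate),
      weibull     = stats::rweibull(n, p$shape, p$scale),
      exponential = stats::rexp(n, p$rate),
      triangular  = qtri(stats::runif(n), p$min, p$mode, p$max),
      uniform     = stats::runif(n, p$min, p$max),
      point_mass  = rep(p$value, n),
      empirical   = sample(p$values, n, replace = TRUE))
    return(x + spec$shift)
  }
  tr <- spec$truncation
  if (spec$family == "empirical") {
    pool <- spec$params$values + spec$shift
    pool <- pool[pool >= tr[1] & pool <= tr[2]]
    assert_that(length(pool) > 0, "spec_sample: truncation leaves no values")
    return(sample(pool, n, replace = TRUE))
  }
  lo <- spec_cdf(spec, tr[1])
  hi <- spec_cdf(spec, tr[2])
  u <- stats::runif(n, lo, hi)
  pmin(pmax(spec_quantile(spec, u), tr[1]), tr[2])
}

# Fitting ------------------------------------------------------------------

.fitdist_name <- c(lognormal = "lnorm", gamma = "gamma", weibull = "weibull",
                   exponential = "exp", uniform = "unif")

.spec_from_fitdist <- function(family, est) {
  switch(family,
    lognormal   = dist_spec("lognormal", meanlog = est[["meanlog"]],
                            sdlog = est[["sdlog"]]),
    gamma       = dist_spec("gamma", shape = est[["shape"]], rate = est[["rate"]]),
    weibull     = dist_spec("weibull", shape = est[["shape"]],
                            scale = est[["scale"]]),
    exponential = dist_spec("exponential", rate = est[["rate"]]),
    uniform     = dist_spec("uniform", min = est[["min"]], max = est[["max"]]))
}

#' Fit a distribution to recorded interval times
#'
#' Maximum-likelihood fits of each candidate family (via
#' [fitdistrplus::fitdist()]) with selection by highest log-likelihood; the
#' Kolmogorov-Smirnov statistic of the winning fit is attached as a
#' goodness-of-fit report.  Missing values are dropped before fitting.  If all
#' observations are identical and `point_mass` is among the candidates, the
#' degenerate spec is returned directly.
#'
#' @param samples Numeric vector of recorded times in minutes (NA allowed).
#' @param families Character vector of candidate family names.
#' @return A [dist_spec()] with attributes `loglik`, `ks_statistic` and
#'   `candidates` (per-family log-likelihoods).
#' @export
fit_spec <- function(samples, families = c("lognormal", "gamma", "weibull",
                                           "exponential")) {
  x <- samples[is.finite(samples)]
  assert_that(length(x) >= 10, "fit_spec: need at least 10 finite samples")
  assert_that(all(x >= 0), "fit_spec: negative times are not valid")
  assert_that(length(families) >= 1, "fit_spec: need at least one family")
  families <- vapply(families, function(f) match.arg(f, spec_families()),
                     character(1))

  if ("point_mass" %in% families && length(unique(x)) == 1L) {
    out <- dist_spec("point_mass", value = x[1])
    attr(out, "loglik") <- Inf
    attr(out, "ks_statistic") <- 0
    attr(out, "candidates") <- c(point_mass = Inf)
    return(out)
  }

  cand <- list()
  ll <- c()
  for (fam in setdiff(families, c("point_mass", "empirical", "triangular"))) {
    fd <- tryCatch(
      suppressWarnings(fitdistrplus::fitdist(x, .fitdist_name[[fam]])),
      error = function(e) NULL)
    if (is.null(fd) || !is.finite(stats::logLik(fd))) next
    cand[[fam]] <- .spec_from_fitdist(fam, fd$estimate)
    ll[fam] <- as.numeric(stats::logLik(fd))
  }
  if (length(cand) == 0)
    stop_config("fit_spec: no candidate family converged (tried: %s)",
                paste(families, collapse = ", "))
  best <- names(which.max(ll))
  out <- cand[[best]]
  ks <- suppressWarnings(stats::ks.test(x, function(q) spec_cdf(out, q)))
  attr(out, "loglik") <- ll[[best]]
  attr(out, "ks_statistic") <- unname(ks$statistic)
  attr(out, "candidates") <- ll
  out
}

#' Five-number validation statistics
#'
#' The statistics used to validate simulated interval times against recorded
#' data: mean, median, standard deviation, minimum and maximum.
#'
#' @param samples Non-empty numeric vector (NA dropped).
#' @return Named numeric vector `mean`, `median`, `sd`, `min`, `max`.
#' @export
summary_stats <- function(samples) {
  x <- samples[is.finite(samples)]
  assert_that(length(x) >= 1, "summary_stats: empty input")
  c(mean = mean(x), median = stats::median(x),
    sd = if (length(x) > 1) stats::sd(x) else 0,
    min = min(x), max = max(x))
}

#' Build a spec from a published median and interquartile range
#'
#' Many service times are reported only as median (IQR), e.g. a ground-EMS
#' response time of 9 (7-12) minutes.  This solves for spec parameters whose
#' 25th/50th/75th percentiles reproduce the three published quantiles.  For
#' two-parameter right-skewed families the location `shift` is used as a third
#' free parameter, which makes the lognormal case exactly solvable in closed
#' form; gamma and Weibull are solved by numerical minimization of relative
#' quantile errors.  A fit whose quantile residuals exceed 1% is rejected.
#'
#' @param median,q1,q3 Published quantiles in minutes, `q1 < median < q3`.
#' @param family One of `"lognormal"`, `"gamma"`, `"weibull"`, `"uniform"`.
#' @return A [dist_spec()] reproducing the three quantiles within 1%.
#' @examples
#' gems <- spec_from_median_iqr(9, 7, 12, "lognormal")
#' spec_quantile(gems, c(0.25, 0.5, 0.75))
#' @export
spec_from_median_iqr <- function(median, q1, q3, family = "lognormal") {
  assert_that(q1 < median && median < q3,
              "spec_from_median_iqr: need q1 < median < q3")
  assert_that(q1 > 0, "spec_from_median_iqr: quantiles must be positive")
  family <- match.arg(family, c("lognormal", "gamma", "weibull", "uniform"))
  z75 <- stats::qnorm(0.75)
  target <- c(q1, median, q3)

  spec <- switch(family,
    uniform = {
      half <- (q3 - q1) / 2
      dist_spec("uniform", min = max(q1 - half, 0), max = q3 + half)
    },
    lognormal = {
      denom <- q1 + q3 - 2 * median
      s <- if (abs(denom) > 1e-12) (q1 * q3 - median^2) / denom else -Inf
      if (is.finite(s) && s >= 0 && s < q1) {
        sdlog <- log((q3 - s) / (median - s)) / z75
        dist_spec("lognormal", meanlog = log(median - s), sdlog = sdlog,
                  shift = s)
      } else {
        # infeasible shift: best two-parameter compromise, checked below
        sdlog <- (log(q3) - log(q1)) / (2 * z75)
        dist_spec("lognormal", meanlog = log(median), sdlog = sdlog)
      }
    },
    {
      .fit_three_quantiles(family, target)
    })

  got <- spec_quantile(spec, c(0.25, 0.5, 0.75))
  rel <- abs(got - target) / target
  if (max(rel) > 0.01)
    stop_config(
      "spec_from_median_iqr: %s cannot reproduce quantiles (%g, %g, %g); max residual %.2f%%",
      family, q1, median, q3, 100 * max(rel))
  spec
}

# Three-quantile matching for gamma/weibull: parameters (log shape,
# log rate-or-scale, shift fraction of q1) optimized by Nelder-Mead from
# several starts.
.fit_three_quantiles <- function(family, target) {
  probs <- c(0.25, 0.5, 0.75)
  mk <- function(par) {
    s <- stats::plogis(par[3]) * target[1] * 0.999
    if (family == "gamma")
      dist_spec("gamma", shape = exp(par[1]), rate = exp(par[2]), shift = s)
    else
      dist_spec("weibull", shape = exp(par[1]), scale = exp(par[2]), shift = s)
  }
  obj <- function(par) {
    sp <- tryCatch(mk(par), error = function(e) NULL)
    if (is.null(sp)) return(1e6)
    sum(((spec_quantile(sp, probs) - target) / target)^2)
  }
  starts <- list(c(log(4), log(4 / target[2]), 0),
                 c(log(2), log(2 / target[2]), 2),
                 c(log(8), log(8 / target[2]), -2))
  if (family == "weibull")
    starts <- lapply(starts, function(s) c(s[1] * 0.5, log(target[2]), s[3]))
  best <- NULL
  for (st in starts) {
    opt <- stats::optim(st, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  mk(best$par)
}

#' Export fitted specs with goodness-of-fit statistics
#'
#' Writes one row per named interval: family, parameters, shift, and (when
#' present from [fit_spec()]) log-likelihood and KS statistic.
#'
#' @param specs Named list of [dist_spec()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_fitted_specs <- function(specs, path) {
  rows <- lapply(names(specs), function(nm) {
    sp <- specs[[nm]]
    data.frame(interval = nm, family = sp$family,
               params = paste(names(sp$params),
                              vapply(sp$params,
                                     function(v) paste(signif(v, 8),
                                                       collapse = ";"),
                                     character(1)),
                              sep = "=", collapse = " "),
               shift = sp$shift,
               loglik = attr(sp, "loglik") %||% NA_real_,
               ks_statistic = attr(sp, "ks_statistic") %||% NA_real_)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
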