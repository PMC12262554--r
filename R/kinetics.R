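#' Single-exponential recovery fit
#'
#' Least squares for `a_inf + (a0 - a_inf) exp(-t / tau)`, the shared
#' model for FMN photocycle dark-state recovery (absorbance at 450 nm
#' versus seconds) and water-population recovery (amplitude versus
#' minutes). The initial tau comes from a log-linearized fit of the
#' tail-subtracted signal.
#'
#' @param curve a [recovery_curve()] with at least 4 points.
#' @return list of class `exp_fit`: `tau`, `a0`, `a_inf`, `se_tau`,
#'   `se_a0`, `se_a_inf`, `r_squared`, `flags` (character vector:
#'   "no_trend" for flat data -- tau is then NA -- and "weak_trend" when
#'   the time-trend is not monotone beyond noise), `time_unit`.
#' @export
fit_exponential_recovery <- function(curve) {
  stopifnot(inherits(curve, "recovery_curve"))
  t <- curve$time; y <- curve$amplitude
  if (length(t) < 4L)
    stop("fit_exponential_recovery: need at least 4 points")
  unit <- attr(curve, "time_unit")
  rng <- diff(range(y))
  if (rng == 0 || stats::sd(y) < 1e-12 * max(abs(y), 1)) {
    warning("fit_exponential_recovery: constant series, no recovery to fit")
    return(structure(list(tau = NA_real_, a0 = y[1], a_inf = y[1],
                          se_tau = NA_real_, se_a0 = NA_real_,
                          se_a_inf = NA_real_, r_squared = NA_real_,
                          flags = "no_trend", time_unit = unit),
                     class = "exp_fit"))
  }
  flags <- character(0)
  if (abs(stats::cor(t, y, method = "spearman")) < 0.3) {
    warning("fit_exponential_recovery: non-monotone trend; fit may be unreliable")
    flags <- c(flags, "weak_trend")
  }
  n_tail <- max(2L, ceiling(length(y) / 5))
  a_inf0 <- mean(y[order(t, decreasing = TRUE)[seq_len(n_tail)]])
  a00 <- y[which.min(t)]
  dev <- y - a_inf0
  ok <- which(abs(dev) > 0.02 * rng & sign(dev) == sign(a00 - a_inf0))
  tau0 <- if (length(ok) >= 2) {
    sl <- unname(stats::coef(stats::lm(log(abs(dev[ok])) ~ t[ok]))[2])
    if (is.finite(sl) && sl < 0) -1 / sl else diff(range(t)) / 3
  } else diff(range(t)) / 3
  df <- data.frame(t = t, y = y)
  fit <- minpack.lm::nlsLM(
    y ~ a_inf + (a0 - a_inf) * exp(-t / tau), data = df,
    start = list(a_inf = a_inf0, a0 = a00, tau = tau0),
    lower = c(-Inf, -Inf, .Machine$double.eps),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e)
                   stats::setNames(rep(NA_real_, 3),
                                   c("a_inf", "a0", "tau")))
  rss <- sum(stats::resid(fit)^2)
  tss <- sum((y - mean(y))^2)
  structure(list(tau = unname(cf["tau"]), a0 = unname(cf["a0"]),
                 a_inf = unname(cf["a_inf"]),
                 se_tau = unname(se["tau"]), se_a0 = unname(se["a0"]),
                 se_a_inf = unname(se["a_inf"]),
                 r_squared = 1 - rss / tss, flags = flags,
                 time_unit = unit),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  if (is.na(x$tau)) {
    cat("exp_fit: no recovery (constant series)\n")
  } else {
    cat(sprintf("exp_fit: tau = %.4g %s (SE %.2g), a0 = %.4g, a_inf = %.4g, R^2 = %.4f\n",
                x$tau, x$time_unit, x$se_tau, x$a0, x$a_inf, x$r_squared))
  }
  invisible(x)
}

#' Ratio of two fitted time constants
#'
#' `tau_a / tau_b` with first-order (delta-method) error propagation.
#' The ratio is also reported rounded to one decimal place, the precision
#' at which slow-photocycle factors are usually quoted.
#'
#' @param fit_a,fit_b `exp_fit` objects (same time unit).
#' @return list: `ratio`, `se`, `ratio_1dp`.
#' @export
time_constant_ratio <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "exp_fit"), inherits(fit_b, "exp_fit"))
  if (is.na(fit_a$tau) || is.na(fit_b$tau))
    stop("time_constant_ratio: one of the fits has no time constant")
  if (!identical(fit_a$time_unit, fit_b$time_unit))
    warning("time_constant_ratio: fits have different time units")
  ratio <- fit_a$tau / fit_b$tau
  se <- if (is.na(fit_a$se_tau) || is.na(fit_b$se_tau)) NA_real_ else
    ratio * sqrt((fit_a$se_tau / fit_a$tau)^2 +
                   (fit_b$se_tau / fit_b$tau)^2)
  list(ratio = ratio, se = se, ratio_1dp = round(ratio, 1))
}
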