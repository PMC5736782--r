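## ABC-transporter membrane ATPase kinetics: Michaelis-Menten fits of ATP
## turnover rate against substrate concentration (0-300 uM design), and a
## non-reactivity flag for membranes showing no turnover.

#' Fit Michaelis-Menten kinetics to an ATPase rate curve
#'
#' Least-squares fit of `v = Vmax * S / (Km + S)`.  Starting values are
#' `Vmax = max(rate)` and `Km` = the concentration nearest half-maximal
#' rate, both bounded positive.  Confidence intervals use the asymptotic
#' covariance with a t quantile.
#'
#' @param conc Substrate concentrations (uM); at least 4 distinct values,
#'   at least one positive.
#' @param rate ATP turnover rates (uM/min).
#' @param conf_level Confidence level for the intervals, default 0.95.
#' @return Object of class `"mm_fit"` with `km`, `vmax`,
#'   `efficiency` (= vmax/km, 1/min), `ci` (matrix), `vcov`, data.
#' @export
#' @examples
#' s <- c(0, 5, 10, 30, 60, 120, 300)
#' fit_mm(s, 10 * s / (30 + s))
fit_mm <- function(conc, rate, conf_level = 0.95) {
  if (is.data.frame(conc)) { rate <- conc[[2L]]; conc <- conc[[1L]] }
  if (length(unique(conc)) < 4L)
    stop("need at least 4 distinct concentrations", call. = FALSE)
  if (any(conc < 0)) stop("concentrations must be non-negative", call. = FALSE)
  if (!any(conc > 0)) stop("need at least one positive concentration",
                           call. = FALSE)
  if (any(!is.finite(rate))) stop("rates must be finite", call. = FALSE)
  if (all(abs(rate) < .Machine$double.eps^0.5))
    stop("all rates are (near) zero; kinetics unidentifiable", call. = FALSE)
  vmax0 <- max(rate)
  km0 <- conc[which.min(abs(rate - vmax0 / 2))]
  if (km0 <= 0) km0 <- max(conc) / 10
  dat <- data.frame(conc = conc, rate = rate)
  fit <- tryCatch(
    minpack.lm::nlsLM(rate ~ vmax * conc / (km + conc), data = dat,
                      start = list(vmax = vmax0, km = km0),
                      lower = c(vmax = 1e-12, km = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("Michaelis-Menten fit did not converge: ", conditionMessage(e),
           call. = FALSE))
  est <- coef(fit)
  vc <- tryCatch(vcov(fit), error = function(e) matrix(NA_real_, 2, 2))
  se <- sqrt(pmax(diag(vc), 0))
  df <- max(nrow(dat) - 2L, 1L)
  tq <- qt(1 - (1 - conf_level) / 2, df)
  ci <- cbind(lower = est - tq * se, upper = est + tq * se)
  structure(list(vmax = unname(est["vmax"]), km = unname(est["km"]),
                 efficiency = unname(est["vmax"] / est["km"]),
                 ci = ci, vcov = vc, conf_level = conf_level,
                 data = dat, nls = fit),
            class = "mm_fit")
}

#' @export
coef.mm_fit <- function(object, ...) c(vmax = object$vmax, km = object$km)

#' @export
vcov.mm_fit <- function(object, ...) object$vcov

#' @export
predict.mm_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$conc else
    if (is.data.frame(newdata)) newdata$conc else as.numeric(newdata)
  object$vmax * conc / (object$km + conc)
}

#' @export
fitted.mm_fit <- function(object, ...) predict(object)

#' @export
residuals.mm_fit <- function(object, ...) object$data$rate - fitted(object)

#' @export
print.mm_fit <- function(x, ...) {
  cat("Michaelis-Menten fit\n")
  cat(sprintf("  Vmax = %.4g uM/min  [%.4g, %.4g]\n",
              x$vmax, x$ci["vmax", 1L], x$ci["vmax", 2L]))
  cat(sprintf("  Km   = %.4g uM      [%.4g, %.4g]\n",
              x$km, x$ci["km", 1L], x$ci["km", 2L]))
  cat(sprintf("  Vmax/Km = %.4g 1/min\n", x$efficiency))
  invisible(x)
}

#' @export
plot.mm_fit <- function(x, ...) {
  plot(x$data$conc, x$data$rate, xlab = "substrate (uM)",
       ylab = "rate (uM/min)", ...)
  ss <- seq(0, max(x$data$conc), length.out = 200)
  graphics::lines(ss, predict(x, ss))
  invisible(x)
}

#' Flag a membrane preparation as non-reactive
#'
#' A curve is non-reactive when the Michaelis-Menten fit fails, or when the
#' fitted Vmax confidence interval covers zero (as seen for most of the
#' panel against the Bcrp membrane).
#'
#' @param conc,rate As in [fit_mm()].
#' @return `TRUE` when no resolvable ATP turnover is present.
#' @export
flag_nonreactive <- function(conc, rate) {
  fit <- tryCatch(fit_mm(conc, rate), error = function(e) NULL)
  if (is.null(fit)) return(TRUE)
  lo <- fit$ci["vmax", 1L]
  !is.finite(lo) || lo <= 0
}
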