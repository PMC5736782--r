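## Isolated perfused mouse lung (IPML) kinetics: serial-sampling-corrected
## cumulative absorption, the first-order accumulating-compartment fit,
## non-compartmental AUC(0-30) and lung-retention mass balance.

#' Perfusate concentration profile for one lung preparation
#'
#' Concentrations are interpreted as measured in the reservoir immediately
#' before each sample is withdrawn; the withdrawn volume is replaced with
#' blank perfusate, which dilutes the reservoir and is what the
#' serial-sampling correction in [cumulative_absorbed()] accounts for.
#'
#' @param times Sampling times in minutes, strictly increasing, first > 0.
#' @param concentrations Reservoir concentrations (nmol/mL) at `times`.
#' @param reservoir_volume Reservoir volume (mL), default 10.
#' @param sample_volume Replaced sample volume (mL), default 0.25.
#' @param deposited_dose Dose deposited in the lung lobes (nmol).
#' @param device_residual Drug left in syringe and cannula (nmol); excluded
#'   from the deposited dose by definition.
#' @return An object of class `"perfusate_profile"`.
#' @export
perfusate_profile <- function(times, concentrations,
                              reservoir_volume = 10, sample_volume = 0.25,
                              deposited_dose, device_residual = 0) {
  times <- as.numeric(times)
  concentrations <- as.numeric(concentrations)
  if (length(times) != length(concentrations))
    stop("times and concentrations must have equal length", call. = FALSE)
  if (length(times) == 0L) stop("empty profile", call. = FALSE)
  if (any(diff(times) <= 0) || times[1L] <= 0)
    stop("times must be strictly increasing with first time > 0",
         call. = FALSE)
  if (any(concentrations < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  if (sample_volume >= reservoir_volume || sample_volume <= 0 ||
      reservoir_volume <= 0)
    stop("need 0 < sample_volume < reservoir_volume", call. = FALSE)
  if (deposited_dose <= 0)
    stop("deposited_dose must be positive", call. = FALSE)
  structure(list(times = times, concentrations = concentrations,
                 reservoir_volume = reservoir_volume,
                 sample_volume = sample_volume,
                 deposited_dose = deposited_dose,
                 device_residual = device_residual),
            class = "perfusate_profile")
}

#' Serial-sampling-corrected cumulative absorption
#'
#' Each 250 uL reservoir sample removes drug mass and is replaced with blank
#' perfusate.  The cumulative mass absorbed up to sample i is therefore the
#' mass currently in the reservoir plus everything previously withdrawn:
#' `M_i = C_i * V_res + sum_{j<i} C_j * V_sample`.
#'
#' @param profile A [perfusate_profile()].
#' @return Data frame with columns `time` (min), `cum_nmol` and `cum_pct`
#'   (cumulative % of deposited dose).
#' @export
#' @examples
#' p <- perfusate_profile(c(5, 10), c(1, 1), deposited_dose = 20)
#' cumulative_absorbed(p)  # 10 and 10.25 nmol
cumulative_absorbed <- function(profile) {
  stopifnot(inherits(profile, "perfusate_profile"))
  conc <- profile$concentrations
  removed <- cumsum(c(0, conc[-length(conc)])) * profile$sample_volume
  cum_nmol <- conc * profile$reservoir_volume + removed
  data.frame(time = profile$times,
             cum_nmol = cum_nmol,
             cum_pct = 100 * cum_nmol / profile$deposited_dose)
}

#' Fit the first-order one-compartment accumulating absorption model
#'
#' Unweighted nonlinear least squares of
#' `%Dose(t) = 100 * F * (1 - exp(-Ka * t))`, giving the extent (`F`,
#' fraction of deposited dose) and first-order rate constant (`Ka`, 1/min)
#' of absorption into the accumulating perfusate compartment.  Per-parameter
#' CV% comes from the asymptotic covariance of the fit.  Starting values are
#' `F = max(pct)/100` and `Ka = 0.1` per min, with bounds `F` in (0, 1.1]
#' and `Ka` in [1e-5, 10].
#'
#' @param time Sampling times (min).
#' @param pct Cumulative % of deposited dose absorbed at `time`; typically
#'   the `cum_pct` column of [cumulative_absorbed()].
#' @return An object of class `"absorption_fit"` with components `f`, `ka`,
#'   `cv_percent` (named), `rss`, `vcov`, and the data.
#' @export
#' @examples
#' t <- c(2, 5, 10, 15, 20, 30)
#' fit <- fit_first_order(t, 100 * 0.5 * (1 - exp(-0.1 * t)))
#' coef(fit)
fit_first_order <- function(time, pct) {
  if (is.data.frame(time)) { pct <- time[[2L]]; time <- time[[1L]] }
  ok <- is.finite(time) & is.finite(pct)
  time <- time[ok]; pct <- pct[ok]
  if (length(time) < 2L)
    stop("need at least two observations to fit F and Ka", call. = FALSE)
  if (any(pct < 0) || any(pct > 110))
    stop("pct values must lie in [0, 110]", call. = FALSE)
  if (all(pct == 0))
    stop("all-zero profile: Ka is unidentifiable", call. = FALSE)
  dat <- data.frame(time = time, pct = pct)
  start <- list(f = max(pct) / 100, ka = 0.1)
  fit <- tryCatch(
    minpack.lm::nlsLM(pct ~ 100 * f * (1 - exp(-ka * time)),
                      data = dat, start = start,
                      lower = c(f = 1e-8, ka = 1e-5),
                      upper = c(f = 1.1, ka = 10),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("absorption model did not converge (best start F = ",
           signif(start$f, 3), ", Ka = ", start$ka, "): ",
           conditionMessage(e), call. = FALSE))
  est <- coef(fit)
  vc <- tryCatch(vcov(fit), error = function(e) matrix(NA_real_, 2, 2))
  se <- sqrt(pmax(diag(vc), 0))
  cv <- 100 * se / abs(est)
  structure(list(f = unname(est["f"]), ka = unname(est["ka"]),
                 cv_percent = c(f = unname(cv[1L]), ka = unname(cv[2L])),
                 rss = sum(residuals(fit)^2),
                 vcov = vc, data = dat, nls = fit),
            class = "absorption_fit")
}

#' @export
coef.absorption_fit <- function(object, ...) c(f = object$f, ka = object$ka)

#' @export
vcov.absorption_fit <- function(object, ...) object$vcov

#' @export
predict.absorption_fit <- function(object, newdata = NULL, ...) {
  time <- if (is.null(newdata)) object$data$time else
    if (is.data.frame(newdata)) newdata$time else as.numeric(newdata)
  100 * object$f * (1 - exp(-object$ka * time))
}

#' @export
fitted.absorption_fit <- function(object, ...) predict(object)

#' @export
residuals.absorption_fit <- function(object, ...)
  object$data$pct - fitted(object)

#' @export
print.absorption_fit <- function(x, ...) {
  cat("First-order accumulating absorption fit\n")
  cat(sprintf("  F  = %.4f  (CV %.1f%%)\n", x$f, x$cv_percent["f"]))
  cat(sprintf("  Ka = %.4f 1/min  (CV %.1f%%)\n", x$ka, x$cv_percent["ka"]))
  cat(sprintf("  RSS = %.4g on %d observations\n", x$rss, nrow(x$data)))
  invisible(x)
}

#' @export
summary.absorption_fit <- function(object, ...) {
  se <- sqrt(pmax(diag(object$vcov), 0))
  out <- data.frame(estimate = c(object$f, object$ka), se = se,
                    cv_percent = object$cv_percent,
                    row.names = c("f", "ka"))
  structure(list(coefficients = out, rss = object$rss,
                 n = nrow(object$data)), class = "summary.absorption_fit")
}

#' @export
print.summary.absorption_fit <- function(x, ...) {
  print(x$coefficients)
  cat(sprintf("RSS %.4g on %d observations\n", x$rss, x$n))
  invisible(x)
}

#' @export
plot.absorption_fit <- function(x, ...) {
  plot(x$data$time, x$data$pct, xlab = "time (min)",
       ylab = "% deposited dose absorbed", ...)
  tt <- seq(0, max(x$data$time), length.out = 200)
  graphics::lines(tt, predict(x, tt))
  invisible(x)
}

#' Non-compartmental AUC over 0-30 min
#'
#' Linear trapezoid on the cumulative %dose-absorbed series with a virtual
#' (0, 0) anchor prepended (no drug can be in the perfusate at t = 0).  If
#' the last sample falls before 30 min the last observed value is carried
#' flat to 30 min; samples beyond 30 min are not used.
#'
#' @param time Times (min), within \[0, 30\].
#' @param pct Cumulative % of deposited dose absorbed.
#' @return An object of class `"nca_result"` with `auc_0_30` (%Dose.min)
#'   and `method`.
#' @export
auc_0_30 <- function(time, pct) {
  if (is.data.frame(time)) { pct <- time[[2L]]; time <- time[[1L]] }
  if (length(time) == 0L) stop("empty series", call. = FALSE)
  if (any(diff(time) <= 0)) stop("times must be increasing", call. = FALSE)
  keep <- time <= 30
  time <- time[keep]; pct <- pct[keep]
  if (length(time) == 0L) stop("no samples at or before 30 min", call. = FALSE)
  if (time[1L] > 0) { time <- c(0, time); pct <- c(0, pct) }
  if (time[length(time)] < 30) {
    time <- c(time, 30)
    pct <- c(pct, pct[length(pct)])
  }
  auc <- sum(diff(time) * (pct[-1L] + pct[-length(pct)]) / 2)
  structure(list(auc_0_30 = auc, method = "trapezoid"), class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("AUC(0-30 min) = %.2f %%Dose.min (%s)\n", x$auc_0_30, x$method))
  invisible(x)
}

#' Lung-retention mass balance
#'
#' The deposited dose excludes drug recovered from the dosing syringe and
#' tracheal cannula (the device residual); whatever was deposited and not
#' absorbed to the perfusate is retained in the lung.
#'
#' @param deposited_dose Dose deposited in the lung lobes (nmol).
#' @param absorbed Mass absorbed to the perfusate (nmol).
#' @param device_residual Drug recovered from the device (nmol), reported
#'   alongside but not part of the deposited dose.
#' @return Object of class `"mass_balance"` with nmol amounts and
#'   percentages of deposited dose (`absorbed_pct` + `retained_pct` = 100).
#' @export
lung_retention <- function(deposited_dose, absorbed, device_residual = 0) {
  if (deposited_dose <= 0) stop("deposited_dose must be positive",
                                call. = FALSE)
  if (absorbed < 0) stop("absorbed mass cannot be negative", call. = FALSE)
  if (absorbed > deposited_dose)
    stop("absorbed mass exceeds deposited dose", call. = FALSE)
  retained <- deposited_dose - absorbed
  structure(list(deposited_dose = deposited_dose,
                 absorbed_to_perfusate = absorbed,
                 lung_retained = retained,
                 device_residual = device_residual,
                 absorbed_pct = 100 * absorbed / deposited_dose,
                 retained_pct = 100 * retained / deposited_dose),
            class = "mass_balance")
}

#' @export
print.mass_balance <- function(x, ...) {
  cat("Lung mass balance (nmol):\n")
  cat(sprintf("  deposited %.4g; absorbed %.4g (%.1f%%); retained %.4g (%.1f%%)\n",
              x$deposited_dose, x$absorbed_to_perfusate, x$absorbed_pct,
              x$lung_retained, x$retained_pct))
  if (x$device_residual > 0)
    cat(sprintf("  device residual %.4g (excluded from deposited dose)\n",
                x$device_residual))
  invisible(x)
}

#' Difference in percentage lung retention between genotypes
#'
#' @param retained_pct_wt,retained_pct_ko Percent of deposited dose retained
#'   in wild-type and knockout lungs.
#' @return `retained_pct_wt - retained_pct_ko`.
#' @export
#' @examples
#' retention_difference(74.5, 58.3)  # 16.2
retention_difference <- function(retained_pct_wt, retained_pct_ko)
  retained_pct_wt - retained_pct_ko

#' IPML preparation quality control
#'
#' A preparation is excluded when the co-instilled paracellular marker
#' mannitol exceeds 65% of deposited dose absorbed by 30 min (strict
#' inequality, as stated for the exclusion rule).  The lung wet:dry weight
#' ratio is reported as an advisory oedema flag only; no numeric threshold
#' is applied.
#'
#' @param mannitol_pct_30min Mannitol %deposited dose absorbed at 30 min.
#' @param wet_dry_ratio Optional lung wet:dry weight ratio.
#' @return List with `verdict` (`"KEEP"`/`"EXCLUDE"`), `mannitol_pct_30min`
#'   and `wet_dry_ratio`.
#' @export
ipml_qc <- function(mannitol_pct_30min, wet_dry_ratio = NA_real_) {
  verdict <- if (mannitol_pct_30min > 65) "EXCLUDE" else "KEEP"
  list(verdict = verdict,
       mannitol_pct_30min = mannitol_pct_30min,
       wet_dry_ratio = wet_dry_ratio)
}
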