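## Ussing-chamber intestinal permeability: TEER quality control, apparent
## permeability (Papp) from serial-sampling-corrected serosal accumulation,
## and knockout:wild-type fold changes.

#' Ussing chamber experiment record
#'
#' @param times Serosal sampling times (min) over \[0, 180\], increasing.
#' @param serosal_concentrations Receiver chamber concentrations (nmol/mL)
#'   measured immediately before each 1 mL replacement draw.
#' @param chamber_volume Receiver chamber volume (mL), default 3.
#' @param sample_volume Replaced sample volume (mL), default 1.
#' @param exposed_area Exposed tissue area (cm^2), default 0.12.
#' @param donor_c0 Initial donor (mucosal) concentration (nmol/mL).
#' @param teer_initial,teer_final TEER readings (Ohm.cm^2).
#' @param genotype `"WT"` or `"KO"`.
#' @return Object of class `"ussing_experiment"`.
#' @export
ussing_experiment <- function(times, serosal_concentrations,
                              chamber_volume = 3, sample_volume = 1,
                              exposed_area = 0.12, donor_c0,
                              teer_initial = NA_real_,
                              teer_final = NA_real_,
                              genotype = c("WT", "KO")) {
  genotype <- match.arg(genotype)
  times <- as.numeric(times)
  conc <- as.numeric(serosal_concentrations)
  if (length(times) != length(conc))
    stop("times and concentrations must have equal length", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be ascending", call. = FALSE)
  if (exposed_area <= 0) stop("exposed_area must be positive", call. = FALSE)
  if (donor_c0 <= 0) stop("donor_c0 must be positive", call. = FALSE)
  if (sample_volume >= chamber_volume || sample_volume <= 0)
    stop("need 0 < sample_volume < chamber_volume", call. = FALSE)
  structure(list(times = times, serosal_concentrations = conc,
                 chamber_volume = chamber_volume,
                 sample_volume = sample_volume,
                 exposed_area = exposed_area, donor_c0 = donor_c0,
                 teer_initial = teer_initial, teer_final = teer_final,
                 genotype = genotype),
            class = "ussing_experiment")
}

#' TEER quality control for an intestinal segment
#'
#' Segments with an initial TEER below 80 Ohm.cm^2, or whose TEER declines
#' by more than 10% over the experiment, are excluded (both thresholds
#' strict, as stated).
#'
#' @param e An [ussing_experiment()], or the initial TEER value.
#' @param teer_final Final TEER, when `e` is given as a number.
#' @return List with `verdict` (`"KEEP"`/`"EXCLUDE"`), `teer_initial`,
#'   `teer_final` and `decline_pct`.
#' @export
#' @examples
#' ussing_qc(83, 79)$verdict   # KEEP (4.8% decline)
#' ussing_qc(79, 79)$verdict   # EXCLUDE
ussing_qc <- function(e, teer_final = NULL) {
  if (inherits(e, "ussing_experiment")) {
    ti <- e$teer_initial; tf <- e$teer_final
  } else {
    ti <- e; tf <- teer_final
  }
  decline <- if (is.na(ti) || is.na(tf)) NA_real_ else 100 * (ti - tf) / ti
  exclude <- (!is.na(ti) && ti < 80) || (!is.na(decline) && decline > 10)
  list(verdict = if (exclude) "EXCLUDE" else "KEEP",
       teer_initial = ti, teer_final = tf, decline_pct = decline)
}

#' Apparent permeability from serosal accumulation
#'
#' The cumulative amount transported is reconstructed with the same
#' serial-sampling correction as the perfusate bookkeeping (each 1 mL
#' receiver sample is replaced with blank buffer):
#' `M_i = C_i * V_chamber + sum_{j<i} C_j * V_sample`.  The transport rate
#' dM/dt is the free-intercept OLS slope of cumulative amount against time
#' over the whole experiment, converted to nmol/s, and
#' `Papp = (dM/dt) / (A * C0)` in cm/s.
#'
#' @param e An [ussing_experiment()] (at least 3 samples).
#' @return Object of class `"papp_result"` with `papp` (cm/s), `slope_nmol_s`,
#'   `r_squared` of the slope regression and a `negative_slope` warning flag.
#' @export
papp <- function(e) {
  stopifnot(inherits(e, "ussing_experiment"))
  conc <- e$serosal_concentrations
  if (length(conc) < 3L) stop("need at least 3 samples", call. = FALSE)
  removed <- cumsum(c(0, conc[-length(conc)])) * e$sample_volume
  cum_nmol <- conc * e$chamber_volume + removed
  fit <- lm(cum_nmol ~ e$times)
  slope_min <- unname(coef(fit)[2L])
  tot <- sum((cum_nmol - mean(cum_nmol))^2)
  r2 <- if (tot > 0) 1 - sum(residuals(fit)^2) / tot else NA_real_
  slope_s <- slope_min / 60
  val <- slope_s / (e$exposed_area * e$donor_c0)
  neg <- slope_min < 0
  if (neg) warning("negative transport slope; Papp reported as computed")
  structure(list(papp = val, slope_nmol_s = slope_s, r_squared = r2,
                 negative_slope = neg, cumulative = cum_nmol,
                 times = e$times, genotype = e$genotype),
            class = "papp_result")
}

#' @export
print.papp_result <- function(x, ...) {
  cat(sprintf("Papp = %.3g cm/s (dM/dt = %.3g nmol/s, r^2 = %.3f)%s\n",
              x$papp, x$slope_nmol_s,
              if (is.na(x$r_squared)) NA else x$r_squared,
              if (x$negative_slope) " [negative slope]" else ""))
  invisible(x)
}

#' Knockout : wild-type permeability ratio
#'
#' @param papp_ko,papp_wt Apparent permeabilities (any shared unit); numbers
#'   or `"papp_result"` objects.
#' @return Object of class `"ko_wt_ratio"`: the full-precision fold change,
#'   printed to 2 decimal places.
#' @export
#' @examples
#' ko_wt_ratio(20.94e-6, 6.04e-6)  # 3.47
ko_wt_ratio <- function(papp_ko, papp_wt) {
  if (inherits(papp_ko, "papp_result")) papp_ko <- papp_ko$papp
  if (inherits(papp_wt, "papp_result")) papp_wt <- papp_wt$papp
  if (any(papp_wt <= 0)) stop("wild-type Papp must be positive", call. = FALSE)
  structure(papp_ko / papp_wt, class = "ko_wt_ratio")
}

#' @export
print.ko_wt_ratio <- function(x, ...) {
  cat(sprintf("KO:WT ratio = %.2f\n", unclass(x)))
  invisible(x)
}
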