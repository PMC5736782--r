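## Membrane-affinity assays: IAM chromatography capacity factor with
## extrapolation of retention to 100% aqueous mobile phase, and equilibrium
## partitioning into multilamellar liposome vesicles (MLVs).

#' Extrapolate IAM retention time to 100% water
#'
#' Retention times measured under isocratic elution at two or more organic
#' modifier fractions (% v/v acetonitrile) are extrapolated to a fully
#' aqueous mobile phase.  The default regresses retention time itself on the
#' organic fraction, as done for the published values; the common
#' chromatographic alternative of extrapolating in log capacity factor
#' space is available via `mode = "logk"`.
#'
#' @param fraction_pct Organic modifier fractions (% v/v), e.g. 10, 20, 30.
#' @param tr_s Retention times (seconds) at those fractions; all must exceed
#'   `t0_s`.
#' @param t0_s Solvent front / dead time (seconds), default 75.
#' @param mode `"time"` (default) extrapolates Tr linearly; `"logk"`
#'   extrapolates log10((Tr - T0)/T0) and back-transforms.
#' @return Extrapolated retention time in 100% water (seconds).
#' @export
#' @examples
#' extrapolate_retention(c(10, 20, 30), c(200, 150, 100))  # 250
extrapolate_retention <- function(fraction_pct, tr_s, t0_s = 75,
                                  mode = c("time", "logk")) {
  mode <- match.arg(mode)
  if (length(fraction_pct) != length(tr_s))
    stop("fraction_pct and tr_s must have equal length", call. = FALSE)
  if (length(fraction_pct) < 2L)
    stop("need at least two (fraction, Tr) pairs", call. = FALSE)
  if (any(tr_s <= t0_s))
    stop("every retention time must exceed the solvent front t0",
         call. = FALSE)
  tr_water <- if (mode == "time") {
    unname(coef(lm(tr_s ~ fraction_pct))[1L])
  } else {
    logk <- log10((tr_s - t0_s) / t0_s)
    k0 <- 10^unname(coef(lm(logk ~ fraction_pct))[1L])
    t0_s * (1 + k0)
  }
  if (tr_water <= t0_s)
    stop("extrapolated retention does not exceed the solvent front; ",
         "LogK(IAM) is undefined", call. = FALSE)
  tr_water
}

#' IAM capacity factor (LogK)
#'
#' `log10((Tr - T0) / T0)` where `Tr` is the (extrapolated) retention time
#' in 100% water and `T0` the solvent front.
#'
#' @param tr_water Retention time in 100% water (seconds).
#' @param t0_s Solvent front (seconds), default 75.
#' @return LogK(IAM), dimensionless (base-10).
#' @export
#' @examples
#' logk_iam(150)          # 0
#' logk_iam(698.9)        # 0.92, digoxin-like
logk_iam <- function(tr_water, t0_s = 75) {
  if (t0_s <= 0) stop("t0 must be positive", call. = FALSE)
  if (any(tr_water <= t0_s))
    stop("retention time must exceed the solvent front", call. = FALSE)
  log10((tr_water - t0_s) / t0_s)
}

#' MLV partitioning fraction
#'
#' Fraction of compound lost from the aqueous phase into multilamellar
#' liposome vesicles at equilibrium: `(C0 - Cs) / C0`.
#'
#' @param c0 Initial compound concentration (ug/mL); 1 ug/mL in the
#'   published assay.
#' @param cs Supernatant concentration after equilibration (ug/mL).
#' @return Partitioned fraction in \[0, 1\].
#' @export
#' @examples
#' mlv_partition(1, 0.70)  # 0.30
mlv_partition <- function(c0, cs) {
  if (any(c0 <= 0)) stop("c0 must be positive", call. = FALSE)
  if (any(cs < 0) || any(cs > c0))
    stop("need 0 <= cs <= c0", call. = FALSE)
  (c0 - cs) / c0
}
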