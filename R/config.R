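#' Analysis configuration
#'
#' Bundles the physical constants of the experimental setups and the OPLS-DA
#' settings used by [run_full_analysis()].  Defaults mirror the experimental
#' designs: a 10 mL recirculating perfusate reservoir sampled with 250 uL
#' replacement draws, 3 mL Ussing half-chambers sampled with 1 mL draws over
#' an exposed area of 0.12 cm^2, and an IAM column solvent front of 75 s.
#'
#' @param reservoir_volume_mL Perfusate reservoir volume (mL).
#' @param sample_volume_mL Perfusate sample volume replaced with blank (mL).
#' @param ussing_chamber_volume_mL Receiver chamber volume (mL).
#' @param ussing_sample_volume_mL Receiver sample volume replaced (mL).
#' @param exposed_area_cm2 Tissue area exposed in the Ussing chamber (cm^2).
#' @param solvent_front_s IAM column dead time T0 (seconds).
#' @param n_orth Number of orthogonal OPLS components, or `"auto"` to add
#'   components only while cross-validated Q2 improves by more than 0.01.
#' @param folds Cross-validation folds (round-robin by row order).
#' @param y_codes Named numeric class coding, default `c(A = 0, B = 1)`.
#' @param threshold Decision threshold on the decoded response scale.
#' @param rng_seed Seed used by any simulation the analysis performs.
#'
#' @return An object of class `"analysis_config"` (a validated list).
#' @seealso [read_analysis_config()] to load the same structure from YAML.
#' @export
analysis_config <- function(reservoir_volume_mL = 10,
                            sample_volume_mL = 0.25,
                            ussing_chamber_volume_mL = 3,
                            ussing_sample_volume_mL = 1,
                            exposed_area_cm2 = 0.12,
                            solvent_front_s = 75,
                            n_orth = "auto",
                            folds = 7,
                            y_codes = c(A = 0, B = 1),
                            threshold = 0.5,
                            rng_seed = 1L) {
  cfg <- list(reservoir_volume_mL = reservoir_volume_mL,
              sample_volume_mL = sample_volume_mL,
              ussing_chamber_volume_mL = ussing_chamber_volume_mL,
              ussing_sample_volume_mL = ussing_sample_volume_mL,
              exposed_area_cm2 = exposed_area_cm2,
              solvent_front_s = solvent_front_s,
              n_orth = n_orth,
              folds = as.integer(folds),
              y_codes = y_codes,
              threshold = threshold,
              rng_seed = as.integer(rng_seed))
  validate_analysis_config(cfg)
  class(cfg) <- "analysis_config"
  cfg
}

validate_analysis_config <- function(cfg) {
  pos <- c("reservoir_volume_mL", "sample_volume_mL",
           "ussing_chamber_volume_mL", "ussing_sample_volume_mL",
           "exposed_area_cm2", "solvent_front_s")
  for (nm in pos) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L || cfg[[nm]] <= 0)
      stop("config field '", nm, "' must be a single strictly positive number",
           call. = FALSE)
  }
  if (cfg$sample_volume_mL >= cfg$reservoir_volume_mL)
    stop("sample_volume_mL must be smaller than reservoir_volume_mL",
         call. = FALSE)
  if (!identical(cfg$n_orth, "auto") &&
      (!is.numeric(cfg$n_orth) || cfg$n_orth < 0 ||
       cfg$n_orth != round(cfg$n_orth)))
    stop("n_orth must be a non-negative integer or \"auto\"", call. = FALSE)
  if (cfg$folds < 2)
    stop("folds must be at least 2", call. = FALSE)
  if (length(cfg$y_codes) != 2L || is.null(names(cfg$y_codes)) ||
      any(!nzchar(names(cfg$y_codes))) || anyDuplicated(names(cfg$y_codes)))
    stop("y_codes must be two named numeric codes", call. = FALSE)
  invisible(cfg)
}

#' Read an analysis configuration from a YAML file
#'
#' The file holds a flat mapping with any subset of the [analysis_config()]
#' fields; missing fields take their defaults.
#'
#' @param path Path to a YAML file.
#' @return An `"analysis_config"` object.
#' @export
read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(raw$y_codes)) raw$y_codes <- unlist(raw$y_codes)
  do.call(analysis_config, raw)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration\n")
  cat(sprintf("  reservoir %g mL, sample %g mL; Ussing chamber %g mL, sample %g mL\n",
              x$reservoir_volume_mL, x$sample_volume_mL,
              x$ussing_chamber_volume_mL, x$ussing_sample_volume_mL))
  cat(sprintf("  exposed area %g cm^2; solvent front %g s\n",
              x$exposed_area_cm2, x$solvent_front_s))
  cat(sprintf("  OPLS-DA: n_orth = %s, folds = %d, coding %s, threshold %g\n",
              if (identical(x$n_orth, "auto")) "auto" else x$n_orth,
              x$folds,
              paste(names(x$y_codes), x$y_codes, sep = "=", collapse = ", "),
              x$threshold))
  invisible(x)
}
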