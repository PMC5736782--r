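## Seeded synthetic-data generators.  Each generator reproduces the exact
## bookkeeping its analysis counterpart assumes (replacement-sampling
## dilution, linear serosal flux, Michaelis-Menten saturation, two-class
## descriptor structure), so that at zero noise the analysis recovers the
## generating parameters to numerical precision.  Every generator draws from
## a single RNG stream seeded explicitly and restores the caller's RNG state.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(expr)
}

## multiplicative log-normal noise with unit mean and given CV
ln_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulation specification
#'
#' Light container bundling a seed, replicate count and noise level with
#' stage-specific parameters, for passing a whole scenario around as one
#' object.
#'
#' @param seed Integer RNG seed.
#' @param n_replicates Replicates per arm/curve.
#' @param cv Multiplicative noise coefficient of variation (default 0.05,
#'   consistent with the stated bioanalytical precision).
#' @param ... Stage-specific parameters forwarded to the generator.
#' @return A list of class `"sim_spec"`.
#' @export
sim_spec <- function(seed, n_replicates = 5, cv = 0.05, ...) {
  if (cv < 0) stop("cv must be non-negative", call. = FALSE)
  structure(list(seed = as.integer(seed), n_replicates = n_replicates,
                 cv = cv, ...), class = "sim_spec")
}

#' Simulate perfusate profiles for one IPML treatment arm
#'
#' First-order transfer of a fraction `f` of the deposited dose into a
#' 10 mL recirculating reservoir, sampled with 250 uL replacement draws at
#' the given schedule.  The reservoir concentration bookkeeping is exact:
#' the mass present at each draw equals the true cumulative absorbed mass
#' minus everything previously withdrawn, so [cumulative_absorbed()] is the
#' exact inverse at zero noise.  Measured concentrations then receive
#' multiplicative log-normal noise with the given CV.
#'
#' @param n Number of lung preparations.
#' @param f Fraction of deposited dose absorbed at infinite time (0, 1].
#' @param ka First-order absorption rate constant (1/min), > 0.
#' @param schedule Sampling times (min); default six samples over 30 min.
#' @param dose Deposited dose (nmol); default 1.25 (25 uL at 50 uM).
#' @param reservoir_volume,sample_volume Reservoir and draw volumes (mL).
#' @param cv Multiplicative noise CV on measured concentrations.
#' @param seed RNG seed.
#' @return List of [perfusate_profile()] objects.
#' @export
gen_ipml_arm <- function(n = 5, f = 0.26, ka = 0.1,
                         schedule = c(2, 5, 10, 15, 20, 30),
                         dose = 1.25, reservoir_volume = 10,
                         sample_volume = 0.25, cv = 0.05, seed = 1L) {
  if (f <= 0 || f > 1) stop("f must lie in (0, 1]", call. = FALSE)
  if (ka <= 0) stop("ka must be positive", call. = FALSE)
  if (any(schedule <= 0)) stop("schedule must start after t = 0",
                               call. = FALSE)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      m_true <- f * dose * (1 - exp(-ka * schedule))
      conc <- numeric(length(schedule))
      removed <- 0
      for (k in seq_along(schedule)) {
        conc[k] <- (m_true[k] - removed) / reservoir_volume
        removed <- removed + conc[k] * sample_volume
      }
      measured <- conc * ln_noise(length(conc), cv)
      perfusate_profile(schedule, measured,
                        reservoir_volume = reservoir_volume,
                        sample_volume = sample_volume,
                        deposited_dose = dose)
    })
  })
}

#' Simulate Ussing chamber experiments
#'
#' Linear serosal flux at a target apparent permeability into a 3 mL
#' receiver chamber sampled with 1 mL replacement draws; the concentration
#' bookkeeping mirrors [papp()] exactly, so the target permeability is
#' recovered to numerical precision at zero noise.  TEER readings are drawn
#' to include quality-control failures (low initial TEER or > 10% decline)
#' at a configured rate.
#'
#' @param n Number of segments.
#' @param papp_target Target apparent permeability (cm/s).
#' @param donor_c0 Donor concentration (nmol/mL), default 50.
#' @param exposed_area Exposed area (cm^2), default 0.12.
#' @param chamber_volume,sample_volume Receiver and draw volumes (mL).
#' @param schedule Sampling times (min), default every 30 min to 180.
#' @param cv Multiplicative noise CV on measured concentrations.
#' @param teer_mean,teer_sd Passing-segment initial TEER distribution
#'   (Ohm.cm^2), defaults 83 and 21 (truncated at the 80 acceptance bound).
#' @param qc_fail_rate Probability a segment is generated as a QC failure.
#' @param genotype `"WT"` or `"KO"` label carried on the experiments.
#' @param seed RNG seed.
#' @return List of [ussing_experiment()] objects.
#' @export
gen_ussing <- function(n = 6, papp_target = 6.04e-6, donor_c0 = 50,
                       exposed_area = 0.12, chamber_volume = 3,
                       sample_volume = 1, schedule = seq(30, 180, by = 30),
                       cv = 0.05, teer_mean = 83, teer_sd = 21,
                       qc_fail_rate = 0, genotype = "WT", seed = 1L) {
  slope_min <- papp_target * exposed_area * donor_c0 * 60  # nmol/min
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      m_true <- slope_min * schedule
      conc <- numeric(length(schedule))
      removed <- 0
      for (k in seq_along(schedule)) {
        conc[k] <- (m_true[k] - removed) / chamber_volume
        removed <- removed + conc[k] * sample_volume
      }
      measured <- conc * ln_noise(length(conc), cv)
      fail <- runif(1) < qc_fail_rate
      if (fail) {
        if (runif(1) < 0.5) {          # low initial TEER
          ti <- runif(1, 40, 79.9)
          tf <- ti * (1 - runif(1, 0, 0.08))
        } else {                        # excessive decline
          ti <- max(80, rnorm(1, teer_mean, teer_sd))
          tf <- ti * (1 - runif(1, 0.105, 0.30))
        }
      } else {
        ti <- max(80, rnorm(1, teer_mean, teer_sd))
        tf <- ti * (1 - runif(1, 0, 0.08))
      }
      ussing_experiment(schedule, measured,
                        chamber_volume = chamber_volume,
                        sample_volume = sample_volume,
                        exposed_area = exposed_area, donor_c0 = donor_c0,
                        teer_initial = ti, teer_final = tf,
                        genotype = genotype)
    })
  })
}

#' Simulate ATPase rate-concentration curves
#'
#' Michaelis-Menten turnover on a serial-dilution concentration grid over
#' the 0-300 uM assay range, with multiplicative noise.
#'
#' @param n Number of replicate curves.
#' @param vmax,km True kinetic parameters (uM/min, uM).
#' @param grid Concentration grid (uM).
#' @param duplicates Measurements per concentration within a curve.
#' @param cv Multiplicative noise CV.
#' @param membrane Membrane label (`"MDR1"`, `"Mdr1a"`, `"Mdr1b"`, `"Bcrp"`).
#' @param seed RNG seed.
#' @return List of data frames with columns `conc`, `rate`, `replicate`,
#'   `membrane`.
#' @export
gen_mm_curves <- function(n = 3, vmax = 10, km = 30,
                          grid = c(0, 2.34, 4.69, 9.38, 18.75, 37.5,
                                   75, 150, 300),
                          duplicates = 2, cv = 0.05,
                          membrane = "MDR1", seed = 1L) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      conc <- rep(grid, each = duplicates)
      rate <- vmax * conc / (km + conc) * ln_noise(length(conc), cv)
      data.frame(conc = conc, rate = rate, replicate = i,
                 membrane = membrane)
    })
  })
}

#' Simulate two-class descriptor matrices with a known discriminant
#'
#' Emulates the group structure of the compound panel: class means are
#' separated along a "polarity" direction loading on PSA, Abraham acidity
#' and basicity and the hydrogen-bond donor/acceptor counts (with
#' `hb_total` generated as `hbd + hba`, as in real descriptor tables), on
#' top of a variance-dominant nuisance direction orthogonal to the class
#' contrast (loading on lipophilicity/size descriptors) that exercises the
#' orthogonal-component removal, plus isotropic noise.  The class-A side
#' carries the higher polarity values.  The realized generative discriminant
#' is stored alongside the data.
#'
#' @param n_a,n_b Compounds per class, defaults 8 and 10.
#' @param shift Mean separation between classes along the polarity
#'   direction (in noise-SD units), default 3.
#' @param nuisance_sd SD of the shared nuisance direction, default 3.
#' @param noise_sd Isotropic noise SD, default 1.
#' @param seed RNG seed.
#' @return List with `x` (matrix, 13 canonical columns), `y` (labels
#'   `"A"`/`"B"`), `table` (data frame in fixture layout) and
#'   `discriminant` (unit vector, the realized class-contrast direction).
#' @export
gen_descriptor_classes <- function(n_a = 8, n_b = 10, shift = 3,
                                   nuisance_sd = 3, noise_sd = 1,
                                   seed = 1L) {
  dn <- descriptor_names()
  p <- length(dn)
  d <- setNames(numeric(p), dn)
  d[c("psa", "abraham_acidity", "abraham_basicity", "hbd", "hba")] <- 1
  d <- d / sqrt(sum(d^2))
  u <- setNames(numeric(p), dn)
  u[c("cLogD7.4", "cLogP", "mw", "abraham_volume", "abraham_mri")] <- 1
  u <- u / sqrt(sum(u^2))
  n <- n_a + n_b
  y <- rep(c("A", "B"), c(n_a, n_b))
  sign_mu <- ifelse(y == "A", +1, -1)  # polarity high on the A side
  with_seed(seed, {
    z <- rnorm(n, sd = nuisance_sd)
    eps <- matrix(rnorm(n * p, sd = noise_sd), n, p,
                  dimnames = list(NULL, dn))
    x <- (shift / 2) * tcrossprod(sign_mu, d) + tcrossprod(z, u) + eps
    x[, "hb_total"] <- x[, "hbd"] + x[, "hba"]
    ## realized discriminant: class-contrast direction incl. derived column
    d_eff <- d
    d_eff["hb_total"] <- d["hbd"] + d["hba"]
    d_eff <- d_eff / sqrt(sum(d_eff^2))
    rownames(x) <- sprintf("cmpd%02d", seq_len(n))
    tab <- data.frame(name = rownames(x), group = y, x,
                      check.names = FALSE, stringsAsFactors = FALSE)
    list(x = x, y = y, table = tab, discriminant = d_eff)
  })
}
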