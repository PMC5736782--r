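---
title: "Models and methods for P-gp-dependent pulmonary disposition analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for P-gp-dependent pulmonary disposition analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgplung)
```

This vignette documents the models behind `pgplung`, the assumptions they
make, the defaults and why they were chosen, and what the synthetic-data
generators do and do not emulate.

## The experimental system

An isolated perfused mouse lung (IPML) receives a small airway dose
(25 µL at 50 µM, i.e. 1.25 nmol for the unlabelled compounds) and is
perfused in recirculating mode from a 10 mL reservoir. Absorption across
the pulmonary barrier moves drug into the reservoir, which acts as a
purely accumulating compartment. Comparing wild-type lungs against
Mdr1a/1b double-knockout lungs isolates the contribution of P-glycoprotein
efflux: substrates whose absorption rises after knockout are under net
P-gp restraint in the lung ("Group B"), those unchanged are not
("Group A"). Parallel Ussing-chamber experiments on ileal segments from
the same animals provide the intestinal contrast, and membrane-affinity
assays plus computed descriptors characterise the physical chemistry that
separates the two groups.

## Serial-sampling bookkeeping

Every reservoir or receiver-chamber sample (250 µL of 10 mL in the IPML,
1 mL of 3 mL in the Ussing chamber) is replaced with blank fluid, diluting
what remains. Concentrations are interpreted as measured immediately
*before* each draw — the assay protocol does not state the order, and
pre-replacement measurement is the physically natural reading of sampling
from a stirred reservoir; this choice is embedded in both the correction
and the generators, so the pair stays exactly consistent. The cumulative
amount transported up to sample $i$ is then

$$M_i = C_i V_{\mathrm{res}} + \sum_{j<i} C_j V_s,$$

which is exact: the test suite verifies, on simulated profiles, that
withdrawn mass plus the post-draw reservoir content equals everything that
entered, to $10^{-9}$ relative.

## Absorption model

The cumulative percent of deposited dose absorbed follows the first-order
one-compartment accumulating model
$\%Dose(t) = 100\,F\,(1 - e^{-K_a t})$, fitted by unweighted nonlinear
least squares (Levenberg–Marquardt via `minpack.lm`). Choices:

* **Start values** $F_0 = \max(\%)/100$, $K_{a,0} = 0.1\,\mathrm{min}^{-1}$;
  **bounds** $F \in (0, 1.1]$ (the soft upper bound tolerates noise above
  100 %), $K_a \in [10^{-5}, 10]\,\mathrm{min}^{-1}$.
* **Unweighted residuals**: with only six samples in 30 min there is no
  information to support a variance model, and weighting is reported not
  to help this design.
* **Uncertainty** as per-parameter CV% from the asymptotic covariance.
  Under the default sparse schedule the rate constant is systematically
  the poorly determined parameter — the Monte-Carlo test shows median
  CV%($K_a$) > CV%($F$) at 5 % assay noise.
* Two noiseless points determine both parameters exactly (the fit matches
  the closed-form inversion), so the fitter accepts $n \ge 2$ even though
  real designs use six or more samples.

`auc_0_30()` uses the linear trapezoid with a virtual $(0, 0)$ anchor — no
drug can be in the perfusate at $t = 0$ — and carries the last observation
flat to 30 min when sampling stops early; with a purely accumulating
compartment this is conservative and bounded above by the true plateau.
Lung retention is the mass-balance complement of absorption, with the
deposited dose defined net of drug recovered from the dosing device.
A preparation is excluded when co-instilled mannitol exceeds 65 % of
deposited dose by 30 min (strictly greater, as the rule is stated); the
wet:dry weight ratio is carried as an advisory oedema flag only, since no
numeric threshold accompanies it.

## Membrane affinity

IAM retention is measured at 10/20/30 % (v/v) acetonitrile and
extrapolated to 100 % water by ordinary least squares *on retention time
itself*, matching how the published values were produced; extrapolation in
$\log_{10} k'$ space — the more common chromatographic convention — is
available via `mode = "logk"` because the two differ on curved data and
the published convention is not stated beyond the regression sentence.
$\mathrm{LogK^{IAM}} = \log_{10}[(T_r - T_0)/T_0]$ with $T_0 = 75$ s.
MLV partitioning is $(C_0 - C_s)/C_0$ with $C_0 = 1$ µg/mL.

## Intestinal permeability

The receiver-chamber series is corrected exactly as above, the transport
rate is the free-intercept OLS slope of cumulative amount against time
over the whole 180 min (no lag-time exclusion — the published rate is the
whole-experiment rate), and
$P_{app} = (dM/dt)/(A\,C_0)$ with $A = 0.12\ \mathrm{cm^2}$, reported in
cm/s. TEER rules are strict as printed: initial < 80 Ω·cm² or a decline
greater than 10 % excludes the segment. A negative slope is reported with
a warning flag rather than an error, since near-zero transport can
legitimately produce one under noise.

## ATPase kinetics

`fit_mm()` fits $v = V_{max} S/(K_m + S)$ with start values
$V_{max,0} = \max(v)$ and $K_{m,0}$ at the half-maximal concentration,
both bounded positive; confidence intervals use the asymptotic covariance
with a $t$ quantile. `flag_nonreactive()` declares a membrane
non-reactive when the fit fails or the $V_{max}$ interval covers zero —
the behaviour seen for most of the panel against the Bcrp membrane.
Group-level comparison of $K_m$, $V_{max}$ and $V_{max}/K_m$ is delegated
to the unpaired t-test, mirroring the "no significant difference" framing
of the transporter-kinetics comparison.

## OPLS-DA

For a single coded class response $y$ (A = 0, B = 1, centred) on the
unit-variance-scaled descriptor matrix $X$:

1. $w \propto X^\top y$ (unit norm), $t = Xw$, $p = X^\top t/t^\top t$;
2. orthogonal component: $w_o \propto p - (w^\top p)w$, $t_o = X w_o$,
   $p_o = X^\top t_o / t_o^\top t_o$, deflate $X \leftarrow X - t_o p_o^\top$
   (repeated `n_orth` times);
3. final predictive component on the filtered $X$ and univariate
   regression of $y$ on $t$.

Because $w_o \perp w \propto X^\top y$, the orthogonal scores satisfy
$t_o^\top y = 0$ exactly; the fit asserts this, the orthogonality of
$t$ to every $t_o$, and deflation conservation on every call.

Design choices where the published description is silent:

* **Scaling** is mean-centring plus unit variance ($n-1$ denominator), the
  standard chemometric default for descriptor matrices of mixed units.
* **Cross-validation** assigns rows to 7 folds round-robin by row order
  and re-estimates all components within each training fold.  The scaling
  parameters and response centre are treated as fixed properties of the
  assembled data set rather than re-derived per fold, which is how
  chemometrics software conventionally reports Q²; full per-fold
  re-estimation is available (`cv_refit_scaling = TRUE`) and gives
  slightly lower Q² on small panels.
* **Number of orthogonal components** defaults to `"auto"`: starting from
  none, a component is added only while cross-validated Q² improves by
  more than 0.01.  This is the usual chemometric stopping rule, and it is
  what reproduces the published fit statistics on the packaged panel: the
  18-compound descriptor table supports no orthogonal component (adding
  one raises apparent fit, R²Y 0.59 → 0.65, while Q² drops 0.48 → 0.26),
  and the published R² equals the single-predictive-component value to
  printed precision.  A fixed `n_orth` can always be requested, and the
  scores export then pairs the predictive score with the first orthogonal
  score; for a 1+0 model the second plot axis is the leading principal
  component of the X-residual, a display axis that is not part of the
  regression.
* **Decision rule**: predicted class is B when the decoded response is at
  or above 0.5; ties go to the positive (larger-coded) class.  The
  predictive axis is oriented so class B has positive mean score, i.e.
  the less-polar group plots to the right and polarity-related
  descriptors (PSA, Abraham acidity/basicity, hydrogen-bond counts) load
  on the left, class-A side.

On the packaged panel the default model misclassifies exactly one
training compound (acrivastine), with R²Y ≈ 0.59 and 7-fold Q² ≈ 0.48 —
both computed live by `run_full_analysis()` and the test suite.

## Comparative statistics

Equal-variance unpaired t-tests are the default (consistent with the
published pairwise comparisons; Welch is an option). Spearman correlation
is Pearson on midranks with a $t$-approximate p-value; an exact
permutation p (two-sided, $|\rho|$-based) enumerates all $n!$ rankings for
$n \le 10$ and matches brute-force enumeration and the classical exact
distribution in the tests. Group summaries use $t$-based 95 % confidence
intervals with $n-1$ degrees of freedom. A printed-precision helper
rounds ratios to 2 and correlations to 3 decimals when comparing against
published tables; recomputed knockout:wild-type ratios agree with the
printed column within ±0.02 everywhere, the largest deviation (saquinavir)
reflecting rounding of the printed permeabilities.

## Synthetic data: what it emulates and what it does not

Each generator encodes exactly the structure its estimator assumes, with
one shared RNG stream per call (the caller's RNG state is restored):

* `gen_ipml_arm()` — first-order transfer into the 10 mL reservoir with
  exact 250 µL replacement bookkeeping; default schedule 2, 5, 10, 15,
  20, 30 min (six samples, a documented assumption — the experimental
  schedule is not printed) and 1.25 nmol deposited dose.
* `gen_ussing()` — linear serosal flux with 1 mL/3 mL replacement
  bookkeeping; passing TEER drawn from N(83, 21) truncated at the
  80 Ω·cm² acceptance bound, with failures injected at a configurable
  rate.
* `gen_mm_curves()` — Michaelis–Menten rates on a serial-dilution grid
  spanning the 0–300 µM assay range.
* `gen_descriptor_classes()` — two descriptor classes separated along a
  polarity direction (PSA, Abraham acidity/basicity, H-bond donor and
  acceptor counts, with `hb_total` generated as their sum as in real
  tables), a variance-dominant nuisance direction on the
  lipophilicity/size descriptors orthogonal to the contrast, and
  isotropic noise.  Defaults (shift 3, nuisance SD 3, noise SD 1, 8 + 10
  compounds) were set to mirror the panel-like separation of roughly one
  misclassified training compound in twenty.

Noise is multiplicative log-normal with 5 % CV by default, consistent
with the stated bioanalytical precision. The generators make no attempt
at physiological realism — no lobar deposition, tissue binding,
lag times, or inter-animal covariance — so passing tests demonstrate that
the estimators are correct and well-behaved under their assumed
statistical structure, not that the models are adequate for arbitrary
real lungs.

## Numerical choices and problem sizes

Exact identities are asserted at 1e-9–1e-12; estimator-vs-oracle
agreements at 1e-6 (nonlinear fits) or 1e-10 (linear-algebra reductions).
Monte-Carlo properties use 100–500 seeded replicates (power and bias
checks), 200 label permutations for the Q² null, and 20 train/test pairs
for held-out accuracy — sizes at which the checked statistics are stable
to well within the asserted margins while the whole suite stays fast.

## Known limitations

* The exact cross-validation conventions of the commercial software used
  for the original fit are proprietary; Q² is therefore convention-
  dependent at the second decimal, which is why both scaling conventions
  are exposed.
* Descriptor values are consumed as published, including typographic
  oddities of the source table (one negative cLogP, donor/acceptor splits
  that read oddly for three compounds); no descriptor computation is
  performed.
* The external 129-compound prediction set is not distributed in
  machine-readable form, so external predictions require user-supplied
  descriptors with the 13 canonical names.
* Exact Spearman permutation p is enumeration-based and limited to
  $n \le 10$.
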