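## Group comparisons and correlation analyses: unpaired t-tests, Pearson and
## Spearman correlations (with exact small-sample permutation p), rank-order
## impact tables and group fold-change summaries.

#' Unpaired two-sample t-test
#'
#' Two-sided Student t-test; equal variances pooled by default (matching the
#' published comparisons), Welch available.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @param var_equal Pool variances (default `TRUE`).
#' @return List with `t`, `p`, `df`, means.
#' @export
unpaired_t <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 observations", call. = FALSE)
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, p = 1, df = length(a) + length(b) - 2L,
                  mean_a = mean(a), mean_b = mean(b)))
    stop("zero pooled variance with unequal means: t undefined",
         call. = FALSE)
  }
  ht <- t.test(a, b, var.equal = var_equal)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_a = mean(a), mean_b = mean(b))
}

cor_result <- function(coefficient, p, n, method) {
  structure(list(coefficient = coefficient, p = p, n = n, method = method),
            class = "cor_result")
}

#' @export
print.cor_result <- function(x, ...) {
  cat(sprintf("%s correlation: r = %.3f, p = %.3g, n = %d\n",
              x$method, x$coefficient, x$p, x$n))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors, n >= 3, finite.
#' @return A `"cor_result"` with `coefficient`, two-sided t-based `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 finite pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  ht <- cor.test(x, y, method = "pearson")
  cor_result(unname(ht$estimate), ht$p.value, length(x), "pearson")
}

## all permutations of 1..n as a matrix (n! rows); fine for n <= 10
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Spearman rank correlation
#'
#' Pearson correlation of average (midrank) ranks.  The two-sided p-value
#' uses the t approximation by default; `exact = TRUE` enumerates all `n!`
#' rank permutations (supported for n <= 10) and reports the proportion of
#' permutations with `|rho|` at least as large as observed.
#'
#' @param x,y Numeric vectors, n >= 3.
#' @param exact Use the exact permutation null distribution.
#' @return A `"cor_result"`.
#' @export
spearman_cor <- function(x, y, exact = FALSE) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 finite pairs", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    stop("zero rank variance: correlation undefined", call. = FALSE)
  rho <- cor(rx, ry)
  if (exact) {
    if (n > 10L)
      stop("exact permutation p supported for n <= 10", call. = FALSE)
    perm <- permutations(n)
    ry_s <- sort(ry)
    rhos <- apply(perm, 1L, function(idx) cor(rx, ry_s[idx]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tt), n - 2)
  }
  cor_result(rho, p, n, if (exact) "spearman (exact)" else "spearman")
}

#' Rank-order impact table
#'
#' Converts a per-compound metric and a per-compound knockout-impact measure
#' (typically the KO:WT permeability ratio) into ranks (1 = smallest) and
#' attaches the per-compound significance flag used to annotate compounds
#' whose knockout effect did not reach significance.
#'
#' @param names Compound names.
#' @param metric Per-compound metric (e.g. LogK(IAM) or WT Papp).
#' @param impact Per-compound knockout impact (e.g. KO:WT ratio).
#' @param p_values Optional per-compound p-values; `significant` is
#'   `p < alpha`.
#' @param significant Optional logical flags (alternative to `p_values`).
#' @param alpha Significance level, default 0.05.
#' @return Data frame with `name`, `metric_rank`, `impact_rank`,
#'   `significant`, ordered as the input.
#' @export
rank_impact_table <- function(names, metric, impact, p_values = NULL,
                              significant = NULL, alpha = 0.05) {
  n <- length(names)
  if (length(metric) != n || length(impact) != n)
    stop("mismatched compound sets", call. = FALSE)
  if (is.null(significant)) {
    significant <- if (is.null(p_values)) rep(NA, n) else p_values < alpha
  }
  if (length(significant) != n)
    stop("mismatched compound sets", call. = FALSE)
  data.frame(name = as.character(names),
             metric_rank = rank(metric),
             impact_rank = rank(impact),
             significant = significant,
             stringsAsFactors = FALSE)
}

#' Group summary with 95% confidence interval
#'
#' @param x Numeric sample of size >= 2.
#' @param label Optional group label.
#' @param conf_level Confidence level (t interval, n - 1 df).
#' @return List with `label`, `n`, `mean`, `sd`, `ci` (length 2).
#' @export
group_summary <- function(x, label = NA_character_, conf_level = 0.95) {
  n <- length(x)
  if (n < 2L) stop("need n >= 2 for a confidence interval", call. = FALSE)
  m <- mean(x); s <- sd(x)
  half <- qt(1 - (1 - conf_level) / 2, n - 1L) * s / sqrt(n)
  list(label = label, n = n, mean = m, sd = s, ci = c(m - half, m + half))
}

#' Per-group fold-change summaries
#'
#' Mean, SD and 95% CI of KO:WT ratios per group, with an optional
#' exclusion list (e.g. dropping an extreme ratio from the display while
#' reporting both versions).
#'
#' @param ratios Positive fold changes, one per compound.
#' @param groups Group label per compound.
#' @param names Optional compound names (needed when `exclude` is used).
#' @param exclude Compound names to drop before summarising.
#' @return Named list of [group_summary()] results, one per group.
#' @export
group_fold_change <- function(ratios, groups, names = NULL, exclude = NULL) {
  if (any(ratios <= 0)) stop("ratios must be positive", call. = FALSE)
  keep <- rep(TRUE, length(ratios))
  if (length(exclude)) {
    if (is.null(names)) stop("names required when excluding compounds",
                             call. = FALSE)
    keep <- !(names %in% exclude)
  }
  ratios <- ratios[keep]; groups <- groups[keep]
  out <- lapply(split(ratios, groups), function(v) group_summary(v))
  for (g in names(out)) out[[g]]$label <- g
  if (any(!lengths(out))) stop("empty group", call. = FALSE)
  out
}

#' Round exactly as the published tables print
#'
#' Helper used when comparing recomputed quantities with printed ones:
#' ratios print to 2 decimal places, correlation coefficients to 3.
#'
#' @param x Numeric.
#' @param what `"ratio"` or `"correlation"`.
#' @return Rounded numeric.
#' @export
round_as_printed <- function(x, what = c("ratio", "correlation")) {
  what <- match.arg(what)
  round(x, if (what == "ratio") 2L else 3L)
}
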