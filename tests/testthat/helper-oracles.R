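# Independent oracle implementations used to check the package's
# estimators against a second code path.

# single-component PLS1 by the normal equations, on pre-scaled data
pls1_oracle <- function(x, y) {
  sc <- scale(x)
  yc <- y - mean(y)
  w <- drop(crossprod(sc, yc))
  w <- w / sqrt(sum(w^2))
  t <- drop(sc %*% w)
  b <- sum(t * yc) / sum(t^2)
  list(w = w, t = t, b = b, yhat = b * t + mean(y))
}

# all permutations of seq_len(n), built by insertion (independent of the
# package's recursive-selection construction)
perm_matrix <- function(n) {
  out <- matrix(1L, 1L, 1L)
  for (k in 2L:n) {
    rows <- nrow(out)
    grown <- vector("list", k)
    for (pos in seq_len(k)) {
      left <- if (pos > 1L) out[, seq_len(pos - 1L), drop = FALSE] else NULL
      right <- if (pos <= k - 1L) out[, pos:(k - 1L), drop = FALSE] else NULL
      grown[[pos]] <- cbind(left, matrix(k, rows, 1L), right)
    }
    out <- do.call(rbind, grown)
  }
  out
}

# brute-force two-sided exact Spearman p over all n! rankings
brute_spearman_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  obs <- cor(rx, ry)
  pm <- perm_matrix(length(y))
  ry_sorted <- sort(ry)
  rhos <- apply(pm, 1L, function(idx) cor(rx, ry_sorted[idx]))
  mean(abs(rhos) >= abs(obs) - 1e-12)
}

# closed-form two-point inversion of the first-order accumulating model,
# valid when t2 = 2 * t1
invert_first_order_2pt <- function(t1, p1, p2) {
  a <- p2 / p1 - 1            # a = exp(-ka * t1)
  ka <- -log(a) / t1
  f <- p1 / (100 * (1 - a))
  c(f = f, ka = ka)
}

# Lineweaver-Burk double-reciprocal regression (excludes S = 0)
lineweaver_burk <- function(conc, rate) {
  keep <- conc > 0
  fit <- lm(I(1 / rate[keep]) ~ I(1 / conc[keep]))
  vmax <- 1 / coef(fit)[[1L]]
  km <- coef(fit)[[2L]] * vmax
  c(vmax = vmax, km = km)
}
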