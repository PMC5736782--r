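tab1 <- load_descriptor_table("table1")
X1 <- as.matrix(tab1)
y1 <- tab1$group

test_that("unit-variance scaling and its inverse", {
  sc <- uv_scale(X1)
  expect_true(all(abs(colMeans(sc$x)) < 1e-12))
  expect_true(all(abs(apply(sc$x, 2, sd) - 1) < 1e-12))
  back <- sweep(sweep(sc$x, 2, sc$scale, "*"), 2, sc$center, "+")
  expect_equal(unname(as.matrix(back)), unname(X1), tolerance = 1e-12,
               ignore_attr = TRUE)

  bad <- cbind(X1, flat = rep(2, nrow(X1)))
  expect_error(uv_scale(bad), "flat")
})

test_that("orthogonal components are orthogonal to y and to the predictive score", {
  fit <- fit_oplsda(X1, y1, n_orth = 2, folds = 7)
  yc <- ifelse(y1 == "B", 1, 0) - mean(y1 == "B")
  expect_lt(max(abs(crossprod(fit$T_o, yc))), 1e-8)
  expect_lt(max(abs(crossprod(fit$T_o, fit$t_pred))), 1e-8)
  # deflation conserves the scaled matrix
  xs <- uv_scale(X1)$x
  rebuilt <- fit$x_deflated +
    Reduce(`+`, lapply(seq_len(fit$n_orth), function(k)
      tcrossprod(fit$T_o[, k], fit$P_o[, k])))
  expect_lt(max(abs(xs - rebuilt)), 1e-10)
})

test_that("with no orthogonal component the fit reduces to PLS1", {
  fit <- fit_oplsda(X1, y1, n_orth = 0, folds = 7)
  oracle <- pls1_oracle(X1, ifelse(y1 == "B", 1, 0))
  expect_lt(max(abs(fit$fitted_y - oracle$yhat)), 1e-10)
  expect_lt(max(abs(abs(fit$w) - abs(oracle$w))), 1e-10)
})

test_that("fitting is deterministic and predict is self-consistent", {
  f1 <- fit_oplsda(X1, y1, n_orth = 1)
  f2 <- fit_oplsda(X1, y1, n_orth = 1)
  keep <- setdiff(names(f1), "call")
  expect_identical(f1[keep], f2[keep])

  pr <- predict(f1, X1)
  expect_equal(pr$y_pred, unname(f1$fitted_y), tolerance = 1e-12)
  expect_identical(pr$class, unname(f1$class_fitted))
  expect_equal(pr$t_pred, unname(f1$t_pred), tolerance = 1e-12)
})

test_that("the recovered weight vector tracks the generative discriminant", {
  # low noise, no nuisance direction
  # n large enough that chance correlations of the pure-noise columns
  # (inflated to unit variance by UV scaling) stay negligible
  sim <- gen_descriptor_classes(n_a = 200, n_b = 200, shift = 3,
                                nuisance_sd = 0, noise_sd = 0.1, seed = 11)
  fit <- fit_oplsda(sim$x, sim$y, n_orth = 0)
  # the raw-space class contrast maps to d / column-scale on the model axes
  expect_gt(abs(cor(fit$w, sim$discriminant / fit$scale)), 0.99)

  # strong orthogonal nuisance, removed by one orthogonal component
  sim2 <- gen_descriptor_classes(n_a = 200, n_b = 200, shift = 3,
                                 nuisance_sd = 4, noise_sd = 0.1, seed = 12)
  fit2 <- fit_oplsda(sim2$x, sim2$y, n_orth = 1)
  expect_gt(abs(cor(fit2$w, sim2$discriminant / fit2$scale)), 0.99)
})

test_that("cross-validated Q2 behaves across designs", {
  # near-noiseless, well-separated classes predict almost perfectly
  sim <- gen_descriptor_classes(n_a = 9, n_b = 9, shift = 6,
                                nuisance_sd = 1, noise_sd = 0.2, seed = 3)
  expect_gt(cross_validate_q2(sim$x, sim$y, n_orth = 0, folds = 6), 0.9)

  # permuted labels carry no signal: mean Q2 is not positive
  q2s <- vapply(1:200, function(s) {
    yp <- pgplung:::with_seed(s, sample(y1))
    if (min(table(yp)) < 2) return(NA_real_)
    cross_validate_q2(X1, yp, n_orth = 0, folds = 7)
  }, numeric(1))
  expect_lte(mean(q2s, na.rm = TRUE), 0)

  # folds = n equals a brute-force leave-one-out PRESS
  ycode <- ifelse(y1 == "B", 1, 0)
  xs <- scale(X1)
  press <- 0
  for (i in seq_len(nrow(xs))) {
    tr <- -i
    yc <- ycode[tr] - mean(ycode)
    w <- drop(crossprod(xs[tr, ], yc)); w <- w / sqrt(sum(w^2))
    t <- drop(xs[tr, ] %*% w)
    b <- sum(t * yc) / sum(t^2)
    yhat <- b * sum(xs[i, ] * w) + mean(ycode)
    press <- press + (ycode[i] - yhat)^2
  }
  q2_loo <- 1 - press / sum((ycode - mean(ycode))^2)
  expect_equal(cross_validate_q2(X1, y1, n_orth = 0, folds = 18), q2_loo,
               tolerance = 1e-12)
})

test_that("scores/loadings export follows the orientation convention", {
  fit <- fit_oplsda(X1, y1)
  ex <- export_scores_loadings(fit)
  b_mean <- mean(ex$scores$t_pred[ex$scores$group == "B"])
  expect_gt(b_mean, 0)
  # the outlier compound sits on the class-B side of the predictive axis
  acr <- ex$scores$t_pred[ex$scores$name == "acrivastine"]
  expect_gt(acr * b_mean, 0)
  # polarity-related descriptors load on the class-A (left) side
  pol <- ex$loadings$w[ex$loadings$descriptor %in%
                         c("abraham_acidity", "abraham_basicity", "hbd",
                           "hba", "hb_total", "psa")]
  expect_true(all(pol < 0))
  # flipping all descriptor signs flips loadings but not class calls
  fit_neg <- fit_oplsda(-X1, y1, n_orth = fit$n_orth)
  expect_equal(fit_neg$w, -fit$w, tolerance = 1e-10)
  expect_identical(fit_neg$class_fitted, fit$class_fitted)
})

test_that("degenerate requests fail informatively", {
  expect_error(fit_oplsda(X1, y1, n_orth = 12), "n_orth")
  expect_error(fit_oplsda(X1, rep("A", 18)), "2 samples")
  expect_error(fit_oplsda(X1, y1, folds = 19), "folds")
  fit <- fit_oplsda(X1, y1)
  expect_error(predict(fit, X1[, -3]), "lacks")
})

test_that("threshold ties classify as the positive class", {
  expect_identical(pgplung:::decode_class(0.5, c(A = 0, B = 1), 0.5), "B")
  expect_identical(pgplung:::decode_class(0.4999, c(A = 0, B = 1), 0.5), "A")
})

test_that("formula interface matches the matrix interface", {
  df <- as.data.frame(tab1)
  fit_f <- oplsda(group ~ . - name, data = df)
  fit_m <- fit_oplsda(X1, y1)
  expect_equal(fit_f$r2y, fit_m$r2y, tolerance = 1e-12)
  expect_identical(fit_f$misclassified, fit_m$misclassified)
})
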