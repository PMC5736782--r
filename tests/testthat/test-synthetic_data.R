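test_that("generators are byte-reproducible for a fixed seed", {
  expect_identical(gen_ipml_arm(n = 3, seed = 7), gen_ipml_arm(n = 3, seed = 7))
  expect_identical(gen_ussing(n = 3, qc_fail_rate = 0.2, seed = 7),
                   gen_ussing(n = 3, qc_fail_rate = 0.2, seed = 7))
  expect_identical(gen_mm_curves(n = 2, seed = 7), gen_mm_curves(n = 2, seed = 7))
  expect_identical(gen_descriptor_classes(seed = 7),
                   gen_descriptor_classes(seed = 7))
  # and leave the caller's RNG stream untouched
  set.seed(123); before <- .Random.seed
  invisible(gen_ipml_arm(n = 1, seed = 99))
  expect_identical(.Random.seed, before)
})

test_that("each generator is the exact inverse pair of its consumer", {
  prof <- gen_ipml_arm(n = 1, f = 0.4, ka = 0.15, cv = 0, seed = 2)[[1L]]
  truth <- 0.4 * prof$deposited_dose * (1 - exp(-0.15 * prof$times))
  expect_equal(cumulative_absorbed(prof)$cum_nmol, truth, tolerance = 1e-12)

  e <- gen_ussing(n = 1, papp_target = 6.04e-6, cv = 0, seed = 2)[[1L]]
  expect_equal(papp(e)$papp, 6.04e-6, tolerance = 1e-9 * 6.04e-6)
  e0 <- gen_ussing(n = 1, papp_target = 1e-12, cv = 0, seed = 2)[[1L]]
  expect_lt(papp(e0)$papp, 1e-11)

  curve <- gen_mm_curves(n = 1, vmax = 12, km = 45, cv = 0, seed = 2)[[1L]]
  expect_equal(coef(fit_mm(curve$conc, curve$rate)),
               c(vmax = 12, km = 45), tolerance = 1e-6)
})

test_that("arm comparisons show the designed power at assay noise", {
  run_scenario <- function(f_ko, seed_base) {
    vapply(1:500, function(i) {
      wt <- gen_ipml_arm(n = 5, f = 0.26, ka = 0.1, cv = 0.05,
                         seed = seed_base + 2L * i)
      ko <- gen_ipml_arm(n = 5, f = f_ko, ka = 0.1, cv = 0.05,
                         seed = seed_base + 2L * i + 1L)
      auc <- function(arm) vapply(arm, function(p) {
        cum <- cumulative_absorbed(p)
        auc_0_30(cum$time, cum$cum_pct)$auc_0_30
      }, numeric(1))
      unpaired_t(auc(wt), auc(ko))$p
    }, numeric(1))
  }
  # equal extents: the knockout contrast is non-significant nearly always
  p_null <- run_scenario(0.26, 10000L)
  expect_gte(mean(p_null > 0.05), 0.90)
  # a 54% increase in extent is detected with high power
  p_alt <- run_scenario(0.40, 20000L)
  expect_gte(mean(p_alt < 0.05), 0.80)
})

test_that("TEER failures appear at the configured rate", {
  segs <- gen_ussing(n = 100, qc_fail_rate = 0.1, cv = 0.05, seed = 31)
  excluded <- sum(vapply(segs, function(e) ussing_qc(e)$verdict, "") ==
                    "EXCLUDE")
  expect_gte(excluded, qbinom(0.025, 100, 0.1))
  expect_lte(excluded, qbinom(0.975, 100, 0.1))
})

test_that("descriptor generator exposes the class structure it encodes", {
  # without orthogonal variation, OPLS-DA and PLS1 classify identically
  sim <- gen_descriptor_classes(n_a = 200, n_b = 200, shift = 3,
                                nuisance_sd = 0, noise_sd = 0.01, seed = 5)
  fit <- fit_oplsda(sim$x, sim$y, n_orth = 0, folds = 6)
  oracle <- pls1_oracle(sim$x, ifelse(sim$y == "B", 1, 0))
  expect_identical(fit$class_fitted,
                   ifelse(oracle$yhat >= 0.5, "B", "A"))
  expect_gt(abs(cor(fit$w, sim$discriminant / fit$scale)), 0.99)

  # held-out accuracy at the panel-like effect size: with 18 training
  # compounds and a variance-dominant nuisance axis the Monte-Carlo mean
  # accuracy settles near 0.88
  acc <- vapply(1:20, function(i) {
    train <- gen_descriptor_classes(seed = 100L + 2L * i)
    test <- gen_descriptor_classes(n_a = 100, n_b = 100, seed = 101L + 2L * i)
    fit2 <- fit_oplsda(train$x, train$y, folds = 6)
    mean(predict(fit2, test$x)$class == test$y)
  }, numeric(1))
  expect_gt(mean(acc), 0.85)
})

test_that("orthogonal-component removal helps under a dominant nuisance axis", {
  # head-to-head on held-out data over 100 seeded repetitions: OPLS-DA with
  # one orthogonal component misclassifies no more than PLS without deflation
  errs <- t(vapply(1:100, function(s) {
    train <- gen_descriptor_classes(n_a = 9, n_b = 9, shift = 2.5,
                                    nuisance_sd = 5, noise_sd = 1,
                                    seed = 1000L + 2L * s)
    test <- gen_descriptor_classes(n_a = 25, n_b = 25, shift = 2.5,
                                   nuisance_sd = 5, noise_sd = 1,
                                   seed = 1000L + 2L * s + 1L)
    f_opls <- fit_oplsda(train$x, train$y, n_orth = 1, folds = 6)
    f_pls <- fit_oplsda(train$x, train$y, n_orth = 0, folds = 6)
    c(opls = mean(predict(f_opls, test$x)$class != test$y),
      pls = mean(predict(f_pls, test$x)$class != test$y))
  }, numeric(2)))
  expect_lte(mean(errs[, "opls"]), mean(errs[, "pls"]))
})
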