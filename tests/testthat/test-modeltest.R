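# Joint ML fitting of the equal / compatible / incompatible rates models
# and the likelihood-ratio cascade.

test_that("rejection thresholds reproduce the mixture calibration", {
  thr <- lrt_thresholds(0.05)
  # boundary-mixture rule: reject equal when LR exceeds the chi2(1)
  # quantile at 1 - 2 alpha, printed as 2.71 at alpha = 0.05
  expect_equal(round(thr[["eq_co"]], 2), 2.71)
  # independent quantile oracle (integrated density + root finding)
  expect_equal(thr[["eq_co"]], chisq_quantile_oracle(0.90, 1),
               tolerance = 1e-6)
  expect_equal(lrt_thresholds(0.01)[["eq_co"]],
               chisq_quantile_oracle(0.98, 1), tolerance = 1e-6)
  expect_equal(thr[["co_in"]], chisq_quantile_oracle(0.95, 1),
               tolerance = 1e-6)
  expect_equal(thr[["eq_in"]], chisq_quantile_oracle(0.95, 2),
               tolerance = 1e-6)
})

test_that("the cascade selects the simplest non-rejected model", {
  mk <- function(ll) list(loglik = ll)
  # all LR = 0: equal
  sel <- lrt_cascade(mk(-100), mk(-100), mk(-100), alpha = 0.05)
  expect_identical(sel$selected, "equal")
  # LR(eq, co) = 2.70 survives, 2.72 does not (worked threshold 2.71)
  expect_identical(lrt_cascade(mk(-100), mk(-100 + 1.35), mk(-100 + 1.35),
                               0.05)$selected, "equal")
  expect_identical(lrt_cascade(mk(-100), mk(-100 + 1.36), mk(-100 + 1.36),
                               0.05)$selected, "compatible")
  # large co -> in gap pushes selection to incompatible
  expect_identical(lrt_cascade(mk(-100), mk(-90), mk(-80), 0.05)$selected,
                   "incompatible")
  # the eq-vs-in comparison alone can reject equal even when eq-vs-co
  # survives: gaps 1.3 and 1.8 give LR 2.6 < 2.71 but 6.2 > 5.99, with
  # co-vs-in 3.6 < 3.84
  sel2 <- lrt_cascade(mk(-100), mk(-98.7), mk(-96.9), 0.05)
  expect_lt(sel2$LR[["eq_co"]], sel2$thresholds[["eq_co"]])
  expect_gt(sel2$LR[["eq_in"]], sel2$thresholds[["eq_in"]])
  expect_identical(sel2$selected, "compatible")
})

test_that("joint fits satisfy the structural constraints and nesting", {
  d <- small_dataset(seed = 101, n = 100, beta = 0.5, lambda_a = 0.04)
  st <- range_statistics(d$ranges)
  rep <- model_fit_report(d$phylo, d$ranges, seed = 1)
  f <- rep$fits
  # closed-form range component of the incompatible fit
  expect_equal(f$incompatible$lambda_star, st$B / st$S, tolerance = 1e-10)
  expect_equal(f$incompatible$mu_star, st$D / st$S, tolerance = 1e-10)
  # constraint surfaces
  expect_identical(f$equal$lambda, f$equal$lambda_star)
  expect_identical(f$equal$mu, f$equal$mu_star)
  expect_equal(f$compatible$lambda_star - f$compatible$lambda,
               f$compatible$mu_star - f$compatible$mu, tolerance = 1e-8)
  expect_gte(f$compatible$lambda_star, f$compatible$lambda)
  # nesting of maximised likelihoods
  expect_gte(f$incompatible$loglik, f$compatible$loglik - 1e-6)
  expect_gte(f$compatible$loglik, f$equal$loglik - 1e-6)
  # all fits respect positive net diversification
  for (ft in f) expect_gt(ft$lambda, ft$mu)
  # report carries the mode summaries
  expect_length(rep$lambda_a_interval$lambda_a, 2L)
  expect_true(rep$mode_prevalence$label %in%
                c("anagenesis-dominant", "budding-dominant", "balanced"))
})

test_that("pure-budding data pin the compatible fit to the boundary", {
  d <- small_dataset(seed = 102, n = 120, beta = 0, lambda_a = 0)
  rep <- model_fit_report(d$phylo, d$ranges, seed = 2)
  expect_lt(rep$fits$compatible$loglik - rep$fits$equal$loglik, 2)
  expect_identical(rep$selected[["0.95"]], "equal")
})

test_that("model selection is invariant to rescaling the time unit", {
  d <- small_dataset(seed = 103, n = 100, beta = 0.5, lambda_a = 0.04)
  st <- range_statistics(d$ranges)
  rep1 <- model_fit_report(d$phylo, stats = st, seed = 3)
  f <- 3.7
  pd2 <- phylo_data(d$phylo$branching_ages * f, t0 = d$phylo$t0 * f)
  st2 <- list(B = st$B, D = st$D, S = st$S * f)
  rep2 <- model_fit_report(pd2, stats = st2, seed = 3)
  expect_identical(rep1$selected, rep2$selected)
  expect_equal(rep1$cascades[["0.95"]]$LR, rep2$cascades[["0.95"]]$LR,
               tolerance = 0.02)
  # rates rescale reciprocally
  expect_equal(rep2$fits$incompatible$lambda,
               rep1$fits$incompatible$lambda / f, tolerance = 1e-3)
})

test_that("selection experiments tabulate reproducibly", {
  ex <- selection_experiment(n_reps = 6, lambda = 0.3, mu = 0.1, beta = 0.5,
                             lambda_a = 0.1, n_tips = 40, restarts = 3,
                             seed = 7)
  expect_identical(ex$failed, 0L)
  expect_equal(rowSums(ex$freq), c(`0.95` = 100, `0.99` = 100))
  ex2 <- selection_experiment(n_reps = 6, lambda = 0.3, mu = 0.1, beta = 0.5,
                              lambda_a = 0.1, n_tips = 40, restarts = 3,
                              seed = 7)
  expect_identical(ex$selections, ex2$selections)
})

test_that("independent generators are flagged incompatible most of the time", {
  ex <- selection_experiment(n_reps = 12, n_tips = 60, independent = TRUE,
                             restarts = 3, seed = 11)
  expect_gt(ex$freq["0.95", "incompatible"], 50)
})

test_that("the equal-rates type-I error stays near its nominal level", {
  # under pure budding the cascade should keep the equal model in roughly
  # 1 - alpha of the replicates (scaled-down replicate count)
  ex <- selection_experiment(n_reps = 40, lambda = 0.2, mu = 0.16,
                             beta = 0, lambda_a = 0, n_tips = 100,
                             restarts = 3, seed = 13)
  expect_gte(ex$freq["0.95", "equal"], 80)
  expect_lte(ex$freq["0.95", "incompatible"], 15)
})
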