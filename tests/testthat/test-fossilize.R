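# Range degradation: whole-range removal, Poisson occurrence sampling,
# observed first/last ranges and the Bayesian endpoint estimator.

make_ranges <- function(n = 400, seed = 10) {
  set.seed(seed)
  dur <- rexp(n, 0.3)
  te <- ifelse(runif(n) < 0.4, 0, rexp(n, 0.1))
  range_set(paste0("sp", 1:n), te + dur, te,
            ifelse(te == 0, "extant", "extinct"),
            parent = c(NA, paste0("sp", 1:(n - 1))),
            mode = c("root", rep("budding", n - 1)))
}

test_that("whole-range removal honours scheme and probability", {
  r <- make_ranges()
  expect_identical(nrow(subsample_ranges(r, sampling_config("uniform", 0))),
                   nrow(r))
  set.seed(11)
  kept <- replicate(200, nrow(subsample_ranges(r, sampling_config("uniform",
                                                                  0.9))))
  expect_lt(abs(mean(kept) - 0.1 * nrow(r)), 3 * sd(kept) / sqrt(200) + 0.5)
  s <- subsample_ranges(r, sampling_config("extinct_only", 0.5), seed = 12)
  expect_identical(sum(s$status == "extant"), sum(r$status == "extant"))
  s2 <- subsample_ranges(r, sampling_config("extant_only", 0.5), seed = 13)
  expect_identical(sum(s2$status == "extinct"), sum(r$status == "extinct"))
  expect_error(subsample_ranges(r, sampling_config("poisson", psi = 1)),
               "sample_occurrences")
})

test_that("range rate estimates stay unbiased under uniform removal", {
  # (B/S, D/S) from retained complete-time ranges, x = 0.5
  set.seed(14)
  tr <- simulate_tree(rate_schedule(0.2, 0.16), 80)
  truth <- fossil_rates_from_bdc(0.2, 0.16, 0.5, 0.04)
  est <- sapply(1:100, function(i) {
    rr <- assign_chronospecies(tr, bdc_params(0.2, 0.16, 0.5, 0.04))
    rr <- subsample_ranges(rr, sampling_config("uniform", 0.5))
    s <- range_statistics(rr)
    c(s$B / s$S, s$D / s$S)
  })
  for (j in 1:2) {
    se <- sd(est[j, ]) / sqrt(ncol(est))
    expect_lt(abs(mean(est[j, ]) - c(truth$lambda_star, truth$mu_star)[j]),
              4 * se + 0.02)
  }
})

test_that("occurrence sampling is Poisson in duration", {
  r <- range_set("sp1", 12, 2, "extinct")
  psi <- 0.4
  set.seed(15)
  counts <- replicate(500, {
    occ <- tryCatch(sample_occurrences(r, psi,
                                       include_extant_at_present = FALSE),
                    error = function(e) NULL)
    if (is.null(occ)) 0L else nrow(occ)
  })
  expect_lt(abs(mean(counts) - psi * 10), 3 * sqrt(psi * 10 / 500))
  expect_lt(abs(mean(counts == 0) - exp(-psi * 10)), 0.03)
  # occurrences always bracket within the true range
  set.seed(16)
  for (i in 1:20) {
    occ <- tryCatch(sample_occurrences(r, psi,
                                       include_extant_at_present = FALSE),
                    error = function(e) NULL)
    if (!is.null(occ)) {
      expect_true(all(occ$age >= 2 & occ$age <= 12))
    }
  }
  # large psi: every range observed
  rmany <- make_ranges(100, seed = 17)
  occ <- sample_occurrences(rmany, 50, seed = 18)
  expect_identical(length(unique(occ$species)), nrow(rmany))
})

test_that("observed ranges are first/last appearances, biased short", {
  occ <- occurrence_table(c("a", "a", "b", "c"), c(5, 3, 7, 2))
  rr <- ranges_from_occurrences(occ, extant_ids = "c")
  rr <- rr[order(rr$species), ]
  expect_equal(rr$origination, c(5, 7, 2))
  expect_equal(rr$extinction, c(3, 7, 0))   # single find: degenerate range
  expect_identical(rr$status, c("extinct", "extinct", "extant"))
  # observed durations never exceed the truth
  r <- make_ranges(200, seed = 19)
  occ2 <- sample_occurrences(r, 0.5, seed = 20)
  obs <- ranges_from_occurrences(occ2, r$species[r$status == "extant"])
  tru <- r[match(obs$species, r$species), ]
  expect_true(all(obs$origination - obs$extinction <=
                    tru$origination - tru$extinction + 1e-9))
  # and consequently B/S from observed ranges overestimates lambda*
  s_obs <- range_statistics(obs)
  s_tru <- range_statistics(r)
  expect_gt(s_obs$B / s_obs$S, s_tru$B / s_tru$S)
})

test_that("per-species occurrence counts survive the round trip", {
  r <- make_ranges(50, seed = 21)
  occ <- sample_occurrences(r, 1, seed = 22)
  k <- table(occ$species)
  expect_identical(sum(k), nrow(occ))
  expect_true(all(k >= 1))
})

test_that("endpoint estimation widens observed ranges and finds psi", {
  set.seed(23)
  tr <- simulate_tree(rate_schedule(0.25, 0.15), 40)
  r <- assign_chronospecies(tr, bdc_params(0.25, 0.15, 0.5, 0.04))
  occ <- sample_occurrences(r, 0.5)
  fit <- suppressWarnings(
    estimate_ranges_hpp(occ, r$species[r$status == "extant"],
                        iterations = 6000, seed = 24))
  obs <- ranges_from_occurrences(occ, r$species[r$status == "extant"])
  # posterior-mean durations at least the observed first/last durations
  expect_true(all(fit$ranges$origination - fit$ranges$extinction >=
                    obs$origination - obs$extinction - 1e-9))
  ci <- quantile(fit$psi, c(0.025, 0.975))
  expect_gt(ci[2], 0.25)            # psi = 0.5 is plausible a posteriori
  expect_lt(ci[1], 1.0)
  expect_true(fit$acceptance > 0.05 && fit$acceptance < 0.95)
  # very dense sampling collapses endpoints onto the appearances
  occ_dense <- sample_occurrences(r, 30, seed = 25)
  fit_d <- suppressWarnings(
    estimate_ranges_hpp(occ_dense, r$species[r$status == "extant"],
                        iterations = 4000, seed = 26))
  obs_d <- ranges_from_occurrences(occ_dense,
                                   r$species[r$status == "extant"])
  gap <- (fit_d$ranges$origination - obs_d$origination)
  expect_lt(mean(gap), 0.2)
})
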