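# Chronospecies delimitation and stratigraphic-range bookkeeping.

test_that("species counts hit the closed-form cases", {
  set.seed(1)
  tr <- simulate_tree(rate_schedule(0.25, 0.15), 25)
  nl <- nrow(tr$lineages)
  # pure budding: one species per lineage
  expect_identical(nrow(assign_chronospecies(tr, bdc_params(0.25, 0.15))),
                   nl)
  # pure bifurcation: one species per edge, root edge included
  expect_identical(nrow(assign_chronospecies(tr, bdc_params(0.25, 0.15,
                                                            beta = 1))),
                   2L * nl - 1L)
  # all-cryptic: a single species spanning origin to youngest tip
  rk <- assign_chronospecies(tr, bdc_params(0.25, 0.15, beta = 0.5,
                                            lambda_a = 0.2, kappa = 1))
  expect_identical(nrow(rk), 1L)
  expect_equal(rk$origination, tr$origin_age)
  expect_equal(rk$extinction, min(tr$lineages$end_age))
})

test_that("anagenesis adds species at rate lambda_a per lineage-time", {
  set.seed(2)
  tr <- simulate_tree(rate_schedule(0.25, 0.1), 20)
  L <- tree_length(tr)
  la <- 0.15
  extra <- replicate(300, {
    nrow(assign_chronospecies(tr, bdc_params(0.25, 0.1, lambda_a = la))) -
      nrow(tr$lineages)
  })
  se <- sd(extra) / sqrt(length(extra))
  expect_lt(abs(mean(extra) - la * L), 3 * se)
})

test_that("ranges tile the tree and event ages sit on tree events", {
  set.seed(3)
  tr <- simulate_tree(rate_schedule(0.3, 0.2), 15)
  for (beta in c(0, 0.5, 1)) {
    r <- assign_chronospecies(tr, bdc_params(0.3, 0.2, beta = beta,
                                             lambda_a = 0.1))
    expect_equal(sum(r$origination - r$extinction), tree_length(tr))
  }
  # with no anagenesis and no merging, all range endpoints are node ages,
  # tip ages or the origin
  r <- assign_chronospecies(tr, bdc_params(0.3, 0.2, beta = 0.6))
  tree_ages <- c(tr$origin_age, tr$lineages$start_age, tr$lineages$end_age)
  expect_true(all(r$origination %in% tree_ages))
  expect_true(all(r$extinction %in% tree_ages))
})

test_that("realised bifurcation frequency converges to beta", {
  set.seed(4)
  tr <- simulate_tree(rate_schedule(0.25, 0.2), 150)
  n_nodes <- nrow(tr$lineages) - 1L
  expect_gte(n_nodes, 500L)  # plenty of branching events
  beta <- 0.3
  r <- assign_chronospecies(tr, bdc_params(0.25, 0.2, beta = beta))
  n_bif <- sum(r$mode == "bifurcation") / 2L
  expect_gt(binom.test(n_bif, n_nodes, beta)$p.value, 0.01)
})

test_that("range statistics follow the bookkeeping identities", {
  expect_equal(range_statistics(range_set("sp1", 10, 0, "extant")),
               list(B = 0L, D = 0L, S = 10))
  r2 <- range_set(c("a", "b"), c(10, 4), c(0, 0.5), c("extant", "extinct"),
                  parent = c(NA, "a"), mode = c("root", "budding"))
  s2 <- range_statistics(r2)
  expect_equal(s2$B, 1L)
  expect_equal(s2$D, 1L)
  expect_equal(s2$S, 13.5)
  # B - D = extant - 1 on complete simulations, any parameters
  set.seed(5)
  tr <- simulate_tree(rate_schedule(0.3, 0.2), 20)
  for (p in list(bdc_params(0.3, 0.2), bdc_params(0.3, 0.2, 0.5, 0.1),
                 bdc_params(0.3, 0.2, 1, 0.3, 0.3))) {
    r <- assign_chronospecies(tr, p)
    s <- range_statistics(r)
    expect_identical(s$B - s$D, sum(r$status == "extant") - 1L)
  }
})

test_that("empirical range event rates recover the implied fossil rates", {
  # (B/S, D/S) over replicates converge to Eq-implied (lambda*, mu*)
  set.seed(6)
  trs <- lapply(1:8, function(i) simulate_tree(rate_schedule(0.2, 0.16), 60))
  truth <- fossil_rates_from_bdc(0.2, 0.16, 0.5, 0.04)
  est <- sapply(1:150, function(i) {
    tr <- trs[[(i %% 8) + 1]]
    s <- range_statistics(assign_chronospecies(tr,
                                               bdc_params(0.2, 0.16, 0.5,
                                                          0.04)))
    c(s$B / s$S, s$D / s$S)
  })
  for (j in 1:2) {
    se <- sd(est[j, ]) / sqrt(ncol(est))
    tr_val <- c(truth$lambda_star, truth$mu_star)[j]
    expect_lt(abs(mean(est[j, ]) - tr_val), 4 * se + 0.01)
  }
})

test_that("cryptic merging unions the segments of one morphospecies", {
  set.seed(7)
  tr <- simulate_tree(rate_schedule(0.3, 0.15), 25)
  r0 <- assign_chronospecies(tr, bdc_params(0.3, 0.15, beta = 0.4,
                                            lambda_a = 0.1, kappa = 0))
  r5 <- assign_chronospecies(tr, bdc_params(0.3, 0.15, beta = 0.4,
                                            lambda_a = 0.1, kappa = 0.5))
  expect_lt(nrow(r5), nrow(r0))
  # merged ranges can overlap in time, so durations may exceed the tree
  expect_gte(sum(r5$origination - r5$extinction) + 1e-9,
             0)
  expect_true(all(r5$origination > r5$extinction |
                    (r5$origination == r5$extinction)))
})

test_that("anagenesis calibration reaches the target and prunes to it", {
  set.seed(8)
  tr <- simulate_tree(rate_schedule(0.25, 0.1), 30)
  base_n <- nrow(assign_chronospecies(tr, bdc_params(0.25, 0.1, beta = 0.5)))
  target <- base_n + 15L
  cal <- calibrate_anagenesis(tr, beta = 0.5, target_ranges = target)
  expect_identical(nrow(cal$ranges), as.integer(target))
  expect_true(cal$lambda_a %in% seq(0.1, 10, by = 0.1))
  # expected range count is non-decreasing in lambda_a
  set.seed(9)
  lo <- mean(replicate(60, nrow(assign_chronospecies(tr,
                bdc_params(0.25, 0.1, 0.5, 0.1)))))
  hi <- mean(replicate(60, nrow(assign_chronospecies(tr,
                bdc_params(0.25, 0.1, 0.5, 0.6)))))
  expect_gt(hi, lo)
  expect_error(calibrate_anagenesis(tr, 0.5, 1e6, max_lambda_a = 0.3),
               "not reached")
})
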