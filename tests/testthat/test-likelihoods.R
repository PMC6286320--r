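# Birth-death likelihoods for timetrees and ranges, constant-rate and
# skyline, against algebraic limits and independent numeric oracles.

test_that("p0 and p1 take their boundary values at the present", {
  for (rho in c(0.3, 0.7, 1)) {
    expect_equal(bd_p0(0, 0.3, 0.1, rho), 1 - rho)
    expect_equal(exp(bd_log_p1(0, 0.3, 0.1, rho)), rho)
  }
})

test_that("the Yule limit reproduces the analytic likelihood", {
  pd <- phylo_data(c(8, 5, 2.5, 1), t0 = 11, rho = 1)
  lambda <- 0.23
  yule <- -lambda * 11 + sum(log(lambda) - lambda * pd$branching_ages)
  expect_equal(phylo_loglik(pd, lambda, 1e-12, "origin"), yule,
               tolerance = 1e-6)
})

test_that("the timetree density normalises to P(n | survival)", {
  # integrating exp(loglik) over the (unordered) branching-time hypercube
  # must give the probability that a surviving process has exactly n
  # sampled tips, computed independently from the zero-modified geometric
  # descendant law
  l <- 0.3; m <- 0.15; rho <- 0.8; t0 <- 12
  f <- function(t1, t2) {
    exp(phylo_loglik(phylo_data(sort(c(t1, t2), decreasing = TRUE),
                                t0 = t0, rho = rho), l, m, "origin"))
  }
  sq <- integrate(Vectorize(function(t1) {
    integrate(function(t2) sapply(t2, f, t1 = t1), 0, t0)$value
  }), 0, t0, rel.tol = 1e-8)$value
  # oracle: one-lineage sampled-descendant law via extinction probability
  # and geometric parameter composed with Bernoulli(rho) sampling
  e <- exp(-(l - m) * t0)
  p0 <- m * (1 - e) / (l - m * e)
  q <- l * (1 - e) / (l - m * e)
  ps <- (p0 + (1 - p0) * (1 - q) * (1 - rho) / (1 - q * (1 - rho)))
  qs <- q * rho / (1 - q * (1 - rho))
  p3 <- (1 - ps) * (1 - qs) * qs^2 / (1 - ps)
  expect_equal(sq, p3, tolerance = 1e-4)
})

test_that("crown conditioning squares the survival factor", {
  pd <- phylo_data(c(8, 5, 2.5, 1), t0 = 11, rho = 0.9)
  l <- 0.3; m <- 0.1
  want <- 2 * (bd_log_p1(8, l, m, 0.9) - log1p(-bd_p0(8, l, m, 0.9))) +
    sum(log(l) + bd_log_p1(c(5, 2.5, 1), l, m, 0.9))
  expect_equal(phylo_loglik(pd, l, m, "crown"), want)
  expect_error(phylo_loglik(pd, 0.1, 0.3, "origin"), "lambda > mu")
  expect_error(phylo_loglik(phylo_data(numeric(0), t0 = NULL, n = 1),
                            0.3, 0.1, "origin"), "t0")
})

test_that("range likelihood and its closed-form maximiser agree with optim", {
  expect_equal(range_loglik(list(B = 0, D = 0, S = 10), 0.2, 0.1), -3)
  expect_identical(range_loglik(list(B = 3, D = 2, S = 10), 0.2, 0), -Inf)
  st <- list(B = 37, D = 21, S = 180)
  ml <- range_mle(st)
  expect_equal(ml$lambda_star, 37 / 180)
  expect_equal(ml$mu_star, 21 / 180)
  num <- optim(c(log(0.5), log(0.5)),
               function(p) -range_loglik(st, exp(p[1]), exp(p[2])),
               method = "Nelder-Mead", control = list(reltol = 1e-14))
  expect_equal(exp(num$par), c(ml$lambda_star, ml$mu_star),
               tolerance = 1e-6)
  expect_equal(-num$value, ml$loglik, tolerance = 1e-8)
  # boundary flags
  expect_true(range_mle(list(B = 0, D = 0, S = 5))$boundary)
  expect_equal(range_mle(list(B = 2, D = 1, S = 10))$lambda_star, 0.2)
  expect_equal(range_mle(list(B = 2, D = 1, S = 10))$mu_star, 0.1)
})

test_that("skyline range likelihood is consistent with the constant model", {
  set.seed(30)
  tr <- simulate_tree(rate_schedule(0.3, 0.2), 15)
  r <- assign_chronospecies(tr, bdc_params(0.3, 0.2, 0.4, 0.1))
  st <- range_statistics(r)
  one <- time_bins(tr$origin_age + 1)  # all data in the youngest bin
  expect_equal(skyline_range_loglik(r, one, c(0.35, 0.35), c(0.28, 0.28)),
               range_loglik(st, 0.35, 0.28), tolerance = 1e-10)
  # splitting bins with equal rates changes nothing
  bins3 <- time_bins(c(3, 9))
  expect_equal(skyline_range_loglik(r, bins3, rep(0.35, 3), rep(0.28, 3)),
               range_loglik(st, 0.35, 0.28), tolerance = 1e-10)
  # per-bin statistics conserve the totals
  sb <- skyline_range_statistics(r, bins3)
  expect_equal(sum(sb$S), st$S)
  expect_equal(sum(sb$B), st$B)
  expect_equal(sum(sb$D), st$D)
})

test_that("skyline timetree likelihood collapses to the constant model", {
  set.seed(31)
  tr <- simulate_tree(rate_schedule(0.3, 0.15), 12)
  pd <- prune_extinct(tr)
  l <- 0.28; m <- 0.12
  for (cond in c("origin", "crown")) {
    base <- phylo_loglik(pd, l, m, cond)
    one <- skyline_phylo_loglik(pd, time_bins(pd$t0 + 5), c(l, l), c(m, m),
                                cond)
    expect_equal(one, base, tolerance = 1e-10)
    two <- skyline_phylo_loglik(pd, time_bins(c(2, 6)), rep(l, 3), rep(m, 3),
                                cond)
    expect_equal(two, base, tolerance = 1e-10)
  }
})

test_that("piecewise survival probabilities match an ODE oracle", {
  skip_if_not_installed("deSolve")
  breaks <- c(4, 9)
  lam <- c(0.25, 0.4, 0.2); mu <- c(0.1, 0.05, 0.3)
  rho <- 0.8
  sched <- rate_schedule(lam, mu, breaks)
  rate_fun <- function(a) {
    i <- findInterval(a, breaks) + 1
    c(lam[i], mu[i])
  }
  deriv <- function(a, y, parms) {
    r <- rate_fun(a)
    list(c(r[2] - (r[1] + r[2]) * y[1] + r[1] * y[1]^2,
           -(r[1] + r[2]) * y[2] + 2 * r[1] * y[1] * y[2]))
  }
  ages <- c(2, 4, 7.3, 9, 14)
  sol <- deSolve::ode(c(p0 = 1 - rho, p1 = rho), c(0, ages), deriv, NULL,
                      rtol = 1e-12, atol = 1e-12)
  got <- bdchrono:::skyline_p0_logp1(sched, ages, rho)
  expect_equal(got$p0, unname(sol[-1, "p0"]), tolerance = 1e-8)
  expect_equal(exp(got$log_p1), unname(sol[-1, "p1"]), tolerance = 1e-8)
})

test_that("timetree ML estimates recover the generating rates", {
  set.seed(32)
  est <- sapply(1:40, function(i) {
    tr <- simulate_tree(rate_schedule(0.2, 0.1), 100)
    fit <- phylo_mle(prune_extinct(tr), "origin", restarts = 3)
    c(fit$lambda, fit$mu)
  })
  for (j in 1:2) {
    se <- sd(est[j, ]) / sqrt(ncol(est))
    expect_lt(abs(mean(est[j, ]) - c(0.2, 0.1)[j]), 4 * se + 0.01)
  }
})

test_that("log-likelihoods are finite inside the domain", {
  pd <- phylo_data(c(8, 5, 1), t0 = 11)
  st <- list(B = 10, D = 4, S = 55)
  for (l in c(0.05, 0.3, 1.2)) {
    for (m in c(0, l / 2, l * 0.95)) {
      expect_true(is.finite(phylo_loglik(pd, l, m, "origin")))
      expect_true(is.finite(range_loglik(st, l, m + 1e-3)))
    }
  }
})
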