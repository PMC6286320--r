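## Metropolis-Hastings samplers for the joint (timetree x ranges) model
## with Gamma(1.1, 1.1) priors on all birth-death rates, under the three
## constraint sets, plus the skyline variant with per-bin rates and the
## posterior model check used in place of the ML cascade.

## parameter vectors by model:
##   equal:        (lambda, mu)              with lambda* = lambda, mu* = mu
##   compatible:   (lambda, mu, c)           with lambda* = lambda + c, ...
##   incompatible: (lambda, mu, lambda*, mu*)
.bayes_pack <- function(model) {
  switch(model,
         equal = c("lambda", "mu"),
         compatible = c("lambda", "mu", "c"),
         incompatible = c("lambda", "mu", "lambda_star", "mu_star"))
}

.bayes_expand <- function(theta, model) {
  if (model == "equal") {
    c(theta[1L], theta[2L], theta[1L], theta[2L])
  } else if (model == "compatible") {
    c(theta[1L], theta[2L], theta[1L] + theta[3L], theta[2L] + theta[3L])
  } else theta
}

.bayes_logpost <- function(theta, model, phylo, stats, conditioning,
                           prior_shape, prior_rate, prior_only) {
  q <- .bayes_expand(theta, model)
  lam <- q[1L]; mu <- q[2L]; ls <- q[3L]; ms <- q[4L]
  if (any(q < 0) || lam <= 0 || ls <= 0) return(-Inf)
  ## positive net diversification is a likelihood-domain constraint, not a
  ## prior one: prior-only runs sample the untruncated gamma prior
  if (!prior_only && lam <= mu) return(-Inf)
  lp <- sum(dgamma(q, prior_shape, prior_rate, log = TRUE))
  if (model == "compatible") {
    ## prior placed on (lambda, mu, c); the expanded lambda*, mu* are
    ## deterministic, so replace their prior terms by the offset's
    lp <- sum(dgamma(c(lam, mu, theta[3L]), prior_shape, prior_rate,
                     log = TRUE))
  }
  if (!is.finite(lp)) return(-Inf)
  if (prior_only) return(lp)
  ll <- tryCatch(phylo_loglik(phylo, lam, mu, conditioning) +
                   range_loglik(stats, ls, ms),
                 error = function(e) -Inf)
  if (is.nan(ll)) stop("NaN posterior encountered")
  lp + ll
}

#' Metropolis-Hastings sampling of birth-death rates
#'
#' Samples the posterior of `(lambda, mu, lambda*, mu*)` under the chosen
#' constraint model, targeting the product of the independent timetree and
#' range likelihoods and Gamma priors (default shape and rate 1.1) on the
#' rates. Proposals are log-scale random walks, tuned during burn-in to an
#' acceptance rate near 0.3. Under the constrained models the chain moves
#' on the constraint surface: 2 free rates (equal) or `(lambda, mu, c >= 0)`
#' (compatible).
#'
#' @param phylo a [phylo_data()] object (ignored when `prior_only`).
#' @param stats range statistics (list with `B`, `D`, `S`).
#' @param model `"equal"`, `"compatible"` or `"incompatible"`.
#' @param prior_shape,prior_rate gamma prior parameters for all rates.
#' @param iterations total MCMC iterations (>= 1e4 recommended).
#' @param burnin fraction discarded as burn-in.
#' @param conditioning timetree conditioning.
#' @param prior_only suppress the likelihood (prior-recovery checks).
#' @param seed optional integer seed; fixed seeds give bit-identical chains.
#' @return A list of class `posterior_sample`: `draws` (post-burn-in matrix
#'   with columns lambda, mu, lambda_star, mu_star), `log_post` trace,
#'   `acceptance` rate, `burnin` fraction and `model`. A warning is issued
#'   when the acceptance rate leaves `[0.1, 0.6]`.
#' @export
mcmc_sample <- function(phylo, stats, model = c("incompatible", "equal",
                                                "compatible"),
                        prior_shape = 1.1, prior_rate = 1.1,
                        iterations = 20000L, burnin = 0.25,
                        conditioning = "origin", prior_only = FALSE,
                        seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  pn <- .bayes_pack(model)
  np <- length(pn)
  theta <- switch(model, equal = c(0.6, 0.2),
                  compatible = c(0.6, 0.2, 0.1),
                  incompatible = c(0.6, 0.2, 0.6, 0.2))
  lp <- .bayes_logpost(theta, model, phylo, stats, conditioning,
                       prior_shape, prior_rate, prior_only)
  step <- rep(0.25, np)
  nburn <- ceiling(iterations * burnin)
  draws <- matrix(NA_real_, iterations, 4L,
                  dimnames = list(NULL, c("lambda", "mu", "lambda_star",
                                          "mu_star")))
  lptr <- numeric(iterations)
  acc <- acc_n <- 0L
  tune_acc <- tune_n <- 0L
  for (it in seq_len(iterations)) {
    j <- ((it - 1L) %% np) + 1L          # cycle over parameters
    prop <- theta
    prop[j] <- theta[j] * exp(step[j] * (runif(1L) - 0.5) * 2)
    lp_p <- .bayes_logpost(prop, model, phylo, stats, conditioning,
                           prior_shape, prior_rate, prior_only)
    ## log-scale multiplicative walk: Jacobian ratio prop[j] / theta[j]
    a <- lp_p - lp + log(prop[j]) - log(theta[j])
    acc_n <- acc_n + 1L; tune_n <- tune_n + 1L
    if (is.finite(a) && log(runif(1L)) < a) {
      theta <- prop; lp <- lp_p
      acc <- acc + 1L; tune_acc <- tune_acc + 1L
    }
    if (it <= nburn && tune_n == 100L) {  # adapt during burn-in only
      r <- tune_acc / tune_n
      step <- step * exp(0.5 * (r - 0.3))
      tune_acc <- tune_n <- 0L
    }
    draws[it, ] <- .bayes_expand(theta, model)
    lptr[it] <- lp
  }
  rate <- acc / acc_n
  if (rate < 0.1 || rate > 0.6) {
    warning("mcmc_sample: acceptance rate ", round(rate, 3),
            " outside [0.1, 0.6]")
  }
  keep <- (nburn + 1L):iterations
  structure(list(draws = draws[keep, , drop = FALSE], log_post = lptr[keep],
                 acceptance = rate, burnin = burnin, model = model,
                 iterations = iterations),
            class = "posterior_sample")
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat(sprintf("Posterior sample (%s model): %d draws, acceptance %.2f\n",
              x$model, nrow(x$draws), x$acceptance))
  print(round(apply(x$draws, 2L, quantile, c(0.025, 0.5, 0.975)), 4L))
  invisible(x)
}

#' Posterior model check from an unconstrained sample
#'
#' Applies the credible-interval rules to a posterior sample drawn under
#' the incompatible (unconstrained) model: the equal rates model is
#' selected when 0 falls inside the credible intervals of both
#' `lambda* - lambda` and `mu* - mu`; otherwise the compatible rates model
#' when 0 falls inside the credible interval of
#' `(lambda* - lambda) - (mu* - mu)` and `P(lambda* >= lambda)` exceeds
#' `1 - level`; otherwise the incompatible model.
#'
#' @param sample a `posterior_sample` from the incompatible model.
#' @param level credible level, 0.95 or 0.99.
#' @return A list with `selected` and the interval diagnostics.
#' @export
posterior_model_check <- function(sample, level = 0.95) {
  stopifnot(inherits(sample, "posterior_sample"), level > 0.5, level < 1)
  d <- sample$draws
  if (nrow(d) < 1000L) stop("too few post-burn-in draws (< 1000)")
  a <- (1 - level) / 2
  dl <- d[, "lambda_star"] - d[, "lambda"]
  dm <- d[, "mu_star"] - d[, "mu"]
  dd <- dl - dm
  ci <- function(v) quantile(v, c(a, 1 - a), names = FALSE)
  ci_dl <- ci(dl); ci_dm <- ci(dm); ci_dd <- ci(dd)
  p_ge <- mean(dl >= 0)
  inside <- function(iv) iv[1L] <= 0 && iv[2L] >= 0
  selected <- if (inside(ci_dl) && inside(ci_dm)) {
    "equal"
  } else if (inside(ci_dd) && p_ge > (1 - level)) {
    "compatible"
  } else "incompatible"
  list(selected = selected, level = level,
       ci_lambda_diff = ci_dl, ci_mu_diff = ci_dm, ci_diff_of_diffs = ci_dd,
       p_lambda_star_ge_lambda = p_ge)
}

#' Skyline Metropolis-Hastings sampler
#'
#' Samples per-bin rate quadruples under the chosen constraint model using
#' the skyline likelihoods ([skyline_phylo_loglik()],
#' [skyline_range_loglik()]), with independent Gamma priors per bin and no
#' smoothing across bins. Bins without any range event are prior-dominated
#' and flagged. Per-bin speciation-mode statistics (`lambda*_b - 2
#' lambda_b`) are derivable from the returned draws.
#'
#' @param phylo a [phylo_data()] object.
#' @param ranges a [range_set()].
#' @param bins a [time_bins()] object.
#' @param model constraint applied within each bin: `"incompatible"`
#'   (free) or `"compatible"` (`lambda*_b = lambda_b + c_b`, `c_b >= 0`).
#' @param prior_shape,prior_rate gamma prior on every rate.
#' @param iterations,burnin MCMC settings.
#' @param conditioning timetree conditioning.
#' @param seed optional integer seed.
#' @return A list of class `skyline_posterior`: `draws` (matrix with
#'   per-bin columns `lambda.b`, `mu.b`, `lambda_star.b`, `mu_star.b`),
#'   `log_post`, `acceptance`, `empty_bins`, and `mode_statistic` (draws of
#'   `lambda*_b - 2 lambda_b` per bin).
#' @export
skyline_mcmc <- function(phylo, ranges, bins,
                         model = c("incompatible", "compatible"),
                         prior_shape = 1.1, prior_rate = 1.1,
                         iterations = 20000L, burnin = 0.25,
                         conditioning = "origin", seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  nb <- n_bins(bins)
  st <- skyline_range_statistics(ranges, bins)
  empty <- which(st$B + st$D == 0 & st$S == 0)
  ## theta: per bin (lambda, mu) + per bin (lambda*, mu*) or offset c
  np_bin <- if (model == "incompatible") 4L else 3L
  theta <- matrix(rep(if (model == "incompatible") {
    c(0.4, 0.1, 0.4, 0.1)
  } else c(0.4, 0.1, 0.1), each = nb), nb, np_bin)
  expand <- function(th) {
    if (model == "incompatible") {
      list(l = th[, 1L], m = th[, 2L], ls = th[, 3L], ms = th[, 4L])
    } else {
      list(l = th[, 1L], m = th[, 2L], ls = th[, 1L] + th[, 3L],
           ms = th[, 2L] + th[, 3L])
    }
  }
  logpost <- function(th) {
    q <- expand(th)
    if (any(q$l <= q$m) || any(th < 0) || any(q$l <= 0) || any(q$ls <= 0)) {
      return(-Inf)
    }
    lp <- sum(dgamma(cbind(q$l, q$m, th[, 3L:np_bin]),
                     prior_shape, prior_rate, log = TRUE))
    if (!is.finite(lp)) return(-Inf)
    ll <- tryCatch(
      skyline_phylo_loglik(phylo, bins, q$l, q$m, conditioning) +
        skyline_range_ll_stats(st, q$ls, q$ms),
      error = function(e) -Inf)
    lp + ll
  }
  lp <- logpost(theta)
  if (!is.finite(lp)) stop("skyline_mcmc: initial state has zero posterior")
  step <- matrix(0.3, nb, np_bin)
  nburn <- ceiling(iterations * burnin)
  ncol_out <- nb * 4L
  cn <- as.vector(outer(c("lambda", "mu", "lambda_star", "mu_star"),
                        seq_len(nb), paste, sep = "."))
  draws <- matrix(NA_real_, iterations, ncol_out,
                  dimnames = list(NULL, cn))
  lptr <- numeric(iterations)
  acc <- acc_n <- 0L
  idx <- cbind(rep(seq_len(nb), np_bin), rep(seq_len(np_bin), each = nb))
  for (it in seq_len(iterations)) {
    k <- ((it - 1L) %% nrow(idx)) + 1L
    b <- idx[k, 1L]; j <- idx[k, 2L]
    prop <- theta
    prop[b, j] <- theta[b, j] * exp(step[b, j] * (runif(1L) - 0.5) * 2)
    lp_p <- logpost(prop)
    a <- lp_p - lp + log(prop[b, j]) - log(theta[b, j])
    acc_n <- acc_n + 1L
    if (is.finite(a) && log(runif(1L)) < a) {
      theta <- prop; lp <- lp_p; acc <- acc + 1L
      if (it <= nburn) step[b, j] <- step[b, j] * 1.05
    } else if (it <= nburn) {
      step[b, j] <- step[b, j] * 0.97
    }
    q <- expand(theta)
    draws[it, ] <- as.vector(t(cbind(q$l, q$m, q$ls, q$ms)))
    lptr[it] <- lp
  }
  keep <- (nburn + 1L):iterations
  d <- draws[keep, , drop = FALSE]
  ms <- sapply(seq_len(nb), function(b) {
    d[, paste0("lambda_star.", b)] - 2 * d[, paste0("lambda.", b)]
  })
  colnames(ms) <- paste0("bin", seq_len(nb))
  if (length(empty)) {
    message("skyline_mcmc: bins with no range data (prior-dominated): ",
            paste(empty, collapse = ", "))
  }
  structure(list(draws = d, log_post = lptr[keep],
                 acceptance = acc / acc_n, empty_bins = empty,
                 mode_statistic = ms, bins = bins, model = model),
            class = "skyline_posterior")
}
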