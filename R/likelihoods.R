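## Exact log-likelihoods for the two data types: the reconstructed
## birth-death process density of an extant timetree (origin or crown
## conditioning, incomplete sampling fraction rho), and the
## stratigraphic-range birth-death likelihood, which depends on the data
## only through (B, D, S). Skyline (piecewise-constant-rate) variants
## propagate the extinction and one-sampled-descendant probabilities
## across bin boundaries from the present backwards.

#' Constant-rate birth-death survival and singleton probabilities
#'
#' `bd_p0(t)` is the probability that a lineage alive at age `t` leaves no
#' sampled descendant at the present (each extant descendant is sampled
#' with probability `rho`); `bd_log_p1(t)` is the log probability that it
#' leaves exactly one. These are the building blocks of the reconstructed
#' birth-death process density. At `t = 0`, `p0 = 1 - rho` and `p1 = rho`.
#'
#' @param t age (time before present), vectorised.
#' @param lambda,mu branching and extinction rates.
#' @param rho sampling fraction in `(0, 1]`.
#' @return `bd_p0`: probability; `bd_log_p1`: log probability.
#' @export
bd_p0 <- function(t, lambda, mu, rho = 1) {
  r <- lambda - mu
  1 - rho * r / (rho * lambda + (lambda * (1 - rho) - mu) * exp(-r * t))
}

#' @rdname bd_p0
#' @export
bd_log_p1 <- function(t, lambda, mu, rho = 1) {
  r <- lambda - mu
  log(rho) + 2 * log(r) - r * t -
    2 * log(rho * lambda + (lambda * (1 - rho) - mu) * exp(-r * t))
}

check_bd_rates <- function(lambda, mu) {
  if (!is.finite(lambda) || !is.finite(mu) || lambda <= 0 || mu < 0) {
    stop("need lambda > 0 and mu >= 0")
  }
  if (lambda <= mu) stop("estimation requires lambda > mu (positive net diversification)")
}

#' Birth-death log-likelihood of an extant timetree
#'
#' Log density of the branching ages of a reconstructed phylogeny of `n`
#' extant species under the constant-rate birth-death process with
#' incomplete sampling. With origin conditioning,
#' \deqn{f(\mathcal{T} \mid t_0) = \frac{p_1(t_0)}{1 - p_0(t_0)}
#'       \prod_{i=1}^{n-1} \lambda\, p_1(t_i),}
#' where `p0(t)`/`p1(t)` are the probabilities that a lineage of age `t`
#' leaves zero / exactly one sampled descendant. With crown conditioning
#' both crown lineages are conditioned on leaving sampled descendants:
#' `[p1(t1)/(1 - p0(t1))]^2 prod_{i>=2} lambda p1(t_i)`.
#'
#' @param phylo a [phylo_data()] object; origin conditioning requires its
#'   `t0`, crown conditioning requires `n >= 2`.
#' @param lambda,mu branching and extinction rates; `lambda > mu` required.
#' @param conditioning `"origin"` or `"crown"`.
#' @return The log-likelihood (proportionality constants dropped).
#' @export
phylo_loglik <- function(phylo, lambda, mu, conditioning = c("origin", "crown")) {
  stopifnot(inherits(phylo, "phylo_data"))
  conditioning <- match.arg(conditioning)
  check_bd_rates(lambda, mu)
  rho <- phylo$rho
  tt <- phylo$branching_ages
  if (any(tt < 0)) stop("negative branching ages")
  if (conditioning == "origin") {
    if (is.null(phylo$t0)) stop("origin conditioning requires the origin age t0")
    cond <- bd_log_p1(phylo$t0, lambda, mu, rho) -
      log1p(-bd_p0(phylo$t0, lambda, mu, rho))
    sum(log(lambda) + bd_log_p1(tt, lambda, mu, rho)) + cond
  } else {
    if (phylo$n < 2L) stop("crown conditioning requires n >= 2")
    t1 <- tt[1L]
    cond <- 2 * (bd_log_p1(t1, lambda, mu, rho) -
                   log1p(-bd_p0(t1, lambda, mu, rho)))
    rest <- tt[-1L]
    sum(log(lambda) + bd_log_p1(rest, lambda, mu, rho)) + cond
  }
}

#' Stratigraphic-range birth-death log-likelihood
#'
#' The likelihood of a set of species ranges depends only on the number of
#' birth events `B`, death events `D`, and summed durations `S`:
#' \deqn{\log P(\mathcal{R}) = B \log\lambda^* + D \log\mu^*
#'       - (\lambda^* + \mu^*) S}
#' (constant dropped). `mu_star = 0` is only admissible when `D = 0`;
#' otherwise the log-likelihood is `-Inf`.
#'
#' @param stats a list with `B`, `D`, `S` (see [range_statistics()]).
#' @param lambda_star,mu_star origination and extinction rates (`lambda_star
#'   > 0`, `mu_star >= 0`).
#' @return The log-likelihood.
#' @examples
#' range_loglik(list(B = 0, D = 0, S = 10), 0.2, 0.1)  # -3
#' @export
range_loglik <- function(stats, lambda_star, mu_star) {
  stopifnot(stats$S > 0, lambda_star > 0, mu_star >= 0)
  if (stats$D > 0 && mu_star == 0) return(-Inf)
  dterm <- if (stats$D > 0) stats$D * log(mu_star) else 0
  stats$B * log(lambda_star) + dterm - (lambda_star + mu_star) * stats$S
}

#' Closed-form maximum-likelihood estimates of the range rates
#'
#' The range likelihood is maximised at `lambda_star = B/S` and `mu_star =
#' D/S`. Estimates of exactly zero sit on the boundary of the admissible
#' rate space (`lambda_star > 0`) and are flagged.
#'
#' @param stats a list with `B`, `D`, `S`.
#' @return A list with `lambda_star`, `mu_star`, `boundary` (TRUE when
#'   either estimate is 0) and `loglik`.
#' @export
range_mle <- function(stats) {
  stopifnot(stats$S > 0)
  ls <- stats$B / stats$S
  ms <- stats$D / stats$S
  ll <- (if (stats$B > 0) stats$B * log(ls) else 0) +
    (if (stats$D > 0) stats$D * log(ms) else 0) - (ls + ms) * stats$S
  list(lambda_star = ls, mu_star = ms,
       boundary = (stats$B == 0) || (stats$D == 0), loglik = ll)
}

#' Maximum-likelihood phylogenetic rates from an extant timetree
#'
#' Maximises [phylo_loglik()] over `(lambda, mu)` under the constraint
#' `lambda > mu >= 0`, enforced by the reparameterisation `d = lambda - mu >
#' 1e-8`, `mu > 0` on the log scale. Optimisation is restarted from several
#' random initial values.
#'
#' @param phylo a [phylo_data()] object.
#' @param conditioning `"origin"` or `"crown"`.
#' @param restarts number of random restarts.
#' @param seed optional integer seed.
#' @return A list with `lambda`, `mu` and `loglik`.
#' @export
phylo_mle <- function(phylo, conditioning = c("origin", "crown"),
                      restarts = 5L, seed = NULL) {
  conditioning <- match.arg(conditioning)
  if (!is.null(seed)) set.seed(seed)
  obj <- function(par) {
    d <- exp(par[1L]) + 1e-8; m <- exp(par[2L])
    -phylo_loglik(phylo, d + m, m, conditioning)
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- log(exp(runif(2L, log(0.01), log(2))))
    fit <- tryCatch(optim(init, obj, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-12)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("phylo_mle: all optimisation restarts failed")
  d <- exp(best$par[1L]) + 1e-8; m <- exp(best$par[2L])
  list(lambda = d + m, mu = m, loglik = -best$value)
}

## ---------------------------------------------------------------------------
## Skyline (piecewise-constant) variants
## ---------------------------------------------------------------------------

#' Time bins for skyline models
#'
#' @param breaks increasing vector of bin boundary ages; bins are
#'   `[0, b1), [b1, b2), ..., [bk, Inf)`, the oldest extending to the origin.
#' @return Object of class `time_bins`.
#' @export
time_bins <- function(breaks) {
  stopifnot(is.numeric(breaks), all(breaks > 0), !is.unsorted(breaks, strictly = TRUE))
  structure(list(breaks = as.numeric(breaks)), class = "time_bins")
}

n_bins <- function(bins) length(bins$breaks) + 1L

#' Per-bin sufficient statistics of a range set
#'
#' Splits the range birth-death sufficient statistics across time bins:
#' `B_b` counts originations inside bin `b` (the oldest range's origination
#' is the process start and is not counted), `D_b` extinctions of extinct
#' ranges, and `S_b` the lineage-time accrued within the bin.
#'
#' @param ranges a [range_set()].
#' @param bins a [time_bins()] object.
#' @return A data frame with one row per bin (youngest first): `B`, `D`, `S`.
#' @export
skyline_range_statistics <- function(ranges, bins) {
  stopifnot(inherits(ranges, "range_set"), inherits(bins, "time_bins"))
  lo <- c(0, bins$breaks)
  hi <- c(bins$breaks, Inf)
  root <- which.max(ranges$origination)
  orig <- ranges$origination[-root]
  dea <- ranges$extinction[ranges$status == "extinct"]
  B <- D <- S <- numeric(length(lo))
  for (b in seq_along(lo)) {
    B[b] <- sum(orig >= lo[b] & orig < hi[b])
    D[b] <- sum(dea >= lo[b] & dea < hi[b])
    S[b] <- sum(pmax(0, pmin(ranges$origination, hi[b]) -
                       pmax(ranges$extinction, lo[b])))
  }
  data.frame(bin = seq_along(lo), lower = lo, upper = hi, B = B, D = D, S = S)
}

#' Skyline stratigraphic-range log-likelihood
#'
#' Sum over bins of the constant-rate range log-likelihood evaluated on the
#' per-bin statistics: `sum_b [B_b log lambda*_b + D_b log mu*_b -
#' (lambda*_b + mu*_b) S_b]`. With a single bin this equals
#' [range_loglik()]; splitting a bin without changing rates leaves the
#' value unchanged.
#'
#' @param ranges a [range_set()].
#' @param bins a [time_bins()] object.
#' @param lambda_star,mu_star per-bin rates, youngest bin first.
#' @return The log-likelihood.
#' @export
skyline_range_loglik <- function(ranges, bins, lambda_star, mu_star) {
  st <- skyline_range_statistics(ranges, bins)
  skyline_range_ll_stats(st, lambda_star, mu_star)
}

## same, from precomputed per-bin statistics (the data part is fixed
## during MCMC, so samplers avoid recomputing it every iteration)
skyline_range_ll_stats <- function(st, lambda_star, mu_star) {
  nb <- nrow(st)
  stopifnot(length(lambda_star) == nb, length(mu_star) == nb,
            all(lambda_star > 0), all(mu_star >= 0))
  ll <- 0
  for (b in seq_len(nb)) {
    if (st$S[b] == 0) next
    if (st$D[b] > 0 && mu_star[b] == 0) return(-Inf)
    dterm <- if (st$D[b] > 0) st$D[b] * log(mu_star[b]) else 0
    ll <- ll + st$B[b] * log(lambda_star[b]) + dterm -
      (lambda_star[b] + mu_star[b]) * st$S[b]
  }
  ll
}

## p0 and log p1 at ages `t` under a piecewise schedule with sampling rho,
## via the fractional-linear generating-function composition
skyline_p0_logp1 <- function(schedule, t, rho = 1) {
  p0 <- numeric(length(t)); lp1 <- numeric(length(t))
  s <- 1 - rho
  for (i in seq_along(t)) {
    pq <- lineage_p0q(schedule, from = t[i], to = 0)
    p0i <- pq[["p0"]]; qi <- pq[["q"]]
    p0[i] <- p0i + (1 - p0i) * (1 - qi) * s / (1 - qi * s)
    lp1[i] <- log(rho) + log1p(-p0i) + log1p(-qi) - 2 * log1p(-qi * s)
  }
  list(p0 = p0, log_p1 = lp1)
}

#' Skyline birth-death log-likelihood of an extant timetree
#'
#' Extends [phylo_loglik()] to piecewise-constant rates: the no-sampled-
#' descendant and one-sampled-descendant probabilities are propagated
#' across bin boundaries from the present backwards (the value at a
#' boundary is the initial condition of the older bin), each branching
#' event contributes `lambda_b(t_i) p1(t_i)` with the rate of the bin the
#' event falls in, and conditioning is as in the constant-rate case.
#'
#' @param phylo a [phylo_data()] object.
#' @param bins a [time_bins()] object.
#' @param lambda,mu per-bin rates, youngest bin first; all `lambda_b > 0`.
#' @param conditioning `"origin"` or `"crown"`.
#' @return The log-likelihood.
#' @export
skyline_phylo_loglik <- function(phylo, bins, lambda, mu,
                                 conditioning = c("origin", "crown")) {
  stopifnot(inherits(phylo, "phylo_data"), inherits(bins, "time_bins"))
  conditioning <- match.arg(conditioning)
  nb <- n_bins(bins)
  stopifnot(length(lambda) == nb, length(mu) == nb, all(lambda > 0),
            all(mu >= 0))
  sched <- rate_schedule(lambda, mu, bins$breaks)
  tt <- phylo$branching_ages
  lam_at <- rates_at_age(sched, tt)$lambda
  pp <- skyline_p0_logp1(sched, tt, phylo$rho)
  if (conditioning == "origin") {
    if (is.null(phylo$t0)) stop("origin conditioning requires the origin age t0")
    p0t <- skyline_p0_logp1(sched, phylo$t0, phylo$rho)
    cond <- p0t$log_p1 - log1p(-p0t$p0)
    sum(log(lam_at) + pp$log_p1) + cond
  } else {
    if (phylo$n < 2L) stop("crown conditioning requires n >= 2")
    cond <- 2 * (pp$log_p1[1L] - log1p(-pp$p0[1L]))
    sum(log(lam_at[-1L]) + pp$log_p1[-1L]) + cond
  }
}
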