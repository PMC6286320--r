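## Degrading true chronospecies ranges into realistic fossil data: whole
## ranges lost at random (uniformly or conditional on extinction status),
## occurrence times drawn under Poisson preservation, observed ranges
## rebuilt from first/last appearances, and a homogeneous-Poisson
## Metropolis-Hastings estimator of the true range endpoints.

#' Fossil sampling configuration
#'
#' @param scheme one of `"uniform"`, `"extinct_only"`, `"extant_only"`
#'   (whole-range removal) or `"poisson"` (occurrence sampling).
#' @param x removal probability in `[0, 1)` for the removal schemes.
#' @param psi Poisson preservation rate (> 0), for `scheme = "poisson"`.
#' @param include_extant_at_present should extant species receive a
#'   present-day record (so their extinction age is known to be 0)?
#' @return An object of class `sampling_config`.
#' @export
sampling_config <- function(scheme = c("uniform", "extinct_only",
                                       "extant_only", "poisson"),
                            x = 0, psi = NULL,
                            include_extant_at_present = TRUE) {
  scheme <- match.arg(scheme)
  stopifnot(x >= 0, x < 1)
  if (scheme == "poisson") {
    stopifnot(is.numeric(psi), length(psi) == 1L, psi > 0)
  }
  structure(list(scheme = scheme, x = x, psi = psi,
                 include_extant_at_present = include_extant_at_present),
            class = "sampling_config")
}

#' Randomly remove whole ranges from a range set
#'
#' Drops each eligible range independently with probability `config$x`.
#' Eligibility is controlled by the scheme: all ranges (`"uniform"`), only
#' extinct ranges (`"extinct_only"`) or only extant ranges
#' (`"extant_only"`); ineligible ranges are always retained.
#'
#' @param ranges a [range_set()].
#' @param config a [sampling_config()] with a removal scheme.
#' @param seed optional integer seed.
#' @return The retained [range_set()].
#' @export
subsample_ranges <- function(ranges, config, seed = NULL) {
  stopifnot(inherits(ranges, "range_set"), inherits(config, "sampling_config"))
  if (config$scheme == "poisson") {
    stop("use sample_occurrences() for the poisson scheme")
  }
  if (!is.null(seed)) set.seed(seed)
  eligible <- switch(config$scheme,
                     uniform = rep(TRUE, nrow(ranges)),
                     extinct_only = ranges$status == "extinct",
                     extant_only = ranges$status == "extant")
  drop <- eligible & runif(nrow(ranges)) < config$x
  if (all(drop)) stop("all ranges removed by subsampling")
  out <- ranges[!drop, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("range_set", "data.frame")
  out
}

#' Occurrence table
#'
#' @param species species identifier per occurrence.
#' @param age occurrence age (time before present, >= 0).
#' @return An object of classes `occurrence_table` and `data.frame`.
#' @export
occurrence_table <- function(species, age) {
  x <- data.frame(species = as.character(species), age = as.numeric(age))
  if (any(x$age < 0)) stop("occurrence ages must be >= 0")
  class(x) <- c("occurrence_table", "data.frame")
  x
}

#' @export
print.occurrence_table <- function(x, ...) {
  cat(sprintf("Fossil occurrences: %d records, %d species\n",
              nrow(x), length(unique(x$species))))
  NextMethod()
}

#' Sample fossil occurrences along ranges
#'
#' Draws, for each range, a Poisson(`psi` x duration) number of occurrence
#' times uniformly within the range. Species with no occurrence (and no
#' present-day record) are absent from the output, so the probability that
#' a range is observed at all increases with its duration.
#'
#' @param ranges a [range_set()].
#' @param psi preservation rate per lineage per time unit (> 0).
#' @param include_extant_at_present give every extant species a record at
#'   age 0 (its extant status is known).
#' @param seed optional integer seed.
#' @return An [occurrence_table()].
#' @export
sample_occurrences <- function(ranges, psi, include_extant_at_present = TRUE,
                               seed = NULL) {
  stopifnot(inherits(ranges, "range_set"), psi > 0)
  if (!is.null(seed)) set.seed(seed)
  dur <- ranges$origination - ranges$extinction
  k <- rpois(nrow(ranges), psi * dur)
  sp <- rep(ranges$species, k)
  age <- rep(ranges$extinction, k) + runif(sum(k)) * rep(dur, k)
  if (include_extant_at_present) {
    ext <- ranges$species[ranges$status == "extant"]
    sp <- c(sp, ext)
    age <- c(age, rep(0, length(ext)))
  }
  if (!length(sp)) stop("no occurrences sampled; psi too small")
  o <- order(sp, -age)
  occurrence_table(sp[o], age[o])
}

#' Observed ranges from first and last appearances
#'
#' Collapses an occurrence table to per-species observed ranges: the
#' origination is the oldest occurrence, the extinction the youngest (0 for
#' species listed as extant, whatever their last appearance). Observed
#' ranges are biased short relative to the true ranges; single-occurrence
#' extinct species yield degenerate zero-duration ranges, which are kept.
#'
#' @param occ an [occurrence_table()].
#' @param extant_ids character vector of species known to be extant.
#' @return A [range_set()] with `mode = "observed"` semantics: parent and
#'   mode are unknown (`NA`/`"observed"`).
#' @export
ranges_from_occurrences <- function(occ, extant_ids = character(0)) {
  stopifnot(inherits(occ, "occurrence_table"), nrow(occ) >= 1L)
  fa <- tapply(occ$age, occ$species, max)
  la <- tapply(occ$age, occ$species, min)
  sp <- names(fa)
  extant <- sp %in% extant_ids
  la[extant] <- 0
  out <- range_set(sp, as.numeric(fa), as.numeric(la),
                   ifelse(extant, "extant", "extinct"),
                   parent = NA, mode = "observed")
  attr(out, "observed") <- TRUE
  out
}

## log-likelihood of the occurrence counts given endpoints and psi under
## homogeneous Poisson preservation, each taxon conditioned on >= 1 find
hpp_loglik <- function(k, dur, psi) {
  if (psi <= 0 || any(dur < 0)) return(-Inf)
  sum(k * log(psi) - psi * dur - log1p(-exp(-psi * pmax(dur, 1e-12))))
}

#' Bayesian range-endpoint estimation under homogeneous Poisson preservation
#'
#' Metropolis-Hastings sampler for the true origination (`ts`) and
#' extinction (`te`) times of each sampled species, jointly with the
#' preservation rate `psi` and the range birth-death rates
#' (`lambda*`, `mu*`). Each taxon's occurrence count is Poisson in its range
#' duration and conditioned on being sampled at least once; endpoints are
#' constrained to bracket the observed first/last appearances, extant
#' species have `te = 0` fixed; `lambda*` and `mu*` are given Gamma(1.1,
#' 1.1) priors and drawn by Gibbs steps from their conjugate conditionals
#' given the current range statistics, `psi` a Gamma(1.1, 1.1) prior with
#' log-scale random-walk updates.
#'
#' @param occ an [occurrence_table()]; every species needs >= 1 occurrence.
#' @param extant_ids species known to be extant (their `te` is fixed at 0).
#' @param iterations MCMC iterations.
#' @param burnin fraction of iterations discarded.
#' @param seed optional integer seed.
#' @return A list with `ranges` (posterior-mean endpoints as a
#'   [range_set()]), `psi` (posterior draws), `rates` (draws of
#'   `lambda_star`, `mu_star`), `ess_psi`, and `acceptance`. A warning is
#'   emitted when the effective sample size of `psi` is below 100.
#' @export
estimate_ranges_hpp <- function(occ, extant_ids = character(0),
                                iterations = 20000L, burnin = 0.25,
                                seed = NULL) {
  stopifnot(inherits(occ, "occurrence_table"))
  if (!is.null(seed)) set.seed(seed)
  obs <- ranges_from_occurrences(occ, extant_ids)
  k <- as.numeric(table(occ$species)[obs$species])
  fa <- obs$origination; la_obs <- tapply(occ$age, occ$species, min)
  la <- as.numeric(la_obs[obs$species])
  extant <- obs$status == "extant"
  ns <- nrow(obs)

  ts <- fa + 0.5            # start above first appearances
  te <- ifelse(extant, 0, pmax(la - 0.5, 0))
  psi <- max(sum(k) / max(sum(ts - te), 1e-6), 0.01)
  keep <- max(1L, ceiling(iterations * burnin)):iterations
  psi_tr <- numeric(iterations)
  ls_tr <- numeric(iterations); ms_tr <- numeric(iterations)
  ts_sum <- numeric(ns); te_sum <- numeric(ns)
  acc <- 0L; acc_n <- 0L
  w_t <- 0.5                 # endpoint slide window

  for (it in seq_len(iterations)) {
    ## Gibbs draws for the range birth-death rates (conjugate given B, D, S)
    S <- sum(ts - te)
    B <- ns - 1L
    D <- sum(!extant)
    lam_s <- rgamma(1L, 1.1 + B, 1.1 + S)
    mu_s <- rgamma(1L, 1.1 + D, 1.1 + S)
    ## psi: log-scale random walk
    psi_p <- psi * exp(runif(1L, -0.3, 0.3))
    lr <- hpp_loglik(k, ts - te, psi_p) - hpp_loglik(k, ts - te, psi) +
      dgamma(psi_p, 1.1, 1.1, log = TRUE) - dgamma(psi, 1.1, 1.1, log = TRUE) +
      log(psi_p) - log(psi)  # proposal asymmetry on the log scale
    acc_n <- acc_n + 1L
    if (is.finite(lr) && log(runif(1L)) < lr) {
      psi <- psi_p; acc <- acc + 1L
    }
    ## endpoints: one random taxon's ts and (if extinct) te per iteration
    for (rep_i in seq_len(max(1L, ns %/% 4L))) {
      i <- sample.int(ns, 1L)
      ts_p <- ts[i] + runif(1L, -w_t, w_t)
      if (ts_p > fa[i]) {
        lr <- (k[i] * 0 - (psi + lam_s + mu_s) * (ts_p - ts[i])) -
          log1p(-exp(-psi * max(ts_p - te[i], 1e-12))) +
          log1p(-exp(-psi * max(ts[i] - te[i], 1e-12)))
        if (log(runif(1L)) < lr) ts[i] <- ts_p
      }
      if (!extant[i]) {
        te_p <- te[i] + runif(1L, -w_t, w_t)
        if (te_p >= 0 && te_p < la[i]) {
          lr <- (-(psi + lam_s + mu_s) * (te[i] - te_p)) -
            log1p(-exp(-psi * max(ts[i] - te_p, 1e-12))) +
            log1p(-exp(-psi * max(ts[i] - te[i], 1e-12)))
          if (log(runif(1L)) < lr) te[i] <- te_p
        }
      }
    }
    psi_tr[it] <- psi; ls_tr[it] <- lam_s; ms_tr[it] <- mu_s
    if (it >= keep[1L]) {
      ts_sum <- ts_sum + ts; te_sum <- te_sum + te
    }
  }
  nk <- length(keep)
  est <- range_set(obs$species, ts_sum / nk, ifelse(extant, 0, te_sum / nk),
                   obs$status, parent = NA, mode = "observed")
  ess <- ess_from_draws(psi_tr[keep])
  if (ess < 100) {
    warning("estimate_ranges_hpp: effective sample size of psi is ",
            round(ess), "; consider more iterations")
  }
  list(ranges = est, psi = psi_tr[keep],
       rates = data.frame(lambda_star = ls_tr[keep], mu_star = ms_tr[keep]),
       ess_psi = ess, acceptance = acc / acc_n)
}

## crude autocorrelation-based effective sample size
ess_from_draws <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(n)
  a <- acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1L]
  pos <- which(a < 0.05)
  cut <- if (length(pos)) pos[1L] else length(a)
  n / (1 + 2 * sum(a[seq_len(cut)]))
}
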