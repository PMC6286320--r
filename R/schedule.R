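#' Piecewise-constant birth-death rate schedule
#'
#' Defines branching and extinction rates as a step function of age (time
#' before the present; present = 0, increasing into the past). Intervals are
#' given by their boundaries: `breaks` are the ages at which rates shift, so
#' `k` breaks define `k + 1` intervals `[0, b1), [b1, b2), ..., [bk, Inf)`.
#' `lambda[i]` and `mu[i]` apply to the i-th interval counted from the
#' present; the last pair applies to all ages beyond the oldest break (and to
#' the whole of time when there are no breaks).
#'
#' @param lambda vector of branching rates (> 0), youngest interval first.
#' @param mu vector of extinction rates (>= 0), same length as `lambda`.
#' @param breaks increasing vector of shift ages; length `length(lambda) - 1`.
#' @return An object of class `rate_schedule`.
#' @examples
#' rate_schedule(0.2, 0.16)  # constant rates
#' # lambda = mu = 0.2 in [0, 15), lambda = 0.3, mu = 0 in [15, 25),
#' # lambda = 0.2, mu = 0.02 beyond 25:
#' rate_schedule(c(0.2, 0.3, 0.2), c(0.2, 0, 0.02), breaks = c(15, 25))
#' @export
rate_schedule <- function(lambda, mu, breaks = numeric(0)) {
  stopifnot(is.numeric(lambda), is.numeric(mu), is.numeric(breaks),
            length(lambda) >= 1L, length(mu) == length(lambda),
            length(breaks) == length(lambda) - 1L,
            all(is.finite(lambda)), all(is.finite(mu)), all(is.finite(breaks)))
  if (any(lambda <= 0)) stop("all branching rates must be > 0")
  if (any(mu < 0)) stop("all extinction rates must be >= 0")
  if (length(breaks) && (any(diff(breaks) <= 0) || any(breaks <= 0))) {
    stop("breaks must be positive and strictly increasing")
  }
  structure(list(lambda = as.numeric(lambda), mu = as.numeric(mu),
                 breaks = as.numeric(breaks)),
            class = "rate_schedule")
}

#' @export
print.rate_schedule <- function(x, ...) {
  lo <- c(0, x$breaks)
  hi <- c(x$breaks, Inf)
  cat("Birth-death rate schedule (ages before present):\n")
  for (i in seq_along(x$lambda)) {
    cat(sprintf("  [%g, %g): lambda = %g, mu = %g\n", lo[i], hi[i],
                x$lambda[i], x$mu[i]))
  }
  invisible(x)
}

n_intervals <- function(schedule) length(schedule$lambda)

## Rates applying at a vector of ages.
rates_at_age <- function(schedule, age) {
  i <- findInterval(age, schedule$breaks) + 1L
  list(lambda = schedule$lambda[i], mu = schedule$mu[i])
}

## ---------------------------------------------------------------------------
## Single-lineage descendant-count generating functions.
##
## For a linear (time-inhomogeneous) birth-death process, the number of
## descendants at the present of a single lineage alive at age `t` follows a
## zero-modified geometric law: P(0) = p0, P(k) = (1 - p0)(1 - q) q^(k-1).
## Its probability generating function is fractional-linear (Moebius) in s,
## and composition across consecutive time intervals is matrix
## multiplication of the associated 2x2 matrices. This gives exact p0/p1
## for piecewise-constant rates, and exact conditioning probabilities
## P(N(0) = n | N(t) = m) used by the conditioned simulator.
## ---------------------------------------------------------------------------

## (p0, q) for one lineage across a constant-rate interval of duration t,
## no sampling at the end (sampling is applied separately via the GF).
bd_segment_p0q <- function(lambda, mu, t) {
  if (t <= 0) return(c(p0 = 0, q = 0))
  if (abs(lambda - mu) < 1e-12) {
    x <- lambda * t / (1 + lambda * t)
    return(c(p0 = x, q = x))
  }
  r <- lambda - mu
  if (r > 0) {
    e <- exp(-r * t)                      # in (0, 1]; stable for large r t
    den <- lambda - mu * e
    c(p0 = mu * (1 - e) / den, q = lambda * (1 - e) / den)
  } else {
    e <- exp(r * t)                       # in (0, 1); stable for mu > lambda
    den <- lambda * e - mu
    c(p0 = mu * (e - 1) / den, q = lambda * (e - 1) / den)
  }
}

## Composite GF for one lineage from age `from` down to age `to` (from > to)
## under a piecewise schedule; returns c(p0, q) of the composite law.
## Earliest segment is the outermost map: F = F_old o ... o F_young.
lineage_p0q <- function(schedule, from, to = 0) {
  stopifnot(from >= to)
  if (from == to) return(c(p0 = 0, q = 0))
  br <- schedule$breaks
  cuts <- c(to, br[br > to & br < from], from)   # ascending
  a <- 1; b <- 0; cc <- 0; d <- 1
  ## compose from the oldest segment outwards (scalar Moebius products,
  ## renormalised so that d = 1)
  for (i in rev(seq_len(length(cuts) - 1L))) {
    lo <- cuts[i]; hi <- cuts[i + 1L]
    j <- findInterval((lo + hi) / 2, br) + 1L
    pq <- bd_segment_p0q(schedule$lambda[j], schedule$mu[j], hi - lo)
    a2 <- 1 - pq[[1L]] - pq[[2L]]; b2 <- pq[[1L]]; c2 <- -pq[[2L]]
    an <- a * a2 + b * c2; bn <- a * b2 + b
    cn <- cc * a2 + d * c2; dn <- cc * b2 + d
    a <- an / dn; b <- bn / dn; cc <- cn / dn; d <- 1
  }
  c(p0 = b, q = -cc)
}

## log P(N(0) = n | m independent lineages at the top of the window), where
## each lineage has descendant law (p0, q). Vectorised over m.
log_pn_given_m <- function(m, n, p0, q) {
  stopifnot(n >= 1)
  if (p0 == 0 && q == 0) return(ifelse(m == n, 0, -Inf))
  lp0 <- log(p0); l1p0 <- log1p(-p0)
  lq <- log(q); l1q <- log1p(-q)
  xlog <- function(k, lv) ifelse(k == 0, 0, k * lv)  # 0 * -Inf := 0
  vapply(m, function(mi) {
    if (mi < 1) return(-Inf)
    j <- seq_len(min(mi, n))
    lt <- lchoose(mi, j) + xlog(mi - j, lp0) + xlog(j, l1p0) +
      lchoose(n - 1, j - 1) + xlog(j, l1q) + xlog(n - j, lq)
    lt[is.nan(lt)] <- -Inf
    mx <- max(lt)
    if (!is.finite(mx)) return(-Inf)
    mx + log(sum(exp(lt - mx)))
  }, numeric(1))
}
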