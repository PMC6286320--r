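#' Parameters of the birth-death chronospecies process
#'
#' Bundles and validates the five generating parameters of the BDC process:
#' the branching rate `lambda`, the lineage-extinction rate `mu`, the
#' probability `beta` that a branching event is a bifurcation (both daughters
#' are new species and the ancestor goes pseudo-extinct), the anagenesis rate
#' `lambda_a` (replacement of a species along a lineage without branching,
#' per lineage per time unit), and the probability `kappa` that any
#' speciation event is cryptic, i.e. produces no recognisable morphological
#' change and is invisible in the range record.
#'
#' @param lambda branching rate (> 0), events per lineage per time unit.
#' @param mu lineage-extinction rate (>= 0).
#' @param beta probability of bifurcation at a branching event, in `[0, 1]`.
#' @param lambda_a anagenesis rate (>= 0) per lineage per time unit.
#' @param kappa probability a speciation event is cryptic, in `[0, 1]`.
#' @return An object of class `bdc_params`.
#' @examples
#' bdc_params(lambda = 0.2, mu = 0.16, beta = 0.5, lambda_a = 0.04)
#' @export
bdc_params <- function(lambda, mu = 0, beta = 0, lambda_a = 0, kappa = 0) {
  stopifnot(
    is.numeric(lambda), length(lambda) == 1L, is.finite(lambda), lambda > 0,
    is.numeric(mu), length(mu) == 1L, is.finite(mu), mu >= 0,
    is.numeric(beta), length(beta) == 1L, beta >= 0, beta <= 1,
    is.numeric(lambda_a), length(lambda_a) == 1L, is.finite(lambda_a), lambda_a >= 0,
    is.numeric(kappa), length(kappa) == 1L, kappa >= 0, kappa <= 1
  )
  structure(list(lambda = lambda, mu = mu, beta = beta,
                 lambda_a = lambda_a, kappa = kappa),
            class = "bdc_params")
}

#' @export
print.bdc_params <- function(x, ...) {
  cat("BDC parameters:\n")
  cat(sprintf("  lambda (branching)    = %g\n", x$lambda))
  cat(sprintf("  mu (extinction)       = %g\n", x$mu))
  cat(sprintf("  beta (bifurcation pr) = %g\n", x$beta))
  cat(sprintf("  lambda_a (anagenesis) = %g\n", x$lambda_a))
  cat(sprintf("  kappa (cryptic pr)    = %g\n", x$kappa))
  invisible(x)
}

#' Stratigraphic rates implied by BDC parameters
#'
#' Computes the morphospecies origination and extinction rates `lambda*` and
#' `mu*` implied by the BDC generating parameters. New morphospecies arise by
#' budding (rate `lambda (1 - beta)`), by bifurcation (rate `2 lambda beta`,
#' two new species per event) and by anagenesis (rate `lambda_a`);
#' morphospecies are lost to bifurcation (`lambda beta`), anagenesis
#' (`lambda_a`) and true extinction (`mu`):
#' \deqn{\lambda^* = \lambda(1-\beta) + 2\lambda\beta + \lambda_a, \qquad
#'       \mu^* = \lambda\beta + \lambda_a + \mu.}
#'
#' Net diversification is conserved: `lambda* - mu* = lambda - mu`.
#'
#' @param lambda,mu,beta,lambda_a BDC parameters, or pass a [bdc_params()]
#'   object as `lambda`.
#' @return A list with components `lambda_star` and `mu_star`.
#' @examples
#' fossil_rates_from_bdc(0.2, 0.16, 0.7, 0.16)  # lambda* = 0.5, mu* = 0.46
#' @export
fossil_rates_from_bdc <- function(lambda, mu = 0, beta = 0, lambda_a = 0) {
  if (inherits(lambda, "bdc_params")) {
    p <- lambda
    lambda <- p$lambda; mu <- p$mu; beta <- p$beta; lambda_a <- p$lambda_a
  }
  stopifnot(lambda > 0, mu >= 0, beta >= 0, beta <= 1, lambda_a >= 0)
  list(lambda_star = lambda * (1 - beta) + 2 * lambda * beta + lambda_a,
       mu_star = lambda * beta + lambda_a + mu)
}

#' Classify a rate quadruple into the equal / compatible / incompatible scenario
#'
#' Given exact phylogenetic rates (`lambda`, `mu`) and stratigraphic rates
#' (`lambda_star`, `mu_star`), determines whether a BDC parameterisation
#' `(beta, lambda_a)` linking them exists. The linear system has a rank-one
#' coefficient matrix, so either exactly one solution (the budding-only
#' solution `beta = 0`, `lambda_a = 0`), infinitely many solutions, or none:
#' * `"equal"`: `lambda* = lambda` and `mu* = mu`;
#' * `"compatible"`: `lambda* - lambda = mu* - mu` with `lambda* > lambda`;
#' * `"incompatible"`: the rate differences disagree, or `lambda* < lambda`.
#'
#' This classification applies to exact (e.g. generating) rates; statistical
#' classification of noisy estimates is the job of the likelihood-ratio
#' cascade ([lrt_cascade()]) or the posterior check
#' ([posterior_model_check()]).
#'
#' @param lambda,mu phylogenetic branching and extinction rates.
#' @param lambda_star,mu_star stratigraphic origination and extinction rates.
#' @param tol numeric tolerance used to call two exact rates equal.
#' @return One of `"equal"`, `"compatible"`, `"incompatible"`.
#' @examples
#' classify_scenario(0.2, 0.16, 0.5, 0.46)  # "compatible"
#' @export
classify_scenario <- function(lambda, mu, lambda_star, mu_star, tol = 1e-8) {
  stopifnot(lambda > 0, mu >= 0, lambda_star > 0, mu_star >= 0)
  dl <- lambda_star - lambda
  dm <- mu_star - mu
  if (abs(dl) <= tol && abs(dm) <= tol) return("equal")
  if (abs(dl - dm) <= tol && dl > tol) return("compatible")
  "incompatible"
}

#' Identifiable intervals for the anagenesis rate and bifurcation probability
#'
#' Under the compatible rates model the pair `(beta, lambda_a)` is not point
#' identifiable: every `beta` in `[0, min(1, lambda*/lambda - 1)]` together
#' with `lambda_a = lambda* - (1 + beta) lambda` solves the BDC equations.
#' The induced interval for the anagenesis rate is
#' `lambda_a` in `[max(0, lambda* - 2 lambda), lambda* - lambda]`,
#' whose width is at most `lambda`.
#'
#' @param lambda phylogenetic branching rate (> 0).
#' @param lambda_star stratigraphic origination rate, must be `>= lambda`.
#' @return A list with `lambda_a` (length-2 interval), `beta` (length-2
#'   interval) and `width` (of the `lambda_a` interval).
#' @examples
#' lambda_a_interval(0.2, 0.5)  # lambda_a in [0.1, 0.3], beta in [0, 1]
#' @export
lambda_a_interval <- function(lambda, lambda_star) {
  stopifnot(lambda > 0)
  if (lambda_star < lambda) {
    stop("lambda_star < lambda: no BDC parameterisation exists (incompatible rates)")
  }
  la <- c(max(0, lambda_star - 2 * lambda), lambda_star - lambda)
  be <- c(0, min(1, lambda_star / lambda - 1))
  list(lambda_a = la, beta = be, width = la[2] - la[1])
}

#' Prevalent speciation mode from the rate gap
#'
#' The difference `lambda* - lambda = lambda_a + lambda beta` measures the
#' combined contribution of anagenesis and bifurcation, and the statistic
#' `lambda* - 2 lambda = lambda_a - lambda(1 - beta)` compares anagenesis
#' with budding: anagenetic speciation exceeds budding cladogenesis when it
#' is positive, budding prevails when it is negative.
#'
#' @param lambda phylogenetic branching rate.
#' @param lambda_star stratigraphic origination rate.
#' @param tol half-width of the band around zero labelled `"balanced"`.
#' @return A list with `statistic` (`lambda* - 2 lambda`), `label` (one of
#'   `"anagenesis-dominant"`, `"budding-dominant"`, `"balanced"`) and
#'   `rate_gap` (`lambda* - lambda`).
#' @examples
#' mode_prevalence(0.2, 0.5)   # anagenesis-dominant
#' mode_prevalence(0.2, 0.34)  # budding-dominant
#' @export
mode_prevalence <- function(lambda, lambda_star, tol = 1e-8) {
  stopifnot(lambda > 0, lambda_star > 0)
  s <- lambda_star - 2 * lambda
  label <- if (abs(s) <= tol) "balanced" else if (s > 0) {
    "anagenesis-dominant"
  } else "budding-dominant"
  list(statistic = s, label = label, rate_gap = lambda_star - lambda)
}
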