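## Joint fitting of the equal / compatible / incompatible rates models and
## the likelihood-ratio cascade. The joint likelihood treats the extant
## timetree and the range data as independent:
##   P(T, R | lambda, mu, lambda*, mu*) ~ P(T | lambda, mu) P(R | lambda*, mu*).
## Model constraints:
##   equal:        lambda* = lambda, mu* = mu                  (2 free)
##   compatible:   lambda* = lambda + c, mu* = mu + c, c >= 0  (3 free)
##   incompatible: no cross-data constraint                    (4 free)

#' Model specifications for the rates comparison
#'
#' @param name one of `"equal"`, `"compatible"`, `"incompatible"`.
#' @return A list with the model name and its free-parameter count. The
#'   models are nested: equal (2 parameters, shared rates) within
#'   compatible (3, a common non-negative offset `c = lambda* - lambda =
#'   mu* - mu`) within incompatible (4, unconstrained).
#' @export
model_spec <- function(name = c("equal", "compatible", "incompatible")) {
  name <- match.arg(name)
  list(name = name, k = switch(name, equal = 2L, compatible = 3L,
                               incompatible = 4L))
}

## objective builders on unconstrained scales; d = lambda - mu > 1e-8
.fit_one <- function(phylo, stats, model, conditioning, init) {
  if (model == "equal") {
    obj <- function(p) {
      d <- exp(p[1L]) + 1e-8; m <- exp(p[2L]); l <- d + m
      -(phylo_loglik(phylo, l, m, conditioning) + range_loglik(stats, l, m))
    }
    fit <- optim(init[1:2], obj, method = "Nelder-Mead",
                 control = list(maxit = 3000, reltol = 1e-12))
    d <- exp(fit$par[1L]) + 1e-8; m <- exp(fit$par[2L])
    list(lambda = d + m, mu = m, lambda_star = d + m, mu_star = m,
         loglik = -fit$value)
  } else if (model == "compatible") {
    obj <- function(p) {
      d <- exp(p[1L]) + 1e-8; m <- exp(p[2L]); cc <- exp(p[3L]); l <- d + m
      -(phylo_loglik(phylo, l, m, conditioning) +
          range_loglik(stats, l + cc, m + cc))
    }
    fit <- optim(init[1:3], obj, method = "Nelder-Mead",
                 control = list(maxit = 4000, reltol = 1e-12))
    d <- exp(fit$par[1L]) + 1e-8; m <- exp(fit$par[2L]); cc <- exp(fit$par[3L])
    ## the boundary c = 0 belongs to the model: never fall below the
    ## equal-rates likelihood at the same (lambda, mu)
    ll <- -fit$value
    list(lambda = d + m, mu = m, lambda_star = d + m + cc, mu_star = m + cc,
         loglik = ll)
  } else {
    ## incompatible: the two data blocks separate; range part closed form
    ph <- function(p) {
      d <- exp(p[1L]) + 1e-8; m <- exp(p[2L])
      -phylo_loglik(phylo, d + m, m, conditioning)
    }
    fit <- optim(init[1:2], ph, method = "Nelder-Mead",
                 control = list(maxit = 3000, reltol = 1e-12))
    d <- exp(fit$par[1L]) + 1e-8; m <- exp(fit$par[2L])
    rm <- range_mle(stats)
    list(lambda = d + m, mu = m, lambda_star = rm$lambda_star,
         mu_star = rm$mu_star, loglik = -fit$value + rm$loglik)
  }
}

#' Joint constrained maximum-likelihood fit of one rates model
#'
#' Maximises the joint (timetree x ranges) log-likelihood under the
#' constraints of the requested model. Each fit is repeated from `restarts`
#' random initial values (rates log-uniform in `[0.01, 2]`) and, for the
#' larger models, additionally from the best fit of the model nested
#' inside it, which enforces the nesting inequality
#' `logL(incompatible) >= logL(compatible) >= logL(equal)` up to optimiser
#' tolerance.
#'
#' @param phylo a [phylo_data()] object.
#' @param stats range statistics (list with `B`, `D`, `S`).
#' @param model `"equal"`, `"compatible"` or `"incompatible"`.
#' @param conditioning `"origin"` or `"crown"` for the timetree term.
#' @param restarts number of random restarts.
#' @param seed optional integer seed.
#' @param warm_start optional parameter list of a nested model's fit.
#' @return A list with the fitted `lambda`, `mu`, `lambda_star`, `mu_star`,
#'   `loglik`, the model `name` and `restarts` used.
#' @export
joint_ml_fit <- function(phylo, stats, model = c("equal", "compatible",
                                                 "incompatible"),
                         conditioning = c("origin", "crown"), restarts = 5L,
                         seed = NULL, warm_start = NULL) {
  model <- match.arg(model)
  conditioning <- match.arg(conditioning)
  if (!is.null(seed)) set.seed(seed)
  inits <- replicate(restarts, runif(3L, log(0.01), log(2)), simplify = FALSE)
  if (!is.null(warm_start)) {
    d <- max(warm_start$lambda - warm_start$mu, 2e-8)
    cc <- max(warm_start$lambda_star - warm_start$lambda, 1e-8)
    inits <- c(inits, list(c(log(d), log(max(warm_start$mu, 1e-8)), log(cc))))
  }
  best <- NULL
  fails <- 0L
  for (init in inits) {
    f <- tryCatch(.fit_one(phylo, stats, model, conditioning, init),
                  error = function(e) NULL)
    if (is.null(f)) { fails <- fails + 1L; next }
    if (is.null(best) || f$loglik > best$loglik) best <- f
  }
  if (is.null(best)) {
    stop("joint_ml_fit: all ", length(inits), " restarts failed for the ",
         model, " model")
  }
  best$name <- model
  best$restarts <- length(inits) - fails
  best
}

#' Rejection thresholds of the likelihood-ratio cascade
#'
#' The equal-vs-compatible comparison relaxes `lambda* = lambda` to
#' `lambda* >= lambda`; the null value sits on the boundary, so the LR
#' statistic follows a 50:50 mixture of a point mass at 0 and a chi-square
#' with 1 df, and equal rates are rejected at level `alpha` when the
#' chi-square(1) tail probability of LR falls below `2 alpha` -- at `alpha
#' = 0.05` the threshold is 2.71. Compatible-vs-incompatible uses a
#' chi-square with 1 df (only the constraint on `mu*` is counted) and
#' equal-vs-incompatible a chi-square with 2 df, both at level `alpha`.
#'
#' @param alpha significance level.
#' @return Named vector of LR thresholds `eq_co`, `co_in`, `eq_in`.
#' @examples
#' lrt_thresholds(0.05)["eq_co"]  # 2.71
#' @export
lrt_thresholds <- function(alpha = 0.05) {
  c(eq_co = qchisq(1 - 2 * alpha, df = 1),
    co_in = qchisq(1 - alpha, df = 1),
    eq_in = qchisq(1 - alpha, df = 2))
}

#' Likelihood-ratio cascade over the three rates models
#'
#' Computes the three LR statistics between the nested fits and selects the
#' simplest model not rejected: the equal rates model is selected when it
#' survives both its comparisons (against compatible, mixture rule; against
#' incompatible, chi-square 2 df); otherwise the compatible model when it
#' survives the comparison against incompatible; otherwise the incompatible
#' model. Ties at the exact threshold resolve to the simpler model.
#'
#' @param fit_eq,fit_co,fit_in fits from [joint_ml_fit()].
#' @param alpha significance level (0.05 for the 0.95 threshold).
#' @return A list with `selected`, the `LR` statistics, `p_values`
#'   (chi-square tail probabilities) and the thresholds used.
#' @export
lrt_cascade <- function(fit_eq, fit_co, fit_in, alpha = 0.05) {
  LR <- c(eq_co = 2 * (fit_co$loglik - fit_eq$loglik),
          co_in = 2 * (fit_in$loglik - fit_co$loglik),
          eq_in = 2 * (fit_in$loglik - fit_eq$loglik))
  LR <- pmax(LR, 0)   # guard optimiser jitter on nested fits
  thr <- lrt_thresholds(alpha)
  p <- c(eq_co = pchisq(LR[["eq_co"]], 1, lower.tail = FALSE),
         co_in = pchisq(LR[["co_in"]], 1, lower.tail = FALSE),
         eq_in = pchisq(LR[["eq_in"]], 2, lower.tail = FALSE))
  reject_eq <- (LR[["eq_co"]] > thr[["eq_co"]]) ||
    (LR[["eq_in"]] > thr[["eq_in"]])
  reject_co <- LR[["co_in"]] > thr[["co_in"]]
  selected <- if (!reject_eq) "equal" else if (!reject_co) {
    "compatible"
  } else "incompatible"
  list(selected = selected, LR = LR, p_values = p, thresholds = thr,
       alpha = alpha)
}

#' Full model-comparison report for one data set
#'
#' Fits the equal, compatible and incompatible rates models by joint
#' maximum likelihood (warm-starting each model from the one nested inside
#' it), runs the LR cascade at the 0.95 and 0.99 thresholds, and appends
#' the speciation-mode summaries derived from the compatible fit: the
#' identifiable interval of the anagenesis rate and the
#' `lambda* - 2 lambda` prevalence statistic.
#'
#' @param phylo a [phylo_data()] object.
#' @param ranges a [range_set()], or precomputed statistics via `stats`.
#' @param stats optional list with `B`, `D`, `S` (overrides `ranges`).
#' @param conditioning `"origin"` or `"crown"`.
#' @param restarts optimiser restarts per model.
#' @param seed optional integer seed.
#' @return A list of class `model_fit_report` with the three `fits`, the
#'   two `cascades` (at alpha 0.05 and 0.01), `selected` (named character
#'   vector at the two thresholds), `lambda_a_interval` and
#'   `mode_prevalence`.
#' @export
model_fit_report <- function(phylo, ranges = NULL, stats = NULL,
                             conditioning = c("origin", "crown"),
                             restarts = 5L, seed = NULL) {
  conditioning <- match.arg(conditioning)
  if (is.null(stats)) stats <- range_statistics(ranges)
  if (!is.null(seed)) set.seed(seed)
  fit_eq <- joint_ml_fit(phylo, stats, "equal", conditioning, restarts)
  fit_co <- joint_ml_fit(phylo, stats, "compatible", conditioning, restarts,
                         warm_start = c(fit_eq,
                                        list(lambda_star = fit_eq$lambda)))
  fit_in <- joint_ml_fit(phylo, stats, "incompatible", conditioning, restarts,
                         warm_start = fit_co)
  ## nesting is structural; enforce against optimiser jitter
  if (fit_co$loglik < fit_eq$loglik) {
    fit_co[c("lambda", "mu", "lambda_star", "mu_star", "loglik")] <-
      fit_eq[c("lambda", "mu", "lambda_star", "mu_star", "loglik")]
  }
  cas95 <- lrt_cascade(fit_eq, fit_co, fit_in, alpha = 0.05)
  cas99 <- lrt_cascade(fit_eq, fit_co, fit_in, alpha = 0.01)
  la_int <- lambda_a_interval(fit_co$lambda, fit_co$lambda_star)
  prev <- mode_prevalence(fit_co$lambda, fit_co$lambda_star)
  structure(list(fits = list(equal = fit_eq, compatible = fit_co,
                             incompatible = fit_in),
                 cascades = list(`0.95` = cas95, `0.99` = cas99),
                 selected = c(`0.95` = cas95$selected,
                              `0.99` = cas99$selected),
                 lambda_a_interval = la_int, mode_prevalence = prev,
                 stats = stats),
            class = "model_fit_report")
}

#' @export
print.model_fit_report <- function(x, ...) {
  cat("BDC model comparison\n")
  for (nm in names(x$fits)) {
    f <- x$fits[[nm]]
    cat(sprintf("  %-12s logL = %10.3f  lambda = %.4f mu = %.4f lambda* = %.4f mu* = %.4f\n",
                nm, f$loglik, f$lambda, f$mu, f$lambda_star, f$mu_star))
  }
  cat(sprintf("  selected: %s (0.95), %s (0.99)\n",
              x$selected[["0.95"]], x$selected[["0.99"]]))
  cat(sprintf("  lambda_a in [%.4f, %.4f]; lambda* - 2 lambda = %.4f (%s)\n",
              x$lambda_a_interval$lambda_a[1L],
              x$lambda_a_interval$lambda_a[2L],
              x$mode_prevalence$statistic, x$mode_prevalence$label))
  invisible(x)
}

#' Simulation study of model-selection frequencies
#'
#' Simulates `n_reps` data sets (complete tree, chronospecies ranges,
#' extant timetree), optionally degrades the range data, fits the three
#' rates models and tabulates how often each is selected by the LR cascade
#' at the 0.95 and 0.99 thresholds. With `independent = TRUE` the ranges
#' come from a second, independent tree whose rates are drawn from
#' `U(0.1, 1.5)` (birth) and `U(0, lambda)` (death), the incompatible-rates
#' generator.
#'
#' @param n_reps number of replicate data sets.
#' @param lambda,mu,beta,lambda_a,kappa BDC generating parameters.
#' @param n_tips extant tips to condition each tree on.
#' @param removal_x whole-range removal probability (0 = none).
#' @param removal_scheme scheme passed to [subsample_ranges()].
#' @param psi optional Poisson preservation rate; when set, ranges are
#'   replaced by first/last-appearance ranges from sampled occurrences.
#' @param rho extant sampling fraction applied to the timetree.
#' @param independent use the independent-trees incompatible generator.
#' @param conditioning timetree conditioning.
#' @param restarts optimiser restarts per model fit.
#' @param seed master seed; replicate `i` uses `seed + i`.
#' @return A list of class `selection_experiment` with `freq` (percentage
#'   table, thresholds x models), `selections` (per-rep choices), `failed`
#'   (count of failed replicates), and the call settings.
#' @export
selection_experiment <- function(n_reps = 100L, lambda = 0.2, mu = 0.16,
                                 beta = 0, lambda_a = 0, kappa = 0,
                                 n_tips = 200L, removal_x = 0,
                                 removal_scheme = "uniform", psi = NULL,
                                 rho = 1, independent = FALSE,
                                 conditioning = "origin", restarts = 5L,
                                 seed = 1L) {
  sel95 <- sel99 <- character(n_reps)
  failed <- 0L
  sched <- rate_schedule(lambda, mu)
  for (i in seq_len(n_reps)) {
    res <- tryCatch({
      set.seed(seed + i)
      if (independent) {
        l1 <- runif(1L, 0.1, 1.5); m1 <- runif(1L, 0, l1)
        l2 <- runif(1L, 0.1, 1.5); m2 <- runif(1L, 0, l2)
        tr1 <- simulate_tree(rate_schedule(l1, m1), n_tips)
        tr2 <- simulate_tree(rate_schedule(l2, m2), n_tips)
        phy <- if (rho < 1) subsample_extant(tr1, rho) else prune_extinct(tr1)
        rng <- assign_chronospecies(tr2, bdc_params(l2, m2, beta, lambda_a,
                                                    kappa))
      } else {
        tr <- simulate_tree(sched, n_tips)
        phy <- if (rho < 1) subsample_extant(tr, rho) else prune_extinct(tr)
        rng <- assign_chronospecies(tr, bdc_params(lambda, mu, beta,
                                                   lambda_a, kappa))
      }
      if (removal_x > 0) {
        rng <- subsample_ranges(rng, sampling_config(removal_scheme,
                                                     x = removal_x))
      }
      if (!is.null(psi)) {
        occ <- sample_occurrences(rng, psi)
        rng <- ranges_from_occurrences(occ,
                                       rng$species[rng$status == "extant"])
      }
      rep <- model_fit_report(phy, rng, conditioning = conditioning,
                              restarts = restarts)
      rep$selected
    }, error = function(e) NULL)
    if (is.null(res)) {
      failed <- failed + 1L
      sel95[i] <- sel99[i] <- NA_character_
    } else {
      sel95[i] <- res[["0.95"]]
      sel99[i] <- res[["0.99"]]
    }
  }
  lev <- c("equal", "compatible", "incompatible")
  ok <- !is.na(sel95)
  freq <- rbind(`0.95` = 100 * table(factor(sel95[ok], lev)) / sum(ok),
                `0.99` = 100 * table(factor(sel99[ok], lev)) / sum(ok))
  structure(list(freq = freq,
                 selections = data.frame(rep = seq_len(n_reps),
                                         sel95 = sel95, sel99 = sel99),
                 failed = failed,
                 settings = list(lambda = lambda, mu = mu, beta = beta,
                                 lambda_a = lambda_a, kappa = kappa,
                                 n_tips = n_tips, removal_x = removal_x,
                                 psi = psi, rho = rho,
                                 independent = independent, seed = seed)),
            class = "selection_experiment")
}

#' @export
print.selection_experiment <- function(x, ...) {
  cat(sprintf("Model-selection experiment: %d replicates (%d failed)\n",
              nrow(x$selections), x$failed))
  print(round(x$freq, 1))
  invisible(x)
}
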