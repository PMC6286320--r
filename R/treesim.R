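## Complete birth-death tree simulation conditioned on the number of extant
## tips, via the general sampling algorithm (GSA): simulate the process
## forward well past n lineages, record the time spans during which a present
## placed there would yield exactly n surviving tips, and sample one span
## with probability proportional to its duration. Plain "stop at the first
## time n tips exist" is not used because it biases origin times.

.bdc_cache <- new.env(parent = emptyenv())

## P(N(present) = n | m lineages at age `window`) for m = 1..M, extended
## until the distribution's mode and tail are covered; returns log-probs.
pn_table <- function(schedule, n, window) {
  key <- paste(c(format(schedule$lambda, digits = 15),
                 format(schedule$mu, digits = 15),
                 format(schedule$breaks, digits = 15), n, window),
               collapse = "|")
  hit <- .bdc_cache[[key]]
  if (!is.null(hit)) return(hit)
  pq <- lineage_p0q(schedule, from = window, to = 0)
  M <- 256L
  repeat {
    lp <- log_pn_given_m(seq_len(M), n, pq[["p0"]], pq[["q"]])
    mx <- which.max(lp)
    if ((mx < M / 2 && lp[M] < max(lp) - 20) || M >= 2^20) break
    M <- M * 2L
  }
  out <- list(logp = lp, mode = mx)
  .bdc_cache[[key]] <- out
  out
}

## Vectorised forward simulation of the lineage-count path of a linear
## birth-death process from `n0` lineages. Stops on extinction, on reaching
## `cap` lineages, or when `t_max` time units have elapsed (Inf = no limit).
## Returns per-event waiting times `dt` (interval durations during which the
## count equalled `n_before`), event types, and the final state.
sim_count_path <- function(lambda, mu, n0, cap = Inf, t_max = Inf,
                           max_events = 1e6) {
  pb <- lambda / (lambda + mu)
  birth <- logical(0); dt <- numeric(0); n_before <- numeric(0)
  N <- n0
  elapsed <- 0
  chunk <- if (is.finite(t_max)) {
    ## size chunks to the expected number of events in the window
    max(128L, min(4096L, as.integer(2 * (lambda + mu) * max(n0, 1) * t_max)))
  } else 2048L
  repeat {
    if (N == 0) return(list(birth = birth, dt = dt, n_before = n_before,
                            N = 0L, elapsed = elapsed, ended = "extinct"))
    if (N >= cap) return(list(birth = birth, dt = dt, n_before = n_before,
                              N = N, elapsed = elapsed, ended = "cap"))
    if (length(birth) >= max_events) {
      return(list(birth = birth, dt = dt, n_before = n_before, N = N,
                  elapsed = elapsed, ended = "max_events"))
    }
    b <- runif(chunk) < pb
    Npath <- N + cumsum(ifelse(b, 1, -1))
    Nb <- c(N, Npath[-chunk])
    w <- rexp(chunk) / ((lambda + mu) * Nb)
    tcum <- elapsed + cumsum(w)
    stop_i <- chunk
    ended <- NA
    hit <- which(Npath == 0 | Npath >= cap)
    if (length(hit)) stop_i <- hit[1L]
    if (is.finite(t_max)) {
      over <- which(tcum > t_max)
      if (length(over) && over[1L] <= stop_i) {
        ## event over[1] does not happen: the window closes first
        keep <- seq_len(over[1L] - 1L)
        birth <- c(birth, b[keep]); dt <- c(dt, w[keep])
        n_before <- c(n_before, Nb[keep])
        N <- if (over[1L] > 1L) Npath[over[1L] - 1L] else N
        return(list(birth = birth, dt = dt, n_before = n_before, N = N,
                    elapsed = if (over[1L] > 1L) tcum[over[1L] - 1L] else elapsed,
                    ended = "time"))
      }
    }
    keep <- seq_len(stop_i)
    birth <- c(birth, b[keep]); dt <- c(dt, w[keep])
    n_before <- c(n_before, Nb[keep])
    N <- Npath[stop_i]
    elapsed <- tcum[stop_i]
  }
}

## Build the lineage table from a chronologically ordered event sequence.
## `birth[i]` TRUE for a branching event, FALSE for an extinction; `time[i]`
## is calendar time since the origin; `t0` is the calendar time of the
## present. Lineage ids are assigned in birth order; each branching event
## attaches one new lineage to a uniformly chosen live lineage.
events_to_lineages <- function(birth, time, t0) {
  n_lin <- 1L + sum(birth)
  parent <- rep(NA_integer_, n_lin)
  born <- numeric(n_lin); died <- rep(NA_real_, n_lin)
  born[1L] <- 0
  alive <- integer(n_lin); alive[1L] <- 1L; n_alive <- 1L
  nxt <- 1L
  for (i in seq_along(birth)) {
    j <- if (n_alive > 1L) sample.int(n_alive, 1L) else 1L
    if (birth[i]) {
      nxt <- nxt + 1L
      parent[nxt] <- alive[j]
      born[nxt] <- time[i]
      n_alive <- n_alive + 1L
      alive[n_alive] <- nxt
    } else {
      died[alive[j]] <- time[i]
      alive[j] <- alive[n_alive]
      n_alive <- n_alive - 1L
    }
  }
  extant <- is.na(died)
  died[extant] <- t0
  data.frame(id = seq_len(n_lin), parent = parent,
             start_age = t0 - born, end_age = t0 - died, extant = extant)
}

## Span weights of a forward run: duration x P(n survivors | count, window).
run_span_weights <- function(run, n, logp) {
  if (is.null(logp)) {
    run$dt * (run$n_before == n)
  } else {
    lp <- rep(-Inf, length(run$n_before))
    ok <- run$n_before <= length(logp)
    lp[ok] <- logp[run$n_before[ok]]
    run$dt * exp(lp)
  }
}

## Upper bound on the per-run total span weight, calibrated from pilot runs
## and cached. Runs are later accepted with probability total/bound, which
## makes span sampling proportional to weight across runs, not just within
## one run (within-run-only sampling underweights runs that spend more time
## in qualifying states and biases origin ages downwards). The pilot uses a
## private RNG stream so that tree draws do not depend on cache warmth.
run_weight_bound <- function(schedule, n, cap, logp, max_events) {
  key <- paste(c("Wmax", format(schedule$lambda, digits = 15),
                 format(schedule$mu, digits = 15),
                 format(schedule$breaks, digits = 15), n),
               collapse = "|")
  hit <- .bdc_cache[[key]]
  if (!is.null(hit)) return(hit)
  k <- n_intervals(schedule)
  lam_o <- schedule$lambda[k]; mu_o <- schedule$mu[k]
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  set.seed(181565137L)
  tots <- numeric(0)
  tries <- 0L
  while (length(tots) < 25L && tries < 1e5L) {
    tries <- tries + 1L
    run <- sim_count_path(lam_o, mu_o, n0 = 1L, cap = cap,
                          max_events = max_events)
    if (run$ended == "max_events" || !length(run$dt)) next
    tot <- sum(run_span_weights(run, n, logp))
    if (is.finite(tot) && tot > 0) tots <- c(tots, tot)
  }
  if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, globalenv())
  }
  if (length(tots) < 5L) {
    stop("simulate_tree: could not calibrate the run-acceptance bound; ",
         "the requested tip count appears unreachable under this schedule")
  }
  bound <- 4 * max(tots)
  .bdc_cache[[key]] <- bound
  bound
}

#' Simulate a complete birth-death tree conditioned on the extant tip count
#'
#' Simulates the (possibly piecewise-constant-rate) birth-death process and
#' returns a complete tree -- extinct lineages included -- conditioned on
#' exactly `n_extant` tips surviving to the present, using the general
#' sampling algorithm: the process is run forward well beyond `n_extant`
#' lineages, every time span during which placing the present there would
#' leave exactly `n_extant` survivors is recorded, and one span is drawn with
#' probability proportional to its duration (runs that never qualify are
#' rejected). Rate schedules are anchored to the present; with shifts, the
#' homogeneous span sampling is applied above the oldest shift age and the
#' recent window is completed forward conditioned on `n_extant` survivors,
#' using the exact lineage-count transition law of the linear birth-death
#' process.
#'
#' @param schedule a [rate_schedule()]; a single interval gives the
#'   constant-rate model. `lambda = mu` is allowed here even though
#'   estimation requires `lambda > mu`.
#' @param n_extant required number of tips at the present (>= 1).
#' @param seed optional integer seed (sets the session RNG).
#' @param max_events cap on birth/death events per forward run; runs hitting
#'   it are abandoned and, if all runs fail, an error is raised rather than a
#'   silently truncated tree returned.
#' @param max_tries maximum number of rejected forward runs before giving up.
#' @return An object of class `bdc_tree`: a list with `lineages` (data frame
#'   of id, parent, start/end ages, extant flag), `origin_age`, `n_extant`
#'   and the `schedule`. Ages are time before present.
#' @examples
#' tr <- simulate_tree(rate_schedule(0.2, 0.1), n_extant = 10, seed = 1)
#' tr
#' @export
simulate_tree <- function(schedule, n_extant, seed = NULL,
                          max_events = 1e6, max_tries = 1e4) {
  stopifnot(inherits(schedule, "rate_schedule"),
            is.numeric(n_extant), length(n_extant) == 1L, n_extant >= 1)
  n <- as.integer(n_extant)
  if (!is.null(seed)) set.seed(seed)
  k <- n_intervals(schedule)
  window <- if (k > 1L) schedule$breaks[k - 1L] else 0
  lam_o <- schedule$lambda[k]; mu_o <- schedule$mu[k]

  if (window > 0) {
    tab <- pn_table(schedule, n, window)
    logp <- tab$logp
    ## the table ends once the tail has dropped 20 log units below the
    ## mode; spans beyond carry negligible weight
    cap <- length(logp)
  } else {
    logp <- NULL
    cap <- 10L * n
  }

  w_bound <- run_weight_bound(schedule, n, cap, logp, max_events)
  ## mixture masses of the two origin-age components under the uniform-
  ## origin-age conditioning: origins inside the recent window versus
  ## beyond it, both exact from the zero-modified-geometric descendant law
  p_young <- 0
  mass <- NULL
  if (window > 0) {
    mass <- window_masses(schedule, n, window, logp)
    p_young <- mass$young / (mass$young + mass$old)
  }

  for (try in seq_len(max_tries)) {
    res <- if (p_young > 0 && runif(1L) < p_young) {
      sim_origin_in_window(schedule, n, window, mass$young, max_events)
    } else {
      sim_origin_beyond_window(schedule, n, window, lam_o, mu_o, cap, logp,
                               w_bound, max_events)
    }
    if (is.null(res)) next
    stopifnot(sum(res$lin$extant) == n)
    return(structure(list(lineages = res$lin, origin_age = res$t0,
                          n_extant = n, schedule = schedule),
                     class = "bdc_tree"))
  }
  stop("simulate_tree: no qualifying run within 'max_tries' forward ",
       "simulations; the parameter regime may be non-terminating or the ",
       "event cap too small")
}

## P(N(present) = n | one lineage at age t0) under the full schedule
g_origin <- function(schedule, n, t0) {
  vapply(t0, function(a) {
    pq <- lineage_p0q(schedule, from = a, to = 0)
    (1 - pq[["p0"]]) * (1 - pq[["q"]]) * pq[["q"]]^(n - 1)
  }, numeric(1))
}

## masses of the origin-age density inside and beyond the recent window
window_masses <- function(schedule, n, window, logp) {
  key <- paste(c("mass", format(schedule$lambda, digits = 15),
                 format(schedule$mu, digits = 15),
                 format(schedule$breaks, digits = 15), n),
               collapse = "|")
  hit <- .bdc_cache[[key]]
  if (!is.null(hit)) return(hit)
  young <- integrate(function(a) g_origin(schedule, n, a), 0, window,
                     rel.tol = 1e-8)$value
  k <- n_intervals(schedule)
  lam_o <- schedule$lambda[k]; mu_o <- schedule$mu[k]
  pn <- exp(logp)
  m_seq <- seq_along(pn)
  h <- function(s) {            # origin-age density at age window + s
    vapply(s, function(si) {
      pq <- bd_segment_p0q(lam_o, mu_o, si)
      if (pq[["q"]] >= 1 - 1e-14) return(0)
      zm <- (1 - pq[["p0"]]) * (1 - pq[["q"]]) * pq[["q"]]^(m_seq - 1)
      sum(zm * pn)
    }, numeric(1))
  }
  old <- integrate(h, 0, Inf, rel.tol = 1e-8)$value
  out <- list(young = young, old = old)
  .bdc_cache[[key]] <- out
  out
}

## simulate the lineage-count events through schedule segments from age
## `from` down to the present; NULL on extinction or event overflow
sim_through_window <- function(schedule, n0, from, max_events) {
  cuts <- sort(unique(c(0, from, schedule$breaks[schedule$breaks < from])),
               decreasing = TRUE)
  N <- n0; ev_b <- list(); ev_t <- list(); off <- 0
  for (i in seq_len(length(cuts) - 1L)) {
    dur <- cuts[i] - cuts[i + 1L]
    r <- rates_at_age(schedule, (cuts[i] + cuts[i + 1L]) / 2)
    sp <- sim_count_path(r$lambda, r$mu, n0 = N, t_max = dur,
                         max_events = max_events)
    if (sp$ended %in% c("extinct", "max_events", "cap")) return(NULL)
    ev_b[[i]] <- sp$birth
    ev_t[[i]] <- off + cumsum(sp$dt)
    off <- off + dur
    N <- sp$N
  }
  list(birth = unlist(ev_b), time = unlist(ev_t), N = N)
}

## origin inside the recent window: joint rejection on (t0, tree)
sim_origin_in_window <- function(schedule, n, window, mass_young,
                                 max_events) {
  attempts <- max(5000L, ceiling(50 * window / max(mass_young, 1e-12)))
  for (a in seq_len(attempts)) {
    t0 <- runif(1L, 0, window)
    got <- sim_through_window(schedule, 1L, t0, max_events)
    if (!is.null(got) && got$N == n) {
      return(list(lin = events_to_lineages(got$birth, got$time, t0),
                  t0 = t0))
    }
  }
  NULL
}

## origin beyond the recent window: span-sampled homogeneous phase above
## the window, then the window completed conditional on n survivors
sim_origin_beyond_window <- function(schedule, n, window, lam_o, mu_o, cap,
                                     logp, w_bound, max_events,
                                     run_attempts = 20000L) {
  ## loop until one run is accepted, so that (like the in-window component)
  ## each entry into this component yields a tree with high probability and
  ## the component mixture stays at its exact masses
  for (ra in seq_len(run_attempts)) {
    run <- sim_count_path(lam_o, mu_o, n0 = 1L, cap = cap,
                          max_events = max_events)
    if (run$ended == "max_events" || !length(run$dt)) next
    w <- run_span_weights(run, n, logp)
    tot <- sum(w)
    if (!is.finite(tot) || tot <= 0) next
    ## accept the whole run in proportion to its total qualifying weight,
    ## so spans are effectively sampled by weight across runs, not only
    ## within one run
    if (runif(1L) > tot / w_bound) next
    J <- sample.int(length(w), 1L, prob = w)
    t_start <- if (J > 1L) sum(run$dt[seq_len(J - 1L)]) else 0
    s_star <- t_start + runif(1L) * run$dt[J]
    m <- run$n_before[J]
    b1 <- run$birth[seq_len(J - 1L)]   # events strictly before s*
    t1 <- cumsum(run$dt)[seq_len(J - 1L)]
    if (window == 0) {
      return(list(lin = events_to_lineages(b1, t1, s_star), t0 = s_star))
    }
    ## complete the window from the m survivors, conditioned on exactly n
    ## tips at the present
    attempts <- max(1000L, ceiling(50 / exp(logp[m])))
    for (a in seq_len(attempts)) {
      got <- sim_through_window(schedule, m, window, max_events)
      if (!is.null(got) && got$N == n) {
        t0 <- s_star + window
        return(list(lin = events_to_lineages(c(b1, got$birth),
                                             c(t1, s_star + got$time), t0),
                    t0 = t0))
      }
    }
  }
  NULL
}

#' @export
print.bdc_tree <- function(x, ...) {
  cat(sprintf(paste0("Complete birth-death tree: %d lineages ",
                     "(%d extant, %d extinct), origin age %.4g\n"),
              nrow(x$lineages), sum(x$lineages$extant),
              sum(!x$lineages$extant), x$origin_age))
  invisible(x)
}

#' Total branch length of a complete tree (root edge included)
#'
#' @param tree a `bdc_tree`.
#' @return Sum of lineage durations in time units.
#' @export
tree_length <- function(tree) {
  stopifnot(inherits(tree, "bdc_tree"))
  sum(tree$lineages$start_age - tree$lineages$end_age)
}

## Branching ages of the tree induced by a subset of tips. An attachment
## event qualifies as a node of the induced tree iff the attached subtree
## and the remainder of the parent's subtree below that event both reach a
## kept tip.
induced_branching_ages <- function(tree, keep_ids) {
  lin <- tree$lineages
  nl <- nrow(lin)
  surv <- logical(nl); surv[keep_ids] <- TRUE
  if (nl == 1L) return(numeric(0))
  kids <- split(2:nl, factor(lin$parent[2:nl], levels = seq_len(nl)))
  ages <- numeric(length(keep_ids) - 1L); na <- 0L
  for (L in nl:1) {
    ch <- kids[[L]]
    if (length(ch)) {
      ch <- ch[order(lin$start_age[ch])]   # youngest event first
      acc <- surv[L]
      for (cc in ch) {
        if (surv[cc] && acc) {
          na <- na + 1L
          ages[na] <- lin$start_age[cc]
        }
        acc <- acc || surv[cc]
      }
      surv[L] <- acc
    }
  }
  sort(ages[seq_len(na)], decreasing = TRUE)
}

#' Branching ages and metadata of an extant phylogeny
#'
#' Container for the sufficient data of the reconstructed birth-death
#' process: the number of sampled extant tips `n`, the branching ages
#' `t1 >= t2 >= ... >= t(n-1)` (with `t1` the crown age), optionally the
#' origin (stem) age `t0`, and the sampling fraction `rho`.
#'
#' @param branching_ages numeric vector of node ages (time before present).
#' @param t0 origin age (>= crown age), or `NULL` when unknown.
#' @param rho probability that an extant species is sampled, in `(0, 1]`.
#' @param n number of extant tips; defaults to `length(branching_ages) + 1`.
#' @return An object of class `phylo_data`.
#' @export
phylo_data <- function(branching_ages, t0 = NULL, rho = 1,
                       n = length(branching_ages) + 1L) {
  branching_ages <- sort(as.numeric(branching_ages), decreasing = TRUE)
  stopifnot(all(branching_ages >= 0), rho > 0, rho <= 1,
            n == length(branching_ages) + 1L)
  if (!is.null(t0)) {
    stopifnot(is.numeric(t0), length(t0) == 1L,
              !length(branching_ages) || t0 >= branching_ages[1L])
  }
  structure(list(n = as.integer(n), branching_ages = branching_ages,
                 t0 = t0, rho = rho),
            class = "phylo_data")
}

#' @export
print.phylo_data <- function(x, ...) {
  cat(sprintf("Extant phylogeny data: n = %d tips, crown age %.4g%s, rho = %g\n",
              x$n,
              if (length(x$branching_ages)) x$branching_ages[1L] else NA,
              if (is.null(x$t0)) "" else sprintf(", origin age %.4g", x$t0),
              x$rho))
  invisible(x)
}

#' Prune extinct lineages from a complete tree
#'
#' Drops all extinct tips and returns the data of the reconstructed extant
#' phylogeny: the branching ages are exactly the ages of the most recent
#' common ancestors among the surviving tips, and the origin age is carried
#' over from the complete tree.
#'
#' @param tree a `bdc_tree` from [simulate_tree()].
#' @return A [phylo_data()] object.
#' @seealso [extant_tree()] for the pruned tree as an `ape::phylo` object.
#' @export
prune_extinct <- function(tree) {
  stopifnot(inherits(tree, "bdc_tree"))
  keep <- tree$lineages$id[tree$lineages$extant]
  if (!length(keep)) stop("clade is extinct: no extant tips to keep")
  phylo_data(induced_branching_ages(tree, keep), t0 = tree$origin_age,
             rho = 1, n = length(keep))
}

#' Binomially subsample the extant tips of a complete tree
#'
#' Retains each extant tip independently with probability `rho` and returns
#' the reconstructed phylogeny of the retained tips, with its `rho` field set
#' accordingly. Mirrors incomplete taxon sampling of a molecular phylogeny.
#'
#' @param tree a `bdc_tree`.
#' @param rho retention probability in `(0, 1]`.
#' @param seed optional integer seed.
#' @return A [phylo_data()] object.
#' @export
subsample_extant <- function(tree, rho, seed = NULL) {
  stopifnot(inherits(tree, "bdc_tree"), rho > 0, rho <= 1)
  if (!is.null(seed)) set.seed(seed)
  ext <- tree$lineages$id[tree$lineages$extant]
  keep <- ext[runif(length(ext)) < rho]
  if (length(keep) < 2L) {
    stop("fewer than 2 extant tips survived subsampling at rho = ", rho)
  }
  phylo_data(induced_branching_ages(tree, keep), t0 = tree$origin_age,
             rho = rho, n = length(keep))
}

#' Convert a complete tree to an ape "phylo" object
#'
#' Each lineage becomes a tip (label `t<id>`), each branching event an
#' internal node, and the stem (origin to first branching event) is stored as
#' the `root.edge`. Branch lengths are in the tree's time units.
#'
#' @param x a `bdc_tree`.
#' @param ... unused.
#' @return An object of class `phylo` (package ape).
#' @export as.phylo.bdc_tree
#' @exportS3Method ape::as.phylo
as.phylo.bdc_tree <- function(x, ...) {
  lin <- x$lineages
  nl <- nrow(lin)
  if (nl == 1L) {
    stop("a one-lineage tree (single pendant edge) cannot be represented ",
         "as a multi-tip 'phylo' object")
  }
  ## internal node numbers: events (= child lineages 2..nl) in order of
  ## decreasing age, so that the oldest event is the root node nl + 1
  ev <- order(lin$start_age[2:nl], decreasing = TRUE) + 1L
  node_of <- integer(nl)                   # event node number by child id
  node_of[ev] <- nl + seq_len(nl - 1L)
  kids <- split(2:nl, factor(lin$parent[2:nl], levels = seq_len(nl)))
  nedge <- 2L * (nl - 1L)
  edge <- matrix(0L, nedge, 2L)
  elen <- numeric(nedge)
  k <- 0L
  for (L in seq_len(nl)) {
    ch <- kids[[L]]
    chain_nodes <- if (length(ch)) {
      node_of[ch[order(lin$start_age[ch], decreasing = TRUE)]]
    } else integer(0)
    chain_nodes <- c(chain_nodes, L)       # path ends at the tip
    chain_ages <- c(lin$start_age[ch][order(lin$start_age[ch],
                                            decreasing = TRUE)],
                    lin$end_age[L])
    entry_node <- if (L == 1L) NA_integer_ else node_of[L]
    entry_age <- lin$start_age[L]
    from <- c(entry_node, chain_nodes[-length(chain_nodes)])
    to <- chain_nodes
    from_age <- c(entry_age, chain_ages[-length(chain_ages)])
    drop1 <- is.na(from)                   # origin -> first node = root edge
    idx <- k + seq_len(sum(!drop1))
    edge[idx, 1L] <- from[!drop1]
    edge[idx, 2L] <- to[!drop1]
    elen[idx] <- from_age[!drop1] - chain_ages[!drop1]
    k <- k + sum(!drop1)
  }
  phy <- structure(list(edge = edge, edge.length = elen,
                        tip.label = paste0("t", seq_len(nl)),
                        Nnode = nl - 1L,
                        root.edge = x$origin_age - max(lin$start_age[2:nl])),
                   class = "phylo", order = "cladewise")
  ape::reorder.phylo(phy)  # canonical cladewise edge order

}

#' Extant (pruned) tree as an ape "phylo" object
#'
#' @param tree a `bdc_tree`.
#' @return An ultrametric `phylo` object containing only the extant tips,
#'   with `root.edge` spanning from the origin to the extant crown.
#' @export
extant_tree <- function(tree) {
  stopifnot(inherits(tree, "bdc_tree"))
  lin <- tree$lineages
  if (sum(lin$extant) < 2L) stop("need at least 2 extant tips")
  phy <- as.phylo.bdc_tree(tree)
  drop <- paste0("t", lin$id[!lin$extant])
  out <- if (length(drop)) {
    ape::drop.tip(phy, drop, root.edge = 1L, collapse.singles = TRUE)
  } else phy
  crown <- max(ape::branching.times(out))
  out$root.edge <- tree$origin_age - crown
  out
}

#' Per-event log of a simulated tree
#'
#' @param tree a `bdc_tree`.
#' @return A data frame (lineage id, age, event type) with one row per
#'   origination and termination event, ordered from oldest to youngest;
#'   useful for debugging and for writing TSV event logs.
#' @export
tree_event_log <- function(tree) {
  lin <- tree$lineages
  ev <- rbind(
    data.frame(id = lin$id, age = lin$start_age,
               event = ifelse(is.na(lin$parent), "origin", "birth")),
    data.frame(id = lin$id[!lin$extant], age = lin$end_age[!lin$extant],
               event = "death"),
    data.frame(id = lin$id[lin$extant], age = lin$end_age[lin$extant],
               event = "extant")
  )
  ev[order(-ev$age, ev$id), , drop = FALSE]
}
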