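## Chronospecies delimitation on a complete tree. Species boundaries are
## placed at branching events (budding keeps the ancestor alive on one
## daughter; bifurcation replaces it by two new species) and at anagenetic
## replacement points drawn as a Poisson process along every branch. Cryptic
## events create a new lineage segment that keeps the ancestor's
## morphospecies label, so the merged range spans from the earliest
## origination to the latest extinction of its segments.

#' Stratigraphic range set
#'
#' A data frame of chronospecies ranges with columns `species`,
#' `origination` and `extinction` (ages before present; extant species have
#' extinction 0), `status` (`"extant"`/`"extinct"`), `parent` (morphospecies
#' that generated this one; `NA` for the root species) and `mode` (`"root"`,
#' `"budding"`, `"bifurcation"` or `"anagenesis"`).
#'
#' @param species character or integer species identifiers (unique).
#' @param origination,extinction range endpoint ages, `origination >
#'   extinction >= 0` (degenerate zero-duration ranges are allowed for
#'   observed first/last-appearance data).
#' @param status `"extant"` or `"extinct"` per species.
#' @param parent parent species identifier (`NA` allowed).
#' @param mode origin mode per species.
#' @return An object of classes `range_set` and `data.frame`.
#' @export
range_set <- function(species, origination, extinction, status,
                      parent = NA, mode = "root") {
  x <- data.frame(species = as.character(species),
                  origination = as.numeric(origination),
                  extinction = as.numeric(extinction),
                  status = as.character(status),
                  parent = as.character(parent),
                  mode = as.character(mode))
  if (anyDuplicated(x$species)) stop("duplicate species identifiers")
  if (any(x$extinction < 0)) stop("extinction ages must be >= 0")
  if (any(x$origination < x$extinction)) {
    stop("origination age must not precede extinction age")
  }
  if (!all(x$status %in% c("extant", "extinct"))) {
    stop("status must be 'extant' or 'extinct'")
  }
  if (any(x$status == "extant" & x$extinction != 0)) {
    stop("extant species must have extinction age 0")
  }
  class(x) <- c("range_set", "data.frame")
  x
}

#' @export
print.range_set <- function(x, ...) {
  cat(sprintf("Stratigraphic ranges: %d species (%d extant), total duration %.4g\n",
              nrow(x), sum(x$status == "extant"),
              sum(x$origination - x$extinction)))
  NextMethod()
}

#' Map chronospecies onto a complete tree
#'
#' Overlays the BDC speciation-mode process on a simulated complete tree.
#' At each branching event the two daughters are both new species with
#' probability `beta` (bifurcation, the ancestor range ends there); with
#' probability `1 - beta` one daughter -- chosen uniformly at random --
#' continues the ancestral species while the other starts a new one
#' (budding). Anagenetic replacement points arrive along every branch as a
#' Poisson process with rate `lambda_a`, each terminating the current
#' species and originating a new one. Any speciation event is cryptic with
#' probability `kappa`, in which case the new species inherits the
#' ancestor's morphospecies label and the merged range spans the union
#' interval of its segments.
#'
#' @param tree a `bdc_tree` from [simulate_tree()].
#' @param params a [bdc_params()] object (`lambda`/`mu` are properties of
#'   the tree; only `beta`, `lambda_a` and `kappa` act here).
#' @param seed optional integer seed.
#' @return A [range_set()] of true chronospecies ranges.
#' @examples
#' tr <- simulate_tree(rate_schedule(0.2, 0.1), 10, seed = 1)
#' assign_chronospecies(tr, bdc_params(0.2, 0.1, beta = 0.5, lambda_a = 0.04))
#' @export
assign_chronospecies <- function(tree, params, seed = NULL) {
  stopifnot(inherits(tree, "bdc_tree"), inherits(params, "bdc_params"))
  if (!is.null(seed)) set.seed(seed)
  lin <- tree$lineages
  nl <- nrow(lin)
  beta <- params$beta; la <- params$lambda_a; kappa <- params$kappa

  ## species bookkeeping (segments, before cryptic merging)
  sp_start <- numeric(0); sp_end <- numeric(0); sp_extant <- logical(0)
  sp_parent <- integer(0); sp_mode <- character(0); sp_label <- integer(0)
  n_sp <- 0L
  new_species <- function(start, parent, mode, cryptic) {
    n_sp <<- n_sp + 1L
    sp_start[n_sp] <<- start
    sp_end[n_sp] <<- NA_real_
    sp_extant[n_sp] <<- FALSE
    sp_parent[n_sp] <<- parent
    sp_mode[n_sp] <<- mode
    sp_label[n_sp] <<- if (cryptic) sp_label[parent] else n_sp
    n_sp
  }
  n_sp <- 1L
  sp_start <- tree$origin_age; sp_end <- NA_real_; sp_extant <- FALSE
  sp_parent <- NA_integer_; sp_mode <- "root"; sp_label <- 1L

  kids <- if (nl > 1L) {
    split(2:nl, factor(lin$parent[2:nl], levels = seq_len(nl)))
  } else rep(list(integer(0)), 1L)
  child_species <- integer(nl)   # species carried into each lineage at birth
  child_species[1L] <- 1L

  for (L in seq_len(nl)) {       # parents precede children in id order
    cur <- child_species[L]
    ch <- kids[[L]]
    ch <- ch[order(lin$start_age[ch], decreasing = TRUE)]   # oldest first
    ## anagenetic replacement points on this lineage
    dur <- lin$start_age[L] - lin$end_age[L]
    n_ana <- if (la > 0) rpois(1L, la * dur) else 0L
    ana <- if (n_ana > 0) {
      lin$end_age[L] + runif(n_ana) * dur
    } else numeric(0)
    ev_age <- c(lin$start_age[ch], ana)
    ev_kind <- c(rep("node", length(ch)), rep("ana", length(ana)))
    ev_who <- c(ch, rep(NA_integer_, length(ana)))
    o <- order(ev_age, decreasing = TRUE)
    ev_age <- ev_age[o]; ev_kind <- ev_kind[o]; ev_who <- ev_who[o]
    for (e in seq_along(ev_age)) {
      cryptic <- kappa > 0 && runif(1L) < kappa
      if (ev_kind[e] == "ana") {
        sp_end[cur] <- ev_age[e]
        cur <- new_species(ev_age[e], cur, "anagenesis", cryptic)
      } else if (runif(1L) < beta) {      # bifurcation: two new species
        sp_end[cur] <- ev_age[e]
        child_species[ev_who[e]] <-
          new_species(ev_age[e], cur, "bifurcation", cryptic)
        cur <- new_species(ev_age[e], cur, "bifurcation", cryptic)
      } else {                            # budding: one new species
        if (runif(1L) < 0.5) {            # new species on the new lineage
          child_species[ev_who[e]] <-
            new_species(ev_age[e], cur, "budding", cryptic)
        } else {                          # ancestor moves to the new lineage
          child_species[ev_who[e]] <- cur
          cur <- new_species(ev_age[e], cur, "budding", cryptic)
        }
      }
    }
    sp_end[cur] <- lin$end_age[L]
    sp_extant[cur] <- lin$extant[L]
  }

  seg <- data.frame(start = sp_start, end = sp_end, extant = sp_extant,
                    parent = sp_parent, mode = sp_mode, label = sp_label)
  ## cryptic merging: union interval per morphospecies label
  first <- !duplicated(seg$label)
  agg_start <- tapply(seg$start, seg$label, max)
  agg_end <- tapply(seg$end, seg$label, min)
  agg_ext <- tapply(seg$extant, seg$label, any)
  labs <- as.integer(names(agg_start))
  ## origin metadata comes from the segment that founded the morphospecies
  founder <- match(labs, seg$label)
  ord <- order(labs)
  labs <- labs[ord]; founder <- founder[ord]
  parent_label <- ifelse(is.na(seg$parent[founder]), NA_integer_,
                         seg$label[seg$parent[founder]])
  range_set(species = paste0("sp", labs),
            origination = as.numeric(agg_start[ord]),
            extinction = as.numeric(agg_end[ord]),
            status = ifelse(as.logical(agg_ext[ord]), "extant", "extinct"),
            parent = ifelse(is.na(parent_label), NA_character_,
                            paste0("sp", parent_label)),
            mode = seg$mode[founder])
}

#' Sufficient statistics of a range set
#'
#' Computes the sufficient statistics of the stratigraphic-range birth-death
#' likelihood: the number of birth events `B`, the number of death events
#' `D`, and the summed range durations `S`. The oldest range is treated as
#' the process origin, so `B = (number of ranges) - 1` (identical to
#' counting ranges whose origin mode is not `"root"` on complete data, and
#' well defined after subsampling); `D` counts extinct ranges; `S` sums
#' `origination - extinction`.
#'
#' @param ranges a [range_set()].
#' @return A list with components `B`, `D` and `S`.
#' @examples
#' r <- range_set("sp1", 10, 0, "extant")
#' range_statistics(r)  # B = 0, D = 0, S = 10
#' @export
range_statistics <- function(ranges) {
  stopifnot(inherits(ranges, "range_set"), nrow(ranges) >= 1L)
  S <- sum(ranges$origination - ranges$extinction)
  if (S <= 0) stop("total range duration S is zero")
  list(B = nrow(ranges) - 1L,
       D = sum(ranges$status == "extinct"),
       S = S)
}

#' Calibrate the anagenesis rate to reach a target range count
#'
#' Iteratively increases `lambda_a` on the grid `step, 2 step, ...` until
#' the number of chronospecies ranges generated on `tree` reaches
#' `target_ranges`, then uniformly prunes the ranges to exactly the target
#' count. Used to match the size of an empirical range data set when
#' simulating from rates estimated on a phylogeny.
#'
#' @param tree a `bdc_tree`.
#' @param beta bifurcation probability used during calibration.
#' @param target_ranges required number of ranges.
#' @param step grid step for `lambda_a`.
#' @param max_lambda_a give up (with an error) beyond this rate.
#' @param seed optional integer seed.
#' @return A list with `lambda_a` (the calibrated rate) and `ranges` (a
#'   [range_set()] with exactly `target_ranges` rows).
#' @export
calibrate_anagenesis <- function(tree, beta, target_ranges, step = 0.1,
                                 max_lambda_a = 10, seed = NULL) {
  stopifnot(inherits(tree, "bdc_tree"), target_ranges >= 1)
  if (!is.null(seed)) set.seed(seed)
  sched <- tree$schedule
  lam <- sched$lambda[1L]; mu <- sched$mu[1L]
  la <- step
  while (la <= max_lambda_a + 1e-12) {
    rs <- assign_chronospecies(tree, bdc_params(lam, mu, beta = beta,
                                                lambda_a = la))
    if (nrow(rs) >= target_ranges) {
      keep <- sort(sample.int(nrow(rs), target_ranges))
      out <- rs[keep, , drop = FALSE]
      rownames(out) <- NULL
      class(out) <- c("range_set", "data.frame")
      return(list(lambda_a = la, ranges = out))
    }
    la <- la + step
  }
  stop("calibrate_anagenesis: target range count not reached at lambda_a <= ",
       max_lambda_a)
}
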