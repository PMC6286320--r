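# Fixtures and independent oracles shared across tests. Everything is
# built in code; nothing is read from disk.

# A hand-built complete tree with known structure (ages before present):
#   lineage 1: origin age 10, extant tip
#   lineage 2: buds off 1 at age 6, goes extinct at age 2
#   lineage 3: buds off 1 at age 4, extant
#   lineage 4: buds off 2 at age 5, extant
toy_tree <- function() {
  structure(list(
    lineages = data.frame(
      id = 1:4,
      parent = c(NA_integer_, 1L, 1L, 2L),
      start_age = c(10, 6, 4, 5),
      end_age = c(0, 2, 0, 0),
      extant = c(TRUE, FALSE, TRUE, TRUE)
    ),
    origin_age = 10,
    n_extant = 3L,
    schedule = rate_schedule(0.2, 0.1)
  ), class = "bdc_tree")
}

# Brute-force MRCA oracle on the lineage table, independent of the
# package's induced-tree computation: the MRCA age of two tips is found by
# walking their ancestor chains to the deepest shared lineage and taking
# the older of the two attachment ages on it.
ancestor_chain <- function(lin, id) {
  out <- id
  while (!is.na(lin$parent[id])) {
    id <- lin$parent[id]
    out <- c(out, id)
  }
  out
}

mrca_age_oracle <- function(tree, u, v) {
  lin <- tree$lineages
  cu <- ancestor_chain(lin, u)
  cv <- ancestor_chain(lin, v)
  common <- intersect(cu, cv)
  c0 <- common[1L]  # deepest shared lineage (chains are root-terminated)
  att <- function(chain, tip) {
    i <- match(c0, chain)
    if (i == 1L) lin$end_age[c0] else lin$start_age[chain[i - 1L]]
  }
  max(att(cu, u), att(cv, v))
}

branching_ages_oracle <- function(tree, keep) {
  prs <- utils::combn(keep, 2L)
  ages <- apply(prs, 2L, function(p) mrca_age_oracle(tree, p[1L], p[2L]))
  sort(unique(ages), decreasing = TRUE)
}

# Independent chi-square quantile oracle: root-finding on the integrated
# density, no use of qchisq().
chisq_quantile_oracle <- function(p, df) {
  dens <- function(x) x^(df / 2 - 1) * exp(-x / 2) / (2^(df / 2) * gamma(df / 2))
  cdf <- function(q) integrate(dens, 0, q, rel.tol = 1e-12)$value
  uniroot(function(q) cdf(q) - p, c(1e-6, 100), tol = 1e-10)$root
}

# A small simulated data set (tree + phylo data + ranges) reused by
# several tests.
small_dataset <- function(seed = 42L, n = 60L, lambda = 0.2, mu = 0.1,
                          beta = 0, lambda_a = 0) {
  tr <- simulate_tree(rate_schedule(lambda, mu), n, seed = seed)
  list(tree = tr,
       phylo = prune_extinct(tr),
       ranges = assign_chronospecies(tr, bdc_params(lambda, mu, beta,
                                                    lambda_a)))
}
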