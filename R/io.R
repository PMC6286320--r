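## Readers and writers for the on-disk artifacts. Trees travel as Newick
## (via ape), ranges and occurrences as TSV with a header, run
## configuration as a flat YAML document. All ages are time before present
## (present = 0); readers validate and refuse to coerce invalid values.

#' Read a dated tree from a Newick file
#'
#' @param path file path to a Newick tree with branch lengths.
#' @param check_ultrametric require the tree to be ultrametric (an extant
#'   timetree); tolerance `ultrametric_tol`.
#' @param ultrametric_tol relative tolerance for the ultrametricity check.
#' @return An `ape::phylo` object.
#' @export
read_newick <- function(path, check_ultrametric = FALSE,
                        ultrametric_tol = 1e-6) {
  if (!file.exists(path)) stop("no such file: ", path)
  phy <- tryCatch(ape::read.tree(path),
                  error = function(e) stop("malformed Newick in ", path, ": ",
                                           conditionMessage(e)))
  if (is.null(phy)) stop("malformed Newick in ", path)
  if (is.null(phy$edge.length)) stop("tree in ", path, " has no branch lengths")
  if (any(phy$edge.length < 0)) stop("negative branch lengths in ", path)
  if (check_ultrametric &&
      !ape::is.ultrametric(phy, tol = ultrametric_tol)) {
    stop("tree in ", path, " is not ultrametric at tolerance ",
         ultrametric_tol, "; extant timetrees must be ultrametric")
  }
  phy
}

#' Write a tree (or complete simulated tree) to Newick
#'
#' @param tree an `ape::phylo` or a `bdc_tree`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "bdc_tree")) tree <- as.phylo.bdc_tree(tree)
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read / write stratigraphic range tables
#'
#' Range TSV files carry the columns `species`, `origination`,
#' `extinction`, `status`, and optionally `parent` and `mode`; ages are
#' time before present with `.` as the decimal separator. Rows with
#' `extinction > origination`, negative ages, extant rows with non-zero
#' extinction, or duplicated species identifiers are rejected.
#'
#' @param path file path.
#' @return [read_ranges()]: a [range_set()].
#' @export
read_ranges <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("species", "origination", "extinction", "status")
  if (!all(need %in% names(x))) {
    stop("range table must have columns: ", paste(need, collapse = ", "))
  }
  range_set(x$species, x$origination, x$extinction, x$status,
            parent = if ("parent" %in% names(x)) x$parent else NA,
            mode = if ("mode" %in% names(x)) x$mode else "root")
}

#' @rdname read_ranges
#' @param ranges a [range_set()].
#' @export
write_ranges <- function(ranges, path) {
  stopifnot(inherits(ranges, "range_set"))
  write.table(ranges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write fossil occurrence tables
#'
#' Occurrence TSVs have columns `species` and `age`. PyRate-style
#' two-column files (taxon, age, in any header spelling with those two
#' columns first) are accepted.
#'
#' @param path file path.
#' @return [read_occurrences()]: an [occurrence_table()].
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("species", "age") %in% names(x))) {
    if (ncol(x) >= 2L) {
      names(x)[1:2] <- c("species", "age")   # PyRate-style two-column input
    } else {
      stop("occurrence table must have columns species, age")
    }
  }
  if (!is.numeric(x$age)) stop("occurrence ages must be numeric")
  occurrence_table(x$species, x$age)
}

#' @rdname read_occurrences
#' @param occ an [occurrence_table()].
#' @export
write_occurrences <- function(occ, path) {
  stopifnot(inherits(occ, "occurrence_table"))
  write.table(occ, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the per-event log of a simulated tree as TSV
#'
#' @param tree a `bdc_tree`.
#' @param path file path.
#' @export
write_event_log <- function(tree, path) {
  write.table(tree_event_log(tree), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

.config_keys <- c("lambda", "mu", "beta", "lambda_a", "kappa", "n_tips",
                  "breaks", "lambdas", "mus", "removal_x", "removal_scheme",
                  "psi", "rho", "alpha", "iterations", "burnin", "seed",
                  "n_reps", "conditioning", "restarts", "independent",
                  "out_dir", "tree_file", "ranges_file", "occurrence_file")

#' Read / write a run configuration
#'
#' Flat key-value YAML documents holding simulator and estimator settings.
#' Unknown keys are rejected so that typos fail loudly; every pipeline
#' command writes its resolved configuration next to its outputs.
#'
#' @param path file path.
#' @return [read_run_config()]: a named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- yaml::read_yaml(path)
  bad <- setdiff(names(cfg), .config_keys)
  if (length(bad)) {
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  }
  cfg
}

#' @rdname read_run_config
#' @param config named list of settings (known keys only).
#' @export
write_run_config <- function(config, path) {
  bad <- setdiff(names(config), .config_keys)
  if (length(bad)) {
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  }
  yaml::write_yaml(config, path)
  invisible(path)
}
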