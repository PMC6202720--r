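# Tree and trait I/O: Newick parsing, representative-tip pruning, and
# validation of the tree-trait binding used by all comparative stages.
# Trees are ape "phylo" objects throughout.

#' Read and validate a rooted phylogeny
#'
#' Parses a Newick string or file into an ape `phylo` object and enforces the
#' invariants the comparative machinery relies on: a single root, unique tip
#' labels, non-negative branch lengths, and a strictly bifurcating topology.
#' Polytomies (e.g. from consensus trees) are resolved deterministically in
#' input order into zero-length bifurcations; the Mk likelihood is invariant
#' to the resolution order because the inserted branches have length zero.
#' Comments in square brackets are skipped by the Newick parser.
#'
#' @param text a Newick string (used when `file` is `NULL`).
#' @param file optionally, path to a Newick file.
#' @return A rooted, bifurcating `phylo` object with branch lengths.
#' @export
read_tree <- function(text = NULL, file = NULL) {
  tr <- if (!is.null(file)) {
    ape::read.tree(file)
  } else {
    if (is.null(text)) stop("supply `text` or `file`", call. = FALSE)
    tryCatch(suppressWarnings(ape::read.tree(text = text)),
             error = function(e)
               stop("malformed Newick: ", conditionMessage(e), call. = FALSE))
  }
  if (is.null(tr)) stop("malformed Newick: parser returned no tree", call. = FALSE)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  validate_tree(tr)
}

#' @rdname read_tree
#' @param tree a `phylo` object.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree must have branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed", call. = FALSE)
  if (!ape::is.binary(tree) || !ape::is.rooted(tree))
    tree <- ape::multi2di(tree, random = FALSE)  # zero-length, input order
  if (!ape::is.rooted(tree))
    stop("tree must be rooted", call. = FALSE)
  tree
}

#' Write a tree to Newick
#'
#' @param tree a `phylo` object.
#' @param file optional path; if `NULL` the Newick string is returned.
#' @export
write_tree <- function(tree, file = NULL) {
  if (is.null(file)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = file)
  invisible(file)
}

#' Prune a tree to representative tips
#'
#' Restricts the tree to the named representatives (one per distinct lineage /
#' genus / species group), suppressing unbranched internal nodes and summing
#' branch lengths so that patristic distances among the kept tips are
#' conserved.
#'
#' @param tree a `phylo` object.
#' @param keep character vector of tip labels to retain (at least 2).
#' @return The induced subtree on `keep`.
#' @export
prune_to_representatives <- function(tree, keep) {
  tree <- validate_tree(tree)
  keep <- as.character(keep)
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown))
    stop("unknown tips: ", paste(unknown, collapse = ", "), call. = FALSE)
  if (length(keep) < 2L) stop("need at least 2 tips to keep", call. = FALSE)
  ape::keep.tip(tree, keep)
}

#' Bind a character matrix to a tree
#'
#' Validates that tip labels and trait assignments cover each other exactly and
#' returns the trait vector ordered as `tree$tip.label`.
#'
#' @param tree a `phylo` object.
#' @param states named vector (names = tip labels) of discrete states, or a
#'   data.frame with columns `species` and `state`.
#' @param state_names optional ordered state set; defaults to the sorted
#'   observed states.
#' @return List with `tree`, `states` (factor ordered by tip label with levels
#'   `state_names`).
#' @export
bind_traits <- function(tree, states, state_names = NULL) {
  tree <- validate_tree(tree)
  if (is.data.frame(states)) {
    if (!all(c("species", "state") %in% names(states)))
      stop("trait table needs columns `species` and `state`", call. = FALSE)
    states <- stats::setNames(as.character(states$state), states$species)
  }
  if (is.null(names(states)))
    stop("states must be named by tip label", call. = FALSE)
  missing_states <- setdiff(tree$tip.label, names(states))
  extra_states <- setdiff(names(states), tree$tip.label)
  if (length(missing_states) || length(extra_states)) {
    msg <- c(
      if (length(missing_states))
        paste0("tips without a state: ", paste(missing_states, collapse = ", ")),
      if (length(extra_states))
        paste0("states without a tip: ", paste(extra_states, collapse = ", ")))
    stop("tree/trait binding failed; ", paste(msg, collapse = "; "),
         call. = FALSE)
  }
  s <- as.character(states[tree$tip.label])
  if (anyNA(s)) stop("missing state values", call. = FALSE)
  lev <- state_names %||% sort(unique(s))
  if (!all(s %in% lev))
    stop("states outside state_names: ",
         paste(setdiff(s, lev), collapse = ", "), call. = FALSE)
  list(tree = tree,
       states = factor(stats::setNames(s, tree$tip.label), levels = lev))
}

#' Read a trait table CSV
#'
#' @param path CSV with at least a `species` column.
#' @export
read_traits <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
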