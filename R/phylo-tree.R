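#' Parse a Newick string into a validated phylogeny
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' rest of the package relies on: unique tip labels, non-negative branch
#' lengths, and branch lengths present on every non-root edge. Polytomies are
#' preserved; single-tip trees are accepted but flagged degenerate with a
#' warning.
#'
#' @param text Newick string (trailing semicolon required).
#' @return An object of class `phylo`.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  check_newick_syntax(text)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree)) stop("Newick parse error: unparseable string", call. = FALSE)
  validate_phylogeny(tree)
  if (ape::Ntip(tree) == 1L)
    warning("degenerate phylogeny: single tip", call. = FALSE)
  tree
}

# Pre-parse structural check so malformed input fails with a character offset
# (ape's parser errors are opaque).
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick parse error: unbalanced ')' at character ", i, call. = FALSE)
    }
  }
  if (depth != 0L)
    stop("Newick parse error: ", depth, " unclosed '(' at end of string", call. = FALSE)
  semi <- which(chars == ";")
  if (length(semi) == 0L)
    stop("Newick parse error: missing terminal ';' (string length ",
         length(chars), ")", call. = FALSE)
  invisible(TRUE)
}

#' Validate a phylogeny against the package's structural invariants
#'
#' @param tree A `phylo` object.
#' @param require_lengths Require branch lengths on all edges.
#' @return The tree, invisibly; errors describe the violated invariant.
#' @export
validate_phylogeny <- function(tree, require_lengths = TRUE) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate tip labels: ", paste(dup, collapse = ", "), call. = FALSE)
  if (require_lengths) {
    if (is.null(tree$edge.length))
      stop("phylogeny has no branch lengths", call. = FALSE)
    if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
      stop("branch lengths must be non-negative and non-missing", call. = FALSE)
  }
  # exactly one root: one node that never appears as a child
  if (ape::Ntip(tree) > 1L) {
    parents <- tree$edge[, 1]
    children <- tree$edge[, 2]
    roots <- setdiff(parents, children)
    if (length(roots) != 1L)
      stop("phylogeny must have exactly one root", call. = FALSE)
    if (anyDuplicated(children))
      stop("a node has more than one parent", call. = FALSE)
  }
  invisible(tree)
}

#' Serialize a phylogeny to Newick
#'
#' @param tree A `phylo` object.
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @return Newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, file = NULL) {
  validate_phylogeny(tree, require_lengths = FALSE)
  if (is.null(file)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = file)
  invisible(ape::write.tree(tree))
}

#' Read a phylogeny from a Newick file
#'
#' @param file Path to a `.nwk`/`.tre` file.
#' @return A validated `phylo` object.
#' @export
read_phylogeny <- function(file) {
  if (!file.exists(file)) stop("tree file not found: ", file, call. = FALSE)
  parse_newick(paste(readLines(file, warn = FALSE), collapse = ""))
}

#' Prune a phylogeny to a set of tips
#'
#' Retained-tip patristic distances are unchanged: unbranched internal nodes
#' created by the pruning are collapsed with their branch lengths summed
#' (ape's behaviour, relied upon throughout the pipeline).
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to retain (at least one).
#' @return The pruned `phylo`.
#' @export
prune_to_tips <- function(tree, keep) {
  keep <- unique(as.character(keep))
  if (length(keep) < 1L) stop("'keep' must contain at least one tip", call. = FALSE)
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing))
    stop("tips not in phylogeny: ", paste(missing, collapse = ", "), call. = FALSE)
  if (length(keep) == ape::Ntip(tree)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Patristic distance matrix among tips
#'
#' Distances are sums of branch lengths along tree paths, computed from
#' node-to-node path lengths ([ape::dist.nodes()]), which scales to the
#' multi-thousand-tip pools this package targets.
#'
#' @param tree A `phylo` object.
#' @param tips Tip labels to include (default: all); at least two.
#' @return Symmetric numeric matrix with tip labels as dimnames.
#' @export
pairwise_distances <- function(tree, tips = NULL) {
  if (is.null(tips)) tips <- tree$tip.label
  tips <- unique(as.character(tips))
  if (length(tips) < 2L) stop("need at least two tips", call. = FALSE)
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing))
    stop("tips not in phylogeny: ", paste(missing, collapse = ", "), call. = FALSE)
  idx <- match(tips, tree$tip.label)
  d <- ape::dist.nodes(tree)[idx, idx, drop = FALSE]
  dimnames(d) <- list(tips, tips)
  d
}

#' Test ultrametricity and report the maximum relative deviation
#'
#' A tree is ultrametric when all root-to-tip path lengths agree (a dated
#' phylogeny). The deviation reported is `(max depth - min depth) / max depth`.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param rel_tol Relative tolerance on root-to-tip depth spread.
#' @return List with `ultrametric` (logical) and `max_deviation` (numeric).
#' @export
is_ultrametric <- function(tree, rel_tol = 1e-6) {
  if (is.null(tree$edge.length)) stop("phylogeny has no branch lengths", call. = FALSE)
  depths <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  dmax <- max(depths)
  dev <- if (dmax > 0) (dmax - min(depths)) / dmax else 0
  list(ultrametric = dev <= rel_tol, max_deviation = dev)
}

# Root-to-node path lengths for all nodes (tips first, ape numbering).
node_depths <- function(tree) {
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  depths <- numeric(n_node)
  # edges in preorder so parents are visited before children
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(ord$edge))) {
    depths[ord$edge[k, 2]] <- depths[ord$edge[k, 1]] + ord$edge.length[k]
  }
  depths[root] <- 0
  depths
}

#' Node ages of an ultrametric phylogeny
#'
#' Age = time before present, i.e. maximum root-to-tip depth minus the node's
#' own depth; tips of an ultrametric tree have age (numerically) zero.
#'
#' @param tree Ultrametric `phylo`.
#' @return Numeric vector of ages indexed by ape node number (tips first).
#' @export
node_ages <- function(tree) {
  depths <- node_depths(tree)
  max(depths[seq_len(ape::Ntip(tree))]) - depths
}
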