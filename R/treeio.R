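#' Parse a newick string into a validated rooted phylogeny
#'
#' Thin, validating wrapper around [ape::read.tree()]. The returned object is
#' an ordinary `ape` `phylo`, so it composes with the wider phylogenetics
#' ecosystem; validation enforces the invariants the comparative machinery
#' relies on (rooted, unique non-empty tip labels, finite non-negative branch
#' lengths on every edge). Internal node labels are accepted and ignored.
#' Polytomies are accepted here; contrast code resolves them downstream.
#'
#' @param text A single newick string (terminating `;` required by the
#'   format). Branch lengths must be present on all edges; a missing root
#'   edge length is treated as 0.
#' @return A rooted `phylo` object.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tip_depths(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) NULL,
    warning = function(w) NULL
  )
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("malformed newick string (near character ",
         regexpr("[^();,:[:alnum:]_. \t-]|$", text), "): could not parse",
         call. = FALSE)
  }
  validate_tree(tree)
}

#' Serialize a phylogeny to newick
#'
#' Inverse of [parse_newick()]: `parse_newick(write_newick(t))` preserves
#' topology and branch lengths to better than 1e-12 (lengths are printed with
#' 15 significant digits).
#'
#' @param tree A `phylo` object.
#' @return A single newick string.
#' @export
write_newick <- function(tree) {
  tree <- validate_tree(tree)
  ape::write.tree(tree, digits = 15)
}

#' Validate the tree invariants required by the comparative statistics
#'
#' @param tree A `phylo` object.
#' @return The tree, invisibly unchanged, or an error.
#' @keywords internal
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  # structural rootedness: exactly one node with no parent (a basal
  # polytomy is accepted; ape::is.rooted would reject it)
  roots <- setdiff(tree$edge[, 1L], tree$edge[, 2L])
  if (length(roots) != 1L) stop("tree must be rooted", call. = FALSE)
  labs <- tree$tip.label
  if (anyDuplicated(labs)) {
    stop("duplicate tip labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(labs))) stop("empty tip label", call. = FALSE)
  if (is.null(tree$edge.length)) {
    stop("branch lengths are required", call. = FALSE)
  }
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
    stop("branch lengths must be finite and >= 0", call. = FALSE)
  }
  tree
}

#' Root-to-tip depths
#'
#' @param tree A `phylo` object.
#' @return Named numeric vector of root-to-tip path lengths, in tip order.
#' @export
tip_depths <- function(tree) {
  tree <- validate_tree(tree)
  n <- ape::Ntip(tree)
  depth <- node_depths(tree)
  stats::setNames(depth[seq_len(n)], tree$tip.label)
}

# depth of every node (tips 1..n, root n+1, ...) by preorder accumulation
node_depths <- function(tree) {
  n <- ape::Ntip(tree)
  root <- n + 1L
  nn <- n + tree$Nnode
  depth <- numeric(nn)
  edge <- tree$edge
  ord <- rev(ape::postorder(tree))  # preorder over edges
  for (e in ord) {
    depth[edge[e, 2L]] <- depth[edge[e, 1L]] + tree$edge.length[e]
  }
  depth
}

#' Departure from ultrametricity
#'
#' Reports `max |tip depth - mean tip depth|`; the comparative methods do not
#' require an ultrametric tree, but the synthetic trees are, and the check is
#' cheap.
#'
#' @param tree A `phylo` object.
#' @return A single non-negative number.
#' @export
ultrametricity_gap <- function(tree) {
  d <- tip_depths(tree)
  max(abs(d - mean(d)))
}

#' Brownian-motion covariance of a rooted phylogeny
#'
#' Returns the matrix `V` with `V[i, j]` equal to the root-to-MRCA shared path
#' length of tips `i` and `j` (tip depth on the diagonal) — the trait
#' covariance structure implied by Brownian evolution, consumed by
#' [blomberg_k()] and by the GLS cross-checks of the contrast code. Computed
#' directly from the edge table rather than delegated, so tests can oracle it
#' against explicit path intersection.
#'
#' @param tree A rooted `phylo` object.
#' @return A symmetric positive semi-definite matrix with tip labels as
#'   dimnames, rows/columns in `tree$tip.label` order.
#' @examples
#' phylo_vcv(parse_newick("((A:1,B:1):1,C:2);"))
#' @export
phylo_vcv <- function(tree) {
  tree <- validate_tree(tree)
  n <- ape::Ntip(tree)
  depth <- node_depths(tree)
  edge <- tree$edge
  # tips descending from each node, accumulated in postorder
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- i
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (e in ape::postorder(tree)) {
    parent <- edge[e, 1L]
    child <- edge[e, 2L]
    if (is.null(desc[[parent]])) {
      desc[[parent]] <- desc[[child]]
    } else {
      # pairs first meeting at `parent` share depth[parent]
      a <- desc[[parent]]
      b <- desc[[child]]
      V[a, b] <- depth[parent]
      V[b, a] <- depth[parent]
      desc[[parent]] <- c(a, b)
    }
  }
  diag(V) <- depth[seq_len(n)]
  V
}

#' Prune a tree and trait table to their shared species
#'
#' Matching is exact and case-sensitive. With `strict = TRUE` (default) any
#' mismatch is an error listing both unmatched sets; otherwise the
#' intersection is kept and reported via a message.
#'
#' @param tree A `phylo` object.
#' @param species Character vector of species names (e.g. trait-table rows).
#' @param strict Error on any mismatch instead of pruning to the overlap.
#' @return A list with elements `tree` and `species` (the matched, ordered
#'   species set, in tip order of the pruned tree).
#' @export
match_tree_species <- function(tree, species, strict = TRUE) {
  tree <- validate_tree(tree)
  missing_tips <- setdiff(tree$tip.label, species)
  missing_rows <- setdiff(species, tree$tip.label)
  if (length(missing_tips) || length(missing_rows)) {
    msg <- paste0(
      "tips absent from table: {", paste(missing_tips, collapse = ", "), "}; ",
      "table rows absent from tree: {", paste(missing_rows, collapse = ", "), "}"
    )
    if (strict) stop("species mismatch — ", msg, call. = FALSE)
    message("pruning to shared species — ", msg)
    if (length(missing_tips)) tree <- ape::drop.tip(tree, missing_tips)
  }
  list(tree = tree, species = tree$tip.label)
}
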