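#' Parse a newick string or file into a validated binary tree
#'
#' Thin wrapper around [ape::read.tree()] that enforces the tree conventions
#' used throughout this package: trees must be binary, leaf labels must be
#' unique and non-empty, and a trifurcation at the root is interpreted as an
#' unrooted binary tree (the conventional serialization of unrooted trees).
#' Any other polytomy is rejected.
#'
#' @param text A newick string. Exactly one of `text`/`file` must be given.
#' @param file Path to a newick file containing a single tree.
#' @return An object of class `"phylo"`. Missing branch lengths are filled
#'   with 0 (with a warning), so that downstream code can rely on
#'   `$edge.length` being present.
#' @examples
#' parse_newick("((A:1,B:1):1,C:2);")
#' parse_newick("(A,B,C);") # unrooted convention
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  stopifnot(xor(is.null(text), is.null(file)))
  tr <- tryCatch(
    suppressWarnings(
      if (is.null(file)) ape::read.tree(text = text) else
        ape::read.tree(file)),
    error = function(e) stop("newick parse error: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (is.null(tr)) stop("newick parse error: no tree found", call. = FALSE)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop("expected a single tree", call. = FALSE)
    tr <- tr[[1L]]
  }
  validate_tree(tr)
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; defaulting to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  }
  tr
}

#' Serialize a tree to newick
#'
#' Rooted trees serialize bifurcating; unrooted trees (trifurcating root
#' representation) keep their trifurcation. Round-tripping through
#' [parse_newick()] preserves topology, labels and branch lengths to
#' within 1e-9.
#'
#' @param tree A `"phylo"` object.
#' @param file Optional path; if `NULL` the newick string is returned.
#' @export
write_newick <- function(tree, file = NULL) {
  s <- ape::write.tree(tree, digits = 12)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Validate the binary-tree invariants
#'
#' @param tree A `"phylo"` object.
#' @return `tree`, invisibly; errors describe the violated invariant.
#' @export
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  lab <- tree$tip.label
  if (anyDuplicated(lab)) {
    stop("duplicate leaf labels: ",
         paste(unique(lab[duplicated(lab)]), collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(lab))) stop("empty leaf label", call. = FALSE)
  if (!ape::is.binary(tree)) {
    stop("tree is not binary (polytomy other than a root trifurcation)",
         call. = FALSE)
  }
  invisible(tree)
}

#' Is the tree stored in rooted (bifurcating-root) form?
#' @param tree A `"phylo"` object.
#' @export
is_rooted_tree <- function(tree) ape::is.rooted(tree)

#' Root an unrooted tree on a given edge
#'
#' Creates a root of degree two in the middle of edge `edge` (an index into
#' `tree$edge`). Together with [enumerate_rootings()] this realizes the
#' one-rooting-per-edge correspondence used by unrooted reconciliation.
#'
#' @param tree An unrooted binary `"phylo"` (trifurcating root form).
#' @param edge Edge index in `tree$edge`.
#' @export
root_at_edge <- function(tree, edge) {
  stopifnot(edge >= 1, edge <= nrow(tree$edge))
  has_el <- !is.null(tree$edge.length)
  if (!has_el) tree$edge.length <- rep(1, nrow(tree$edge))
  node <- tree$edge[edge, 2L]
  rooted <- phytools::reroot(tree, node.number = node,
                             position = tree$edge.length[edge] / 2)
  if (!has_el) rooted$edge.length <- NULL
  rooted
}

#' All rootings of an unrooted tree
#'
#' Returns the 2m-3 rooted trees obtained by placing the root on each edge
#' of the unrooted topology (1 rooting for m = 2).
#'
#' @param tree A binary `"phylo"`; rooted input is unrooted first.
#' @return A list of rooted `"phylo"` objects.
#' @export
enumerate_rootings <- function(tree) {
  m <- ape::Ntip(tree)
  stopifnot(m >= 2)
  if (m == 2L) {
    return(list(tree))
  }
  tree <- ape::unroot(tree)
  lapply(seq_len(nrow(tree$edge)), function(e) root_at_edge(tree, e))
}

#' Random nearest-neighbour-interchange move
#'
#' One NNI on a uniformly chosen internal edge of the unrooted topology
#' (rooted input is unrooted first). The result differs from the input by
#' exactly one split on each side (unnormalized RF distance 2). Randomness
#' comes from R's RNG; use `set.seed()` for reproducibility.
#'
#' @param tree A binary `"phylo"` with at least 4 leaves.
#' @export
random_nni <- function(tree) {
  stopifnot(ape::Ntip(tree) >= 4)
  phangorn::rNNI(ape::unroot(tree), moves = 1)
}

#' Random subtree-prune-and-regraft move
#'
#' Prunes a random subtree of the unrooted topology and regrafts it onto a
#' random other edge. Leaf set is always preserved; the topology changes
#' unless the subtree is regrafted adjacent to its origin.
#'
#' @param tree A binary `"phylo"` with at least 4 leaves.
#' @export
random_spr <- function(tree) {
  stopifnot(ape::Ntip(tree) >= 4)
  phangorn::rSPR(ape::unroot(tree), moves = 1)
}

#' Non-trivial splits of a tree, as canonical strings
#'
#' Each internal edge of the unrooted topology induces a bipartition of the
#' leaf set; trivial splits (one leaf versus the rest) are excluded. The
#' canonical string for a split is the sorted, comma-joined side that does
#' not contain the alphabetically first leaf label, so two trees over the
#' same leaves share a split if and only if the strings are equal.
#'
#' @param tree A `"phylo"` object (rooted or unrooted; may be
#'   multifurcating, e.g. after support-based collapsing).
#' @return Character vector of canonical split strings (possibly empty).
#' @export
tree_splits <- function(tree) {
  tr <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  m <- ape::Ntip(tr)
  if (m < 4) return(character(0))
  labs <- tr$tip.label
  ref <- sort(labs)[1L]
  pp <- ape::prop.part(tr)
  root_id <- m + 1L
  internal <- setdiff(unique(tr$edge[, 1L]), root_id)
  out <- character(0)
  for (v in internal) {
    tips <- labs[pp[[v - m]]]
    if (length(tips) < 2L || length(tips) > m - 2L) next
    side <- if (ref %in% tips) setdiff(labs, tips) else tips
    out <- c(out, paste(sort(side), collapse = ","))
  }
  unique(out)
}

#' Canonical key for an unrooted topology
#'
#' Two trees get the same key iff they have the same leaf set and the same
#' unrooted split set (64-bit hash of the canonical split-set string).
#' Used for topology memoization during search.
#'
#' @param tree A `"phylo"` object.
#' @export
topology_key <- function(tree) {
  .str_hash(paste(c(paste(sort(tree$tip.label), collapse = ","),
                    sort(tree_splits(tree))), collapse = ";"))
}

#' Normalized Robinson-Foulds distance between unrooted topologies
#'
#' The fraction of non-trivial splits present in only one of the two trees:
#' the size of the symmetric difference of split sets divided by 2(m-3),
#' the total number of non-trivial splits in two binary trees with m
#' leaves. For binary trees an NRFD of x means a fraction x of splits of
#' either tree is absent from the other. Zero iff the unrooted topologies
#' are identical. Multifurcating inputs (e.g. support-collapsed trees) are
#' allowed; their missing splits count against them while the denominator
#' stays 2(m-3).
#'
#' @param t1,t2 `"phylo"` objects over identical leaf sets.
#' @return A number in `[0, 1]`.
#' @export
nrfd <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees have different leaf sets", call. = FALSE)
  }
  m <- ape::Ntip(t1)
  if (m <= 3) return(0)
  s1 <- tree_splits(t1)
  s2 <- tree_splits(t2)
  length(c(setdiff(s1, s2), setdiff(s2, s1))) / (2 * (m - 3))
}
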