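#' Parse a Newick string into an unrooted tree
#'
#' Reads a single tree in Newick format and returns an [ape::phylo] object.
#' Rooted inputs (basal bifurcation) are accepted and unrooted by suppressing
#' the degree-2 root, so all downstream metrics operate on unrooted trees.
#' Support values decorating internal nodes are accepted and ignored. Missing
#' branch lengths default to 0.
#'
#' @param text a Newick string (terminating `;` optional).
#' @return an object of class `phylo`, unrooted, with `edge.length` set.
#' @seealso [write_newick()], [tree_splits()]
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:1,D:1);")
#' ape::Ntip(tr)
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl(";\\s*$", text)) text <- paste0(text, ";")
  tr <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) NULL
  )
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("malformed Newick string: ", substr(text, 1L, 60L))
  if (ape::Ntip(tr) < 3L)
    stop("tree has fewer than 3 leaves (", ape::Ntip(tr), ")")
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup))
    stop("duplicate leaf label: ", paste(dQuote(dup), collapse = ", "))
  if (any(!nzchar(tr$tip.label)))
    stop("empty leaf label in Newick input")
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0, nrow(tr$edge))
  tr$edge.length[is.na(tr$edge.length)] <- 0
  if (any(tr$edge.length < 0))
    stop("negative branch length in input")
  if (ape::is.rooted(tr)) tr <- ape::unroot(tr)
  tr$node.label <- NULL
  ape::reorder.phylo(tr, "cladewise")
}

#' Serialize a tree to Newick
#'
#' Round-trip stable: re-parsing the output yields an identical split set and
#' branch lengths to within 1e-12 (lengths are written with 15 significant
#' digits). Multifurcations are preserved.
#'
#' @param tree a `phylo` object.
#' @return a single Newick string.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, digits = 15)
}

## Canonical split encoding: for every internal edge, the tip set on the
## child side, complemented if it contains the lexicographically smallest
## leaf, sorted and collapsed with ",".  Trivial splits dropped.
split_strings <- function(tree) {
  nt <- ape::Ntip(tree)
  labs <- tree$tip.label
  tree <- ape::reorder.phylo(tree, "postorder")
  e <- tree$edge
  nnode <- tree$Nnode
  ## accumulate tip memberships bottom-up
  memb <- matrix(FALSE, nt + nnode, nt)
  memb[cbind(seq_len(nt), seq_len(nt))] <- TRUE
  for (i in seq_len(nrow(e)))
    memb[e[i, 1L], ] <- memb[e[i, 1L], ] | memb[e[i, 2L], ]
  ref <- order(labs)[1L]           # lexicographically smallest leaf
  out <- character(0)
  internal_child <- e[, 2L] > nt
  for (i in which(internal_child)) {
    side <- memb[e[i, 2L], ]
    if (side[ref]) side <- !side
    sz <- sum(side)
    if (sz < 2L || sz > nt - 2L) next
    out <- c(out, paste(sort(labs[side]), collapse = ","))
  }
  unique(out)
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Returns the set of non-trivial splits (bipartitions of the leaf set induced
#' by internal edges), each encoded canonically as the comma-separated sorted
#' labels of the side *not* containing the lexicographically smallest leaf.
#' For a fully binary unrooted tree on n leaves there are n - 3 of them; a
#' star tree has none.
#'
#' @param tree a `phylo` object with >= 4 leaves.
#' @return character vector of canonical split encodings (class `split_set`).
#' @export
#' @examples
#' tree_splits(parse_newick("((A,B),C,(D,(E,F)));"))
tree_splits <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (ape::Ntip(tree) < 4L)
    stop("bipartitions need at least 4 leaves")
  s <- split_strings(tree)
  structure(s, class = "split_set")
}

check_same_leaves <- function(t1, t2) {
  l1 <- sort(t1$tip.label); l2 <- sort(t2$tip.label)
  if (!identical(l1, l2)) {
    only1 <- setdiff(l1, l2); only2 <- setdiff(l2, l1)
    stop("leaf sets differ; only in first: {",
         paste(only1, collapse = ","), "}; only in second: {",
         paste(only2, collapse = ","), "}")
  }
}

#' Robinson-Foulds distance
#'
#' Symmetric-difference count of the two trees' non-trivial split sets, plus
#' the normalization raw / (2 (n - 3)) used throughout the benchmark, which is
#' 0 for identical topologies and 1 for maximally different binary trees.
#'
#' @param t1,t2 `phylo` objects on the same leaf set (n >= 4).
#' @return list with elements `raw` (integer) and `normalized` (in [0, 1]).
#' @export
rf_distance <- function(t1, t2) {
  check_same_leaves(t1, t2)
  n <- ape::Ntip(t1)
  if (n < 4L) stop("RF distance needs at least 4 leaves")
  s1 <- split_strings(t1); s2 <- split_strings(t2)
  raw <- length(setdiff(s1, s2)) + length(setdiff(s2, s1))
  list(raw = as.integer(raw), normalized = raw / (2 * (n - 3)))
}

#' Normalized tree distance
#'
#' Split symmetric difference scaled by the total number of non-trivial splits
#' in both trees, |S1 delta S2| / (|S1| + |S2|).  Coincides with normalized RF
#' for two binary trees and stays well defined for multifurcating trees; two
#' star trees (denominator 0) are defined to be at distance 0.
#'
#' @inheritParams rf_distance
#' @return numeric in [0, 1].
#' @export
ntd_distance <- function(t1, t2) {
  check_same_leaves(t1, t2)
  s1 <- split_strings(t1); s2 <- split_strings(t2)
  den <- length(s1) + length(s2)
  if (den == 0L) return(0)
  (length(setdiff(s1, s2)) + length(setdiff(s2, s1))) / den
}

## Quartet resolution codes for every 4-subset of leaves, given a split
## membership matrix (splits x leaves, canonical side TRUE).
## 0 = unresolved, 1 = 12|34, 2 = 13|24, 3 = 14|23 w.r.t. the subset order.
quartet_codes <- function(memb, quads) {
  ns <- nrow(memb)
  codes <- integer(nrow(quads))
  if (ns == 0L) return(codes)
  for (q in seq_len(nrow(quads))) {
    m <- memb[, quads[q, ], drop = FALSE]
    rs <- rowSums(m)
    idx <- which(rs == 2L)
    if (!length(idx)) next
    pair <- m[idx[1L], ]
    codes[q] <- if (pair[1L]) {
      if (pair[2L]) 1L else if (pair[3L]) 2L else 3L
    } else {
      if (pair[2L]) { if (pair[3L]) 3L else 2L } else 1L
    }
  }
  codes
}

split_membership <- function(tree) {
  labs <- sort(tree$tip.label)
  s <- split_strings(tree)
  memb <- matrix(FALSE, length(s), length(labs),
                 dimnames = list(NULL, labs))
  for (i in seq_along(s))
    memb[i, strsplit(s[i], ",", fixed = TRUE)[[1L]]] <- TRUE
  memb
}

#' Quartet distance between two trees
#'
#' Fraction of the C(n, 4) leaf quadruples whose induced quartet topologies
#' differ. Exact brute-force enumeration; a quartet left unresolved by a
#' multifurcation counts as differing unless it is unresolved in both trees.
#' Because enumeration is quartic in n, a practical cap guards against
#' accidental use on very large trees.
#'
#' @inheritParams rf_distance
#' @param max_leaves refuse trees larger than this (default 200).
#' @return numeric in [0, 1].
#' @export
quartet_distance <- function(t1, t2, max_leaves = 200L) {
  check_same_leaves(t1, t2)
  n <- ape::Ntip(t1)
  if (n < 4L) stop("quartet distance needs at least 4 leaves")
  if (n > max_leaves)
    stop("brute-force quartet enumeration capped at ", max_leaves,
         " leaves; raise max_leaves explicitly to override")
  quads <- t(utils::combn(n, 4L))
  c1 <- quartet_codes(split_membership(t1), quads)
  c2 <- quartet_codes(split_membership(t2), quads)
  mean(c1 != c2)
}

topology_key <- function(tree) {
  paste(sort(split_strings(tree)), collapse = ";")
}

#' Number of unique topologies in a collection of trees
#'
#' Trees are equivalent when their canonical split sets are equal; branch
#' lengths are ignored.
#'
#' @param trees list of `phylo` objects on a common leaf set.
#' @return integer count (0 for an empty list).
#' @export
unique_topology_count <- function(trees) {
  if (!length(trees)) return(0L)
  length(unique(vapply(trees, topology_key, character(1L))))
}

#' Mean pairwise normalized RF distance
#'
#' Average of the normalized Robinson-Foulds distance over all unordered pairs
#' of trees; defined as 0 for fewer than two trees.
#'
#' @param trees list of `phylo` objects on a common leaf set.
#' @return numeric in [0, 1].
#' @export
mean_pairwise_rf <- function(trees) {
  m <- length(trees)
  if (m <= 1L) return(0)
  n <- ape::Ntip(trees[[1L]])
  ss <- lapply(trees, split_strings)
  tot <- 0
  for (i in seq_len(m - 1L))
    for (j in (i + 1L):m) {
      raw <- length(setdiff(ss[[i]], ss[[j]])) +
        length(setdiff(ss[[j]], ss[[i]]))
      tot <- tot + raw / (2 * (n - 3))
    }
  tot / (m * (m - 1L) / 2)
}

#' Random binary tree by sequential leaf attachment
#'
#' Builds a uniform random unrooted binary topology by attaching leaves one at
#' a time to a uniformly chosen edge, then draws independent exponential
#' branch lengths. Leaves are labeled `T1 .. Tn`.
#'
#' @param n_taxa number of leaves (>= 3).
#' @param bl_mean mean of the exponential branch-length distribution
#'   (expected substitutions per site).
#' @param seed optional integer seed for reproducibility.
#' @return a `phylo` object.
#' @export
random_tree <- function(n_taxa, bl_mean = 0.1, seed = NULL) {
  stopifnot(n_taxa >= 3L, bl_mean > 0)
  if (!is.null(seed)) set.seed(seed)
  ## nodes: 1..n_taxa leaves; internal nodes numbered upward from n_taxa+1
  edges <- matrix(c(n_taxa + 1L, 1L, n_taxa + 1L, 2L, n_taxa + 1L, 3L),
                  ncol = 2L, byrow = TRUE)
  nxt <- n_taxa + 2L
  if (n_taxa > 3L) for (leaf in 4L:n_taxa) {
    i <- sample.int(nrow(edges), 1L)
    u <- edges[i, 1L]; v <- edges[i, 2L]
    w <- nxt; nxt <- nxt + 1L
    edges <- rbind(edges[-i, , drop = FALSE],
                   c(u, w), c(w, v), c(w, leaf))
  }
  tr <- structure(list(
    edge = edges,
    tip.label = paste0("T", seq_len(n_taxa)),
    Nnode = n_taxa - 2L,
    edge.length = stats::rexp(nrow(edges), rate = 1 / bl_mean)
  ), class = "phylo", order = NULL)
  ape::reorder.phylo(tr, "cladewise")
}
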