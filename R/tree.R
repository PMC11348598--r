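#' Build a rooted genome tree from a distance matrix
#'
#' Classic neighbor joining on the pairwise distance matrix, with negative
#' estimated branch lengths clamped to zero, followed by midpoint rooting
#' (root placed halfway along the longest leaf-to-leaf path). Deterministic
#' given the input. On an additive matrix the result reproduces the generating
#' topology and branch lengths exactly.
#'
#' @param d Symmetric numeric distance matrix with genome ids as dimnames
#'   (e.g. from [distance_matrix()]); at least 3 taxa, finite entries.
#' @return A rooted `phylo` tree.
#' @export
build_tree <- function(d) {
  d <- unclass(d)
  if (!is.matrix(d) || nrow(d) != ncol(d) || nrow(d) < 3) {
    stop("need a square distance matrix on >= 3 taxa", call. = FALSE)
  }
  if (any(!is.finite(d))) stop("distance matrix has non-finite entries", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix is not symmetric", call. = FALSE)
  tree <- ape::nj(d)
  tree$edge.length <- pmax(tree$edge.length, 0)
  tree <- phangorn::midpoint(tree)
  tree
}

#' Ultrametrize a rooted tree by iterative subtree balancing
#'
#' Iterates from the leaves toward the root. At each internal node with child
#' subtrees `i = 1..k`, the stem-inclusive height of child subtree `i` is
#' `H_i = edge_length(i) + height(i)` (leaf depths within already-processed
#' subtrees are uniform). The node's balanced height is the mean
#' `H_0 = mean(H_1..H_k)`, and every edge of subtree `i`, including its stem
#' edge, is multiplied by `q_i = H_0 / H_i`, bringing all subtrees to height
#' `H_0`. A zero-height child (`H_i = 0`) gets its stem edge set to `H_0`
#' directly. The result has all leaves exactly equidistant from the root;
#' the topology is unchanged and the operation is idempotent.
#'
#' @param tree A rooted `phylo` tree with non-negative edge lengths.
#' @return The ultrametrized `phylo` tree.
#' @export
ultrametrize <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no edge lengths", call. = FALSE)
  if (any(tree$edge.length < 0)) stop("negative edge lengths", call. = FALSE)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge
  # stem length of each non-root node, updated in place as subtrees balance
  len <- rep(NA_real_, nnode)
  len[edge[, 2]] <- po$edge.length
  height <- numeric(nnode)       # uniform leaf depth within each subtree
  mult <- rep(1, nnode)          # deferred scaling of edges strictly below node
  internal_po <- unique(edge[, 1])  # postorder: children before parents
  children <- split(edge[, 2], edge[, 1])
  for (v in internal_po) {
    cs <- children[[as.character(v)]]
    h <- len[cs] + height[cs]
    h0 <- mean(h)
    for (k in seq_along(cs)) {
      c <- cs[k]
      if (h[k] > 0) {
        q <- h0 / h[k]
        len[c] <- len[c] * q
        mult[c] <- q
      } else {
        len[c] <- h0
        mult[c] <- 1
      }
    }
    height[v] <- h0
  }
  # propagate deferred multipliers root-down: the final length of the edge
  # above node c is len[c] times the product of mult[] over c's proper
  # ancestors (excluding the root)
  scale <- rep(1, nnode)
  pre <- edge[rev(seq_len(nrow(edge))), , drop = FALSE]  # parents before children
  final_len <- len
  for (r in seq_len(nrow(pre))) {
    p <- pre[r, 1]; c <- pre[r, 2]
    final_len[c] <- len[c] * scale[p]
    scale[c] <- scale[p] * mult[c]
  }
  out <- tree
  out$edge.length <- final_len[tree$edge[, 2]]
  out
}

# leaf depths below every node; nodes indexed as in the phylo edge matrix
node_leaf_depth_range <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  hmin <- rep(Inf, nnode); hmax <- rep(-Inf, nnode)
  hmin[seq_len(ntip)] <- 0; hmax[seq_len(ntip)] <- 0
  for (r in seq_len(nrow(po$edge))) {
    p <- po$edge[r, 1]; c <- po$edge[r, 2]; el <- po$edge.length[r]
    hmin[p] <- min(hmin[p], hmin[c] + el)
    hmax[p] <- max(hmax[p], hmax[c] + el)
  }
  list(min = hmin, max = hmax)
}

#' Height of an ultrametric subtree
#'
#' The common leaf depth below a node of an ultrametric tree (0 for leaves).
#' Errors if the leaf depths below the node spread by more than `tol` relative
#' to the subtree height.
#'
#' @param tree An ultrametric rooted `phylo` tree.
#' @param node Node number (tips are `1..Ntip`, root is `Ntip + 1`).
#' @param tol Relative tolerance for the ultrametricity check.
#' @return The subtree height (numeric).
#' @export
subtree_height <- function(tree, node, tol = 1e-9) {
  rng <- node_leaf_depth_range(tree)
  h <- rng$max[node]
  spread <- rng$max[node] - rng$min[node]
  if (spread > tol * max(h, .Machine$double.eps)) {
    stop("subtree below node ", node, " is not ultrametric", call. = FALSE)
  }
  h
}

assert_ultrametric <- function(tree, tol = 1e-9) {
  rng <- node_leaf_depth_range(tree)
  root <- length(tree$tip.label) + 1L
  h <- rng$max[root]
  if (h > 0 && (rng$max[root] - rng$min[root]) > tol * h) {
    stop("tree is not ultrametric (relative leaf-depth spread ",
         format((rng$max[root] - rng$min[root]) / h), ")", call. = FALSE)
  }
  invisible(h)
}

#' Cut an ultrametric tree into maximal fixed-depth clades
#'
#' Returns the maximal subtrees of height at most `depth`: every node whose
#' subtree height is `<= depth` and whose parent's subtree height is
#' `> depth` (the root itself if the whole tree is no taller than `depth`).
#' The clade leaf sets partition the leaves. Depth is measured from the leaves
#' of the ultrametric tree, so a subtree's "depth" equals its height.
#'
#' @param tree An ultrametric rooted `phylo` tree.
#' @param depth Cut depth (> 0); the analysis default is 0.15.
#' @param tol Relative ultrametricity tolerance.
#' @return An object of class `clade_partition`: a list with `membership`
#'   (tibble: `clade_id`, `genome_id`, `clade_height`, `is_singleton`),
#'   `clades` (tibble: `clade_id`, `node`, `clade_height`, `n_genomes`,
#'   `is_singleton`), the `depth`, and the tree height. Clades are numbered in
#'   tree leaf order.
#' @export
cut_clades <- function(tree, depth = 0.15, tol = 1e-9) {
  stopifnot(inherits(tree, "phylo"))
  if (depth <= 0) stop("depth must be positive", call. = FALSE)
  tree_height <- assert_ultrametric(tree, tol)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  rng <- node_leaf_depth_range(tree)
  h <- rng$max
  parent <- rep(NA_integer_, nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  is_clade <- vapply(seq_len(nnode), function(v) {
    if (h[v] > depth) return(FALSE)
    if (v == root) return(TRUE)
    h[parent[v]] > depth
  }, logical(1))
  nodes <- which(is_clade)
  tips_below <- function(v) {
    if (v <= ntip) return(v)
    unlist(phangorn::Descendants(tree, v, type = "tips"))
  }
  tip_sets <- lapply(nodes, tips_below)
  # order clades by the position of their first leaf in the tree's tip order
  ord <- order(vapply(tip_sets, min, numeric(1)))
  nodes <- nodes[ord]
  tip_sets <- tip_sets[ord]
  clade_id <- sprintf("clade_%03d", seq_along(nodes))
  clades <- tibble(
    clade_id = clade_id,
    node = nodes,
    clade_height = h[nodes],
    n_genomes = lengths(tip_sets),
    is_singleton = lengths(tip_sets) == 1L
  )
  membership <- tibble(
    clade_id = rep(clade_id, lengths(tip_sets)),
    genome_id = tree$tip.label[unlist(tip_sets)],
    clade_height = rep(h[nodes], lengths(tip_sets)),
    is_singleton = rep(clades$is_singleton, lengths(tip_sets))
  )
  structure(list(membership = membership, clades = clades, depth = depth,
                 tree_height = tree_height),
            class = "clade_partition")
}

#' @export
print.clade_partition <- function(x, ...) {
  cat(sprintf("Clade partition: %d clades (%d singletons) at depth %g; tree height %.4g\n",
              nrow(x$clades), sum(x$clades$is_singleton), x$depth, x$tree_height))
  print(x$clades, ...)
  invisible(x)
}

#' @export
tidy.clade_partition <- function(x, ...) x$membership

#' Write a clade partition as TSV
#'
#' @param partition A `clade_partition`.
#' @param path Output path (columns clade_id, genome_id, clade_height,
#'   is_singleton).
#' @return `partition`, invisibly.
#' @export
write_clades <- function(partition, path) {
  readr::write_tsv(partition$membership, path)
  invisible(partition)
}
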