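random_additive_matrix <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, br = stats::runif(2 * n_taxa - 2, 0.01, 1))
  list(tree = tr, d = stats::cophenetic(tr))
}

test_that("neighbor joining is exact on additive matrices", {
  set.seed(31)
  for (i in 1:30) {
    n <- sample(5:8, 1)
    gen <- random_additive_matrix(n)
    est <- build_tree(gen$d)
    expect_s3_class(est, "phylo")
    expect_equal(phangorn::RF.dist(ape::unroot(est), ape::unroot(gen$tree)), 0)
    expect_lt(max(abs(stats::cophenetic(est)[rownames(gen$d), colnames(gen$d)] -
                        gen$d)), 1e-9)
  }
})

test_that("an all-equal matrix yields equal leaf-to-leaf path lengths", {
  d <- matrix(0.6, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(d) <- 0
  tr <- build_tree(d)
  co <- stats::cophenetic(tr)
  expect_lt(max(abs(co[upper.tri(co)] - 0.6)), 1e-12)
})

test_that("malformed matrices are rejected", {
  d <- matrix(c(0, 1, 2, 0.5, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_error(build_tree(d), "symmetric")
  d2 <- matrix(0.5, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(d2) <- 0
  d2[1, 2] <- d2[2, 1] <- NA
  expect_error(build_tree(d2), "non-finite")
})

test_that("ultrametrization reproduces the worked example exactly", {
  tr <- ape::read.tree(text = "((a:1,b:3):2,c:10);")
  ut <- ultrametrize(tr)
  depths <- ape::node.depth.edgelength(ut)[1:3]
  expect_equal(depths, rep(7, 3))
  # edges: inner node's children a and b at 3.5, inner stem 3.5, c at 7
  lens <- stats::setNames(ut$edge.length, ut$edge[, 2])
  tipno <- stats::setNames(seq_along(ut$tip.label), ut$tip.label)
  expect_equal(unname(lens[as.character(tipno["a"])]), 3.5)
  expect_equal(unname(lens[as.character(tipno["b"])]), 3.5)
  expect_equal(unname(lens[as.character(tipno["c"])]), 7)
  inner <- setdiff(ut$edge[, 2], seq_along(ut$tip.label))
  expect_equal(unname(lens[as.character(inner)]), 3.5)
})

test_that("ultrametrization balances, preserves topology, and is idempotent", {
  set.seed(32)
  for (i in 1:60) {
    n <- sample(4:20, 1)
    tr <- ape::rtree(n, br = stats::runif(2 * n - 2, 0.01, 1))
    ut <- ultrametrize(tr)
    depths <- ape::node.depth.edgelength(ut)[seq_len(n)]
    h <- max(depths)
    expect_lt((max(depths) - min(depths)) / h, 1e-12)
    expect_equal(phangorn::RF.dist(ut, tr), 0)
    again <- ultrametrize(ut)
    expect_equal(again$edge.length, ut$edge.length, tolerance = 1e-12)
  }
})

test_that("a tree that is already ultrametric is returned unchanged", {
  tr <- simulate_tree(8, tree_height = 0.4, seed = 33)
  ut <- ultrametrize(tr)
  expect_equal(ut$edge.length, tr$edge.length, tolerance = 1e-12)
})

test_that("binary root height equals the recursive mean of stem-inclusive child heights", {
  set.seed(34)
  for (i in 1:20) {
    tr <- ape::rtree(6, br = stats::runif(10, 0.05, 1))
    ut <- ultrametrize(tr)
    ntip <- 6L
    root <- ntip + 1L
    kids <- ut$edge[ut$edge[, 1] == root, 2]
    stem <- ut$edge.length[ut$edge[, 1] == root]
    kid_h <- vapply(kids, function(v) subtree_height(ut, v), numeric(1))
    # after balancing both stem-inclusive child heights equal the root height
    expect_equal(stem[1] + kid_h[1], stem[2] + kid_h[2], tolerance = 1e-12)
    # and the root height is the mean of the pre-balancing H_i, which equals
    # the common post-balancing value
    expect_equal(subtree_height(ut, root), stem[1] + kid_h[1], tolerance = 1e-12)
  }
})

test_that("zero-length child subtrees are aligned to the balanced height", {
  tr <- ape::read.tree(text = "((a:0,b:0):0,c:4);")
  ut <- ultrametrize(tr)
  depths <- ape::node.depth.edgelength(ut)[1:3]
  expect_equal(max(depths) - min(depths), 0)
})

test_that("subtree heights report the worked example and leaves are height zero", {
  tr <- ultrametrize(ape::read.tree(text = "((a:1,b:3):2,c:10);"))
  expect_equal(subtree_height(tr, 1), 0)
  expect_equal(subtree_height(tr, 4), 7)    # root
  expect_equal(subtree_height(tr, 5), 3.5)  # (a,b) node
  expect_error(subtree_height(ape::read.tree(text = "((a:1,b:3):2,c:10);"), 4),
               "not ultrametric")
})

test_that("clade cutting returns the whole tree when it is shallow enough", {
  tr <- simulate_tree(6, tree_height = 0.10, seed = 35)
  part <- cut_clades(tr, depth = 0.15)
  expect_equal(nrow(part$clades), 1)
  expect_setequal(part$membership$genome_id, tr$tip.label)
})

test_that("the worked example rescaled to height 0.30 cuts into {a,b} and {c}", {
  tr <- ultrametrize(ape::read.tree(text = "((a:1,b:3):2,c:10);"))
  tr$edge.length <- tr$edge.length * (0.30 / 7)
  part <- cut_clades(tr, depth = 0.15)
  expect_equal(nrow(part$clades), 2)
  sets <- split(part$membership$genome_id, part$membership$clade_id)
  expect_setequal(vapply(sets, function(s) paste(sort(s), collapse = ","), ""),
                  c("a,b", "c"))
  expect_equal(sum(part$clades$is_singleton), 1)
})

test_that("clade partitions satisfy partition, height and maximality properties", {
  set.seed(36)
  for (i in 1:30) {
    n <- sample(5:40, 1)
    tr <- simulate_tree(n, tree_height = 0.45, seed = 1000 + i)
    part <- cut_clades(tr, depth = 0.15)
    # partition: every leaf in exactly one clade
    expect_setequal(part$membership$genome_id, tr$tip.label)
    expect_equal(nrow(part$membership), n)
    # height and maximality
    expect_true(all(part$clades$clade_height <= 0.15 + 1e-12))
    root <- n + 1L
    parent <- rep(NA_integer_, n + tr$Nnode)
    parent[tr$edge[, 2]] <- tr$edge[, 1]
    for (v in part$clades$node) {
      if (v != root) {
        expect_gt(subtree_height(tr, parent[v]), 0.15)
      }
    }
  }
})

test_that("non-ultrametric trees are rejected by cut_clades", {
  tr <- ape::read.tree(text = "((a:1,b:3):2,c:10);")
  expect_error(cut_clades(tr, 0.15), "not ultrametric")
})
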