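# four-clade ultrametric toy tree: clades {a,b}, {c,d}, {e,f}, {g,h} at height
# 0.1, joined well above the 0.15 cut
toy_tree <- function() {
  ape::read.tree(text = paste0(
    "(((a:0.1,b:0.1):0.3,(c:0.1,d:0.1):0.3):0.2,",
    "((e:0.1,f:0.1):0.3,(g:0.1,h:0.1):0.3):0.2);"))
}

toy_calls <- function(df) {
  tibble::tibble(
    genome_id = df$genome, orf_id = paste0(df$genome, "|", seq_len(nrow(df))),
    family = df$family,
    subgroup = if ("subgroup" %in% names(df)) df$subgroup else NA_character_,
    best_ref_id = "r", evalue = 1e-20, bit_score = 100, protein = "M")
}

test_that("clade profiles flag the two heterogeneity types per their definitions", {
  tr <- toy_tree()
  part <- cut_clades(tr, depth = 0.15)
  # clade {a,b}: one PolA each -> homogeneous
  # clade {c,d}: PolA vs PolB singles -> type i
  # clade {e,f}: e carries PolA+PolB, f none -> type ii only
  calls <- toy_calls(data.frame(
    genome = c("a", "b", "c", "d", "e", "e"),
    family = c("PolA", "PolA", "PolA", "PolB", "PolA", "PolB")))
  prof <- profile_clades(part, calls)
  get <- function(g) prof[vapply(prof$clade_id, function(id) {
    g %in% part$membership$genome_id[part$membership$clade_id == id]
  }, TRUE), ]
  ab <- get("a"); cd <- get("c"); ef <- get("e"); gh <- get("g")
  expect_false(ab$het_type_i); expect_false(ab$het_type_ii)
  expect_true(cd$het_type_i); expect_false(cd$het_type_ii)
  expect_false(ef$het_type_i); expect_true(ef$het_type_ii)
  expect_false(gh$het_type_i)
  expect_equal(gh$n_dnap_genomes, 0)
  expect_error(profile_clades(part, toy_calls(data.frame(genome = "zz", family = "PolA"))),
               "outside the partition")
})

test_that("sister grouping stops at DNAP-free sisters and merges DNAP-bearing ones", {
  tr <- toy_tree()
  part <- cut_clades(tr, depth = 0.15)
  # hotspot {c,d}; its sister {a,b} carries DNAPs -> merge to the MRCA of
  # {a,b,c,d}; the next sister {e..h} has no calls -> stop
  calls <- toy_calls(data.frame(
    genome = c("a", "b", "c", "d"),
    family = c("PolA", "PolA", "PolA", "PolB")))
  prof <- profile_clades(part, calls)
  sc <- group_sister_clades(tr, part, prof)
  expect_equal(nrow(sc), 1)
  expect_setequal(sc$genomes[[1]], c("a", "b", "c", "d"))

  # hotspot {c,d} with a DNAP-free sister -> the swap clade is the hotspot alone
  calls2 <- toy_calls(data.frame(genome = c("c", "d"),
                                 family = c("PolA", "PolB")))
  prof2 <- profile_clades(part, calls2)
  sc2 <- group_sister_clades(tr, part, prof2)
  expect_equal(nrow(sc2), 1)
  expect_setequal(sc2$genomes[[1]], c("c", "d"))

  # two sister clades, one all-PolA and one all-PolB: both hotspots? no --
  # neither clade is heterogeneous, so no swap clade is seeded
  calls3 <- toy_calls(data.frame(genome = c("a", "b", "c", "d"),
                                 family = c("PolA", "PolA", "PolB", "PolB")))
  prof3 <- profile_clades(part, calls3)
  expect_equal(nrow(group_sister_clades(tr, part, prof3)), 0)
})

test_that("two hotspots under one grandparent merge into one maximal swap clade", {
  tr <- toy_tree()
  part <- cut_clades(tr, depth = 0.15)
  calls <- toy_calls(data.frame(
    genome = c("a", "b", "c", "d", "e", "f"),
    family = c("PolA", "PolB", "PolA", "PolB", "PolA", "PolA")))
  prof <- profile_clades(part, calls)
  sc <- group_sister_clades(tr, part, prof)
  # hotspots {a,b} and {c,d} both climb to their MRCA, then further to the
  # root because {e,f} carries DNAPs; deduplicated to one maximal clade
  expect_equal(nrow(sc), 1)
  expect_setequal(sc$genomes[[1]], letters[1:8])
  # exhaustive check of the merge rule: every internal node on the climb had a
  # DNAP-bearing sister
  expect_equal(sc$node, length(tr$tip.label) + 1L)
})

test_that("parsimony counting matches trivial cases and handles wildcards", {
  tr <- ape::read.tree(text = "((w:1,x:1):1,(y:1,z:1):1);")
  expect_equal(count_swaps_fitch(tr, c(w = "A", x = "A", y = "A", z = "A")), 0L)
  expect_equal(count_swaps_fitch(tr, c(w = "A", x = "A", y = "A", z = "B")), 1L)
  expect_equal(count_swaps_fitch(tr, c(w = "A", x = "B", y = "B", z = "A")), 2L)
  # wildcards carry the universal set and force nothing
  expect_equal(count_swaps_fitch(tr, c(w = "A", x = NA, y = NA, z = NA)), 0L)
  expect_equal(count_swaps_fitch(tr, c(w = "A", x = NA, y = "B", z = NA)), 1L)
  # ambiguous leaf sets
  expect_equal(count_swaps_fitch(
    tr, list(w = c("A", "B"), x = "B", y = "A", z = "A")), 1L)
  expect_error(count_swaps_fitch(tr, c(w = "A", x = "B", y = "B")), "missing")
})

test_that("parsimony equals the exhaustive minimum on random trees incl. multifurcations", {
  set.seed(51)
  for (i in 1:60) {
    n <- sample(4:9, 1)
    tr <- ape::rtree(n)
    if (i %% 3 == 0) {
      # collapse some internal edges into multifurcations
      tr$edge.length[tr$edge[, 2] > n] <-
        tr$edge.length[tr$edge[, 2] > n] * rbinom(sum(tr$edge[, 2] > n), 1, 0.5)
      tr <- ape::di2multi(tr, tol = 1e-9)
    }
    ns <- sample(2:4, 1)
    states <- LETTERS[seq_len(ns)]
    labels <- sample(states, n, replace = TRUE)
    nw <- sample(0:2, 1)
    if (nw > 0) labels[sample(n, min(nw, n - 1))] <- NA
    ls <- stats::setNames(labels, tr$tip.label)
    expect_equal(count_swaps_fitch(tr, ls), brute_force_parsimony(tr, ls))
  }
})

test_that("parsimony is invariant under state relabeling and child reordering", {
  set.seed(52)
  for (i in 1:20) {
    tr <- ape::rtree(7)
    ls <- stats::setNames(sample(c("A", "B", "C"), 7, replace = TRUE),
                          tr$tip.label)
    base <- count_swaps_fitch(tr, ls)
    relab <- c(A = "Z", B = "Q", C = "A")[ls]
    names(relab) <- names(ls)
    expect_equal(count_swaps_fitch(tr, relab), base)
    rot <- ape::rotateConstr(tr, sample(tr$tip.label))
    expect_equal(count_swaps_fitch(rot, ls), base)
  }
})

test_that("swap reports count planted events and respect state refinement", {
  # negative control: no planted swaps
  ds0 <- small_sim(seed = 53, n_leaves = 12, n_genes = 8)
  res0 <- analyze_genomes(ds0$genomes, ds0$refdb, truth = ds0$truth)
  s0 <- glance(res0$report)
  expect_equal(s0$n_hotspots_type_i, 0)
  expect_equal(s0$total_min_swaps_family, 0)
  expect_equal(s0$total_min_swaps_subgroup, 0)

  # one inter-family and one intra-family event planted on distinct leaves
  cfg <- sim_config(n_leaves = 12, n_genes = 8, seed = 54)
  ds <- simulate_dataset(cfg)
  ev <- choose_swap_branches(ds$tree, n_swaps = 2, n_families = 3)
  ev$family <- c(2L, 1L)       # PolB inter-family; PolA subgroup 2 intra-family
  ev$subgroup <- c(1L, 2L)
  ds <- simulate_dataset(sim_config(n_leaves = 12, n_genes = 8, seed = 54,
                                    swap_events = ev))
  res <- analyze_genomes(ds$genomes, ds$refdb, truth = ds$truth)
  s <- glance(res$report)
  # family-level parsimony sees only the inter-family event; subgroup-level
  # parsimony sees both
  expect_equal(s$total_min_swaps_family, 1)
  expect_equal(s$total_min_swaps_subgroup, 2)
  expect_gte(s$total_min_swaps_subgroup, s$total_min_swaps_family)
  # report bookkeeping is conserved
  prof <- res$report$clade_profiles
  multi <- prof[!prof$is_singleton, ]
  expect_equal(sum(multi$het_type_i) + sum(!multi$het_type_i & multi$n_dnap_genomes > 0) +
                 sum(multi$n_dnap_genomes == 0), nrow(multi))
})

test_that("subgroup-level parsimony is never below family-level parsimony", {
  set.seed(55)
  for (seed in c(61, 62, 63)) {
    ds <- small_sim(seed = seed, n_leaves = 10, n_genes = 6, n_swaps = 2)
    res <- analyze_genomes(ds$genomes, ds$refdb)
    s <- glance(res$report)
    expect_gte(s$total_min_swaps_subgroup, s$total_min_swaps_family)
    if (nrow(res$report$swap_clades) > 0) {
      expect_true(all(res$report$swap_clades$min_swaps_subgroup >=
                        res$report$swap_clades$min_swaps_family))
    }
  }
})
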