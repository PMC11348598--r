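make_orfs <- function(genome_id, proteins, gene_len = NULL) {
  n <- length(proteins)
  len <- if (is.null(gene_len)) (nchar(proteins) + 1) * 3 else gene_len
  start <- cumsum(c(0, head(len + 50, -1)))
  tibble::tibble(
    genome_id = genome_id,
    start = as.integer(start), end = as.integer(start + len),
    strand = "+", frame = 0L, nt_len = as.integer(len),
    protein = proteins,
    orf_id = paste(genome_id, start, start + len, "+", sep = "|")
  )
}

test_that("identical single-gene proteomes form one reciprocal best hit", {
  set.seed(21)
  p <- random_protein(120)
  a <- make_orfs("gA", p)
  b <- make_orfs("gB", p)
  rbh <- reciprocal_best_hits(a, b)
  expect_equal(nrow(rbh), 1)
  expect_equal(rbh$orf_a, a$orf_id)
  expect_equal(rbh$orf_b, b$orf_id)
})

test_that("hits failing the thresholds produce no pairs; empty proteomes warn", {
  set.seed(22)
  a <- make_orfs("gA", random_protein(100))
  b <- make_orfs("gB", random_protein(100))
  expect_equal(nrow(reciprocal_best_hits(a, b, seed_filter = FALSE)), 0)
  expect_warning(out <- reciprocal_best_hits(a[0, ], b), "empty proteome")
  expect_equal(nrow(out), 0)
})

test_that("RBH recovers planted orthology against an exhaustive all-vs-all oracle", {
  set.seed(23)
  # ten orthologous genes at high identity plus one shuffled decoy per side
  base <- replicate(10, random_protein(100))
  mutate_p <- function(p, k) {
    v <- strsplit(p, "")[[1]]
    i <- sample(length(v), k)
    v[i] <- sample(AA20, k, replace = TRUE)
    paste(v, collapse = "")
  }
  pa <- vapply(base, mutate_p, "", k = 5)
  pb <- vapply(base, mutate_p, "", k = 5)
  decoy_a <- paste(sample(strsplit(base[1], "")[[1]]), collapse = "")
  decoy_b <- paste(sample(strsplit(base[2], "")[[1]]), collapse = "")
  a <- make_orfs("gA", c(pa, decoy_a))
  b <- make_orfs("gB", c(pb, decoy_b))
  rbh <- reciprocal_best_hits(a, b, seed_filter = FALSE)
  planted <- paste(a$orf_id[1:10], b$orf_id[1:10])
  expect_setequal(paste(rbh$orf_a, rbh$orf_b), planted)

  # exhaustive oracle: align every pair with align_pair, apply the qualifying
  # and mutual-best rules independently
  n_a <- sum(nchar(a$protein)); n_b <- sum(nchar(b$protein))
  best <- function(orfs_q, orfs_s, n_db) {
    vapply(seq_len(nrow(orfs_q)), function(i) {
      hits <- lapply(seq_len(nrow(orfs_s)), function(j) {
        h <- align_pair(orfs_q$protein[i], orfs_s$protein[j], subject_db_size = n_db)
        cbind(j = j, h)
      })
      hits <- do.call(rbind, hits)
      hits <- hits[hits$evalue <= 1e-3 & hits$query_cover >= 0.5, , drop = FALSE]
      if (nrow(hits) == 0) return(NA_integer_)
      hits <- hits[order(-hits$raw_score, -hits$aln_len, orfs_s$orf_id[hits$j]), ]
      hits$j[1]
    }, integer(1))
  }
  fwd <- best(a, b, n_b)
  rev <- best(b, a, n_a)
  mutual <- which(!is.na(fwd) & rev[fwd] == seq_len(nrow(a)))
  expect_setequal(paste(a$orf_id[mutual], b$orf_id[fwd[mutual]]),
                  paste(rbh$orf_a, rbh$orf_b))
})

test_that("coverage term is the union of RBH ORF intervals", {
  genome <- c(gA = strrep("A", 1000))
  orfs <- tibble::tibble(
    genome_id = "gA", start = c(0L, 150L), end = c(300L, 450L),
    strand = "+", frame = 0L, nt_len = c(300L, 300L),
    protein = c("M", "M"),
    orf_id = c("gA|0|300|+", "gA|150|450|+"))
  rbh_none <- tibble::tibble(genome_a = character(), orf_a = character(),
                             genome_b = character(), orf_b = character())
  expect_equal(coverage_term(genome, orfs, rbh_none), 0L)
  rbh <- tibble::tibble(genome_a = "gA", orf_a = orfs$orf_id,
                        genome_b = "gB", orf_b = c("x", "y"))
  expect_equal(coverage_term(genome, orfs, rbh), 450L)
})

test_that("interval union matches a per-position boolean-marking oracle", {
  set.seed(24)
  for (i in 1:50) {
    n <- sample(1:12, 1)
    start <- sample(0:200, n, replace = TRUE)
    end <- start + sample(1:80, n, replace = TRUE)
    mask <- logical(300)
    for (k in seq_len(n)) mask[(start[k] + 1):end[k]] <- TRUE
    expect_equal(polswap:::interval_union_length(start, end), sum(mask))
  }
})

test_that("the distance formula evaluates, clamps and validates", {
  expect_equal(genome_distance(600, 500, 1000, 1000), 0.45)
  expect_equal(genome_distance(1000, 900, 1000, 900), 0)
  expect_equal(genome_distance(0, 0, 1000, 900), 1)
  expect_error(genome_distance(1001, 0, 1000, 1000), "coverage")
  expect_error(genome_distance(1, 1, 0, 10), "positive")
})

test_that("identical genomes give D = 1 - ORF-covered fraction; matrix is symmetric in [0,1]", {
  set.seed(25)
  ds <- small_sim(seed = 25, n_leaves = 4, n_genes = 6)
  g <- ds$genomes$seq[1]
  genomes <- as_genome_tbl(c(c1 = g, c2 = g, c3 = g))
  orfs <- find_orfs(genomes)
  d <- distance_matrix(genomes, orfs = orfs)
  one <- orfs[orfs$genome_id == "c1", ]
  covered <- polswap:::interval_union_length(one$start, one$end)
  expected <- 1 - covered / nchar(g)
  off <- d[upper.tri(d)]
  expect_true(all(abs(off - expected) < 1e-12))
  expect_equal(unclass(d), t(unclass(d)))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("genomes with no cross-hits are at distance 1", {
  set.seed(26)
  # three unrelated random genomes: any ORFs they carry share no homology
  genomes <- as_genome_tbl(stats::setNames(
    replicate(3, random_dna(2000)), c("r1", "r2", "r3")))
  d <- distance_matrix(genomes)
  expect_true(all(d[upper.tri(d)] > 0.95))
})

test_that("distance increases with simulated divergence time", {
  # small matrices are noisy, so the monotone trend is averaged over seeds
  cors <- vapply(c(27, 28, 29), function(seed) {
    ds <- small_sim(seed = seed, n_leaves = 6, n_genes = 10, tree_height = 0.5)
    d <- distance_matrix(ds$genomes)
    true_div <- ds$truth$expected_divergence[rownames(d), colnames(d)]
    stats::cor(d[upper.tri(d)], true_div[upper.tri(true_div)],
               method = "spearman")
  }, numeric(1))
  expect_gt(mean(cors), 0.7)
  expect_true(all(cors > 0.3))
})

test_that("removing a non-RBH ORF leaves D unchanged; removing an RBH ORF never decreases it", {
  ds <- small_sim(seed = 28, n_leaves = 4, n_genes = 6)
  genomes <- ds$genomes[1:2, ]
  orfs <- find_orfs(genomes)
  oa <- orfs[orfs$genome_id == genomes$genome_id[1], ]
  ob <- orfs[orfs$genome_id == genomes$genome_id[2], ]
  rbh <- reciprocal_best_hits(oa, ob)
  expect_gt(nrow(rbh), 0)
  d0 <- genome_distance(coverage_term(genomes[1, ], oa, rbh),
                        coverage_term(genomes[2, ], ob, rbh),
                        genomes$length[1], genomes$length[2])
  non_rbh <- setdiff(oa$orf_id, rbh$orf_a)
  if (length(non_rbh) > 0) {
    oa2 <- oa[oa$orf_id != non_rbh[1], ]
    rbh2 <- reciprocal_best_hits(oa2, ob)
    d2 <- genome_distance(coverage_term(genomes[1, ], oa2, rbh2),
                          coverage_term(genomes[2, ], ob, rbh2),
                          genomes$length[1], genomes$length[2])
    expect_equal(d2, d0)
  }
  hit <- rbh$orf_a[1]
  oa3 <- oa[oa$orf_id != hit, ]
  rbh3 <- reciprocal_best_hits(oa3, ob)
  d3 <- genome_distance(coverage_term(genomes[1, ], oa3, rbh3),
                        coverage_term(genomes[2, ], ob, rbh3),
                        genomes$length[1], genomes$length[2])
  expect_gte(d3, d0)
})
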