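#' Reciprocal best hits between two ORF complements
#'
#' Every ORF protein of genome A is compared with every ORF protein of genome
#' B by local alignment (see [align_pair()]). A hit qualifies if its e-value
#' is at most `evalue_max` and the alignment covers at least `min_cover` of
#' the query. Each ORF's best qualifying hit is the one with the highest bit
#' score, ties broken by longer alignment, then by lexicographically smaller
#' subject `orf_id`. The returned pairs are exactly the mutual best hits.
#'
#' @param orfs_a,orfs_b ORF tibbles ([find_orfs()]) of two distinct genomes.
#' @param evalue_max Qualifying-hit e-value ceiling (the subject search space
#'   for the e-value is the partner genome's whole ORF complement).
#' @param min_cover Minimum fraction of the query covered by the alignment.
#' @param seed_filter If `TRUE`, skip Smith-Waterman for protein pairs that
#'   share no exact `word_size`-mer (BLAST-like word seeding; pairs skipped
#'   this way are treated as having no hit).
#' @param word_size Word length for the seed filter.
#' @return Tibble of RBH pairs: `genome_a`, `orf_a`, `genome_b`, `orf_b`,
#'   `raw_score`, `bit_score`, `query_cover_a`, `query_cover_b`. Empty (with a
#'   warning) if either proteome is empty.
#' @export
reciprocal_best_hits <- function(orfs_a, orfs_b, evalue_max = 1e-3,
                                 min_cover = 0.5, seed_filter = TRUE,
                                 word_size = 4L) {
  empty <- tibble(genome_a = character(), orf_a = character(),
                  genome_b = character(), orf_b = character(),
                  raw_score = integer(), bit_score = double(),
                  query_cover_a = double(), query_cover_b = double())
  if (nrow(orfs_a) == 0 || nrow(orfs_b) == 0) {
    warning("empty proteome; no reciprocal best hits", call. = FALSE)
    return(empty)
  }
  ga <- orfs_a$genome_id[1]
  gb <- orfs_b$genome_id[1]
  if (ga == gb) stop("proteomes must come from two distinct genomes", call. = FALSE)

  len_a <- nchar(orfs_a$protein)
  len_b <- nchar(orfs_b$protein)
  n_res_a <- sum(len_a)
  n_res_b <- sum(len_b)
  min_raw <- min(min_qualifying_raw(evalue_max, min(len_a), n_res_b),
                 min_qualifying_raw(evalue_max, min(len_b), n_res_a))
  hits <- sw_batch(orfs_a$protein, orfs_b$protein,
                   seed_filter = seed_filter, word_size = word_size,
                   min_score = min_raw)
  if (nrow(hits) == 0) return(empty)

  hits$bit_score <- bit_score_from_raw(hits$raw_score)
  hits$cover_a <- (hits$q_end - hits$q_start + 1) / len_a[hits$q_idx]
  hits$cover_b <- (hits$s_end - hits$s_start + 1) / len_b[hits$s_idx]
  hits$evalue_ab <- evalue_from_bit(hits$bit_score, len_a[hits$q_idx], n_res_b)
  hits$evalue_ba <- evalue_from_bit(hits$bit_score, len_b[hits$s_idx], n_res_a)
  hits$orf_a <- orfs_a$orf_id[hits$q_idx]
  hits$orf_b <- orfs_b$orf_id[hits$s_idx]

  # best qualifying hit of each A-ORF in B (query = A side)
  best_ab <- hits %>%
    dplyr::filter(.data$evalue_ab <= evalue_max, .data$cover_a >= min_cover) %>%
    dplyr::arrange(.data$q_idx, dplyr::desc(.data$bit_score),
                   dplyr::desc(.data$aln_len), .data$orf_b) %>%
    dplyr::distinct(.data$q_idx, .keep_all = TRUE)
  # best qualifying hit of each B-ORF in A (query = B side)
  best_ba <- hits %>%
    dplyr::filter(.data$evalue_ba <= evalue_max, .data$cover_b >= min_cover) %>%
    dplyr::arrange(.data$s_idx, dplyr::desc(.data$bit_score),
                   dplyr::desc(.data$aln_len), .data$orf_a) %>%
    dplyr::distinct(.data$s_idx, .keep_all = TRUE)

  rbh <- dplyr::inner_join(
    best_ab[, c("q_idx", "s_idx", "raw_score", "bit_score", "cover_a", "cover_b")],
    best_ba[, c("q_idx", "s_idx")],
    by = c("q_idx", "s_idx"))
  if (nrow(rbh) == 0) return(empty)
  tibble(
    genome_a = ga,
    orf_a = orfs_a$orf_id[rbh$q_idx],
    genome_b = gb,
    orf_b = orfs_b$orf_id[rbh$s_idx],
    raw_score = rbh$raw_score,
    bit_score = rbh$bit_score,
    query_cover_a = rbh$cover_a,
    query_cover_b = rbh$cover_b
  )
}

#' Nucleotide coverage of a genome by its RBH ORFs
#'
#' The coverage term C is the total length of the genome covered by ORFs that
#' participate in a reciprocal best hit with the partner genome: the size of
#' the union of the `[start, end)` intervals of those ORFs (overlaps counted
#' once, both strands projected onto the single genome axis).
#'
#' @param genome One-row genome tibble (or anything [as_genome_tbl()] takes).
#' @param orfs The genome's ORF tibble.
#' @param rbh RBH pair tibble from [reciprocal_best_hits()]; ORFs of this
#'   genome are looked up in `orf_a` and `orf_b`.
#' @return Covered length in nucleotides (integer).
#' @export
coverage_term <- function(genome, orfs, rbh) {
  genome <- as_genome_tbl(genome)
  stopifnot(nrow(genome) == 1)
  if (nrow(orfs) > 0 && !all(orfs$genome_id == genome$genome_id)) {
    stop("ORFs do not belong to the given genome", call. = FALSE)
  }
  ids <- unique(c(rbh$orf_a[rbh$genome_a == genome$genome_id],
                  rbh$orf_b[rbh$genome_b == genome$genome_id]))
  hit <- orfs[orfs$orf_id %in% ids, , drop = FALSE]
  interval_union_length(hit$start, hit$end)
}

# total length of the union of 0-based half-open intervals
interval_union_length <- function(start, end) {
  if (length(start) == 0) return(0L)
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  tot <- 0L
  cur_s <- start[1]; cur_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= cur_e) {
      if (end[i] > cur_e) cur_e <- end[i]
    } else {
      tot <- tot + (cur_e - cur_s)
      cur_s <- start[i]; cur_e <- end[i]
    }
  }
  as.integer(tot + (cur_e - cur_s))
}

#' RBH-coverage distance between two genomes
#'
#' `D = 1 - (C_ab + C_ba) / (L_a + L_b)`, clamped to `[0, 1]`, where `C_ab` is
#' the length of genome A covered by ORFs with reciprocal best hits in genome
#' B (and vice versa) and `L` are the genome lengths.
#'
#' @param c_ab,c_ba Coverage terms in nucleotides.
#' @param l_a,l_b Genome lengths in nucleotides (positive).
#' @return The distance, a number in `[0, 1]`.
#' @export
genome_distance <- function(c_ab, c_ba, l_a, l_b) {
  if (l_a <= 0 || l_b <= 0) stop("genome lengths must be positive", call. = FALSE)
  if (c_ab < 0 || c_ba < 0 || c_ab > l_a || c_ba > l_b) {
    stop("coverage term outside [0, genome length]", call. = FALSE)
  }
  d <- 1 - (c_ab + c_ba) / (l_a + l_b)
  min(max(d, 0), 1)
}

#' Pairwise RBH-coverage distance matrix for a genome set
#'
#' Runs [find_orfs()], [reciprocal_best_hits()], [coverage_term()] and
#' [genome_distance()] for every unordered genome pair. The diagonal is 0 by
#' convention (a genome's self-distance under the formula would equal its
#' intergenic fraction and distort tree building).
#'
#' @param genomes Genomes in any representation accepted by [as_genome_tbl()]
#'   (at least 3, unique ids).
#' @param orfs Optional precomputed ORF tibble for all genomes (saves
#'   recomputation in a pipeline); computed with `min_orf_len` if `NULL`.
#' @param min_orf_len Minimum ORF length passed to [find_orfs()].
#' @param evalue_max,min_cover,seed_filter,word_size Passed to
#'   [reciprocal_best_hits()].
#' @param keep_rbh If `TRUE`, attach all RBH pair tables as attribute `"rbh"`.
#' @param verbose Emit one message per pair with C_ab, C_ba and D.
#' @return A symmetric numeric matrix of class `polswap_dist` with genome ids
#'   as dimnames and zero diagonal.
#' @export
distance_matrix <- function(genomes, orfs = NULL, min_orf_len = 75,
                            evalue_max = 1e-3, min_cover = 0.5,
                            seed_filter = TRUE, word_size = 4L,
                            keep_rbh = FALSE, verbose = FALSE) {
  genomes <- as_genome_tbl(genomes)
  if (nrow(genomes) < 3) stop("need at least 3 genomes", call. = FALSE)
  if (is.null(orfs)) orfs <- find_orfs(genomes, min_len = min_orf_len)
  orfs_by <- split(orfs, factor(orfs$genome_id, levels = genomes$genome_id))
  n <- nrow(genomes)
  ids <- genomes$genome_id
  L <- stats::setNames(genomes$length, ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  rbh_all <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      rbh <- suppressWarnings(reciprocal_best_hits(
        orfs_by[[i]], orfs_by[[j]], evalue_max = evalue_max,
        min_cover = min_cover, seed_filter = seed_filter,
        word_size = word_size))
      c_ab <- coverage_term(genomes[i, ], orfs_by[[i]], rbh)
      c_ba <- coverage_term(genomes[j, ], orfs_by[[j]], rbh)
      d <- genome_distance(c_ab, c_ba, L[[i]], L[[j]])
      D[i, j] <- D[j, i] <- d
      if (verbose) {
        message(sprintf("[distance] %s vs %s: C_ab=%d C_ba=%d D=%.4f",
                        ids[i], ids[j], c_ab, c_ba, d))
      }
      if (keep_rbh) rbh_all[[paste(ids[i], ids[j], sep = "|")]] <- rbh
    }
  }
  class(D) <- c("polswap_dist", class(D))
  if (keep_rbh) attr(D, "rbh") <- dplyr::bind_rows(rbh_all)
  D
}

#' @export
tidy.polswap_dist <- function(x, ...) {
  ids <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble(genome_a = ids[idx[, 1]], genome_b = ids[idx[, 2]],
         distance = x[idx])
}

#' Write a distance matrix as square TSV and/or PHYLIP
#'
#' @param d A `polswap_dist` matrix.
#' @param tsv_path,phylip_path Output paths; either may be `NULL`.
#' @return `d`, invisibly.
#' @export
write_distance_matrix <- function(d, tsv_path = NULL, phylip_path = NULL) {
  if (!is.null(tsv_path)) {
    df <- as.data.frame(unclass(d))
    df <- cbind(genome_id = rownames(d), df)
    readr::write_tsv(as_tibble(df), tsv_path)
  }
  if (!is.null(phylip_path)) {
    con <- file(phylip_path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(d)), con)
    for (i in seq_len(nrow(d))) {
      writeLines(paste(c(formatC(rownames(d)[i], width = -10),
                         sprintf("%.6f", d[i, ])), collapse = " "), con)
    }
  }
  invisible(d)
}
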