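# Karlin-Altschul constants used to turn raw Smith-Waterman scores into bit
# scores and e-values. Fixed (ungapped-style approximation): e-values are used
# only as thresholds, not reported as calibrated significance.
KA_LAMBDA <- 0.267
KA_K <- 0.041
DEFAULT_GAP_OPEN <- 11L
DEFAULT_GAP_EXT <- 1L

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

bit_score_from_raw <- function(raw) {
  (KA_LAMBDA * raw - log(KA_K)) / log(2)
}

evalue_from_bit <- function(bit, m, n) {
  m * n * 2^(-bit)
}

#' Align two protein sequences locally
#'
#' Smith-Waterman local alignment under BLOSUM62 with affine gap costs (a gap
#' of length k costs `gap_open + k * gap_ext`). The raw score is converted to
#' a bit score with fixed Karlin-Altschul constants (lambda = 0.267,
#' K = 0.041), and the e-value is `m * n * 2^-bit` where `m` is the query
#' length and `n` the total residue count of the subject search space.
#'
#' @param query,subject Amino-acid strings (non-empty).
#' @param gap_open,gap_ext Affine gap costs.
#' @param subject_db_size Total residues in the subject search space; defaults
#'   to `nchar(subject)` when the subject is searched alone.
#' @return A one-row tibble: `raw_score`, `bit_score`, `evalue`, `query_cover`
#'   (aligned query span / query length), plus the aligned spans (1-based,
#'   inclusive) `q_start`, `q_end`, `s_start`, `s_end` and `aln_len`
#'   (alignment columns).
#' @export
align_pair <- function(query, subject, gap_open = DEFAULT_GAP_OPEN,
                       gap_ext = DEFAULT_GAP_EXT, subject_db_size = NULL) {
  if (!nzchar(query) || !nzchar(subject)) {
    stop("align_pair requires non-empty sequences", call. = FALSE)
  }
  S <- blosum62()
  r <- .sw_pair_cpp(query, subject, S, colnames(S), gap_open, gap_ext)
  m <- nchar(query)
  n <- if (is.null(subject_db_size)) nchar(subject) else subject_db_size
  bit <- bit_score_from_raw(r$raw_score)
  tibble(
    raw_score = r$raw_score,
    bit_score = bit,
    evalue = evalue_from_bit(bit, m, n),
    query_cover = if (r$raw_score > 0) (r$q_end - r$q_start + 1) / m else 0,
    q_start = r$q_start, q_end = r$q_end,
    s_start = r$s_start, s_end = r$s_end,
    aln_len = r$aln_len
  )
}

# all-vs-all local alignments between two protein vectors; returns a tibble
# with one row per pair with positive score (pairs suppressed by the word
# prefilter yield no row)
sw_batch <- function(qseqs, sseqs, gap_open = DEFAULT_GAP_OPEN,
                     gap_ext = DEFAULT_GAP_EXT, seed_filter = FALSE,
                     word_size = 4L, min_score = 0L) {
  S <- blosum62()
  as_tibble(.sw_batch_cpp(qseqs, sseqs, S, colnames(S),
                          gap_open, gap_ext, seed_filter, word_size,
                          as.integer(min_score)))
}

# smallest raw score at which a hit could still reach `evalue_max` in either
# search direction; used to prune the all-vs-all batch without changing which
# qualifying hits are reported
min_qualifying_raw <- function(evalue_max, min_m, n_other) {
  bit_required <- log2(min_m * n_other / evalue_max)
  raw <- (bit_required * log(2) + log(KA_K)) / KA_LAMBDA
  max(0L, as.integer(floor(raw)))  # floor: never prunes a qualifying hit
}
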