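STOP_CODONS <- c("TAA", "TAG", "TGA")
DEFAULT_START_CODONS <- c("ATG", "GTG", "TTG")

#' Find open reading frames in phage genomes
#'
#' Scans all six reading frames (three per strand) of each genome. Within each
#' frame, for every stop-to-stop segment, the single longest ORF is emitted:
#' from the first start codon after the previous stop (or the frame start)
#' through the next stop codon, inclusive. A trailing ORF that reaches the end
#' of the sequence without a stop codon is also emitted (phage genome records
#' are often permuted mid-gene). ORFs in different frames may overlap; the
#' genome is treated as linear. Codons containing N never match a start or a
#' stop codon.
#'
#' @param genomes Genomes in any representation accepted by [as_genome_tbl()].
#' @param min_len Minimum ORF length in nucleotides, counted including the
#'   stop codon when present. Must be >= 6 and divisible by 3. Default 75.
#' @param start_codons Character vector of permitted initiation codons
#'   (prokaryotic set, genetic code 11).
#' @return A tibble with one row per ORF: `genome_id`, `start`, `end` (0-based
#'   half-open), `strand` (`"+"`/`"-"`), `frame` (0..2 on its own strand),
#'   `nt_len`, `protein` (translated, initiator rendered M, terminal stop
#'   omitted, N-containing codons rendered X), `orf_id`
#'   (`genome_id|start|end|strand`). Sorted by (start, end, strand) within
#'   each genome.
#' @export
find_orfs <- function(genomes, min_len = 75, start_codons = DEFAULT_START_CODONS) {
  genomes <- as_genome_tbl(genomes)
  if (min_len < 6 || min_len %% 3 != 0) {
    stop("min_len must be >= 6 and divisible by 3", call. = FALSE)
  }
  start_codons <- toupper(start_codons)
  out <- purrr::map2(genomes$genome_id, genomes$seq, function(id, seq) {
    find_orfs_one(id, seq, min_len, start_codons)
  })
  dplyr::bind_rows(out)
}

find_orfs_one <- function(genome_id, seq, min_len, start_codons) {
  L <- nchar(seq)
  if (L == 0) stop("genome '", genome_id, "' has an empty sequence", call. = FALSE)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else reverse_complement(seq)
    for (frame in 0:2) {
      if (L - frame < min_len) next
      segs <- frame_orfs(s, frame, min_len, start_codons)
      if (is.null(segs) || nrow(segs) == 0) next
      # 0-based half-open coordinates on strand s, then map to genome axis
      if (strand == "+") {
        segs$gstart <- segs$start0
        segs$gend <- segs$end0
      } else {
        segs$gstart <- L - segs$end0
        segs$gend <- L - segs$start0
      }
      segs$strand <- strand
      segs$frame <- frame
      segs$genome_id <- genome_id
      rows[[length(rows) + 1L]] <- segs
    }
  }
  if (length(rows) == 0) {
    return(tibble(genome_id = character(), start = integer(), end = integer(),
                  strand = character(), frame = integer(), nt_len = integer(),
                  protein = character(), orf_id = character()))
  }
  res <- dplyr::bind_rows(rows)
  res <- tibble(
    genome_id = res$genome_id,
    start = as.integer(res$gstart),
    end = as.integer(res$gend),
    strand = res$strand,
    frame = as.integer(res$frame),
    nt_len = as.integer(res$end0 - res$start0),
    protein = res$protein
  )
  res$orf_id <- paste(res$genome_id, res$start, res$end, res$strand, sep = "|")
  dplyr::arrange(res, .data$start, .data$end, .data$strand)
}

# ORFs of one frame on one strand; returns 0-based half-open coords on that
# strand plus the translated protein
frame_orfs <- function(s, frame, min_len, start_codons) {
  L <- nchar(s)
  cstart <- seq.int(frame + 1L, L - 2L, by = 3L)
  if (length(cstart) == 0) return(NULL)
  codons <- substring(s, cstart, cstart + 2L)
  is_stop <- codons %in% STOP_CODONS
  is_start <- codons %in% start_codons
  n <- length(codons)
  # segment index: codons after the k-th stop belong to segment k+1
  seg <- cumsum(c(FALSE, is_stop[-n]))
  out <- vector("list", 16L)
  nout <- 0L
  for (sg in split(seq_len(n), seg)) {
    last <- sg[length(sg)]
    has_stop <- is_stop[last]
    starts_in <- sg[is_start[sg]]
    if (has_stop) starts_in <- starts_in[starts_in < last]
    if (length(starts_in) == 0) next
    first <- starts_in[1]
    ncod <- last - first + 1L
    nt_len <- 3L * ncod
    if (nt_len < min_len) next
    start0 <- cstart[first] - 1L
    end0 <- start0 + nt_len
    cds <- substr(s, start0 + 1L, end0)
    nout <- nout + 1L
    out[[nout]] <- list(start0 = start0, end0 = end0,
                        protein = translate_cds(cds, initiator_m = TRUE))
  }
  if (nout == 0L) return(NULL)
  dplyr::bind_rows(out[seq_len(nout)])
}

#' Translate a coding sequence under genetic code 11
#'
#' @param cds Nucleotide string whose length is a multiple of 3.
#' @param initiator_m Render the first codon as M regardless of identity
#'   (prokaryotic initiation).
#' @return Amino-acid string. A terminal stop codon is omitted; internal stops
#'   translate to `*`; codons containing N translate to `X`.
#' @export
translate_cds <- function(cds, initiator_m = TRUE) {
  n <- nchar(cds)
  if (n %% 3 != 0) stop("coding sequence length not divisible by 3", call. = FALSE)
  if (n == 0) return("")
  code <- genetic_code_11()
  codons <- substring(toupper(cds), seq.int(1L, n - 2L, by = 3L),
                      seq.int(3L, n, by = 3L))
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  if (initiator_m) aa[1] <- "M"
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

genetic_code_11 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- Biostrings::getGeneticCode("11")
    cache
  }
})

#' Translate ORF records against their genomes
#'
#' Re-extracts each ORF's coding sequence from its genome using the recorded
#' coordinates and strand, and translates it under genetic code 11 (initiator
#' forced to M, terminal stop omitted, N codons rendered X).
#'
#' @param orfs An ORF tibble as produced by [find_orfs()] (columns
#'   `genome_id`, `start`, `end`, `strand` are used).
#' @param genomes The corresponding genomes.
#' @return Character vector of proteins, one per ORF row.
#' @export
translate_orf <- function(orfs, genomes) {
  genomes <- as_genome_tbl(genomes)
  gseq <- stats::setNames(genomes$seq, genomes$genome_id)
  glen <- stats::setNames(genomes$length, genomes$genome_id)
  purrr::pmap_chr(orfs[, c("genome_id", "start", "end", "strand")],
    function(genome_id, start, end, strand) {
      if (!genome_id %in% names(gseq)) {
        stop("ORF references unknown genome '", genome_id, "'", call. = FALSE)
      }
      if (start < 0 || end > glen[[genome_id]] || start >= end) {
        stop("ORF coordinates out of range for genome '", genome_id, "'",
             call. = FALSE)
      }
      cds <- substr(gseq[[genome_id]], start + 1L, end)
      if (strand == "-") cds <- reverse_complement(cds)
      translate_cds(cds)
    })
}

#' Write ORF proteins to FASTA and the ORF table to TSV
#'
#' @param orfs An ORF tibble from [find_orfs()].
#' @param proteins_path,table_path Output paths; either may be `NULL` to skip.
#'   The table is BED-like: genome_id, start, end, orf_id, nt_len, strand
#'   (0-based half-open coordinates).
#' @return `orfs`, invisibly.
#' @export
write_orfs <- function(orfs, proteins_path = NULL, table_path = NULL) {
  if (!is.null(proteins_path)) {
    x <- Biostrings::AAStringSet(stats::setNames(orfs$protein, orfs$orf_id))
    Biostrings::writeXStringSet(x, proteins_path)
  }
  if (!is.null(table_path)) {
    readr::write_tsv(
      orfs[, c("genome_id", "start", "end", "orf_id", "nt_len", "strand")],
      table_path)
  }
  invisible(orfs)
}
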