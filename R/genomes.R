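#' Coerce genome sequences to the standard genome table
#'
#' Genomes move through the pipeline as a tibble with one row per genome and
#' columns `genome_id` and `seq` (uppercase nucleotide string over A, C, G, T,
#' N). Accepts a tibble/data.frame with those columns, a named character
#' vector, or a [Biostrings::DNAStringSet].
#'
#' @param x Genomes in any accepted representation.
#' @return A tibble with columns `genome_id`, `seq`, `length`.
#' @export
as_genome_tbl <- function(x) {
  if (inherits(x, "DNAStringSet")) {
    x <- stats::setNames(as.character(x), names(x))
  }
  if (is.character(x)) {
    if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == "")) {
      stop("genome sequences must be named", call. = FALSE)
    }
    x <- tibble(genome_id = names(x), seq = unname(x))
  }
  if (!is.data.frame(x) || !all(c("genome_id", "seq") %in% names(x))) {
    stop("genomes must have columns 'genome_id' and 'seq'", call. = FALSE)
  }
  out <- as_tibble(x)[, c("genome_id", "seq")]
  out$seq <- toupper(out$seq)
  if (anyDuplicated(out$genome_id)) {
    stop("duplicate genome ids: ",
         paste(unique(out$genome_id[duplicated(out$genome_id)]), collapse = ", "),
         call. = FALSE)
  }
  validate_nucleotides(out)
  out$length <- nchar(out$seq)
  out
}

validate_nucleotides <- function(genomes) {
  bad <- regexpr("[^ACGTN]", genomes$seq)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("genome '%s' has a non-ACGTN character at position %d ('%s')",
                 genomes$genome_id[i], bad[i],
                 substr(genomes$seq[i], bad[i], bad[i])),
         call. = FALSE)
  }
  invisible(genomes)
}

#' Read genomes from a nucleotide FASTA file
#'
#' @param path Path to a (multi-record) nucleotide FASTA file.
#' @return A genome tibble (see [as_genome_tbl()]).
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path, call. = FALSE)
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  as_genome_tbl(x)
}

#' Write genomes to a nucleotide FASTA file
#'
#' @param genomes A genome tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genomes, path) {
  genomes <- as_genome_tbl(genomes)
  x <- Biostrings::DNAStringSet(stats::setNames(genomes$seq, genomes$genome_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}
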