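#' Read a labeled DNAP reference protein FASTA
#'
#' The family label is the last `|`-separated token of each header (e.g.
#' `>refX|PolA`).
#'
#' @param path Protein FASTA path.
#' @return A reference tibble: `ref_id` (full header), `family`, `protein`.
#' @export
read_refdb <- function(path) {
  if (!file.exists(path)) stop("reference FASTA not found: ", path, call. = FALSE)
  x <- Biostrings::readAAStringSet(path)
  as_refdb(tibble(
    ref_id = names(x),
    family = vapply(strsplit(names(x), "|", fixed = TRUE),
                    function(p) p[length(p)], character(1)),
    protein = unname(as.character(x))
  ))
}

as_refdb <- function(x) {
  if (!is.data.frame(x) || !all(c("ref_id", "family", "protein") %in% names(x))) {
    stop("reference db needs columns ref_id, family, protein", call. = FALSE)
  }
  x <- as_tibble(x)
  if (nrow(x) == 0) stop("reference db is empty", call. = FALSE)
  if (anyDuplicated(x$ref_id)) stop("duplicate reference ids", call. = FALSE)
  if (any(is.na(x$family) | !nzchar(x$family))) {
    stop("every reference record must carry a family label", call. = FALSE)
  }
  x
}

#' Write a reference tibble to FASTA (family as last header token)
#'
#' @param refdb Reference tibble (`ref_id`, `family`, `protein`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_refdb <- function(refdb, path) {
  refdb <- as_refdb(refdb)
  hdr <- ifelse(endsWith(refdb$ref_id, paste0("|", refdb$family)),
                refdb$ref_id, paste0(refdb$ref_id, "|", refdb$family))
  x <- Biostrings::AAStringSet(stats::setNames(refdb$protein, hdr))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Classify ORFs into DNAP families by best reference hit
#'
#' Each ORF protein is aligned (full Smith-Waterman, see [align_pair()])
#' against every reference protein. If the best hit (highest bit score; ties
#' broken by longer alignment, then smaller reference id) has an e-value at or
#' below `evalue_max`, the ORF is called with that reference's family. The
#' e-value search space is the whole reference set. One call per qualifying
#' ORF; a genome may carry 0, 1 or several calls.
#'
#' @param orfs ORF tibble from [find_orfs()].
#' @param refdb Reference tibble (see [read_refdb()]).
#' @param evalue_max Classification e-value threshold (analysis default 1e-4).
#' @return Tibble of calls: `genome_id`, `orf_id`, `family`,
#'   `subgroup` (NA until [assign_subgroups()]), `best_ref_id`, `evalue`,
#'   `bit_score`, `protein`.
#' @export
classify_dnaps <- function(orfs, refdb, evalue_max = 1e-4) {
  refdb <- as_refdb(refdb)
  empty <- tibble(genome_id = character(), orf_id = character(),
                  family = character(), subgroup = character(),
                  best_ref_id = character(), evalue = double(),
                  bit_score = double(), protein = character())
  if (nrow(orfs) == 0) return(empty)
  hits <- sw_batch(orfs$protein, refdb$protein, seed_filter = FALSE)
  if (nrow(hits) == 0) return(empty)
  n_res <- sum(nchar(refdb$protein))
  hits$bit_score <- bit_score_from_raw(hits$raw_score)
  hits$evalue <- evalue_from_bit(hits$bit_score,
                                 nchar(orfs$protein)[hits$q_idx], n_res)
  hits$ref_id <- refdb$ref_id[hits$s_idx]
  best <- hits %>%
    dplyr::arrange(.data$q_idx, dplyr::desc(.data$bit_score),
                   dplyr::desc(.data$aln_len), .data$ref_id) %>%
    dplyr::distinct(.data$q_idx, .keep_all = TRUE) %>%
    dplyr::filter(.data$evalue <= evalue_max)
  tibble(
    genome_id = orfs$genome_id[best$q_idx],
    orf_id = orfs$orf_id[best$q_idx],
    family = refdb$family[best$s_idx],
    subgroup = NA_character_,
    best_ref_id = best$ref_id,
    evalue = best$evalue,
    bit_score = best$bit_score,
    protein = orfs$protein[best$q_idx]
  )
}

# global pairwise identity: matches / alignment columns
global_identity <- function(p1, p2) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(p1), Biostrings::AAString(p2), type = "global",
    substitutionMatrix = blosum62(),
    gapOpening = DEFAULT_GAP_OPEN, gapExtension = DEFAULT_GAP_EXT)
  Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

#' Assign within-family subgroups by single-linkage identity clustering
#'
#' All called DNAP proteins of the same family are compared pairwise by global
#' alignment; proteins with identity (matches / alignment columns) at or above
#' `identity_threshold` are linked, and single-linkage clusters become
#' subgroups. Labels are the family letter plus an ordinal by decreasing
#' cluster size (A1 is the largest PolA cluster; ties broken by the smallest
#' member `orf_id`).
#'
#' @param calls Call tibble from [classify_dnaps()] (column `protein` is used).
#' @param identity_threshold Linkage threshold on global identity.
#' @return `calls` with the `subgroup` column filled in.
#' @export
assign_subgroups <- function(calls, identity_threshold = 0.5) {
  if (nrow(calls) == 0) return(calls)
  calls$subgroup <- NA_character_
  for (fam in unique(calls$family)) {
    idx <- which(calls$family == fam)
    k <- length(idx)
    parent <- seq_len(k)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    if (k > 1) {
      for (a in seq_len(k - 1)) {
        for (b in seq.int(a + 1, k)) {
          id <- global_identity(calls$protein[idx[a]], calls$protein[idx[b]])
          if (id >= identity_threshold) {
            ra <- find(a); rb <- find(b)
            if (ra != rb) parent[rb] <- ra
          }
        }
      }
    }
    comp <- vapply(seq_len(k), find, integer(1))
    sizes <- table(comp)
    first_id <- vapply(split(calls$orf_id[idx], comp), min, character(1))
    ord <- order(-as.integer(sizes), first_id)
    rank <- stats::setNames(seq_along(ord), names(sizes)[ord])
    letter <- sub("^Pol", "", fam)
    calls$subgroup[idx] <- paste0(letter, rank[as.character(comp)])
  }
  calls
}

#' Write DNAP calls as TSV
#'
#' @param calls Call tibble.
#' @param path Output path.
#' @return `calls`, invisibly.
#' @export
write_calls <- function(calls, path) {
  readr::write_tsv(
    calls[, c("genome_id", "orf_id", "family", "subgroup",
              "best_ref_id", "evalue", "bit_score")], path)
  invisible(calls)
}
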