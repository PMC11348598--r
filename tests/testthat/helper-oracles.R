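# Independent oracles used across the suite. These deliberately re-derive
# results with different algorithms/code paths than the package.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

blosum62_oracle <- local({
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

# position-by-position ORF enumeration: every (start codon, next in-frame
# stop) pair, then the longest-per-stop-segment rule; linear genome,
# N-containing codons match nothing
brute_force_orfs <- function(seq, min_len = 75,
                             start_codons = c("ATG", "GTG", "TTG")) {
  L <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    for (frame in 0:2) {
      pos <- frame + 1L
      cands <- integer(0)  # candidate start positions (1-based, on s)
      while (pos + 2L <= L) {
        if (substr(s, pos, pos + 2L) %in% start_codons) cands <- c(cands, pos)
        pos <- pos + 3L
      }
      for (st in cands) {
        # walk to the next in-frame stop
        p <- st
        stop_at <- NA_integer_
        while (p + 2L <= L) {
          if (substr(s, p, p + 2L) %in% stops) { stop_at <- p; break }
          p <- p + 3L
        }
        if (!is.na(stop_at)) {
          start0 <- st - 1L
          end0 <- stop_at + 2L
        } else {
          # trailing ORF to the last complete codon of the frame
          last_full <- st + 3L * ((L - st + 1L) %/% 3L) - 1L
          start0 <- st - 1L
          end0 <- last_full
        }
        if (end0 - start0 < min_len) next
        res[[length(res) + 1L]] <- data.frame(
          start0 = start0, end0 = end0, strand = strand, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(start = integer(), end = integer(), strand = character()))
  }
  df <- do.call(rbind, res)
  # longest per stop-segment = earliest start per (strand, end)
  df <- df[order(df$strand, df$end0, df$start0), ]
  df <- df[!duplicated(df[, c("strand", "end0")]), ]
  out <- df
  if (any(df$strand == "-")) {
    m <- df$strand == "-"
    out$start0[m] <- L - df$end0[m]
    out$end0[m] <- L - df$start0[m]
  }
  out <- data.frame(start = out$start0, end = out$end0, strand = out$strand)
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

orf_key <- function(df) {
  paste(df$start, df$end, df$strand, sep = "|")
}

# exhaustive small-parsimony minimum: enumerate states of internal nodes and
# wildcard leaves, count edges whose endpoints differ
brute_force_parsimony <- function(tree, leaf_states) {
  tips <- tree$tip.label
  ntip <- length(tips)
  if (!is.list(leaf_states)) leaf_states <- as.list(leaf_states)
  sets <- lapply(leaf_states[tips], function(s) {
    if (is.null(s) || all(is.na(s))) NULL else unique(s[!is.na(s)])
  })
  states <- sort(unique(unlist(sets)))
  if (length(states) <= 1) return(0L)
  fixed <- which(vapply(sets, function(s) !is.null(s) && length(s) == 1, TRUE))
  free <- setdiff(seq_len(ntip + tree$Nnode), fixed)
  # ambiguous (multi-state) leaves are enumerated over their own sets
  domain <- lapply(free, function(v) {
    if (v <= ntip && !is.null(sets[[v]])) match(sets[[v]], states)
    else seq_along(states)
  })
  grid <- as.matrix(expand.grid(domain, KEEP.OUT.ATTRS = FALSE))
  assign <- matrix(0L, nrow(grid), ntip + tree$Nnode)
  assign[, free] <- grid
  for (v in fixed) assign[, v] <- match(sets[[v]], states)
  changes <- rep(0L, nrow(grid))
  for (r in seq_len(nrow(tree$edge))) {
    p <- tree$edge[r, 1]; c <- tree$edge[r, 2]
    changes <- changes + (assign[, p] != assign[, c])
  }
  as.integer(min(changes))
}

# tiny in-code simulated dataset used by several files
small_sim <- function(seed = 7, n_leaves = 10, n_swaps = 0, swap_events = NULL,
                      ...) {
  cfg <- sim_config(n_leaves = n_leaves, seed = seed,
                    swap_events = swap_events, ...)
  simulate_dataset(cfg, n_swaps = n_swaps)
}
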