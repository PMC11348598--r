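#' Per-clade DNAP family profiles and heterogeneity flags
#'
#' For every clade of a partition, summarizes the DNAP calls of its genomes
#' and flags the two types of DNAP heterogeneity: type i, at least two
#' distinct families among genomes that each carry exactly one call (implying
#' gene swapping); type ii, some genome in the clade carries two or more calls
#' of different families.
#'
#' @param partition A `clade_partition` from [cut_clades()].
#' @param calls DNAP call tibble from [classify_dnaps()]. Every call's genome
#'   must belong to the partition.
#' @return Tibble with one row per clade: `clade_id`, `node`, `n_genomes`,
#'   `is_singleton`, `families_present` (comma-separated), `n_families`,
#'   `n_dnap_genomes`, `n_single_dnap_genomes`, `n_multi_dnap_genomes`,
#'   `het_type_i`, `het_type_ii`.
#' @export
profile_clades <- function(partition, calls) {
  stopifnot(inherits(partition, "clade_partition"))
  mem <- partition$membership
  unknown <- setdiff(calls$genome_id, mem$genome_id)
  if (length(unknown) > 0) {
    stop("calls reference genomes outside the partition: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  per_genome <- calls %>%
    dplyr::group_by(.data$genome_id) %>%
    dplyr::summarise(n_calls = dplyr::n(),
                     n_fams = dplyr::n_distinct(.data$family),
                     fams = list(sort(unique(.data$family))),
                     .groups = "drop")
  m <- dplyr::left_join(mem, per_genome, by = "genome_id")
  m$n_calls[is.na(m$n_calls)] <- 0L
  prof <- m %>%
    dplyr::group_by(.data$clade_id) %>%
    dplyr::summarise(
      n_genomes = dplyr::n(),
      families_present = paste(sort(unique(unlist(.data$fams))), collapse = ","),
      n_families = dplyr::n_distinct(unlist(.data$fams)),
      n_dnap_genomes = sum(.data$n_calls > 0),
      n_single_dnap_genomes = sum(.data$n_calls == 1),
      n_multi_dnap_genomes = sum(.data$n_calls > 1),
      het_type_i = dplyr::n_distinct(unlist(.data$fams[.data$n_calls == 1])) >= 2,
      het_type_ii = any(.data$n_calls > 1 & vapply(.data$fams, length, 1L) >= 2,
                        na.rm = TRUE),
      .groups = "drop"
    )
  dplyr::left_join(partition$clades[, c("clade_id", "node", "is_singleton")],
                   prof, by = "clade_id")
}

#' Group heterogeneous clades with their DNAP-bearing sisters
#'
#' Starting from each type-i heterogeneous (hotspot) clade, the clade is
#' repeatedly merged with its sister subtree(s) as long as the sister contains
#' at least one DNAP-encoding genome; merging stops when the sister has none.
#' The emitted swap clade is the MRCA subtree of the merged set; overlapping
#' groups are deduplicated to the maximal ones.
#'
#' @param tree The ultrametric genome tree the partition was cut from.
#' @param partition A `clade_partition`.
#' @param profiles Output of [profile_clades()] on this partition.
#' @return Tibble with one row per swap clade: `swap_clade_id`, `node`,
#'   `n_genomes`, `genomes` (list), `clade_ids` (list of member clade ids),
#'   `seed_clade_id`.
#' @export
group_sister_clades <- function(tree, partition, profiles) {
  ntip <- length(tree$tip.label)
  parent <- rep(NA_integer_, ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  # any sister subtree encountered while climbing is a union of whole clades,
  # so "sister contains a DNAP-encoding genome" can be read off the profiles
  mem <- partition$membership
  dnap_clades <- profiles$clade_id[profiles$n_dnap_genomes > 0]
  dnap_genomes <- unique(mem$genome_id[mem$clade_id %in% dnap_clades])
  # restrict to genomes that actually carry a call: a DNAP-bearing clade may
  # contain call-free genomes, but since whole clades sit inside each sister,
  # clade-level presence is exactly the sister-level presence rule
  hot <- profiles$clade_id[profiles$het_type_i & !profiles$is_singleton]
  if (length(hot) == 0) {
    return(tibble(swap_clade_id = character(), node = integer(),
                  n_genomes = integer(), genomes = list(),
                  clade_ids = list(), seed_clade_id = character()))
  }
  node_of <- stats::setNames(partition$clades$node, partition$clades$clade_id)
  tips_below <- function(v) {
    if (v <= ntip) return(v)
    unlist(phangorn::Descendants(tree, v, type = "tips"))
  }
  out <- list()
  for (cid in hot) {
    v <- node_of[[cid]]
    repeat {
      p <- parent[v]
      if (is.na(p)) break
      sib_tips <- setdiff(tips_below(p), tips_below(v))
      sib_genomes <- tree$tip.label[sib_tips]
      if (!any(sib_genomes %in% dnap_genomes)) break
      v <- p
    }
    out[[cid]] <- v
  }
  nodes <- unlist(out)
  tip_sets <- lapply(nodes, tips_below)
  # deduplicate to maximal subtrees
  keep <- rep(TRUE, length(nodes))
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (i != j && keep[i] &&
          all(tip_sets[[i]] %in% tip_sets[[j]]) &&
          (length(tip_sets[[i]]) < length(tip_sets[[j]]) || i > j)) {
        keep[i] <- FALSE
      }
    }
  }
  nodes <- nodes[keep]; tip_sets <- tip_sets[keep]; seeds <- names(out)[keep]
  ord <- order(vapply(tip_sets, min, numeric(1)))
  nodes <- nodes[ord]; tip_sets <- tip_sets[ord]; seeds <- seeds[ord]
  genomes <- lapply(tip_sets, function(t) tree$tip.label[t])
  clade_ids <- lapply(genomes, function(g) {
    sort(unique(partition$membership$clade_id[partition$membership$genome_id %in% g]))
  })
  tibble(
    swap_clade_id = sprintf("swap_%02d", seq_along(nodes)),
    node = unname(nodes),
    n_genomes = lengths(genomes),
    genomes = genomes,
    clade_ids = clade_ids,
    seed_clade_id = seeds
  )
}

#' Minimum number of state changes on a tree (small parsimony)
#'
#' Exact unit-cost small parsimony (Sankoff recursion), valid for binary and
#' multifurcating rooted trees: the minimum number of edges on which the state
#' changes, over all ancestral labelings. On binary trees this equals the
#' Fitch count. Leaves may carry a single state, an ambiguous state set, or be
#' wildcards (`NA`): a wildcard leaf can take any state and never forces a
#' change (absence of a DNAP is not evidence of a family transition).
#'
#' @param tree A rooted `phylo` tree.
#' @param leaf_states Named character vector (`NA` = wildcard) or named list
#'   of character vectors (ambiguous sets; `NULL`/`NA` = wildcard). Names must
#'   cover every tip label.
#' @return Integer: the minimum number of state changes.
#' @export
count_swaps_fitch <- function(tree, leaf_states) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  if (!all(tips %in% names(leaf_states))) {
    stop("leaf_states missing for: ",
         paste(setdiff(tips, names(leaf_states)), collapse = ", "),
         call. = FALSE)
  }
  if (!is.list(leaf_states)) leaf_states <- as.list(leaf_states)
  sets <- lapply(leaf_states[tips], function(s) {
    if (is.null(s) || all(is.na(s))) return(NULL)
    s <- s[!is.na(s)]
    if (any(!nzchar(s))) stop("empty state label on a non-wildcard leaf", call. = FALSE)
    unique(s)
  })
  states <- sort(unique(unlist(sets)))
  ns <- length(states)
  if (ns <= 1) return(0L)
  ntip <- length(tips)
  nnode <- ntip + tree$Nnode
  cost <- matrix(Inf, nnode, ns)
  for (i in seq_len(ntip)) {
    s <- sets[[i]]
    if (is.null(s)) cost[i, ] <- 0 else cost[i, match(s, states)] <- 0
  }
  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge
  for (v in unique(edge[, 1])) {
    cs <- edge[edge[, 1] == v, 2]
    acc <- numeric(ns)
    for (c in cs) {
      child_min <- min(cost[c, ])
      acc <- acc + pmin(cost[c, ], child_min + 1)
    }
    cost[v, ] <- acc
  }
  as.integer(min(cost[ntip + 1L, ]))
}

#' Assemble the swap report
#'
#' Combines the clade partition, per-clade profiles, swap clades and DNAP
#' calls into one report: summary counts (clades with more than one genome,
#' clades with at least one DNAP, genomes with more than one call, hotspot
#' clades by heterogeneity type), and per-swap-clade minimum swap-event counts
#' computed twice by small parsimony on the genome tree -- on family states
#' (inter-family swaps) and on family+subgroup states (total swaps including
#' intra-family replacements). Genomes without a DNAP call are wildcards;
#' genomes with several calls carry the ambiguous set of their families.
#'
#' @param tree The ultrametric genome tree.
#' @param partition A `clade_partition`.
#' @param profiles [profile_clades()] output.
#' @param swap_clades [group_sister_clades()] output.
#' @param calls DNAP call tibble (after [assign_subgroups()] if subgroup-level
#'   counts are wanted).
#' @param truth Optional simulation truth (the `truth` element of a
#'   [simulate_dataset()] result) for planted-truth comparison.
#' @return An object of class `swap_report`: list with `summary` (one-row
#'   tibble), `clade_profiles`, `swap_clades` (with `min_swaps_family` and
#'   `min_swaps_subgroup`), `calls`, and optionally `truth_comparison`.
#' @export
swap_report <- function(tree, partition, profiles, swap_clades, calls,
                        truth = NULL) {
  fam_states <- leaf_state_sets(tree, calls, level = "family")
  sub_states <- leaf_state_sets(tree, calls, level = "subgroup")

  if (nrow(swap_clades) > 0) {
    swap_clades$min_swaps_family <- vapply(swap_clades$node, function(v) {
      sub <- subtree_of(tree, v)
      count_swaps_fitch(sub, fam_states[sub$tip.label])
    }, integer(1))
    swap_clades$min_swaps_subgroup <- vapply(swap_clades$node, function(v) {
      sub <- subtree_of(tree, v)
      count_swaps_fitch(sub, sub_states[sub$tip.label])
    }, integer(1))
    swap_clades$families <- vapply(swap_clades$genomes, function(g) {
      paste(sort(unique(calls$family[calls$genome_id %in% g])), collapse = ",")
    }, character(1))
  } else {
    swap_clades$min_swaps_family <- integer(0)
    swap_clades$min_swaps_subgroup <- integer(0)
    swap_clades$families <- character(0)
  }

  n_calls_per_genome <- table(calls$genome_id)
  multi <- !profiles$is_singleton
  summary <- tibble(
    n_genomes = length(tree$tip.label),
    n_clades = nrow(profiles),
    n_clades_multi = sum(multi),
    n_clades_multi_with_dnap = sum(multi & profiles$n_dnap_genomes > 0),
    n_genomes_multi_dnap = sum(n_calls_per_genome > 1),
    n_hotspots_type_i = sum(profiles$het_type_i & multi),
    n_hotspots_type_ii = sum(profiles$het_type_ii & multi),
    n_swap_clades = nrow(swap_clades),
    total_min_swaps_family = count_swaps_fitch(tree, fam_states),
    total_min_swaps_subgroup = count_swaps_fitch(tree, sub_states)
  )
  report <- structure(
    list(summary = summary, clade_profiles = profiles,
         swap_clades = swap_clades, calls = calls,
         membership = partition$membership, depth = partition$depth),
    class = "swap_report")
  if (!is.null(truth)) {
    report$truth_comparison <- compare_truth(report, partition, truth)
  }
  report
}

# leaf -> state set from calls; NA for genomes without a call
leaf_state_sets <- function(tree, calls, level = c("family", "subgroup")) {
  level <- match.arg(level)
  st <- stats::setNames(vector("list", length(tree$tip.label)), tree$tip.label)
  if (nrow(calls) > 0) {
    lab <- if (level == "family") calls$family else {
      ifelse(is.na(calls$subgroup), calls$family,
             paste0(calls$family, ":", calls$subgroup))
    }
    by_g <- split(lab, calls$genome_id)
    for (g in names(by_g)) if (g %in% names(st)) st[[g]] <- unique(by_g[[g]])
  }
  st
}

subtree_of <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node == ntip + 1L) return(tree)
  if (node <= ntip) {
    # single-leaf "subtree": trivial two-node stand-in never needed; callers
    # only pass internal nodes or the root, but guard anyway
    stop("subtree_of expects an internal node", call. = FALSE)
  }
  ape::extract.clade(tree, node)
}

compare_truth <- function(report, partition, truth) {
  swapped <- truth$leaf_states$leaf_id[truth$leaf_states$swapped]
  mem <- partition$membership
  clades_with_swapped <- sort(unique(mem$clade_id[mem$genome_id %in% swapped]))
  hotspot_ids <- report$clade_profiles$clade_id[
    report$clade_profiles$het_type_i & !report$clade_profiles$is_singleton]
  list(
    n_planted_swaps = nrow(truth$swap_events),
    clades_with_swapped_leaves = clades_with_swapped,
    hotspot_clades = hotspot_ids,
    all_swapped_clades_recovered =
      length(clades_with_swapped) > 0 && all(clades_with_swapped %in% hotspot_ids)
  )
}

#' @export
print.swap_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0(
    "DNAP swap report (clade depth %g)\n",
    "  genomes: %d; clades: %d (%d with >1 genome, %d of those DNAP-bearing)\n",
    "  hotspot clades: %d type i, %d type ii; swap clades: %d\n",
    "  tree-wide minimum swaps: %d (family), %d (family+subgroup)\n"),
    x$depth, s$n_genomes, s$n_clades, s$n_clades_multi,
    s$n_clades_multi_with_dnap, s$n_hotspots_type_i, s$n_hotspots_type_ii,
    s$n_swap_clades, s$total_min_swaps_family, s$total_min_swaps_subgroup))
  if (nrow(x$swap_clades) > 0) {
    print(x$swap_clades[, c("swap_clade_id", "n_genomes", "families",
                            "min_swaps_family", "min_swaps_subgroup")], ...)
  }
  invisible(x)
}

#' @export
tidy.swap_report <- function(x, ...) {
  out <- x$swap_clades
  out$genomes <- vapply(out$genomes, paste, character(1), collapse = ",")
  out$clade_ids <- vapply(out$clade_ids, paste, character(1), collapse = ",")
  out
}

#' @export
glance.swap_report <- function(x, ...) x$summary

#' Write a swap report as JSON and flat TSV
#'
#' @param report A `swap_report`.
#' @param json_path,tsv_path Output paths; either may be `NULL`.
#' @return `report`, invisibly.
#' @export
write_swap_report <- function(report, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    payload <- list(
      summary = report$summary,
      clade_profiles = report$clade_profiles[, setdiff(names(report$clade_profiles), "node")],
      swap_clades = tidy(report),
      truth_comparison = report$truth_comparison
    )
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(tsv_path)) {
    readr::write_tsv(tidy(report), tsv_path)
  }
  invisible(report)
}
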