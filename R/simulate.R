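NON_STOP_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

#' Simulation configuration for synthetic phage genome datasets
#'
#' Defines the conditions the simulator emulates: a Yule genome phylogeny,
#' genomes composed of protein-coding genes separated by spacers, Jukes-Cantor
#' nucleotide evolution with ORF-preserving constraints, per-gene rate
#' variation (so reciprocal-best-hit loss, and hence the genome distance,
#' grows gradually with divergence), one designated DNAP gene slot per genome,
#' and optional planted DNAP replacement events on chosen branches.
#'
#' @param n_leaves Number of genomes (>= 3).
#' @param tree_height Root-to-leaf depth in expected substitutions per site at
#'   rate multiplier 1.
#' @param n_genes Genes per genome (the DNAP occupies the middle slot).
#' @param gene_len Gene length in nt (multiple of 3, >= 75), stop codon
#'   included.
#' @param spacer_len Intergenic spacer length in nt.
#' @param sub_rate Global substitution-rate scale (per site per unit height).
#' @param gene_rate_sd Standard deviation (log scale) of per-gene lognormal
#'   rate multipliers; 0 disables rate variation.
#' @param dnap_rate Fixed rate multiplier of the DNAP gene (DNA polymerases
#'   are among the more conserved phage genes).
#' @param n_families Number of DNAP families (<= 3: PolA, PolB, PolC).
#' @param n_subgroups Within-family subgroups in the donor pool (subgroup
#'   exemplars are ~40% amino-acid identity variants of the family exemplar:
#'   unambiguous family members that stay below the 0.5 subgroup-clustering
#'   threshold even after further drift).
#' @param swap_events Tibble with columns `branch` (node or tip label
#'   identifying the edge above it), `family` (1-based index), `subgroup`, or
#'   `NULL` for none. See [choose_swap_branches()].
#' @param dnap_slot2 If `TRUE`, a second DNAP slot carrying a different family
#'   is added to every genome (exercises type-ii heterogeneity).
#' @param seed Integer seed; identical configs reproduce identical datasets.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_leaves = 32, tree_height = 0.35, n_genes = 20,
                       gene_len = 300, spacer_len = 60, sub_rate = 1,
                       gene_rate_sd = 0.7, dnap_rate = 0.3, n_families = 3,
                       n_subgroups = 2, swap_events = NULL,
                       dnap_slot2 = FALSE, seed = 1) {
  stopifnot(n_leaves >= 3, n_genes >= 1, gene_len >= 75, gene_len %% 3 == 0,
            spacer_len >= 0, tree_height > 0, sub_rate >= 0,
            n_families >= 1, n_families <= 3, n_subgroups >= 1)
  if (!is.null(swap_events)) {
    swap_events <- as_tibble(swap_events)
    stopifnot(all(c("branch", "family", "subgroup") %in% names(swap_events)))
    if (anyDuplicated(swap_events$branch)) {
      stop("conflicting swap events on the same branch", call. = FALSE)
    }
  }
  structure(list(
    n_leaves = as.integer(n_leaves), tree_height = tree_height,
    n_genes = as.integer(n_genes), gene_len = as.integer(gene_len),
    spacer_len = as.integer(spacer_len), sub_rate = sub_rate,
    gene_rate_sd = gene_rate_sd, dnap_rate = dnap_rate,
    n_families = as.integer(n_families), n_subgroups = as.integer(n_subgroups),
    swap_events = swap_events, dnap_slot2 = isTRUE(dnap_slot2),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a Yule genome tree
#'
#' Pure-birth (Yule) topology with branch times rescaled so the tree is
#' ultrametric with the requested height. Tips are labeled `g001..`, internal
#' nodes `n<number>` (used as branch ids for swap placement). Deterministic
#' for a fixed seed.
#'
#' @param n_leaves Number of tips (>= 3).
#' @param tree_height Root-to-leaf depth after rescaling.
#' @param seed Integer seed.
#' @return An ultrametric rooted `phylo` tree.
#' @export
simulate_tree <- function(n_leaves, tree_height = 1, seed = 1) {
  stopifnot(n_leaves >= 3)
  set.seed(seed)
  tree <- ape::rphylo(n_leaves, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * (tree_height / depth)
  tree$tip.label <- sprintf("g%03d", seq_len(n_leaves))
  tree$node.label <- sprintf("n%d", n_leaves + seq_len(tree$Nnode))
  tree
}

random_gene <- function(gene_len) {
  ncod <- gene_len %/% 3L
  c("ATG", sample(NON_STOP_CODONS, ncod - 2L, replace = TRUE), "TAA")
}

random_spacer <- function(spacer_len) {
  paste(sample(c("A", "C", "G", "T"), spacer_len, replace = TRUE), collapse = "")
}

# within-family subgroup variant: redraw a fraction of internal codons.
# The default leaves ~40% amino-acid identity to the family exemplar: far
# above what family assignment needs, but comfortably below the 0.5
# single-linkage subgrouping threshold even after further drift along the
# tree, so planted subgroups stay distinguishable.
subgroup_variant <- function(codons, redraw_frac = 0.65) {
  internal <- seq.int(2L, length(codons) - 1L)
  k <- round(redraw_frac * length(internal))
  pick <- sample(internal, k)
  codons[pick] <- sample(NON_STOP_CODONS, k, replace = TRUE)
  codons
}

# Jukes-Cantor substitution of one coding gene (vector of codons) along a
# branch: per-site substitution probability p; substitutions that would create
# an internal stop codon or destroy the start codon are redrawn among the
# permitted bases (reverted if none is permitted)
mutate_gene <- function(codons, p) {
  if (p <= 0) return(codons)
  ncod <- length(codons)
  seqv <- strsplit(paste(codons, collapse = ""), "", fixed = TRUE)[[1]]
  n <- length(seqv)
  mut <- which(stats::runif(n) < p)
  # never touch the terminal stop codon
  mut <- mut[mut <= n - 3L]
  bases <- c("A", "C", "G", "T")
  for (i in mut) {
    alts <- setdiff(bases, seqv[i])
    cod_idx <- (i - 1L) %/% 3L
    off <- i - cod_idx * 3L           # position within codon, 1..3
    cod <- seqv[(cod_idx * 3L + 1L):(cod_idx * 3L + 3L)]
    ok <- vapply(alts, function(b) {
      cod2 <- cod; cod2[off] <- b
      w <- paste(cod2, collapse = "")
      if (cod_idx == 0L) w %in% DEFAULT_START_CODONS
      else !(w %in% STOP_CODONS)
    }, logical(1))
    alts <- alts[ok]
    if (length(alts) > 0) seqv[i] <- alts[sample.int(length(alts), 1L)]
  }
  cods <- substring(paste(seqv, collapse = ""),
                    seq.int(1L, n - 2L, 3L), seq.int(3L, n, 3L))
  cods
}

# unconstrained Jukes-Cantor substitution of a spacer string
mutate_spacer <- function(spacer, p) {
  if (p <= 0 || nchar(spacer) == 0) return(spacer)
  seqv <- strsplit(spacer, "", fixed = TRUE)[[1]]
  mut <- which(stats::runif(length(seqv)) < p)
  if (length(mut) > 0) {
    bases <- c("A", "C", "G", "T")
    seqv[mut] <- vapply(seqv[mut], function(b) {
      sample(setdiff(bases, b), 1L)
    }, character(1))
  }
  paste(seqv, collapse = "")
}

jc_prob <- function(rate, t) 0.75 * (1 - exp(-4 / 3 * rate * t))

#' Evolve genomes along a tree
#'
#' The root genome consists of `n_genes` random genes (ATG start, stop-free
#' coding frame, terminal TAA) separated by random spacers; the middle gene
#' slot carries the PolA family-1 exemplar from the DNAP donor pool. Sequences
#' evolve along branches under Jukes-Cantor with per-site substitution
#' probability `p = 3/4 (1 - exp(-4/3 r t))` (rate `r` = `sub_rate` times the
#' element's rate multiplier, `t` = branch length); substitutions that would
#' create an in-frame internal stop or destroy the start codon are redrawn.
#'
#' @param tree Tree from [simulate_tree()].
#' @param config A [sim_config()]. The caller controls the RNG seed.
#' @return A `phage_sim` list: `tree`, `config`, `elements` (per-leaf list of
#'   gene codon vectors and spacer strings), `coords` (per-element genome
#'   coordinates), `donors` (DNAP donor pool), `rates`, `dnap_slot`,
#'   `leaf_states` (root family/subgroup for every leaf, updated by
#'   [plant_swaps()]).
#' @export
evolve_genomes <- function(tree, config) {
  ng <- config$n_genes
  dnap_slot <- (ng + 1L) %/% 2L
  # donor pool: unrelated random exemplar genes per family, ~60%-identity
  # subgroup variants within families
  donors <- vector("list", config$n_families)
  for (f in seq_len(config$n_families)) {
    fam <- vector("list", config$n_subgroups)
    fam[[1]] <- random_gene(config$gene_len)
    if (config$n_subgroups > 1) {
      for (sg in seq.int(2L, config$n_subgroups)) {
        fam[[sg]] <- subgroup_variant(fam[[1]])
      }
    }
    donors[[f]] <- fam
  }
  # per-gene lognormal rate multipliers; the DNAP slot is conserved
  gene_rates <- exp(stats::rnorm(ng, 0, config$gene_rate_sd))
  gene_rates[dnap_slot] <- config$dnap_rate
  slot2 <- if (config$dnap_slot2) ng + 1L else NULL

  root_genes <- lapply(seq_len(ng), function(i) random_gene(config$gene_len))
  root_genes[[dnap_slot]] <- donors[[1]][[1]]
  if (!is.null(slot2)) {
    f2 <- if (config$n_families > 1) 2L else 1L
    root_genes[[ng + 1L]] <- donors[[f2]][[1]]
    gene_rates <- c(gene_rates, config$dnap_rate)
  }
  n_all_genes <- length(root_genes)
  root_spacers <- replicate(n_all_genes + 1L, random_spacer(config$spacer_len))

  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  genes_at <- vector("list", nnode)
  spacers_at <- vector("list", nnode)
  root <- ntip + 1L
  genes_at[[root]] <- root_genes
  spacers_at[[root]] <- root_spacers

  pre <- ape::reorder.phylo(tree, "postorder")
  edges <- pre$edge[rev(seq_len(nrow(pre$edge))), , drop = FALSE]
  elens <- rev(pre$edge.length)
  for (r in seq_len(nrow(edges))) {
    p <- edges[r, 1]; ch <- edges[r, 2]; t <- elens[r]
    g <- genes_at[[p]]
    for (i in seq_len(n_all_genes)) {
      g[[i]] <- mutate_gene(g[[i]], jc_prob(config$sub_rate * gene_rates[i], t))
    }
    sp <- vapply(spacers_at[[p]], mutate_spacer,
                 character(1), p = jc_prob(config$sub_rate, t))
    genes_at[[ch]] <- g
    spacers_at[[ch]] <- sp
  }

  glen <- config$gene_len
  slen <- config$spacer_len
  starts <- slen + (seq_len(n_all_genes) - 1L) * (glen + slen)
  coords <- tibble(
    element = seq_len(n_all_genes),
    start = starts, end = starts + glen,
    is_dnap = seq_len(n_all_genes) %in% c(dnap_slot, slot2)
  )
  leaf_states <- tibble(
    leaf_id = tree$tip.label, family = 1L, subgroup = 1L, swapped = FALSE
  )
  structure(list(
    tree = tree, config = config,
    genes = genes_at[seq_len(ntip)], spacers = spacers_at[seq_len(ntip)],
    donors = donors, rates = gene_rates, dnap_slot = dnap_slot,
    dnap_slot2 = slot2, coords = coords, leaf_states = leaf_states,
    swap_events = tibble(branch = character(), family = integer(),
                         subgroup = integer())
  ), class = "phage_sim")
}

node_by_label <- function(tree, label) {
  ntip <- length(tree$tip.label)
  i <- match(label, tree$tip.label)
  if (!is.na(i)) return(i)
  j <- match(label, tree$node.label)
  if (!is.na(j)) return(ntip + j)
  stop("no branch named '", label, "' in the simulated tree", call. = FALSE)
}

#' Plant DNAP replacement events on tree branches
#'
#' Each swap event replaces the DNAP gene, at the top of the named branch,
#' with the designated family/subgroup donor gene; the replacement then
#' evolves down the subtree and is inherited by all descendant leaves,
#' flanking genes untouched (the "in situ" property). Events deeper on the
#' same root-to-leaf path override shallower ones; two events on the same
#' branch are a configuration error.
#'
#' @param sim A `phage_sim` from [evolve_genomes()].
#' @param swap_events Tibble (`branch`, `family`, `subgroup`); defaults to the
#'   config's events.
#' @return The updated `phage_sim` (leaf genes, `leaf_states`, `swap_events`).
#' @export
plant_swaps <- function(sim, swap_events = sim$config$swap_events) {
  if (is.null(swap_events) || nrow(swap_events) == 0) return(sim)
  if (anyDuplicated(swap_events$branch)) {
    stop("conflicting swap events on the same branch", call. = FALSE)
  }
  tree <- sim$tree
  ntip <- length(tree$tip.label)
  cfg <- sim$config
  nodes <- vapply(swap_events$branch, node_by_label, integer(1), tree = tree)
  depth <- ape::node.depth.edgelength(tree)
  ord <- order(depth[nodes])  # shallow first, deeper events override
  parent <- rep(NA_integer_, ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen <- rep(NA_real_, ntip + tree$Nnode)
  elen[tree$edge[, 2]] <- tree$edge.length
  children <- split(tree$edge[, 2], tree$edge[, 1])

  for (k in ord) {
    v <- nodes[k]
    fam <- swap_events$family[k]
    sg <- swap_events$subgroup[k]
    if (fam > cfg$n_families || sg > cfg$n_subgroups) {
      stop("swap event references an unknown family/subgroup", call. = FALSE)
    }
    donor <- sim$donors[[fam]][[sg]]
    # evolve the donor from the top of branch v down to every descendant leaf
    evolve_down <- function(node, gene, t) {
      gene <- mutate_gene(gene, jc_prob(cfg$sub_rate * cfg$dnap_rate, t))
      if (node <= ntip) {
        sim$genes[[node]][[sim$dnap_slot]] <<- gene
        i <- node
        sim$leaf_states$family[i] <<- fam
        sim$leaf_states$subgroup[i] <<- sg
        sim$leaf_states$swapped[i] <<- TRUE
      } else {
        for (c in children[[as.character(node)]]) evolve_down(c, gene, elen[c])
      }
    }
    evolve_down(v, donor, elen[v])
  }
  sim$swap_events <- as_tibble(swap_events)
  sim
}

#' Pick well-separated shallow branches for swap planting
#'
#' Selects `n_swaps` terminal branches whose nearest neighbor in the tree is
#' close (so the swapped genome shares a shallow clade with an unswapped
#' relative) while the selected leaves are mutually distant (so each planted
#' event is an independent swap on the tree). Families cycle over the non-root
#' families (2, 3, 2, ...), subgroup 1.
#'
#' @param tree A simulated tree ([simulate_tree()]).
#' @param n_swaps Number of events.
#' @param n_families Families available (>= 2).
#' @param min_sep Minimum pairwise cophenetic distance between selected
#'   leaves, as a fraction of the tree diameter. If no selection satisfies it,
#'   the requirement is halved (deterministically) until one does.
#' @return A swap-event tibble (`branch`, `family`, `subgroup`).
#' @export
choose_swap_branches <- function(tree, n_swaps = 3, n_families = 3,
                                 min_sep = 0.5) {
  stopifnot(n_families >= 2)
  d <- stats::cophenetic(tree)
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  cand <- names(sort(nn))  # tips with the closest relatives first
  diam <- max(d[is.finite(d)])
  greedy <- function(sep) {
    sel <- character(0)
    for (tip in cand) {
      if (length(sel) == n_swaps) break
      if (all(d[tip, sel] >= sep * diam) &&
          # never pick a tip that is the nearest neighbor of one already chosen
          !tip %in% names(which(nn[sel] == d[sel, tip]))) {
        sel <- c(sel, tip)
      }
    }
    sel
  }
  sep <- min_sep
  sel <- greedy(sep)
  while (length(sel) < n_swaps && sep > 1e-4) {
    sep <- sep / 2
    sel <- greedy(sep)
  }
  if (length(sel) < n_swaps) {
    stop("could not find ", n_swaps, " sufficiently separated branches",
         call. = FALSE)
  }
  fams <- rep(seq.int(2L, n_families), length.out = n_swaps)
  tibble(branch = sel, family = as.integer(fams), subgroup = 1L)
}

leaf_sequence <- function(sim, leaf_index) {
  genes <- vapply(sim$genes[[leaf_index]], paste, character(1), collapse = "")
  sp <- sim$spacers[[leaf_index]]
  paste0(paste0(sp[seq_along(genes)], genes, collapse = ""), sp[length(sp)])
}

family_name <- function(i) paste0("Pol", LETTERS[i])

#' Simulate a complete phage genome dataset with planted ground truth
#'
#' Runs [simulate_tree()], [evolve_genomes()] and [plant_swaps()] under one
#' seed and assembles the pipeline-ready dataset. If the config has no
#' explicit `swap_events` and `n_swaps > 0`, branches are chosen with
#' [choose_swap_branches()].
#'
#' @param config A [sim_config()].
#' @param n_swaps Planted events when `config$swap_events` is `NULL`.
#' @return A list: `genomes` (genome tibble), `refdb` (labeled reference
#'   tibble, one exemplar per family/subgroup), `tree` (true tree), `truth`
#'   (list: `tree_newick`, `leaf_states` tibble with `family`/`subgroup`
#'   labels, `swap_events`, `expected_divergence` cophenetic matrix), `sim`
#'   (the full `phage_sim`), `config`.
#' @export
simulate_dataset <- function(config, n_swaps = 0) {
  set.seed(config$seed)
  tree <- ape::rphylo(config$n_leaves, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * (config$tree_height / depth)
  tree$tip.label <- sprintf("g%03d", seq_len(config$n_leaves))
  tree$node.label <- sprintf("n%d", config$n_leaves + seq_len(tree$Nnode))

  sim <- evolve_genomes(tree, config)
  events <- config$swap_events
  if (is.null(events) && n_swaps > 0) {
    events <- choose_swap_branches(tree, n_swaps, config$n_families)
  }
  if (!is.null(events) && nrow(events) > 0) sim <- plant_swaps(sim, events)

  genomes <- as_genome_tbl(stats::setNames(
    vapply(seq_len(config$n_leaves), function(i) leaf_sequence(sim, i),
           character(1)),
    tree$tip.label))
  refdb <- refdb_from_donors(sim)
  states <- sim$leaf_states
  states$family_label <- family_name(states$family)
  states$subgroup_label <- paste0(sub("Pol", "", family_name(states$family)),
                                  states$subgroup)
  truth <- list(
    tree_newick = ape::write.tree(tree),
    leaf_states = states,
    swap_events = sim$swap_events,
    expected_divergence = stats::cophenetic(tree)
  )
  list(genomes = genomes, refdb = refdb, tree = tree, truth = truth,
       sim = sim, config = config)
}

refdb_from_donors <- function(sim) {
  rows <- list()
  for (f in seq_along(sim$donors)) {
    for (sg in seq_along(sim$donors[[f]])) {
      fam <- family_name(f)
      cds <- paste(sim$donors[[f]][[sg]], collapse = "")
      rows[[length(rows) + 1L]] <- tibble(
        ref_id = sprintf("%s_%d|%s", fam, sg, fam),
        family = fam,
        protein = translate_cds(cds)
      )
    }
  }
  as_refdb(dplyr::bind_rows(rows))
}

#' Write a simulated dataset to disk
#'
#' Writes `genomes.fna`, `refs.faa`, `tree.nwk`, `truth.json` and
#' `config.json` under `outdir`. Re-running with the same config reproduces
#' identical files.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
emit_dataset <- function(dataset, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir,
                                call. = FALSE)
  write_genome_fasta(dataset$genomes, file.path(outdir, "genomes.fna"))
  write_refdb(dataset$refdb, file.path(outdir, "refs.faa"))
  writeLines(dataset$truth$tree_newick, file.path(outdir, "tree.nwk"))
  truth <- dataset$truth
  truth$expected_divergence <- NULL  # recomputable from tree.nwk
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- dataset$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
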