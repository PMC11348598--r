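#' Pipeline run configuration
#'
#' Bundles input paths and all stage parameters. Defaults are the analysis
#' values: 75 nt minimum ORF length, 50% query coverage for reciprocal best
#' hits, classification e-value 1e-4, clade depth 0.15, subgroup identity 0.5.
#'
#' @param genomes Path to the genome nucleotide FASTA.
#' @param refs Path to the labeled DNAP reference protein FASTA.
#' @param out_dir Output directory for all intermediates.
#' @param truth Optional path to a simulation `truth.json` for planted-truth
#'   comparison.
#' @param min_orf_len,rbh_evalue,min_cover,classify_evalue,clade_depth,subgroup_identity
#'   Stage parameters (see the stage functions).
#' @param seed_filter,word_size Word-seeding options of the RBH search.
#' @param verbose Log stage progress to stderr.
#' @return A `run_config` list.
#' @export
run_config <- function(genomes, refs, out_dir, truth = NULL,
                       min_orf_len = 75, rbh_evalue = 1e-3, min_cover = 0.5,
                       classify_evalue = 1e-4, clade_depth = 0.15,
                       subgroup_identity = 0.5, seed_filter = TRUE,
                       word_size = 4L, verbose = TRUE) {
  structure(list(
    genomes = genomes, refs = refs, truth = truth, out_dir = out_dir,
    min_orf_len = min_orf_len, rbh_evalue = rbh_evalue, min_cover = min_cover,
    classify_evalue = classify_evalue, clade_depth = clade_depth,
    subgroup_identity = subgroup_identity, seed_filter = seed_filter,
    word_size = as.integer(word_size), verbose = isTRUE(verbose)
  ), class = "run_config")
}

#' Run the full DNAP swap-detection pipeline
#'
#' Executes all stages in order -- ORF extraction, RBH distance matrix,
#' neighbor-joining tree, ultrametrization, fixed-depth clade cutting, DNAP
#' classification and subgrouping, swap detection -- writing every
#' intermediate plus a manifest JSON (parameters, input checksums, package
#' version, output checksums) to `out_dir`. Reruns on identical inputs and
#' config reproduce identical outputs. A failing stage raises an error naming
#' the stage.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with every stage result (`orfs`, `dist`,
#'   `tree_nj`, `tree`, `partition`, `calls`, `profiles`, `swap_clades`,
#'   `report`, `manifest`).
#' @examples
#' \donttest{
#' ex <- system.file("extdata", "example", package = "polswap")
#' out <- file.path(tempdir(), "polswap-example")
#' res <- run_pipeline(run_config(
#'   genomes = file.path(ex, "genomes.fna"),
#'   refs = file.path(ex, "refs.faa"),
#'   truth = file.path(ex, "truth.json"),
#'   out_dir = out, verbose = FALSE))
#' res$report
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  say <- function(stage, ...) {
    if (config$verbose) message(sprintf("[%s] ", stage), ...)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  say("input", "reading genomes and references")
  genomes <- stage("input", {
    if (!file.exists(config$genomes)) stop("missing genome FASTA: ", config$genomes)
    read_genome_fasta(config$genomes)
  })
  refdb <- stage("input", {
    if (!file.exists(config$refs)) stop("missing reference FASTA: ", config$refs)
    read_refdb(config$refs)
  })
  truth <- NULL
  if (!is.null(config$truth)) {
    truth <- stage("input", read_truth_json(config$truth))
  }

  say("orfs", "extracting ORFs (min length ", config$min_orf_len, " nt)")
  orfs <- stage("orfs", find_orfs(genomes, min_len = config$min_orf_len))
  write_orfs(orfs, out("proteins.faa"), out("orfs.tsv"))

  say("distance", "computing RBH coverage distances for ",
      nrow(genomes) * (nrow(genomes) - 1) / 2, " genome pairs")
  d <- stage("distance", distance_matrix(
    genomes, orfs = orfs, evalue_max = config$rbh_evalue,
    min_cover = config$min_cover, seed_filter = config$seed_filter,
    word_size = config$word_size, keep_rbh = TRUE, verbose = FALSE))
  write_distance_matrix(d, out("distance.tsv"), out("distance.phy"))
  readr::write_tsv(attr(d, "rbh"), out("rbh.tsv"))

  say("tree", "neighbor joining + midpoint rooting + ultrametrization")
  tree_nj <- stage("tree", build_tree(d))
  tree <- stage("tree", ultrametrize(tree_nj))
  ape::write.tree(tree_nj, out("tree_nj.nwk"))
  ape::write.tree(tree, out("tree_ultrametric.nwk"))

  say("clades", "cutting clades at depth ", config$clade_depth)
  partition <- stage("clades", cut_clades(tree, depth = config$clade_depth))
  write_clades(partition, out("clades.tsv"))

  say("classify", "classifying DNAPs against ", nrow(refdb), " references")
  calls <- stage("classify", {
    cl <- classify_dnaps(orfs, refdb, evalue_max = config$classify_evalue)
    assign_subgroups(cl, identity_threshold = config$subgroup_identity)
  })
  write_calls(calls, out("dnap_calls.tsv"))

  say("detect", "profiling clades and counting swaps")
  report <- stage("detect", {
    profiles <- profile_clades(partition, calls)
    swap_clades <- group_sister_clades(tree, partition, profiles)
    swap_report(tree, partition, profiles, swap_clades, calls, truth = truth)
  })
  write_swap_report(report, out("swap_report.json"), out("swap_report.tsv"))

  manifest <- list(
    package = "polswap",
    version = as.character(utils::packageVersion("polswap")),
    parameters = unclass(config)[setdiff(names(unclass(config)),
                                         c("genomes", "refs", "truth", "out_dir"))],
    inputs = input_checksums(config),
    outputs = local({
      fs <- c("orfs.tsv", "proteins.faa", "rbh.tsv", "distance.tsv",
              "distance.phy", "tree_nj.nwk", "tree_ultrametric.nwk",
              "clades.tsv", "dnap_calls.tsv", "swap_report.json",
              "swap_report.tsv")
      as.list(stats::setNames(unname(tools::md5sum(file.path(config$out_dir, fs))), fs))
    })
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  say("done", "all outputs in ", config$out_dir)
  invisible(list(orfs = orfs, dist = d, tree_nj = tree_nj, tree = tree,
                 partition = partition, calls = calls,
                 profiles = report$clade_profiles,
                 swap_clades = report$swap_clades, report = report,
                 manifest = manifest))
}

input_checksums <- function(config) {
  paths <- c(genomes = config$genomes, refs = config$refs)
  if (!is.null(config$truth)) paths <- c(paths, truth = config$truth)
  as.list(stats::setNames(unname(tools::md5sum(paths)), names(paths)))
}

read_truth_json <- function(path) {
  if (!file.exists(path)) stop("missing truth JSON: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$leaf_states <- as_tibble(x$leaf_states)
  x$swap_events <- as_tibble(x$swap_events)
  x
}

#' Run the whole analysis on in-memory objects
#'
#' Convenience wrapper equivalent to [run_pipeline()] without file IO: ORFs,
#' distances, tree, clades, classification and swap detection in one call.
#'
#' @param genomes Genomes ([as_genome_tbl()]).
#' @param refdb Reference tibble ([read_refdb()] / [as_refdb]).
#' @param truth Optional simulation truth list.
#' @inheritParams run_config
#' @return The same list [run_pipeline()] returns (minus the manifest).
#' @export
analyze_genomes <- function(genomes, refdb, truth = NULL, min_orf_len = 75,
                            rbh_evalue = 1e-3, min_cover = 0.5,
                            classify_evalue = 1e-4, clade_depth = 0.15,
                            subgroup_identity = 0.5, seed_filter = TRUE,
                            word_size = 4L) {
  genomes <- as_genome_tbl(genomes)
  refdb <- as_refdb(refdb)
  orfs <- find_orfs(genomes, min_len = min_orf_len)
  d <- distance_matrix(genomes, orfs = orfs, evalue_max = rbh_evalue,
                       min_cover = min_cover, seed_filter = seed_filter,
                       word_size = word_size)
  tree_nj <- build_tree(d)
  tree <- ultrametrize(tree_nj)
  partition <- cut_clades(tree, depth = clade_depth)
  calls <- classify_dnaps(orfs, refdb, evalue_max = classify_evalue)
  calls <- assign_subgroups(calls, identity_threshold = subgroup_identity)
  profiles <- profile_clades(partition, calls)
  swap_clades <- group_sister_clades(tree, partition, profiles)
  report <- swap_report(tree, partition, profiles, swap_clades, calls,
                        truth = truth)
  list(orfs = orfs, dist = d, tree_nj = tree_nj, tree = tree,
       partition = partition, calls = calls, profiles = profiles,
       swap_clades = swap_clades, report = report)
}
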