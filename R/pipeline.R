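#' Default thresholds of the clustering and IP-MS pipelines
#'
#' Sequence stage: identity >= 0.2, coverage >= 0.7 of both partners.
#' Structure stage: TM-score >= 0.4, coverage >= 0.7. Merge step: link
#' fraction strictly > 0.65. IP-MS selection: log2 fold change >= 1, raw
#' p < 0.01, >= 3 quantified replicates. Consensus TMD: >= 2 of 3
#' predictors. Interface contacts: < 8 Angstrom.
#'
#' @return Named list of thresholds.
#' @export
default_config <- function() {
  list(min_identity = 0.2, min_tm = 0.4, min_cov = 0.7,
       merge_threshold = 0.65, lfc_min = 1, p_max = 0.01, min_reps = 3,
       k_tmd = 2, interface_cutoff = 8.0, seed = 0)
}

#' Run the two-stage clustering pipeline with merge and annotation
#'
#' Orchestrates: sequence-stage greedy clustering -> structure-stage
#' clustering of the sequence representatives -> composition -> connectivity
#' merge, and (when a taxonomy is supplied) per-cluster LCA annotation. The
#' cluster-count sequence across stages is non-increasing by construction.
#'
#' @param universe Character vector of all protein ids.
#' @param seq_edges,struct_edges,merge_edges `gv_edges` tables: sequence
#'   hits, structural hits for the representative stage, and the all-vs-all
#'   structural hits used by the merge step (defaults to `struct_edges`).
#' @param genome_of,taxonomy,focal_genome Optional annotation inputs (see
#'   [annotate_clusters()]).
#' @param config Threshold list as from [default_config()].
#' @return List with `seq_clustering`, `two_stage`, `merged`, `events`,
#'   `annotation` (or `NULL`) and `report` (stage cluster counts and, when
#'   annotated, the LCA histogram).
#' @export
run_orthogroup_pipeline <- function(universe, seq_edges, struct_edges,
                                    merge_edges = struct_edges,
                                    genome_of = NULL, taxonomy = NULL,
                                    focal_genome = NULL,
                                    config = default_config()) {
  cfg <- utils::modifyList(default_config(), config)
  seq_cl <- cluster_greedy(seq_edges, cfg$min_identity, cfg$min_cov, universe)
  reps <- unname(seq_cl$representatives)
  rep_edges <- struct_edges[struct_edges$query %in% reps &
                              struct_edges$target %in% reps, , drop = FALSE]
  struct_cl <- cluster_greedy(rep_edges, cfg$min_tm, cfg$min_cov, reps)
  two_stage <- compose_two_stage(seq_cl, struct_cl)
  mg <- merge_clusters(two_stage, merge_edges,
                       threshold = cfg$merge_threshold)
  annotation <- NULL
  if (!is.null(taxonomy) && !is.null(genome_of)) {
    annotation <- annotate_clusters(mg$clustering, genome_of, taxonomy,
                                    focal_genome %||% taxonomy$genome_id[1])
  }
  report <- list(
    n_proteins = length(universe),
    clusters_sequence = n_clusters(seq_cl),
    clusters_two_stage = n_clusters(two_stage),
    clusters_merged = n_clusters(mg$clustering),
    n_merge_events = sum(mg$events$merged))
  if (!is.null(annotation))
    report$lca_histogram <- as.list(lca_histogram(annotation))
  list(seq_clustering = seq_cl, two_stage = two_stage,
       merged = mg$clustering, events = mg$events,
       annotation = annotation, report = report)
}

#' Run the IP-MS enrichment pipeline for one bait experiment
#'
#' Orchestrates: replicate filtering, log2 transform, normalisation,
#' imputation, moderated t-test, threshold selection and replicate
#' invalidation.
#'
#' @param x A raw-scale `gv_abundance`.
#' @param config Threshold list as from [default_config()].
#' @param normalization Passed to [preprocess_abundance()].
#' @param bait_protein Reference protein for `bait_median` normalisation.
#' @return List with `records` (full [select_interactors()] output),
#'   `interactors` (selected ids) and `report`.
#' @export
run_ipms_pipeline <- function(x, config = default_config(),
                              normalization = "median_mad",
                              bait_protein = NULL) {
  cfg <- utils::modifyList(default_config(), config)
  pre <- preprocess_abundance(x, min_reps = cfg$min_reps,
                              normalization = normalization,
                              bait_protein = bait_protein)
  records <- moderated_t_test(pre)
  records <- select_interactors(records, attr(pre, "n_quantified"),
                                lfc_min = cfg$lfc_min, p_max = cfg$p_max,
                                min_reps = cfg$min_reps)
  list(records = records,
       interactors = interactor_set(records),
       report = list(n_tested = nrow(records),
                     n_selected = sum(records$selected),
                     n_invalidated = sum(records$invalidated)))
}

#' Run the bait-network stage over several IP-MS experiments
#'
#' Builds the bait summary network from per-bait interactor sets and
#' partitions it with Louvain community detection.
#'
#' @param interactors Named list, `bait -> interactor id vector`.
#' @param seed Louvain seed (default 0).
#' @return List with `network` (igraph), `communities` (named membership
#'   vector) and `report`.
#' @export
run_bait_network <- function(interactors, seed = 0) {
  net <- build_bait_network(interactors)
  comm <- detect_communities(net, seed = seed)
  list(network = net, communities = comm,
       report = list(n_baits = length(interactors),
                     n_edges = igraph::ecount(net),
                     n_communities = length(unique(comm)),
                     interactors_per_bait = lapply(interactors, length)))
}
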