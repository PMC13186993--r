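#' Taxonomic ranks, deepest first
#'
#' The fixed rank order used throughout:
#' species < genus < subfamily < family < order < class < phylum <
#' superkingdom (species is the deepest level). Subfamily may be absent for
#' genomes outside the families where it was annotated.
#' @return Character vector of the 8 ranks, deepest first.
#' @export
taxonomy_ranks <- function() rev(TAX_RANKS)

#' Last-common-ancestor taxonomic level of a protein set
#'
#' Returns the deepest rank at which all member genomes carry one identical,
#' non-absent taxon, together with that taxon. Scanning proceeds from species
#' up to superkingdom; a rank where any genome has no annotation can never be
#' the LCA level. If even the superkingdom differs the sentinel
#' `("none", NA)` is returned.
#'
#' @param members Character vector of protein ids.
#' @param genome_of Named character vector, `protein_id -> genome_id`.
#' @param taxonomy A `gv_taxonomy` table covering every member's genome.
#' @return List with elements `rank` and `taxon`.
#' @export
lca_level <- function(members, genome_of, taxonomy) {
  genomes <- unique(genome_of[members])
  if (anyNA(genomes))
    stop("protein with unknown genome: ",
         members[is.na(genome_of[members])][1], call. = FALSE)
  miss <- setdiff(genomes, taxonomy$genome_id)
  if (length(miss))
    stop("genome absent from taxonomy: ", miss[1], call. = FALSE)
  rows <- taxonomy[genomes, , drop = FALSE]
  for (rank in taxonomy_ranks()) {
    vals <- rows[[rank]]
    if (!anyNA(vals) && length(unique(vals)) == 1)
      return(list(rank = rank, taxon = vals[1]))
  }
  list(rank = "none", taxon = NA_character_)
}

#' Validate tree-consistency of a taxonomy table
#'
#' Under a tree-shaped taxonomy, genomes sharing a deeper rank value must
#' also share every shallower rank value. Violations are reported with a
#' warning (they make LCA levels ambiguous).
#'
#' @param taxonomy A `gv_taxonomy` table.
#' @return `TRUE` invisibly if consistent, otherwise `FALSE` with a warning.
#' @export
check_taxonomy_consistency <- function(taxonomy) {
  ranks <- taxonomy_ranks()
  ok <- TRUE
  for (i in seq_len(length(ranks) - 1)) {
    deep <- taxonomy[[ranks[i]]]
    for (j in seq(i + 1, length(ranks))) {
      shallow <- taxonomy[[ranks[j]]]
      keep <- !is.na(deep) & !is.na(shallow)
      tab <- unique(data.frame(d = deep[keep], s = shallow[keep]))
      dup <- tab$d[duplicated(tab$d)]
      if (length(dup)) {
        warning(sprintf(
          "taxonomy not tree-consistent: %s '%s' maps to several %s values",
          ranks[i], dup[1], ranks[j]), call. = FALSE)
        ok <- FALSE
      }
    }
  }
  invisible(ok)
}

#' Paralog counts and bins per cluster for a focal genome
#'
#' Counts, for every cluster, the number of proteins contributed by the
#' focal genome and bins the count into the classes `1`, `2-5`, `6-10`,
#' `11-20`, `21+` (clusters with no focal protein get count 0 and bin `0`).
#'
#' @param clustering A `gv_clustering`.
#' @param genome_of Named character vector, `protein_id -> genome_id`.
#' @param focal_genome Genome id whose paralogs are counted.
#' @return Data frame `cluster_id, paralog_count, paralog_bin`.
#' @export
paralog_counts <- function(clustering, genome_of, focal_genome) {
  members <- cluster_members(clustering)
  count <- vapply(members, function(m)
    sum(genome_of[m] == focal_genome, na.rm = TRUE), integer(1))
  data.frame(cluster_id = names(members), paralog_count = count,
             paralog_bin = paralog_bin(count),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname paralog_counts
#' @param count Integer vector of paralog counts.
#' @export
paralog_bin <- function(count) {
  cut(count, breaks = c(-Inf, 0, 1, 5, 10, 20, Inf),
      labels = c("0", "1", "2-5", "6-10", "11-20", "21+"))
}

#' Virion-shape class of a cluster
#'
#' `icosahedral_only` when every member genome with a known virion shape is
#' icosahedral (and at least one shape is known); `mixed` as soon as one
#' member genome builds non-icosahedral virions; `unknown` when no member
#' shape is known.
#'
#' @param members Character vector of protein ids.
#' @param genome_of Named character vector, `protein_id -> genome_id`.
#' @param taxonomy A `gv_taxonomy` table with the `shape` column.
#' @return One of `"icosahedral_only"`, `"mixed"`, `"unknown"`.
#' @export
shape_class <- function(members, genome_of, taxonomy) {
  genomes <- unique(genome_of[members])
  shapes <- taxonomy[genomes, "shape"]
  shapes <- shapes[!is.na(shapes) & shapes != "unknown"]
  if (length(shapes) == 0) return("unknown")
  if (any(shapes == "non_icosahedral")) return("mixed")
  "icosahedral_only"
}

#' Annotate all clusters of a clustering
#'
#' Per-cluster LCA rank and taxon, genus-ORFan status, focal-genome paralog
#' count/bin and virion-shape class. A cluster is a genus ORFan when its LCA
#' rank is genus or species and the shared genus is the focal genus (no
#' homolog detectable outside that genus).
#'
#' @param clustering A `gv_clustering`.
#' @param genome_of Named character vector, `protein_id -> genome_id`.
#' @param taxonomy A `gv_taxonomy` table.
#' @param focal_genome Genome id used for paralog counting.
#' @param focal_genus Genus name defining ORFan status (default: the focal
#'   genome's genus).
#' @return Data frame, one row per cluster, columns `cluster_id, n_members,
#'   lca_rank, lca_taxon, is_genus_orfan, paralog_count, paralog_bin,
#'   shape_class`.
#' @export
annotate_clusters <- function(clustering, genome_of, taxonomy, focal_genome,
                              focal_genus = NULL) {
  if (is.null(focal_genus)) {
    if (!focal_genome %in% taxonomy$genome_id)
      stop("focal genome absent from taxonomy: ", focal_genome, call. = FALSE)
    focal_genus <- taxonomy[focal_genome, "genus"]
  }
  members <- cluster_members(clustering)
  pc <- paralog_counts(clustering, genome_of, focal_genome)
  pc <- pc[match(names(members), pc$cluster_id), ]
  lca <- lapply(members, lca_level, genome_of = genome_of,
                taxonomy = taxonomy)
  rank <- vapply(lca, `[[`, character(1), "rank")
  taxon <- vapply(lca, `[[`, character(1), "taxon")
  genus_of_cluster <- vapply(members, function(m) {
    g <- unique(taxonomy[unique(genome_of[m]), "genus"])
    if (length(g) == 1 && !is.na(g)) g else NA_character_
  }, character(1))
  orfan <- rank %in% c("genus", "species") &
    !is.na(genus_of_cluster) & genus_of_cluster == focal_genus
  shp <- vapply(members, shape_class, character(1),
                genome_of = genome_of, taxonomy = taxonomy)
  data.frame(cluster_id = names(members),
             n_members = lengths(members),
             lca_rank = rank, lca_taxon = taxon,
             is_genus_orfan = orfan,
             paralog_count = pc$paralog_count,
             paralog_bin = pc$paralog_bin,
             shape_class = shp,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Histogram of LCA ranks over clusters
#' @param annotation Output of [annotate_clusters()].
#' @return Named integer vector over `c(taxonomy_ranks(), "none")`.
#' @export
lca_histogram <- function(annotation) {
  levs <- c(taxonomy_ranks(), "none")
  table(factor(annotation$lca_rank, levels = levs))
}
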