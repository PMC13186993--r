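#' Clustering objects
#'
#' A clustering is a partition of protein ids into clusters, each with a
#' designated representative that is itself a member. Cluster ids are the
#' representative ids, which keeps labels stable and deterministic.
#'
#' @param assignment Named character vector, `protein_id -> cluster_id`.
#' @param representatives Named character vector,
#'   `cluster_id -> representative protein_id`.
#' @return A `gv_clustering` object.
#' @export
new_clustering <- function(assignment, representatives) {
  if (anyDuplicated(names(assignment)))
    stop("clustering assignment is not a partition: duplicated protein",
         call. = FALSE)
  if (!setequal(unique(assignment), names(representatives)))
    stop("cluster ids and representatives disagree", call. = FALSE)
  ok <- assignment[representatives] == names(representatives)
  if (!all(ok))
    stop("representative not a member of its own cluster: ",
         representatives[!ok][1], call. = FALSE)
  structure(list(assignment = assignment, representatives = representatives),
            class = "gv_clustering")
}

#' @export
print.gv_clustering <- function(x, ...) {
  cat(sprintf("gv_clustering: %d proteins in %d clusters\n",
              length(x$assignment), length(x$representatives)))
  invisible(x)
}

#' Number of clusters in a clustering
#' @param clustering A `gv_clustering` object.
#' @return Integer cluster count.
#' @export
n_clusters <- function(clustering) length(clustering$representatives)

#' Cluster membership as a list of protein-id vectors
#' @param clustering A `gv_clustering` object.
#' @return Named list `cluster_id -> character vector of members`.
#' @export
cluster_members <- function(clustering) {
  split(names(clustering$assignment), clustering$assignment)
}

filter_edges <- function(edges, min_score, min_cov) {
  keep <- edges$score >= min_score & edges$qcov >= min_cov &
    edges$tcov >= min_cov & edges$query != edges$target
  edges[keep, , drop = FALSE]
}

#' Greedy set-cover clustering of a similarity graph
#'
#' Edges are first filtered: an edge is retained iff its score is at least
#' `min_score` and the coverage of *both* query and target is at least
#' `min_cov` (the stringent both-ways coverage rule used when building
#' orthogroups at 20% identity / 70% coverage, then TM-score 0.4 / 70%
#' coverage for structures). Self-edges are ignored. Clustering is greedy
#' set-cover: candidate representatives are visited in decreasing
#' retained-edge degree (ties broken by longer protein when lengths are
#' supplied, then lexicographic id); each unclaimed candidate becomes a
#' representative and claims all of its still-unclaimed neighbours. Proteins
#' with no retained edge become singletons. A connected-components mode is
#' available via `method = "components"`.
#'
#' @param edges A `gv_edges` data frame.
#' @param min_score Minimum score (identity fraction or TM-score).
#' @param min_cov Minimum coverage of both query and target.
#' @param universe Character vector of all protein ids to partition; must
#'   contain every protein referenced by an edge.
#' @param protein_lengths Optional named numeric vector of protein lengths
#'   used for representative tie-breaking.
#' @param method `"setcover"` (default) or `"components"`.
#' @return A `gv_clustering` over `universe`.
#' @export
cluster_greedy <- function(edges, min_score, min_cov, universe,
                           protein_lengths = NULL,
                           method = c("setcover", "components")) {
  method <- match.arg(method)
  universe <- as.character(universe)
  refd <- unique(c(edges$query, edges$target))
  miss <- setdiff(refd, universe)
  if (length(miss))
    stop("edge references protein absent from universe: ", miss[1],
         call. = FALSE)
  kept <- filter_edges(edges, min_score, min_cov)
  nbr <- adjacency_list(kept, universe)
  if (method == "components") {
    g <- igraph::graph_from_data_frame(kept[, c("query", "target")],
                                       directed = FALSE,
                                       vertices = universe)
    comp <- igraph::components(g)$membership
    members <- split(names(comp), comp)
    assignment <- character(0); reps <- character(0)
    for (mem in members) {
      rep <- rep_choice(mem, protein_lengths)
      assignment[mem] <- rep
      reps[rep] <- rep
    }
    return(new_clustering(assignment[universe], reps))
  }
  deg <- lengths(nbr)
  len <- if (is.null(protein_lengths)) rep(0, length(universe)) else {
    v <- protein_lengths[universe]; v[is.na(v)] <- 0; v
  }
  ord <- universe[order(-deg, -len, universe)]
  claimed <- setNames(rep(FALSE, length(universe)), universe)
  assignment <- setNames(rep(NA_character_, length(universe)), universe)
  reps <- character(0)
  for (p in ord) {
    if (claimed[p]) next
    claimed[p] <- TRUE
    assignment[p] <- p
    reps[p] <- p
    for (q in nbr[[p]]) {
      if (!claimed[q]) {
        claimed[q] <- TRUE
        assignment[q] <- p
      }
    }
  }
  new_clustering(assignment, reps)
}

adjacency_list <- function(edges, universe) {
  nbr <- setNames(vector("list", length(universe)), universe)
  if (nrow(edges)) {
    und <- rbind(data.frame(a = edges$query, b = edges$target),
                 data.frame(a = edges$target, b = edges$query))
    und <- unique(und)
    sp <- split(und$b, und$a)
    nbr[names(sp)] <- sp
  }
  nbr
}

rep_choice <- function(members, protein_lengths = NULL) {
  if (!is.null(protein_lengths)) {
    v <- protein_lengths[members]; v[is.na(v)] <- 0
    members <- members[order(-v, members)]
  } else members <- sort(members)
  members[1]
}

#' Compose sequence-stage and structure-stage clusterings
#'
#' Second stage of the two-stage pipeline: structures of the sequence-cluster
#' representatives are clustered, and every protein inherits the structural
#' cluster of its sequence representative. Cluster count can only shrink.
#'
#' @param seq_clustering Sequence-stage `gv_clustering`.
#' @param struct_clustering_of_reps Structure-stage `gv_clustering` whose
#'   universe must contain every sequence-stage representative.
#' @return A `gv_clustering` over the full protein universe.
#' @export
compose_two_stage <- function(seq_clustering, struct_clustering_of_reps) {
  reps <- seq_clustering$representatives
  miss <- setdiff(reps, names(struct_clustering_of_reps$assignment))
  if (length(miss))
    stop("representative absent from structural stage: ", miss[1],
         call. = FALSE)
  rep_of_protein <- reps[seq_clustering$assignment]
  assignment <- struct_clustering_of_reps$assignment[rep_of_protein]
  names(assignment) <- names(seq_clustering$assignment)
  used <- unique(assignment)
  new_clustering(assignment, struct_clustering_of_reps$representatives[used])
}

#' Fraction of one cluster linked into another
#'
#' The merge-step connectivity measure: the fraction of proteins in cluster
#' `a` that have at least one (undirected) similarity edge to a member of
#' cluster `b`.
#'
#' @param cluster_a,cluster_b Non-empty, disjoint character vectors of
#'   protein ids.
#' @param edges A `gv_edges` data frame of the retained all-vs-all structural
#'   hits (e.g. TM-score > 0.4, coverage > 0.7).
#' @return Fraction in `[0, 1]`.
#' @export
link_fraction <- function(cluster_a, cluster_b, edges) {
  if (length(cluster_a) == 0 || length(cluster_b) == 0)
    stop("link_fraction: empty cluster", call. = FALSE)
  in_b <- edges$query %in% cluster_a & edges$target %in% cluster_b
  in_b2 <- edges$target %in% cluster_a & edges$query %in% cluster_b
  linked <- unique(c(edges$query[in_b], edges$target[in_b2]))
  length(intersect(linked, cluster_a)) / length(cluster_a)
}

#' Merge highly connected clusters
#'
#' Post-clustering merge step: for every cluster pair with at least one
#' cross-cluster structural hit, the link fraction is computed in both
#' directions on the ORIGINAL clusters; a pair is eligible when the fraction
#' strictly exceeds `threshold` in at least one direction ("over 65% of
#' proteins in one cluster have links to at least one member of the other").
#' Eligible pairs are then closed transitively by union-find, so chains of
#' eligibility collapse into a single cluster. With `iterate = TRUE` the
#' whole pass is repeated on its own output until a fixed point.
#'
#' @param clustering A `gv_clustering`.
#' @param edges Retained all-vs-all structural hits (`gv_edges`); scores are
#'   assumed already thresholded upstream.
#' @param threshold Merge threshold in `(0, 1]`, default 0.65.
#' @param iterate Recompute eligibility on the merged clustering until no
#'   further merges occur (off by default).
#' @param protein_lengths Optional protein lengths for representative
#'   tie-breaks.
#' @return A list with elements `clustering` (the merged `gv_clustering`) and
#'   `events` (data frame of all cluster pairs with a nonzero fraction:
#'   `cluster_a, cluster_b, fraction_a_to_b, fraction_b_to_a, merged`).
#' @export
merge_clusters <- function(clustering, edges, threshold = 0.65,
                           iterate = FALSE, protein_lengths = NULL) {
  stopifnot(threshold > 0, threshold <= 1)
  res <- merge_pass(clustering, edges, threshold, protein_lengths)
  if (iterate) {
    while (n_clusters(res$clustering) < n_clusters(clustering)) {
      clustering <- res$clustering
      nxt <- merge_pass(clustering, edges, threshold, protein_lengths)
      if (n_clusters(nxt$clustering) == n_clusters(clustering)) break
      res <- list(clustering = nxt$clustering,
                  events = rbind(res$events, nxt$events))
    }
  }
  res
}

merge_pass <- function(clustering, edges, threshold, protein_lengths) {
  members <- cluster_members(clustering)
  assign_of <- clustering$assignment
  ed <- edges[edges$query != edges$target, , drop = FALSE]
  ca <- assign_of[ed$query]
  cb <- assign_of[ed$target]
  keep <- !is.na(ca) & !is.na(cb) & ca != cb
  ed <- ed[keep, , drop = FALSE]; ca <- ca[keep]; cb <- cb[keep]
  events <- data.frame(cluster_a = character(), cluster_b = character(),
                       fraction_a_to_b = numeric(),
                       fraction_b_to_a = numeric(),
                       merged = logical(), stringsAsFactors = FALSE)
  if (nrow(ed) == 0)
    return(list(clustering = clustering, events = events))
  key <- ifelse(ca < cb, paste(ca, cb, sep = "\r"), paste(cb, ca, sep = "\r"))
  pairs <- unique(key)
  ab <- do.call(rbind, strsplit(pairs, "\r", fixed = TRUE))
  fa <- fb <- numeric(nrow(ab))
  for (i in seq_len(nrow(ab))) {
    fa[i] <- link_fraction(members[[ab[i, 1]]], members[[ab[i, 2]]], ed)
    fb[i] <- link_fraction(members[[ab[i, 2]]], members[[ab[i, 1]]], ed)
  }
  merged <- pmax(fa, fb) > threshold
  events <- data.frame(cluster_a = ab[, 1], cluster_b = ab[, 2],
                       fraction_a_to_b = fa, fraction_b_to_a = fb,
                       merged = merged, stringsAsFactors = FALSE)
  if (!any(merged))
    return(list(clustering = clustering, events = events))
  # union-find transitive closure over eligible pairs
  parent <- setNames(names(members), names(members))
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in which(merged)) {
    ra <- find(ab[i, 1]); rb <- find(ab[i, 2])
    if (ra != rb) parent[[ra]] <- rb
  }
  root <- vapply(names(members), find, character(1))
  new_groups <- split(names(members), root)
  assignment <- clustering$assignment
  reps <- character(0)
  for (grp in new_groups) {
    mem <- unlist(members[grp], use.names = FALSE)
    # representative of merged cluster = representative of largest constituent
    sizes <- lengths(members[grp])
    best <- sort(grp[sizes == max(sizes)])[1]
    rep <- clustering$representatives[[best]]
    assignment[mem] <- rep
    reps[rep] <- rep
  }
  list(clustering = new_clustering(assignment, reps), events = events)
}

#' Normalised mutual information between two clusterings
#'
#' Compares two partitions on the proteins present in both universes, using
#' arithmetic-mean normalisation `I(U;V) / mean(H(U), H(V))` (the default of
#' the scikit-learn implementation commonly used for this comparison). The
#' score is symmetric, lies in `[0, 1]`, and equals 1 iff the partitions are
#' identical up to relabelling. By convention two partitions with zero
#' entropy each (both a single cluster) score 1; one informative and one
#' zero-entropy partition score 0.
#'
#' @param c1,c2 `gv_clustering` objects.
#' @return NMI score in `[0, 1]`.
#' @export
compare_clusterings_nmi <- function(c1, c2) {
  common <- intersect(names(c1$assignment), names(c2$assignment))
  if (length(common) == 0)
    stop("clusterings share no proteins", call. = FALSE)
  u <- as.integer(factor(c1$assignment[common]))
  v <- as.integer(factor(c2$assignment[common]))
  n <- length(common)
  tab <- table(u, v)
  pij <- tab / n
  pi_ <- rowSums(pij); pj_ <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj_)[nz]))
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  hu <- h(pi_); hv <- h(pj_)
  denom <- (hu + hv) / 2
  if (denom == 0) return(1)       # both partitions trivial: identical
  max(0, min(1, mi / denom))
}
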