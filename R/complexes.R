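#' Cosine similarity between two homolog sets
#'
#' Binary incidence-vector cosine: `|a intersect b| / sqrt(|a| * |b|)`. Used
#' to group redundant PDB complexes by the overlap of their query-protein
#' homolog sets.
#'
#' @param set_a,set_b Non-empty character vectors.
#' @return Similarity in `[0, 1]`.
#' @export
complex_cosine_similarity <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(set_a) == 0 || length(set_b) == 0)
    stop("empty homolog set", call. = FALSE)
  length(intersect(set_a, set_b)) / sqrt(length(set_a) * length(set_b))
}

#' Rank PDB complexes by homologous chain count and group redundant hits
#'
#' Complexes are sorted by decreasing number of chains with at least one
#' query-protein homolog (ties: lexicographic PDB id) and greedily grouped:
#' each complex joins the first existing group whose representative's homolog
#' set has cosine similarity >= `sim_threshold`, else it opens a new group.
#' The representative of each group is its highest-ranked member, so it
#' always carries the maximal chain count within the group.
#'
#' @param hits Either a data frame `protein, pdb_id, chain_id` of homology
#'   hits, or a named list `pdb_id -> (chain_id -> character vector of
#'   homologous query proteins)`.
#' @param sim_threshold Cosine grouping threshold in `(0, 1]` (default 0.8).
#' @return Data frame `pdb_id, n_homologous_chains, group, representative`,
#'   sorted in ranking order.
#' @export
rank_and_group_complexes <- function(hits, sim_threshold = 0.8) {
  if (is.data.frame(hits)) {
    if (nrow(hits) == 0) stop("empty hit table", call. = FALSE)
    hits <- lapply(split(hits, hits$pdb_id),
                   function(df) split(unique(df$protein), df$chain_id))
  }
  if (length(hits) == 0) stop("empty hit table", call. = FALSE)
  n_chains <- vapply(hits, function(ch)
    sum(lengths(ch) > 0), integer(1))
  homolog_set <- lapply(hits, function(ch)
    unique(unlist(ch, use.names = FALSE)))
  ord <- order(-n_chains, names(hits))
  ids <- names(hits)[ord]
  group <- setNames(rep(NA_character_, length(ids)), ids)
  reps <- character(0)
  for (id in ids) {
    placed <- FALSE
    for (r in reps) {
      if (complex_cosine_similarity(homolog_set[[id]],
                                    homolog_set[[r]]) >= sim_threshold) {
        group[id] <- r
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      group[id] <- id
    }
  }
  data.frame(pdb_id = ids,
             n_homologous_chains = unname(n_chains[ids]),
             group = unname(group[ids]),
             representative = ids %in% reps,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Minimum distance between two point clouds
#'
#' Exact minimum Euclidean distance over all point pairs. The scan is
#' vectorised in blocks; for large clouds a coarse grid prefilter discards
#' cell pairs that cannot contain a pair closer than `prefilter`, falling
#' back to the exact scan on the surviving points.
#'
#' @param a,b Numeric matrices with 3 columns (x, y, z in Angstrom).
#' @param prefilter Optional distance of interest enabling the grid
#'   prefilter when both clouds are large.
#' @return The minimum pairwise distance (possibly larger than `prefilter`
#'   only if no pair is within it, in which case the returned value is still
#'   exact over the retained points or `Inf` when the prefilter empties the
#'   candidate set).
#' @export
min_point_distance <- function(a, b, prefilter = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) == 0 || nrow(b) == 0)
    stop("chain with no points", call. = FALSE)
  if (!is.null(prefilter) && nrow(a) * nrow(b) > 25e6) {
    cell <- prefilter
    key <- function(m) paste(floor(m[, 1] / cell), floor(m[, 2] / cell),
                             floor(m[, 3] / cell))
    kb <- key(b)
    keep_b <- rep(FALSE, nrow(b))
    ka <- unique(floor(a / cell))
    cand <- unique(do.call(rbind, lapply(seq_len(nrow(ka)), function(i) {
      expand.grid(ka[i, 1] + (-1:1), ka[i, 2] + (-1:1), ka[i, 3] + (-1:1))
    })))
    cand_keys <- paste(cand[, 1], cand[, 2], cand[, 3])
    keep_b <- kb %in% cand_keys
    if (!any(keep_b)) return(Inf)
    b <- b[keep_b, , drop = FALSE]
  }
  best <- Inf
  step <- max(1, floor(5e6 / nrow(b)))
  for (start in seq(1, nrow(a), by = step)) {
    ai <- a[start:min(start + step - 1, nrow(a)), , drop = FALSE]
    d2 <- outer(rowSums(ai^2), rowSums(b^2), "+") - 2 * tcrossprod(ai, b)
    best <- min(best, min(d2))
  }
  sqrt(max(best, 0))
}

#' Interface-contact edges between homolog-labelled chains
#'
#' For every pair of chains carrying a homolog label, an edge is emitted iff
#' the minimum inter-chain point distance is strictly below `cutoff`
#' (default 8 Angstrom). Edges are reported on the query-protein labels, so
#' they can overlay the global PPI network.
#'
#' @param chains Data frame `pdb_id, chain_id, x, y, z` (one point per row)
#'   or a named list `chain_id -> 3-column coordinate matrix`.
#' @param cutoff Contact distance in Angstrom (strict, default 8).
#' @param homologs Named character vector, `chain_id -> query protein`;
#'   chains without an entry are ignored.
#' @return Data frame `chain_a, chain_b, protein_a, protein_b, min_distance`
#'   for every contacting pair.
#' @export
interface_edges <- function(chains, cutoff = 8.0, homologs) {
  if (is.data.frame(chains))
    chains <- lapply(split(chains, chains$chain_id),
                     function(df) as.matrix(df[, c("x", "y", "z")]))
  labelled <- intersect(names(chains), names(homologs))
  if (length(labelled) < 2)
    stop("need >= 2 homolog-labelled chains", call. = FALSE)
  if (any(vapply(chains[labelled], nrow, integer(1)) == 0))
    stop("chain with no points", call. = FALSE)
  pairs <- combn(sort(labelled), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    ca <- pairs[1, j]; cb <- pairs[2, j]
    d <- min_point_distance(chains[[ca]], chains[[cb]], prefilter = cutoff)
    if (d < cutoff)
      data.frame(chain_a = ca, chain_b = cb,
                 protein_a = unname(homologs[ca]),
                 protein_b = unname(homologs[cb]),
                 min_distance = d, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chain_a = character(), chain_b = character(),
                      protein_a = character(), protein_b = character(),
                      min_distance = numeric())
  out
}
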