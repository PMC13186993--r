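#' Consensus transmembrane-domain calling
#'
#' A protein is called transmembrane iff at least `k` of the configured
#' predictors (e.g. Phobius, DeepTMHMM, TMBed) predict at least one TMD.
#' Requiring agreement of two of three predictors trades the union's
#' sensitivity for a lower false-positive rate.
#'
#' @param calls Data frame with first column `protein` and one logical (or
#'   0/1) column per predictor; a missing call counts as `FALSE`.
#' @param k Minimum number of agreeing predictors (default 2).
#' @return Named logical vector, `protein -> consensus call`.
#' @export
consensus_tmd <- function(calls, k = 2) {
  preds <- setdiff(names(calls), "protein")
  if (k > length(preds))
    stop("k exceeds the number of predictors", call. = FALSE)
  m <- as.matrix(calls[, preds, drop = FALSE])
  m[is.na(m)] <- FALSE
  setNames(rowSums(m) >= k, calls$protein)
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' Reports the sample odds ratio `ad / bc` (`Inf` when `bc = 0` and
#' `ad > 0`; `NaN` when both products are 0) and the exact hypergeometric
#' p-value, computed by summing the conditional (fixed-margin) probabilities
#' of the qualifying tables. Two-sided p sums all tables with probability not
#' exceeding that of the observed table (up to a relative tolerance of 1e-7).
#'
#' @param table 2x2 numeric matrix or length-4 vector `(a, b, c, d)` read
#'   row-wise: rows = group membership, columns = property.
#' @param alternative `"two_sided"`, `"greater"` or `"less"` (on the odds
#'   ratio of the first row).
#' @return List with `odds_ratio` and `p_value`.
#' @export
fisher_exact_2x2 <- function(table,
                             alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  v <- as.numeric(t(table))
  if (length(v) != 4) stop("need a 2x2 table", call. = FALSE)
  if (any(v < 0) || any(v != round(v)))
    stop("table entries must be non-negative integers", call. = FALSE)
  a <- v[1]; b <- v[2]; c <- v[3]; d <- v[4]
  if (a + b + c + d == 0) stop("empty table", call. = FALSE)
  or <- (a * d) / (b * c)   # sample OR; Inf / NaN per convention
  m1 <- a + b; m2 <- c + d; n1 <- a + c
  lo <- max(0, n1 - m2); hi <- min(m1, n1)
  xs <- lo:hi
  probs <- stats::dhyper(xs, m1, m2, n1)
  p_obs <- probs[xs == a]
  p <- switch(alternative,
    greater = sum(probs[xs >= a]),
    less = sum(probs[xs <= a]),
    two_sided = sum(probs[probs <= p_obs * (1 + 1e-7)]))
  list(odds_ratio = or, p_value = min(1, p))
}

#' GO-term enrichment of a study set against a background
#'
#' Per term: a one-sided (greater) Fisher exact test on the 2x2 table of
#' study vs non-study proteins annotated vs not annotated with the term,
#' with Bonferroni correction over all tested terms. Terms are used exactly
#' as annotated (no propagation up the ontology); to propagate, supply
#' pre-expanded annotations.
#'
#' @param study Character vector of study proteins (subset of `background`).
#' @param background Character vector of background proteins.
#' @param annotations Named list `protein -> character vector of terms`, or a
#'   data frame `protein, term`.
#' @param alpha Significance level on the Bonferroni-corrected p
#'   (default 0.01).
#' @return Data frame `term, n_study, n_background, odds_ratio, p_value,
#'   p_bonferroni, significant`, ordered by p-value.
#' @export
go_enrichment <- function(study, background, annotations, alpha = 0.01) {
  if (length(study) == 0) stop("empty study set", call. = FALSE)
  if (!all(study %in% background))
    stop("study set must be a subset of the background", call. = FALSE)
  if (is.data.frame(annotations))
    annotations <- split(annotations$term, annotations$protein)
  ann <- annotations[intersect(names(annotations), background)]
  terms <- unique(unlist(ann, use.names = FALSE))
  prot_of_term <- split(rep(names(ann), lengths(ann)),
                        unlist(ann, use.names = FALSE))
  n_s <- length(study); n_rest <- length(background) - n_s
  rows <- lapply(terms, function(tm) {
    with_term <- prot_of_term[[tm]]
    a <- length(intersect(with_term, study))
    b <- n_s - a
    c <- length(setdiff(with_term, study))
    d <- n_rest - c
    ft <- fisher_exact_2x2(c(a, b, c, d), alternative = "greater")
    data.frame(term = tm, n_study = a, n_background = a + c,
               odds_ratio = ft$odds_ratio, p_value = ft$p_value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(term = character(), n_study = integer(),
                      n_background = integer(), odds_ratio = numeric(),
                      p_value = numeric(), p_bonferroni = numeric(),
                      significant = logical()))
  res$p_bonferroni <- pmin(1, res$p_value * nrow(res))
  res$significant <- res$p_bonferroni < alpha
  res[order(res$p_value, res$term), ]
}

#' Nucleoid spectral-count enrichment filter
#'
#' A protein is called potentially nucleoid-enriched iff it was identified
#' with at least `min_peptides` peptides and, in the pellet or in the
#' supernatant comparison, it is either detected only in the nucleoid
#' fraction or its nucleoid/virion spectral-count ratio is at least
#' `min_ratio`.
#'
#' @param counts Data frame with columns `protein, peptides, nucleoid_pellet,
#'   nucleoid_supernatant, virion_pellet, virion_supernatant`.
#' @param min_peptides Minimum peptide count (default 2).
#' @param min_ratio Minimum nucleoid/virion ratio (default 2).
#' @return Character vector of enriched protein ids.
#' @export
nucleoid_enrichment_filter <- function(counts, min_peptides = 2,
                                       min_ratio = 2.0) {
  frac_ok <- function(nuc, vir) {
    (nuc > 0 & vir == 0) | (vir > 0 & nuc / vir >= min_ratio)
  }
  ok <- counts$peptides >= min_peptides &
    (frac_ok(counts$nucleoid_pellet, counts$virion_pellet) |
       frac_ok(counts$nucleoid_supernatant, counts$virion_supernatant))
  counts$protein[ok]
}

#' Reciprocal-best-hit mapping between two proteomes
#'
#' A pair `(a, b)` is mapped iff `b` is `a`'s unique best hit in the A->B
#' table and `a` is `b`'s unique best hit in the B->A table. "Best" means
#' lowest e-value, with deterministic tie-breaking by higher score, then
#' lexicographic target id. Used to transfer region and expression-cluster
#' labels between proteomes.
#'
#' @param hits_ab,hits_ba `gv_edges` data frames of directed hits.
#' @return Data frame `a, b` of mapped pairs (a one-to-one partial matching).
#' @export
reciprocal_best_hit <- function(hits_ab, hits_ba) {
  best_ab <- best_hits(hits_ab)
  best_ba <- best_hits(hits_ba)
  if (nrow(best_ab) == 0 || nrow(best_ba) == 0)
    return(data.frame(a = character(), b = character()))
  back <- setNames(best_ba$target, best_ba$query)
  keep <- !is.na(back[best_ab$target]) & back[best_ab$target] == best_ab$query
  data.frame(a = best_ab$query[keep], b = best_ab$target[keep],
             row.names = NULL, stringsAsFactors = FALSE)
}

best_hits <- function(hits) {
  if (nrow(hits) == 0)
    return(data.frame(query = character(), target = character()))
  ord <- order(hits$query, hits$evalue, -hits$score, hits$target)
  h <- hits[ord, , drop = FALSE]
  h[!duplicated(h$query), c("query", "target"), drop = FALSE]
}

#' Shape-by-region enrichment tables
#'
#' Builds the 2x2 contingency table comparing cluster virion-shape class
#' (`icosahedral_only` vs `mixed`) with virion region membership, and tests
#' it with the two-sided Fisher exact test. Counting is per cluster by
#' default; `unit = "protein"` counts member proteins instead.
#'
#' @param annotation Output of [annotate_clusters()] with a `shape_class`
#'   column, plus a `region` column giving the region of each cluster (or
#'   protein).
#' @param region_a,region_b The two region labels to contrast (e.g.
#'   `"membrane"` vs `"nucleoid"`).
#' @param unit `"cluster"` or `"protein"` (protein counting weights each
#'   cluster by `n_members`).
#' @return List with the 2x2 `table` (rows icosahedral_only/mixed, columns
#'   region_a/region_b), `odds_ratio` and `p_value`.
#' @export
shape_region_enrichment <- function(annotation, region_a, region_b,
                                    unit = c("cluster", "protein")) {
  unit <- match.arg(unit)
  w <- if (unit == "cluster") rep(1L, nrow(annotation)) else
    annotation$n_members
  cnt <- function(shape, region)
    sum(w[annotation$shape_class == shape & annotation$region == region])
  tab <- matrix(c(cnt("icosahedral_only", region_a),
                  cnt("icosahedral_only", region_b),
                  cnt("mixed", region_a),
                  cnt("mixed", region_b)),
                2, 2, byrow = TRUE,
                dimnames = list(c("icosahedral_only", "mixed"),
                                c(region_a, region_b)))
  ft <- fisher_exact_2x2(tab, alternative = "two_sided")
  list(table = tab, odds_ratio = ft$odds_ratio, p_value = ft$p_value)
}
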