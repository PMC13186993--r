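#' Preprocess an IP-MS abundance matrix
#'
#' Standard label-free pre-processing before differential testing:
#' contaminant-flagged proteins are removed; a protein is kept iff it is
#' quantified (observed, pre-imputation) in at least `min_reps` replicates of
#' at least one condition; intensities are log2-transformed; per-sample
#' normalisation is applied; and missing values are imputed. Two imputation
#' regimes are used per protein and condition: values missing in a condition
#' where the protein is partially observed are predicted from the most
#' correlated fully observed proteins (a least-squares neighbour regression);
#' values in a condition where the protein is entirely absent are set to a
#' deterministic low quantile of that sample's observed values, reflecting
#' the censoring interpretation of condition-wide absence.
#'
#' @param x A `gv_abundance` object (raw scale).
#' @param min_reps Minimum number of quantified replicates (default 3).
#' @param replicate_rule `"any"` keeps proteins quantified in >= `min_reps`
#'   replicates of at least one condition (default); `"both"` requires it in
#'   every condition.
#' @param normalization `"median_mad"` (per-sample median centring, then each
#'   sample's MAD equalised to the median MAD across samples — scale
#'   preserving, so log2 fold changes remain interpretable), `"bait_median"`
#'   (centre each sample on a reference protein, typically the bait itself)
#'   or `"none"`.
#' @param bait_protein Protein id used by `normalization = "bait_median"`.
#' @param impute Apply imputation (default `TRUE`).
#' @param k Number of neighbour proteins for partial-missing imputation.
#' @param quantile_prob Quantile for condition-wide-absent imputation
#'   (default 0.025), applied per sample with multiplier `quantile_mult`.
#' @param quantile_mult Multiplier on the imputed quantile (default 1).
#' @return A `gv_abundance` object on the log2 scale with no missing values
#'   (when `impute = TRUE`); attribute `n_quantified` holds the
#'   pre-imputation per-condition observation counts used later for
#'   invalidation.
#' @export
preprocess_abundance <- function(x, min_reps = 3,
                                 replicate_rule = c("any", "both"),
                                 normalization = c("median_mad",
                                                   "bait_median", "none"),
                                 bait_protein = NULL,
                                 impute = TRUE, k = 10,
                                 quantile_prob = 0.025, quantile_mult = 1) {
  replicate_rule <- match.arg(replicate_rule)
  normalization <- match.arg(normalization)
  stopifnot(inherits(x, "gv_abundance"), !x$log2)
  m <- x$intensities
  cond <- x$design$condition
  for (cn in unique(cond))
    if (sum(cond == cn) == 0) stop("condition with zero samples")
  if (max(table(cond)) < min_reps)
    stop("no condition has >= ", min_reps, " samples", call. = FALSE)

  m <- m[!x$contaminant[rownames(m)], , drop = FALSE]
  nq <- quantified_counts(m, cond)
  keep <- if (replicate_rule == "any")
    apply(nq >= min_reps, 1, any) else apply(nq >= min_reps, 1, all)
  m <- m[keep, , drop = FALSE]
  nq <- nq[keep, , drop = FALSE]

  m <- log2(m)
  m <- switch(normalization,
    none = m,
    median_mad = {
      centred <- apply(m, 2, function(v) v - median(v, na.rm = TRUE))
      s <- apply(centred, 2, mad, na.rm = TRUE)
      # equalise per-sample spread at the median MAD: scale-preserving, so
      # log2 fold changes keep their fold-change meaning downstream
      target <- median(s)
      s[is.na(s) | s == 0] <- target
      if (target > 0) sweep(centred, 2, s / target, "/") else centred
    },
    bait_median = {
      if (is.null(bait_protein) || !bait_protein %in% rownames(m))
        stop("bait_median normalization needs a quantified bait_protein",
             call. = FALSE)
      ref <- m[bait_protein, ]
      if (anyNA(ref))
        stop("bait protein not quantified in every sample", call. = FALSE)
      sweep(m, 2, ref - median(ref))
    })

  if (impute && anyNA(m)) m <- impute_matrix(m, cond, k,
                                             quantile_prob, quantile_mult)
  out <- x
  out$intensities <- m
  out$contaminant <- x$contaminant[rownames(m)]
  out$log2 <- TRUE
  attr(out, "n_quantified") <- nq
  out
}

quantified_counts <- function(m, cond) {
  sapply(unique(cond), function(cn)
    rowSums(!is.na(m[, cond == cn, drop = FALSE])))
}

#' Impute missing values in a log2 abundance matrix
#'
#' Implements the two-regime scheme of [preprocess_abundance()] directly on a
#' matrix. A value missing in a condition where the protein is partially
#' observed is predicted from the protein's `k` most correlated neighbours
#' among the fully observed proteins: correlation is computed on the columns
#' where the target is observed, and the missing cell is read off the
#' neighbours' mean profile after a least-squares offset fit (the
#' slope-1 regression intercept) to the target's observed values. Proteins
#' entirely absent in a condition receive the `quantile_prob` quantile of
#' each sample's observed values — the deterministic low-abundance
#' interpretation of condition-wide absence. The neighbour computation is
#' batched by missingness mask, so large matrices impute in vectorised
#' passes.
#'
#' @param m Numeric matrix (log2 scale) with `NA` for missing.
#' @param cond Character vector of per-column conditions.
#' @param k Number of neighbour rows (default 10).
#' @param quantile_prob,quantile_mult Low-quantile rule parameters.
#' @return The matrix with all `NA` replaced.
#' @export
impute_matrix <- function(m, cond, k = 10, quantile_prob = 0.025,
                          quantile_mult = 1) {
  lowq <- apply(m, 2, function(v)
    quantile(v, probs = quantile_prob, na.rm = TRUE, names = FALSE)) *
    quantile_mult
  out <- m
  n_missing_cond <- sapply(unique(cond), function(cn)
    rowSums(is.na(m[, cond == cn, drop = FALSE])))
  reps_per_cond <- table(cond)[colnames(n_missing_cond)]
  # condition-wide absence first: DetQuantile-style low quantile
  for (cn in colnames(n_missing_cond)) {
    absent <- n_missing_cond[, cn] == reps_per_cond[cn]
    cols <- which(cond == cn)
    if (any(absent))
      out[absent, cols] <- matrix(lowq[cols], sum(absent), length(cols),
                                  byrow = TRUE)
  }
  # partial rows: neighbour imputation against the fully complete pool
  partial <- which(rowSums(is.na(out)) > 0)
  if (length(partial) == 0) return(out)
  pool <- which(rowSums(is.na(m)) == 0)
  if (length(pool) == 0) {   # no complete protein: fall back to low quantile
    for (j in seq_len(ncol(out))) {
      nas <- is.na(out[, j])
      out[nas, j] <- lowq[j]
    }
    return(out)
  }
  P <- m[pool, , drop = FALSE]
  masks <- apply(!is.na(m[partial, , drop = FALSE]), 1,
                 function(v) paste(as.integer(v), collapse = ""))
  for (msk in unique(masks)) {
    rows <- partial[masks == msk]
    obs <- strsplit(msk, "", fixed = TRUE)[[1]] == "1"
    Y <- m[rows, obs, drop = FALSE]
    Xo <- P[, obs, drop = FALSE]
    if (sum(obs) >= 3 && length(pool) > 1) {
      cs <- function(mm) {
        mu <- rowMeans(mm)
        sdv <- sqrt(pmax(rowSums((mm - mu)^2), 1e-12))
        (mm - mu) / sdv
      }
      corm <- tcrossprod(cs(Y), cs(Xo))   # rows x pool correlations
    } else {
      corm <- matrix(0, length(rows), length(pool))   # no usable ranking
    }
    kk <- min(k, length(pool))
    for (i in seq_along(rows)) {
      top <- order(-corm[i, ])[seq_len(kk)]
      xbar <- colMeans(P[top, , drop = FALSE])
      offset <- mean(Y[i, ] - xbar[obs])
      fill <- is.na(out[rows[i], ])
      out[rows[i], fill] <- xbar[fill] + offset
    }
  }
  out
}

#' Empirical-Bayes moderated t-test for bait vs control
#'
#' Per-protein two-sample test with variance shrinkage. For each protein the
#' pooled sample variance `s2` on `d = n1 + n2 - 2` degrees of freedom is
#' shrunk toward a prior `s0^2` with prior degrees of freedom `d0`:
#' `s2_post = (d0 s0^2 + d s2) / (d0 + d)`. The moderated statistic
#' `t = log2fc / (s_post * sqrt(1/n1 + 1/n2))` is referred to a t
#' distribution on `d0 + d` degrees of freedom (two-sided p). `(d0, s0^2)`
#' are estimated from the marginal distribution of the sample variances by
#' the classical method of moments on `log s2` (fitting a scaled F
#' distribution); `d0` is capped at `1e6`, representing effectively complete
#' shrinkage. `d0 = 0` may be forced to recover the ordinary pooled t-test.
#'
#' @param x A fully imputed `gv_abundance` on the log2 scale, or a numeric
#'   matrix together with `cond`.
#' @param cond Per-column condition vector when `x` is a bare matrix.
#' @param d0 Optional fixed prior degrees of freedom (estimated when `NULL`).
#' @return Data frame of class `gv_enrichment`: `protein_id, log2fc, t,
#'   p_value, df_total, s2, s2_post`; attributes `d0` and `s0_sq`.
#' @export
moderated_t_test <- function(x, cond = NULL, d0 = NULL) {
  if (inherits(x, "gv_abundance")) {
    cond <- x$design$condition
    m <- x$intensities
  } else m <- x
  if (anyNA(m)) stop("matrix must be fully imputed", call. = FALSE)
  i1 <- cond == "bait"; i2 <- cond == "control"
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2 || n2 < 2)
    stop("each condition needs >= 2 samples", call. = FALSE)
  m1 <- rowMeans(m[, i1, drop = FALSE])
  m2 <- rowMeans(m[, i2, drop = FALSE])
  v1 <- apply(m[, i1, drop = FALSE], 1, var)
  v2 <- apply(m[, i2, drop = FALSE], 1, var)
  d <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
  if (is.null(d0)) {
    fd <- fit_f_dist(s2, d)
    d0 <- fd$d0; s0_sq <- fd$s0_sq
  } else if (d0 == 0) {
    s0_sq <- 0
  } else {
    s0_sq <- exp(mean(log(pmax(s2, 1e-12))))
  }
  s2_post <- if (d0 >= 1e6) rep(s0_sq, length(s2)) else
    (d0 * s0_sq + d * s2) / (d0 + d)
  lfc <- m1 - m2
  tstat <- lfc / sqrt(s2_post * (1 / n1 + 1 / n2))
  df_total <- min(d0 + d, 1e6)
  p <- 2 * pt(-abs(tstat), df = df_total)
  res <- data.frame(protein_id = rownames(m), log2fc = lfc, t = tstat,
                    p_value = p, df_total = df_total, s2 = s2,
                    s2_post = s2_post,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "d0") <- d0
  attr(res, "s0_sq") <- s0_sq
  class(res) <- c("gv_enrichment", "data.frame")
  res
}

#' Method-of-moments fit of a scaled F distribution to sample variances
#'
#' Models `s2 ~ s0^2 F(d, d0)` and estimates `(d0, s0^2)` by matching the
#' mean and variance of `log s2` to the digamma/trigamma moments of the log-F
#' distribution; `trigamma` is inverted by Newton iteration. When the
#' observed spread of `log s2` does not exceed the sampling spread
#' `trigamma(d/2)`, `d0` is set to `1e6` ("infinite" shrinkage).
#'
#' @param s2 Positive sample variances.
#' @param d Residual degrees of freedom of each variance.
#' @return List `d0`, `s0_sq`.
#' @export
fit_f_dist <- function(s2, d) {
  s2 <- pmax(s2, 1e-5 * max(median(s2), 1e-12))
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(d / 2)
  if (evar <= 0)
    return(list(d0 = 1e6, s0_sq = mean(s2)))
  d0 <- min(2 * trigamma_inverse(evar), 1e6)
  list(d0 = d0, s0_sq = exp(emean + digamma(d0 / 2) - log(d0 / 2)))
}

trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Select and validate enriched interactors
#'
#' Applies the enrichment thresholds (log2 fold change >= `lfc_min` and raw
#' p < `p_max`) and then the replicate-validation rule: a selected protein
#' quantified (pre-imputation) in fewer than `min_reps` replicates of the
#' condition in which it is more abundant is invalidated — its p-value is
#' reset to 1 and it is deselected. Benjamini-Hochberg adjusted p-values over
#' all tested proteins are reported for audit.
#'
#' @param records A `gv_enrichment` data frame from [moderated_t_test()].
#' @param n_quantified Matrix of pre-imputation observation counts with
#'   columns `bait` and `control` (rows matching `records$protein_id`),
#'   e.g. `attr(preprocessed, "n_quantified")`.
#' @param lfc_min Minimum log2 fold change (default 1).
#' @param p_max Raw p-value threshold (default 0.01).
#' @param min_reps Minimum quantified replicates in the more-abundant
#'   condition (default 3).
#' @return The records with added columns `adjusted_p, n_quantified_bait,
#'   n_quantified_control, selected, invalidated`.
#' @export
select_interactors <- function(records, n_quantified, lfc_min = 1,
                               p_max = 0.01, min_reps = 3) {
  stopifnot(all(c("bait", "control") %in% colnames(n_quantified)))
  nq <- n_quantified[records$protein_id, , drop = FALSE]
  records$adjusted_p <- p.adjust(records$p_value, method = "BH")
  records$n_quantified_bait <- nq[, "bait"]
  records$n_quantified_control <- nq[, "control"]
  selected <- records$log2fc >= lfc_min & records$p_value < p_max
  up_cond_n <- ifelse(records$log2fc >= 0,
                      records$n_quantified_bait,
                      records$n_quantified_control)
  invalidated <- selected & up_cond_n < min_reps
  records$p_value[invalidated] <- 1
  records$selected <- selected & !invalidated
  records$invalidated <- invalidated
  records
}

#' Interactor set of one IP-MS experiment
#' @param records Output of [select_interactors()].
#' @return Character vector of selected (validated) protein ids.
#' @export
interactor_set <- function(records) {
  records$protein_id[records$selected]
}

#' Build the bait summary network
#'
#' One node per bait; for every bait pair, `Nc` is the number of shared
#' interactors and `Ndc` in `{0, 1, 2}` counts the directions in which one
#' bait is itself found among the other's interactors. An edge is created iff
#' `Nc + 10 * Ndc > 0`, with exactly that weight.
#'
#' @param interactors Named list, `bait -> character vector of interactors`.
#' @param baits Optional bait id vector (defaults to `names(interactors)`).
#' @return An undirected `igraph` graph with edge attributes `Nc`, `Ndc`,
#'   `weight`.
#' @export
build_bait_network <- function(interactors, baits = names(interactors)) {
  if (anyDuplicated(baits)) stop("bait listed twice", call. = FALSE)
  stopifnot(all(baits %in% names(interactors)))
  pairs <- if (length(baits) > 1) combn(baits, 2) else
    matrix(character(), 2, 0)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    nc <- length(intersect(interactors[[a]], interactors[[b]]))
    ndc <- (a %in% interactors[[b]]) + (b %in% interactors[[a]])
    data.frame(from = a, to = b, Nc = nc, Ndc = ndc,
               weight = nc + 10 * ndc, stringsAsFactors = FALSE)
  })
  el <- do.call(rbind, rows)
  if (is.null(el))
    el <- data.frame(from = character(), to = character(), Nc = integer(),
                     Ndc = integer(), weight = numeric())
  el <- el[el$weight > 0, , drop = FALSE]
  igraph::graph_from_data_frame(el, directed = FALSE,
                                vertices = data.frame(name = baits))
}

#' Louvain community detection on the bait network
#'
#' Weighted modularity-maximising Louvain partition, deterministic for a
#' given seed. Isolated baits form their own communities. Community labels
#' are canonicalised to the lexicographically smallest member id.
#'
#' @param network An `igraph` graph with a `weight` edge attribute.
#' @param seed Integer RNG seed (default 0).
#' @return Named character vector, `bait -> community label`.
#' @export
detect_communities <- function(network, seed = 0) {
  if (igraph::vcount(network) == 0) stop("empty network", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  cl <- igraph::cluster_louvain(network,
                                weights = igraph::E(network)$weight)
  mem <- igraph::membership(cl)
  labs <- vapply(split(names(mem), mem), function(v) sort(v)[1], character(1))
  setNames(labs[as.character(mem)], names(mem))
}

#' Assemble the annotated global bait-prey network
#'
#' Directed bait -> prey edges for every selected interactor, with node
#' attributes: `origin` (`viral`/`host`), `region`, functional `category` and
#' `expression` cluster. Viral proteins carrying several region labels are
#' resolved by the precedence membrane > nucleoid > vf_il > virion; host
#' proteins are always region `host`; viral preys with no label are
#' `virion_unassigned`.
#'
#' @param interactors Named list, `bait -> character vector of prey ids`.
#' @param regions Data frame `protein, region` (may list a protein several
#'   times) or named character vector.
#' @param host_proteins Character vector of host protein ids.
#' @param categories Optional named character vector,
#'   `protein -> functional category`.
#' @param expression Optional named character vector,
#'   `protein -> GV1..GV5 expression cluster`.
#' @return A directed `igraph` graph; edge attribute `bait` records the
#'   source experiment.
#' @export
assemble_global_network <- function(interactors, regions = NULL,
                                    host_proteins = character(),
                                    categories = NULL, expression = NULL) {
  el <- do.call(rbind, lapply(names(interactors), function(b) {
    if (length(interactors[[b]]) == 0) return(NULL)
    data.frame(from = b, to = interactors[[b]], bait = b,
               stringsAsFactors = FALSE)
  }))
  if (is.null(el)) stop("no interactors to assemble", call. = FALSE)
  nodes <- unique(c(names(interactors), el$to))
  reg <- resolve_regions(nodes, regions, host_proteins)
  vert <- data.frame(
    name = nodes,
    origin = ifelse(nodes %in% host_proteins, "host", "viral"),
    region = reg[nodes],
    category = if (is.null(categories)) NA_character_ else
      unname(categories[nodes]),
    expression = if (is.null(expression)) "none" else {
      e <- expression[nodes]; e[is.na(e)] <- "none"; unname(e)
    },
    is_bait = nodes %in% names(interactors),
    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(el, directed = TRUE, vertices = vert)
}

REGION_PRECEDENCE <- c("membrane", "nucleoid", "vf_il", "virion")

resolve_regions <- function(nodes, regions, host_proteins) {
  out <- setNames(rep("virion_unassigned", length(nodes)), nodes)
  if (!is.null(regions)) {
    if (is.data.frame(regions)) {
      for (p in unique(regions$protein)) {
        if (!p %in% nodes) next
        labs <- regions$region[regions$protein == p]
        hit <- REGION_PRECEDENCE[REGION_PRECEDENCE %in% labs]
        out[p] <- if (length(hit)) hit[1] else labs[1]
      }
    } else {
      known <- intersect(names(regions), nodes)
      out[known] <- regions[known]
    }
  }
  out[nodes %in% host_proteins] <- "host"
  out
}
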