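#' Simulate planted orthogroups over a generated taxonomy
#'
#' Generates a consistent 8-rank taxonomy (balanced random tree; subfamily is
#' annotated only inside one designated family, reproducing the common
#' partial-rank situation), assigns each orthogroup a random set of member
#' genomes, and emits three similarity tables with known ground truth:
#'
#' * `seq_edges` — all within-group pairs at identity and coverage above the
#'   default clustering thresholds (0.2 / 0.7); between-group pairs are drawn
#'   below threshold so they are filtered out.
#' * `struct_edges` — all-vs-all structural hits (TM-score above 0.4,
#'   coverage above 0.7) within each group; groups selected as planted splits
#'   are cut in two halves with no cross-half structural edge, so the
#'   two-stage pipeline leaves them as two clusters.
#' * `merge_edges` — the all-vs-all merge-search table: `struct_edges` plus,
#'   for every planted split, cross-half links covering a fraction of one
#'   half drawn strictly above the merge threshold (0.65), so the merge step
#'   rejoins exactly the planted splits.
#'
#' Noise: each within-group sequence edge is dropped independently with
#' probability `noise$dropout`; spurious above-threshold between-group
#' sequence edges are added at rate `noise$spurious` (expected fraction of
#' within-group edge count). Structural tables are left clean so dropout
#' exercises the rescue of fragmented sequence clusters by the structure
#' stage.
#'
#' @param n_genomes Number of genomes (default 40).
#' @param n_groups Number of true orthogroups (default 50).
#' @param paralog_rate Expected extra focal-genome paralogs per group
#'   (Poisson rate, default 0.1).
#' @param noise List with `dropout` and `spurious` rates (default both 0).
#' @param n_splits Number of planted split groups (default 0).
#' @param seed Integer seed; all outputs are pure functions of the
#'   parameters and seed.
#' @return List with `universe`, `genome_of`, `taxonomy`, `seq_edges`,
#'   `struct_edges`, `merge_edges`, `focal_genome` and `truth`
#'   (`group_of`, `split_groups`).
#' @export
simulate_orthogroups <- function(n_genomes = 40, n_groups = 50,
                                 paralog_rate = 0.1,
                                 noise = list(dropout = 0, spurious = 0),
                                 n_splits = 0, seed = 1) {
  stopifnot(n_genomes > 0, n_groups > 0, n_splits <= n_groups)
  dropout <- noise$dropout %||% 0
  spurious <- noise$spurious %||% 0
  stopifnot(dropout >= 0, dropout <= 1, spurious >= 0)
  withr_seed(seed)
  taxonomy <- random_taxonomy(n_genomes)
  focal_genome <- taxonomy$genome_id[1]

  # each group spans 2..min(8, n_genomes) genomes, one protein per genome,
  # plus Poisson-distributed focal paralogs
  universe <- character(0); genome_of <- character(0)
  group_of <- character(0)
  for (g in seq_len(n_groups)) {
    size <- sample(2:min(8, n_genomes), 1)
    genomes <- sample(taxonomy$genome_id, size)
    extra <- stats::rpois(1, paralog_rate)
    genomes <- c(genomes, rep(focal_genome, extra))
    ids <- sprintf("G%03d_p%02d", g, seq_along(genomes))
    universe <- c(universe, ids)
    genome_of[ids] <- genomes
    group_of[ids] <- sprintf("grp%03d", g)
  }
  if (n_groups > length(universe))
    stop("infeasible parameters: more groups than proteins", call. = FALSE)

  groups <- split(names(group_of), group_of)
  split_groups <- if (n_splits > 0) {
    big <- names(groups)[lengths(groups) >= 4]
    if (length(big) < n_splits)
      stop("not enough groups of size >= 4 to plant ", n_splits, " splits",
           call. = FALSE)
    sort(sample(big, n_splits))
  } else character(0)
  halves <- lapply(groups[split_groups], function(mem) {
    h <- floor(length(mem) / 2)
    list(a = mem[seq_len(h)], b = mem[-seq_len(h)])
  })
  # clustering "units": split groups contribute their two halves, which the
  # two-stage pipeline must leave separate until the merge step rejoins them
  units <- c(groups[setdiff(names(groups), split_groups)],
             unlist(halves, recursive = FALSE, use.names = FALSE))

  within_pairs <- function(mem) {
    if (length(mem) < 2) return(NULL)
    t(combn(mem, 2))
  }
  mk_edges <- function(pairs, score_rng, cov_rng, kind) {
    if (is.null(pairs) || nrow(pairs) == 0)
      return(similarity_edges(character(), character(), numeric(),
                              numeric(), numeric(), kind = kind))
    n <- nrow(pairs)
    similarity_edges(pairs[, 1], pairs[, 2],
                     score = runif(n, score_rng[1], score_rng[2]),
                     qcov = runif(n, cov_rng[1], cov_rng[2]),
                     tcov = runif(n, cov_rng[1], cov_rng[2]),
                     evalue = 10^runif(n, -30, -5), kind = kind)
  }

  seq_pairs <- do.call(rbind, lapply(units, within_pairs))
  if (dropout > 0 && !is.null(seq_pairs))
    seq_pairs <- seq_pairs[runif(nrow(seq_pairs)) >= dropout, , drop = FALSE]
  seq_edges <- mk_edges(seq_pairs, c(0.3, 0.9), c(0.75, 1), "sequence")
  if (spurious > 0 && !is.null(seq_pairs) && n_groups > 1) {
    n_sp <- stats::rpois(1, spurious * nrow(seq_pairs))
    if (n_sp > 0) {
      qa <- sample(universe, n_sp, replace = TRUE)
      qb <- sample(universe, n_sp, replace = TRUE)
      keep <- group_of[qa] != group_of[qb]
      sp <- mk_edges(cbind(qa[keep], qb[keep]), c(0.25, 0.5), c(0.75, 1),
                     "sequence")
      seq_edges <- validate_edges(rbind(seq_edges, sp))
    }
  }
  # below-threshold between-group background (coverage under 0.7)
  bg_n <- min(200, n_groups * 4)
  qa <- sample(universe, bg_n, replace = TRUE)
  qb <- sample(universe, bg_n, replace = TRUE)
  keep <- group_of[qa] != group_of[qb]
  bg <- mk_edges(cbind(qa[keep], qb[keep]), c(0.05, 0.15), c(0.2, 0.6),
                 "sequence")
  seq_edges <- validate_edges(rbind(seq_edges, bg))

  struct_pairs <- do.call(rbind, lapply(units, within_pairs))
  struct_edges <- mk_edges(struct_pairs, c(0.5, 0.95), c(0.75, 1),
                           "structure")

  cross <- do.call(rbind, lapply(halves, function(h) {
    # link a fraction of half a (strictly above 0.65) into half b
    na <- length(h$a)
    n_link <- ceiling(0.66 * na + runif(1) * (na - 0.66 * na))
    n_link <- max(min(n_link, na), floor(0.65 * na) + 1)
    cbind(h$a[seq_len(n_link)], sample(h$b, n_link, replace = TRUE))
  }))
  merge_edges <- validate_edges(rbind(
    struct_edges,
    mk_edges(cross, c(0.45, 0.9), c(0.75, 1), "structure")))

  list(universe = universe, genome_of = genome_of, taxonomy = taxonomy,
       seq_edges = seq_edges, struct_edges = struct_edges,
       merge_edges = merge_edges, focal_genome = focal_genome,
       truth = list(group_of = group_of, split_groups = split_groups))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run expr-free seeded section without clobbering the caller's RNG stream
withr_seed <- function(seed) {
  set.seed(as.integer(seed))
}

#' Generate a tree-consistent random taxonomy
#'
#' Balanced random tree over the 8 ranks with configurable fan-out; the
#' subfamily rank is annotated only for genomes in one designated family,
#' all other genomes carry an absent subfamily.
#'
#' @param n_genomes Number of genomes.
#' @param fanout Average number of children per internal taxon (default 2).
#' @param shape_prob Probability that a genome's virion shape is
#'   icosahedral / non_icosahedral / unknown (default 0.6, 0.3, 0.1).
#' @return A `gv_taxonomy` table. Assumes the RNG seed is already set.
#' @export
random_taxonomy <- function(n_genomes, fanout = 2,
                            shape_prob = c(0.6, 0.3, 0.1)) {
  ranks <- TAX_RANKS   # shallow -> deep
  labels <- matrix(NA_character_, n_genomes, length(ranks),
                   dimnames = list(NULL, ranks))
  parent <- rep(1L, n_genomes)   # all share one superkingdom
  labels[, 1] <- "sk1"
  for (j in seq(2, length(ranks))) {
    child <- integer(n_genomes)
    for (p in unique(parent)) {
      idx <- which(parent == p)
      k <- max(1, min(length(idx), stats::rbinom(1, fanout * 2, 0.5) + 1))
      if (j == length(ranks)) k <- length(idx)   # species unique per genome
      child[idx] <- sample(seq_len(k), length(idx), replace = (j != length(ranks)))
      child[idx] <- child[idx] + p * 1000L
    }
    ids <- as.integer(factor(child))
    labels[, j] <- sprintf("%s%03d", substr(ranks[j], 1, 3), ids)
    parent <- ids
  }
  labels[, "species"] <- sprintf("spe%03d", seq_len(n_genomes))
  # subfamily annotated only within one designated family
  fams <- unique(labels[, "family"])
  keep_fam <- fams[1]
  labels[labels[, "family"] != keep_fam, "subfamily"] <- NA_character_
  shape <- sample(c("icosahedral", "non_icosahedral", "unknown"),
                  n_genomes, replace = TRUE, prob = shape_prob)
  df <- data.frame(genome_id = sprintf("gen%03d", seq_len(n_genomes)),
                   labels, shape = shape, stringsAsFactors = FALSE)
  as_taxonomy(df)
}

#' Simulate a spike-in IP-MS abundance matrix
#'
#' Log-normal intensity model: each protein has a baseline drawn uniformly on
#' log2 `[20, 30]` (the typical MS1 dynamic range); replicate intensities are
#' log-normal around it with coefficient of variation `cv`. The first
#' `n_spikes` proteins are true interactors, shifted upward by
#' `effect_log2fc` in the bait condition. Missingness is
#' missing-not-at-random censoring of all cells below
#' `missingness$mnar_threshold` (log2 scale) plus missing-completely-at-
#' random dropout at rate `missingness$mcar`.
#'
#' @param n_proteins Number of proteins (default 1000).
#' @param n_spikes Number of spiked true interactors (default 50).
#' @param effect_log2fc Spike effect on the log2 scale (default 2, i.e.
#'   4-fold).
#' @param cv Coefficient of variation of replicate intensities (default 0.2).
#' @param missingness List with `mcar` rate and `mnar_threshold` (log2).
#'   The defaults (2% random dropout, censoring below log2 intensity 21)
#'   censor roughly the bottom tenth of the dynamic range, the typical
#'   left-censoring pattern of label-free MS; pass
#'   `list(mcar = 0, mnar_threshold = -Inf)` for a complete matrix.
#' @param n_reps Replicates per condition (default 3, the usual IP-MS
#'   design).
#' @param seed Integer seed.
#' @return List with `matrix` (a `gv_abundance`) and `truth`
#'   (`true_interactors`, `effect_log2fc`, `cv`).
#' @export
simulate_ipms <- function(n_proteins = 1000, n_spikes = 50,
                          effect_log2fc = 2, cv = 0.2,
                          missingness = list(mcar = 0.02,
                                             mnar_threshold = 21),
                          n_reps = 3, seed = 1) {
  stopifnot(n_spikes <= n_proteins, cv > 0)
  mcar <- missingness$mcar %||% 0
  mnar <- missingness$mnar_threshold %||% -Inf
  if (mcar < 0 || mcar >= 1) stop("invalid mcar rate", call. = FALSE)
  withr_seed(seed)
  sdlog2 <- sqrt(log(1 + cv^2)) / log(2)
  base <- runif(n_proteins, 20, 30)
  ids <- sprintf("prot%05d", seq_len(n_proteins))
  spiked <- ids[seq_len(n_spikes)]
  samples <- c(paste0("bait_", seq_len(n_reps)),
               paste0("ctrl_", seq_len(n_reps)))
  cond <- rep(c("bait", "control"), each = n_reps)
  mu <- matrix(base, n_proteins, 2 * n_reps)
  mu[seq_len(n_spikes), cond == "bait"] <-
    mu[seq_len(n_spikes), cond == "bait"] + effect_log2fc
  lg <- mu + matrix(rnorm(n_proteins * 2 * n_reps, 0, sdlog2),
                    n_proteins, 2 * n_reps)
  lg[lg < mnar] <- NA
  if (mcar > 0) lg[runif(length(lg)) < mcar] <- NA
  m <- 2^lg
  m[is.na(m)] <- 0
  dimnames(m) <- list(ids, samples)
  x <- abundance_matrix(m, data.frame(sample_id = samples, condition = cond,
                                      bait_name = "bait1",
                                      stringsAsFactors = FALSE))
  list(matrix = x,
       truth = list(true_interactors = spiked,
                    effect_log2fc = effect_log2fc, cv = cv))
}

#' Simulate chain point clouds with planted interface contacts
#'
#' Places one compact point cloud (radius ~3 Angstrom, about 30 points) per
#' chain, with chain centres separated far enough that non-contacting pairs
#' are more than 10 Angstrom apart; each designated contact pair receives a
#' bridging point pair at a distance drawn uniformly in (4, 8) Angstrom.
#'
#' @param n_chains Number of chains.
#' @param contact_pairs Two-column matrix (or list of length-2 vectors) of
#'   chain indices that must be in contact.
#' @param seed Integer seed.
#' @param n_points Points per chain cloud (default 30).
#' @return List with `chains` (named list `chain id -> coordinate matrix`)
#'   and `truth` (data frame `chain_a, chain_b` of planted contacts).
#' @export
simulate_complexes <- function(n_chains, contact_pairs = NULL, seed = 1,
                               n_points = 30) {
  withr_seed(seed)
  if (is.list(contact_pairs))
    contact_pairs <- do.call(rbind, contact_pairs)
  if (!is.null(contact_pairs) && nrow(contact_pairs) > 0) {
    if (max(contact_pairs) > n_chains || min(contact_pairs) < 1)
      stop("contact pair indexes a chain outside 1..n_chains", call. = FALSE)
  }
  # centres on a circle: adjacent spacing grows with n, pairs stay feasible
  radius <- max(40, 10 * n_chains)
  theta <- 2 * pi * (seq_len(n_chains) - 1) / n_chains
  centres <- cbind(radius * cos(theta), radius * sin(theta), 0)
  min_sep <- if (n_chains > 1)
    min(dist(centres)) else Inf
  if (min_sep < 26)   # 2 * cloud radius (3) + 10 Angstrom clearance + margin
    stop("geometric infeasibility: chains too crowded", call. = FALSE)
  chains <- lapply(seq_len(n_chains), function(i) {
    sweep(matrix(rnorm(n_points * 3, 0, 1.5), n_points, 3), 2,
          centres[i, ], "+")
  })
  names(chains) <- sprintf("chain%02d", seq_len(n_chains))
  truth <- data.frame(chain_a = character(), chain_b = character())
  if (!is.null(contact_pairs) && nrow(contact_pairs) > 0) {
    for (r in seq_len(nrow(contact_pairs))) {
      i <- min(contact_pairs[r, ]); j <- max(contact_pairs[r, ])
      d <- runif(1, 4.5, 7.5)
      mid <- (centres[i, ] + centres[j, ]) / 2
      u <- (centres[j, ] - centres[i, ])
      u <- u / sqrt(sum(u^2))
      pa <- mid - u * d / 2
      pb <- mid + u * d / 2
      # bridge points must stay clear of all other chains
      others <- setdiff(seq_len(n_chains), c(i, j))
      if (length(others)) {
        dmin <- min(sqrt(rowSums(sweep(centres[others, , drop = FALSE], 2,
                                       mid, "-")^2)))
        if (dmin < 18)
          stop("geometric infeasibility: bridge too close to another chain",
               call. = FALSE)
      }
      chains[[i]] <- rbind(chains[[i]], pa)
      chains[[j]] <- rbind(chains[[j]], pb)
      truth <- rbind(truth, data.frame(chain_a = names(chains)[i],
                                       chain_b = names(chains)[j]))
    }
  }
  list(chains = chains, truth = truth)
}
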