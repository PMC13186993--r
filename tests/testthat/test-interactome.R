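mk_abundance <- function(m) {
  abundance_matrix(m, data.frame(
    sample_id = colnames(m),
    condition = rep(c("bait", "control"), each = ncol(m) / 2)))
}

test_that("preprocess_abundance filters, normalises and imputes as specified", {
  set.seed(1)
  m <- 2^matrix(rnorm(8 * 6, 25, 1), 8, 6,
                dimnames = list(paste0("p", 1:8),
                                c("b1", "b2", "b3", "c1", "c2", "c3")))
  # p1: full bait, absent control -> kept, control imputed at the low quantile
  m[1, 4:6] <- 0
  # p2: quantified twice per condition -> dropped under the >=3-of-one rule
  m[2, c(1, 4)] <- 0
  # p3: partially observed in bait -> neighbour-imputed
  m[3, 2] <- 0
  x <- mk_abundance(m)
  pre <- preprocess_abundance(x, min_reps = 3)
  expect_false("p2" %in% rownames(pre$intensities))
  expect_true(all(c("p1", "p3") %in% rownames(pre$intensities)))
  expect_false(anyNA(pre$intensities))
  # condition-wide absence is imputed low in the sample's distribution
  expect_lt(pre$intensities["p1", "c1"],
            median(pre$intensities[, "c1"], na.rm = TRUE))
  # per-sample medians are zero and spreads equalised after median_mad
  pre0 <- preprocess_abundance(x, min_reps = 3, impute = FALSE)
  expect_equal(unname(apply(pre0$intensities, 2, median, na.rm = TRUE)),
               rep(0, 6), tolerance = 1e-9)
  mads <- apply(pre0$intensities, 2, mad, na.rm = TRUE)
  expect_equal(max(mads) - min(mads), 0, tolerance = 1e-9)

  # contaminants removed
  xc <- abundance_matrix(m, x$design, contaminant_ids = "p4")
  prec <- preprocess_abundance(xc, min_reps = 3)
  expect_false("p4" %in% rownames(prec$intensities))

  # no missing values -> imputation is the identity
  full <- mk_abundance(2^matrix(rnorm(5 * 6, 25, 1), 5, 6,
                                dimnames = list(paste0("q", 1:5),
                                                colnames(m))))
  a <- preprocess_abundance(full, normalization = "none")$intensities
  expect_equal(a, log2(full$intensities))
})

test_that("n_quantified records pre-imputation observation counts", {
  m <- 2^matrix(25, 3, 6, dimnames = list(paste0("p", 1:3),
                                          c("b1", "b2", "b3",
                                            "c1", "c2", "c3")))
  m[1, 4:6] <- 0
  m[2, 4] <- 0
  pre <- preprocess_abundance(mk_abundance(m), normalization = "none")
  nq <- attr(pre, "n_quantified")
  expect_equal(unname(nq[c("p1", "p2", "p3"), "control"]), c(0, 2, 3))
  expect_equal(unname(nq[, "bait"]), c(3, 3, 3))
})

test_that("moderated t reduces to the pooled t when d0 is forced to 0", {
  set.seed(21)
  m <- matrix(rnorm(15 * 6, 0, 1), 15, 6,
              dimnames = list(paste0("p", 1:15), paste0("s", 1:6)))
  cond <- rep(c("bait", "control"), each = 3)
  rec <- moderated_t_test(m, cond, d0 = 0)
  for (i in c(1, 7, 15)) {
    expect_equal(rec$t[i], bf_pooled_t(m[i, 1:3], m[i, 4:6]),
                 tolerance = 1e-12)
  }
  expect_equal(unique(rec$df_total), 4)
})

test_that("moderated t matches an independent from-the-formulas oracle", {
  set.seed(22)
  m <- matrix(rnorm(20 * 6, 25, 1), 20, 6,
              dimnames = list(sprintf("p%02d", 1:20), paste0("s", 1:6)))
  m <- m * exp(rep(rnorm(20, 0, 0.5), 6))   # heterogeneous row variances
  cond <- rep(c("bait", "control"), each = 3)
  rec <- moderated_t_test(m, cond)
  d0 <- attr(rec, "d0"); s0 <- attr(rec, "s0_sq")
  # recompute every statistic straight from the published formulas
  for (i in seq_len(20)) {
    x1 <- m[i, 1:3]; x2 <- m[i, 4:6]
    s2 <- (2 * var(x1) + 2 * var(x2)) / 4
    s2p <- (d0 * s0 + 4 * s2) / (d0 + 4)
    tt <- (mean(x1) - mean(x2)) / sqrt(s2p * (1 / 3 + 1 / 3))
    expect_equal(rec$t[i], tt, tolerance = 1e-10)
    expect_equal(rec$p_value[i], 2 * pt(-abs(tt), d0 + 4), tolerance = 1e-10)
  }
})

test_that("moderated t agrees with the reference empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  set.seed(23)
  m <- matrix(rnorm(60 * 6, 25, 1), 60, 6,
              dimnames = list(sprintf("p%02d", 1:60), paste0("s", 1:6)))
  m <- m * exp(rep(rnorm(60, 0, 0.4), 6))
  cond <- rep(c("bait", "control"), each = 3)
  rec <- moderated_t_test(m, cond)
  design <- cbind(control = as.numeric(cond == "control"),
                  bait = as.numeric(cond == "bait"))
  fit <- limma::eBayes(limma::contrasts.fit(limma::lmFit(m, design),
                                            c(-1, 1)))
  expect_equal(attr(rec, "d0"), unname(fit$df.prior), tolerance = 1e-8)
  expect_equal(attr(rec, "s0_sq"), unname(fit$s2.prior), tolerance = 1e-8)
  expect_equal(rec$t, unname(fit$t[, 1]), tolerance = 1e-10)
  expect_equal(rec$p_value, unname(fit$p.value[, 1]), tolerance = 1e-10)
})

test_that("null simulation keeps the type-I error near nominal", {
  sim <- simulate_ipms(n_proteins = 10000, n_spikes = 0, seed = 101,
                       missingness = list(mcar = 0, mnar_threshold = -Inf))
  pre <- preprocess_abundance(sim$matrix)
  rec <- moderated_t_test(pre)
  rate <- mean(rec$p_value < 0.01)
  expect_gte(rate, 0.005)
  expect_lte(rate, 0.02)
})

test_that("selection thresholds and the invalidation rule apply in order", {
  rec <- data.frame(protein_id = c("hit", "low_fc", "low_p", "few_reps"),
                    log2fc = c(1.2, 0.9, 2.0, 2.0),
                    t = 5, p_value = c(0.005, 1e-4, 0.1, 0.001),
                    df_total = 6, s2 = 1, s2_post = 1)
  class(rec) <- c("gv_enrichment", "data.frame")
  nq <- matrix(c(3, 3, 3, 2, 3, 3, 3, 3), 4, 2,
               dimnames = list(rec$protein_id, c("bait", "control")))
  out <- select_interactors(rec, nq)
  sel <- setNames(out$selected, out$protein_id)
  expect_true(sel[["hit"]])
  expect_false(sel[["low_fc"]])    # log2fc 0.9 < 1 despite tiny p
  expect_false(sel[["low_p"]])
  expect_false(sel[["few_reps"]])  # invalidated: 2 bait replicates
  inv <- setNames(out$invalidated, out$protein_id)
  expect_true(inv[["few_reps"]])
  expect_equal(out$p_value[out$protein_id == "few_reps"], 1)
  expect_equal(interactor_set(out), "hit")
})

test_that("selection is monotone in its thresholds, invalidation only removes", {
  set.seed(31)
  n <- 200
  rec <- data.frame(protein_id = paste0("p", 1:n),
                    log2fc = rnorm(n, 0.8, 0.8), t = 0,
                    p_value = runif(n)^2, df_total = 6, s2 = 1, s2_post = 1)
  class(rec) <- c("gv_enrichment", "data.frame")
  nq <- matrix(sample(0:3, 2 * n, TRUE, prob = c(.05, .1, .15, .7)), n, 2,
               dimnames = list(rec$protein_id, c("bait", "control")))
  strict <- select_interactors(rec, nq, lfc_min = 1, p_max = 0.01)
  loose <- select_interactors(rec, nq, lfc_min = 0.5, p_max = 0.05)
  pre_strict <- rec$log2fc >= 1 & rec$p_value < 0.01
  pre_loose <- rec$log2fc >= 0.5 & rec$p_value < 0.05
  expect_true(all(pre_loose[pre_strict]))          # monotone pre-invalidation
  expect_true(all(!strict$selected | pre_strict))  # invalidation only removes
  expect_true(all(strict$adjusted_p >= strict$p_value - 1e-12 |
                    strict$invalidated))
})

test_that("bait network edges satisfy the Nc + 10 Ndc weight formula", {
  inter <- list(A = c("x1", "x2", "x3", "B"), B = c("x1", "x2", "A"),
                C = c("z1"))
  net <- build_bait_network(inter)
  ed <- igraph::as_data_frame(net)
  ab <- ed[ed$from %in% c("A", "B") & ed$to %in% c("A", "B"), ]
  expect_equal(ab$Nc, 2)
  expect_equal(ab$Ndc, 2)        # A lists B and B lists A
  expect_equal(ab$weight, 22)
  # C shares nothing and is direct with nobody -> no incident edge
  expect_equal(igraph::degree(net)[["C"]], 0)
  expect_true(all(ed$weight == ed$Nc + 10 * ed$Ndc))
  expect_true(all(ed$weight > 0))

  # removing one shared prey decreases Nc by exactly 1
  inter2 <- inter; inter2$A <- setdiff(inter2$A, "x1")
  ed2 <- igraph::as_data_frame(build_bait_network(inter2))
  ab2 <- ed2[ed2$from %in% c("A", "B") & ed2$to %in% c("A", "B"), ]
  expect_equal(ab2$Nc, ab$Nc - 1)

  expect_error(build_bait_network(inter, baits = c("A", "A", "B")), "twice")
})

test_that("one-directional detection gives weight Nc + 10", {
  inter <- list(A = c(paste0("s", 1:15)), B = c(paste0("s", 1:15), "A"))
  ed <- igraph::as_data_frame(build_bait_network(inter))
  expect_equal(ed$weight, 15 + 10)
  inter$B <- setdiff(inter$B, "A")
  ed <- igraph::as_data_frame(build_bait_network(inter))
  expect_equal(ed$weight, 15)
})

test_that("Louvain recovers the two printed bait subnetworks", {
  inter <- printed_bait_interactors()
  res <- run_bait_network(inter, seed = 0)
  expect_equal(res$report$n_communities, 2)
  comm <- res$communities
  expect_length(unique(comm[c("R443", "L323", "R595")]), 1)
  expect_length(unique(comm[c("L410", "R721", "R252")]), 1)
  expect_false(comm[["R443"]] == comm[["L410"]])
})

test_that("community detection matches exhaustive modularity maximisation", {
  # two 3-cliques joined by one weight-1 bridge
  el <- data.frame(
    from = c("a", "a", "b", "d", "d", "e", "c"),
    to   = c("b", "c", "c", "e", "f", "f", "d"),
    weight = c(5, 5, 5, 5, 5, 5, 1))
  g <- igraph::graph_from_data_frame(el, directed = FALSE)
  got <- detect_communities(g, seed = 0)
  nodes <- igraph::V(g)$name
  best_q <- -Inf; best <- NULL
  for (p in all_partitions(length(nodes))) {
    q <- igraph::modularity(g, p, weights = igraph::E(g)$weight)
    if (q > best_q) { best_q <- q; best <- p }
  }
  names(best) <- nodes
  expect_equal(igraph::modularity(g, as.integer(factor(got[nodes])),
                                  weights = igraph::E(g)$weight),
               best_q, tolerance = 1e-12)
  expect_true(same_partition(got, setNames(as.character(best), nodes)))
  expect_equal(length(unique(got)), 2)

  # a single equal-weight triangle is one community
  tri <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "b", "c"), to = c("b", "c", "a"), weight = 1),
    directed = FALSE)
  expect_equal(length(unique(detect_communities(tri, seed = 0))), 1)
})

test_that("disconnected components are never co-clustered", {
  set.seed(17)
  for (rep in 1:5) {
    n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
    v1 <- paste0("u", 1:n1); v2 <- paste0("v", 1:n2)
    el <- rbind(
      data.frame(from = sample(v1, 6, TRUE), to = sample(v1, 6, TRUE)),
      data.frame(from = sample(v2, 6, TRUE), to = sample(v2, 6, TRUE)))
    el <- el[el$from != el$to, ]
    el$weight <- sample(1:5, nrow(el), TRUE)
    g <- igraph::simplify(igraph::graph_from_data_frame(el, directed = FALSE))
    comm <- detect_communities(g, seed = rep)
    expect_equal(length(intersect(comm[intersect(v1, names(comm))],
                                  comm[intersect(v2, names(comm))])), 0)
  }
})

test_that("global network attaches regions with the documented precedence", {
  inter <- list(B1 = c("vm", "vn", "host1", "plain"), B2 = c("vm"))
  regions <- data.frame(protein = c("vm", "vm", "vn", "host1"),
                        region = c("virion", "membrane", "nucleoid",
                                   "virion"))
  g <- assemble_global_network(inter, regions, host_proteins = "host1",
                               expression = c(vm = "GV4"))
  at <- igraph::vertex_attr(g)
  reg <- setNames(at$region, at$name)
  expect_equal(reg[["vm"]], "membrane")     # membrane beats virion
  expect_equal(reg[["host1"]], "host")      # host dominates any label
  expect_equal(reg[["plain"]], "virion_unassigned")
  expect_equal(setNames(at$expression, at$name)[["vm"]], "GV4")
  # edge count equals the sum of interactor-set sizes
  expect_equal(igraph::ecount(g), length(inter$B1) + length(inter$B2))
})
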