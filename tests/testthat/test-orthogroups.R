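mk_edges <- function(q, t, score = 0.9, cov = 0.9, kind = "sequence") {
  similarity_edges(q, t, score = rep_len(score, length(q)),
                   qcov = rep_len(cov, length(q)),
                   tcov = rep_len(cov, length(q)), kind = kind)
}

test_that("cluster_greedy handles empty input, triangles and the coverage filter", {
  empty <- mk_edges(character(), character())
  cl <- cluster_greedy(empty, 0.2, 0.7, c("a", "b", "c"))
  expect_equal(n_clusters(cl), 3)

  tri <- mk_edges(c("a", "b", "a"), c("b", "c", "c"))
  cl <- cluster_greedy(tri, 0.2, 0.7, c("a", "b", "c"))
  expect_equal(n_clusters(cl), 1)

  # one-sided coverage below threshold discards the edge entirely
  low <- similarity_edges("a", "b", 0.9, qcov = 0.60, tcov = 0.95)
  cl <- cluster_greedy(low, 0.2, 0.7, c("a", "b"))
  expect_equal(n_clusters(cl), 2)

  expect_error(cluster_greedy(tri, 0.2, 0.7, c("a", "b")), "universe")
})

test_that("cluster_greedy output is always a partition (property)", {
  set.seed(7)
  for (rep in 1:10) {
    universe <- paste0("p", 1:30)
    n <- 40
    ed <- similarity_edges(sample(universe, n, TRUE), sample(universe, n, TRUE),
                           score = runif(n), qcov = runif(n), tcov = runif(n))
    cl <- cluster_greedy(ed, 0.2, 0.7, universe)
    expect_setequal(names(cl$assignment), universe)
    expect_true(all(cl$assignment[cl$representatives] ==
                      names(cl$representatives)))
    cc <- cluster_greedy(ed, 0.2, 0.7, universe, method = "components")
    # set-cover refines connected components: cluster count never smaller
    expect_gte(n_clusters(cl), n_clusters(cc))
  }
})

test_that("compose_two_stage equals direct relabelling and shrinks counts", {
  seq_cl <- clustering_from_groups(list(g1 = c("a", "b"), g2 = c("c", "d"),
                                        g3 = c("e")))
  reps <- unname(seq_cl$representatives)
  # structure stage joins the reps of g1 and g2
  struct <- clustering_from_groups(list(s1 = reps[1:2], s2 = reps[3]))
  comp <- compose_two_stage(seq_cl, struct)
  expect_equal(n_clusters(comp), 2)
  # oracle: relabel each member by its representative's structural cluster
  oracle <- struct$assignment[seq_cl$representatives[seq_cl$assignment]]
  names(oracle) <- names(seq_cl$assignment)
  expect_true(same_partition(comp$assignment, oracle))
  expect_lte(n_clusters(comp), n_clusters(seq_cl))

  # all-singleton structure stage is the identity
  singl <- clustering_from_groups(setNames(as.list(reps), reps))
  id <- compose_two_stage(seq_cl, singl)
  expect_true(same_partition(id$assignment, seq_cl$assignment))

  bad <- clustering_from_groups(list(s1 = reps[1:2]))
  expect_error(compose_two_stage(seq_cl, bad), "absent")
})

test_that("link_fraction matches its definition on crafted clusters", {
  a <- sprintf("a%03d", 1:100)
  b <- sprintf("b%03d", 1:10)
  # exactly 69 members of a have >= 1 link into b
  ed <- mk_edges(a[1:69], rep(b, length.out = 69), kind = "structure")
  expect_equal(link_fraction(a, b, ed), 0.69)
  expect_equal(link_fraction(a, b, mk_edges(character(), character())), 0)
  full <- mk_edges(rep(a, each = length(b)), rep(b, times = length(a)),
                   kind = "structure")
  expect_equal(link_fraction(a, b, full), 1.0)
  # undirected: reversed edges count too
  rev_ed <- mk_edges(rep(b, length.out = 69), a[1:69], kind = "structure")
  expect_equal(link_fraction(a, b, rev_ed), 0.69)
  expect_error(link_fraction(character(), b, ed), "empty")
})

test_that("merge_clusters reproduces the four-pair worked example", {
  # four cluster pairs whose one-directional link fractions realise the
  # printed minimum connected percentages: 96, 96, 69, 96
  fracs <- c(0.96, 0.96, 0.69, 0.96)
  groups <- list(); edges <- NULL
  for (i in seq_along(fracs)) {
    a <- sprintf("p%d_a%03d", i, 1:100)
    b <- sprintf("p%d_b%02d", i, 1:5)
    groups[[paste0("A", i)]] <- a
    groups[[paste0("B", i)]] <- b
    n_link <- round(fracs[i] * 100)
    e <- mk_edges(a[seq_len(n_link)], rep(b, length.out = n_link),
                  kind = "structure")
    edges <- if (is.null(edges)) e else validate_edges(rbind(edges, e))
  }
  cl <- clustering_from_groups(groups)
  res <- merge_clusters(cl, edges, threshold = 0.65)
  expect_equal(sum(res$events$merged), 4)
  expect_equal(n_clusters(res$clustering), 4)
  # the A-side (100-member) clusters realise the printed fractions
  got <- res$events
  a_side <- ifelse(startsWith(got$cluster_a, "p") &
                     grepl("_a", got$cluster_a),
                   got$fraction_a_to_b, got$fraction_b_to_a)
  expect_setequal(round(a_side, 2), unique(fracs))
})

test_that("merge_clusters threshold semantics and transitivity", {
  groups <- list(A = paste0("a", 1:4), B = paste0("b", 1:4),
                 C = paste0("c", 1:4))
  cl <- clustering_from_groups(groups)
  # A->B eligible (4/4), B->C eligible (4/4), A-C unlinked
  ed <- mk_edges(c(groups$A, groups$B), c(rep("b1", 4), rep("c1", 4)),
                 kind = "structure")
  res <- merge_clusters(cl, ed, threshold = 0.65)
  expect_equal(n_clusters(res$clustering), 1)

  # threshold 1.0 can never be strictly exceeded -> identity
  res1 <- merge_clusters(cl, ed, threshold = 1.0)
  expect_true(same_partition(res1$clustering$assignment, cl$assignment))

  # strict inequality: a fraction exactly at the threshold does not merge
  ed65 <- mk_edges(paste0("a", 1:2), c("b1", "b2"), kind = "structure")
  res65 <- merge_clusters(clustering_from_groups(groups[c("A", "B")]),
                          ed65, threshold = 0.5)
  expect_equal(sum(res65$events$merged), 0)
})

test_that("merge_clusters matches brute-force transitive closure (property)", {
  set.seed(11)
  for (rep in 1:8) {
    n_cl <- sample(3:5, 1)
    groups <- lapply(seq_len(n_cl), function(i)
      sprintf("c%d_p%02d", i, seq_len(sample(2:6, 1))))
    names(groups) <- paste0("cl", seq_len(n_cl))
    universe <- unlist(groups)
    n <- 25
    ed <- mk_edges(sample(universe, n, TRUE), sample(universe, n, TRUE),
                   kind = "structure")
    cl <- clustering_from_groups(groups)
    res <- merge_clusters(cl, ed, threshold = 0.65)
    oracle <- bf_merge_partition(groups, ed, 0.65)
    expect_true(same_partition(res$clustering$assignment, oracle))
    # a second pass on the merged output can only merge further, never split
    res2 <- merge_clusters(res$clustering, ed, threshold = 0.65)
    expect_lte(n_clusters(res2$clustering), n_clusters(res$clustering))
    expect_lte(n_clusters(res$clustering), n_clusters(cl))
    # with a threshold above the largest observed fraction nothing merges
    fmax <- max(c(res$events$fraction_a_to_b, res$events$fraction_b_to_a, 0))
    if (fmax < 1) {
      keep <- merge_clusters(cl, ed, threshold = min(fmax + 1e-9, 1))
      expect_equal(n_clusters(keep$clustering), n_clusters(cl))
    }
  }
})

test_that("NMI has the right fixed points and closed-form values", {
  ab_cd <- clustering_from_groups(list(g1 = c("a", "b"), g2 = c("c", "d")))
  ac_bd <- clustering_from_groups(list(g1 = c("a", "c"), g2 = c("b", "d")))
  expect_equal(compare_clusterings_nmi(ab_cd, ab_cd), 1.0)
  # hand enumeration: all four cells of the contingency table equal 1,
  # so I(U;V) = 0 and the arithmetic-mean normalised score is 0
  expect_equal(compare_clusterings_nmi(ab_cd, ac_bd), 0.0)

  ids <- paste0("p", 1:10)
  one <- clustering_from_groups(list(g = ids))
  singletons <- clustering_from_groups(setNames(as.list(ids), ids))
  expect_equal(compare_clusterings_nmi(one, singletons), 0.0)
  expect_equal(compare_clusterings_nmi(singletons, singletons), 1.0)

  other <- clustering_from_groups(list(g1 = c("x", "y")))
  expect_error(compare_clusterings_nmi(ab_cd, other), "share no proteins")
})

test_that("NMI agrees with the igraph implementation on random partitions", {
  set.seed(5)
  ids <- paste0("p", 1:40)
  for (rep in 1:10) {
    m1 <- setNames(sample(letters[1:5], 40, TRUE), ids)
    m2 <- setNames(sample(letters[1:4], 40, TRUE), ids)
    mine <- compare_clusterings_nmi(clustering_from_membership(m1),
                                    clustering_from_membership(m2))
    ref <- igraph::compare(as.integer(factor(m1)), as.integer(factor(m2)),
                           method = "nmi")
    expect_equal(mine, ref, tolerance = 1e-12)
    # symmetry
    expect_equal(mine,
                 compare_clusterings_nmi(clustering_from_membership(m2),
                                         clustering_from_membership(m1)))
  }
})
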