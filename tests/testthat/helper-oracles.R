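# Independent brute-force oracles used across the suite. These deliberately
# re-derive results from first principles (loops, enumeration, closed forms)
# rather than reusing package internals.

# clustering from a named list group_id -> member ids (rep = first member)
clustering_from_groups <- function(groups) {
  assignment <- character(0)
  reps <- character(0)
  for (g in names(groups)) {
    rep <- sort(groups[[g]])[1]
    assignment[groups[[g]]] <- rep
    reps[rep] <- rep
  }
  new_clustering(assignment, reps)
}

clustering_from_membership <- function(membership) {
  clustering_from_groups(split(names(membership), membership))
}

# TRUE iff two label vectors over the same elements induce the same partition
same_partition <- function(a, b) {
  b <- b[names(a)]
  identical(unname(tapply(names(a), a, function(v) paste(sort(v), collapse = "|"))[
              order(tapply(names(a), a, function(v) sort(v)[1]))]),
            unname(tapply(names(b), b, function(v) paste(sort(v), collapse = "|"))[
              order(tapply(names(b), b, function(v) sort(v)[1]))]))
}

# per-protein loop version of the link fraction
bf_link_fraction <- function(a, b, edges) {
  linked <- 0
  for (p in a) {
    hit <- any(edges$query == p & edges$target %in% b) ||
      any(edges$target == p & edges$query %in% b)
    if (hit) linked <- linked + 1
  }
  linked / length(a)
}

# brute-force merge: all pair fractions, then naive transitive closure
bf_merge_partition <- function(members, edges, threshold) {
  ids <- names(members)
  n <- length(ids)
  comp <- seq_len(n)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      f <- max(bf_link_fraction(members[[i]], members[[j]], edges),
               bf_link_fraction(members[[j]], members[[i]], edges))
      if (f > threshold) comp[comp == comp[j]] <- comp[i]
    }
  }
  out <- character(0)
  for (i in seq_len(n)) out[members[[i]]] <- paste0("m", comp[i])
  out
}

# shallow-to-deep rank scan keeping the deepest shared non-absent taxon
bf_lca <- function(genomes, taxonomy) {
  best <- list(rank = "none", taxon = NA_character_)
  for (r in c("superkingdom", "phylum", "class", "order", "family",
              "subfamily", "genus", "species")) {
    vals <- taxonomy[genomes, r]
    if (!anyNA(vals) && length(unique(vals)) == 1)
      best <- list(rank = r, taxon = vals[1])
  }
  best
}

# all set partitions of n elements as restricted growth strings
all_partitions <- function(n) {
  res <- list()
  rec <- function(s, m) {
    if (length(s) == n) {
      res[[length(res) + 1]] <<- s
      return(invisible())
    }
    for (v in seq_len(m + 1)) rec(c(s, v), max(m, v))
  }
  rec(integer(0), 0L)
  res
}

# exact Fisher p by direct enumeration of all tables with the fixed margins,
# probabilities from factorials (independent of dhyper)
bf_fisher_p <- function(a, b, c, d, alternative = "two_sided") {
  m1 <- a + b; m2 <- c + d; n1 <- a + c; n <- m1 + m2
  prob <- function(x) {
    if (x < 0 || x > m1 || n1 - x < 0 || n1 - x > m2) return(0)
    exp(lchoose(m1, x) + lchoose(m2, n1 - x) - lchoose(n, n1))
  }
  xs <- 0:n1
  ps <- vapply(xs, prob, numeric(1))
  p_obs <- prob(a)
  switch(alternative,
         greater = sum(ps[xs >= a]),
         less = sum(ps[xs <= a]),
         two_sided = sum(ps[ps <= p_obs * (1 + 1e-7)]))
}

# ordinary pooled two-sample t statistic
bf_pooled_t <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  s2 <- ((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2)
  (mean(x1) - mean(x2)) / sqrt(s2 * (1 / n1 + 1 / n2))
}

# O(n * m) min-distance scan over all point pairs
bf_min_distance <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b)))
    best <- min(best, sqrt(sum((a[i, ] - b[j, ])^2)))
  best
}

# the six printed shared-interactor counts of the bait summary network,
# realised as synthetic interactor sets with the stated overlaps
printed_bait_interactors <- function() {
  shared <- list(c("R443", "L323", 6), c("R443", "R595", 3),
                 c("L323", "R595", 15), c("L410", "R721", 34),
                 c("L410", "R252", 13), c("R721", "R252", 15))
  inter <- setNames(vector("list", 6),
                    c("R443", "L323", "R595", "L410", "R721", "R252"))
  inter[] <- list(character(0))
  for (s in shared) {
    ids <- sprintf("%s_%s_prey%02d", s[1], s[2], seq_len(as.integer(s[3])))
    inter[[s[1]]] <- c(inter[[s[1]]], ids)
    inter[[s[2]]] <- c(inter[[s[2]]], ids)
  }
  inter
}

truth_clustering <- function(sim) clustering_from_membership(sim$truth$group_of)
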