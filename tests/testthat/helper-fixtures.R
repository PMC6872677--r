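# Shared fixtures and independent oracles.

# the 3-tip worked tree used throughout: ((A:1,B:1):1,C:2);
worked_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,C:2);")
}

toy_counts <- function() {
  m <- matrix(c(4L, 1L, 0L,
                0L, 3L, 2L,
                5L, 0L, 5L), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), c("A", "B", "C")))
  m
}

# independent naive Bray-Curtis: direct formula, no vegan
naive_bray <- function(x, y) sum(abs(x - y)) / sum(x + y)

# independent naive betaMNTD: explicit double loop over taxa, written
# without reference to the package implementation
naive_bmntd <- function(x, y, pd, weighted = TRUE) {
  ix <- names(x)[x > 0]
  iy <- names(y)[y > 0]
  fx <- if (weighted) x[ix] / sum(x[ix]) else rep(1 / length(ix), length(ix))
  fy <- if (weighted) y[iy] / sum(y[iy]) else rep(1 / length(iy), length(iy))
  s1 <- 0
  for (k in seq_along(ix)) {
    best <- Inf
    for (l in seq_along(iy)) best <- min(best, pd[ix[k], iy[l]])
    s1 <- s1 + fx[k] * best
  }
  s2 <- 0
  for (l in seq_along(iy)) {
    best <- Inf
    for (k in seq_along(ix)) best <- min(best, pd[iy[l], ix[k]])
    s2 <- s2 + fy[l] * best
  }
  unname(0.5 * (s1 + s2))
}

# random small community + tree instance for oracle equivalence checks
random_instance <- function(n_taxa, n_samples = 3) {
  tree <- ape::rtree(n_taxa, rooted = TRUE)
  tree$edge.length <- stats::rexp(nrow(tree$edge))
  tree$tip.label <- paste0("T", seq_len(n_taxa))
  counts <- matrix(0L, n_samples, n_taxa,
                   dimnames = list(paste0("s", seq_len(n_samples)),
                                   tree$tip.label))
  for (s in seq_len(n_samples)) {
    k <- sample(2:n_taxa, 1)
    pick <- sample(n_taxa, k)
    counts[s, pick] <- as.integer(stats::rpois(k, 4) + 1L)
  }
  list(tree = tree, counts = counts)
}

small_bundle <- function(regime = "drift", seed = 1L, n_taxa = 60,
                         depth = 500) {
  generate_bundle(scenario_config(regime = regime, n_taxa = n_taxa,
                                  depth = depth, seed = seed))
}
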