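test_that("patristic distances match hand-computed path sums", {
  tree <- worked_tree()
  pd <- patristic_matrix(tree)
  expect_equal(pd["A", "B"], 2)
  expect_equal(pd["A", "C"], 4)
  expect_equal(pd["B", "C"], 4)
  expect_true(isSymmetric(pd))
  expect_true(all(diag(pd) == 0))

  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  ps <- patristic_matrix(star)
  expect_true(all(ps[upper.tri(ps)] == 2))
})

test_that("betaMNTD matches hand evaluation and degenerate identities", {
  tree <- worked_tree()
  pd <- patristic_matrix(tree)
  cnt <- function(...) stats::setNames(as.numeric(c(...)), c("A", "B", "C"))

  expect_equal(bmntd(cnt(1, 0, 0), cnt(0, 0, 1), pd), 4)
  expect_equal(bmntd(cnt(2, 3, 1), cnt(1, 5, 2), pd), 0)  # same taxon sets
  # weighted equals unweighted when abundances are equal
  expect_equal(bmntd(cnt(1, 1, 0), cnt(0, 1, 1), pd, weighted = TRUE),
               bmntd(cnt(1, 1, 0), cnt(0, 1, 1), pd, weighted = FALSE))
  expect_error(bmntd(cnt(0, 0, 0), cnt(1, 0, 0), pd), "empty")
})

test_that("optimized betaMNTD equals the brute-force oracle on random instances", {
  set.seed(77)
  for (i in 1:50) {
    inst <- random_instance(sample(4:8, 1))
    pd <- patristic_matrix(inst$tree)
    for (w in c(TRUE, FALSE)) {
      bn <- bnti_matrix(inst$counts, inst$tree, n_null = 99, weighted = w,
                        seed = i)
      obs <- as.matrix(bn$bmntd_obs)
      for (a in 1:2) for (b in (a + 1):3) {
        expect_equal(obs[a, b],
                     naive_bmntd(inst$counts[a, ], inst$counts[b, ], pd, w),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("the tip-shuffling null matches a naive per-iteration recomputation", {
  set.seed(99)
  inst <- random_instance(7)
  K <- 7
  n_null <- 199
  bn <- bnti_matrix(inst$counts, inst$tree, n_null = n_null, seed = 31)
  pd <- patristic_matrix(inst$tree)

  # replay the same permutation stream and recompute naively
  set.seed(31)
  perms <- matrix(0L, n_null + 1L, K)
  perms[1L, ] <- seq_len(K)
  for (i in seq_len(n_null)) perms[i + 1L, ] <- sample.int(K)
  naive_null <- matrix(0, 3, n_null)
  pairs <- utils::combn(3, 2)
  naive_null <- array(0, c(ncol(pairs), n_null))
  for (it in seq_len(n_null)) {
    p <- perms[it + 1L, ]
    pdp <- pd[p, p]
    dimnames(pdp) <- dimnames(pd)
    for (j in seq_len(ncol(pairs))) {
      naive_null[j, it] <- naive_bmntd(inst$counts[pairs[1, j], ],
                                       inst$counts[pairs[2, j], ], pdp)
    }
  }
  expect_equal(as.vector(bn$null_mean), rowMeans(naive_null), tolerance = 1e-12)
  expect_equal(as.vector(bn$null_sd), apply(naive_null, 1, sd),
               tolerance = 1e-12)
})

test_that("betaMNTD agrees with an independent library implementation", {
  set.seed(55)
  inst <- random_instance(8, n_samples = 4)
  bn <- bnti_matrix(inst$counts, inst$tree, n_null = 99, weighted = TRUE,
                    seed = 1)
  ref <- as.matrix(picante::comdistnt(inst$counts,
                                      patristic_matrix(inst$tree),
                                      abundance.weighted = TRUE))
  got <- as.matrix(bn$bmntd_obs)
  expect_equal(got, ref[rownames(got), colnames(got)], tolerance = 1e-10)
})

test_that("betaNTI is invariant to uniform branch-length scaling", {
  inst <- random_instance(8, n_samples = 4)
  tree2 <- inst$tree
  tree2$edge.length <- tree2$edge.length * 7.3
  b1 <- bnti_matrix(inst$counts, inst$tree, n_null = 199, seed = 5)
  b2 <- bnti_matrix(inst$counts, tree2, n_null = 199, seed = 5)
  expect_equal(as.vector(b1$bnti), as.vector(b2$bnti), tolerance = 1e-10)
})

test_that("identical communities give zero observed turnover and non-positive betaNTI", {
  b <- small_bundle(seed = 21, n_taxa = 40, depth = 300)
  counts <- b$counts[rep(1, 4), ]
  rownames(counts) <- paste0("s", 1:4)
  expect_warning(bn <- bnti_matrix(counts, b$tree, n_null = 99, seed = 1),
                 "degenerate")
  expect_true(all(as.vector(bn$bmntd_obs) == 0))
  expect_true(all(is.na(as.vector(bn$bnti))))
})

test_that("RC_bray sits at the extremes for extreme configurations and is bounded", {
  set.seed(33)
  # duplicated sample in a diverse pool: observed BC = 0, null almost surely > 0
  b <- small_bundle(seed = 22, n_taxa = 80, depth = 600)
  counts <- b$counts[1:6, ]
  counts[2, ] <- counts[1, ]
  rownames(counts) <- paste0("s", 1:6)
  rc <- as.matrix(rc_bray_matrix(counts, n_null = 199, seed = 3))
  expect_lt(rc["s1", "s2"], -0.95)

  # two samples on disjoint halves of a large pool: observed BC = 1
  K <- 60
  half <- matrix(0L, 6, K, dimnames = list(paste0("s", 1:6), paste0("o", 1:K)))
  for (s in 1:3) half[s, 1:30] <- as.integer(rpois(30, 5) + 1L)
  for (s in 4:6) half[s, 31:60] <- as.integer(rpois(30, 5) + 1L)
  rc2 <- as.matrix(rc_bray_matrix(half, n_null = 199, seed = 4))
  expect_gt(rc2["s1", "s4"], 0.95)
  expect_true(all(rc2 >= -1 & rc2 <= 1))

  expect_error(rc_bray_matrix(half[1, , drop = FALSE]), "at least 2")
})

test_that("RC_bray is deterministic under seed", {
  b <- small_bundle(seed = 23, n_taxa = 50, depth = 400)
  r1 <- rc_bray_matrix(b$counts[1:5, ], n_null = 99, seed = 9)
  r2 <- rc_bray_matrix(b$counts[1:5, ], n_null = 99, seed = 9)
  expect_identical(as.vector(r1), as.vector(r2))
})

test_that("process classification applies the two-step rule", {
  expect_equal(as.character(classify_process(2.5, 0)), "heterogeneous_selection")
  expect_equal(as.character(classify_process(-2.5, 0)), "homogeneous_selection")
  expect_equal(as.character(classify_process(0.5, 0.97)), "dispersal_limitation")
  expect_equal(as.character(classify_process(-1.0, -0.96)), "homogenizing_dispersal")
  expect_equal(as.character(classify_process(0, 0.2)), "drift")
  expect_true(is.na(classify_process(NA, 0.5)))
  expect_true(is.na(classify_process(0.1, NA)))
  # vectorised and threshold-configurable
  lab <- classify_process(c(3, -3, 0, 0, 0), c(0, 0, 0.99, -0.99, 0))
  expect_equal(as.character(lab),
               c("heterogeneous_selection", "homogeneous_selection",
                 "dispersal_limitation", "homogenizing_dispersal", "drift"))
  expect_equal(as.character(classify_process(2.5, 0, bnti_threshold = 3)),
               "drift")
})

test_that("process summaries are proper fractions over the right pair sets", {
  pairs <- tibble::tibble(
    sample_a = c("a1", "a1", "a2", "b1", "a1"),
    sample_b = c("a2", "a3", "a3", "b2", "b1"),
    process = factor(c("drift", "drift", "dispersal_limitation", "drift", NA),
                     levels = levels(classify_process(numeric(0), numeric(0))))
  )
  grouping <- c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B")
  s <- summarize_processes(pairs, grouping)
  sA <- s[s$group == "A", ]
  expect_equal(sum(sA$fraction), 1)
  expect_equal(sA$fraction[sA$process == "drift"], 2 / 3)
  expect_equal(unique(sA$n_pairs), 3L)
  sB <- s[s$group == "B", ]
  expect_equal(sB$fraction[sB$process == "drift"], 1)

  all_drift <- pairs
  all_drift$process[] <- "drift"
  s2 <- summarize_processes(all_drift, grouping)
  expect_true(all(s2$fraction[s2$process == "drift"] == 1))
  expect_true(all(s2$fraction[s2$process != "drift"] == 0))
})

test_that("run_assembly is deterministic and partitions every pair", {
  b <- small_bundle(seed = 24, n_taxa = 50, depth = 400)
  counts <- b$counts[1:8, ]
  r1 <- run_assembly(counts, b$tree, b$meta[1:8, ], n_null = 99, seed = 2)
  r2 <- run_assembly(counts, b$tree, b$meta[1:8, ], n_null = 99, seed = 2)
  expect_identical(r1$pairs, r2$pairs)
  expect_equal(nrow(r1$pairs), choose(8, 2))
  expect_true(all(!is.na(r1$pairs$process) | is.na(r1$pairs$bnti)))
  g <- glance(r1)
  expect_equal(g$n_pairs, 28L)
  expect_identical(tidy(r1), r1$pairs)
})

test_that("doubling the null count barely moves betaNTI (Monte-Carlo stability)", {
  b <- small_bundle(seed = 25, n_taxa = 60, depth = 500)
  counts <- b$counts[1:5, ]
  b1 <- bnti_matrix(counts, b$tree, n_null = 999, seed = 1)
  b2 <- bnti_matrix(counts, b$tree, n_null = 1998, seed = 2)
  expect_lt(max(abs(as.vector(b1$bnti) - as.vector(b2$bnti)), na.rm = TRUE), 0.3)
})
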