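test_that("community and environment transforms match their definitions", {
  expect_equal(transform_community(matrix(0, 1, 1,
    dimnames = list("s", "o")))[1, 1], 0)
  expect_equal(transform_community(matrix(1L, 1, 1,
    dimnames = list("s", "o")))[1, 1], log(2))
  m <- matrix(c(0L, 3L, 9L), 1, dimnames = list("s", c("a", "b", "c")))
  expect_true(all(diff(transform_community(m)[1, ]) > 0))

  env <- tibble::tibble(salinity = 25, pH = 8.1, Cd = 0.04)
  t <- transform_env(env)
  expect_equal(t$salinity, 5)
  expect_equal(t$pH, 8.1)
  expect_equal(t$Cd, sqrt(0.04))
  expect_error(transform_env(tibble::tibble(Cd = -0.2)), "Cd")
})

test_that("Bray-Curtis matches the direct formula", {
  m <- rbind(x = c(1, 2), y = c(2, 1))
  colnames(m) <- c("o1", "o2")
  expect_equal(as.vector(bray_curtis(m)), 1 / 3)

  ident <- rbind(a = c(3, 1, 0), b = c(3, 1, 0))
  colnames(ident) <- paste0("o", 1:3)
  expect_equal(as.vector(bray_curtis(ident)), 0)

  disj <- rbind(a = c(3, 1, 0, 0), b = c(0, 0, 2, 5))
  colnames(disj) <- paste0("o", 1:4)
  expect_equal(as.vector(bray_curtis(disj)), 1)

  set.seed(2)
  r <- matrix(rpois(40, 3), 4, dimnames = list(paste0("s", 1:4), paste0("o", 1:10)))
  r[1, ] <- r[1, ] + 1L
  got <- as.matrix(bray_curtis(r))
  expect_equal(got["s1", "s2"], naive_bray(r[1, ], r[2, ]))
  expect_equal(got["s3", "s4"], naive_bray(r[3, ], r[4, ]))

  zero <- rbind(a = c(0, 0), b = c(1, 2))
  colnames(zero) <- c("o1", "o2")
  expect_error(bray_curtis(zero), "all-zero")
})

test_that("NMDS recovers a Euclidean configuration with near-zero stress", {
  set.seed(3)
  pts <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("s", 1:10), NULL))
  d <- dist(pts)
  fit <- run_nmds(d, k = 2, n_restarts = 10, seed = 1)
  expect_lt(fit$stress, 0.01)
  expect_true(all(is.finite(as.matrix(fit$points[, -1]))))

  fit2 <- run_nmds(d, k = 2, n_restarts = 10, seed = 1)
  expect_identical(fit$points, fit2$points)

  # duplicated samples embed at (nearly) the same spot
  pts2 <- rbind(pts, s11 = pts[1, ])
  d2 <- dist(pts2)
  fit3 <- run_nmds(d2, k = 2, n_restarts = 10, seed = 2)
  xy <- as.matrix(fit3$points[, c("NMDS1", "NMDS2")])
  span <- max(dist(xy))
  expect_lt(sqrt(sum((xy[1, ] - xy[11, ])^2)), 0.01 * span)

  expect_error(run_nmds(dist(pts[1:3, ]), k = 2), "k \\+ 2")
  g <- glance(fit)
  expect_equal(g$k, 2)
  expect_true(is.finite(g$stress))
})

test_that("ANOSIM equals 1 for perfectly separated groups, including the hand-ranked case", {
  # 4 samples, 2+2: within distances 1,1; between distances 5,5,5,5
  m <- matrix(5, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  diag(m) <- 0
  m[1, 2] <- m[2, 1] <- 1
  m[3, 4] <- m[4, 3] <- 1
  res <- anosim_test(as.dist(m), c("a", "a", "b", "b"), n_perm = 999, seed = 1)
  expect_equal(res$statistic, 1)
  expect_gt(res$p_value, 0)

  set.seed(4)
  within <- matrix(rnorm(20, 0, 0.1), 10, 2)
  pts <- rbind(within[1:5, ], within[6:10, ] + 10)
  rownames(pts) <- paste0("s", 1:10)
  res2 <- anosim_test(dist(pts), rep(c("a", "b"), each = 5),
                      n_perm = 999, seed = 2)
  expect_equal(res2$statistic, 1)
  expect_lte(res2$p_value, 0.05)

  expect_error(anosim_test(dist(pts), c(rep("a", 9), "b")), "at least 2")
  td <- tidy(res2)
  expect_equal(td$statistic, 1)
})

test_that("ANOSIM R is invariant to monotone transforms of the distances", {
  set.seed(5)
  pts <- matrix(rnorm(24), 12, 2, dimnames = list(paste0("s", 1:12), NULL))
  d <- dist(pts)
  g <- rep(c("a", "b"), each = 6)
  r1 <- anosim_test(d, g, n_perm = 99, seed = 1)$statistic
  r2 <- anosim_test(d^2, g, n_perm = 99, seed = 1)$statistic
  r3 <- anosim_test(sqrt(d), g, n_perm = 99, seed = 1)$statistic
  expect_equal(r1, r2)
  expect_equal(r1, r3)
})

test_that("Mantel tests recover identity and anti-identity", {
  set.seed(6)
  d1 <- dist(matrix(rnorm(30), 10))
  expect_equal(mantel_test(d1, d1, n_perm = 99, seed = 1)$statistic, 1)

  # a decreasing monotone transform reverses every rank
  d_rev <- max(d1) + 1 - d1
  expect_equal(mantel_test(d1, d_rev, n_perm = 99, seed = 1,
                           method = "spearman")$statistic, -1)

  const <- d1; const[] <- 2
  expect_error(mantel_test(d1, const), "constant")
})

test_that("partial Mantel controls for a third matrix", {
  set.seed(7)
  n <- 15
  # d2 = noisy copy of d1; d3 independent
  base <- matrix(rnorm(n * 3), n)
  d1 <- dist(base)
  d2 <- dist(base + matrix(rnorm(n * 3, 0, 0.2), n))
  d3 <- dist(matrix(rnorm(n * 3), n))
  r12 <- mantel_test(d1, d2, n_perm = 99, seed = 1)$statistic
  r123 <- partial_mantel_test(d1, d2, d3, n_perm = 99, seed = 1)$statistic
  expect_lt(abs(r12 - r123), 0.1)

  expect_error(partial_mantel_test(d1, d2, d1), "degenerate")

  # d2 (almost) purely a function of d3: controlling for d3 wipes the
  # correlation; an exactly collinear control is rejected
  d3b <- dist(matrix(rnorm(n * 3), n))
  d2b <- d3b * 2 + abs(rnorm(length(d3b), 0, 1e-3 * mean(d3b)))
  r <- partial_mantel_test(d1, d2b, d3b, n_perm = 99, seed = 1)$statistic
  expect_lt(abs(r), 0.15)
  expect_error(partial_mantel_test(d1, d3b * 2, d3b), "degenerate")
})

test_that("geographic distances match great-circle geometry", {
  meta <- tibble::tibble(sample_id = c("a", "b"), habitat = "water",
                         size_fraction = "micro", season = "spring",
                         latitude = c(0, 0), longitude = c(0, 1))
  d <- geo_distance_matrix(meta, mode = "haversine")
  expect_equal(as.vector(d), 111.195, tolerance = 1e-3)

  same <- meta; same$longitude <- c(5, 5); same$latitude <- c(10, 10)
  expect_equal(as.vector(geo_distance_matrix(same, "haversine")), 0)
  expect_equal(as.vector(geo_distance_matrix(same, "cartesian")), 0)

  # both modes agree within 1% at <100 km spans near 24 N
  set.seed(8)
  m <- tibble::tibble(sample_id = paste0("s", 1:8), habitat = "water",
                      size_fraction = "nano", season = "spring",
                      latitude = 24.5 + runif(8, -0.05, 0.05),
                      longitude = 118.1 + runif(8, 0, 0.6))
  h <- as.vector(geo_distance_matrix(m, "haversine"))
  c_ <- as.vector(geo_distance_matrix(m, "cartesian"))
  ok <- h > 1  # relative comparison is meaningless at sub-km separations
  expect_lt(max(abs(h[ok] - c_[ok]) / h[ok]), 0.01)

  m$latitude[1] <- NA
  expect_error(geo_distance_matrix(m), "missing")
})

test_that("distance-decay is -1 for strictly decaying similarity", {
  n <- 8
  geo <- as.matrix(dist(seq_len(n) * 3))
  sim <- 1 - geo / (max(geo) + 1)
  comm <- 1 - sim
  dimnames(comm) <- dimnames(geo) <- list(paste0("s", 1:n), paste0("s", 1:n))
  res <- distance_decay(as.dist(comm), as.dist(geo), n_perm = 199, seed = 1)
  expect_equal(res$statistic, -1)
  expect_lt(res$p_value, 0.05)
})

test_that("environmental PCA is a proper spectral decomposition", {
  set.seed(9)
  env <- tibble::tibble(sample_id = paste0("s", 1:20),
                        a = rnorm(20), b = rnorm(20), c = rnorm(20))
  env$b <- env$a * 0.5 + env$b * 0.5
  fit <- pca_env(env)
  expect_equal(sum(fit$variance_fraction), 1)
  expect_equal(t(fit$loadings) %*% fit$loadings, diag(ncol(fit$loadings)),
               tolerance = 1e-10, ignore_attr = TRUE)

  rank1 <- tibble::tibble(x = 1:10, y = 2 * (1:10))
  fit1 <- pca_env(rank1)
  expect_equal(fit1$variance_fraction[1], 1)

  env$a[1:18] <- NA
  expect_error(pca_env(env[, c("sample_id", "a", "b")]), "fewer than 3")
})

test_that("environmental t-tests handle identity, power and missing groups", {
  g <- rep(c("w", "s"), each = 8)
  env <- tibble::tibble(v = rep(c(1.5, 1.5), each = 8))
  res <- env_group_test(env, g)
  expect_equal(res$t_statistic, 0)
  expect_equal(res$p_value, 1)

  set.seed(10)
  env2 <- tibble::tibble(v = c(rnorm(8), rnorm(8, 5)))
  res2 <- env_group_test(env2, g)
  expect_lt(res2$p_value, 0.001)

  env3 <- tibble::tibble(v = c(rnorm(8), rep(NA_real_, 7), 1))
  expect_message(res3 <- env_group_test(env3, g), "<2 values")
  expect_true(is.na(res3$p_value))
})
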