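#' Log(x + 1) transform of a community count matrix
#'
#' @param counts Samples x OTUs matrix.
#' @return Numeric matrix, element-wise natural log(count + 1).
#' @export
transform_community <- function(counts) {
  log1p(as.matrix(counts) * 1.0)
}

#' Square-root transform of environmental variables (pH exempt)
#'
#' @param env Data frame / tibble of environmental measurements, optionally
#'   with a `sample_id` column that is passed through untouched.
#' @return Tibble with all numeric variables square-rooted except `pH`.
#' @export
transform_env <- function(env) {
  env <- tibble::as_tibble(env)
  for (v in names(env)) {
    if (v %in% c("sample_id", "pH") || !is.numeric(env[[v]])) next
    bad <- which(env[[v]] < 0)
    if (length(bad) > 0L) {
      stop("negative value in '", v, "' (row ", bad[1L],
           "): cannot square-root transform")
    }
    env[[v]] <- sqrt(env[[v]])
  }
  env
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = sum|x_i - y_i| / sum(x_i + y_i) over features.
#'
#' @param mat Samples x features non-negative matrix (counts or transformed
#'   abundances).
#' @return A `dist` object.
#' @export
bray_curtis <- function(mat) {
  mat <- as.matrix(mat)
  zero <- rowSums(mat) == 0
  if (any(zero)) {
    stop("all-zero sample(s): Bray-Curtis undefined for ",
         paste(rownames(mat)[zero], collapse = ", "))
  }
  vegan::vegdist(mat, method = "bray")
}

#' Permutation-test result container
#' @keywords internal
new_perm_test <- function(method, statistic, p_value, n_perm, n = NA_integer_,
                          extra = list()) {
  structure(
    c(list(method = method, statistic = unname(statistic),
           p_value = unname(p_value), n_perm = n_perm, n = n), extra),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g (%d permutations, n = %s)\n",
              x$method, x$statistic, x$p_value, x$n_perm, x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a permutation-test result
#' @param x A `perm_test` object.
#' @param ... Unused.
#' @return One-row tibble with method, statistic, p_value, n_perm, n.
#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic,
                 p_value = x$p_value, n_perm = x$n_perm, n = x$n)
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal stress-1 NMDS via monotone-regression stress minimisation,
#' taking the best of `n_restarts` random starts; deterministic under
#' `seed`.
#'
#' @param d A `dist` or symmetric matrix of dissimilarities.
#' @param k Embedding dimension (default 2).
#' @param n_restarts Random restarts (default 20).
#' @param seed Integer RNG seed.
#' @param max_iter Maximum iterations per restart.
#' @return An object of class `nmds_result`: list with `points` (tibble of
#'   sample coordinates), `stress`, `converged`, `n_restarts`.
#' @export
run_nmds <- function(d, k = 2, n_restarts = 20, seed = 1L, max_iter = 300) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (n < k + 2) stop("need at least k + 2 samples for k-dimensional NMDS")
  set.seed(seed)
  fit <- vegan::metaMDS(d, k = k, try = n_restarts, trymax = n_restarts,
                        maxit = max_iter, trace = 0, autotransform = FALSE,
                        wascores = FALSE, sratmax = 1 - 1e-7)
  pts <- tibble::as_tibble(as.data.frame(fit$points), rownames = "sample_id")
  names(pts) <- c("sample_id", paste0("NMDS", seq_len(k)))
  if (!isTRUE(fit$converged)) {
    warning("NMDS did not converge in any restart; returning best solution")
  }
  structure(list(points = pts, stress = fit$stress,
                 converged = isTRUE(fit$converged), n_restarts = n_restarts,
                 k = k),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS (k = %d): stress = %.4f, converged = %s\n",
              x$k, x$stress, x$converged))
  invisible(x)
}

#' Glance at an NMDS fit
#' @param x An `nmds_result`.
#' @param ... Unused.
#' @return One-row tibble: k, stress, converged, n_restarts.
#' @export
glance.nmds_result <- function(x, ...) {
  tibble::tibble(k = x$k, stress = x$stress, converged = x$converged,
                 n_restarts = x$n_restarts)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based contrast of between- vs within-group dissimilarities:
#' R = (mean between-rank - mean within-rank) / (M / 2), M = n(n-1)/2.
#' The permutation p-value carries the +1 correction and can never be 0.
#'
#' @param d Dissimilarity `dist` or matrix.
#' @param groups Group labels, one per sample.
#' @param n_perm Number of label permutations (default 9999).
#' @param seed Integer RNG seed.
#' @return A `perm_test` with the ANOSIM R statistic.
#' @export
anosim_test <- function(d, groups, n_perm = 9999, seed = 1L) {
  d <- stats::as.dist(d)
  groups <- as.factor(groups)
  if (length(groups) != attr(d, "Size")) stop("groups must match samples")
  if (nlevels(droplevels(groups)) < 2L) stop("need at least 2 groups")
  if (any(table(droplevels(groups)) < 2L)) {
    stop("every group needs at least 2 samples")
  }
  set.seed(seed)
  fit <- vegan::anosim(d, groups, permutations = n_perm)
  new_perm_test("ANOSIM", fit$statistic, fit$signif, n_perm,
                n = attr(d, "Size"))
}

#' Mantel test between two distance matrices
#'
#' Correlation of the off-diagonal entries with significance by jointly
#' permuting rows and columns of the second matrix.
#'
#' @param d1,d2 `dist` objects or symmetric matrices over the same samples
#'   (matching ids when named).
#' @param n_perm Number of permutations (default 9999).
#' @param method Correlation method, `"spearman"` (default) or `"pearson"`.
#' @param seed Integer RNG seed.
#' @return A `perm_test` with the Mantel r statistic.
#' @export
mantel_test <- function(d1, d2, n_perm = 9999,
                        method = c("spearman", "pearson"), seed = 1L) {
  method <- match.arg(method)
  d1 <- stats::as.dist(d1); d2 <- stats::as.dist(d2)
  check_dist_ids(d1, d2)
  if (stats::sd(as.vector(d1)) == 0 || stats::sd(as.vector(d2)) == 0) {
    stop("constant distance matrix: correlation undefined")
  }
  set.seed(seed)
  fit <- vegan::mantel(d1, d2, method = method, permutations = n_perm)
  new_perm_test(paste0("Mantel (", method, ")"), fit$statistic, fit$signif,
                n_perm, n = attr(d1, "Size"))
}

#' Partial Mantel test controlling for a third matrix
#'
#' r_12.3 = (r12 - r13 r23) / sqrt((1 - r13^2)(1 - r23^2)), significance by
#' permutation of the first matrix as in [mantel_test()].
#'
#' @inheritParams mantel_test
#' @param d3 Control distance matrix.
#' @return A `perm_test` with the partial Mantel r statistic.
#' @export
partial_mantel_test <- function(d1, d2, d3, n_perm = 9999,
                                method = c("spearman", "pearson"), seed = 1L) {
  method <- match.arg(method)
  d1 <- stats::as.dist(d1); d2 <- stats::as.dist(d2); d3 <- stats::as.dist(d3)
  check_dist_ids(d1, d2); check_dist_ids(d1, d3)
  cf <- function(a, b) stats::cor(as.vector(a), as.vector(b), method = method)
  r13 <- cf(d1, d3); r23 <- cf(d2, d3)
  if (abs(r13) >= 1 - 1e-12 || abs(r23) >= 1 - 1e-12) {
    stop("degenerate control: a matrix is perfectly correlated with the control")
  }
  set.seed(seed)
  fit <- vegan::mantel.partial(d1, d2, d3, method = method,
                               permutations = n_perm)
  new_perm_test(paste0("Partial Mantel (", method, ")"), fit$statistic,
                fit$signif, n_perm, n = attr(d1, "Size"))
}

#' @keywords internal
check_dist_ids <- function(a, b) {
  la <- attr(a, "Labels"); lb <- attr(b, "Labels")
  if (attr(a, "Size") != attr(b, "Size")) {
    stop("distance matrices differ in size")
  }
  if (!is.null(la) && !is.null(lb) && !identical(la, lb)) {
    stop("distance matrix ids do not match")
  }
  invisible(TRUE)
}

#' Pairwise geographic distances between samples (km)
#'
#' `cartesian` (default) projects coordinates onto a local equirectangular
#' plane (x = R cos(lat0) dlon, y = R dlat) and takes Euclidean distances;
#' `haversine` computes great-circle distances (R = 6371 km). The two agree
#' to well under 1% at sub-100-km spans.
#'
#' @param meta Metadata tibble with latitude/longitude (decimal degrees).
#' @param mode `"cartesian"` or `"haversine"`.
#' @return A `dist` in km, labelled by sample_id.
#' @export
geo_distance_matrix <- function(meta, mode = c("cartesian", "haversine")) {
  mode <- match.arg(mode)
  if (anyNA(meta$latitude) || anyNA(meta$longitude)) {
    stop("missing coordinates")
  }
  if (mode == "haversine") {
    m <- geosphere::distm(cbind(meta$longitude, meta$latitude),
                          fun = function(p1, p2)
                            geosphere::distHaversine(p1, p2, r = 6371000)) / 1000
  } else {
    R <- 6371
    lat0 <- mean(meta$latitude) * pi / 180
    x <- R * cos(lat0) * meta$longitude * pi / 180
    y <- R * meta$latitude * pi / 180
    m <- as.matrix(stats::dist(cbind(x, y)))
  }
  rownames(m) <- colnames(m) <- meta$sample_id
  stats::as.dist(m)
}

#' Distance-decay of community similarity
#'
#' Spearman correlation between community similarity (1 - Bray-Curtis) and
#' geographic distance, with a Mantel-style permutation p-value; a negative
#' statistic is a distance-decay pattern.
#'
#' @param comm Community dissimilarity `dist` (e.g. from [bray_curtis()]).
#' @param geo Geographic distance `dist` over the same samples.
#' @param n_perm Number of permutations.
#' @param seed Integer RNG seed.
#' @param two_sided Report a two-sided permutation p instead of the default
#'   one-sided test of the directional decay hypothesis (similarity
#'   declining with distance, i.e. negative r).
#' @return A `perm_test`; `statistic` is Spearman's r between similarity
#'   and distance.
#' @export
distance_decay <- function(comm, geo, n_perm = 9999, seed = 1L,
                           two_sided = FALSE) {
  comm <- stats::as.dist(comm); geo <- stats::as.dist(geo)
  check_dist_ids(comm, geo)
  sim <- 1 - comm
  r_obs <- stats::cor(as.vector(sim), as.vector(geo), method = "spearman")
  set.seed(seed)
  n <- attr(comm, "Size")
  gm <- as.matrix(geo)
  perm_r <- vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    stats::cor(as.vector(sim), as.vector(stats::as.dist(gm[p, p])),
               method = "spearman")
  }, 0)
  p <- if (two_sided) {
    (sum(abs(perm_r) >= abs(r_obs)) + 1) / (n_perm + 1)
  } else {
    (sum(perm_r <= r_obs) + 1) / (n_perm + 1)
  }
  new_perm_test("distance-decay (Spearman)", r_obs, p, n_perm, n = n)
}

#' PCA of (transformed) environmental variables
#'
#' Centred, unit-variance PCA by singular value decomposition. Rows with
#' any missing value among the selected variables are dropped with a
#' message; constant variables are dropped too.
#'
#' @param env Data frame of environmental variables (optionally with
#'   `sample_id`).
#' @param scale. Scale variables to unit variance (default TRUE).
#' @return List of class `env_pca`: `scores` tibble, `loadings` matrix,
#'   `variance_fraction` vector summing to 1, `n_dropped`.
#' @export
pca_env <- function(env, scale. = TRUE) {
  env <- tibble::as_tibble(env)
  ids <- if ("sample_id" %in% names(env)) env$sample_id else
    as.character(seq_len(nrow(env)))
  num <- env[vapply(env, is.numeric, TRUE)]
  if (ncol(num) < 2L) stop("need at least 2 numeric variables")
  complete <- stats::complete.cases(num)
  if (sum(complete) < 3L) stop("fewer than 3 complete rows for PCA")
  if (any(!complete)) {
    message("pca_env: dropping ", sum(!complete), " row(s) with missing values")
  }
  num <- num[complete, , drop = FALSE]
  keep <- vapply(num, function(v) stats::sd(v) > 0, TRUE)
  if (any(!keep)) {
    message("pca_env: dropping constant variable(s): ",
            paste(names(num)[!keep], collapse = ", "))
    num <- num[, keep, drop = FALSE]
  }
  fit <- stats::prcomp(num, center = TRUE, scale. = scale.)
  vf <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- tibble::as_tibble(as.data.frame(fit$x))
  scores <- dplyr::bind_cols(tibble::tibble(sample_id = ids[complete]), scores)
  structure(list(scores = scores, loadings = fit$rotation,
                 variance_fraction = vf, n_dropped = sum(!complete)),
            class = "env_pca")
}

#' @export
print.env_pca <- function(x, ...) {
  cat("Environmental PCA:", nrow(x$scores), "samples,",
      ncol(x$loadings), "variables; PC1-2 variance:",
      sprintf("%.1f%% + %.1f%%",
              100 * x$variance_fraction[1],
              100 * ifelse(length(x$variance_fraction) > 1,
                           x$variance_fraction[2], 0)), "\n")
  invisible(x)
}

#' Per-variable Welch t-tests of environment between two groups
#'
#' @param env Data frame of environmental variables with `sample_id`
#'   optional.
#' @param groups Two-level factor aligned with the rows of `env`.
#' @return Tibble with columns variable, t_statistic, df, p_value,
#'   n_group1, n_group2 (NA rows where a group has < 2 non-missing values).
#' @export
env_group_test <- function(env, groups) {
  env <- tibble::as_tibble(env)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2L) stop("groups must have exactly 2 levels")
  vars <- names(env)[vapply(env, is.numeric, TRUE)]
  vars <- setdiff(vars, c("latitude", "longitude", "shore_km"))
  purrr::map_dfr(vars, function(v) {
    x <- env[[v]]
    lv <- levels(droplevels(groups))
    n1 <- sum(is.finite(x[groups == lv[1L]]))
    n2 <- sum(is.finite(x[groups == lv[2L]]))
    if (n1 < 2L || n2 < 2L) {
      message("env_group_test: '", v, "' has a group with <2 values; NA")
      return(tibble::tibble(variable = v, t_statistic = NA_real_,
                            df = NA_real_, p_value = NA_real_,
                            n_group1 = n1, n_group2 = n2))
    }
    tt <- tryCatch(stats::t.test(x ~ droplevels(groups)), error = function(e) NULL)
    if (is.null(tt)) {
      # degenerate (constant) data: identical groups carry no evidence
      m1 <- mean(x[groups == lv[1L]], na.rm = TRUE)
      m2 <- mean(x[groups == lv[2L]], na.rm = TRUE)
      equal <- isTRUE(all.equal(m1, m2))
      return(tibble::tibble(variable = v,
                            t_statistic = if (equal) 0 else NA_real_,
                            df = NA_real_,
                            p_value = if (equal) 1 else NA_real_,
                            n_group1 = n1, n_group2 = n2))
    }
    tibble::tibble(variable = v, t_statistic = unname(tt$statistic),
                   df = unname(tt$parameter), p_value = tt$p.value,
                   n_group1 = n1, n_group2 = n2)
  })
}
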