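#' Patristic distance matrix of a phylogeny
#'
#' Sum of branch lengths along the path between every pair of tips.
#'
#' @param tree An [ape::phylo] with branch lengths.
#' @return Symmetric zero-diagonal matrix over tips.
#' @export
patristic_matrix <- function(tree) {
  m <- ape::cophenetic.phylo(tree)
  m[tree$tip.label, tree$tip.label]
}

#' Between-community mean nearest taxon distance (betaMNTD) for one pair
#'
#' betaMNTD = 0.5 [ sum_i f_i(x) min_{j in y} d(i, j)
#'                + sum_j f_j(y) min_{i in x} d(j, i) ], where f is the
#' relative abundance (`weighted = TRUE`) or 1/richness. A taxon shared by
#' both samples has nearest-neighbour distance 0.
#'
#' This reference implementation is a plain double loop; [bnti_matrix()]
#' uses a compiled kernel for the all-pairs null model.
#'
#' @param x,y Named count vectors over the same OTU set.
#' @param pd Patristic matrix covering the OTUs (see [patristic_matrix()]).
#' @param weighted Abundance-weight the taxon contributions.
#' @return Non-negative scalar in branch-length units.
#' @export
bmntd <- function(x, y, pd, weighted = TRUE) {
  ix <- names(x)[x > 0]; iy <- names(y)[y > 0]
  if (length(ix) == 0L || length(iy) == 0L) stop("empty sample in bmntd")
  fx <- if (weighted) x[ix] / sum(x[ix]) else rep(1 / length(ix), length(ix))
  fy <- if (weighted) y[iy] / sum(y[iy]) else rep(1 / length(iy), length(iy))
  sub <- pd[ix, iy, drop = FALSE]
  0.5 * (sum(fx * apply(sub, 1L, min)) + sum(fy * apply(sub, 2L, min)))
}

#' Pairwise beta nearest taxon index (betaNTI)
#'
#' Standardised effect size of betaMNTD against a tip-shuffling null: OTU
#' labels are permuted across the tips of the phylogeny (equivalently, rows
#' and columns of the patristic matrix are permuted jointly) `n_null`
#' times, betaMNTD recomputed for every pair each time, and
#' betaNTI = (betaMNTD_obs - mean_null) / sd_null. |betaNTI| > 2 is the
#' conventional evidence for selection (positive: heterogeneous, negative:
#' homogeneous). Pairs with a degenerate null (sd = 0) are NA with a
#' warning.
#'
#' @param counts Samples x OTUs count matrix (rarefied, untransformed).
#' @param tree Phylogeny covering the OTU columns.
#' @param n_null Null iterations (>= 99; default 999).
#' @param weighted Abundance-weight betaMNTD (default TRUE).
#' @param seed Integer RNG seed.
#' @return List of class `bnti_result`: `bnti`, `bmntd_obs`, `null_mean`,
#'   `null_sd` (all `dist` objects) and `n_null`.
#' @export
bnti_matrix <- function(counts, tree, n_null = 999, weighted = TRUE,
                        seed = 1L) {
  if (n_null < 99) stop("n_null must be >= 99")
  otus <- colnames(counts)
  if (!all(otus %in% tree$tip.label)) stop("counts contain OTUs absent from tree")
  tree <- ape::keep.tip(tree, otus)
  pd <- patristic_matrix(tree)[otus, otus]
  K <- length(otus)
  n <- nrow(counts)
  if (n < 2L) stop("need at least 2 samples")

  taxa <- lapply(seq_len(n), function(s) which(counts[s, ] > 0) - 1L)
  if (any(lengths(taxa) == 0L)) stop("empty sample in count table")
  weights <- lapply(seq_len(n), function(s) {
    v <- counts[s, counts[s, ] > 0]
    if (weighted) v / sum(v) else rep(1 / length(v), length(v))
  })

  set.seed(seed)
  perms <- matrix(0L, n_null + 1L, K)
  perms[1L, ] <- seq_len(K) - 1L
  for (i in seq_len(n_null)) perms[i + 1L, ] <- sample.int(K) - 1L

  vals <- bmntd_perm_cpp(pd, taxa, weights, perms)
  obs <- vals[, 1L]
  null_mean <- rowMeans(vals[, -1L, drop = FALSE])
  null_sd <- apply(vals[, -1L, drop = FALSE], 1L, stats::sd)
  bnti <- (obs - null_mean) / null_sd
  degenerate <- null_sd == 0
  if (any(degenerate)) {
    warning(sum(degenerate), " pair(s) have a degenerate null (sd = 0); ",
            "betaNTI reported as NA")
    bnti[degenerate] <- NA_real_
  }

  as_pair_dist <- function(v) {
    d <- stats::as.dist(matrix(0, n, n, dimnames = list(rownames(counts),
                                                        rownames(counts))))
    # cpp emits pairs (a,b), a<b in row-major order; dist stores columns of
    # the lower triangle, i.e. (1,2),(1,3),...,(2,3),... -- same ordering
    d[seq_along(v)] <- v
    d
  }
  structure(list(bnti = as_pair_dist(bnti), bmntd_obs = as_pair_dist(obs),
                 null_mean = as_pair_dist(null_mean),
                 null_sd = as_pair_dist(null_sd), n_null = n_null,
                 weighted = weighted),
            class = "bnti_result")
}

#' Pairwise Bray-Curtis based Raup-Crick (RC_bray)
#'
#' For each null iteration every sample is re-assembled independently from
#' the regional pool: its observed richness is drawn as taxa sampled with
#' probability proportional to regional occupancy frequency (each receiving
#' one read), then filled to the sample's observed read total with
#' probability proportional to pooled regional relative abundance
#' (`fill = "richness_only"` skips the abundance fill and compares
#' presence/absence-seeded communities). Bray-Curtis between the two null
#' assemblies locates the observed dissimilarity in its null distribution:
#' RC_raw = (no. null < obs + 0.5 no. null = obs) / n_null, rescaled to
#' RC_bray = 2 (RC_raw - 0.5) in [-1, 1]. RC_bray > 0.95 indicates
#' dispersal limitation, < -0.95 homogenizing dispersal (given |betaNTI|
#' < 2).
#'
#' @param counts Samples x OTUs count matrix (rarefied, untransformed).
#' @param n_null Null iterations (>= 99; default 999).
#' @param seed Integer RNG seed.
#' @param fill `"abundance"` (default) or `"richness_only"`.
#' @return A `dist` of RC_bray values in [-1, 1].
#' @export
rc_bray_matrix <- function(counts, n_null = 999, seed = 1L,
                           fill = c("abundance", "richness_only")) {
  fill <- match.arg(fill)
  if (n_null < 99) stop("n_null must be >= 99")
  counts <- as.matrix(counts)
  n <- nrow(counts); K <- ncol(counts)
  if (n < 2L) stop("need at least 2 samples")
  occ <- colSums(counts > 0)
  pool_ab <- colSums(counts)
  rich <- rowSums(counts > 0)
  tot <- rowSums(counts)
  if (any(rich == 0L)) stop("empty sample in count table")

  obs <- as.matrix(vegan::vegdist(counts, method = "bray"))
  less <- matrix(0, n, n)
  equal <- matrix(0, n, n)
  eps <- 1e-12
  set.seed(seed)
  for (it in seq_len(n_null)) {
    null <- matrix(0, n, K)
    for (s in seq_len(n)) {
      pick <- sample.int(K, rich[s], prob = occ)
      null[s, pick] <- 1
      extra <- tot[s] - rich[s]
      if (fill == "abundance" && extra > 0) {
        null[s, pick] <- null[s, pick] +
          as.numeric(stats::rmultinom(1, extra, pool_ab[pick]))
      }
    }
    nbc <- as.matrix(vegan::vegdist(null, method = "bray"))
    less <- less + (nbc < obs - eps)
    equal <- equal + (abs(nbc - obs) <= eps)
  }
  rc <- 2 * ((less + 0.5 * equal) / n_null - 0.5)
  dimnames(rc) <- dimnames(obs)
  stats::as.dist(rc)
}

#' Classify a sample pair's assembly process
#'
#' Two-step rule: |betaNTI| > `bnti_threshold` assigns selection
#' (heterogeneous if positive, homogeneous if negative); otherwise RC_bray
#' beyond +/- `rc_threshold` assigns dispersal limitation / homogenizing
#' dispersal; the remainder is ecological drift. Vectorised; NA inputs give
#' NA labels.
#'
#' @param bnti Numeric vector of betaNTI values.
#' @param rc Numeric vector of RC_bray values (same length).
#' @param bnti_threshold Selection cutoff (default 2).
#' @param rc_threshold Dispersal cutoff (default 0.95).
#' @return Factor with levels heterogeneous_selection,
#'   homogeneous_selection, dispersal_limitation, homogenizing_dispersal,
#'   drift.
#' @export
classify_process <- function(bnti, rc, bnti_threshold = 2,
                             rc_threshold = 0.95) {
  lv <- c("heterogeneous_selection", "homogeneous_selection",
          "dispersal_limitation", "homogenizing_dispersal", "drift")
  out <- rep(NA_character_, length(bnti))
  ok <- !is.na(bnti) & !is.na(rc)
  out[ok & bnti > bnti_threshold] <- "heterogeneous_selection"
  out[ok & bnti < -bnti_threshold] <- "homogeneous_selection"
  rest <- ok & abs(bnti) <= bnti_threshold
  out[rest & rc > rc_threshold] <- "dispersal_limitation"
  out[rest & rc < -rc_threshold] <- "homogenizing_dispersal"
  out[rest & abs(rc) <= rc_threshold] <- "drift"
  factor(out, levels = lv)
}

#' Per-group fractions of assembly processes
#'
#' @param pairs Tibble of pairwise results with columns `sample_a`,
#'   `sample_b`, `process` (e.g. from [run_assembly()]).
#' @param grouping Named vector or factor mapping sample_id -> group label.
#' @param scope `"within_group"` (default: only pairs whose two samples
#'   share a group, the per-subgroup convention) or `"all_pairs"` (every
#'   pair counted for both its samples' groups).
#' @return Tibble with columns group, process, fraction, n_pairs; fractions
#'   within a group sum to 1 over non-NA pairs.
#' @export
summarize_processes <- function(pairs, grouping,
                                scope = c("within_group", "all_pairs")) {
  scope <- match.arg(scope)
  grouping <- stats::setNames(as.character(grouping), names(grouping))
  ga <- grouping[pairs$sample_a]
  gb <- grouping[pairs$sample_b]
  lv <- levels(classify_process(numeric(0), numeric(0)))
  if (scope == "within_group") {
    keep <- !is.na(ga) & !is.na(gb) & ga == gb
    dat <- tibble::tibble(group = ga[keep], process = pairs$process[keep])
  } else {
    dat <- dplyr::bind_rows(
      tibble::tibble(group = ga, process = pairs$process),
      tibble::tibble(group = gb, process = pairs$process)
    )
    dat <- dat[!is.na(dat$group), ]
  }
  out <- purrr::map_dfr(sort(unique(dat$group)), function(g) {
    pr <- dat$process[dat$group == g]
    valid <- pr[!is.na(pr)]
    n <- length(valid)
    if (n == 0L) {
      return(tibble::tibble(group = g, process = factor(lv, levels = lv),
                            fraction = NA_real_, n_pairs = 0L))
    }
    tab <- table(factor(valid, levels = lv))
    tibble::tibble(group = g, process = factor(lv, levels = lv),
                   fraction = as.numeric(tab) / n, n_pairs = n)
  })
  out
}

#' Run the two-step null-model assembly analysis
#'
#' Composes [bnti_matrix()], [rc_bray_matrix()], [classify_process()] and
#' [summarize_processes()] on a (rarefied) count table, and optionally
#' writes bnti.tsv, rcbray.tsv, processes.tsv and process_summary.tsv.
#'
#' @param counts Samples x OTUs rarefied count matrix.
#' @param tree Phylogeny covering the OTUs.
#' @param meta Metadata tibble with `sample_id` and the grouping column.
#' @param group_var Metadata column defining the process-summary groups
#'   (default `"habitat"`).
#' @param n_null Null iterations for both null models.
#' @param weighted Abundance-weight betaMNTD.
#' @param bnti_threshold,rc_threshold Classification cutoffs.
#' @param scope Summary scope, see [summarize_processes()].
#' @param seed Integer RNG seed (betaNTI and RC_bray consume independent
#'   streams derived from it).
#' @param out_dir Optional output directory for TSV results.
#' @return List of class `assembly_result`: `pairs` tibble (sample_a,
#'   sample_b, bmntd_obs, bnti, rc_bray, process), `summary` tibble,
#'   `bnti_fit`, and the configuration used.
#' @export
run_assembly <- function(counts, tree, meta, group_var = "habitat",
                         n_null = 999, weighted = TRUE, bnti_threshold = 2,
                         rc_threshold = 0.95,
                         scope = c("within_group", "all_pairs"),
                         seed = 1L, out_dir = NULL) {
  scope <- match.arg(scope)
  if (!group_var %in% names(meta)) stop("group_var not in metadata")
  bn <- bnti_matrix(counts, tree, n_null = n_null, weighted = weighted,
                    seed = seed)
  rc <- rc_bray_matrix(counts, n_null = n_null, seed = seed + 1L)

  ids <- rownames(counts)
  pr <- utils::combn(ids, 2L)
  # dist lower-triangle order matches combn's (a,b), a<b ordering
  pairs <- tibble::tibble(
    sample_a = pr[1L, ], sample_b = pr[2L, ],
    bmntd_obs = as.vector(bn$bmntd_obs),
    bnti = as.vector(bn$bnti),
    rc_bray = as.vector(rc)
  )
  pairs$process <- classify_process(pairs$bnti, pairs$rc_bray,
                                    bnti_threshold, rc_threshold)
  grouping <- stats::setNames(meta[[group_var]], meta$sample_id)
  summ <- summarize_processes(pairs, grouping, scope = scope)

  res <- structure(
    list(pairs = pairs, summary = summ, bnti_fit = bn,
         config = list(group_var = group_var, n_null = n_null,
                       weighted = weighted, bnti_threshold = bnti_threshold,
                       rc_threshold = rc_threshold, scope = scope,
                       seed = seed)),
    class = "assembly_result"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_distance_matrix(bn$bnti, file.path(out_dir, "bnti.tsv"))
    write_distance_matrix(rc, file.path(out_dir, "rcbray.tsv"))
    utils::write.table(pairs, file.path(out_dir, "processes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
    utils::write.table(summ, file.path(out_dir, "process_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  res
}

#' @export
print.assembly_result <- function(x, ...) {
  n_na <- sum(is.na(x$pairs$process))
  cat("<assembly_result>", nrow(x$pairs), "pairs,", x$config$n_null,
      "null iterations;", n_na, "NA pair(s)\n")
  tab <- table(x$pairs$process)
  frac <- round(100 * tab / sum(tab), 1)
  for (p in names(tab)) cat(sprintf("  %-24s %5d  (%.1f%%)\n", p, tab[[p]],
                                    frac[[p]]))
  invisible(x)
}

#' Tidy pairwise assembly results
#' @param x An `assembly_result`.
#' @param ... Unused.
#' @return The `pairs` tibble.
#' @export
tidy.assembly_result <- function(x, ...) x$pairs

#' Glance at an assembly analysis
#' @param x An `assembly_result`.
#' @param ... Unused.
#' @return One-row tibble with pair counts and overall process fractions.
#' @export
glance.assembly_result <- function(x, ...) {
  pr <- x$pairs$process
  valid <- pr[!is.na(pr)]
  frac <- as.list(table(valid) / length(valid))
  dplyr::bind_cols(
    tibble::tibble(n_pairs = nrow(x$pairs), n_na = sum(is.na(pr)),
                   n_null = x$config$n_null),
    tibble::as_tibble(frac)
  )
}
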