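#' Rarefy a count table to even depth
#'
#' Subsamples each sample's reads without replacement down to exactly
#' `depth`; samples with fewer total reads are dropped with a message.
#' Single-draw rarefaction (not an average over draws); record the seed for
#' exact reproducibility.
#'
#' @param counts Samples x OTUs integer matrix.
#' @param depth Target reads per sample (default 13595, the conventional
#'   even depth for this survey design).
#' @param seed Integer RNG seed.
#' @return Integer matrix with every row summing to `depth`; OTUs that end
#'   up absent everywhere are retained (columns are not dropped) so the
#'   rarefied table stays aligned with the phylogeny.
#' @export
rarefy_counts <- function(counts, depth = 13595, seed = 1L) {
  if (depth < 1) stop("depth must be >= 1")
  totals <- rowSums(counts)
  keep <- totals >= depth
  if (!any(keep)) stop("all samples have fewer than ", depth, " reads")
  if (any(!keep)) {
    message("rarefy_counts: dropping ", sum(!keep), " sample(s) below depth ",
            depth, ": ", paste(rownames(counts)[!keep], collapse = ", "))
  }
  set.seed(seed)
  out <- vegan::rrarefy(counts[keep, , drop = FALSE], depth)
  storage.mode(out) <- "integer"
  out
}

#' Observed OTU richness of one sample
#' @param x Non-negative count vector.
#' @return Integer count of OTUs with positive abundance.
#' @export
richness <- function(x) {
  if (all(x == 0)) stop("all-zero sample: richness undefined")
  sum(x > 0)
}

#' Shannon diversity of one sample
#'
#' H' = -sum p_i log p_i over OTUs with positive abundance. Natural-log
#' units by default (`base = exp(1)`); pass `base = 2` for bits.
#'
#' @param x Non-negative count vector.
#' @param base Logarithm base.
#' @return Shannon index (>= 0).
#' @export
shannon <- function(x, base = exp(1)) {
  if (all(x == 0)) stop("all-zero sample: Shannon undefined")
  p <- x[x > 0] / sum(x)
  -sum(p * log(p, base = base))
}

#' Faith's phylogenetic diversity of one or more samples
#'
#' Sum of branch lengths of the minimal subtree connecting a sample's
#' observed OTUs, including the path to the root (root-inclusive
#' convention; set `include_root = FALSE` for the unrooted variant).
#'
#' @param counts Count vector (named by OTU) or samples x OTUs matrix.
#' @param tree Phylogeny whose tips include every observed OTU.
#' @param include_root Include the root in the spanning subtree.
#' @return Numeric vector of PD values, one per sample.
#' @export
faith_pd <- function(counts, tree, include_root = TRUE) {
  if (is.null(dim(counts))) {
    counts <- matrix(counts, nrow = 1L,
                     dimnames = list("s1", names(counts)))
  }
  missing <- setdiff(colnames(counts)[colSums(counts) > 0], tree$tip.label)
  if (length(missing) > 0L) {
    stop("OTU(s) absent from tree: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  res <- picante::pd(counts, tree, include.root = include_root)
  stats::setNames(res$PD, rownames(counts))
}

#' Alpha-diversity table: richness, Shannon, Faith's PD per sample
#'
#' @param counts Samples x OTUs matrix (typically rarefied).
#' @param tree Phylogeny covering the OTUs.
#' @param base Log base for Shannon.
#' @param include_root Root convention for PD.
#' @return Tibble with columns sample_id, richness, shannon, faith_pd.
#' @export
alpha_table <- function(counts, tree, base = exp(1), include_root = TRUE) {
  tibble::tibble(
    sample_id = rownames(counts),
    richness = unname(apply(counts, 1L, richness)),
    shannon = unname(apply(counts, 1L, shannon, base = base)),
    faith_pd = unname(faith_pd(counts, tree, include_root = include_root))
  )
}

#' One-way ANOVA of alpha-diversity metrics across groups
#'
#' Classic equal-variance one-way ANOVA per metric (Welch's variant with
#' `welch = TRUE`).
#'
#' @param alpha Tibble from [alpha_table()].
#' @param groups Factor (or coercible) of group labels aligned with
#'   `alpha$sample_id`.
#' @param metrics Which metric columns to test.
#' @param welch Use Welch's unequal-variance ANOVA.
#' @return Tibble with columns metric, f_statistic, df_between, df_within,
#'   p_value.
#' @export
alpha_group_test <- function(alpha, groups,
                             metrics = c("richness", "shannon", "faith_pd"),
                             welch = FALSE) {
  groups <- as.factor(groups)
  if (length(groups) != nrow(alpha)) {
    stop("groups must match the number of alpha records")
  }
  if (any(table(groups) < 2L)) stop("every group needs at least 2 samples")
  purrr::map_dfr(metrics, function(m) {
    x <- alpha[[m]]
    if (stats::var(x) == 0) {
      # no variation at all: no between-group signal by construction
      return(tibble::tibble(metric = m, f_statistic = 0,
                            df_between = nlevels(groups) - 1,
                            df_within = length(x) - nlevels(groups),
                            p_value = 1))
    }
    fit <- stats::oneway.test(x ~ groups, var.equal = !welch)
    tibble::tibble(
      metric = m,
      f_statistic = unname(fit$statistic),
      df_between = unname(fit$parameter[1L]),
      df_within = unname(fit$parameter[2L]),
      p_value = unname(fit$p.value)
    )
  })
}

#' Spearman correlations between alpha diversity and environment
#'
#' For every (metric, environmental variable) pair, Spearman's rho with
#' Holm-corrected p-values; the Holm family is the set of environmental
#' variables within each metric. Samples with a missing value of a variable
#' are dropped for that variable only and the effective n is reported.
#' Variables with fewer than 4 complete pairs yield NA and a message.
#'
#' @param alpha Tibble from [alpha_table()].
#' @param meta Metadata tibble containing `sample_id` and the variables.
#' @param env_vars Character vector of environmental column names; default:
#'   every numeric metadata column except coordinates.
#' @param metrics Metric columns of `alpha` to correlate.
#' @return Tibble with columns metric, variable, rho, p_value, p_holm, n.
#' @export
alpha_env_correlations <- function(alpha, meta, env_vars = NULL,
                                   metrics = c("richness", "shannon", "faith_pd")) {
  meta <- meta[match(alpha$sample_id, meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) stop("metadata missing some alpha samples")
  if (is.null(env_vars)) {
    num <- vapply(meta, is.numeric, TRUE)
    env_vars <- setdiff(names(meta)[num], c("latitude", "longitude", "shore_km"))
  }
  res <- purrr::map_dfr(metrics, function(m) {
    purrr::map_dfr(env_vars, function(v) {
      ok <- is.finite(alpha[[m]]) & is.finite(meta[[v]])
      n <- sum(ok)
      if (n < 4L) {
        message("alpha_env_correlations: <4 complete pairs for ", v,
                " (n=", n, "), reporting NA")
        return(tibble::tibble(metric = m, variable = v, rho = NA_real_,
                              p_value = NA_real_, n = n))
      }
      ct <- suppressWarnings(
        stats::cor.test(alpha[[m]][ok], meta[[v]][ok], method = "spearman",
                        exact = FALSE)
      )
      tibble::tibble(metric = m, variable = v,
                     rho = unname(ct$estimate), p_value = ct$p.value, n = n)
    })
  })
  dplyr::mutate(dplyr::group_by(res, .data$metric),
                p_holm = stats::p.adjust(.data$p_value, method = "holm")) |>
    dplyr::ungroup() |>
    dplyr::select("metric", "variable", "rho", "p_value", "p_holm", "n")
}
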