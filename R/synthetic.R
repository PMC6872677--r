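#' Scenario configuration for the synthetic community generator
#'
#' Builds a validated configuration describing one simulated intertidal
#' survey. Defaults mirror the field design the package targets: 13 sites
#' along a 66 km shoreline, 36 samples (21 planktonic split 10 micro / 11
#' nano, 15 benthic split 8 spring / 7 summer), and a rarefaction-scale
#' read depth of 13,595.
#'
#' The `regime` chooses a preset of generative forces:
#' \describe{
#'   \item{heterogeneous_selection}{strong trait filtering against an
#'     environmental gradient that varies across sites}
#'   \item{homogeneous_selection}{the same strong filtering but an identical
#'     environment everywhere}
#'   \item{dispersal_limitation}{no filtering; per-site pools diverge by
#'     drift and mix only with near neighbours (small `dispersal_scale`)}
#'   \item{homogenizing_dispersal}{no filtering; mass effects mix all site
#'     pools into one (`dispersal_scale` far exceeding the shoreline)}
#'   \item{drift}{neutral assembly: each sample is a random draw from the
#'     regional species pool — random membership at a target occupancy,
#'     abundances refilled from the regional abundance distribution}
#'   \item{mixed}{moderate filtering, moderate dispersal limitation and
#'     drift acting together}
#' }
#'
#' Preset knobs (`filter_strength`, `dispersal_scale`, `site_noise_sd`,
#' `sample_noise_sd`, `occupancy_fraction`) may be overridden explicitly.
#' `filter_strength` is the width of the Gaussian trait-matching kernel in
#' units of the trait standard deviation across tips; `dispersal_scale` is
#' the e-folding distance (km) of mass-effect mixing between site pools.
#'
#' @param n_sites Number of shoreline sites (>= 3).
#' @param shoreline_km Length of the 1-D site arrangement in km.
#' @param n_taxa Number of OTUs in the regional pool (>= 10).
#' @param regime Assembly regime preset; see Details.
#' @param filter_strength Selection kernel width (trait SD units); `Inf`
#'   disables selection.
#' @param dispersal_scale Mass-effect mixing scale in km.
#' @param depth Reads per sample (>= 100).
#' @param seed Integer RNG seed; every draw in the generator derives from it.
#' @param groups Sampling plan: a data frame with columns `habitat`,
#'   `size_fraction`, `season`, `n`. Default [default_grouping()].
#' @param site_noise_sd SD of per-site log-normal drift on the regional pool.
#' @param sample_noise_sd SD of per-sample log-normal noise on assembly
#'   weights.
#' @param pool_sdlog SD (log scale) of the regional log-normal abundance
#'   distribution.
#' @param occupancy_fraction Target fraction of the pool present per sample
#'   under the drift regime.
#' @param trait_sigma Brownian-motion rate for trait evolution.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_sites = 13,
                            shoreline_km = 66,
                            n_taxa = 500,
                            regime = c("mixed", "heterogeneous_selection",
                                       "homogeneous_selection",
                                       "dispersal_limitation",
                                       "homogenizing_dispersal", "drift"),
                            filter_strength = NULL,
                            dispersal_scale = NULL,
                            depth = 13595,
                            seed = 1L,
                            groups = default_grouping(),
                            site_noise_sd = NULL,
                            sample_noise_sd = NULL,
                            pool_sdlog = NULL,
                            occupancy_fraction = 0.6,
                            trait_sigma = 1) {
  regime <- match.arg(regime)
  preset <- .regime_presets[[regime]]
  cfg <- list(
    n_sites = as.integer(n_sites),
    shoreline_km = as.numeric(shoreline_km),
    n_taxa = as.integer(n_taxa),
    regime = regime,
    filter_strength = filter_strength %||% preset$filter_strength,
    dispersal_scale = dispersal_scale %||% preset$dispersal_scale,
    depth = as.integer(depth),
    seed = as.integer(seed),
    groups = as.data.frame(groups),
    site_noise_sd = site_noise_sd %||% preset$site_noise_sd,
    sample_noise_sd = sample_noise_sd %||% preset$sample_noise_sd,
    pool_sdlog = pool_sdlog %||% preset$pool_sdlog,
    occupancy_fraction = occupancy_fraction,
    trait_sigma = trait_sigma,
    env_gradient = preset$env_gradient
  )
  if (cfg$n_sites < 3L) stop("n_sites must be >= 3")
  if (cfg$n_taxa < 10L) stop("n_taxa must be >= 10")
  if (cfg$depth < 100L) stop("depth must be >= 100")
  if (cfg$dispersal_scale <= 0) stop("dispersal_scale must be > 0")
  if (cfg$filter_strength <= 0) stop("filter_strength must be > 0")
  if (!all(c("habitat", "size_fraction", "season", "n") %in% names(cfg$groups))) {
    stop("groups must have columns habitat, size_fraction, season, n")
  }
  class(cfg) <- "scenario_config"
  cfg
}

# Preset generative forces per regime. Selection kernels are expressed in
# trait-SD units; dispersal scales in km (1e4 km >> any shoreline = fully
# mixed). Chosen once from the ecology each regime is meant to embody:
# strong filtering needs a kernel much narrower than the trait spread;
# limited dispersal needs an e-folding scale near the inter-site spacing so
# neighbours stay correlated while distant sites diverge.
.regime_presets <- list(
  heterogeneous_selection = list(filter_strength = 0.10, dispersal_scale = 1e4,
                                 site_noise_sd = 0, sample_noise_sd = 2.0,
                                 env_gradient = TRUE, pool_sdlog = 0.5),
  homogeneous_selection   = list(filter_strength = 0.10, dispersal_scale = 1e4,
                                 site_noise_sd = 0, sample_noise_sd = 2.5,
                                 env_gradient = FALSE, pool_sdlog = 0.5),
  dispersal_limitation    = list(filter_strength = Inf, dispersal_scale = 6,
                                 site_noise_sd = 2.5, sample_noise_sd = 0.5,
                                 env_gradient = FALSE, pool_sdlog = 1.2),
  homogenizing_dispersal  = list(filter_strength = Inf, dispersal_scale = 1e4,
                                 site_noise_sd = 2.5, sample_noise_sd = 0.15,
                                 env_gradient = FALSE, pool_sdlog = 1.2),
  drift                   = list(filter_strength = Inf, dispersal_scale = 1e4,
                                 site_noise_sd = 0, sample_noise_sd = 0,
                                 env_gradient = FALSE, pool_sdlog = 1.2),
  mixed                   = list(filter_strength = 1.0, dispersal_scale = 15,
                                 site_noise_sd = 1.5, sample_noise_sd = 0.4,
                                 env_gradient = TRUE, pool_sdlog = 1.2)
)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default sampling plan: 21 planktonic + 15 benthic samples
#'
#' 10 micro-fraction and 11 nano-fraction water samples collected in spring,
#' plus 8 spring and 7 summer sediment samples.
#'
#' @return A data frame with columns habitat, size_fraction, season, n.
#' @export
default_grouping <- function() {
  data.frame(
    habitat = c("water", "water", "sediment", "sediment"),
    size_fraction = c("micro", "nano", "none", "none"),
    season = c("spring", "spring", "spring", "summer"),
    n = c(10L, 11L, 8L, 7L),
    stringsAsFactors = FALSE
  )
}

#' Simulate a rooted phylogeny with a clustered-radiation shape
#'
#' Two-timescale pure-birth tree: a random Yule backbone whose exponential
#' branch lengths are scaled by `deep_scale` carries many small Yule
#' radiations (about `clade_size` tips each) with branch lengths scaled by
#' `shallow_scale`. This is the shape typical of OTU phylogenies from
#' amplicon surveys — tight clusters of closely related sequence variants
#' separated by deep divergences between higher taxa — and it is what makes
#' nearest-taxon phylogenetic statistics informative: membership confined
#' to a few clusters differs sharply from membership scattered across the
#' backbone. Not ultrametric; deterministic under `seed`.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param seed Integer RNG seed.
#' @param clade_size Target number of tips per terminal radiation.
#' @param deep_scale Mean branch length on the backbone.
#' @param shallow_scale Mean branch length within radiations.
#' @return An [ape::phylo] with tips labelled `OTU0001`, `OTU0002`, ...
#' @export
simulate_tree <- function(n_taxa, seed = 1L, clade_size = 3,
                          deep_scale = 5, shallow_scale = 0.05) {
  if (n_taxa < 2L) stop("n_taxa must be >= 2")
  set.seed(seed)
  n_clades <- max(1L, ceiling(n_taxa / clade_size))
  if (n_clades < 2L || n_taxa < 4L) {
    tree <- ape::rtree(n_taxa, rooted = TRUE)
    tree$edge.length <- stats::rexp(nrow(tree$edge)) * shallow_scale
  } else {
    m <- rep(n_taxa %/% n_clades, n_clades)
    extra <- n_taxa - sum(m)
    if (extra > 0L) m[seq_len(extra)] <- m[seq_len(extra)] + 1L
    tree <- ape::rtree(n_clades, rooted = TRUE)
    tree$edge.length <- stats::rexp(nrow(tree$edge)) * deep_scale
    for (i in seq_len(n_clades)) {
      if (m[i] > 1L) {
        sub <- ape::rtree(m[i], rooted = TRUE)
        sub$edge.length <- stats::rexp(nrow(sub$edge)) * shallow_scale
        sub$tip.label <- paste0("c", i, "_", seq_len(m[i]))
        sub$root.edge <- 0
        tree <- ape::bind.tree(tree, sub,
                               where = which(tree$tip.label == paste0("t", i)))
      }
    }
  }
  width <- max(4L, nchar(as.character(n_taxa)))
  tree$tip.label <- sprintf("OTU%0*d", width, seq_len(length(tree$tip.label)))
  tree
}

#' Evolve a continuous niche trait along a phylogeny
#'
#' Brownian motion from a root value of 0 with rate `sigma^2` at the root,
#' decaying toward the present as `exp(-conservatism * t / T)` (t = time
#' from the root, T = tree depth). With `conservatism = 0` this is plain
#' Brownian motion; positive values concentrate trait variance on the deep
#' branches, giving the strong niche conservatism (clade-structured
#' niches) that lets phylogenetic turnover track niche turnover. Plain BM
#' on trees of a few hundred tips produces considerable trait convergence
#' between distant clades, which would decouple trait filtering from
#' phylogenetic clustering.
#'
#' @param tree An [ape::phylo] with branch lengths.
#' @param sigma Brownian rate parameter at the root (> 0).
#' @param seed Integer RNG seed.
#' @param conservatism Early-burst decay rate of the Brownian rate (>= 0;
#'   default 0 = plain Brownian motion, appropriate for trees whose deep
#'   branches already dominate, as from [simulate_tree()]).
#' @return Named numeric vector of trait values, one per tip.
#' @export
evolve_trait <- function(tree, sigma = 1, seed = 1L, conservatism = 0) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (conservatism < 0) stop("conservatism must be >= 0")
  set.seed(seed)
  scaled <- tree
  if (conservatism > 0 && !is.null(tree$edge.length)) {
    depth <- ape::node.depth.edgelength(tree)
    total <- max(depth)
    if (total > 0) {
      mid <- (depth[tree$edge[, 1L]] + depth[tree$edge[, 2L]]) / 2
      scaled$edge.length <- tree$edge.length * exp(-conservatism * mid / total)
    }
  }
  tr <- ape::rTraitCont(scaled, model = "BM", sigma = sigma, root.value = 0)
  stats::setNames(as.numeric(tr), tree$tip.label)
}

#' Lay out sites and samples along a model shoreline
#'
#' Places `n_sites` positions evenly (plus jitter) along `shoreline_km`,
#' converts them to latitude/longitude around 24.5N 118.1E, assigns samples
#' to sites per the grouping plan, and attaches a dimensionless
#' environmental driver (`env_driver`, a smooth 0-1 gradient along the shore
#' for gradient regimes, constant 0.5 otherwise) plus correlated nuisance
#' environmental variables.
#'
#' @param config A [scenario_config()].
#' @return A metadata tibble, one row per sample, with columns sample_id,
#'   habitat, size_fraction, season, site_code, latitude, longitude,
#'   shore_km, env_driver and environmental measurements.
#' @export
simulate_sites <- function(config) {
  set.seed(config$seed + 1L)
  n <- config$n_sites
  L <- config$shoreline_km
  spacing <- L / n
  x <- (seq_len(n) - 0.5) * spacing +
    stats::runif(n, -0.25, 0.25) * spacing
  site_code <- sprintf("S%02d", seq_len(n))
  ref_lat <- 24.5
  ref_lon <- 118.1
  km_per_deg <- 111.195
  lat <- ref_lat + stats::runif(n, -0.005, 0.005)
  lon <- ref_lon + x / (km_per_deg * cos(ref_lat * pi / 180))
  g <- if (isTRUE(config$env_gradient)) x / L else rep(0.5, n)

  plan <- config$groups
  rows <- list()
  for (i in seq_len(nrow(plan))) {
    k <- plan$n[i]
    sites <- round(seq(1, n, length.out = k))
    code <- paste0(
      toupper(substr(plan$habitat[i], 1, 1)),
      toupper(substr(ifelse(plan$size_fraction[i] == "none",
                            plan$season[i], plan$size_fraction[i]), 1, 2))
    )
    rows[[i]] <- tibble::tibble(
      sample_id = sprintf("%s_%s_%02d", code, site_code[sites], seq_len(k)),
      habitat = plan$habitat[i],
      size_fraction = plan$size_fraction[i],
      season = plan$season[i],
      site = sites
    )
  }
  meta <- dplyr::bind_rows(rows)
  meta$site_code <- site_code[meta$site]
  meta$latitude <- lat[meta$site]
  meta$longitude <- lon[meta$site]
  meta$shore_km <- x[meta$site]
  meta$env_driver <- g[meta$site]

  # Nuisance environmental variables, each correlated ~0.3 with its
  # predecessor in an AR-1 chain seeded by the driver, then mapped onto
  # plausible field scales. Sediment-only measurements are NA for water.
  z <- as.numeric(scale(meta$env_driver))
  if (any(!is.finite(z))) z <- rep(0, nrow(meta))
  ar_next <- function(prev) 0.3 * prev + sqrt(1 - 0.3^2) * stats::rnorm(length(prev))
  z1 <- ar_next(z); z2 <- ar_next(z1); z3 <- ar_next(z2)
  z4 <- ar_next(z3); z5 <- ar_next(z4); z6 <- ar_next(z5)
  meta$salinity <- pmax(0, 30 + 2 * z1)
  meta$pH <- 8 + 0.3 * z2
  meta$Cd <- exp(-1 + 0.5 * z3)
  meta$Cu <- exp(1 + 0.5 * z4)
  meta$water_content <- ifelse(meta$habitat == "sediment",
                               pmin(95, pmax(5, 40 + 8 * z5)), NA_real_)
  meta$chl_a <- ifelse(meta$habitat == "sediment", exp(0.5 + 0.6 * z6), NA_real_)
  meta$site <- NULL
  validate_sample_metadata(meta)
}

#' Assemble community count data under a scenario's regime
#'
#' Each sample's counts are a multinomial draw of `depth` reads whose OTU
#' weights combine (i) regional log-normal abundances, (ii) a Gaussian
#' trait-matching selection kernel against the site environment, (iii)
#' mass-effect mixing between site-specific drifted pools with weight
#' `exp(-d / dispersal_scale)`, and (iv) per-sample log-normal noise. The
#' drift regime instead assembles each sample as a random draw from the
#' regional pool: membership sampled at a target occupancy with propensity
#' proportional to the square root of regional abundance, then reads filled
#' multinomially from the regional abundance distribution.
#'
#' @param config A [scenario_config()].
#' @param tree Phylogeny whose tips are the OTU pool.
#' @param traits Named trait vector covering all tips (see [evolve_trait()]).
#' @param meta Metadata from [simulate_sites()].
#' @return Samples x OTUs integer count matrix; every row sums to
#'   `config$depth`.
#' @export
assemble_communities <- function(config, tree, traits, meta) {
  if (config$depth > 1e7) stop("depth exceeds practical bound 1e7")
  if (!all(tree$tip.label %in% names(traits))) {
    stop("traits must cover all tips of the tree")
  }
  set.seed(config$seed + 2L)
  otus <- tree$tip.label
  K <- length(otus)
  tr <- traits[otus]
  n_samp <- nrow(meta)

  pool <- stats::rlnorm(K, meanlog = 0, sdlog = config$pool_sdlog)

  if (config$regime == "drift") {
    # pure ecological drift: membership is a uniform random draw at the
    # target occupancy (no taxon holds a presence advantage), abundances
    # are refilled from the regional abundance distribution
    counts <- matrix(0L, n_samp, K, dimnames = list(meta$sample_id, otus))
    for (s in seq_len(n_samp)) {
      r <- max(2L, stats::rbinom(1L, K, config$occupancy_fraction))
      pick <- sample.int(K, r)
      cts <- rep(1L, r)
      if (config$depth > r) {
        cts <- cts + as.integer(stats::rmultinom(1, config$depth - r, pool[pick]))
      }
      counts[s, pick] <- cts
    }
    return(counts)
  }

  # site-specific drifted pools, then mass-effect mixing along the shore
  sites <- sort(unique(meta$site_code))
  site_x <- vapply(sites, function(sc) meta$shore_km[match(sc, meta$site_code)], 0)
  n_site <- length(sites)
  base <- matrix(pool, n_site, K, byrow = TRUE,
                 dimnames = list(sites, otus))
  if (config$site_noise_sd > 0) {
    base <- base * exp(matrix(stats::rnorm(n_site * K, 0, config$site_noise_sd),
                              n_site, K))
  }
  d_site <- abs(outer(site_x, site_x, "-"))
  W <- exp(-d_site / config$dispersal_scale)
  W <- W / rowSums(W)
  site_pool <- W %*% base

  # selection kernel, truncated at 2.5 widths (hard physiological limits,
  # so a lucky abundance draw cannot override a strong niche mismatch).
  # Along a gradient the environment maps onto the trait scale through the
  # 5th-95th percentile span; a spatially uniform environment sits at the
  # densest trait neighbourhood (an occupied niche syndrome), not at the
  # trait median, which can fall between clades.
  sel <- matrix(1, n_site, K)
  if (is.finite(config$filter_strength)) {
    width <- config$filter_strength * stats::sd(tr)
    g_site <- vapply(sites,
                     function(sc) meta$env_driver[match(sc, meta$site_code)], 0)
    if (diff(range(g_site)) == 0) {
      cand <- sort(tr)
      dens <- vapply(cand, function(o) sum(abs(tr - o) <= width), 0L)
      env_site <- rep(cand[which.max(dens)], n_site)
    } else {
      q <- stats::quantile(tr, c(0.05, 0.95))
      env_site <- q[1] + g_site * (q[2] - q[1])
    }
    delta <- outer(env_site, tr, "-")
    sel <- exp(-delta^2 / (2 * width^2))
    sel[abs(delta) > 2.5 * width] <- 0
  }

  counts <- matrix(0L, n_samp, K, dimnames = list(meta$sample_id, otus))
  for (s in seq_len(n_samp)) {
    i_site <- match(meta$site_code[s], sites)
    w <- site_pool[i_site, ] * sel[i_site, ]
    if (config$sample_noise_sd > 0) {
      w <- w * exp(stats::rnorm(K, 0, config$sample_noise_sd))
    }
    if (config$regime == "homogenizing_dispersal") {
      # mass effects maintain a common regional abundance ranking while
      # local capacity varies: communities are nested subsets of the
      # shared ranking, so membership is far more concordant than random
      # assembly at the same occupancy frequencies
      r_cap <- round(stats::runif(1, 0.35, 0.8) * K)
      keep <- order(w, decreasing = TRUE)[seq_len(max(2L, r_cap))]
      w[-keep] <- 0
    }
    if (sum(w) <= 0) stop("degenerate assembly weights for sample ", s)
    counts[s, ] <- as.integer(stats::rmultinom(1, config$depth, w))
  }
  counts
}

#' Generate a complete synthetic survey bundle
#'
#' Composes [simulate_tree()], [evolve_trait()], [simulate_sites()] and
#' [assemble_communities()] into one reproducible bundle, optionally writing
#' the standard files (otu_table.tsv, tree.nwk, metadata.tsv, truth.tsv,
#' config.json) to `out_dir`.
#'
#' @param config A [scenario_config()].
#' @param out_dir Optional output directory; created if missing.
#' @return A list of class `synthetic_bundle` with elements `counts`,
#'   `tree`, `meta`, `traits`, `truth` (tibble of sample pairs and their
#'   generative regime) and `config`.
#' @export
generate_bundle <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  tree <- simulate_tree(config$n_taxa, seed = config$seed)
  traits <- evolve_trait(tree, sigma = config$trait_sigma,
                         seed = config$seed + 3L)
  meta <- simulate_sites(config)
  counts <- assemble_communities(config, tree, traits, meta)

  ids <- meta$sample_id
  pairs <- utils::combn(ids, 2L)
  truth <- tibble::tibble(sample_a = pairs[1L, ], sample_b = pairs[2L, ],
                          true_regime = config$regime)

  bundle <- structure(
    list(counts = counts, tree = tree, meta = meta, traits = traits,
         truth = truth, config = config),
    class = "synthetic_bundle"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_otu_table(counts, file.path(out_dir, "otu_table.tsv"))
    ape::write.tree(tree, file.path(out_dir, "tree.nwk"))
    write_sample_metadata(meta, file.path(out_dir, "metadata.tsv"))
    utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
    cfg <- config
    class(cfg) <- NULL
    cfg$groups <- NULL
    jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  bundle
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("<synthetic_bundle>", nrow(x$counts), "samples x", ncol(x$counts),
      "OTUs, regime:", x$config$regime, "\n")
  invisible(x)
}
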