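#' Read a site-by-OTU count table from TSV
#'
#' The on-disk layout follows the common amplicon convention: rows are OTUs,
#' columns are samples, first column holds OTU identifiers, header row holds
#' sample identifiers. The returned matrix is transposed to the samples x OTUs
#' orientation used throughout the package (the `vegan` convention).
#'
#' Samples or OTUs whose counts are all zero are dropped with a message; a
#' negative, non-integer or missing cell is an error naming the offending
#' row and column.
#'
#' @param path Path to a tab-separated file.
#' @param samples_in_rows If `TRUE` the file already has samples in rows and
#'   is not transposed on load.
#' @return An integer matrix, samples in rows, OTUs in columns, with
#'   dimnames set.
#' @export
read_otu_table <- function(path, samples_in_rows = FALSE) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t", row.names = NULL,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
  if (ncol(raw) < 2L) {
    stop("OTU table must have an identifier column plus at least one data column")
  }
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicated identifiers in first column: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  header <- names(raw)[-1L]  # data-frame subsetting would uniquify these
  if (anyDuplicated(header)) {
    stop("duplicated column names: ",
         paste(unique(header[duplicated(header)]), collapse = ", "))
  }
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  colnames(mat) <- header
  bad <- which(!is.finite(mat) | mat < 0 | mat != round(mat), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("invalid count at row '%s', column '%s': must be a non-negative integer",
                 ids[bad[1L, 1L]], colnames(mat)[bad[1L, 2L]]))
  }
  storage.mode(mat) <- "integer"
  rownames(mat) <- ids
  counts <- if (samples_in_rows) mat else t(mat)
  validate_otu_table(counts)
}

#' @keywords internal
validate_otu_table <- function(counts, drop_empty = TRUE) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count matrix must carry sample (row) and OTU (column) names")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (drop_empty) {
    empty_s <- rowSums(counts) == 0
    if (any(empty_s)) {
      message("dropping ", sum(empty_s), " all-zero sample(s): ",
              paste(rownames(counts)[empty_s], collapse = ", "))
      counts <- counts[!empty_s, , drop = FALSE]
    }
    empty_o <- colSums(counts) == 0
    if (any(empty_o)) {
      message("dropping ", sum(empty_o), " all-zero OTU(s)")
      counts <- counts[, !empty_o, drop = FALSE]
    }
  }
  if (nrow(counts) == 0L) stop("no non-empty samples in OTU table")
  storage.mode(counts) <- "integer"
  counts
}

#' Write a site-by-OTU count table to TSV
#'
#' Inverse of [read_otu_table()]: emits OTUs in rows, samples in columns,
#' UTF-8, tab-delimited, '.' decimal.
#'
#' @param counts Samples x OTUs integer matrix.
#' @param path Output path.
#' @export
write_otu_table <- function(counts, path) {
  out <- t(counts)
  df <- data.frame(otu_id = rownames(out), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a rooted phylogeny from a newick file
#'
#' Branch lengths are required for all downstream phylogenetic statistics;
#' a tree without them is accepted with all lengths set to zero and a
#' warning. Duplicate tip labels are an error.
#'
#' @param path Path to a newick file containing a single tree.
#' @return An [ape::phylo] object.
#' @export
read_phylogeny <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("unparseable newick file: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("unparseable newick file: ", path)
  if (inherits(tree, "multiPhylo")) {
    stop("expected a single tree, found ", length(tree))
  }
  validate_phylogeny(tree)
}

#' @keywords internal
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; treating all as 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning("missing branch lengths treated as 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths not allowed")
  tree
}

#' Metadata column enumerations
#' @keywords internal
.habitat_levels <- c("water", "sediment")
.size_levels <- c("micro", "nano", "none")
.season_levels <- c("spring", "summer")

#' Read per-sample metadata from TSV
#'
#' Required columns: `sample_id`, `habitat` (water/sediment), `season`
#' (spring/summer), `latitude`, `longitude`. Optional: `size_fraction`
#' (micro/nano/none), `site_code`, and any number of numeric environmental
#' columns (salinity, pH, nutrients, heavy metals, ...). Missing
#' environmental values are allowed and propagate as `NA`.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A tibble, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  validate_sample_metadata(tibble::as_tibble(df))
}

#' @keywords internal
validate_sample_metadata <- function(meta) {
  required <- c("sample_id", "habitat", "season", "latitude", "longitude")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0L) {
    stop("metadata missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(meta$sample_id)) stop("duplicated sample_id in metadata")
  bad_hab <- setdiff(unique(meta$habitat), .habitat_levels)
  if (length(bad_hab) > 0L) {
    stop("unknown habitat value(s): ", paste(bad_hab, collapse = ", "),
         " (expected ", paste(.habitat_levels, collapse = "/"), ")")
  }
  bad_season <- setdiff(unique(meta$season), .season_levels)
  if (length(bad_season) > 0L) {
    stop("unknown season value(s): ", paste(bad_season, collapse = ", "))
  }
  if (!"size_fraction" %in% names(meta)) {
    meta$size_fraction <- ifelse(meta$habitat == "sediment", "none", NA_character_)
  }
  bad_size <- setdiff(unique(meta$size_fraction[!is.na(meta$size_fraction)]),
                      .size_levels)
  if (length(bad_size) > 0L) {
    stop("unknown size_fraction value(s): ", paste(bad_size, collapse = ", "))
  }
  if (any(meta$habitat == "water" & meta$size_fraction == "none", na.rm = TRUE)) {
    stop("water samples must carry a size_fraction of micro or nano")
  }
  if (any(meta$habitat == "sediment" & meta$size_fraction != "none", na.rm = TRUE)) {
    stop("sediment samples must have size_fraction 'none'")
  }
  if (any(!is.finite(meta$latitude)) || any(abs(meta$latitude) > 90)) {
    stop("latitude out of range [-90, 90]")
  }
  if (any(!is.finite(meta$longitude)) || any(abs(meta$longitude) > 180)) {
    stop("longitude out of range [-180, 180]")
  }
  meta
}

#' Write sample metadata to TSV
#' @param meta Metadata tibble.
#' @param path Output path.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a square distance matrix
#'
#' Plain TSV with row and column identifiers; validated to be symmetric,
#' zero-diagonal, finite and non-negative.
#'
#' @param path File path.
#' @return A symmetric numeric matrix with dimnames.
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                          check.names = FALSE)
  validate_distance_matrix(as.matrix(df))
}

#' @rdname read_distance_matrix
#' @param d Symmetric matrix or `dist` object.
#' @export
write_distance_matrix <- function(d, path) {
  m <- as.matrix(d)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @keywords internal
validate_distance_matrix <- function(m, nonneg = TRUE) {
  if (!isSymmetric(unname(m), tol = 1e-8)) stop("distance matrix not symmetric")
  if (any(!is.finite(m))) stop("distance matrix has non-finite entries")
  if (any(abs(diag(m)) > 1e-12)) stop("distance matrix diagonal not zero")
  if (nonneg && any(m < 0)) stop("distance matrix has negative entries")
  m
}

#' Align an OTU table, a phylogeny and sample metadata
#'
#' Restricts the count matrix to samples present in the metadata and to OTUs
#' that are tips of the tree, prunes the tree to the surviving OTUs, and
#' subsets/reorders the metadata to the surviving samples. All drops are
#' reported with counts. Aligning twice is a no-op.
#'
#' @param counts Samples x OTUs integer matrix.
#' @param tree An [ape::phylo] whose tips are a superset of the OTUs in scope.
#' @param meta Sample metadata tibble (see [read_sample_metadata()]).
#' @return A list with elements `counts`, `tree`, `meta`, aligned and
#'   consistently ordered.
#' @export
align_inputs <- function(counts, tree, meta) {
  shared_samples <- intersect(rownames(counts), meta$sample_id)
  if (length(shared_samples) == 0L) {
    stop("no samples shared between OTU table and metadata")
  }
  dropped_s <- (nrow(counts) - length(shared_samples)) +
    (nrow(meta) - length(shared_samples))
  shared_otus <- intersect(colnames(counts), tree$tip.label)
  if (length(shared_otus) == 0L) stop("no OTUs shared between table and tree")
  dropped_o <- ncol(counts) - length(shared_otus)
  if (dropped_s > 0L || dropped_o > 0L) {
    message("align_inputs: dropped ", dropped_s, " unmatched sample record(s) and ",
            dropped_o, " OTU(s) absent from the tree")
  }
  counts <- counts[shared_samples, shared_otus, drop = FALSE]
  counts <- validate_otu_table(counts)
  shared_otus <- colnames(counts)
  shared_samples <- rownames(counts)
  if (length(shared_samples) < 2L) stop("fewer than 2 samples survive alignment")
  if (length(shared_otus) < 3L) stop("fewer than 3 OTUs survive alignment")
  tree <- ape::keep.tip(tree, shared_otus)
  meta <- meta[match(shared_samples, meta$sample_id), , drop = FALSE]
  list(counts = counts, tree = tree, meta = meta)
}
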