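#' Construct a microbial profile dataset
#'
#' The package's container for samples-by-species numeric profiles: a matrix
#' with samples as rows and features (species) as columns, optional class
#' labels, an optional per-sample `unclassified` remainder (the share of the
#' community not attributed to any retained species, so that per-sample
#' totals are conserved by filtering), and optional per-sample metadata.
#'
#' @param abundance Numeric matrix, samples x features, with unique row
#'   (sample id) and column (feature) names. Values are relative abundances
#'   in percent (0-100) or binary presence (0/1).
#' @param labels Optional character/factor vector of class labels, one per
#'   sample (named or in row order).
#' @param unclassified Optional non-negative numeric vector, one value per
#'   sample: abundance not assigned to any feature column.
#' @param metadata Optional `data.frame` with at least a `sample_id` column
#'   covering all samples; conventional columns are `class`, `sex`
#'   (`male`/`female`/`unknown`), `age` (years) and `study`.
#'
#' @return An object of class `"profile_dataset"`.
#' @export
profile_dataset <- function(abundance, labels = NULL, unclassified = NULL,
                            metadata = NULL) {
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance)) || is.null(colnames(abundance)))
    stop("abundance matrix must have sample (row) and feature (column) names")
  if (anyDuplicated(rownames(abundance)))
    stop("duplicate sample ids")
  if (anyDuplicated(colnames(abundance)))
    stop("duplicate feature names")
  if (!is.numeric(abundance)) stop("abundance values must be numeric")
  if (any(abundance < 0)) stop("negative abundance values are not allowed")
  n <- nrow(abundance)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n)
      stop("labels must have one entry per sample")
    names(labels) <- rownames(abundance)
  }
  if (!is.null(unclassified)) {
    if (length(unclassified) != n)
      stop("unclassified must have one value per sample")
    if (any(unclassified < 0)) stop("unclassified values must be >= 0")
    unclassified <- as.numeric(unclassified)
    names(unclassified) <- rownames(abundance)
  }
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if (!"sample_id" %in% names(metadata))
      stop("metadata must contain a sample_id column")
    if (!all(rownames(abundance) %in% metadata$sample_id))
      stop("metadata must cover all samples")
    metadata <- metadata[match(rownames(abundance), metadata$sample_id), ,
                         drop = FALSE]
    rownames(metadata) <- NULL
  }
  structure(
    list(abundance = abundance, labels = labels,
         unclassified = unclassified, metadata = metadata),
    class = "profile_dataset")
}

#' @export
print.profile_dataset <- function(x, ...) {
  cat(sprintf("Microbial profile dataset: %d samples x %d features\n",
              nrow(x$abundance), ncol(x$abundance)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  classes:", paste(sprintf("%s (%d)", names(tab), tab),
                            collapse = ", "), "\n")
  }
  if (!is.null(x$unclassified))
    cat(sprintf("  unclassified remainder tracked (mean %.2f)\n",
                mean(x$unclassified)))
  if (!is.null(x$metadata))
    cat("  metadata columns:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

#' Subset the samples of a profile dataset
#'
#' @param x A [profile_dataset()].
#' @param samples Sample ids or a logical/integer index over rows.
#' @return A `profile_dataset` restricted to the chosen samples.
#' @export
subset_samples <- function(x, samples) {
  stopifnot(inherits(x, "profile_dataset"))
  ab <- x$abundance[samples, , drop = FALSE]
  ids <- rownames(ab)
  profile_dataset(
    ab,
    labels = if (!is.null(x$labels)) x$labels[ids],
    unclassified = if (!is.null(x$unclassified)) x$unclassified[ids],
    metadata = if (!is.null(x$metadata))
      x$metadata[x$metadata$sample_id %in% ids, , drop = FALSE])
}

# internal: drop feature columns, moving their abundance into the
# unclassified remainder so per-sample totals are conserved
drop_features <- function(x, drop) {
  if (length(drop) == 0L) return(x)
  moved <- rowSums(x$abundance[, drop, drop = FALSE])
  keep <- setdiff(colnames(x$abundance), drop)
  uncl <- if (is.null(x$unclassified)) rep(0, nrow(x$abundance)) else
    x$unclassified
  profile_dataset(x$abundance[, keep, drop = FALSE],
                  labels = x$labels,
                  unclassified = uncl + moved,
                  metadata = x$metadata)
}
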