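#' Read a MetaPhlAn-style relative-abundance table
#'
#' Parses a TSV with clade names in the first column and one column per
#' sample, values in percent (0-100). Only species-level rows (last clade
#' component starting with `s__`) are kept; rows of other taxonomic ranks
#' are ignored with a message. A row named `unclassified` (case
#' insensitive, or `UNKNOWN`) supplies the per-sample unclassified
#' remainder; when absent it is synthesized as `100 - column sum` (floored
#' at 0) with a warning.
#'
#' @param path Path to the TSV file. Lines starting with `#` before the
#'   header are skipped.
#' @param metadata Optional metadata `data.frame` (e.g. from
#'   [read_metadata()]); its `class` column, when present, supplies labels.
#' @return A [profile_dataset()] with samples as rows.
#' @export
read_profiles <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop("profile table not found: ", path)
  tab <- read.delim(path, check.names = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("profile table needs a clade column and >= 1 sample")
  clades <- as.character(tab[[1L]])
  vals <- tab[, -1L, drop = FALSE]
  bad <- which(!vapply(vals, is.numeric, TRUE))
  if (length(bad) > 0L) {
    col <- names(vals)[bad[1L]]
    row <- which(is.na(suppressWarnings(as.numeric(vals[[bad[1L]]]))))[1L]
    stop(sprintf("non-numeric abundance value at row '%s', sample '%s'",
                 clades[if (is.na(row)) 1L else row], col))
  }
  m <- as.matrix(vals)
  if (any(m < 0 | m > 100))
    stop("relative abundances must be within [0, 100]")
  is_uncl <- grepl("^(unclassified|unknown)$", clades, ignore.case = TRUE)
  is_species <- grepl("(^|\\|)s__[^|]+$", clades)
  skipped <- clades[!is_uncl & !is_species]
  if (length(skipped) > 0L)
    message(length(skipped), " non-species rows ignored (e.g. ",
            skipped[1L], ")")
  species <- m[is_species, , drop = FALSE]
  rownames(species) <- clades[is_species]
  if (any(is_uncl)) {
    unclassified <- colSums(m[is_uncl, , drop = FALSE])
  } else {
    warning("no unclassified row; synthesizing as 100 - column sums")
    unclassified <- pmax(0, 100 - colSums(species))
  }
  profile_dataset(t(species),
                  labels = if (!is.null(metadata) && "class" %in% names(metadata))
                    metadata$class[match(colnames(species),
                                         metadata$sample_id)],
                  unclassified = unclassified,
                  metadata = metadata)
}

#' Write a profile dataset as a MetaPhlAn-style table
#'
#' Inverse of [read_profiles()]: species as rows, samples as columns, with
#' an `unclassified` row when the dataset tracks one.
#'
#' @param x A [profile_dataset()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_profiles <- function(x, path) {
  stopifnot(inherits(x, "profile_dataset"))
  m <- t(x$abundance)
  if (!is.null(x$unclassified))
    m <- rbind(unclassified = x$unclassified, m)
  tab <- data.frame(clade_name = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write sample metadata tables
#'
#' Metadata TSVs have the columns `sample_id`, `class`, `sex`, `age`,
#' `study` (missing values as empty or NA).
#'
#' @param path TSV path.
#' @return `read_metadata`: a `data.frame`; `write_metadata`: `path`,
#'   invisibly.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata table not found: ", path)
  md <- read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(md))
    stop("metadata must contain a sample_id column")
  if (anyDuplicated(md$sample_id)) stop("duplicate sample ids in metadata")
  if ("age" %in% names(md)) {
    md$age <- suppressWarnings(as.numeric(md$age))
    if (any(md$age < 0, na.rm = TRUE)) stop("ages must be >= 0")
  }
  md
}

#' @rdname read_metadata
#' @param metadata A metadata `data.frame`.
#' @export
write_metadata <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
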