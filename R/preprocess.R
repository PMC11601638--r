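#' Harmonize abundance tables from multiple studies
#'
#' Merges per-study profile datasets into one: only species detected
#' (abundance > 0 in at least one sample) in *every* study are kept, and
#' every excluded species' abundance is added, per sample, to that sample's
#' unclassified remainder, so per-sample totals are conserved. Sample
#' columns are concatenated across studies.
#'
#' @param studies A list of [profile_dataset()] objects, one per study,
#'   each with an `unclassified` component. Names, when present, are
#'   recorded as the study of origin in the merged metadata.
#' @return A merged `profile_dataset`; the species dropped from each study
#'   are reported in `attr(, "excluded")`.
#' @export
harmonize_studies <- function(studies) {
  stopifnot(is.list(studies), length(studies) >= 1L)
  lapply(studies, function(s) stopifnot(inherits(s, "profile_dataset")))
  ids <- unlist(lapply(studies, function(s) rownames(s$abundance)))
  if (anyDuplicated(ids))
    stop("duplicate sample ids across studies: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  detected <- lapply(studies, function(s) {
    colnames(s$abundance)[colSums(s$abundance > 0) > 0]
  })
  keep <- Reduce(intersect, detected)
  if (length(keep) == 0L) stop("no species detected in every study")
  parts <- lapply(seq_along(studies), function(i) {
    s <- studies[[i]]
    drop <- setdiff(colnames(s$abundance), keep)
    s <- drop_features(s, drop)
    # align column order across studies
    s$abundance <- s$abundance[, keep, drop = FALSE]
    s
  })
  abundance <- do.call(rbind, lapply(parts, `[[`, "abundance"))
  labels <- unlist(lapply(parts, `[[`, "labels"))
  uncl <- unlist(lapply(parts, function(p) {
    if (is.null(p$unclassified)) rep(0, nrow(p$abundance)) else p$unclassified
  }))
  metas <- lapply(seq_along(parts), function(i) {
    m <- parts[[i]]$metadata
    if (is.null(m))
      m <- data.frame(sample_id = rownames(parts[[i]]$abundance))
    if (!"study" %in% names(m))
      m$study <- if (!is.null(names(studies))) names(studies)[i] else
        as.character(i)
    m
  })
  cols <- Reduce(union, lapply(metas, names))
  metas <- lapply(metas, function(m) {
    m[setdiff(cols, names(m))] <- NA
    m[cols]
  })
  out <- profile_dataset(abundance,
                         labels = if (!is.null(labels)) labels[rownames(abundance)],
                         unclassified = uncl,
                         metadata = do.call(rbind, metas))
  attr(out, "excluded") <- lapply(studies, function(s)
    setdiff(colnames(s$abundance), keep))
  out
}

#' Remove very low abundant species
#'
#' Species whose abundance never reaches `threshold` percent (by default:
#' whose *maximum* relative abundance across all samples is below 1%) are
#' removed and their abundance moved into the per-sample unclassified
#' remainder. `stat = "mean"` applies the criterion to the mean abundance
#' instead.
#'
#' @param x A [profile_dataset()] of relative abundances.
#' @param threshold Relative-abundance threshold in percent (default 1).
#' @param stat Summary the criterion is applied to: `"max"` (default,
#'   the most conservative remover) or `"mean"`.
#' @return The filtered dataset; removed species in `attr(, "excluded")`.
#' @export
filter_low_abundance <- function(x, threshold = 1.0,
                                 stat = c("max", "mean")) {
  stopifnot(inherits(x, "profile_dataset"))
  if (threshold < 0) stop("abundance threshold must be >= 0")
  stat <- match.arg(stat)
  s <- switch(stat,
              max = apply(x$abundance, 2L, max),
              mean = colMeans(x$abundance))
  drop <- colnames(x$abundance)[s < threshold]
  out <- drop_features(x, drop)
  attr(out, "excluded") <- drop
  out
}

#' Remove rarely detected species
#'
#' Species detected (abundance strictly greater than zero) in fewer than
#' `min_fraction` of the samples are removed, with their abundance moved
#' into the unclassified remainder. The inequality is strict: with 100
#' samples and the default 0.05, a species detected in 4 samples is removed
#' while one detected in 5 is kept.
#'
#' @param x A [profile_dataset()].
#' @param min_fraction Minimum detection fraction in `[0, 1]` (default 0.05).
#' @return The filtered dataset; removed species in `attr(, "excluded")`.
#' @export
filter_low_prevalence <- function(x, min_fraction = 0.05) {
  stopifnot(inherits(x, "profile_dataset"))
  if (min_fraction < 0 || min_fraction > 1)
    stop("min_fraction must be in [0, 1]")
  detected <- colSums(x$abundance > 0)
  drop <- colnames(x$abundance)[detected < min_fraction * nrow(x$abundance)]
  out <- drop_features(x, drop)
  attr(out, "excluded") <- drop
  out
}

#' Binarize abundance profiles to presence/absence
#'
#' Replaces every value by 1 when the relative abundance is strictly
#' positive and 0 otherwise. The unclassified remainder is dropped (it is
#' not a species feature). Idempotent.
#'
#' @param x A [profile_dataset()].
#' @return A binary `profile_dataset` without an unclassified component.
#' @export
binarize <- function(x) {
  stopifnot(inherits(x, "profile_dataset"))
  if (any(x$abundance < 0)) stop("negative abundance values are not allowed")
  b <- (x$abundance > 0) + 0
  profile_dataset(b, labels = x$labels, unclassified = NULL,
                  metadata = x$metadata)
}

#' Stratify samples by biological sex or age category
#'
#' Splits a dataset into strata using its metadata: `by = "sex"` yields
#' `male` and `female` subsets; `by = "age_category"` yields `adult`
#' (age <= 65) and `senior` (age > 65). Samples with a missing or unknown
#' stratification value are excluded from all strata and reported.
#'
#' @param x A [profile_dataset()] with metadata covering all samples.
#' @param by One of `"sex"`, `"age_category"`, `"none"`.
#' @return A list with `strata` (named list of `profile_dataset`s) and
#'   `excluded` (sample ids not assignable to a stratum). With
#'   `by = "none"` the single stratum `all` contains every sample.
#' @export
stratify_samples <- function(x, by = c("sex", "age_category", "none")) {
  stopifnot(inherits(x, "profile_dataset"))
  by <- match.arg(by)
  if (by == "none")
    return(list(strata = list(all = x), excluded = character(0)))
  md <- x$metadata
  if (is.null(md)) stop("sample metadata is required for stratification")
  ids <- rownames(x$abundance)
  value <- switch(by,
    sex = {
      v <- as.character(md$sex)
      v[!v %in% c("male", "female")] <- NA
      v
    },
    age_category = {
      age <- suppressWarnings(as.numeric(md$age))
      ifelse(is.na(age), NA, ifelse(age <= 65, "adult", "senior"))
    })
  names(value) <- md$sample_id
  value <- value[ids]
  groups <- if (by == "sex") c("male", "female") else c("adult", "senior")
  strata <- lapply(groups, function(g) {
    keep <- ids[!is.na(value) & value == g]
    if (length(keep) == 0L) return(NULL)
    subset_samples(x, keep)
  })
  names(strata) <- groups
  list(strata = strata[!vapply(strata, is.null, TRUE)],
       excluded = ids[is.na(value)])
}
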