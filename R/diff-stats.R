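#' Prevalence of a species within a class
#'
#' Percentage of samples in a class in which the species is present.
#'
#' @param presence Binary (0/1 or logical) presence vector over all samples.
#' @param class_mask Logical vector selecting the class's samples.
#' @return `100 * positives / class size`.
#' @examples
#' prevalence(c(1, 1, 0, 0), rep(TRUE, 4))  # 50
#' @export
prevalence <- function(presence, class_mask) {
  stopifnot(length(presence) == length(class_mask))
  if (!all(presence %in% c(0, 1)))
    stop("presence values must be binary (0/1)")
  n <- sum(class_mask)
  if (n == 0L) stop("empty class: prevalence is undefined")
  100 * sum(presence[class_mask] > 0) / n
}

#' log2 fold change of mean abundances
#'
#' `log2(mean(case) / mean(control))` on relative-abundance values. When
#' either group mean is zero the ratio is undefined in the usual sense; the
#' IEEE limit value is returned (`-Inf` when the case mean is 0, `Inf` when
#' the control mean is 0, `NaN` when both are) and flagged via the
#' `"defined"` attribute rather than raising an error.
#'
#' @param case,control Non-negative abundance values for each group.
#' @return The log2 ratio of means, with attribute `defined` (logical).
#' @examples
#' log2fc(c(2, 2), c(1, 1))  # 1
#' @export
log2fc <- function(case, control) {
  if (length(case) == 0L || length(control) == 0L)
    stop("both groups must be non-empty")
  if (any(case < 0) || any(control < 0))
    stop("abundance values must be non-negative")
  mc <- mean(case); mk <- mean(control)
  out <- log2(mc / mk)
  attr(out, "defined") <- mc > 0 && mk > 0
  out
}

#' Differential abundance of species between two classes
#'
#' For every species: prevalence per class (percentage of samples with
#' abundance > 0), log2 fold change of the mean relative abundances
#' (case over control), a two-sided Wilcoxon rank-sum p-value (exact when
#' the pooled sample size is below 50 and there are no ties, otherwise the
#' normal approximation with tie correction — `stats::wilcox.test`'s
#' default), and the Benjamini-Hochberg adjusted value computed across the
#' whole tested species family. A species is significant when both
#' `p_value <= p_threshold` and `fdr <= fdr_threshold`.
#'
#' @param x Samples x species relative-abundance matrix or
#'   [profile_dataset()].
#' @param labels Class label per sample (defaults to the dataset's labels).
#' @param case The label of the case class; the other label is the control.
#' @param species Optional subset of species to *report*; the BH correction
#'   is still computed over `family`.
#' @param family Species family the BH correction runs over: `"all"`
#'   (default; every species in `x`) or `"subset"` (only the reported ones).
#' @param p_threshold,fdr_threshold Significance thresholds (defaults 0.05
#'   and 0.2).
#' @return A `data.frame` with one row per reported species: `species`,
#'   `prevalence_case`, `prevalence_control`, `log2fc`, `log2fc_defined`,
#'   `p_value`, `fdr`, `significant`, `degenerate` (constant values in both
#'   groups, for which `p` is set to 1).
#' @export
diff_abundance <- function(x, labels = NULL, case = NULL, species = NULL,
                           family = c("all", "subset"),
                           p_threshold = 0.05, fdr_threshold = 0.2) {
  if (inherits(x, "profile_dataset")) {
    if (is.null(labels)) labels <- x$labels
    x <- x$abundance
  }
  x <- as.matrix(x)
  labels <- as.character(labels)
  family <- match.arg(family)
  classes <- sort(unique(labels))
  if (length(classes) != 2L)
    stop("differential abundance requires exactly 2 classes")
  if (is.null(case)) case <- classes[1L]
  if (!case %in% classes) stop("unknown case label: ", case)
  mask_case <- labels == case
  mask_ctrl <- !mask_case
  if (sum(mask_case) < 2L || sum(mask_ctrl) < 2L)
    stop("at least 2 samples per class are required")

  tested <- if (family == "subset" && !is.null(species)) species else
    colnames(x)
  stats_one <- function(sp) {
    v <- x[, sp]
    a <- v[mask_case]; b <- v[mask_ctrl]
    degenerate <- length(unique(c(a, b))) == 1L
    p <- if (degenerate) 1 else
      suppressWarnings(wilcox.test(a, b, alternative = "two.sided")$p.value)
    fc <- log2fc(a, b)
    data.frame(
      species = sp,
      prevalence_case = prevalence((v > 0) + 0, mask_case),
      prevalence_control = prevalence((v > 0) + 0, mask_ctrl),
      log2fc = as.numeric(fc),
      log2fc_defined = attr(fc, "defined"),
      p_value = p,
      degenerate = degenerate,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(tested, stats_one))
  out$fdr <- p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value <= p_threshold & out$fdr <= fdr_threshold
  if (!is.null(species)) out <- out[out$species %in% species, , drop = FALSE]
  rownames(out) <- NULL
  out[, c("species", "prevalence_case", "prevalence_control", "log2fc",
          "log2fc_defined", "p_value", "fdr", "significant", "degenerate")]
}
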