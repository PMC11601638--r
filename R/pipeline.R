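#' Run the end-to-end analysis pipeline
#'
#' Binds the package together behind one call, mirroring the command-line
#' interface (`inst/cli/hdselect.R`). Modes:
#' \describe{
#'   \item{`simulate`}{Generate a synthetic cohort ([simulate_profiles()])
#'     and write `profiles.tsv`, `metadata.tsv` and
#'     `informative_features.txt`.}
#'   \item{`classify`}{Preprocess and cross-validate the classifier; write
#'     `classification.json` (fold and mean accuracies).}
#'   \item{`select`}{Preprocess, run backward elimination, then
#'     differential abundance on the surviving species; write
#'     `selection_ledger.tsv`, `selection_summary.json` and `stats.tsv`.}
#'   \item{`stats`}{Preprocess and write `stats.tsv` only.}
#' }
#' Preprocessing applies the low-abundance and low-prevalence filters, then
#' optional binarization and stratification. Outputs are deterministic for
#' a fixed configuration and seed; on error, partial outputs of the failed
#' run are removed.
#'
#' @param mode One of `"simulate"`, `"classify"`, `"select"`, `"stats"`.
#' @param input Path to the profile TSV (all modes but `simulate`).
#' @param metadata Path to the metadata TSV (optional; required for
#'   stratification and labels).
#' @param output_dir Directory artifacts are written into (created when
#'   missing).
#' @param d,L Hypervector dimensionality and level count (defaults 10000
#'   and, per data type, 2 for binary / 1000 for relative abundances).
#' @param retrain Maximum retraining passes (default 10).
#' @param folds Cross-validation folds (default 5).
#' @param threshold Selection accuracy threshold as a fraction
#'   (default 0.60).
#' @param uncertainty Accuracy uncertainty percentage (default 1).
#' @param suboptimal_floor Sub-optimal model accuracy floor (default 0.70).
#' @param abundance_filter,prevalence_filter Preprocessing thresholds
#'   (defaults 1% RA and 0.05 detection fraction; set to 0 to disable).
#' @param binary Binarize profiles before classification/selection
#'   (default `TRUE`).
#' @param stratify_by `"none"` (default), `"sex"` or `"age_category"`;
#'   strata are processed independently into subdirectories.
#' @param case Case class label for the statistics (defaults to the first
#'   sorted label).
#' @param seed Integer seed controlling all randomness.
#' @param sim_args List of overrides passed to [simulate_profiles()] in
#'   `simulate` mode.
#' @param verbose Print progress to stderr (default `TRUE`).
#' @return Invisibly, a list of written artifact paths (per stratum).
#' @export
run_pipeline <- function(mode = c("select", "classify", "stats", "simulate"),
                         input = NULL, metadata = NULL, output_dir = ".",
                         d = 10000, L = NULL, retrain = 10, folds = 5,
                         threshold = 0.60, uncertainty = 1,
                         suboptimal_floor = 0.70,
                         abundance_filter = 1.0, prevalence_filter = 0.05,
                         binary = TRUE, stratify_by = "none", case = NULL,
                         seed = 1, sim_args = list(), verbose = TRUE) {
  mode <- match.arg(mode)
  say <- function(...) if (verbose) message(sprintf(...))
  if (!dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE)
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    stop(sprintf("pipeline stage '%s' failed: %s", mode, conditionMessage(e)),
         call. = FALSE)
  }
  tryCatch({
    if (mode == "simulate") {
      sim <- do.call(simulate_profiles, c(sim_args, list(seed = seed)))
      p1 <- file.path(output_dir, "profiles.tsv")
      p2 <- file.path(output_dir, "metadata.tsv")
      p3 <- file.path(output_dir, "informative_features.txt")
      write_profiles(sim$profiles, p1); written <- c(written, p1)
      write_metadata(sim$profiles$metadata, p2); written <- c(written, p2)
      writeLines(sim$informative, p3); written <- c(written, p3)
      say("simulate: wrote %d samples x %d species to %s",
          nrow(sim$profiles$abundance), ncol(sim$profiles$abundance),
          output_dir)
      return(invisible(list(paths = written)))
    }

    md <- if (!is.null(metadata)) read_metadata(metadata) else NULL
    ds <- read_profiles(input, metadata = md)
    say("loaded %d samples x %d species", nrow(ds$abundance),
        ncol(ds$abundance))
    if (abundance_filter > 0) ds <- filter_low_abundance(ds, abundance_filter)
    if (prevalence_filter > 0) ds <- filter_low_prevalence(ds, prevalence_filter)
    say("after filters: %d species", ncol(ds$abundance))
    ds_ra <- ds                       # statistics use relative abundances
    strata <- stratify_samples(ds, by = stratify_by)$strata

    out <- list()
    for (nm in names(strata)) {
      sd_ra <- if (stratify_by == "none") ds_ra else
        subset_samples(ds_ra, rownames(strata[[nm]]$abundance))
      work <- if (binary) binarize(strata[[nm]]) else strata[[nm]]
      dir <- if (stratify_by == "none") output_dir else
        file.path(output_dir, nm)
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      if (is.null(work$labels))
        stop("class labels are required (provide a metadata table)")

      if (mode == "classify") {
        cvres <- hd_crossval(work, k = folds, d = d, L = L,
                             retrain = retrain, seed = seed)
        p <- file.path(dir, "classification.json")
        jsonlite::write_json(list(
          stratum = nm, n_samples = nrow(work$abundance),
          n_features = ncol(work$abundance),
          mean_accuracy = round(cvres$mean_accuracy, 6),
          fold_accuracy = round(cvres$fold_accuracy, 6),
          fold_retrain_iterations = cvres$fold_retrain_iterations,
          seed = seed), p, auto_unbox = TRUE, pretty = TRUE)
        written <- c(written, p)
        say("[%s] mean CV accuracy %.4f", nm, cvres$mean_accuracy)
        out[[nm]] <- cvres
      } else if (mode == "select") {
        sel <- hd_select(work, threshold = threshold,
                         uncertainty = uncertainty,
                         suboptimal_floor = suboptimal_floor, folds = folds,
                         retrain = retrain, d = d, L = L, seed = seed)
        paths <- c(file.path(dir, "selection_ledger.tsv"),
                   file.path(dir, "selection_summary.json"))
        write_selection(sel, paths[1L], paths[2L])
        written <- c(written, paths)
        say("[%s] selected %d features; best accuracy %.4f (%d fold-models)",
            nm, length(sel$selected_features), sel$best_accuracy,
            sel$models_evaluated)
        stats <- diff_abundance(sd_ra, case = case)
        p <- file.path(dir, "stats.tsv")
        write.table(stats, p, sep = "\t", quote = FALSE, row.names = FALSE)
        written <- c(written, p)
        out[[nm]] <- sel
      } else if (mode == "stats") {
        stats <- diff_abundance(sd_ra, case = case)
        p <- file.path(dir, "stats.tsv")
        write.table(stats, p, sep = "\t", quote = FALSE, row.names = FALSE)
        written <- c(written, p)
        say("[%s] %d species tested, %d significant", nm, nrow(stats),
            sum(stats$significant))
        out[[nm]] <- stats
      }
    }
    invisible(list(paths = written, results = out))
  }, error = on_fail)
}
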