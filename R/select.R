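#' Backward variable elimination over hyperdimensional classifiers
#'
#' Wrapper feature selection: starting from all features, every iteration
#' evaluates (by stratified k-fold cross-validated accuracy) one candidate
#' model per feature, each lacking exactly that feature, and permanently
#' removes the features whose candidate accuracy falls within an uncertainty
#' band below the iteration best. Selection only starts if the full model's
#' accuracy reaches the threshold `T`, and stops when the iteration best
#' drops below `T`, below the previous iteration's best, or when no features
#' remain.
#'
#' The accuracy band: with iteration best `ACC*` and uncertainty percentage
#' `u`, every candidate with accuracy `>= ACC* * (1 - u/100)` (and `>= T`)
#' is removed in the same iteration, in exact arithmetic. Set
#' `multi_removal = FALSE` to remove only the single best candidate per
#' iteration (ties go to the feature earliest in the original feature
#' order). The previous-best stop is band-adjusted and checked before any
#' removal: the run ends, leaving the current subset intact, as soon as the
#' iteration best drops below `prev_best * (1 - u/100)`. The reported
#' alternative optimum, `best_feature_set`, is the globally best-accuracy
#' subset evaluated at any point (ties: fewest features, then
#' lexicographic).
#'
#' Per-subset RNG seeds are derived from a hash of the sorted feature subset
#' and the global seed, so candidate evaluations are order-independent and
#' repeated subsets are served from a cache. `models_evaluated` counts
#' fold-models: `k` per distinct subset evaluated.
#'
#' @param x Samples x features matrix or [profile_dataset()].
#' @param labels Class labels (defaults to the dataset's labels).
#' @param threshold Accuracy threshold `T` as a fraction (default 0.60).
#' @param uncertainty Accuracy uncertainty percentage `u` (default 1).
#' @param suboptimal_floor Accuracy floor for the sub-optimal model record
#'   (default 0.70).
#' @param folds Cross-validation folds `k` (default 5).
#' @param retrain Maximum retraining passes `R` (default 10).
#' @param d Hypervector dimensionality (default 10000).
#' @param L Number of levels (default: 2 for binary data, 1000 otherwise).
#' @param registry Optional pre-built [hd_levels()] registry shared by all
#'   candidate models; built once from the full dataset when omitted.
#' @param seed Global seed: registry generation and per-subset fold
#'   partitions derive from it.
#' @param multi_removal Remove all features in the uncertainty band
#'   (default `TRUE`) or only the single best candidate.
#' @param oracle Optional accuracy oracle for testing: a function taking a
#'   character vector of feature names and returning the mean accuracy of
#'   the model restricted to them (`NA` for subsets outside its domain).
#'   Replaces HD training entirely.
#'
#' @return An object of class `"hd_selection"`: `selected_features` (the
#'   surviving subset), `bucket` (removed features in removal order),
#'   `history` (one row per evaluated candidate: iteration, missing
#'   feature, subset size, mean accuracy, below-threshold and removed
#'   flags), `fold_accuracy` (list parallel to `history`), `subsets` (list
#'   of evaluated feature sets parallel to `history`), `best_accuracy` and
#'   `best_feature_set`, `suboptimal` (see [suboptimal_best()]),
#'   `models_evaluated`, `iterations`, and the configuration.
#'
#' @examples
#' sim <- simulate_profiles(n_case = 20, n_control = 20, n_species = 8,
#'                          n_informative = 2, seed = 1)
#' bin <- binarize(sim$profiles)
#' sel <- hd_select(bin, d = 256, folds = 4, seed = 1)
#' print(sel)
#' @export
hd_select <- function(x, labels = NULL, threshold = 0.60, uncertainty = 1,
                      suboptimal_floor = 0.70, folds = 5, retrain = 10,
                      d = 10000, L = NULL, registry = NULL, seed = 1,
                      multi_removal = TRUE, oracle = NULL) {
  if (inherits(x, "profile_dataset")) {
    if (is.null(labels)) labels <- x$labels
    x <- x$abundance
  }
  x <- as.matrix(x)
  if (nrow(x) == 0L || ncol(x) == 0L) stop("dataset must be non-empty")
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be a fraction in (0, 1)")
  if (uncertainty < 0 || uncertainty >= 100)
    stop("uncertainty must be a percentage in [0, 100)")
  if (suboptimal_floor <= 0 || suboptimal_floor >= 1)
    stop("suboptimal_floor must be a fraction in (0, 1)")
  feature_names <- colnames(x)
  if (is.null(feature_names)) {
    feature_names <- sprintf("F%d", seq_len(ncol(x)))
    colnames(x) <- feature_names
  }
  if (is.null(oracle) && is.null(registry))
    registry <- default_registry(x, d, L, seed)

  cache <- new.env(parent = emptyenv())
  n_subsets <- 0L
  eval_subset <- function(features) {
    key <- paste(sort(features), collapse = "\r")
    if (!is.null(cache[[key]])) return(cache[[key]])
    n_subsets <<- n_subsets + 1L
    res <- if (!is.null(oracle)) {
      acc <- oracle(sort(features))
      if (is.null(acc) || length(acc) != 1L || is.na(acc))
        stop("accuracy oracle has no value for subset {",
             paste(sort(features), collapse = ", "), "}")
      list(mean_accuracy = as.numeric(acc),
           fold_accuracy = rep(NA_real_, folds))
    } else {
      cv <- hd_crossval(x[, features, drop = FALSE], labels, k = folds,
                        registry = registry, retrain = retrain,
                        seed = subset_seed(seed, features))
      list(mean_accuracy = cv$mean_accuracy, fold_accuracy = cv$fold_accuracy)
    }
    cache[[key]] <- res
    res
  }

  history <- list()
  subsets <- list()
  fold_accs <- list()
  record <- function(iteration, missing, features, res, removed = FALSE) {
    i <- length(history) + 1L
    history[[i]] <<- data.frame(
      iteration = iteration,
      missing_feature = if (is.na(missing)) NA_character_ else missing,
      n_features = length(features),
      mean_accuracy = res$mean_accuracy,
      below_threshold = res$mean_accuracy < threshold,
      removed = removed,
      stringsAsFactors = FALSE)
    subsets[[i]] <<- sort(features)
    fold_accs[[i]] <<- res$fold_accuracy
    i
  }

  S <- feature_names
  bucket <- character(0)
  full <- eval_subset(S)
  record(0L, NA_character_, S, full)
  iterations <- 0L

  if (full$mean_accuracy >= threshold) {
    prev_best <- full$mean_accuracy
    repeat {
      # a single surviving feature is terminal: the only thinner candidate
      # would be the empty set, which no classifier can be built on
      if (length(S) <= 1L) break
      iterations <- iterations + 1L
      rows <- integer(length(S))
      accs <- numeric(length(S))
      for (j in seq_along(S)) {
        cand <- setdiff(S, S[j])
        res <- eval_subset(cand)
        rows[j] <- record(iterations, S[j], cand, res)
        accs[j] <- res$mean_accuracy
      }
      acc_star <- max(accs)
      if (acc_star < threshold) break
      # stop before removing anything once the iteration best falls out of
      # the uncertainty band below the previous iteration's best
      if (acc_star < prev_best * (1 - uncertainty / 100)) break
      if (multi_removal) {
        band <- acc_star * (1 - uncertainty / 100)
        rm_idx <- which(accs >= band & accs >= threshold)
      } else {
        rm_idx <- which(accs == acc_star)[1L]
      }
      removed <- S[rm_idx]
      for (i in rows[rm_idx]) history[[i]]$removed <- TRUE
      bucket <- c(bucket, removed)
      S <- setdiff(S, removed)
      prev_best <- acc_star
    }
  }

  history <- do.call(rbind, history)
  rownames(history) <- NULL
  acc_all <- history$mean_accuracy
  sizes <- history$n_features
  keys <- vapply(subsets, paste, "", collapse = ", ")
  ord <- order(-acc_all, sizes, keys)    # ties: fewest features, then lexicographic
  best <- ord[1L]

  structure(
    list(selected_features = S, bucket = bucket, history = history,
         fold_accuracy = fold_accs, subsets = subsets,
         best_accuracy = acc_all[best], best_feature_set = subsets[[best]],
         suboptimal = suboptimal_best(subsets, acc_all,
                                      floor = suboptimal_floor),
         models_evaluated = n_subsets * as.integer(folds),
         iterations = iterations,
         config = list(threshold = threshold, uncertainty = uncertainty,
                       suboptimal_floor = suboptimal_floor, folds = folds,
                       retrain = retrain,
                       d = if (is.null(registry)) d else registry$d,
                       L = if (is.null(registry)) L else registry$L,
                       seed = seed, multi_removal = multi_removal)),
    class = "hd_selection")
}

#' Sub-optimal model: fewest features above an accuracy floor
#'
#' Scans evaluated feature subsets for the one with the minimum number of
#' features whose accuracy is still strictly greater than `floor` (the
#' "sub-optimal" model: slightly less accurate than the best, far fewer
#' features). Ties are broken by higher accuracy, then by lexicographic
#' feature list.
#'
#' @param subsets Either an `"hd_selection"` object, or a list of character
#'   feature vectors (one per evaluated model).
#' @param accuracy Mean accuracies parallel to `subsets` (ignored when an
#'   `"hd_selection"` is given).
#' @param floor Accuracy floor as a fraction (default 0.70).
#' @return A list with `features`, `n_features` and `accuracy`, or `NULL`
#'   when no evaluated subset exceeds the floor.
#' @examples
#' recs <- list(c("a", "b", "c", "d", "e"), c("a", "b", "c"), c("c", "d", "e"))
#' suboptimal_best(recs, c(0.72, 0.71, 0.69), floor = 0.70)
#' @export
suboptimal_best <- function(subsets, accuracy = NULL, floor = 0.70) {
  if (inherits(subsets, "hd_selection")) {
    accuracy <- subsets$history$mean_accuracy
    subsets <- subsets$subsets
  }
  stopifnot(length(subsets) == length(accuracy))
  ok <- which(accuracy > floor)
  if (length(ok) == 0L) return(NULL)
  sizes <- lengths(subsets)[ok]
  keys <- vapply(subsets[ok], paste, "", collapse = ", ")
  pick <- ok[order(sizes, -accuracy[ok], keys)][1L]
  list(features = subsets[[pick]], n_features = length(subsets[[pick]]),
       accuracy = accuracy[pick])
}

#' @export
print.hd_selection <- function(x, ...) {
  cat("Backward variable elimination over hyperdimensional classifiers\n")
  cat(sprintf("  %d iterations, %d fold-models evaluated\n",
              x$iterations, x$models_evaluated))
  cat(sprintf("  selected %d features (removed %d): %s\n",
              length(x$selected_features), length(x$bucket),
              paste(x$selected_features, collapse = ", ")))
  cat(sprintf("  best accuracy %.4f with %d features\n",
              x$best_accuracy, length(x$best_feature_set)))
  if (!is.null(x$suboptimal))
    cat(sprintf(
      "  sub-optimal model (> %.0f%% accuracy): %d features at %.4f\n",
      100 * x$config$suboptimal_floor, x$suboptimal$n_features,
      x$suboptimal$accuracy))
  invisible(x)
}

#' @export
summary.hd_selection <- function(object, ...) {
  h <- object$history
  per_iter <- do.call(rbind, lapply(split(h, h$iteration), function(g) {
    data.frame(iteration = g$iteration[1L], candidates = nrow(g),
               best_accuracy = max(g$mean_accuracy),
               removed = sum(g$removed))
  }))
  rownames(per_iter) <- NULL
  out <- list(per_iteration = per_iter,
              selected = object$selected_features,
              bucket = object$bucket,
              best_accuracy = object$best_accuracy,
              best_feature_set = object$best_feature_set,
              suboptimal = object$suboptimal,
              models_evaluated = object$models_evaluated)
  class(out) <- "summary.hd_selection"
  out
}

#' @export
print.summary.hd_selection <- function(x, ...) {
  cat("Backward variable elimination summary\n")
  print(x$per_iteration, row.names = FALSE)
  cat(sprintf("selected: %s\n", paste(x$selected, collapse = ", ")))
  cat(sprintf("best accuracy %.4f with %d features\n",
              x$best_accuracy, length(x$best_feature_set)))
  invisible(x)
}

#' Write a selection ledger and summary to disk
#'
#' Writes the per-candidate evaluation ledger as TSV (iteration, candidate
#' missing feature, mean accuracy as a fraction with 6 decimals, per-fold
#' accuracies, removed flag) and a JSON summary (selected features, best
#' accuracy and subset, sub-optimal record, models evaluated).
#'
#' @param selection An `"hd_selection"` object.
#' @param ledger_path,summary_path Output file paths (either may be `NULL`
#'   to skip that file).
#' @return Invisibly, the paths written.
#' @export
write_selection <- function(selection, ledger_path = NULL,
                            summary_path = NULL) {
  stopifnot(inherits(selection, "hd_selection"))
  written <- character(0)
  if (!is.null(ledger_path)) {
    h <- selection$history
    led <- data.frame(
      iteration = h$iteration,
      candidate_missing_feature = ifelse(is.na(h$missing_feature), "-",
                                         h$missing_feature),
      n_features = h$n_features,
      mean_accuracy = sprintf("%.6f", h$mean_accuracy),
      fold_accuracies = vapply(selection$fold_accuracy, function(a) {
        if (all(is.na(a))) "-" else paste(sprintf("%.6f", a), collapse = ",")
      }, ""),
      below_threshold = h$below_threshold,
      removed = h$removed)
    write.table(led, ledger_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    written <- c(written, ledger_path)
  }
  if (!is.null(summary_path)) {
    sub <- selection$suboptimal
    out <- list(
      selected_features = selection$selected_features,
      removed_features = selection$bucket,
      best_accuracy = round(selection$best_accuracy, 6),
      best_feature_set = selection$best_feature_set,
      suboptimal = if (is.null(sub)) NULL else
        list(features = sub$features, n_features = sub$n_features,
             accuracy = round(sub$accuracy, 6)),
      models_evaluated = selection$models_evaluated,
      iterations = selection$iterations,
      config = selection$config)
    jsonlite::write_json(out, summary_path, auto_unbox = TRUE, null = "null",
                         pretty = TRUE)
    written <- c(written, summary_path)
  }
  invisible(written)
}
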