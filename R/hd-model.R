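#' Encode samples into hypervectors
#'
#' Encodes each sample (a length-F numeric vector) as the bundle, over
#' features `n = 0 .. F-1`, of the level hypervector of the n-th value
#' rotated by `n` positions: the first feature's level vector is not
#' permuted, the second is rotated by one position, and so on. Rotation tags
#' the feature identity, bundling superposes the tagged values.
#'
#' @param registry An [hd_levels()] registry whose range covers all values.
#' @param x A numeric vector (one sample) or a samples x features matrix.
#' @return A numeric vector of length `d` for a single sample, otherwise an
#'   `n x d` matrix with one encoding per row.
#' @examples
#' reg <- hd_levels(d = 64, L = 2, v_min = 0, v_max = 1, seed = 1)
#' enc <- encode_samples(reg, c(0, 1, 1))
#' length(enc)  # 64
#' @export
encode_samples <- function(registry, x) {
  stopifnot(inherits(registry, "hd_levels"))
  single <- !is.matrix(x)
  if (single) x <- matrix(x, nrow = 1L)
  if (ncol(x) < 1L) stop("at least one feature is required")
  idx <- level_index(registry, x) + 1L     # rows into the level matrix
  if (!is.matrix(idx)) idx <- matrix(idx, nrow = nrow(x))
  d <- registry$d
  E <- matrix(0, nrow(x), d)
  cols <- seq_len(d) - 1L
  for (n in seq_len(ncol(x))) {
    p <- (n - 1L) %% d
    # rows of `levels` right-rotated by p: new column j takes old (j-p) mod d
    rot <- registry$levels[, ((cols - p) %% d) + 1L, drop = FALSE]
    E <- E + rot[idx[, n], , drop = FALSE]
  }
  rownames(E) <- rownames(x)
  if (single) E[1L, ] else E
}

#' Fit a hyperdimensional classifier
#'
#' Trains the vector-symbolic classifier: every training sample is encoded
#' with [encode_samples()] and the class hypervector of each class is the
#' element-wise sum (bundle) of its samples' encodings. Bundling introduces
#' crosstalk noise, which is mitigated by iterative retraining: samples are
#' revisited in dataset order and each misclassified sample's encoding is
#' subtracted from the wrongly predicted class vector and added to the true
#' one, until the training error count stops changing or `retrain` passes
#' have run.
#'
#' @param x Samples x features numeric matrix, or a [profile_dataset()]
#'   (its `labels` are used when `labels` is missing).
#' @param labels Class label per sample (at least two distinct classes).
#' @param registry An [hd_levels()] registry; built from `d`, `L` and the
#'   observed value range when omitted.
#' @param d Hypervector dimensionality used when building a registry
#'   (default 10000).
#' @param L Number of levels when building a registry; defaults to 2 for
#'   binary (0/1) data and 1000 otherwise.
#' @param retrain Maximum number of retraining passes `R` (default 10);
#'   `0` disables retraining.
#' @param seed Seed for registry generation when one is built here.
#'
#' @return An object of class `"hd_model"` with components `class_vectors`
#'   (one row per class, in sorted label order), `classes`, `registry`,
#'   `R`, `retrain_iterations_used`, `training_error_trace` (error count at
#'   each evaluation, starting from the un-retrained model), `adjustments`
#'   (one row per retraining update: pass, sample index, wrong class, true
#'   class) and `n_features`.
#'
#' @seealso [predict.hd_model()], [hd_evaluate()], [hd_crossval()]
#' @export
hd_model <- function(x, labels = NULL, registry = NULL, d = 10000,
                     L = NULL, retrain = 10, seed = NULL) {
  if (inherits(x, "profile_dataset")) {
    if (is.null(labels)) labels <- x$labels
    x <- x$abundance
  }
  x <- as.matrix(x)
  if (is.null(labels)) stop("class labels are required for training")
  labels <- as.character(labels)
  if (length(labels) != nrow(x)) stop("one label per sample is required")
  if (nrow(x) == 0L) stop("training data must be non-empty")
  if (length(unique(labels)) < 2L)
    stop("at least 2 distinct classes are required for training")
  if (retrain < 0) stop("the retraining iteration cap must be >= 0")
  if (is.null(registry)) registry <- default_registry(x, d, L, seed)
  E <- encode_samples(registry, x)
  fit_from_encodings(E, labels, registry, retrain,
                     feature_names = colnames(x))
}

# build a registry from the data: binary data gets L = 2 over [0, 1],
# anything else L = 1000 over the observed range
default_registry <- function(x, d, L, seed) {
  vals <- range(x)
  binary <- all(x %in% c(0, 1))
  if (is.null(L)) L <- if (binary) 2L else 1000L
  if (binary) { vals <- c(0, 1) }
  if (vals[1] == vals[2]) vals[2] <- vals[1] + 1  # degenerate constant data
  hd_levels(d = d, L = L, v_min = vals[1], v_max = vals[2], seed = seed)
}

# core fit from precomputed encodings (shared with cross-validation, where
# encodings are computed once and folds reuse them)
fit_from_encodings <- function(E, labels, registry, retrain,
                               feature_names = NULL) {
  classes <- sort(unique(labels))
  y <- match(labels, classes)
  cv0 <- rowsum(E, labels)             # initial bundles, sorted label order
  cv0 <- cv0[classes, , drop = FALSE]
  res <- .hd_retrain_cpp(E, y, cv0, as.integer(retrain))
  cvs <- res$class_vectors
  rownames(cvs) <- classes
  adj <- res$adjustments
  adj$from <- classes[adj$from]
  adj$to <- classes[adj$to]
  structure(
    list(class_vectors = cvs, classes = classes, registry = registry,
         R = as.integer(retrain), retrain_iterations_used = res$passes,
         training_error_trace = res$error_trace, adjustments = adj,
         initial_class_vectors = cv0,
         n_features = ncol_or_null(feature_names, registry),
         feature_names = feature_names, n_train = nrow(E)),
    class = "hd_model")
}

ncol_or_null <- function(feature_names, registry) {
  if (!is.null(feature_names)) length(feature_names) else NA_integer_
}

#' Continue retraining a fitted classifier
#'
#' Runs additional error-mitigation passes of the online retraining loop on
#' a training set, starting from the model's current class vectors. Exposed
#' mainly so the retraining contract (iteration cap, convergence on equal
#' consecutive error counts, exact adjustment accounting) can be exercised
#' independently of [hd_model()].
#'
#' @param model A fitted `"hd_model"`.
#' @param x Training samples x features matrix (or [profile_dataset()]).
#' @param labels Class labels (defaults to the dataset's labels).
#' @param max_iterations Pass cap `R` (>= 0).
#' @return The updated `"hd_model"`; `retrain_iterations_used`,
#'   `training_error_trace` and `adjustments` describe this run.
#' @export
hd_retrain <- function(model, x, labels = NULL, max_iterations = 10) {
  stopifnot(inherits(model, "hd_model"))
  if (inherits(x, "profile_dataset")) {
    if (is.null(labels)) labels <- x$labels
    x <- x$abundance
  }
  if (max_iterations < 0) stop("the retraining iteration cap must be >= 0")
  labels <- as.character(labels)
  y <- match(labels, model$classes)
  if (anyNA(y)) stop("labels contain classes unknown to the model")
  E <- encode_samples(model$registry, as.matrix(x))
  res <- .hd_retrain_cpp(E, y, model$class_vectors,
                         as.integer(max_iterations))
  out <- model
  out$class_vectors <- res$class_vectors
  rownames(out$class_vectors) <- model$classes
  out$R <- as.integer(max_iterations)
  out$retrain_iterations_used <- res$passes
  out$training_error_trace <- res$error_trace
  adj <- res$adjustments
  adj$from <- model$classes[adj$from]
  adj$to <- model$classes[adj$to]
  out$adjustments <- adj
  out
}

#' Predict classes with a hyperdimensional classifier
#'
#' Encodes each new sample and assigns the label of the class hypervector
#' with the highest cosine similarity. Exact ties are broken in favour of
#' the lexicographically smallest class label.
#'
#' @param object A fitted `"hd_model"`.
#' @param newdata Samples x features matrix (or a numeric vector for a
#'   single sample, or a [profile_dataset()]).
#' @param type `"class"` for labels (default), `"similarity"` for the full
#'   samples x classes cosine matrix.
#' @param ... Unused.
#' @return Character vector of predicted labels, or the similarity matrix.
#' @export
predict.hd_model <- function(object, newdata, type = c("class", "similarity"),
                             ...) {
  type <- match.arg(type)
  if (inherits(newdata, "profile_dataset")) newdata <- newdata$abundance
  E <- encode_samples(object$registry, newdata)
  if (!is.matrix(E)) E <- matrix(E, nrow = 1L)
  sims <- cosine_matrix(E, object$class_vectors)
  if (type == "similarity") return(sims)
  object$classes[max.col(sims, ties.method = "first")]
}

# cosine between every row of E (samples) and every row of cvs (classes);
# errors on zero-norm vectors, naming the offending class
cosine_matrix <- function(E, cvs) {
  ne <- sqrt(rowSums(E^2))
  if (any(ne == 0))
    stop("cosine similarity is undefined: a sample encodes to the zero vector")
  ncl <- sqrt(rowSums(cvs^2))
  if (any(ncl == 0))
    stop("cosine similarity is undefined: class vector for '",
         rownames(cvs)[which(ncl == 0)[1L]], "' is all-zero")
  sims <- tcrossprod(E, cvs) / outer(ne, ncl)
  colnames(sims) <- rownames(cvs)
  sims
}

#' @export
print.hd_model <- function(x, ...) {
  cat(sprintf(
    "Hyperdimensional classifier: %d classes, d = %d, L = %d levels\n",
    length(x$classes), x$registry$d, x$registry$L))
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat(sprintf("  retraining: %d of at most %d passes; training errors %s\n",
              x$retrain_iterations_used, x$R,
              paste(x$training_error_trace, collapse = " -> ")))
  invisible(x)
}

#' @export
summary.hd_model <- function(object, ...) {
  tr <- object$training_error_trace
  out <- list(
    classes = object$classes,
    d = object$registry$d, L = object$registry$L,
    n_train = object$n_train,
    retrain_cap = object$R,
    retrain_passes = object$retrain_iterations_used,
    error_trace = tr,
    final_training_accuracy = 1 - tr[length(tr)] / object$n_train,
    n_adjustments = nrow(object$adjustments))
  class(out) <- "summary.hd_model"
  out
}

#' @export
print.summary.hd_model <- function(x, ...) {
  cat(sprintf("Hyperdimensional classifier (d = %d, L = %d)\n", x$d, x$L))
  cat(sprintf("  trained on %d samples over %d classes: %s\n", x$n_train,
              length(x$classes), paste(x$classes, collapse = ", ")))
  cat(sprintf("  retraining passes used: %d / %d (%d adjustments)\n",
              x$retrain_passes, x$retrain_cap, x$n_adjustments))
  cat(sprintf("  training error trace: %s (final accuracy %.4f)\n",
              paste(x$error_trace, collapse = " -> "),
              x$final_training_accuracy))
  invisible(x)
}

#' @export
coef.hd_model <- function(object, ...) object$class_vectors

#' Evaluate classifier accuracy on a labelled dataset
#'
#' @param model A fitted `"hd_model"`.
#' @param x Samples x features matrix or [profile_dataset()].
#' @param labels True class labels (defaults to the dataset's labels).
#' @return A list with `accuracy` (correct / total) and `errors`
#'   (total - correct).
#' @export
hd_evaluate <- function(model, x, labels = NULL) {
  if (inherits(x, "profile_dataset")) {
    if (is.null(labels)) labels <- x$labels
    x <- x$abundance
  }
  if (is.null(dim(x)) || nrow(x) == 0L) stop("evaluation data must be non-empty")
  labels <- as.character(labels)
  pred <- predict(model, x)
  correct <- sum(pred == labels)
  list(accuracy = correct / length(labels),
       errors = length(labels) - correct)
}

#' Stratified k-fold cross-validation of the classifier
#'
#' Partitions samples into `k` class-stratified folds (seeded, so the
#' partition is reproducible), then for each fold trains and retrains on
#' the remaining folds and evaluates on the held-out one. The level
#' registry is built once from the whole dataset's value range and shared
#' across folds: levels encode values, not samples, and a shared registry
#' keeps fold accuracies comparable.
#'
#' @inheritParams hd_model
#' @param k Number of folds (>= 2); every class must have at least `k`
#'   samples.
#' @param seed Seed controlling the fold partition (and registry
#'   generation when no registry is supplied).
#' @return A list with `mean_accuracy`, `fold_accuracy`,
#'   `fold_retrain_iterations`, and `folds` (fold id per sample).
#' @export
hd_crossval <- function(x, labels = NULL, k = 5, registry = NULL, d = 10000,
                        L = NULL, retrain = 10, seed = NULL) {
  if (inherits(x, "profile_dataset")) {
    if (is.null(labels)) labels <- x$labels
    x <- x$abundance
  }
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (k < 2) stop("at least 2 folds are required")
  if (is.null(registry)) registry <- default_registry(x, d, L, seed)
  folds <- stratified_folds(labels, k, seed)
  E <- encode_samples(registry, x)   # encodings do not depend on the fold
  fold_acc <- numeric(k)
  fold_iters <- integer(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- fit_from_encodings(E[tr, , drop = FALSE], labels[tr],
                              registry, retrain)
    sims <- cosine_matrix(E[!tr, , drop = FALSE], fit$class_vectors)
    pred <- fit$classes[max.col(sims, ties.method = "first")]
    fold_acc[f] <- mean(pred == labels[!tr])
    fold_iters[f] <- fit$retrain_iterations_used
  }
  list(mean_accuracy = mean(fold_acc), fold_accuracy = fold_acc,
       fold_retrain_iterations = fold_iters, folds = folds)
}

# class-stratified fold assignment, deterministic per seed
stratified_folds <- function(labels, k, seed = NULL) {
  f <- integer(length(labels))
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      if (length(idx) < k)
        stop(sprintf("class '%s' has %d samples, fewer than %d folds",
                     cl, length(idx), k))
      f[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  })
  f
}
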