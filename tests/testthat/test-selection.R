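test_that("the worked elimination trace selects F1 and F4", {
  oracle <- figure_trace_oracle()
  x <- random_binary_matrix(10, 5, seed = 1)
  colnames(x) <- paste0("F", 1:5)
  sel <- hd_select(x, rep(c("a", "b"), 5), threshold = 0.70,
                   uncertainty = 5, folds = 5, oracle = oracle)
  expect_setequal(sel$selected_features, c("F1", "F4"))
  expect_equal(sel$bucket, c("F2", "F3", "F5"))  # F2/F3 together, then F5
  expect_equal(sel$best_accuracy, 0.93)
  expect_setequal(sel$best_feature_set, c("F1", "F3", "F4", "F5"))
  # full set + 5 + 3 + 2 distinct candidate subsets, k folds each; the
  # final iteration evaluates both one-feature models before stopping
  expect_equal(sel$models_evaluated, 11 * 5)
  expect_equal(sel$iterations, 3)
  expect_setequal(
    sel$history$missing_feature[sel$history$iteration == 3], c("F1", "F4"))
  # the sub-optimal record: fewest features strictly above the floor —
  # the one-feature model evaluated in the final iteration qualifies
  expect_equal(sel$suboptimal$features, "F1")
  expect_equal(sel$suboptimal$accuracy, 0.74)
  # the below-threshold candidate is kept in the history, flagged
  h <- sel$history
  expect_true(h$below_threshold[h$iteration == 1 &
                                  !is.na(h$missing_feature) &
                                  h$missing_feature == "F5"])
})

test_that("selection never starts when the full model misses the threshold", {
  oracle <- function(features) 0.55
  x <- random_binary_matrix(8, 4, seed = 2)
  sel <- hd_select(x, rep(c("a", "b"), 4), threshold = 0.60, folds = 5,
                   oracle = oracle)
  expect_equal(sel$selected_features, colnames(x))
  expect_length(sel$bucket, 0)
  expect_equal(sel$iterations, 0)
  expect_equal(sel$models_evaluated, 5)  # one evaluation per fold only
})

test_that("an unknown subset raises an oracle-domain error", {
  oracle <- function(features)
    if (length(features) == 3) 0.9 else NA_real_
  x <- random_binary_matrix(8, 3, seed = 3)
  expect_error(
    hd_select(x, rep(c("a", "b"), 4), oracle = oracle),
    "oracle has no value")
})

test_that("single-removal mode drops one feature, earliest on ties", {
  tab <- c("A,B,C" = 0.80, "B,C" = 0.90, "A,C" = 0.90, "A,B" = 0.70,
           "C" = 0.70, "B" = 0.65, "A" = 0.6)
  oracle <- function(features) unname(tab[paste(sort(features),
                                                collapse = ",")])
  x <- random_binary_matrix(8, 3, seed = 4)
  colnames(x) <- c("A", "B", "C")
  sel <- hd_select(x, rep(c("a", "b"), 4), threshold = 0.6, uncertainty = 5,
                   multi_removal = FALSE, oracle = oracle)
  expect_equal(sel$bucket[1], "A")  # tie between removing A and B
  h1 <- sel$history[sel$history$iteration == 1, ]
  expect_equal(sum(h1$removed), 1)
})

test_that("sub-optimal records prefer fewer features, then accuracy", {
  recs <- list(c("a", "b", "c", "d", "e"), c("a", "b", "c"), c("c", "d", "e"))
  got <- suboptimal_best(recs, c(0.72, 0.71, 0.69), floor = 0.70)
  expect_equal(got$features, c("a", "b", "c"))
  expect_equal(got$accuracy, 0.71)
  expect_null(suboptimal_best(recs, c(0.5, 0.6, 0.7), floor = 0.70))
  one <- suboptimal_best(list(c("z")), 0.71, floor = 0.70)
  expect_equal(one$n_features, 1)
  # equal sizes: higher accuracy wins
  tie <- suboptimal_best(list(c("a", "b"), c("c", "d")), c(0.71, 0.75),
                         floor = 0.70)
  expect_equal(tie$features, c("c", "d"))
})

test_that("candidate evaluation order does not change the outcome", {
  ds <- disjoint_pattern_dataset(n_per_class = 9, f = 6, noise = 0.1,
                                 seed = 17)
  reg <- hd_levels(d = 128, L = 2, v_min = 0, v_max = 1, seed = 5)
  perm <- c(4, 1, 6, 3, 5, 2)
  s1 <- hd_select(ds$x, ds$labels, folds = 3, registry = reg, seed = 11,
                  threshold = 0.5)
  s2 <- hd_select(ds$x[, perm], ds$labels, folds = 3, registry = reg,
                  seed = 11, threshold = 0.5)
  expect_setequal(s1$selected_features, s2$selected_features)
  expect_setequal(s1$bucket, s2$bucket)
  expect_equal(s1$best_accuracy, s2$best_accuracy)
})

test_that("elimination shrinks monotonically with exact bookkeeping", {
  ds <- disjoint_pattern_dataset(n_per_class = 9, f = 8, noise = 0.15,
                                 seed = 23)
  reg <- hd_levels(d = 128, L = 2, v_min = 0, v_max = 1, seed = 6)
  sel <- hd_select(ds$x, ds$labels, folds = 3, registry = reg, seed = 7,
                   threshold = 0.5)
  # selected and bucket partition the feature set
  expect_setequal(c(sel$selected_features, sel$bucket), colnames(ds$x))
  expect_length(intersect(sel$selected_features, sel$bucket), 0)
  expect_lte(sel$iterations, ncol(ds$x))
  # every iteration after the full evaluation removes at least one feature
  h <- sel$history[sel$history$iteration > 0, ]
  if (nrow(h) > 0) {
    removed_per_iter <- tapply(h$removed, h$iteration, sum)
    complete <- removed_per_iter[-length(removed_per_iter)]
    if (length(complete) > 0) expect_true(all(complete >= 1))
  }
  # fold-model count is folds x distinct evaluated subsets
  keys <- vapply(sel$subsets, paste, "", collapse = ",")
  expect_equal(sel$models_evaluated, 3 * length(unique(keys)))
  # the selection ledger and summary round-trip to disk
  led <- tempfile(fileext = ".tsv"); summ <- tempfile(fileext = ".json")
  write_selection(sel, led, summ)
  tab <- read.delim(led)
  expect_equal(nrow(tab), nrow(sel$history))
  js <- jsonlite::read_json(summ, simplifyVector = TRUE)
  expect_equal(sort(as.character(unlist(js$selected_features))),
               sort(sel$selected_features))
  expect_equal(js$models_evaluated, sel$models_evaluated)
})
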