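# Shared fixture builders: all synthetic, generated at test time.

# small random binary dataset with named samples/features
random_binary_matrix <- function(n, f, seed) {
  set.seed(seed)
  m <- matrix(sample(0:1, n * f, replace = TRUE), n, f,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              sprintf("F%02d", seq_len(f))))
  m
}

# two classes with disjoint planted presence patterns plus flip noise:
# a linearly trivial classification problem
disjoint_pattern_dataset <- function(n_per_class = 20, f = 12,
                                     noise = 0.05, seed = 1) {
  set.seed(seed)
  half <- f %/% 2
  pattern_a <- c(rep(1, half), rep(0, f - half))
  pattern_b <- 1 - pattern_a
  m <- rbind(matrix(pattern_a, n_per_class, f, byrow = TRUE),
             matrix(pattern_b, n_per_class, f, byrow = TRUE))
  flips <- matrix(runif(length(m)) < noise, nrow(m), ncol(m))
  m[flips] <- 1 - m[flips]
  dimnames(m) <- list(sprintf("s%03d", seq_len(nrow(m))),
                      sprintf("F%02d", seq_len(f)))
  list(x = m, labels = rep(c("case", "ctrl"), each = n_per_class))
}

# hand-rolled step-up false-discovery-rate adjustment, kept deliberately
# naive (direct min over j >= i) as an oracle independent of p.adjust
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    cand <- sorted[i:m] * m / (i:m)
    adj[i] <- min(1, min(cand))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# cosine-argmax classification oracle with explicit loops and the
# smallest-label tie-break
predict_oracle <- function(E, class_vectors) {
  labs <- rownames(class_vectors)
  out <- character(nrow(E))
  for (i in seq_len(nrow(E))) {
    best <- -Inf; pick <- NA_character_
    for (c in seq_len(nrow(class_vectors))) {
      cs <- sum(E[i, ] * class_vectors[c, ]) /
        (sqrt(sum(E[i, ]^2)) * sqrt(sum(class_vectors[c, ]^2)))
      if (cs > best) { best <- cs; pick <- labs[c] }
    }
    out[i] <- pick
  }
  out
}

# accuracy oracle encoding the worked backward-elimination narrative on
# five features (band 5%, threshold 70%)
figure_trace_oracle <- function() {
  tab <- c(
    "F1,F2,F3,F4,F5" = 0.75,
    "F2,F3,F4,F5" = 0.80,  # missing F1
    "F1,F3,F4,F5" = 0.93,  # missing F2: iteration best
    "F1,F2,F4,F5" = 0.91,  # missing F3: inside the 5% band
    "F1,F2,F3,F5" = 0.72,  # missing F4
    "F1,F2,F3,F4" = 0.68,  # missing F5: below threshold, discarded
    "F4,F5" = 0.62,        # missing F1
    "F1,F5" = 0.65,        # missing F4
    "F1,F4" = 0.90,        # missing F5: iteration best
    "F1" = 0.74,
    "F4" = 0.72)
  function(features) unname(tab[paste(sort(features), collapse = ",")])
}

# tiny multi-study fixture worked by hand: species s3 undetected in study B
toy_studies <- function() {
  a <- profile_dataset(
    matrix(c(10, 20,   # s__A
             5, 15,    # s__B
             3, 0),    # s__C: detected in study A only
           nrow = 2, ncol = 3,
           dimnames = list(c("a1", "a2"), c("s__A", "s__B", "s__C"))),
    labels = c("case", "control"),
    unclassified = c(82, 65))
  b <- profile_dataset(
    matrix(c(30, 1, 12, 40, 0, 0), nrow = 2, ncol = 3,
           dimnames = list(c("b1", "b2"), c("s__A", "s__B", "s__C"))),
    labels = c("case", "control"),
    unclassified = c(58, 59))
  list(A = a, B = b)
}

total_abundance <- function(x) {
  rowSums(x$abundance) + if (is.null(x$unclassified)) 0 else x$unclassified
}
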