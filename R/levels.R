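#' Generate a registry of bipolar level hypervectors
#'
#' Builds the associative memory used to encode numeric values: an ordered
#' family of `L` quasi-orthogonal bipolar hypervectors of dimensionality `d`
#' that quantize the range `[v_min, v_max]`. The first level is a
#' uniform-random bipolar vector; each subsequent level flips the sign of
#' `N = floor(d / 2 / L)` coordinates never flipped before, so that adjacent
#' levels are similar while distant levels become quasi-orthogonal. Because
#' the flipped index sets are disjoint across steps, the similarity decays
#' linearly: `cosine(level i, level j) = 1 - 2 * N * |i - j| / d` exactly.
#'
#' @param d Hypervector dimensionality (positive integer, typically 10000).
#' @param L Number of levels (>= 2); use `L = 2` for binary presence/absence
#'   data and e.g. `L = 1000` for relative abundances in \[0, 100\].
#' @param v_min,v_max Bounds of the numeric range being quantized
#'   (`v_min < v_max`), in the units of the data (e.g. relative-abundance %).
#' @param seed Optional integer seed; the same seed yields an identical
#'   registry. The caller's RNG state is preserved.
#'
#' @return An object of class `"hd_levels"`: a list with the `L x d` integer
#'   matrix `levels` (one level per row), `d`, `L`, the per-step flip count
#'   `N`, and the range bounds.
#'
#' @examples
#' reg <- hd_levels(d = 100, L = 10, v_min = 0, v_max = 100, seed = 1)
#' reg$N                         # 5 flips per step
#' hd_cosine(reg$levels[1, ], reg$levels[2, ])   # 1 - 2*5/100 = 0.9
#' @export
hd_levels <- function(d, L, v_min = 0, v_max = 100, seed = NULL) {
  d <- as.integer(d); L <- as.integer(L)
  if (L < 2) stop("at least 2 levels are required (L >= 2)")
  if (d < 2L * L) stop("dimensionality too small: d must be >= 2*L so that ",
                       "at least one coordinate is flipped per level")
  if (!is.numeric(v_min) || !is.numeric(v_max) || v_min >= v_max)
    stop("invalid range: v_min must be < v_max")
  N <- d %/% (2L * L)
  levels <- with_seed(seed, {
    base <- sample(c(-1L, 1L), d, replace = TRUE)
    # pre-draw (L-1)*N distinct indices, reveal N per step: flipped sets are
    # disjoint, which makes the similarity decay exact and monotone
    flips <- sample.int(d, (L - 1L) * N)
    m <- matrix(0L, nrow = L, ncol = d)
    m[1L, ] <- base
    for (i in seq_len(L - 1L)) {
      idx <- flips[((i - 1L) * N + 1L):(i * N)]
      base[idx] <- -base[idx]
      m[i + 1L, ] <- base
    }
    m
  })
  structure(
    list(levels = levels, d = d, L = L, N = N,
         v_min = v_min, v_max = v_max),
    class = "hd_levels")
}

#' @export
print.hd_levels <- function(x, ...) {
  cat(sprintf(
    "Level-hypervector registry: L = %d levels, d = %d, N = %d flips/step\n",
    x$L, x$d, x$N))
  cat(sprintf("  quantized range: [%g, %g]\n", x$v_min, x$v_max))
  invisible(x)
}

#' Map numeric values to level indices
#'
#' Quantizes values into the registry's uniform bins of width
#' `(v_max - v_min) / L`. Bins are half-open with the last bin closed, so
#' `v_max` maps to the last level. Indices are 0-based (`0 .. L-1`), i.e.
#' the bin number, matching `registry$levels[index + 1, ]`.
#'
#' @param registry An [hd_levels()] registry.
#' @param x Numeric vector (or matrix) of values in `[v_min, v_max]`.
#' @return Integer level indices in `[0, L-1]`, same shape as `x`.
#' @examples
#' reg <- hd_levels(d = 400, L = 100, v_min = 0, v_max = 100, seed = 1)
#' level_index(reg, c(0, 50, 100))  # 0, 50, 99
#' @export
level_index <- function(registry, x) {
  stopifnot(inherits(registry, "hd_levels"))
  if (any(x < registry$v_min | x > registry$v_max, na.rm = TRUE))
    stop(sprintf("value out of range [%g, %g]",
                 registry$v_min, registry$v_max))
  if (anyNA(x)) stop("missing values cannot be mapped to a level")
  w <- (registry$v_max - registry$v_min) / registry$L
  idx <- floor((x - registry$v_min) / w)
  idx[idx > registry$L - 1L] <- registry$L - 1L  # v_max closes the last bin
  storage.mode(idx) <- "integer"
  idx
}

#' Rotate (circularly permute) a hypervector
#'
#' Right circular shift by `p` positions: the element at index `i` moves to
#' index `(i + p) mod d` (0-based). Rotation is the permutation used to tag
#' the feature a value belongs to; it is bijective and preserves norms, so
#' cosine similarities are invariant under a common rotation.
#'
#' @param hv Numeric vector.
#' @param p Number of positions (reduced modulo `length(hv)`).
#' @return The rotated vector.
#' @examples
#' hd_rotate(c(1, -1, -1, 1), 1)  # c(1, 1, -1, -1)
#' @export
hd_rotate <- function(hv, p) {
  d <- length(hv)
  p <- ((as.integer(p) %% d) + d) %% d
  if (p == 0L) return(hv)
  hv[((seq_len(d) - 1L - p) %% d) + 1L]
}

#' Bundle hypervectors by element-wise summation
#'
#' Superposes information from several hypervectors into one by element-wise
#' integer addition; the result of bundling atomic bipolar vectors is
#' integer-valued and is kept unthresholded so that later element-wise
#' adjustments (retraining) remain exact.
#'
#' @param hvs A list of equal-length numeric vectors, or a matrix with one
#'   hypervector per row.
#' @return The element-wise sum.
#' @examples
#' hd_bundle(list(c(1, 1), c(1, -1), c(1, 1)))  # c(3, 1)
#' @export
hd_bundle <- function(hvs) {
  if (is.matrix(hvs)) {
    if (nrow(hvs) == 0L) stop("cannot bundle an empty set of hypervectors")
    return(colSums(hvs))
  }
  if (!is.list(hvs) || length(hvs) == 0L)
    stop("cannot bundle an empty set of hypervectors")
  d <- unique(lengths(hvs))
  if (length(d) != 1L)
    stop("all hypervectors must have the same dimensionality")
  out <- hvs[[1L]]
  for (v in hvs[-1L]) out <- out + v
  out
}

#' Cosine similarity between two hypervectors
#'
#' @param u,v Equal-length numeric vectors, neither all-zero.
#' @return `dot(u, v) / (|u| * |v|)`, in `[-1, 1]`.
#' @examples
#' hd_cosine(c(1, 1, 1, 1), c(1, 1, -1, -1))  # 0
#' @export
hd_cosine <- function(u, v) {
  if (length(u) != length(v))
    stop("hypervectors must have the same dimensionality")
  nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0)
    stop("cosine similarity is undefined for an all-zero hypervector")
  sum(u * v) / (nu * nv)
}
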