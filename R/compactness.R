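#' Coordinate sequence of areas in tree order
#'
#' Aligns centroid coordinates to a serial leaf order. For bilateral
#' analyses the LR coordinate is rectified (`|LR|`) so that homotopic
#' partners coincide on the left-right axis; per-hemisphere analyses use
#' signed LR.
#'
#' @param order A `leaf_order`.
#' @param atlas The matching `area_atlas`.
#' @param rectify_lr Rectify the LR coordinate (default `TRUE`).
#' @return A `layout_sequence`: numeric matrix (areas x 3, columns `lr`,
#'   `pa`, `is`, rows in tree order) with attribute `rectified`.
#' @export
layout_sequence <- function(order, atlas, rectify_lr = TRUE) {
  idx <- match(order$label, atlas$label)
  if (anyNA(idx)) {
    stop("labels absent from atlas: ",
         paste(order$label[is.na(idx)], collapse = ", "))
  }
  x <- area_coordinates(atlas, rectify_lr = rectify_lr)[idx, , drop = FALSE]
  if (nrow(x) < 2) stop("a layout sequence needs at least 2 areas")
  structure(x, rectified = rectify_lr, class = c("layout_sequence", "matrix"))
}

#' Euclidean distances between successive areas of a sequence
#'
#' For a sequence of n areas there are `M = n - 1` successive distances
#' (e.g. M = 51 for the 52-area bilateral tree, M = 25 per hemisphere).
#'
#' @param seq Coordinate matrix (areas x 3) in sequence order.
#' @return Numeric vector of `n - 1` distances in mm.
#' @export
successive_distances <- function(seq) {
  seq <- as.matrix(seq)
  n <- nrow(seq)
  if (n < 2) stop("need at least 2 areas")
  unname(sqrt(rowSums((seq[-1, , drop = FALSE] - seq[-n, , drop = FALSE])^2)))
}

#' @rdname successive_distances
#' @return For `mean_successive_distance`, the arithmetic mean distance.
#' @export
mean_successive_distance <- function(seq) mean(successive_distances(seq))

# deterministic child seed; keeps values below 2^31
child_seed <- function(root, i) {
  as.integer((as.numeric(root) %% 2147483629 * 48271 + i * 1000003) %%
               2147483629 + 1)
}

# mean successive distance of n_perms uniform random permutations, using
# the current RNG state; O(n^2) precomputation then O(n) per permutation
perm_mean_distances <- function(coords, n_perms) {
  n <- nrow(coords)
  dm <- as.matrix(stats::dist(coords))
  p <- vapply(seq_len(n_perms), function(k) sample.int(n), integer(n))
  a <- p[-n, , drop = FALSE]
  b <- p[-1, , drop = FALSE]
  colMeans(matrix(dm[cbind(as.vector(a), as.vector(b))], n - 1L))
}

#' Permutation test of the adjacency rule
#'
#' Compares the observed mean successive distance of the tree layout,
#' `D_tree`, with the null distribution obtained by uniformly permuting the
#' placement of areas: `violations` counts permutations whose mean
#' successive distance is strictly smaller than the observed one, and the
#' compactness index `c = mean_k(D_perm_k) / D_tree` measures the gain in
#' compactness of the tree layout over a random placement (c > 1 means the
#' layout is compact). The identity permutation, if drawn, ties rather than
#' violates, consistent with the strict inequality.
#'
#' @param seq A `layout_sequence` (or plain coordinate matrix).
#' @param n_perms Number of permutations N (the analysis default is 1000).
#' @param seed Optional root seed; permutations are drawn from a child
#'   stream so results are reproducible and order independent.
#' @return A `compactness_result`: list with `d_tree`, `d_perm_grand`,
#'   `c_index`, `n_perms`, `violations`, `m`, `seed`, `perm_means`.
#' @export
adjacency_test <- function(seq, n_perms = 1000, seed = NULL) {
  stopifnot(n_perms >= 1)
  seq <- as.matrix(seq)
  d_tree <- mean_successive_distance(seq)
  if (d_tree == 0) stop("degenerate sequence: all coordinates identical")
  if (!is.null(seed)) set.seed(child_seed(seed, 1))
  pm <- perm_mean_distances(seq, n_perms)
  structure(list(d_tree = d_tree, d_perm_grand = mean(pm),
                 c_index = mean(pm) / d_tree, n_perms = n_perms,
                 violations = sum(pm < d_tree), m = nrow(seq) - 1L,
                 seed = seed, perm_means = pm),
            class = "compactness_result")
}

#' @export
print.compactness_result <- function(x, ...) {
  cat(sprintf(
    "compactness: D_tree = %.2f mm, D_perm = %.2f mm, c = %.2f (M = %d)\n",
    x$d_tree, x$d_perm_grand, x$c_index, x$m))
  cat(sprintf("violations (D_perm_k < D_tree): %d / %d permutations\n",
              x$violations, x$n_perms))
  invisible(x)
}

# shared engine for the subset analyses: contiguous windows of length L at
# uniformly random start positions (with replacement, over the full
# inclusive range 1..(n - L + 1)), each permuted internally n_perms times.
# Window w always uses child stream child_seed(seed, w); the start stream is
# child_seed(seed, 0). This makes the one-window full-length case coincide
# exactly with adjacency_test(seed).
subset_engine <- function(seq, subset_sizes, n_subsets, n_perms, seed) {
  seq <- as.matrix(seq)
  n <- nrow(seq)
  res <- lapply(subset_sizes, function(L) {
    if (L < 2 || L > n) {
      stop("subset size L = ", L, " must lie in [2, ", n, "]")
    }
    if (!is.null(seed)) set.seed(child_seed(seed, 0))
    starts <- sample.int(n - L + 1, n_subsets, replace = TRUE)
    log_c <- numeric(n_subsets)
    viol <- 0L
    for (w in seq_len(n_subsets)) {
      win <- seq[starts[w] + 0:(L - 1), , drop = FALSE]
      d_obs <- mean_successive_distance(win)
      if (d_obs == 0) {
        stop("degenerate window: identical coordinates throughout ",
             "(start ", starts[w], ", L = ", L, ")")
      }
      if (!is.null(seed)) set.seed(child_seed(seed, w))
      pm <- perm_mean_distances(win, n_perms)
      log_c[w] <- log(mean(pm) / d_obs)
      viol <- viol + sum(pm < d_obs)
    }
    list(L = L, c_geomean = exp(mean(log_c)), violations = viol,
         n_evaluations = n_subsets * n_perms)
  })
  res
}

#' Size-law curve: subset compactness versus subset size
#'
#' For each subset size L, contiguous windows of the tree sequence are
#' sampled at random start positions and each window's compactness index is
#' computed by internal permutation. Because the index is a ratio, window
#' values are log-transformed before averaging and the geometric mean is
#' reported. Under the size law the curve increases with L toward the
#' full-set index.
#'
#' @inheritParams adjacency_test
#' @param subset_sizes Integer vector of window lengths L (each in
#'   `[2, n]`; the analysis uses `10 < L <= M`).
#' @param n_subsets Windows sampled per size (analysis default 1000).
#' @param n_perms Permutations per window (analysis default 1000).
#' @return Data frame with `L`, `c_geomean`, `n_subsets`, `n_perms`.
#' @export
size_law_curve <- function(seq, subset_sizes, n_subsets = 1000,
                           n_perms = 1000, seed = NULL) {
  res <- subset_engine(seq, subset_sizes, n_subsets, n_perms, seed)
  data.frame(L = vapply(res, `[[`, numeric(1), "L"),
             c_geomean = vapply(res, `[[`, numeric(1), "c_geomean"),
             n_subsets = n_subsets, n_perms = n_perms)
}

#' Metamodule grouping test: subset violation counts
#'
#' Counts, over all sampled windows and internal permutations of each
#' subset size, how often a permuted window is strictly more compact than
#' the observed contiguous window. Under metamodule grouping this count is
#' zero or near zero: contiguous subsets of a compact layout are themselves
#' compact.
#'
#' @inheritParams size_law_curve
#' @return Data frame with `L`, `violations`, `n_evaluations`.
#' @export
metamodule_test <- function(seq, subset_sizes, n_subsets = 1000,
                            n_perms = 1000, seed = NULL) {
  res <- subset_engine(seq, subset_sizes, n_subsets, n_perms, seed)
  data.frame(L = vapply(res, `[[`, numeric(1), "L"),
             violations = vapply(res, function(r) as.numeric(r$violations),
                                 numeric(1)),
             n_evaluations = vapply(res, `[[`, numeric(1), "n_evaluations"))
}
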