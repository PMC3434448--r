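#' Fisher z transform of correlation coefficients
#'
#' `z = atanh(r)`; correlations are averaged on the z scale because z is
#' approximately normal with variance independent of the true correlation.
#' Magnitudes at or above 1 are clipped to `1 - 1e-7` so degenerate perfect
#' correlations keep a finite z; inputs outside `[-1, 1]` are an error.
#'
#' @param r Numeric vector of correlations.
#' @param clip Clipping bound for `|r|`.
#' @return `atanh` of the clipped correlations.
#' @seealso [fisher_z_inverse()]
#' @export
fisher_z <- function(r, clip = 1 - 1e-7) {
  if (any(!is.finite(r)) || any(abs(r) > 1)) {
    stop("correlations must be finite and lie in [-1, 1]")
  }
  atanh(pmin(pmax(r, -clip), clip))
}

#' @rdname fisher_z
#' @param z Numeric vector of z values.
#' @export
fisher_z_inverse <- function(z) tanh(z)

#' Pooled mean correlation between the voxels of two areas
#'
#' Every voxel innovation series of area A is correlated with every voxel
#' innovation series of area B (all `|A| * |B|` cross pairs; for A = B, all
#' unordered distinct pairs), the Pearson coefficients are Fisher
#' z-transformed, arithmetically averaged, and the mean is transformed back
#' to a correlation. Zero-variance voxel series cannot be correlated; pairs
#' involving them are skipped and counted.
#'
#' @param a Voxels x time innovations matrix for area A.
#' @param b Voxels x time matrix for area B, or `NULL` for the within-area
#'   case (equivalent to `b = a`).
#' @return The back-transformed mean correlation, with attributes
#'   `n_pairs` and `n_skipped`.
#' @export
area_pair_mean_correlation <- function(a, b = NULL) {
  if (is.vector(a)) a <- matrix(a, nrow = 1)
  within <- is.null(b)
  if (within) b <- a else if (is.vector(b)) b <- matrix(b, nrow = 1)
  stopifnot(nrow(a) >= 1, nrow(b) >= 1, ncol(a) == ncol(b))
  ok_a <- apply(a, 1, stats::sd) > 0
  ok_b <- apply(b, 1, stats::sd) > 0
  if (within) {
    total <- nrow(a) * (nrow(a) - 1) / 2
    usable <- sum(ok_a) * (sum(ok_a) - 1) / 2
  } else {
    total <- nrow(a) * nrow(b)
    usable <- sum(ok_a) * sum(ok_b)
  }
  if (usable == 0) stop("no voxel pair with nonzero variance on both sides")
  r <- stats::cor(t(a[ok_a, , drop = FALSE]), t(b[ok_b, , drop = FALSE]))
  vals <- if (within) r[upper.tri(r)] else as.vector(r)
  out <- fisher_z_inverse(mean(fisher_z(vals)))
  attr(out, "n_pairs") <- usable
  attr(out, "n_skipped") <- total - usable
  out
}

#' Subject-averaged area proximity matrix
#'
#' Per subject, the pooled mean correlation (see
#' [area_pair_mean_correlation()]) is computed for every unordered area
#' pair -- each pair once, so the matrix is symmetric by construction --
#' and shifted by a positive constant (default 2) so that proximities are
#' positive even for negative correlations. The per-subject matrices are
#' then arithmetically averaged. The diagonal stores the within-area mean
#' correlation plus the constant; downstream profile distances exclude
#' self-columns.
#'
#' @param innov An `innovations_dataset`, or a list of subjects (each a
#'   named list: area label -> voxels x time matrix).
#' @param atlas An `area_atlas`; defaults to the one attached to `innov`.
#' @param constant The proximity shift (the analysis uses +2).
#' @param add Whether the constant is added `"before"` (per subject,
#'   default) or `"after"` averaging across subjects; identical by
#'   linearity, both kept for the documented equivalence.
#' @return A `proximity_matrix`: symmetric areas x areas matrix with
#'   off-diagonal entries in (constant - 1, constant + 1), with attributes
#'   `n_subjects`, `constant`, `n_clipped`.
#' @export
build_proximity <- function(innov, atlas = NULL, constant = 2,
                            add = c("before", "after")) {
  add <- match.arg(add)
  if (inherits(innov, "innovations_dataset")) {
    if (is.null(atlas)) atlas <- innov$atlas
    subjects <- innov$subjects
  } else {
    subjects <- innov
  }
  if (is.null(atlas)) stop("an area_atlas is required")
  labels <- atlas$label
  n <- length(labels)
  acc <- matrix(0, n, n, dimnames = list(labels, labels))
  n_clipped <- 0
  for (s in names(subjects)) {
    areas <- subjects[[s]]
    missing <- setdiff(labels, names(areas))
    if (length(missing)) {
      stop("subject ", s, " lacks data for area(s): ",
           paste(missing, collapse = ", "))
    }
    nv <- vapply(areas[labels], function(m) if (length(m)) nrow(m) else 0L,
                 integer(1))
    empty <- labels[nv == 0]
    if (length(empty)) {
      stop("area ", empty[1], " has no retained voxels in subject ", s)
    }
    big <- do.call(rbind, areas[labels])
    grp <- factor(rep(labels, nv), levels = labels)
    r <- stats::cor(t(big))
    n_clipped <- n_clipped + sum(abs(r[upper.tri(r)]) >= 1 - 1e-7)
    z <- atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
    diag(z) <- 0  # self-pairs excluded from within-area means
    sums <- rowsum(t(rowsum(z, grp)), grp)  # area x area sums of z
    cnt <- outer(nv, nv)
    # within-area means exclude self-pairs; single-voxel areas get NA there
    # (the diagonal never enters profile distances)
    diag(cnt) <- ifelse(nv > 1, nv * (nv - 1), NA_integer_)
    p_s <- fisher_z_inverse(as.matrix(sums) / cnt)
    acc <- acc + if (add == "before") p_s + constant else p_s
  }
  n_sub <- length(subjects)
  p <- acc / n_sub
  if (add == "after") p <- p + constant
  p <- (p + t(p)) / 2
  structure(p, class = c("proximity_matrix", class(p)),
            n_subjects = n_sub, constant = constant, n_clipped = n_clipped)
}

#' @export
print.proximity_matrix <- function(x, ...) {
  cat(sprintf(
    "proximity_matrix: %d x %d, %d subject(s), constant +%g, range [%.3f, %.3f]\n",
    nrow(x), ncol(x), attr(x, "n_subjects"), attr(x, "constant"),
    min(x[upper.tri(x)]), max(x[upper.tri(x)])))
  invisible(x)
}

#' Mean correlation by connectivity tier
#'
#' Summarizes a proximity matrix (with the constant removed) into the four
#' tiers whose ordering the analysis presumes: within-area, homotopic,
#' ipsilateral non-homotopic, and contralateral non-homotopic.
#'
#' @param p A `proximity_matrix`.
#' @param atlas The matching `area_atlas`.
#' @return Named numeric vector `within`, `homotopic`, `ipsilateral`,
#'   `contralateral` of mean correlations.
#' @export
correlation_tiers <- function(p, atlas) {
  stopifnot(nrow(p) == nrow(atlas))
  r <- unclass(p) - attr(p, "constant")
  hom <- homotopic_pairs(atlas)
  same <- outer(atlas$hemisphere, atlas$hemisphere, "==")
  eye <- diag(nrow(r)) == 1
  c(within = mean(diag(r)),
    homotopic = mean(r[hom]),
    ipsilateral = mean(r[same & !eye]),
    contralateral = mean(r[!same & !hom]))
}

#' Write a proximity matrix as labeled CSV
#'
#' @param p A `proximity_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proximity_csv <- function(p, path) {
  utils::write.csv(as.data.frame(unclass(p)), path, row.names = TRUE)
  invisible(path)
}
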