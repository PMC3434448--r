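#' Squared Euclidean profile distance between proximity rows
#'
#' Each area is characterized by its row of proximities to every other area
#' (cases x variables), and pairs of areas are compared by the squared
#' Euclidean distance between those profiles. The self-columns of the two
#' areas compared are excluded, so an area's (arbitrary) self-proximity
#' cannot dominate the distance:
#' `d(a, b) = sum_{k != a, b} (P[a, k] - P[b, k])^2`.
#'
#' @param p A `proximity_matrix` (any symmetric labeled matrix works).
#' @return Symmetric matrix of squared distances with zero diagonal.
#' @export
profile_distance_matrix <- function(p) {
  x <- unclass(p)
  stopifnot(is.matrix(x), nrow(x) == ncol(x))
  n <- nrow(x)
  g <- as.matrix(stats::dist(x))^2  # over all columns
  dg <- diag(x)
  m1 <- (matrix(dg, n, n) - t(x))^2           # column a terms: (P[a,a]-P[b,a])^2
  m2 <- (x - matrix(dg, n, n, byrow = TRUE))^2 # column b terms: (P[a,b]-P[b,b])^2
  d <- g - m1 - m2
  d <- pmax((d + t(d)) / 2, 0)
  diag(d) <- 0
  dimnames(d) <- dimnames(x)
  d
}

#' UPGMA (average linkage) agglomerative clustering
#'
#' Iteratively merges the closest pair of clusters, defining the distance
#' between two clusters as the unweighted arithmetic mean of all cross-pair
#' distances between their members. Merge heights are non-decreasing
#' (UPGMA admits no inversions), which is validated on the result.
#'
#' @param d Square symmetric distance matrix with zero diagonal (or a
#'   [stats::dist] object), `n >= 2` leaves, no missing values.
#' @return A `upgma_tree`: list with `merge`, `height`, `labels` (the
#'   [stats::hclust] encoding) and the underlying `hclust` object.
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (nrow(d) < 2) stop("need at least 2 leaves")
  if (any(!is.finite(d))) stop("distance matrix contains NaN/NA/Inf")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have zero diagonal")
  if (is.null(rownames(d))) {
    dimnames(d) <- list(paste0("L", seq_len(nrow(d))),
                        paste0("L", seq_len(nrow(d))))
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  if (any(diff(hc$height) < -1e-10)) {
    stop("internal error: non-monotone UPGMA heights")
  }
  structure(list(merge = hc$merge, height = hc$height, labels = hc$labels,
                 hclust = hc, dist = d),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("upgma_tree: %d leaves, %d merges, height range [%.4g, %.4g]\n",
              length(x$labels), length(x$height), min(x$height),
              max(x$height)))
  invisible(x)
}

#' Deterministic serial leaf order of a dendrogram
#'
#' Dendrogram leaf order is not unique (each internal node's children can be
#' swapped), so an explicit, recorded policy makes the serial order
#' reproducible. The default policy `"olo"` is exact optimal leaf ordering:
#' among all `2^(n-1)` child orientations compatible with the tree, the one
#' minimizing the total dissimilarity between successive leaves (computed by
#' dynamic programming on the distance matrix stored in the tree). This
#' untangles the dendrogram into its underlying serial gradient, which
#' simple index-based conventions need not do. Alternatives: `"min-index"`
#' (at every internal node the child whose subtree contains the smaller
#' minimum original label index comes first) and `"tighter-first"` (the
#' child subtree with the lower merge height first; leaves count as height
#' 0; ties fall back to min-index). The `"olo"` order is canonically
#' oriented so its first leaf has a smaller original index than its last;
#' rank 1 is the top of the dendrogram.
#'
#' @param tree A `upgma_tree`.
#' @param policy `"olo"` (default), `"min-index"` or `"tighter-first"`.
#' @return A `leaf_order` data frame with columns `rank` and `label`, and
#'   attributes `serial_order` (named rank vector) and `policy`.
#' @export
leaf_order <- function(tree, policy = c("olo", "min-index", "tighter-first")) {
  policy <- match.arg(policy)
  merge <- tree$merge
  n <- length(tree$labels)
  n_nodes <- nrow(merge)
  if (policy == "olo") {
    idx <- optimal_leaf_order(tree)
    labels <- tree$labels[idx]
    ranks <- seq_along(labels)
    return(structure(
      data.frame(rank = ranks, label = labels, stringsAsFactors = FALSE),
      class = c("leaf_order", "data.frame"),
      serial_order = stats::setNames(ranks, labels), policy = policy))
  }
  min_idx <- numeric(n_nodes)
  node_h <- numeric(n_nodes)
  child_min <- function(ch) if (ch < 0) -ch else min_idx[ch]
  child_h <- function(ch) if (ch < 0) 0 else node_h[ch]
  for (i in seq_len(n_nodes)) {
    min_idx[i] <- min(child_min(merge[i, 1]), child_min(merge[i, 2]))
    node_h[i] <- tree$height[i]
  }
  first_child <- function(i) {
    a <- merge[i, 1]; b <- merge[i, 2]
    if (policy == "tighter-first" && child_h(a) != child_h(b)) {
      return(if (child_h(a) < child_h(b)) c(a, b) else c(b, a))
    }
    if (child_min(a) <= child_min(b)) c(a, b) else c(b, a)
  }
  walk <- function(node) {
    if (node < 0) return(-node)
    ch <- first_child(node)
    c(walk(ch[1]), walk(ch[2]))
  }
  idx <- walk(n_nodes)
  labels <- tree$labels[idx]
  ranks <- seq_along(labels)
  out <- data.frame(rank = ranks, label = labels, stringsAsFactors = FALSE)
  so <- stats::setNames(ranks, labels)
  structure(out, class = c("leaf_order", "data.frame"),
            serial_order = so, policy = policy)
}

# Exact optimal leaf ordering (Bar-Joseph style dynamic program).
# For every node and every admissible (leftmost, rightmost) leaf pair it
# stores the minimal sum of successive dissimilarities inside the subtree;
# children are combined by minimizing over the two boundary leaves at the
# junction. Ties resolve to the first minimum, so the order is
# deterministic. Returns leaf indices in optimal serial order.
optimal_leaf_order <- function(tree) {
  d <- tree$dist
  if (is.null(d)) stop("tree carries no distance matrix; rebuild with upgma()")
  merge <- tree$merge
  n <- length(tree$labels)
  if (n == 1) return(1L)
  leaves <- vector("list", nrow(merge))
  cost <- vector("list", nrow(merge))   # cost[l, r], Inf when l, r same child
  arg_m <- vector("list", nrow(merge))  # junction leaf on the l side
  arg_k <- vector("list", nrow(merge))  # junction leaf on the r side
  node_info <- function(ch) {
    if (ch < 0) {
      list(leaves = -ch,
           cost = matrix(0, 1, 1, dimnames = list(-ch, -ch)))
    } else {
      list(leaves = leaves[[ch]], cost = cost[[ch]])
    }
  }
  for (v in seq_len(nrow(merge))) {
    a <- node_info(merge[v, 1])
    b <- node_info(merge[v, 2])
    la <- a$leaves; lb <- b$leaves
    na_ <- length(la); nb <- length(lb)
    dd <- d[la, lb, drop = FALSE]
    all_lv <- c(la, lb)
    nv <- na_ + nb
    cv <- matrix(Inf, nv, nv, dimnames = list(all_lv, all_lv))
    am <- matrix(NA_integer_, nv, nv, dimnames = list(all_lv, all_lv))
    ak <- am
    for (li in seq_len(na_)) {
      ca <- a$cost[li, ]
      for (ri in seq_len(nb)) {
        tot <- outer(ca, b$cost[, ri], "+") + dd
        w <- arrayInd(which.min(tot), dim(tot))
        cv[li, na_ + ri] <- cv[na_ + ri, li] <- tot[w]
        am[li, na_ + ri] <- am[na_ + ri, li] <- la[w[1]]
        ak[li, na_ + ri] <- ak[na_ + ri, li] <- lb[w[2]]
      }
    }
    leaves[[v]] <- all_lv
    cost[[v]] <- cv
    arg_m[[v]] <- am
    arg_k[[v]] <- ak
  }
  root <- nrow(merge)
  cr <- cost[[root]]
  best <- arrayInd(which.min(cr), dim(cr))
  l_star <- leaves[[root]][best[1]]
  r_star <- leaves[[root]][best[2]]
  child_leaves <- function(ch) if (ch < 0) -ch else leaves[[ch]]
  build <- function(node, l, r) {
    if (node < 0) return(-node)
    first <- merge[node, 1]
    second <- merge[node, 2]
    m <- arg_m[[node]][as.character(l), as.character(r)]
    k <- arg_k[[node]][as.character(l), as.character(r)]
    if (!(l %in% child_leaves(first))) {
      tmp <- first; first <- second; second <- tmp
    }
    # arg matrices store the junction leaf on the l side as m
    if (!(m %in% child_leaves(first))) { tmp <- m; m <- k; k <- tmp }
    c(build(first, l, m), build(second, k, r))
  }
  idx <- build(root, l_star, r_star)
  if (idx[1] > idx[length(idx)]) idx <- rev(idx)
  idx
}

#' Orient a leaf order so the anterior end comes first
#'
#' A serial leaf order and its reverse describe the same dendrogram; this
#' helper applies the figure-reading convention that rank 1 is the anterior
#' end, by comparing the mean PA coordinate of the first and last quarter
#' of the sequence and reversing if needed.
#'
#' @param order A `leaf_order`.
#' @param atlas The matching `area_atlas`.
#' @return A `leaf_order`, possibly reversed.
#' @export
orient_anterior <- function(order, atlas) {
  pa <- atlas$pa[match(order$label, atlas$label)]
  k <- max(1L, nrow(order) %/% 4)
  n <- nrow(order)
  if (mean(pa[seq_len(k)]) < mean(pa[seq(n - k + 1, n)])) {
    labels <- rev(order$label)
    ranks <- seq_along(labels)
    order <- structure(
      data.frame(rank = ranks, label = labels, stringsAsFactors = FALSE),
      class = c("leaf_order", "data.frame"),
      serial_order = stats::setNames(ranks, labels),
      policy = attr(order, "policy"))
  }
  order
}

#' @export
print.leaf_order <- function(x, ...) {
  cat(sprintf("leaf_order (%s policy): %s ... %s [%d leaves]\n",
              attr(x, "policy"), x$label[1], x$label[nrow(x)], nrow(x)))
  invisible(x)
}

#' Export a dendrogram as a Newick string or file
#'
#' Branch lengths follow the [ape::as.phylo()] convention for `hclust`
#' trees (merge height halved along each child branch). Raw merge heights
#' are preserved in the merge-table export.
#'
#' @param tree A `upgma_tree`.
#' @param path Output file; if `NULL` the Newick string is returned.
#' @return The path (invisibly) or the Newick string.
#' @export
write_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree$hclust)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
write_merge_table <- function(tree, path) {
  df <- data.frame(step = seq_along(tree$height),
                   cluster_i = tree$merge[, 1], cluster_j = tree$merge[, 2],
                   height = tree$height)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @param order A `leaf_order`.
#' @param atlas Optional `area_atlas` supplying the hemisphere column.
#' @rdname write_newick
#' @export
write_leaf_order_csv <- function(order, path, atlas = NULL) {
  df <- as.data.frame(order)
  if (!is.null(atlas)) {
    df$hemisphere <- atlas$hemisphere[match(df$label, atlas$label)]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Sibling leaf at each area's first merge
#'
#' For each leaf, reports the other leaf it is merged with if its first
#' merge joins two leaves (its dendrogram nearest neighbor), or `NA` when
#' the first merge joins the leaf to an existing cluster. Used to check
#' homotopic pairing of the tree.
#'
#' @param tree A `upgma_tree`.
#' @return Named character vector: leaf label -> sibling leaf label or NA.
#' @export
leaf_siblings <- function(tree) {
  out <- stats::setNames(rep(NA_character_, length(tree$labels)),
                         tree$labels)
  for (i in seq_len(nrow(tree$merge))) {
    a <- tree$merge[i, 1]; b <- tree$merge[i, 2]
    if (a < 0 && b < 0) {
      out[tree$labels[-a]] <- tree$labels[-b]
      out[tree$labels[-b]] <- tree$labels[-a]
    }
  }
  out
}
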