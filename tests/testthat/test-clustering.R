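test_that("profile distance excludes self-columns and is symmetric", {
  # symmetric 4x4 proximity; rows 1 and 2 differ by 0.1 in the two shared
  # columns (3 and 4) only
  p <- matrix(c(3.0, 2.5, 2.1, 2.3,
                2.5, 3.0, 2.0, 2.2,
                2.1, 2.0, 3.0, 2.6,
                2.3, 2.2, 2.6, 3.0), 4, 4, byrow = TRUE,
              dimnames = list(letters[1:4], letters[1:4]))
  d <- profile_distance_matrix(p)
  expect_equal(d["a", "b"], 0.1^2 + 0.1^2, tolerance = 1e-12)
  expect_equal(d, t(d))
  expect_equal(diag(d), stats::setNames(rep(0, 4), letters[1:4]))
  # identical rows (and identical self-proximities) -> zero distance
  q <- matrix(2, 3, 3); diag(q) <- 3
  dimnames(q) <- list(letters[1:3], letters[1:3])
  expect_equal(max(profile_distance_matrix(q)), 0)
  # random symmetric input stays symmetric
  set.seed(1)
  r <- matrix(rnorm(36), 6); r <- r + t(r)
  dr <- profile_distance_matrix(r)
  expect_equal(dr, t(dr))
})

test_that("UPGMA reproduces hand-computed merges", {
  d1 <- matrix(c(0, 1, 4, 1, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t1 <- upgma(d1)
  expect_equal(t1$height, c(1, 4))
  d2 <- matrix(c(0, 1, 2, 1, 0, 4, 2, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t2 <- upgma(d2)
  expect_equal(t2$height, c(1, 3))  # (2 + 4) / 2
  d3 <- matrix(c(0, 7, 7, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(upgma(d3)$height, 7)
  expect_error(upgma(matrix(c(0, NaN, NaN, 0), 2)), "NaN")
})

test_that("UPGMA heights equal a brute-force recomputation (n <= 7)", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:7, 1)
    x <- matrix(rnorm(n * 4), n)
    d <- as.matrix(dist(x))
    got <- upgma(d)$height
    want <- upgma_bruteforce(d)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("UPGMA merge heights are monotone non-decreasing", {
  set.seed(7)
  for (rep in 1:20) {
    d <- as.matrix(dist(matrix(rnorm(30), 10)))
    expect_true(all(diff(upgma(d)$height) >= -1e-12))
  }
})

test_that("leaf order is a deterministic permutation under every policy", {
  # chain of 4 points on a line with unique nearest neighbors
  x <- c(0, 1, 2.6, 4.8)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(paste0("P", 1:4), paste0("P", 1:4))
  tree <- upgma(d)
  for (pol in c("olo", "min-index", "tighter-first")) {
    ord <- leaf_order(tree, policy = pol)
    expect_setequal(ord$label, paste0("P", 1:4))
    expect_equal(attr(ord, "policy"), pol)
  }
  expect_equal(leaf_order(tree, "min-index")$label, paste0("P", 1:4))
  expect_equal(leaf_order(tree, "olo")$label, paste0("P", 1:4))
  so <- attr(leaf_order(tree, "olo"), "serial_order")
  expect_equal(unname(so[paste0("P", 1:4)]), 1:4)
})

test_that("optimal leaf ordering minimizes total successive dissimilarity", {
  set.seed(9)
  path_cost <- function(tree, ord) {
    idx <- match(ord$label, tree$labels)
    sum(tree$dist[cbind(idx[-length(idx)], idx[-1])])
  }
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    d <- as.matrix(dist(matrix(rnorm(n * 3), n)))
    tree <- upgma(d)
    c_olo <- path_cost(tree, leaf_order(tree, "olo"))
    expect_lte(c_olo, path_cost(tree, leaf_order(tree, "min-index")) + 1e-10)
    expect_lte(c_olo,
               path_cost(tree, leaf_order(tree, "tighter-first")) + 1e-10)
  }
})

test_that("anterior orientation flips a posterior-first order", {
  atlas <- toy_atlas()
  ord <- structure(
    data.frame(rank = 1:12, label = rev(atlas$label)),
    class = c("leaf_order", "data.frame"),
    serial_order = stats::setNames(1:12, rev(atlas$label)),
    policy = "olo")
  # reversed atlas order runs posterior -> anterior; orientation restores it
  fixed <- orient_anterior(ord, atlas)
  pa <- atlas$pa[match(fixed$label, atlas$label)]
  expect_gt(pa[1], pa[12])
  expect_identical(orient_anterior(fixed, atlas)$label, fixed$label)
})

test_that("tree exports round-trip through Newick and CSV", {
  d <- as.matrix(dist(matrix(rnorm(18), 6)))
  dimnames(d) <- list(paste0("A", 1:6), paste0("A", 1:6))
  tree <- upgma(d)
  nwk <- tempfile(fileext = ".nwk")
  write_newick(tree, nwk)
  phy <- ape::read.tree(nwk)
  expect_setequal(phy$tip.label, paste0("A", 1:6))
  mt <- tempfile(fileext = ".csv")
  write_merge_table(tree, mt)
  df <- read.csv(mt)
  expect_equal(df$height, tree$height)
  lo <- tempfile(fileext = ".csv")
  write_leaf_order_csv(leaf_order(tree), lo)
  expect_equal(nrow(read.csv(lo)), 6)
})

test_that("strong homotopic coupling pairs partners as dendrogram siblings", {
  run <- acceptance_run()
  sib <- leaf_siblings(run$tree)
  paired <- !is.na(sib) & area_stem(names(sib)) == area_stem(sib)
  expect_gte(mean(paired), 0.9)
})

test_that("recovered serial order tracks the anterior-posterior gradient", {
  run <- acceptance_run()
  atlas <- run$atlas
  # homotopic partners share their PA rank
  pa_shared <- ave(atlas$pa, area_stem(atlas$label))
  pa_rank <- rank(-pa_shared)[match(run$order$label, atlas$label)]
  rho <- stats::cor(run$order$rank, pa_rank, method = "spearman")
  expect_gte(rho, 0.8)
})
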