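test_that("successive distances count n - 1 and match hand values", {
  atlas <- load_reference_atlas()
  full <- structure(
    data.frame(rank = 1:52, label = atlas$label),
    class = c("leaf_order", "data.frame"), policy = "olo")
  seq52 <- layout_sequence(full, atlas, rectify_lr = TRUE)
  expect_equal(length(successive_distances(seq52)), 51)
  expect_true(attr(seq52, "rectified"))
  expect_true(all(seq52[, "lr"] >= 0))

  # homotopic precentral pair, rectified LR
  two <- structure(
    data.frame(rank = 1:2, label = c("L_Precentral", "R_Precentral")),
    class = c("leaf_order", "data.frame"), policy = "olo")
  d <- successive_distances(layout_sequence(two, atlas, rectify_lr = TRUE))
  expect_equal(d, sqrt((44.1 - 42.3)^2 + (-7.0 - (-7.2))^2 +
                         (39.3 - 39.4)^2), tolerance = 1e-12)
  expect_equal(d, 1.8138, tolerance = 1e-4)

  # consecutive identical coordinates give a zero distance
  m <- rbind(c(0, 0, 0), c(0, 0, 0), c(3, 4, 0))
  expect_equal(successive_distances(m), c(0, 5))
})

test_that("mean successive distance is reversal invariant", {
  expect_equal(mean_successive_distance(cbind(0:2, 0, 0)), 1)
  set.seed(2)
  m <- matrix(rnorm(30), 10)
  expect_equal(mean_successive_distance(m),
               mean_successive_distance(m[10:1, ]), tolerance = 1e-12)
})

test_that("adjacency test matches the exhaustive oracle on 3 points", {
  line <- cbind(c(0, 1, 2), 0, 0)
  oracle <- exhaustive_perm_mean(line)
  expect_equal(oracle$grand_mean, 4 / 3, tolerance = 1e-12)
  res <- adjacency_test(line, n_perms = 2000, seed = 5)
  se <- sd(oracle$means) / sqrt(2000)
  expect_lt(abs(res$d_perm_grand - 4 / 3), 3 * se + 1e-9)
  expect_equal(res$violations, 0)  # the observed order is minimal
  expect_equal(res$d_tree, 1)
  expect_equal(res$m, 2)

  # worst-case observed order (middle point last): 2 of 6 permutations win
  worst <- line[c(1, 3, 2), ]
  res2 <- adjacency_test(worst, n_perms = 2000, seed = 5)
  expect_equal(res2$d_tree, 1.5)
  p_se <- sqrt((1 / 3) * (2 / 3) / 2000)
  expect_lt(abs(res2$violations / 2000 - 2 / 6), 3 * p_se + 1e-9)
})

test_that("Monte-Carlo grand mean converges to the exact average (n <= 7)", {
  set.seed(31)
  for (rep in 1:3) {
    n <- sample(5:7, 1)
    coords <- matrix(rnorm(n * 3, sd = 10), n)
    oracle <- exhaustive_perm_mean(coords)
    res <- adjacency_test(coords, n_perms = 10000, seed = rep)
    se <- sd(oracle$means) / sqrt(10000)
    expect_lt(abs(res$d_perm_grand - oracle$grand_mean), 3 * se)
  }
})

test_that("adjacency test is reproducible and guards degenerate input", {
  coords <- matrix(rnorm(24), 8)
  a <- adjacency_test(coords, n_perms = 100, seed = 9)
  b <- adjacency_test(coords, n_perms = 100, seed = 9)
  expect_identical(a[setdiff(names(a), "seed")], b[setdiff(names(b), "seed")])
  expect_error(adjacency_test(matrix(1, 4, 3)), "degenerate")
})

test_that("a random observed order has compactness index near 1", {
  set.seed(4)
  coords <- matrix(rnorm(60), 20, 3)
  cs <- replicate(100, adjacency_test(coords[sample(20), ], 400)$c_index)
  expect_gt(mean(cs), 0.95)
  expect_lt(mean(cs), 1.05)
})

test_that("subset analyses honor their boundary cases", {
  set.seed(12)
  coords <- matrix(rnorm(30), 10)
  # L = 2: the two orderings of a pair tie exactly
  sl2 <- size_law_curve(coords, 2, n_subsets = 20, n_perms = 50, seed = 3)
  expect_equal(sl2$c_geomean, 1, tolerance = 1e-12)
  mm2 <- metamodule_test(coords, 2, n_subsets = 20, n_perms = 50, seed = 3)
  expect_equal(mm2$violations, 0)
  # L = n with a single window reproduces the whole-set test exactly
  at <- adjacency_test(coords, n_perms = 200, seed = 11)
  sl <- size_law_curve(coords, 10, n_subsets = 1, n_perms = 200, seed = 11)
  expect_equal(sl$c_geomean, at$c_index, tolerance = 1e-12)
  expect_error(size_law_curve(coords, 11, 5, 5, seed = 1), "must lie")
  # seeded reproducibility
  expect_identical(metamodule_test(coords, c(3, 5), 10, 50, seed = 2),
                   metamodule_test(coords, c(3, 5), 10, 50, seed = 2))
})

test_that("contiguous windows of a collinear equally spaced layout are optimal", {
  line <- cbind(seq(0, 14, by = 2), 0, 0)  # 8 collinear equally spaced areas
  mm <- metamodule_test(line, c(3, 4, 6), n_subsets = 20, n_perms = 200,
                        seed = 8)
  expect_equal(mm$violations, c(0, 0, 0))
  # exhaustive check for one window size: no permutation of 4 consecutive
  # equally spaced points beats the contiguous order
  win <- line[1:4, ]
  oracle <- exhaustive_perm_mean(win)
  expect_equal(sum(oracle$means < mean_successive_distance(win)), 0)
})

test_that("size law and adjacency hold on the recovered synthetic tree", {
  run <- acceptance_run()
  res <- adjacency_test(run$seq, n_perms = 1000, seed = 17)
  expect_equal(res$violations, 0)
  expect_gt(res$c_index, 1)
  # per-hemisphere sequences use signed LR and M = 25
  for (h in c("left", "right")) {
    hs <- run$hemis[[h]]$seq
    expect_false(attr(hs, "rectified"))
    expect_equal(nrow(hs) - 1, 25)
  }
})
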