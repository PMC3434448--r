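test_that("ground-truth correlation follows the distance-decay closed form", {
  atlas <- area_atlas(c("L_A", "L_B"), c("left", "left"), c(0, 0),
                      c(0, 10), c(0, 0), c(1, 1))
  cfg <- synth_config(distance_decay = 0.05, homotopic_boost = 0)
  gt <- ground_truth_correlation(atlas, cfg)
  expect_equal(gt["L_A", "L_B"], exp(-0.5), tolerance = 1e-12)
  expect_equal(diag(gt), stats::setNames(c(1, 1), atlas$label))

  # zero distance between a pair -> correlation 1
  atlas0 <- area_atlas(c("L_A", "L_B", "L_C"), rep("left", 3), c(0, 0, 0),
                       c(0, 0, 30), c(0, 0, 0), rep(1, 3))
  gt0 <- ground_truth_correlation(atlas0, cfg)
  expect_equal(gt0["L_A", "L_B"], 1)

  # homotopic boost of 1 saturates the pair at 1 exactly
  bi <- area_atlas(c("L_A", "L_B", "R_A", "R_B"),
                   c("left", "left", "right", "right"),
                   c(-40, -40, 40, 40), c(0, -30, 0, -30), rep(0, 4),
                   rep(1, 4))
  cfg1 <- synth_config(homotopic_boost = 1, contralateral_attenuation = 1)
  gt1 <- ground_truth_correlation(bi, cfg1)
  expect_equal(gt1["L_A", "R_A"], 1)

  # contralateral attenuation orders ipsilateral above contralateral
  cfg2 <- synth_config(contralateral_attenuation = 0.8, psd_repair = TRUE)
  gt2 <- ground_truth_correlation(toy_atlas(), cfg2)
  hom <- homotopic_pairs(toy_atlas())
  same <- outer(toy_atlas()$hemisphere, toy_atlas()$hemisphere, "==")
  eye <- diag(nrow(gt2)) == 1
  expect_gt(mean(gt2[hom]), mean(gt2[same & !eye]))
  expect_gt(mean(gt2[same & !eye]), mean(gt2[!same & !hom]))
})

test_that("degenerate and non-PSD configurations are rejected", {
  atlas <- toy_atlas()
  cfg <- synth_config(distance_decay = 0, homotopic_boost = 0,
                      contralateral_attenuation = 1)
  expect_error(ground_truth_correlation(atlas, cfg), "degenerate")

  # transitivity-breaking boost: homotopic partners coincide after
  # rectification while nearby ipsilateral areas correlate strongly,
  # which no correlation matrix can satisfy
  tight <- area_atlas(c("L_A", "L_B", "R_A", "R_B"),
                      c("left", "left", "right", "right"),
                      c(-50, -50, 50, 50), c(0, 1, 0, 1), c(0, 0, 0, 0),
                      rep(1, 4))
  bad <- synth_config(distance_decay = 0.01, homotopic_boost = 1,
                      contralateral_attenuation = 0.5)
  expect_error(ground_truth_correlation(tight, bad), "semi-definite")
  repaired <- ground_truth_correlation(
    tight, synth_config(distance_decay = 0.01, homotopic_boost = 1,
                        contralateral_attenuation = 0.5, psd_repair = TRUE))
  ev <- eigen(repaired, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
})

test_that("configuration validation rejects unstable dynamics and bad counts", {
  expect_error(synth_config(n_subjects = 0), "counts")
  expect_error(synth_config(distance_decay = -1), "distance_decay")
  expect_error(synth_config(ar_coefs = c(0.9, 0.3)), "stationary")
  expect_error(synth_config(ma_coefs = -1.5), "invertible")
  expect_error(synth_config(homotopic_boost = 2), "homotopic_boost")
})

test_that("simulation is bit-reproducible under a fixed seed", {
  atlas <- toy_atlas()
  cfg <- toy_synth_config(seed = 7)
  d1 <- simulate_dataset(atlas, cfg)
  d2 <- simulate_dataset(atlas, cfg)
  expect_identical(d1$subjects, d2$subjects)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_dataset_csv(d1, f1); write_dataset_csv(d2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("noise-free voxels of one area share the latent series exactly", {
  atlas <- toy_atlas(3)
  cfg <- toy_synth_config(noise_sd = 0, within_area_weight = 1)
  ds <- simulate_dataset(atlas, cfg)
  m <- ds$subjects[[1]][["L_A"]]
  # drift and coloring are shared within a subject-area, so rows coincide
  expect_equal(max(abs(sweep(m, 2, m[1, ]))), 0)
})

test_that("raw series are nonstationary and strongly autocorrelated", {
  atlas <- toy_atlas()
  ds <- simulate_dataset(atlas, toy_synth_config(series_length = 203,
                                                 voxels_per_area = 5))
  ac1 <- unlist(lapply(ds$subjects, function(s) lapply(s, function(m) {
    apply(m, 1, function(x) stats::acf(x, lag.max = 1, plot = FALSE)$acf[2])
  })))
  expect_gte(length(ac1), 100)
  expect_gt(mean(ac1), 0.5)
})

test_that("dataset round-trips through the long-format CSV", {
  atlas <- toy_atlas(3)
  ds <- simulate_dataset(atlas, toy_synth_config(n_subjects = 2))
  f <- tempfile(fileext = ".csv")
  write_dataset_csv(ds, f)
  back <- read_dataset_csv(f, atlas = atlas)
  expect_equal(length(back$subjects), 2)
  for (s in names(ds$subjects)) {
    for (a in names(ds$subjects[[s]])) {
      expect_equal(unname(back$subjects[[s]][[a]]),
                   unname(ds$subjects[[s]][[a]]), tolerance = 1e-12)
    }
  }
})

test_that("volume-proportional voxel allocation follows atlas volumes", {
  atlas <- load_reference_atlas()
  cfg <- synth_config(n_subjects = 1, voxels_per_area = 4,
                      series_length = 10, psd_repair = TRUE,
                      voxel_allocation = "volume")
  ds <- simulate_dataset(atlas, cfg)
  nv <- vapply(ds$subjects[[1]], nrow, integer(1))
  expect_gt(nv[["L_Middle_Frontal"]], nv[["R_Superior_Occipital"]])
  expect_true(all(nv >= 1))
})
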