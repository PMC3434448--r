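#' Configuration for the synthetic resting-state generator
#'
#' Bundles and validates the parameters of [simulate_dataset()]. The
#' generator emulates the statistical structure the downstream analysis
#' assumes: nonstationary, autocorrelated raw voxel series (linear drift +
#' once-integrated ARMA coloring) on top of latent area signals whose
#' correlation decays exponentially with inter-centroid distance, is boosted
#' for homotopic (left-right partner) areas, and is strongest within an area.
#'
#' @param n_subjects Number of subjects (default 18, a typical study size).
#' @param voxels_per_area Voxels sampled per area (uniform by default; see
#'   `voxel_allocation`).
#' @param series_length Raw series length in volumes (default 203; the first
#'   volumes are meant to be trimmed downstream).
#' @param distance_decay Decay rate (1/mm) of latent correlation with
#'   centroid distance: `corr(a, b) = exp(-distance_decay * d(a, b))`,
#'   where `d` is computed on LR-rectified centroids so the kernel is
#'   left-right symmetric, as real inter-area connectivity approximately
#'   is.
#' @param contralateral_attenuation In `(0, 1]`; contralateral
#'   non-homotopic correlations are scaled by this factor, realizing the
#'   ipsilateral > contralateral ordering of real data (1 disables it).
#' @param homotopic_boost In `[0, 1]`; homotopic entries are moved toward 1
#'   by convex combination `c + boost * (1 - c)`.
#' @param within_area_weight In `[0, 1]`; loading of each voxel on its
#'   area's latent signal. The within-area voxel correlation (before
#'   coloring) is `w^2 / (w^2 + noise_sd^2)`.
#' @param noise_sd Standard deviation of idiosyncratic voxel noise (signal
#'   units; latent signals have unit variance).
#' @param trend_slope_sd SD of the subject-specific linear drift slope
#'   (signal units per volume).
#' @param ar_coefs,ma_coefs ARMA coloring coefficients applied to the voxel
#'   innovations before integration; the AR polynomial must be stationary
#'   and the MA polynomial invertible.
#' @param baseline Constant added to every series so raw signals resemble
#'   positive BOLD intensities (needed for a meaningful coefficient of
#'   variation).
#' @param psd_repair If `TRUE`, a latent correlation matrix that the
#'   homotopic boost has pushed outside the positive semi-definite cone is
#'   projected back with [Matrix::nearPD()]; if `FALSE` (default) such a
#'   matrix is an error suggesting a parameter change.
#' @param voxel_allocation `"uniform"` (default) or `"volume"` to allocate
#'   voxels proportionally to area volume.
#' @param seed Integer seed; identical configurations reproduce bit-identical
#'   datasets.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_subjects = 18, voxels_per_area = 20,
                         series_length = 203, distance_decay = 0.02,
                         contralateral_attenuation = 0.8,
                         homotopic_boost = 0.9, within_area_weight = 0.9,
                         noise_sd = 0.3, trend_slope_sd = 0.05,
                         ar_coefs = c(0.5, 0.2), ma_coefs = 0.3,
                         baseline = 1000, psd_repair = FALSE,
                         voxel_allocation = c("uniform", "volume"),
                         seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              voxels_per_area = as.integer(voxels_per_area),
              series_length = as.integer(series_length),
              distance_decay = distance_decay,
              contralateral_attenuation = contralateral_attenuation,
              homotopic_boost = homotopic_boost,
              within_area_weight = within_area_weight,
              noise_sd = noise_sd, trend_slope_sd = trend_slope_sd,
              ar_coefs = as.numeric(ar_coefs),
              ma_coefs = as.numeric(ma_coefs),
              baseline = baseline, psd_repair = isTRUE(psd_repair),
              voxel_allocation = match.arg(voxel_allocation),
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$n_subjects < 1 || cfg$voxels_per_area < 1 || cfg$series_length < 1) {
    stop("counts must be >= 1")
  }
  if (cfg$distance_decay < 0) stop("distance_decay must be >= 0")
  if (cfg$contralateral_attenuation <= 0 || cfg$contralateral_attenuation > 1) {
    stop("contralateral_attenuation must lie in (0, 1]")
  }
  if (cfg$homotopic_boost < 0 || cfg$homotopic_boost > 1) {
    stop("homotopic_boost must lie in [0, 1]")
  }
  if (cfg$within_area_weight < 0 || cfg$within_area_weight > 1) {
    stop("within_area_weight must lie in [0, 1]")
  }
  if (cfg$noise_sd < 0 || cfg$trend_slope_sd < 0) {
    stop("noise_sd and trend_slope_sd must be >= 0")
  }
  # stationarity/invertibility: roots of 1 - sum(a_i z^i) (resp. 1 + sum(b_i z^i))
  # must lie outside the unit circle
  if (length(cfg$ar_coefs) && any(cfg$ar_coefs != 0) &&
      min(Mod(polyroot(c(1, -cfg$ar_coefs)))) <= 1) {
    stop("AR polynomial is not stationary")
  }
  if (length(cfg$ma_coefs) && any(cfg$ma_coefs != 0) &&
      min(Mod(polyroot(c(1, cfg$ma_coefs)))) <= 1) {
    stop("MA polynomial is not invertible")
  }
  cfg
}

#' Latent area-level correlation matrix implied by a configuration
#'
#' Returns the correlation matrix of the latent area signals before voxel
#' noise and temporal coloring: exponential distance decay, lifted toward 1
#' for homotopic pairs, with positive semi-definiteness checked (and, only
#' when `cfg$psd_repair` is on, restored by nearest-correlation projection).
#' This is the ground truth that recovery tests compare estimates against.
#'
#' @param atlas An `area_atlas`.
#' @param cfg A `synth_config`.
#' @return Symmetric correlation matrix (areas x areas) with unit diagonal.
#' @export
ground_truth_correlation <- function(atlas, cfg) {
  validate_synth_config(cfg)
  d <- atlas_distance_matrix(atlas, rectify_lr = TRUE)
  C <- exp(-cfg$distance_decay * d)
  hom <- homotopic_pairs(atlas)
  contra <- outer(atlas$hemisphere, atlas$hemisphere, "!=") & !hom
  C[contra] <- cfg$contralateral_attenuation * C[contra]
  C[hom] <- C[hom] + cfg$homotopic_boost * (1 - C[hom])
  C <- (C + t(C)) / 2
  diag(C) <- 1
  off <- C[upper.tri(C)]
  if (length(off) && min(off) > 1 - 1e-12) {
    stop("degenerate configuration: all latent pairwise correlations are 1 ",
         "(increase distance_decay or lower homotopic_boost)")
  }
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    if (cfg$psd_repair) {
      C <- as.matrix(Matrix::nearPD(C, corr = TRUE, maxit = 200)$mat)
      dimnames(C) <- list(atlas$label, atlas$label)
    } else {
      stop("latent correlation matrix is not positive semi-definite after ",
           "the homotopic boost (min eigenvalue ", signif(min(ev), 3),
           "); reduce homotopic_boost or distance_decay, or set ",
           "psd_repair = TRUE to project to the nearest correlation matrix")
    }
  }
  C
}

# zero-padded ARMA coloring of innovation columns, then d = 1 integration
color_series <- function(innov, ar, ma) {
  u <- innov
  for (j in seq_along(ma)) {
    if (ma[j] != 0) {
      nr <- nrow(innov)
      u[(1 + j):nr, ] <- u[(1 + j):nr, ] + ma[j] * innov[1:(nr - j), ]
    }
  }
  if (length(ar) && any(ar != 0)) {
    u <- apply(u, 2, function(col) {
      as.numeric(stats::filter(col, ar, method = "recursive"))
    })
  }
  apply(u, 2, cumsum)
}

#' Simulate a multi-subject voxel time-series dataset
#'
#' Draws latent area signals from the configuration's ground-truth
#' correlation, mixes each voxel as
#' `within_area_weight * latent + N(0, noise_sd)`, and colors each voxel
#' series with a zero-initialized ARMA filter, a cumulative sum (one order
#' of integration) and a subject-specific linear drift on top of a constant
#' baseline. The result is intentionally nonstationary and autocorrelated,
#' so that ARIMA(p, 1, q) prewhitening is well specified.
#'
#' @param atlas An `area_atlas`.
#' @param cfg A `synth_config`.
#' @return A `raw_dataset`: list with `subjects` (each a named list mapping
#'   area label to a voxels x time matrix), `atlas`, `config`, and the
#'   latent correlation actually used in `ground_truth`.
#' @export
simulate_dataset <- function(atlas, cfg) {
  validate_atlas(atlas)
  C <- ground_truth_correlation(atlas, cfg)
  n_areas <- nrow(atlas)
  tt <- cfg$series_length
  e <- eigen(C, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), n_areas)
  nv <- voxel_counts(atlas, cfg)
  set.seed(cfg$seed)
  subjects <- vector("list", cfg$n_subjects)
  names(subjects) <- sprintf("subject_%02d", seq_len(cfg$n_subjects))
  drift_t <- seq_len(tt)
  for (s in seq_len(cfg$n_subjects)) {
    slope <- stats::rnorm(1, 0, cfg$trend_slope_sd)
    latent <- matrix(stats::rnorm(tt * n_areas), tt, n_areas) %*% t(L)
    areas <- vector("list", n_areas)
    names(areas) <- atlas$label
    for (a in seq_len(n_areas)) {
      v <- nv[a]
      base <- cfg$within_area_weight * latent[, a] +
        matrix(stats::rnorm(tt * v, 0, cfg$noise_sd), tt, v)
      x <- color_series(base, cfg$ar_coefs, cfg$ma_coefs)
      x <- x + cfg$baseline + slope * drift_t
      m <- t(x)
      rownames(m) <- sprintf("%s_v%03d", atlas$label[a], seq_len(v))
      areas[[a]] <- m
    }
    subjects[[s]] <- areas
  }
  structure(list(subjects = subjects, atlas = atlas, config = cfg,
                 ground_truth = C),
            class = "raw_dataset")
}

voxel_counts <- function(atlas, cfg) {
  if (cfg$voxel_allocation == "volume") {
    pmax(1L, as.integer(round(cfg$voxels_per_area *
                                atlas$volume / mean(atlas$volume))))
  } else {
    rep(cfg$voxels_per_area, nrow(atlas))
  }
}

#' @export
print.raw_dataset <- function(x, ...) {
  nv <- sum(vapply(x$subjects[[1]], nrow, integer(1)))
  cat(sprintf(
    "raw_dataset: %d subjects, %d areas, %d voxels/subject, %d volumes\n",
    length(x$subjects), nrow(x$atlas), nv, x$config$series_length))
  invisible(x)
}

#' Serialize a raw dataset to a long-format CSV
#'
#' One row per (subject, area, voxel, time) observation; the plain-text
#' interchange format used instead of volumetric images.
#'
#' @param dataset A `raw_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(dataset, path) {
  rows <- lapply(names(dataset$subjects), function(s) {
    areas <- dataset$subjects[[s]]
    do.call(rbind, lapply(names(areas), function(a) {
      m <- areas[[a]]
      data.frame(subject = s, area = a,
                 voxel = rep(seq_len(nrow(m)), each = ncol(m)),
                 t = rep(seq_len(ncol(m)), times = nrow(m)),
                 value = as.vector(t(m)))
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format dataset CSV written by [write_dataset_csv()]
#'
#' @param path CSV path.
#' @param atlas Optional `area_atlas` to attach and validate against.
#' @return A `raw_dataset` (with `config` and `ground_truth` absent).
#' @export
read_dataset_csv <- function(path, atlas = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "area", "voxel", "t", "value")
  if (!all(need %in% names(df))) {
    stop("dataset CSV must have columns ", paste(need, collapse = ", "))
  }
  subjects <- lapply(split(df, df$subject), function(sd) {
    lapply(split(sd, sd$area)[unique(sd$area)], function(ad) {
      nt <- max(ad$t)
      m <- matrix(ad$value[order(ad$voxel, ad$t)],
                  nrow = max(ad$voxel), ncol = nt, byrow = TRUE)
      rownames(m) <- sprintf("%s_v%03d", ad$area[1], seq_len(nrow(m)))
      m
    })
  })
  if (!is.null(atlas)) {
    missing <- setdiff(atlas$label, names(subjects[[1]]))
    if (length(missing)) stop("areas missing from dataset: ",
                              paste(missing, collapse = ", "))
  }
  structure(list(subjects = subjects, atlas = atlas, config = NULL,
                 ground_truth = NULL),
            class = "raw_dataset")
}
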