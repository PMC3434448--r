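# small bilateral atlas spanning an anterior-posterior gradient
toy_atlas <- function(n_stems = 6) {
  stems <- LETTERS[seq_len(n_stems)]
  pa <- seq(40, -60, length.out = n_stems)
  is <- rep(c(30, 10, 45), length.out = n_stems)
  jitter_lr <- rep(seq(-5, 5, length.out = n_stems), 2)
  area_atlas(label = c(paste0("L_", stems), paste0("R_", stems)),
             hemisphere = rep(c("left", "right"), each = n_stems),
             lr = c(rep(-40, n_stems), rep(40, n_stems)) + jitter_lr,
             pa = rep(pa, 2), is = rep(is, 2), volume = 1000)
}

toy_synth_config <- function(...) {
  args <- list(n_subjects = 2, voxels_per_area = 4, series_length = 80,
               psd_repair = TRUE, seed = 5)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synth_config, args)
}

# series with exact mean/sd (for CV-filter cases)
series_with <- function(mean, sd, n = 50, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  (x - base::mean(x)) / stats::sd(x) * sd + mean
}

# pair of series with an exact Pearson correlation r
correlated_pair <- function(r, n = 60, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  z <- stats::rnorm(n)
  x <- x - mean(x)
  z <- stats::residuals(stats::lm(z ~ x))
  y <- r * x / stats::sd(x) + sqrt(1 - r^2) * z / stats::sd(z)
  rbind(x = x, y = y)
}
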