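#' Load the packaged 52-area cortical atlas
#'
#' Reads the packaged fixture of 52 cortical gray-matter areas (26 per
#' hemisphere) with their mean Talairach coordinates and mean volumes, and
#' validates it. Coordinates follow the stereotaxic convention: LR
#' (left-right, left negative), PA (posterior-anterior, posterior negative)
#' and IS (inferior-superior, inferior negative), all in mm.
#'
#' @param path Path to an atlas CSV with columns
#'   `label,hemisphere,x,y,z,volume`. Defaults to the packaged fixture.
#' @return An `area_atlas`: a data frame with columns `label`, `hemisphere`
#'   (`"left"`/`"right"`), `lr`, `pa`, `is` (mm) and `volume` (mm^3).
#' @examples
#' atlas <- load_reference_atlas()
#' nrow(atlas)  # 52
#' @export
load_reference_atlas <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cortical_areas_52.csv",
                        package = "cortexlayout", mustWork = FALSE)
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("atlas fixture not found: ", path, call. = FALSE)
  }
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("corrupt atlas fixture '", path,
                                          "': ", conditionMessage(e),
                                          call. = FALSE))
  need <- c("label", "hemisphere", "x", "y", "z", "volume")
  if (!all(need %in% names(df))) {
    stop("corrupt atlas fixture '", path, "': missing columns ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  area_atlas(label = df$label, hemisphere = df$hemisphere,
             lr = df$x, pa = df$y, is = df$z, volume = df$volume)
}

#' Construct and validate an area atlas
#'
#' @param label Character vector of unique area labels; homotopic partners
#'   share the label stem after the `L_`/`R_` hemisphere prefix.
#' @param hemisphere `"left"` or `"right"` per area.
#' @param lr,pa,is Mean Talairach coordinates in mm (signed).
#' @param volume Mean area volume in mm^3; must be positive.
#' @return An `area_atlas` data frame.
#' @export
area_atlas <- function(label, hemisphere, lr, pa, is, volume) {
  atlas <- data.frame(label = as.character(label),
                      hemisphere = as.character(hemisphere),
                      lr = as.numeric(lr), pa = as.numeric(pa),
                      is = as.numeric(is), volume = as.numeric(volume),
                      stringsAsFactors = FALSE)
  class(atlas) <- c("area_atlas", "data.frame")
  validate_atlas(atlas)
}

#' @rdname area_atlas
#' @param atlas An object to validate as an `area_atlas`.
#' @export
validate_atlas <- function(atlas) {
  stopifnot(is.data.frame(atlas))
  if (anyDuplicated(atlas$label)) stop("atlas labels must be unique")
  if (!all(atlas$hemisphere %in% c("left", "right"))) {
    stop("hemisphere must be 'left' or 'right'")
  }
  if (!all(is.finite(atlas$lr)) || !all(is.finite(atlas$pa)) ||
      !all(is.finite(atlas$is))) {
    stop("atlas coordinates must be finite")
  }
  if (any(!is.finite(atlas$volume)) || any(atlas$volume <= 0)) {
    stop("atlas volumes must be positive")
  }
  n_left <- sum(atlas$hemisphere == "left")
  n_right <- sum(atlas$hemisphere == "right")
  if (n_left > 0 && n_right > 0) {
    if (n_left != n_right) {
      stop("bilateral atlas must have equal area counts per hemisphere")
    }
    stems <- area_stem(atlas$label)
    left <- sort(stems[atlas$hemisphere == "left"])
    right <- sort(stems[atlas$hemisphere == "right"])
    if (!identical(left, right)) {
      stop("homotopic pairs must share the label stem across hemispheres")
    }
  }
  atlas
}

#' Strip the hemisphere prefix from area labels
#'
#' @param label Character vector of labels such as `"L_Precentral"`.
#' @return The label stems, e.g. `"Precentral"`.
#' @export
area_stem <- function(label) sub("^[LR]_", "", label)

#' Area coordinate matrix
#'
#' @param atlas An `area_atlas`.
#' @param rectify_lr If `TRUE`, replace LR with `|LR|` so homotopic partners
#'   coincide on the left-right axis (used for bilateral compactness tests).
#' @return Numeric matrix (areas x 3) with columns `lr`, `pa`, `is` and the
#'   labels as row names.
#' @export
area_coordinates <- function(atlas, rectify_lr = FALSE) {
  x <- cbind(lr = atlas$lr, pa = atlas$pa, is = atlas$is)
  if (rectify_lr) x[, "lr"] <- abs(x[, "lr"])
  rownames(x) <- atlas$label
  x
}

#' Pairwise Euclidean distances between area centroids
#'
#' @inheritParams area_coordinates
#' @return Symmetric matrix of distances in mm.
#' @export
atlas_distance_matrix <- function(atlas, rectify_lr = FALSE) {
  as.matrix(stats::dist(area_coordinates(atlas, rectify_lr)))
}

#' Logical matrix marking homotopic (left-right partner) area pairs
#'
#' @param atlas An `area_atlas`.
#' @return Logical areas x areas matrix, `TRUE` where the two areas share a
#'   label stem but lie in opposite hemispheres.
#' @export
homotopic_pairs <- function(atlas) {
  stems <- area_stem(atlas$label)
  m <- outer(stems, stems, "==") &
    outer(atlas$hemisphere, atlas$hemisphere, "!=")
  dimnames(m) <- list(atlas$label, atlas$label)
  m
}

#' @export
print.area_atlas <- function(x, ...) {
  cat(sprintf("area_atlas: %d areas (%d left, %d right)\n", nrow(x),
              sum(x$hemisphere == "left"), sum(x$hemisphere == "right")))
  NextMethod()
}
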