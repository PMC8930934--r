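#' Tibial-surface footprint of the meniscus
#'
#' Projects the solid meniscus mask onto the tibial plane: footprint cell
#' `(y, x)` is set iff the meniscus column at `(y, x)` contains at least one
#' voxel. This is the discrete analogue of the tibial surface of the
#' meniscus, against which plateau coverage and extrusion are measured.
#'
#' @param seg A [segmented_compartment()].
#' @param require_nonempty Raise an error when the meniscus mask is empty
#'   (default); internal callers may disable.
#' @return Logical matrix over `(y, x)`.
#' @export
meniscus_tibial_footprint <- function(seg, require_nonempty = TRUE) {
  stopifnot(inherits(seg, "segmented_compartment"))
  d <- dim(seg$meniscus)
  fp <- matrix(apply(seg$meniscus, c(1L, 3L), any), nrow = d[1L], ncol = d[3L])
  if (require_nonempty && !any(fp))
    abort_menisq("meniscus mask is empty", "menisq_empty_meniscus")
  fp
}

#' Signed extrusion distance in one coronal slice
#'
#' Distance between the external margin of the tibial plateau and the
#' external margin of the tibial surface of the meniscus, in slice `y`:
#' `(x_max_meniscus - x_max_plateau) * x_spacing`. Positive values mean the
#' meniscus protrudes beyond the plateau margin; negative values mean its
#' margin lies internal to the plateau margin. Margins are the external-most
#' occupied cells (no sub-voxel contour fit).
#'
#' @param seg A [segmented_compartment()].
#' @param y Coronal slice index.
#' @return Signed distance in mm.
#' @export
extrusion_distance_slice <- function(seg, y) {
  stopifnot(inherits(seg, "segmented_compartment"))
  y <- as.integer(y)
  d <- dim(seg$meniscus)
  if (y < 1L || y > d[1L])
    abort_menisq(sprintf("slice %d outside grid (1..%d)", y, d[1L]),
                 "menisq_undefined_slice")
  men_cols <- which(apply(seg$meniscus[y, , , drop = FALSE], 3L, any))
  plat_cols <- which(seg$plateau[y, ])
  if (!length(men_cols) || !length(plat_cols))
    abort_menisq(sprintf("slice %d lacks %s; extrusion undefined", y,
                         if (length(men_cols)) "plateau" else "meniscus"),
                 "menisq_undefined_slice")
  (max(men_cols) - max(plat_cols)) * unname(seg$spacing["x"])
}

#' Central coronal slice window
#'
#' Finds the central slice of the slices containing meniscus and returns a
#' window of `n_slices` around it, intersected with the occupied slices.
#' The central index is `floor((y_first + y_last) / 2)`; for an even number
#' of occupied slices this picks the anterior of the two middle slices (a
#' deterministic tie-break).
#'
#' @param seg A [segmented_compartment()].
#' @param n_slices Odd window size, typically 1 or 5.
#' @return Integer vector of slice indices.
#' @export
central_window <- function(seg, n_slices = 1L) {
  n_slices <- as.integer(n_slices)
  if (n_slices < 1L || n_slices %% 2L == 0L)
    abort_menisq("n_slices must be a positive odd integer",
                 "menisq_invalid_input")
  occ <- meniscus_slices(seg)
  if (!length(occ))
    abort_menisq("meniscus mask is empty", "menisq_empty_meniscus")
  ctr <- (min(occ) + max(occ)) %/% 2L
  half <- (n_slices - 1L) %/% 2L
  intersect(seq.int(ctr - half, ctr + half), occ)
}

# Per-slice signed extrusions over the eligible slices of a window.
slice_extrusions <- function(seg, window = c("all", "central5", "central1")) {
  window <- match.arg(window)
  slices <- switch(window,
    all = meniscus_slices(seg),
    central5 = central_window(seg, 5L),
    central1 = central_window(seg, 1L))
  slices <- intersect(slices, plateau_slices(seg))
  if (!length(slices))
    abort_menisq(sprintf("no slice with both meniscus and plateau in window '%s'", window),
                 "menisq_undefined_measure")
  vapply(slices, function(y) extrusion_distance_slice(seg, y), numeric(1))
}

#' Mean signed extrusion distance
#'
#' Arithmetic mean of the per-slice signed extrusion over all slices in the
#' window where both meniscus and plateau are present. Slices lacking either
#' structure are excluded (not zero-imputed), and negative per-slice values
#' are kept: a meniscus margin internal to the plateau margin contributes a
#' negative distance.
#'
#' @param seg A [segmented_compartment()].
#' @param window `"all"` (entire meniscus), `"central5"` or `"central1"`.
#' @return Mean signed extrusion in mm.
#' @export
mean_extrusion <- function(seg, window = c("all", "central5", "central1")) {
  mean(slice_extrusions(seg, match.arg(window)))
}

#' Maximum extrusion distance
#'
#' Maximum of the per-slice signed extrusion over all eligible slices.
#'
#' @inheritParams mean_extrusion
#' @return Maximum signed extrusion in mm.
#' @export
max_extrusion <- function(seg) {
  max(slice_extrusions(seg, "all"))
}

#' Tibial plateau coverage
#'
#' Percentage of the tibial plateau area covered by the tibial surface of
#' the meniscus. Cell areas are uniform, so the ratio reduces to cell counts.
#'
#' @param seg A [segmented_compartment()].
#' @return Coverage in percent, in `[0, 100]`.
#' @export
coverage_pct <- function(seg) {
  stopifnot(inherits(seg, "segmented_compartment"))
  n_plat <- sum(seg$plateau)
  if (n_plat == 0L)
    abort_menisq("plateau footprint is empty", "menisq_empty_plateau")
  fp <- meniscus_tibial_footprint(seg, require_nonempty = FALSE)
  100 * sum(fp & seg$plateau) / n_plat
}

#' Extruded meniscus area
#'
#' Area of the tibial meniscus surface not covering the tibial plateau, as a
#' percentage of the tibial meniscus surface.
#'
#' @param seg A [segmented_compartment()].
#' @return Percentage in `[0, 100]`.
#' @export
extrusion_area_pct <- function(seg) {
  fp <- meniscus_tibial_footprint(seg)
  100 * sum(fp & !seg$plateau) / sum(fp)
}

#' Meniscus height (thickness) statistics
#'
#' Per occupied column `(y, x)`, height = meniscus voxel count times the
#' z-spacing; returns the mean and maximum over occupied columns.
#'
#' @param seg A [segmented_compartment()].
#' @return Named numeric: `height_mean_mm`, `height_max_mm`.
#' @export
height_stats <- function(seg) {
  stopifnot(inherits(seg, "segmented_compartment"))
  cnt <- apply(seg$meniscus, c(1L, 3L), sum)
  occ <- cnt[cnt > 0L]
  if (!length(occ))
    abort_menisq("meniscus mask is empty", "menisq_empty_meniscus")
  h <- occ * unname(seg$spacing["z"])
  c(height_mean_mm = mean(h), height_max_mm = max(h))
}

#' Mean meniscus width
#'
#' Per slice containing meniscus, width = medio-lateral extent of the
#' meniscus footprint, `(x_max - x_min + 1) * x_spacing`; mean over those
#' slices.
#'
#' @param seg A [segmented_compartment()].
#' @return Mean width in mm.
#' @export
width_mean <- function(seg) {
  fp <- meniscus_tibial_footprint(seg)
  rows <- which(rowSums(fp) > 0L)
  w <- vapply(rows, function(y) {
    xs <- which(fp[y, ])
    (max(xs) - min(xs) + 1L)
  }, numeric(1))
  mean(w) * unname(seg$spacing["x"])
}

#' Meniscus volume
#'
#' Voxel count times the voxel volume, converted from cubic mm to ml.
#' An empty mask has volume 0.
#'
#' @param seg A [segmented_compartment()].
#' @return Volume in ml.
#' @export
volume_ml <- function(seg) {
  stopifnot(inherits(seg, "segmented_compartment"))
  sum(seg$meniscus) * prod(seg$spacing) / 1000
}

#' All position and morphology measures of one compartment
#'
#' Computes the ten aggregate measures: extrusion area (%), mean / maximum
#' signed extrusion (mm) and mean extrusion over the central 5 slices and
#' the central slice, tibial plateau coverage (%), mean width (mm), mean and
#' maximum height (mm), and volume (ml). Component errors propagate; no
#' partial result is returned.
#'
#' @param seg A [segmented_compartment()].
#' @return Named numeric vector of class `meniscus_measures`.
#' @export
compute_all_measures <- function(seg) {
  hs <- height_stats(seg)
  out <- c(
    extrusion_area_pct        = extrusion_area_pct(seg),
    mean_extrusion_mm         = mean_extrusion(seg, "all"),
    max_extrusion_mm          = max_extrusion(seg),
    mean_extrusion_central5_mm = mean_extrusion(seg, "central5"),
    mean_extrusion_central1_mm = mean_extrusion(seg, "central1"),
    coverage_pct              = coverage_pct(seg),
    width_mean_mm             = width_mean(seg),
    height_mean_mm            = unname(hs["height_mean_mm"]),
    height_max_mm             = unname(hs["height_max_mm"]),
    volume_ml                 = volume_ml(seg))
  class(out) <- c("meniscus_measures", class(out))
  out
}

#' Measures over a central window
#'
#' Restricts the compartment to the central `n`-slice window (both meniscus
#' and plateau) and computes the aggregate measures there, so e.g. coverage
#' within the window is relative to the plateau area within the window.
#'
#' @param seg A [segmented_compartment()].
#' @param n_slices Odd window size (1 or 5).
#' @return Named numeric vector of class `meniscus_measures`.
#' @export
central_measures <- function(seg, n_slices = 5L) {
  compute_all_measures(restrict_slices(seg, central_window(seg, n_slices)))
}

measure_names <- function() {
  c("extrusion_area_pct", "mean_extrusion_mm", "max_extrusion_mm",
    "mean_extrusion_central5_mm", "mean_extrusion_central1_mm",
    "coverage_pct", "width_mean_mm", "height_mean_mm", "height_max_mm",
    "volume_ml")
}

#' @export
print.meniscus_measures <- function(x, ...) {
  cat("<meniscus_measures>\n")
  print(round(unclass(x), 3))
  invisible(x)
}
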