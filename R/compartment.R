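#' Segmented femorotibial compartment
#'
#' Container for the voxelized segmentation of one femorotibial compartment:
#' a solid binary meniscus mask plus the tibial plateau footprint (the total
#' area of subchondral bone, ACdAB, projected onto the tibial plane).
#'
#' Axis convention (fixed throughout the package):
#' * axis 1 (`y`): coronal slice index, anterior to posterior;
#' * axis 2 (`z`): inferior to superior;
#' * axis 3 (`x`): internal to external, where "external" points away from
#'   the knee midline for the given compartment (medially for a medial
#'   compartment, laterally for a lateral one). Extrusion is measured along
#'   this axis, per coronal slice.
#'
#' The meniscus is stored as a solid region; the tibial surface of the
#' meniscus is derived as the per-column projection
#' (see [meniscus_tibial_footprint()]).
#'
#' @param meniscus_mask 3D logical/0-1 array with dimensions `(y, z, x)`.
#' @param plateau_footprint 2D logical/0-1 matrix over `(y, x)`; must share
#'   the `(y, x)` extent of `meniscus_mask`.
#' @param spacing Numeric length 3: voxel spacing in mm as
#'   `(slice_thickness, z, x)`. Default `c(1.5, 0.37, 0.37)`, the coronal
#'   DESS reconstruction spacing.
#' @param compartment `"medial"` or `"lateral"`.
#'
#' @return An object of class `segmented_compartment`.
#' @export
segmented_compartment <- function(meniscus_mask, plateau_footprint,
                                  spacing = c(1.5, 0.37, 0.37),
                                  compartment = c("medial", "lateral")) {
  compartment <- match.arg(compartment)
  if (!is.array(meniscus_mask) || length(dim(meniscus_mask)) != 3L)
    abort_menisq("meniscus_mask must be a 3D array (y, z, x)",
                 "menisq_invalid_input")
  if (length(dim(plateau_footprint)) != 2L)
    abort_menisq("plateau_footprint must be a 2D matrix (y, x)",
                 "menisq_invalid_input")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    abort_menisq("spacing must be 3 positive numbers (slice, z, x) in mm",
                 "menisq_invalid_input")
  dm <- dim(meniscus_mask)
  dp <- dim(plateau_footprint)
  if (dm[1L] != dp[1L] || dm[3L] != dp[2L])
    abort_menisq(sprintf(
      "meniscus_mask (y=%d, x=%d) and plateau_footprint (y=%d, x=%d) must share the (y, x) grid",
      dm[1L], dm[3L], dp[1L], dp[2L]), "menisq_invalid_input")
  men <- array(as.logical(meniscus_mask), dim = dm)
  plat <- matrix(as.logical(plateau_footprint), nrow = dp[1L], ncol = dp[2L])
  men[is.na(men)] <- FALSE
  plat[is.na(plat)] <- FALSE
  structure(
    list(meniscus = men, plateau = plat,
         spacing = c(slice = spacing[1L], z = spacing[2L], x = spacing[3L]),
         compartment = compartment),
    class = "segmented_compartment")
}

#' @export
print.segmented_compartment <- function(x, ...) {
  d <- dim(x$meniscus)
  cat(sprintf(
    "<segmented_compartment> %s | grid %d slices x %d (z) x %d (x) | spacing %.2f/%.2f/%.2f mm\n",
    x$compartment, d[1L], d[2L], d[3L],
    x$spacing[1L], x$spacing[2L], x$spacing[3L]))
  cat(sprintf("  meniscus voxels: %d | plateau cells: %d | slices with both: %d\n",
              sum(x$meniscus), sum(x$plateau), length(eligible_slices(x))))
  invisible(x)
}

# Slice indices (y) containing at least one meniscus voxel.
meniscus_slices <- function(seg) {
  fp <- meniscus_tibial_footprint(seg, require_nonempty = FALSE)
  which(rowSums(fp) > 0L)
}

plateau_slices <- function(seg) which(rowSums(seg$plateau) > 0L)

# Slices where extrusion is defined: both structures present.
eligible_slices <- function(seg) intersect(meniscus_slices(seg), plateau_slices(seg))

#' Restrict a compartment to a set of coronal slices
#'
#' Returns a copy of `seg` in which both the meniscus mask and the plateau
#' footprint are blanked outside `slices`. Used to compute measures over a
#' central-slice window with the same code path as the entire meniscus.
#'
#' @param seg A [segmented_compartment()].
#' @param slices Integer vector of slice (y) indices to keep.
#' @return A `segmented_compartment`.
#' @export
restrict_slices <- function(seg, slices) {
  stopifnot(inherits(seg, "segmented_compartment"))
  ny <- dim(seg$meniscus)[1L]
  keep <- intersect(as.integer(slices), seq_len(ny))
  drop <- setdiff(seq_len(ny), keep)
  if (length(drop)) {
    seg$meniscus[drop, , ] <- FALSE
    seg$plateau[drop, ] <- FALSE
  }
  seg
}
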