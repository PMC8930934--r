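#' C-phantom specification
#'
#' A geometrically idealized meniscus: a C-shaped (annulus-sector) wedge
#' whose thickness rises linearly from the inner to the outer radius,
#' sitting on a half-disc tibial plateau. The meniscus centre can be shifted
#' externally by `extrusion_shift_mm` to emulate extrusion. The defaults
#' approximate an adult medial compartment (outer radius 22 mm, inner 9 mm,
#' 170 deg arc, 6 mm peripheral height, 22 mm plateau radius).
#'
#' This phantom is a rasterization testbed, not an anatomical model: it
#' exists so that measures computed at clinical voxel sizes can be compared
#' against the same geometry rasterized on a much finer grid.
#'
#' @param inner_radius_mm,outer_radius_mm Annulus radii (outer > inner > 0).
#' @param arc_span_deg Arc span centred on the external (+x) direction,
#'   in `(0, 360]`.
#' @param wedge_height_outer_mm Meniscus thickness at the outer radius.
#' @param extrusion_shift_mm External shift of the meniscus centre.
#' @param plateau_radius_mm Radius of the half-disc plateau (`x >= 0`).
#' @param spacing Voxel spacing `(slice, z, x)` in mm.
#' @param margin_mm Empty border added around the geometry.
#' @return A list of class `c_phantom_spec`.
#' @export
c_phantom_spec <- function(inner_radius_mm = 9, outer_radius_mm = 22,
                           arc_span_deg = 170, wedge_height_outer_mm = 6,
                           extrusion_shift_mm = 3, plateau_radius_mm = 22,
                           spacing = c(1.5, 0.37, 0.37), margin_mm = 2) {
  spec <- list(inner_radius_mm = inner_radius_mm,
               outer_radius_mm = outer_radius_mm,
               arc_span_deg = arc_span_deg,
               wedge_height_outer_mm = wedge_height_outer_mm,
               extrusion_shift_mm = extrusion_shift_mm,
               plateau_radius_mm = plateau_radius_mm,
               spacing = as.numeric(spacing), margin_mm = margin_mm)
  if (!(spec$outer_radius_mm > spec$inner_radius_mm && spec$inner_radius_mm > 0))
    abort_menisq("need outer_radius > inner_radius > 0", "menisq_invalid_input")
  if (spec$arc_span_deg <= 0 || spec$arc_span_deg > 360)
    abort_menisq("arc_span_deg must be in (0, 360]", "menisq_invalid_input")
  if (spec$wedge_height_outer_mm <= 0 || spec$plateau_radius_mm <= 0)
    abort_menisq("heights and radii must be positive", "menisq_invalid_input")
  class(spec) <- "c_phantom_spec"
  spec
}

# Rasterize the continuous C geometry at the given spacing. Cell centres
# are tested against the continuous sets; a column's voxel count is the
# number of z-cell centres below the local wedge height.
rasterize_c_phantom <- function(spec, spacing) {
  sy <- spacing[1L]; sz <- spacing[2L]; sx <- spacing[3L]
  s <- spec$extrusion_shift_mm
  r_o <- spec$outer_radius_mm; r_i <- spec$inner_radius_mm
  rp <- spec$plateau_radius_mm
  half_arc <- spec$arc_span_deg / 2 * pi / 180
  mg <- spec$margin_mm
  ymax <- max(r_o, rp) + mg
  xmin <- -mg
  xmax <- max(rp, s + r_o) + mg
  zmax <- spec$wedge_height_outer_mm + mg
  ny <- ceiling(2 * ymax / sy)
  nx <- ceiling((xmax - xmin) / sx)
  nz <- ceiling(zmax / sz)
  yc <- -ymax + (seq_len(ny) - 0.5) * sy
  xc <- xmin + (seq_len(nx) - 0.5) * sx
  zc <- (seq_len(nz) - 0.5) * sz

  Y <- matrix(yc, ny, nx)
  X <- matrix(xc, ny, nx, byrow = TRUE)
  plat <- (X^2 + Y^2 <= rp^2) & (X >= 0)

  U <- X - s
  rho <- sqrt(U^2 + Y^2)
  theta <- atan2(Y, U)
  inside <- rho >= r_i & rho <= r_o & abs(theta) <= half_arc
  hgt <- ifelse(inside,
                spec$wedge_height_outer_mm * (rho - r_i) / (r_o - r_i), 0)
  men <- array(FALSE, dim = c(ny, nz, nx))
  for (k in seq_len(nz))
    men[, k, ] <- hgt > zc[k]
  segmented_compartment(men, plat, spacing = c(sy, sz, sx),
                        compartment = "medial")
}

#' Build a C-phantom with a fine-grid reference
#'
#' Rasterizes the C geometry at the requested spacing and, independently,
#' at `refine`-fold finer spacing along every axis; the measures of the
#' fine rasterization serve as the reference against which coarse-grid
#' accuracy is judged.
#'
#' @param spec A [c_phantom_spec()].
#' @param refine Refinement factor for the reference grid (>= 2).
#' @return List with `seg` (coarse compartment), `reference` (measures on
#'   the fine grid) and `refine`.
#' @export
make_c_phantom <- function(spec, refine = 4L) {
  stopifnot(inherits(spec, "c_phantom_spec"))
  refine <- as.integer(refine)
  if (refine < 2L)
    abort_menisq("refine must be >= 2", "menisq_invalid_input")
  seg <- rasterize_c_phantom(spec, spec$spacing)
  ref_seg <- rasterize_c_phantom(spec, spec$spacing / refine)
  list(seg = seg, reference = compute_all_measures(ref_seg), refine = refine)
}
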