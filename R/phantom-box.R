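#' Box phantom specification
#'
#' Rectangular test geometry with closed-form measures: a plateau footprint
#' spanning `x = 1..plateau_extent_x` in every slice and a rectangular
#' meniscus slab of constant width and height whose external margin sits
#' `external_offset` cells beyond (or, if negative, inside) the plateau
#' margin, per slice.
#'
#' @param n_slices Number of coronal slices (>= 1).
#' @param plateau_extent_x Plateau width in cells.
#' @param meniscus_extent_x Meniscus width in cells.
#' @param external_offset Integer offset of the external meniscus margin
#'   relative to the plateau margin, in cells; scalar or one per slice.
#' @param meniscus_height Meniscus thickness in voxels.
#' @param spacing Voxel spacing `(slice, z, x)` in mm.
#' @param compartment `"medial"` or `"lateral"`.
#' @return A list of class `box_phantom_spec`.
#' @export
box_phantom_spec <- function(n_slices = 11L, plateau_extent_x = 20L,
                             meniscus_extent_x = 10L, external_offset = 2L,
                             meniscus_height = 6L,
                             spacing = c(1.5, 0.37, 0.37),
                             compartment = "medial") {
  spec <- list(n_slices = as.integer(n_slices),
               plateau_extent_x = as.integer(plateau_extent_x),
               meniscus_extent_x = as.integer(meniscus_extent_x),
               external_offset = as.integer(external_offset),
               meniscus_height = as.integer(meniscus_height),
               spacing = as.numeric(spacing), compartment = compartment)
  if (spec$n_slices < 1L || spec$plateau_extent_x < 1L ||
      spec$meniscus_extent_x < 1L || spec$meniscus_height < 1L)
    abort_menisq("all box phantom extents must be >= 1", "menisq_invalid_input")
  if (!length(spec$external_offset) %in% c(1L, spec$n_slices))
    abort_menisq("external_offset must be scalar or one per slice",
                 "menisq_invalid_input")
  class(spec) <- "box_phantom_spec"
  spec
}

#' Build a box phantom with analytic ground truth
#'
#' Rasterizes the specification into a [segmented_compartment()] and
#' returns, alongside, the ten aggregate measures computed from pencil-and-
#' paper formulas (offsets, extents and voxel counts), independent of the
#' morphometry code path.
#'
#' @param spec A [box_phantom_spec()].
#' @return List with `seg` (the compartment) and `truth` (named measures).
#' @export
make_box_phantom <- function(spec) {
  stopifnot(inherits(spec, "box_phantom_spec"))
  ns <- spec$n_slices
  pe <- spec$plateau_extent_x
  me <- spec$meniscus_extent_x
  off <- rep(spec$external_offset, length.out = ns)
  h <- spec$meniscus_height
  sp <- spec$spacing
  ends <- pe + off                      # external meniscus margin per slice
  starts <- ends - me + 1L
  if (any(starts < 1L))
    abort_menisq("meniscus extends below x = 1; reduce extent or raise offset",
                 "menisq_invalid_input")
  nx <- max(pe, max(ends))
  men <- array(FALSE, dim = c(ns, h, nx))
  plat <- matrix(FALSE, nrow = ns, ncol = nx)
  for (y in seq_len(ns)) {
    plat[y, seq_len(pe)] <- TRUE
    men[y, seq_len(h), starts[y]:ends[y]] <- TRUE
  }
  seg <- segmented_compartment(men, plat, spacing = sp,
                               compartment = spec$compartment)

  sx <- sp[3L]; sz <- sp[2L]
  ctr <- (1L + ns) %/% 2L
  w5 <- intersect(seq.int(ctr - 2L, ctr + 2L), seq_len(ns))
  overlap <- vapply(seq_len(ns), function(y)
    length(intersect(starts[y]:ends[y], seq_len(pe))), integer(1))
  outside <- me - overlap
  truth <- c(
    extrusion_area_pct         = 100 * sum(outside) / (ns * me),
    mean_extrusion_mm          = mean(off) * sx,
    max_extrusion_mm           = max(off) * sx,
    mean_extrusion_central5_mm = mean(off[w5]) * sx,
    mean_extrusion_central1_mm = off[ctr] * sx,
    coverage_pct               = 100 * sum(overlap) / (ns * pe),
    width_mean_mm              = me * sx,
    height_mean_mm             = h * sz,
    height_max_mm              = h * sz,
    volume_ml                  = ns * me * h * prod(sp) / 1000)
  list(seg = seg, truth = truth)
}
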