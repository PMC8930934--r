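# Label-volume encoding: one NIfTI volume with axes (y, z, x) as in
# segmented_compartment. Meniscus voxels carry the meniscus label bit; the
# plateau footprint lives in the inferior-most (z = 1) layer and carries the
# plateau label bit, so a z = 1 voxel holding both structures is
# meniscus_label + plateau_label.

default_label_map <- function() c(meniscus = 1L, plateau = 2L)

#' Write a segmented compartment as a NIfTI label volume
#'
#' @param seg A [segmented_compartment()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param labels Named integer vector with `meniscus` and `plateau` labels.
#' @return `path`, invisibly.
#' @export
write_segmented_compartment <- function(seg, path,
                                        labels = default_label_map()) {
  stopifnot(inherits(seg, "segmented_compartment"))
  vol <- array(0L, dim = dim(seg$meniscus))
  vol[seg$meniscus] <- labels[["meniscus"]]
  vol[, 1L, ][seg$plateau] <- vol[, 1L, ][seg$plateau] + labels[["plateau"]]
  attr(vol, "pixdim") <- unname(seg$spacing)
  attr(vol, "pixunits") <- "mm"
  RNifti::writeNifti(RNifti::asNifti(vol, datatype = "uint8"), path)
  invisible(path)
}

#' Read a segmented compartment from a NIfTI label volume
#'
#' Voxel spacing is taken from the header unless overridden.
#'
#' @param path NIfTI file written by [write_segmented_compartment()] (or
#'   following the same convention).
#' @param labels Named integer vector with `meniscus` and `plateau` labels.
#' @param spacing Optional spacing override `(slice, z, x)` in mm.
#' @param compartment `"medial"` or `"lateral"`.
#' @return A [segmented_compartment()].
#' @export
read_segmented_compartment <- function(path, labels = default_label_map(),
                                       spacing = NULL,
                                       compartment = "medial") {
  img <- RNifti::readNifti(path)
  vol <- as.array(img)
  if (length(dim(vol)) != 3L)
    abort_menisq(sprintf("%s: expected a 3D label volume", path),
                 "menisq_invalid_input")
  if (is.null(spacing)) spacing <- RNifti::pixdim(img)[1:3]
  men_lab <- labels[["meniscus"]]; plat_lab <- labels[["plateau"]]
  men <- vol == men_lab | vol == men_lab + plat_lab
  plat_plane <- vol[, 1L, ]
  plat <- plat_plane == plat_lab | plat_plane == men_lab + plat_lab
  if (!any(plat))
    abort_menisq(sprintf("%s: no voxel carries plateau label %d", path, plat_lab),
                 "menisq_missing_label")
  if (!any(men))
    abort_menisq(sprintf("%s: no voxel carries meniscus label %d", path, men_lab),
                 "menisq_missing_label")
  segmented_compartment(men, plat, spacing = spacing, compartment = compartment)
}

#' Write per-knee measures to CSV
#'
#' One row per (knee, compartment); measure columns rounded to 3 decimals
#' (units mm, ml or percent).
#'
#' @param measures data.frame containing the measure columns (and any id
#'   columns, kept verbatim).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measures_csv <- function(measures, path) {
  out <- measures
  for (nm in intersect(measure_names(), names(out)))
    out[[nm]] <- round(out[[nm]], 3)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort records CSV
#'
#' @param path CSV with one row per knee (see [simulate_cohort()] record
#'   schema).
#' @return data.frame.
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a cohort records CSV
#'
#' @param records data.frame of knee records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
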