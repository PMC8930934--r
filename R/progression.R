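#' Smallest detectable change from test-retest differences
#'
#' SDC = 1.96 x SD of the paired test-retest change differences (sample SD,
#' n-1 denominator); equivalently `1.96 * sqrt(2) * SEM` with
#' `SEM = SD_diff / sqrt(2)`. An observed longitudinal change larger than
#' the SDC is unlikely (at the 5% level) to be measurement noise.
#'
#' @param test_retest_differences Numeric vector (length >= 2) of paired
#'   change differences, in the units of the measurement.
#' @return SDC threshold in the same units.
#' @export
compute_sdc <- function(test_retest_differences) {
  d <- as.numeric(test_retest_differences)
  d <- d[!is.na(d)]
  if (length(d) < 2L)
    abort_menisq("need at least 2 test-retest differences",
                 "menisq_invalid_input")
  1.96 * stats::sd(d)
}

#' SDC progression thresholds
#'
#' Published smallest-detectable-change thresholds, in micrometres, for
#' 12-month loss in medial (`mftc_um`) and lateral (`lftc_um`) femorotibial
#' cartilage thickness and in medial minimum joint space width
#' (`minjsw_um`). The defaults are injected as constants, not recomputed.
#'
#' @param mftc_um,lftc_um,minjsw_um Positive thresholds in micrometres.
#' @return A list of class `sdc_thresholds`.
#' @export
sdc_thresholds <- function(mftc_um = 102, lftc_um = 92, minjsw_um = 328) {
  thr <- list(mftc_um = as.numeric(mftc_um), lftc_um = as.numeric(lftc_um),
              minjsw_um = as.numeric(minjsw_um))
  if (any(vapply(thr, function(v) !is.finite(v) || v <= 0, logical(1))))
    abort_menisq("all SDC thresholds must be positive", "menisq_invalid_input")
  class(thr) <- "sdc_thresholds"
  thr
}

# 12-month losses in micrometres from a one-row record / named list.
knee_losses_um <- function(rec) {
  need <- c("mftc_mm_baseline", "mftc_mm_y1", "lftc_mm_baseline",
            "lftc_mm_y1", "minjsw_mm_baseline", "minjsw_mm_y1")
  vals <- lapply(need, function(f) {
    v <- rec[[f]]
    if (is.null(v) || length(v) != 1L || is.na(v)) NA_real_ else as.numeric(v)
  })
  names(vals) <- need
  if (anyNA(unlist(vals)))
    abort_menisq(
      paste("record unclassifiable; missing:",
            paste(need[is.na(unlist(vals))], collapse = ", ")),
      "menisq_unclassifiable")
  c(mftc   = (vals$mftc_mm_baseline - vals$mftc_mm_y1) * 1000,
    lftc   = (vals$lftc_mm_baseline - vals$lftc_mm_y1) * 1000,
    minjsw = (vals$minjsw_mm_baseline - vals$minjsw_mm_y1) * 1000)
}

#' Classify one knee as progressor / non-progressor / indeterminate
#'
#' A knee is a structural progressor when both its medial cartilage
#' thickness loss and its medial minJSW loss exceed their SDC thresholds; a
#' non-progressor when medial thickness loss, minJSW loss and lateral
#' thickness loss all fail to exceed their thresholds; anything else is
#' indeterminate. Losses are `baseline - year1`, converted from mm to
#' micrometres to match the thresholds.
#'
#' With `strict = TRUE` (default) "exceeding" is a strict inequality, so a
#' loss exactly at the threshold is compatible with non-progression.
#'
#' @param rec A one-row data.frame or named list with
#'   `mftc_mm_baseline`, `mftc_mm_y1`, `lftc_mm_baseline`, `lftc_mm_y1`,
#'   `minjsw_mm_baseline`, `minjsw_mm_y1` (mm).
#' @param thresholds An [sdc_thresholds()] object.
#' @param strict Use `>` (default) rather than `>=` for "exceeding".
#' @return `"progressor"`, `"non_progressor"` or `"indeterminate"`.
#' @export
classify_knee <- function(rec, thresholds = sdc_thresholds(), strict = TRUE) {
  stopifnot(inherits(thresholds, "sdc_thresholds"))
  loss <- knee_losses_um(rec)
  exceeds <- if (strict) `>` else `>=`
  p_mftc <- exceeds(loss[["mftc"]], thresholds$mftc_um)
  p_jsw  <- exceeds(loss[["minjsw"]], thresholds$minjsw_um)
  p_lftc <- exceeds(loss[["lftc"]], thresholds$lftc_um)
  if (p_mftc && p_jsw) return("progressor")
  if (!p_mftc && !p_jsw && !p_lftc) return("non_progressor")
  "indeterminate"
}

#' Classify a cohort table
#'
#' Vectorised [classify_knee()]: appends a `class` column. Records with
#' missing longitudinal values are labelled `"unclassifiable"` with the
#' reason in `exclusion_reason` (they are excluded, mirroring a selection
#' funnel, rather than raising).
#'
#' @param records data.frame with one row per knee.
#' @inheritParams classify_knee
#' @return `records` with `class` and `exclusion_reason` columns.
#' @export
classify_knees <- function(records, thresholds = sdc_thresholds(),
                           strict = TRUE) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  cls <- character(n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    res <- tryCatch(
      classify_knee(records[i, , drop = FALSE], thresholds, strict),
      menisq_unclassifiable = function(e) e)
    if (inherits(res, "condition")) {
      cls[i] <- "unclassifiable"
      reason[i] <- conditionMessage(res)
    } else cls[i] <- res
  }
  records$class <- cls
  records$exclusion_reason <- reason
  records
}

#' Radiographic eligibility filter
#'
#' Retains knees with definite but not end-stage radiographic osteoarthritis:
#' Kellgren-Lawrence grade within `[klg_min, klg_max]` (default grades 2-3).
#' Per-grade counts of the input are attached as attribute `klg_counts`.
#'
#' @param records data.frame with a `klg` column.
#' @param klg_min,klg_max Inclusive KLG bounds.
#' @return Filtered data.frame.
#' @export
apply_eligibility <- function(records, klg_min = 2L, klg_max = 3L) {
  stopifnot(is.data.frame(records), "klg" %in% names(records))
  counts <- table(factor(records$klg, levels = 0:4), useNA = "ifany")
  keep <- !is.na(records$klg) & records$klg >= klg_min & records$klg <= klg_max
  out <- records[keep, , drop = FALSE]
  attr(out, "klg_counts") <- counts
  out
}
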