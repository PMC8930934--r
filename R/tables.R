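# Row order and display labels of the matched-comparison tables (height_max
# is computed but, like in the summary tables, not tabulated).
comparison_measure_labels <- function() {
  c(extrusion_area_pct         = "Extrusion area (%)",
    mean_extrusion_mm          = "Mean extrusion distance (mm)",
    max_extrusion_mm           = "Max. extrusion distance (mm)",
    mean_extrusion_central5_mm = "Mean extrusion 5 central slices (mm)",
    mean_extrusion_central1_mm = "Mean extrusion central slice (mm)",
    coverage_pct               = "Tibial plateau coverage (%)",
    width_mean_mm              = "Width mean total (mm)",
    height_mean_mm             = "Height mean (mm)",
    volume_ml                  = "Volume (ml)")
}

#' Matched case-control comparison table
#'
#' For each measure, group means and SDs, the mean within-pair difference
#' (cases minus controls) with its paired-t 95% confidence interval,
#' pooled-SD Cohen's D and the paired-t p-value. Rows `i` of `cases` and
#' `controls` must belong to the same matched pair.
#'
#' Values are returned at full precision; use [format_comparison_table()]
#' for the printed-table rendering (1 dp measures, 2 dp effect sizes,
#' "< 0.01" p-value floor).
#'
#' @param cases,controls data.frames of per-knee measures with identical
#'   row counts; columns selected by `measures`.
#' @param measures Character vector of measure columns (default: the nine
#'   tabulated measures, in table order).
#' @return data.frame with one `PairedComparison` row per measure.
#' @export
comparison_table <- function(cases, controls,
                             measures = names(comparison_measure_labels())) {
  stopifnot(is.data.frame(cases), is.data.frame(controls))
  if (nrow(cases) != nrow(controls))
    abort_menisq("cases and controls must be paired (equal row counts)",
                 "menisq_invalid_input")
  measures <- intersect(measures, intersect(names(cases), names(controls)))
  rows <- lapply(measures, function(mv) {
    xc <- as.numeric(cases[[mv]]); xk <- as.numeric(controls[[mv]])
    d <- xc - xk
    ci <- mean_diff_ci95(d)
    p <- tryCatch(paired_t_test(d)$p_value,
                  menisq_degenerate = function(e) NA_real_)
    dd <- tryCatch(
      cohens_d_pooled(mean(xc), stats::sd(xc), mean(xk), stats::sd(xk)),
      menisq_degenerate = function(e) NA_real_)
    data.frame(
      measure = mv, n_pairs = length(d),
      mean_case = mean(xc), sd_case = stats::sd(xc),
      mean_control = mean(xk), sd_control = stats::sd(xk),
      mean_diff = unname(ci["mean"]),
      ci95_low = unname(ci["ci95_low"]), ci95_high = unname(ci["ci95_high"]),
      cohens_d = dd,
      p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Render a comparison table at printed precision
#'
#' Rounds (half away from zero) means/SDs/differences/CIs to 1 decimal
#' place and Cohen's D to 2; p-values are shown to 2 decimals with the
#' floor notation `"< 0.01"` below 0.005.
#'
#' @param tab Output of [comparison_table()].
#' @return data.frame of character/numeric display columns.
#' @export
format_comparison_table <- function(tab) {
  lab <- comparison_measure_labels()
  fmt1 <- function(x) sprintf("%.1f", round_half_away(x, 1L))
  out <- data.frame(
    measure = ifelse(tab$measure %in% names(lab), lab[tab$measure], tab$measure),
    mean_case = fmt1(tab$mean_case), sd_case = fmt1(tab$sd_case),
    mean_control = fmt1(tab$mean_control), sd_control = fmt1(tab$sd_control),
    mean_diff = fmt1(tab$mean_diff),
    ci95 = sprintf("(%s, %s)", fmt1(tab$ci95_low), fmt1(tab$ci95_high)),
    cohens_d = sprintf("%.2f", round_half_away(tab$cohens_d, 2L)),
    p = ifelse(is.na(tab$p_value), "-",
        ifelse(round_half_away(tab$p_value, 2L) < 0.01, "< 0.01",
               sprintf("%.2f", round_half_away(tab$p_value, 2L)))),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Entire-versus-central-slice correlation table
#'
#' Pearson correlation and variance explained (integer percent) between
#' measures over the entire meniscus and the same measures over the central
#' window: mean extrusion entire vs central 5 and entire vs central slice,
#' then plateau coverage, volume, mean height and mean width entire vs
#' central 5. Inputs must be aligned per knee (same row = same knee).
#'
#' @param entire_measures data.frame of whole-meniscus measures.
#' @param central5_measures data.frame of central-5-slice measures (needs
#'   `mean_extrusion_mm`, `coverage_pct`, `volume_ml`, `height_mean_mm`,
#'   `width_mean_mm`).
#' @param central1_measures data.frame with `mean_extrusion_mm` of the
#'   central slice.
#' @return data.frame with `comparison`, `r`, `r2_pct`.
#' @export
correlation_table <- function(entire_measures, central5_measures,
                              central1_measures) {
  n <- nrow(entire_measures)
  if (nrow(central5_measures) != n || nrow(central1_measures) != n)
    abort_menisq("measure tables must be aligned per knee", "menisq_invalid_input")
  pairs <- list(
    list("Mean extrusion distance: entire vs. central 5 slices",
         entire_measures$mean_extrusion_mm, central5_measures$mean_extrusion_mm),
    list("Mean extrusion distance: entire vs. central slice",
         entire_measures$mean_extrusion_mm, central1_measures$mean_extrusion_mm),
    list("Tibia plateau coverage (%): entire vs. central 5 slices",
         entire_measures$coverage_pct, central5_measures$coverage_pct),
    list("Volume: entire vs. central 5 slices",
         entire_measures$volume_ml, central5_measures$volume_ml),
    list("Mean height: entire vs. central 5 slices",
         entire_measures$height_mean_mm, central5_measures$height_mean_mm),
    list("Mean width: entire vs. central 5 slices",
         entire_measures$width_mean_mm, central5_measures$width_mean_mm))
  rows <- lapply(pairs, function(p) {
    r <- pearson_r(p[[2L]], p[[3L]])
    data.frame(comparison = p[[1L]], r = r,
               r2_pct = variance_explained_pct(r), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
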