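#' Pipeline configuration
#'
#' Validated bundle of the tunable settings shared by the pipeline stages.
#' Invalid values fail fast with field-level messages.
#'
#' @param spacing Voxel spacing override `(slice, z, x)` mm, or `NULL` to
#'   use each mask file's header.
#' @param labels Named integer vector with `meniscus` and `plateau` labels.
#' @param thresholds An [sdc_thresholds()] object (or list coercible to one).
#' @param calipers Named caliper vector for [match_spec()].
#' @param exact_vars Exact-match variables for [match_spec()].
#' @param seed Integer seed for simulation stages.
#' @param out_dir Output directory.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(spacing = NULL,
                            labels = default_label_map(),
                            thresholds = sdc_thresholds(),
                            calipers = c(height_cm = 3, bmi_kg_m2 = 5,
                                         womac_pain = 5),
                            exact_vars = c("sex", "klg"),
                            seed = 1L, out_dir = ".") {
  if (!is.null(spacing)) {
    spacing <- as.numeric(spacing)
    if (length(spacing) != 3L || any(spacing <= 0) || any(!is.finite(spacing)))
      abort_menisq("config field 'spacing': need 3 positive numbers",
                   "menisq_config_error")
  }
  if (!all(c("meniscus", "plateau") %in% names(labels)))
    abort_menisq("config field 'labels': need named entries meniscus, plateau",
                 "menisq_config_error")
  if (!inherits(thresholds, "sdc_thresholds"))
    thresholds <- do.call(sdc_thresholds, as.list(thresholds))
  spec <- match_spec(exact_vars = exact_vars, calipers = calipers)
  seed <- suppressWarnings(as.integer(seed))
  if (is.na(seed))
    abort_menisq("config field 'seed': must be an integer", "menisq_config_error")
  structure(list(spacing = spacing, labels = labels, thresholds = thresholds,
                 match = spec, seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration file
#'
#' YAML (or JSON, which YAML subsumes) with any subset of the
#' [pipeline_config()] fields; missing fields take their defaults.
#'
#' @param path Config file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("spacing", "labels", "thresholds", "calipers", "exact_vars",
             "seed", "out_dir")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    abort_menisq(paste("unknown config fields:", paste(bad, collapse = ", ")),
                 "menisq_config_error")
  if (!is.null(raw$labels)) raw$labels <- unlist(raw$labels)
  if (!is.null(raw$calipers)) raw$calipers <- unlist(raw$calipers)
  do.call(pipeline_config, raw)
}

write_provenance <- function(out_dir, config, stage, inputs = character()) {
  rec <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("menisq")),
    seed = config$seed,
    input_checksums = vapply(inputs, function(f)
      if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_,
      character(1)),
    config_hash = unname(tools::md5sum(
      local({
        tf <- tempfile()
        saveRDS(unclass(config)[c("spacing", "labels", "seed")], tf)
        tf
      }))))
  jsonlite::write_json(rec, file.path(out_dir, paste0(stage, "_provenance.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(rec)
}

#' Measure stage: mask files to measures CSV
#'
#' Computes the ten aggregate measures for each label volume. Files are
#' processed in lexicographic path order; per-file failures are recorded
#' (not raised) and reported in the returned `errors` table.
#'
#' @param mask_paths Character vector of NIfTI label-volume paths.
#' @param out_csv Output CSV path.
#' @param config A [pipeline_config()].
#' @param compartment Compartment recorded for all inputs.
#' @return List with `measures` (data.frame, one row per successful file)
#'   and `errors` (data.frame path/message).
#' @export
run_measure <- function(mask_paths, out_csv, config = pipeline_config(),
                        compartment = "medial") {
  mask_paths <- sort(mask_paths)
  rows <- list(); errs <- list()
  for (p in mask_paths) {
    res <- tryCatch({
      seg <- read_segmented_compartment(p, labels = config$labels,
                                        spacing = config$spacing,
                                        compartment = compartment)
      m <- compute_all_measures(seg)
      cbind(data.frame(path = p, compartment = compartment,
                       stringsAsFactors = FALSE),
            as.data.frame(as.list(unclass(m))))
    }, error = function(e) e)
    if (inherits(res, "error"))
      errs[[p]] <- data.frame(path = p, message = conditionMessage(res),
                              stringsAsFactors = FALSE)
    else rows[[p]] <- res
  }
  measures <- if (length(rows)) do.call(rbind, unname(rows)) else
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = 2 + length(measure_names()))),
                    c("path", "compartment", measure_names()))
  write_measures_csv(measures, out_csv)
  list(measures = measures,
       errors = if (length(errs)) do.call(rbind, unname(errs)) else
         data.frame(path = character(), message = character()))
}

#' Classification stage
#'
#' @param records data.frame or CSV path of knee records.
#' @param out_csv Optional output CSV path.
#' @param config A [pipeline_config()].
#' @return Classified records (data.frame with `class` column).
#' @export
run_classify <- function(records, out_csv = NULL, config = pipeline_config()) {
  if (is.character(records)) records <- read_cohort_csv(records)
  out <- classify_knees(records, thresholds = config$thresholds)
  if (!is.null(out_csv)) write_cohort_csv(out, out_csv)
  out
}

#' Matching stage
#'
#' Applies radiographic eligibility (KLG 2-3) to classified records, then
#' matches progressors 1:1 to non-progressors under the configured calipers.
#'
#' @param records Classified records (data.frame or CSV path with a
#'   `class` column).
#' @param out_csv Optional output CSV for the pair list.
#' @param config A [pipeline_config()].
#' @return The [match_pairs()] result.
#' @export
run_match <- function(records, out_csv = NULL, config = pipeline_config()) {
  if (is.character(records)) records <- read_cohort_csv(records)
  if (!"class" %in% names(records))
    abort_menisq("records must be classified first (no 'class' column)",
                 "menisq_config_error")
  elig <- apply_eligibility(records)
  pairs <- match_pairs(elig[elig$class == "progressor", , drop = FALSE],
                       elig[elig$class == "non_progressor", , drop = FALSE],
                       spec = config$match)
  if (!is.null(out_csv))
    utils::write.csv(pairs, out_csv, row.names = FALSE, quote = FALSE)
  pairs
}

#' Comparison stage
#'
#' @param cases,controls Paired measure tables (data.frames or CSV paths).
#' @param out_csv Optional output CSV for the comparison table.
#' @return The [comparison_table()] result.
#' @export
run_compare <- function(cases, controls, out_csv = NULL) {
  if (is.character(cases)) cases <- utils::read.csv(cases)
  if (is.character(controls)) controls <- utils::read.csv(controls)
  tab <- comparison_table(cases, controls)
  if (!is.null(out_csv))
    utils::write.csv(tab, out_csv, row.names = FALSE, quote = FALSE)
  tab
}

#' Correlation stage
#'
#' @param entire,central5,central1 Aligned measure tables (data.frames or
#'   CSV paths).
#' @param out_csv Optional output CSV.
#' @return The [correlation_table()] result.
#' @export
run_correlate <- function(entire, central5, central1, out_csv = NULL) {
  if (is.character(entire)) entire <- utils::read.csv(entire)
  if (is.character(central5)) central5 <- utils::read.csv(central5)
  if (is.character(central1)) central1 <- utils::read.csv(central1)
  tab <- correlation_table(entire, central5, central1)
  if (!is.null(out_csv))
    utils::write.csv(tab, out_csv, row.names = FALSE, quote = FALSE)
  tab
}

#' Simulation stage
#'
#' Simulates a matched cohort and writes `records.csv`, `measures.csv`,
#' `central5.csv`, `central1.csv` and a provenance record into
#' `config$out_dir`.
#'
#' @param n_pairs Number of matched pairs.
#' @param config A [pipeline_config()]; supplies seed and output directory.
#' @return The `meniscus_cohort`, invisibly.
#' @export
run_simulate <- function(n_pairs = 37L, config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(n_pairs = n_pairs, seed = config$seed)
  write_cohort_csv(cohort$records, file.path(config$out_dir, "records.csv"))
  write_measures_csv(cohort$measures, file.path(config$out_dir, "measures.csv"))
  write_measures_csv(cohort$central5, file.path(config$out_dir, "central5.csv"))
  write_measures_csv(cohort$central1, file.path(config$out_dir, "central1.csv"))
  write_provenance(config$out_dir, config, "simulate")
  invisible(cohort)
}
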