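#' Default cohort simulation parameters
#'
#' Group-level parameters (mean, SD per measure and group) used by
#' [simulate_cohort()]. The defaults are the published summary statistics
#' of the matched 37-pair progressor / non-progressor sample:
#' baseline covariates, per-grade Kellgren-Lawrence and joint-space-
#' narrowing frequencies, baseline and 12-month-change cartilage thickness
#' and minimum joint space width, medial and lateral meniscus measures, and
#' the entire-versus-central-slice correlations. Everything is overridable.
#'
#' Only the printed moments and correlations are constrained; unprinted
#' cross-measure correlations default to zero, and the correlation between
#' medial cartilage-thickness change and minJSW change defaults to 0.6
#' (both track medial structural loss, so a moderate positive correlation
#' is the realistic choice).
#'
#' @return Nested list of parameters.
#' @export
cohort_sim_defaults <- function() {
  list(
    covariates = list(
      # mean, sd per group (cases = progressors, controls = non-progressors)
      age_years  = list(cases = c(64.7, 8.0), controls = c(64.6, 9.8)),
      height_cm  = list(cases = c(165.6, 7.9), controls = c(165.6, 7.7)),
      bmi_kg_m2  = list(cases = c(30.2, 4.6), controls = c(30.2, 4.4)),
      womac_pain = list(cases = c(3.5, 3.8), controls = c(2.8, 3.3)),
      sex_male_n = c(13L, 37L),          # 13 of 37 pairs male
      klg_n      = c(klg2 = 21L, klg3 = 16L),
      med_jsn_n  = list(cases = c(7L, 17L, 13L, 0L),   # grades 0..3
                        controls = c(14L, 11L, 12L, 0L)),
      lat_jsn_n  = list(cases = c(32L, 2L, 3L, 0L),
                        controls = c(28L, 4L, 5L, 0L))),
    longitudinal = list(
      baseline = list(  # mm
        minjsw = list(cases = c(3.9, 1.4), controls = c(3.8, 1.3)),
        mftc   = list(cases = c(3.2, 0.6), controls = c(3.3, 0.6)),
        lftc   = list(cases = c(3.8, 0.5), controls = c(3.6, 0.5))),
      change_um = list( # baseline -> year 1, micrometres
        minjsw = list(cases = c(-1052, 788), controls = c(88, 259)),
        mftc   = list(cases = c(-254, 165), controls = c(21, 78)),
        lftc   = list(cases = c(-39, 144), controls = c(19, 59))),
      change_mftc_minjsw_r = 0.6),
    medial = list(
      extrusion_area_pct         = list(cases = c(30.4, 13.4), controls = c(26.7, 17.3)),
      mean_extrusion_mm          = list(cases = c(2.6, 1.1),  controls = c(2.2, 1.2)),
      max_extrusion_mm           = list(cases = c(4.8, 1.3),  controls = c(4.0, 1.1)),
      mean_extrusion_central5_mm = list(cases = c(3.3, 1.4),  controls = c(2.5, 1.5)),
      mean_extrusion_central1_mm = list(cases = c(3.4, 1.5),  controls = c(2.4, 1.6)),
      coverage_pct               = list(cases = c(34.6, 12.5), controls = c(36.8, 13.5)),
      width_mean_mm              = list(cases = c(7.9, 1.7),  controls = c(8.2, 1.8)),
      height_mean_mm             = list(cases = c(2.8, 0.4),  controls = c(2.6, 0.4)),
      volume_ml                  = list(cases = c(1.9, 0.7),  controls = c(1.8, 0.7))),
    lateral = list(
      extrusion_area_pct         = list(cases = c(7.8, 7.3),  controls = c(8.6, 10.6)),
      mean_extrusion_mm          = list(cases = c(-0.3, 1.2), controls = c(-0.4, 1.2)),
      max_extrusion_mm           = list(cases = c(2.0, 1.5),  controls = c(1.8, 1.3)),
      mean_extrusion_central5_mm = list(cases = c(0.1, 1.4),  controls = c(-0.2, 1.2)),
      mean_extrusion_central1_mm = list(cases = c(0.0, 1.4),  controls = c(-0.2, 1.2)),
      coverage_pct               = list(cases = c(54.1, 8.3), controls = c(51.7, 11.6)),
      width_mean_mm              = list(cases = c(8.4, 1.1),  controls = c(8.0, 1.3)),
      height_mean_mm             = list(cases = c(2.7, 0.3),  controls = c(2.4, 0.3)),
      volume_ml                  = list(cases = c(1.8, 0.4),  controls = c(1.6, 0.5))),
    correlations = list(  # entire-vs-central (medial), published
      extrusion_entire_c5 = 0.93,
      extrusion_entire_c1 = 0.88,
      coverage_entire_c5  = 0.84,
      volume_entire_c5    = 0.85,
      height_entire_c5    = 0.73,
      width_entire_c5     = 0.90))
}

# Draw n correlated normals given means, sds and a correlation matrix.
draw_mvn <- function(n, means, sds, corr) {
  k <- length(means)
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    abort_menisq("correlation matrix is not positive semi-definite",
                 "menisq_invalid_input")
  if (all(sds == 0))
    return(matrix(rep(means, each = n), n, k))
  sigma <- diag(sds, k) %*% corr %*% diag(sds, k)
  z <- MASS::mvrnorm(n, mu = means, Sigma = sigma)
  matrix(z, n, k)
}

clip_log <- function(x, lo = -Inf, hi = Inf, counter) {
  n_clip <- sum(x < lo | x > hi)
  counter$n <- counter$n + n_clip
  counter$total <- counter$total + length(x)
  pmin(pmax(x, lo), hi)
}

# One group's meniscus measures for one compartment, with the published
# entire-vs-central correlation structure. The unobserved central5-central1
# correlation is completed as the product of the two published entire-vs-
# central correlations (a single-factor structure, always PSD).
simulate_measures_group <- function(n, par, corr, group, counter) {
  g <- function(m) par[[m]][[group]]
  r5 <- corr$extrusion_entire_c5
  r1 <- corr$extrusion_entire_c1
  Re <- matrix(c(1, r5, r1,
                 r5, 1, r5 * r1,
                 r1, r5 * r1, 1), 3, 3)
  ext <- draw_mvn(n,
                  c(g("mean_extrusion_mm")[1], g("mean_extrusion_central5_mm")[1],
                    g("mean_extrusion_central1_mm")[1]),
                  c(g("mean_extrusion_mm")[2], g("mean_extrusion_central5_mm")[2],
                    g("mean_extrusion_central1_mm")[2]),
                  Re)
  bivar <- function(meas, r) {
    R <- matrix(c(1, r, r, 1), 2, 2)
    draw_mvn(n, rep(g(meas)[1], 2), rep(g(meas)[2], 2), R)
  }
  cov2 <- bivar("coverage_pct", corr$coverage_entire_c5)
  vol2 <- bivar("volume_ml", corr$volume_entire_c5)
  hgt2 <- bivar("height_mean_mm", corr$height_entire_c5)
  wid2 <- bivar("width_mean_mm", corr$width_entire_c5)
  uni <- function(meas) stats::rnorm(n, g(meas)[1], g(meas)[2])

  height_mean <- clip_log(hgt2[, 1L], lo = 0, counter = counter)
  entire <- data.frame(
    extrusion_area_pct = clip_log(uni("extrusion_area_pct"), 0, 100, counter),
    mean_extrusion_mm = ext[, 1L],
    max_extrusion_mm = uni("max_extrusion_mm"),
    mean_extrusion_central5_mm = ext[, 2L],
    mean_extrusion_central1_mm = ext[, 3L],
    coverage_pct = clip_log(cov2[, 1L], 0, 100, counter),
    width_mean_mm = clip_log(wid2[, 1L], lo = 0, counter = counter),
    height_mean_mm = height_mean,
    # height_max is not tabulated in print; modelled as mean height plus a
    # positive peak increment so the max >= mean invariant holds.
    height_max_mm = height_mean +
      abs(stats::rnorm(n, 1.5, 0.3)),
    volume_ml = clip_log(vol2[, 1L], lo = 0, counter = counter))
  central5 <- data.frame(
    mean_extrusion_mm = ext[, 2L],
    coverage_pct = clip_log(cov2[, 2L], 0, 100, counter),
    volume_ml = clip_log(vol2[, 2L], lo = 0, counter = counter),
    height_mean_mm = clip_log(hgt2[, 2L], lo = 0, counter = counter),
    width_mean_mm = clip_log(wid2[, 2L], lo = 0, counter = counter))
  central1 <- data.frame(mean_extrusion_mm = ext[, 3L])
  list(entire = entire, central5 = central5, central1 = central1)
}

#' Simulate a matched progressor / non-progressor cohort
#'
#' Draws `n_pairs` matched case-control pairs whose group-level moments
#' follow the parameters in `params` (defaults:
#' [cohort_sim_defaults()], the published 37-pair sample): baseline
#' covariates, longitudinal cartilage-thickness and minJSW values, and
#' per-knee medial and lateral meniscus measures with the published
#' entire-versus-central-slice correlation structure.
#'
#' Pairs are matched by construction: sex and KLG are shared within a pair
#' and the control's height, BMI and WOMAC pain are the case's value plus a
#' uniform perturbation within half the matching caliper, so every
#' simulated pair satisfies the default [match_spec()]. Measures are drawn
#' from per-group normal distributions; draws outside physical bounds
#' (negative volumes or heights, percentages outside 0-100, WOMAC outside
#' 0-20) are clipped and the clipping rate is reported in attribute
#' `truncation_rate`.
#'
#' @param n_pairs Number of matched pairs.
#' @param seed Integer seed; required, so every draw is reproducible.
#' @param params Parameter list shaped like [cohort_sim_defaults()].
#' @return List of class `meniscus_cohort`: `records` (one row per knee,
#'   columns `pair_id`, `group`, covariates, longitudinal values),
#'   `measures` (per knee and compartment, ten measure columns),
#'   `central5` / `central1` (medial central-window measures aligned with
#'   the medial rows of `measures`).
#' @export
simulate_cohort <- function(n_pairs = 37L, seed, params = cohort_sim_defaults()) {
  if (missing(seed) || is.null(seed))
    abort_menisq("simulate_cohort requires an explicit seed", "menisq_invalid_input")
  n_pairs <- as.integer(n_pairs)
  stopifnot(n_pairs >= 1L)
  set.seed(as.integer(seed))
  counter <- new.env()
  counter$n <- 0L; counter$total <- 0L
  cv <- params$covariates

  draw_cov <- function(var, group, n) {
    p <- cv[[var]][[group]]
    stats::rnorm(n, p[1], p[2])
  }
  sex_pair <- ifelse(stats::runif(n_pairs) < cv$sex_male_n[1] / cv$sex_male_n[2],
                     "M", "F")
  klg_pair <- ifelse(stats::runif(n_pairs) < cv$klg_n[["klg2"]] / sum(cv$klg_n),
                     2L, 3L)
  draw_jsn <- function(freqs, n)
    sample(seq_along(freqs) - 1L, n, replace = TRUE, prob = freqs / sum(freqs))
  spec <- match_spec()
  perturb <- function(x, caliper, n)
    x + stats::runif(n, -caliper / 2, caliper / 2)

  case_height <- draw_cov("height_cm", "cases", n_pairs)
  case_bmi <- draw_cov("bmi_kg_m2", "cases", n_pairs)
  case_womac <- clip_log(draw_cov("womac_pain", "cases", n_pairs), 0, 20, counter)
  ctrl_height <- perturb(case_height, spec$calipers[["height_cm"]], n_pairs)
  ctrl_bmi <- perturb(case_bmi, spec$calipers[["bmi_kg_m2"]], n_pairs)
  ctrl_womac <- clip_log(perturb(case_womac, spec$calipers[["womac_pain"]],
                                 n_pairs), 0, 20, counter)

  lng <- params$longitudinal
  draw_longitudinal <- function(group, n) {
    b <- function(s) lng$baseline[[s]][[group]]
    ch <- function(s) lng$change_um[[s]][[group]]
    r <- lng$change_mftc_minjsw_r
    chg <- draw_mvn(n,
                    c(ch("mftc")[1], ch("minjsw")[1]),
                    c(ch("mftc")[2], ch("minjsw")[2]),
                    matrix(c(1, r, r, 1), 2, 2))
    base_mftc <- clip_log(stats::rnorm(n, b("mftc")[1], b("mftc")[2]),
                          lo = 0.1, counter = counter)
    base_lftc <- clip_log(stats::rnorm(n, b("lftc")[1], b("lftc")[2]),
                          lo = 0.1, counter = counter)
    base_jsw <- clip_log(stats::rnorm(n, b("minjsw")[1], b("minjsw")[2]),
                         lo = 0.1, counter = counter)
    chg_lftc <- stats::rnorm(n, ch("lftc")[1], ch("lftc")[2])
    data.frame(
      mftc_mm_baseline = base_mftc,
      mftc_mm_y1 = base_mftc + chg[, 1L] / 1000,
      lftc_mm_baseline = base_lftc,
      lftc_mm_y1 = base_lftc + chg_lftc / 1000,
      minjsw_mm_baseline = base_jsw,
      minjsw_mm_y1 = base_jsw + chg[, 2L] / 1000)
  }

  mk_records <- function(group, height, bmi, womac) {
    data.frame(
      knee_id = sprintf("%s%04d", if (group == "cases") "P" else "N",
                        seq_len(n_pairs)),
      pair_id = seq_len(n_pairs),
      group = if (group == "cases") "progressor" else "non_progressor",
      sex = sex_pair, klg = klg_pair,
      age_years = draw_cov("age_years", group, n_pairs),
      height_cm = height, bmi_kg_m2 = bmi, womac_pain = womac,
      med_jsn = draw_jsn(cv$med_jsn_n[[group]], n_pairs),
      lat_jsn = draw_jsn(cv$lat_jsn_n[[group]], n_pairs),
      draw_longitudinal(group, n_pairs),
      stringsAsFactors = FALSE)
  }
  rec_cases <- mk_records("cases", case_height, case_bmi, case_womac)
  rec_ctrls <- mk_records("controls", ctrl_height, ctrl_bmi, ctrl_womac)

  sim_comp <- function(comp_par, group)
    simulate_measures_group(n_pairs, comp_par, params$correlations, group, counter)
  med_cases <- sim_comp(params$medial, "cases")
  med_ctrls <- sim_comp(params$medial, "controls")
  lat_cases <- sim_comp(params$lateral, "cases")
  lat_ctrls <- sim_comp(params$lateral, "controls")

  tag <- function(df, rec, compartment)
    cbind(data.frame(knee_id = rec$knee_id, pair_id = rec$pair_id,
                     group = rec$group, compartment = compartment,
                     stringsAsFactors = FALSE), df)
  measures <- rbind(
    tag(med_cases$entire, rec_cases, "medial"),
    tag(med_ctrls$entire, rec_ctrls, "medial"),
    tag(lat_cases$entire, rec_cases, "lateral"),
    tag(lat_ctrls$entire, rec_ctrls, "lateral"))
  central5 <- rbind(tag(med_cases$central5, rec_cases, "medial"),
                    tag(med_ctrls$central5, rec_ctrls, "medial"))
  central1 <- rbind(tag(med_cases$central1, rec_cases, "medial"),
                    tag(med_ctrls$central1, rec_ctrls, "medial"))

  out <- list(records = rbind(rec_cases, rec_ctrls), measures = measures,
              central5 = central5, central1 = central1)
  attr(out, "truncation_rate") <-
    if (counter$total > 0L) counter$n / counter$total else 0
  attr(out, "seed") <- as.integer(seed)
  class(out) <- "meniscus_cohort"
  out
}

#' @export
print.meniscus_cohort <- function(x, ...) {
  cat(sprintf("<meniscus_cohort> %d pairs | truncation rate %.4f | seed %d\n",
              nrow(x$records) / 2L, attr(x, "truncation_rate"),
              attr(x, "seed")))
  invisible(x)
}

#' Split cohort measures into paired case/control tables
#'
#' Helper extracting, for one compartment, the case and control measure
#' tables aligned by `pair_id` — the shape [comparison_table()] expects.
#'
#' @param cohort A `meniscus_cohort`.
#' @param compartment `"medial"` or `"lateral"`.
#' @return List with `cases` and `controls` data.frames.
#' @export
cohort_paired_measures <- function(cohort, compartment = "medial") {
  m <- cohort$measures[cohort$measures$compartment == compartment, ]
  cases <- m[m$group == "progressor", ]
  ctrls <- m[m$group == "non_progressor", ]
  cases <- cases[order(cases$pair_id), ]
  ctrls <- ctrls[order(ctrls$pair_id), ]
  list(cases = cases, controls = ctrls)
}
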