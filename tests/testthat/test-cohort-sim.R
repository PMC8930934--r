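test_that("identical spec and seed give identical cohorts", {
  a <- simulate_cohort(n_pairs = 40, seed = 99)
  b <- simulate_cohort(n_pairs = 40, seed = 99)
  expect_identical(a$records, b$records)
  expect_identical(a$measures, b$measures)
  c2 <- simulate_cohort(n_pairs = 40, seed = 100)
  expect_false(identical(a$measures, c2$measures))
  expect_error(simulate_cohort(n_pairs = 5), class = "menisq_invalid_input")
})

test_that("degenerate zero-SD parameters reproduce the group means exactly", {
  par <- cohort_sim_defaults()
  for (comp in c("medial", "lateral"))
    for (m in names(par[[comp]]))
      for (g in c("cases", "controls"))
        par[[comp]][[m]][[g]][2] <- 0
  co <- simulate_cohort(n_pairs = 6, seed = 3, params = par)
  med_cases <- co$measures[co$measures$compartment == "medial" &
                           co$measures$group == "progressor", ]
  for (m in names(par$medial))
    expect_equal(med_cases[[m]], rep(par$medial[[m]]$cases[1], 6))
})

test_that("simulated group moments converge to the published parameters", {
  co <- simulate_cohort(n_pairs = 5000, seed = 12)
  chg <- (co$records$mftc_mm_y1 - co$records$mftc_mm_baseline) * 1000
  prog <- co$records$group == "progressor"
  # SE = 165 / sqrt(5000) ~ 2.3 um; 5 um is > 2 SE
  expect_lt(abs(mean(chg[prog]) - (-254)), 5)
  expect_lt(abs(sd(chg[prog]) - 165), 5)
  expect_lt(abs(mean(chg[!prog]) - 21), 3)

  med <- cohort_paired_measures(co, "medial")
  expect_lt(abs(mean(med$cases$max_extrusion_mm) - 4.8), 0.05)
  expect_lt(abs(sd(med$cases$max_extrusion_mm) - 1.3), 0.05)
  expect_lt(abs(mean(med$controls$coverage_pct) - 36.8), 0.6)

  # entire-vs-central correlation structure
  ct <- correlation_table(med$cases, co$central5[co$central5$group ==
                            "progressor", ], co$central1[co$central1$group ==
                            "progressor", ])
  expect_lt(abs(ct$r[1] - 0.93), 0.02)
  expect_lt(abs(ct$r[2] - 0.88), 0.02)
  expect_lt(abs(ct$r[6] - 0.90), 0.02)
})

test_that("simulated pairs satisfy the matching calipers by construction", {
  co <- simulate_cohort(n_pairs = 300, seed = 8)
  r <- co$records
  cases <- r[r$group == "progressor", ][order(r$pair_id[r$group == "progressor"]), ]
  ctrls <- r[r$group == "non_progressor", ][order(r$pair_id[r$group == "non_progressor"]), ]
  expect_identical(cases$sex, ctrls$sex)
  expect_identical(cases$klg, ctrls$klg)
  expect_true(all(abs(cases$height_cm - ctrls$height_cm) <= 3))
  expect_true(all(abs(cases$bmi_kg_m2 - ctrls$bmi_kg_m2) <= 5))
  expect_true(all(abs(cases$womac_pain - ctrls$womac_pain) <= 5))
  expect_true(all(r$womac_pain >= 0 & r$womac_pain <= 20))
  expect_true(all(r$klg %in% 2:3))
})

test_that("progressor-parameter draws classify at the bivariate-normal rate", {
  co <- simulate_cohort(n_pairs = 4000, seed = 17)
  prog <- co$records[co$records$group == "progressor", ]
  cls <- classify_knees(prog)$class
  rate <- mean(cls == "progressor")
  par <- cohort_sim_defaults()$longitudinal
  # losses exceed thresholds jointly: correlated normal tails
  a <- (102 - 254) / 165    # standardized MFTC-loss threshold
  b <- (328 - 1052) / 788
  expected <- phi2_upper(a, b, par$change_mftc_minjsw_r)
  expect_lt(abs(rate - expected), 3 * sqrt(expected * (1 - expected) / 4000) + 0.01)
})

test_that("non-PSD correlation requests are rejected", {
  par <- cohort_sim_defaults()
  par$correlations$extrusion_entire_c5 <- 0.99
  par$correlations$extrusion_entire_c1 <- -0.99
  # completion r(c5,c1) = -0.9801 with r(e,c5)=0.99, r(e,c1)=-0.99 stays PSD,
  # so force an impossible triple via direct draw
  expect_error(menisq:::draw_mvn(10, c(0, 0, 0), c(1, 1, 1),
                                 matrix(c(1, 0.9, -0.9,
                                          0.9, 1, 0.9,
                                          -0.9, 0.9, 1), 3, 3)),
               class = "menisq_invalid_input")
})

test_that("end-to-end: simulated funnel recovers constructed class counts", {
  set.seed(77)
  n_prog <- 14; n_non <- 25; n_ind <- 6
  mk <- function(n, mftc_loss, jsw_loss, lftc_loss, klg) data.frame(
    knee_id = sprintf("X%03d", seq_len(n)), sex = "F", klg = klg,
    height_cm = 165, bmi_kg_m2 = 30, womac_pain = 3,
    mftc_mm_baseline = 3.2, mftc_mm_y1 = 3.2 - mftc_loss / 1000,
    lftc_mm_baseline = 3.8, lftc_mm_y1 = 3.8 - lftc_loss / 1000,
    minjsw_mm_baseline = 3.9, minjsw_mm_y1 = 3.9 - jsw_loss / 1000,
    stringsAsFactors = FALSE)
  cohort <- rbind(mk(n_prog, 250, 1000, 0, 2),
                  mk(n_non, 10, 50, 10, 2),
                  mk(n_ind, 250, 100, 0, 2),
                  mk(4, 250, 1000, 0, 4))   # progressors lost to eligibility
  cohort$knee_id <- sprintf("K%03d", seq_len(nrow(cohort)))
  cls <- classify_knees(cohort)
  expect_equal(sum(cls$class == "progressor"), n_prog + 4)
  elig <- apply_eligibility(cls)
  expect_equal(sum(elig$class == "progressor"), n_prog)
  expect_equal(sum(elig$class == "indeterminate"), n_ind)
  pairs <- match_pairs(elig[elig$class == "progressor", ],
                       elig[elig$class == "non_progressor", ])
  expect_equal(nrow(pairs), n_prog)
})

test_that("comparison table recovers the generator's implied effect sizes", {
  co <- simulate_cohort(n_pairs = 5000, seed = 2024)
  par <- cohort_sim_defaults()
  # closed-form mean/SD of max(X, 0) for X ~ N(mu, s): the population
  # moments of the clipped measures
  cens0 <- function(mu, s) {
    a <- mu / s
    m1 <- mu * pnorm(a) + s * dnorm(a)
    m2 <- (mu^2 + s^2) * pnorm(a) + mu * s * dnorm(a)
    c(m1, sqrt(m2 - m1^2))
  }
  clipped <- c("extrusion_area_pct", "coverage_pct", "width_mean_mm",
               "height_mean_mm", "volume_ml")
  for (comp in c("medial", "lateral")) {
    pm <- cohort_paired_measures(co, comp)
    tab <- comparison_table(pm$cases, pm$controls)
    for (m in names(par[[comp]])) {
      pc <- par[[comp]][[m]]$cases; pn <- par[[comp]][[m]]$controls
      if (m %in% clipped) {
        pc <- cens0(pc[1], pc[2]); pn <- cens0(pn[1], pn[2])
      }
      d_true <- (pc[1] - pn[1]) / sqrt((pc[2]^2 + pn[2]^2) / 2)
      expect_lt(abs(tab$cohens_d[tab$measure == m] - d_true), 0.05,
                label = sprintf("d recovery gap for %s %s", comp, m))
    }
  }
})
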