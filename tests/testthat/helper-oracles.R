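# Independent brute-force oracles: explicit voxel/cell loops, no shared code
# with the implementation beyond the container fields.

oracle_measures <- function(seg) {
  men <- seg$meniscus; plat <- seg$plateau
  sp <- unname(seg$spacing)  # (slice, z, x)
  ny <- dim(men)[1]; nz <- dim(men)[2]; nx <- dim(men)[3]

  fp <- matrix(FALSE, ny, nx)
  for (y in seq_len(ny)) for (x in seq_len(nx))
    for (z in seq_len(nz)) if (men[y, z, x]) { fp[y, x] <- TRUE; break }

  men_slices <- integer(0); plat_slices <- integer(0)
  for (y in seq_len(ny)) {
    if (any(fp[y, ])) men_slices <- c(men_slices, y)
    if (any(plat[y, ])) plat_slices <- c(plat_slices, y)
  }
  both <- intersect(men_slices, plat_slices)

  extr <- numeric(0)
  for (y in both) {
    xm <- 0L; xp <- 0L
    for (x in seq_len(nx)) {
      if (fp[y, x]) xm <- x
      if (plat[y, x]) xp <- x
    }
    extr <- c(extr, (xm - xp) * sp[3])
  }

  ctr <- (min(men_slices) + max(men_slices)) %/% 2L
  win5 <- intersect(seq(ctr - 2L, ctr + 2L), men_slices)
  win1 <- intersect(ctr, men_slices)
  extr_in <- function(win) {
    e <- numeric(0)
    for (y in intersect(win, both)) {
      xm <- max(which(fp[y, ])); xp <- max(which(plat[y, ]))
      e <- c(e, (xm - xp) * sp[3])
    }
    e
  }

  n_fp <- 0L; n_out <- 0L; n_plat <- 0L; n_cov <- 0L
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    if (fp[y, x]) {
      n_fp <- n_fp + 1L
      if (!plat[y, x]) n_out <- n_out + 1L
    }
    if (plat[y, x]) {
      n_plat <- n_plat + 1L
      if (fp[y, x]) n_cov <- n_cov + 1L
    }
  }

  heights <- numeric(0)
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    cnt <- 0L
    for (z in seq_len(nz)) if (men[y, z, x]) cnt <- cnt + 1L
    if (cnt > 0L) heights <- c(heights, cnt * sp[2])
  }

  widths <- numeric(0)
  for (y in men_slices) {
    xs <- which(fp[y, ])
    widths <- c(widths, (max(xs) - min(xs) + 1L) * sp[3])
  }

  nvox <- 0L
  for (y in seq_len(ny)) for (z in seq_len(nz)) for (x in seq_len(nx))
    if (men[y, z, x]) nvox <- nvox + 1L

  c(extrusion_area_pct = 100 * n_out / n_fp,
    mean_extrusion_mm = mean(extr),
    max_extrusion_mm = max(extr),
    mean_extrusion_central5_mm = mean(extr_in(win5)),
    mean_extrusion_central1_mm = mean(extr_in(win1)),
    coverage_pct = 100 * n_cov / n_plat,
    width_mean_mm = mean(widths),
    height_mean_mm = mean(heights),
    height_max_mm = max(heights),
    volume_ml = nvox * sp[1] * sp[2] * sp[3] / 1000)
}

# Random compartment guaranteed valid for all ten measures: at least one
# slice with both structures and a non-empty window intersection.
random_compartment <- function(ny = 8, nz = 8, nx = 8, p_men = 0.15,
                               p_plat = 0.4, spacing = c(1.5, 0.37, 0.37)) {
  repeat {
    men <- array(runif(ny * nz * nx) < p_men, dim = c(ny, nz, nx))
    plat <- matrix(runif(ny * nx) < p_plat, ny, nx)
    ok <- tryCatch({
      seg <- segmented_compartment(men, plat, spacing = spacing)
      compute_all_measures(seg)
      seg
    }, menisq_error = function(e) NULL, error = function(e) NULL)
    if (!is.null(ok)) return(ok)
  }
}

# Exhaustive maximum-cardinality (then minimum-distance) matching by
# recursion over cases; D is the distance matrix with NA = ineligible.
oracle_best_matching <- function(D) {
  m <- nrow(D); n <- ncol(D)
  best <- list(card = -1L, dist = Inf)
  rec <- function(i, used, card, dist) {
    if (i > m) {
      if (card > best$card ||
          (card == best$card && dist < best$dist - 1e-12))
        best <<- list(card = card, dist = dist)
      return(invisible())
    }
    # upper bound prune
    if (card + (m - i + 1L) < best$card) return(invisible())
    rec(i + 1L, used, card, dist)  # leave case i unmatched
    for (j in seq_len(n)) {
      if (!used[j] && !is.na(D[i, j])) {
        used[j] <- TRUE
        rec(i + 1L, used, card + 1L, dist + D[i, j])
        used[j] <- FALSE
      }
    }
  }
  rec(1L, logical(n), 0L, 0)
  best
}

# P(Z1 > a, Z2 > b) for standard bivariate normal with correlation rho,
# by numerical integration of the conditional normal.
phi2_upper <- function(a, b, rho) {
  f <- function(x)
    dnorm(x) * pnorm((b - rho * x) / sqrt(1 - rho^2), lower.tail = FALSE)
  integrate(f, a, Inf, rel.tol = 1e-10)$value
}

# Random knee record with complete longitudinal data.
random_record <- function(n = 1) {
  data.frame(
    knee_id = sprintf("K%03d", seq_len(n)),
    sex = sample(c("M", "F"), n, TRUE),
    klg = sample(0:4, n, TRUE),
    age_years = rnorm(n, 64, 9),
    height_cm = rnorm(n, 165, 8),
    bmi_kg_m2 = rnorm(n, 30, 4.5),
    womac_pain = pmin(pmax(rnorm(n, 3, 3.5), 0), 20),
    mftc_mm_baseline = rnorm(n, 3.2, 0.6),
    mftc_mm_y1 = rnorm(n, 3.1, 0.6),
    lftc_mm_baseline = rnorm(n, 3.7, 0.5),
    lftc_mm_y1 = rnorm(n, 3.7, 0.5),
    minjsw_mm_baseline = rnorm(n, 3.8, 1.3),
    minjsw_mm_y1 = rnorm(n, 3.5, 1.3),
    stringsAsFactors = FALSE)
}
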