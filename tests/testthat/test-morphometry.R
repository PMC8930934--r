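# Small hand-built grids: men(y, z, x) voxel lists, plat(y, x) cell lists.
seg_from_voxels <- function(dims, men_voxels, plat_cells,
                            spacing = c(1.5, 0.37, 0.37)) {
  men <- array(FALSE, dim = dims)
  for (v in men_voxels) men[v[1], v[2], v[3]] <- TRUE
  plat <- matrix(FALSE, dims[1], dims[3])
  for (p in plat_cells) plat[p[1], p[2]] <- TRUE
  segmented_compartment(men, plat, spacing = spacing)
}

# Slab meniscus spanning x in [mx1, mx2] at every slice, height h voxels;
# plateau spanning x in [1, px] at every slice.
slab_seg <- function(ny, nz, nx, mx1, mx2, px, h = nz,
                     spacing = c(1.5, 0.37, 0.37)) {
  men <- array(FALSE, dim = c(ny, nz, nx))
  men[, seq_len(h), mx1:mx2] <- TRUE
  plat <- matrix(FALSE, ny, nx)
  plat[, seq_len(px)] <- TRUE
  segmented_compartment(men, plat, spacing = spacing)
}

test_that("tibial footprint is the per-column projection", {
  seg <- seg_from_voxels(c(8, 8, 8), list(c(3, 2, 5)), list(c(3, 5)))
  fp <- meniscus_tibial_footprint(seg)
  expect_equal(sum(fp), 1)
  expect_true(fp[3, 5])

  seg2 <- seg_from_voxels(c(6, 6, 6),
                          lapply(1:4, function(z) c(2, z, 4)), list(c(2, 4)))
  fp2 <- meniscus_tibial_footprint(seg2)
  expect_equal(sum(fp2), 1)  # z collapses
  expect_true(fp2[2, 4])

  empty <- array(FALSE, dim = c(3, 3, 3))
  plat <- matrix(TRUE, 3, 3)
  seg3 <- segmented_compartment(empty, plat)
  expect_error(meniscus_tibial_footprint(seg3), class = "menisq_empty_meniscus")
})

test_that("slice extrusion is the signed margin offset times x-spacing", {
  # plateau x in [1,10], meniscus x in [8,13] (offsets as 0-based [0,9]/[7,12])
  seg <- slab_seg(3, 2, 15, mx1 = 8, mx2 = 13, px = 10,
                  spacing = c(1.5, 0.37, 1.0))
  expect_equal(extrusion_distance_slice(seg, 2), 3.0)

  seg0 <- slab_seg(3, 2, 12, mx1 = 5, mx2 = 10, px = 10,
                   spacing = c(1.5, 0.37, 1.0))
  expect_equal(extrusion_distance_slice(seg0, 1), 0.0)

  # plateau [1,10], meniscus [3,8]: two cells internal at 0.37 mm
  segn <- slab_seg(3, 2, 12, mx1 = 3, mx2 = 8, px = 10,
                   spacing = c(1.5, 0.37, 0.37))
  expect_equal(extrusion_distance_slice(segn, 3), -0.74)

  # a slice lacking a structure is an error, not zero
  seg_gap <- seg_from_voxels(c(4, 2, 6), list(c(1, 1, 3)),
                             list(c(1, 4), c(2, 4)))
  expect_error(extrusion_distance_slice(seg_gap, 2),
               class = "menisq_undefined_slice")
  expect_error(extrusion_distance_slice(seg_gap, 99),
               class = "menisq_undefined_slice")
})

test_that("central window picks the documented midpoint and tie-break", {
  mk <- function(slices, ny = 30) {
    men <- array(FALSE, dim = c(ny, 2, 4))
    men[slices, 1, 2] <- TRUE
    plat <- matrix(TRUE, ny, 4)
    segmented_compartment(men, plat)
  }
  expect_equal(central_window(mk(10:20), 1), 15)
  expect_equal(central_window(mk(10:21), 1), 15)  # anterior of the two middles
  expect_equal(central_window(mk(10:20), 5), 13:17)
  # window clipped to occupied slices
  expect_equal(central_window(mk(c(10, 12, 14)), 5), c(10, 12, 14))
  expect_error(central_window(mk(10:20), 4), class = "menisq_invalid_input")
})

test_that("mean and max extrusion aggregate per-slice values", {
  mk_offsets <- function(offs, px = 10, me = 4) {
    ny <- length(offs)
    nx <- px + max(offs) + 1
    men <- array(FALSE, dim = c(ny, 2, nx))
    plat <- matrix(FALSE, ny, nx)
    for (y in seq_len(ny)) {
      plat[y, 1:px] <- TRUE
      e <- px + offs[y]
      men[y, 1:2, (e - me + 1):e] <- TRUE
    }
    segmented_compartment(men, plat, spacing = c(1.5, 0.37, 1.0))
  }
  seg <- mk_offsets(c(2, 3, 4))
  expect_equal(mean_extrusion(seg, "all"), 3.0)
  expect_equal(max_extrusion(seg), 4.0)

  segsym <- mk_offsets(c(-1, 0, 1))
  expect_equal(mean_extrusion(segsym, "all"), 0.0)

  segc <- mk_offsets(0:4)  # slices 1..5, centre 3
  expect_equal(mean_extrusion(segc, "central1"), 2.0)
  expect_equal(mean_extrusion(segc, "central5"), 2.0)

  segneg <- mk_offsets(c(-1, -1, -1))
  expect_equal(max_extrusion(segneg), -1.0)
})

test_that("coverage and extrusion area are cell-count ratios", {
  # plateau 10x10 = 100 cells; meniscus footprint covers 37 of them
  men <- array(FALSE, dim = c(10, 1, 12))
  men[1:3, 1, 1:10] <- TRUE   # 30 covered cells
  men[4, 1, 1:7] <- TRUE      # 7 more
  plat <- matrix(FALSE, 10, 12)
  plat[, 1:10] <- TRUE
  seg <- segmented_compartment(men, plat)
  expect_equal(coverage_pct(seg), 37.0)

  sup <- slab_seg(4, 2, 8, mx1 = 1, mx2 = 8, px = 5)  # footprint covers plateau
  expect_equal(coverage_pct(sup), 100.0)
  expect_equal(extrusion_area_pct(slab_seg(4, 2, 8, 1, 5, 5)), 0.0)

  disj <- slab_seg(4, 2, 12, mx1 = 8, mx2 = 12, px = 5)
  expect_equal(coverage_pct(disj), 0.0)
  expect_equal(extrusion_area_pct(disj), 100.0)

  # 50-cell footprint with 10 outside the plateau
  men2 <- array(FALSE, dim = c(5, 1, 12))
  men2[1:5, 1, 3:12] <- TRUE          # 50 cells, x in [3,12]
  plat2 <- matrix(FALSE, 5, 12)
  plat2[, 1:10] <- TRUE               # x > 10: 2 cells per slice outside
  seg2 <- segmented_compartment(men2, plat2)
  expect_equal(extrusion_area_pct(seg2), 20.0)
})

test_that("height, width and volume follow the voxel geometry", {
  slab <- slab_seg(3, 6, 10, mx1 = 2, mx2 = 5, px = 8, h = 6)
  hs <- height_stats(slab)
  expect_equal(unname(hs["height_mean_mm"]), 2.22)
  expect_equal(unname(hs["height_max_mm"]), 2.22)

  two <- seg_from_voxels(c(2, 4, 4),
                         c(lapply(1:2, function(z) c(1, z, 2)),
                           lapply(1:4, function(z) c(1, z, 3))),
                         list(c(1, 1)), spacing = c(1.5, 0.5, 0.37))
  hs2 <- height_stats(two)
  expect_equal(unname(hs2["height_mean_mm"]), 1.5)
  expect_equal(unname(hs2["height_max_mm"]), 2.0)

  wseg <- slab_seg(4, 2, 16, mx1 = 5, mx2 = 14, px = 10)
  expect_equal(width_mean(wseg), 3.7)

  # slices spanning 10 and 20 cells at 1 mm spacing
  men <- array(FALSE, dim = c(2, 1, 25))
  men[1, 1, 1:10] <- TRUE
  men[2, 1, 1:20] <- TRUE
  plat <- matrix(TRUE, 2, 25)
  expect_equal(width_mean(segmented_compartment(men, plat,
                                                spacing = c(1, 1, 1))), 15.0)

  expect_equal(volume_ml(segmented_compartment(array(FALSE, c(2, 2, 2)),
                                               matrix(TRUE, 2, 2))), 0.0)
  v <- slab_seg(10, 10, 10, 1, 10, 10, h = 10)  # 1000 voxels at DESS spacing
  expect_equal(volume_ml(v), 1000 * 1.5 * 0.37 * 0.37 / 1000)
  cube <- segmented_compartment(array(TRUE, c(20, 20, 20)),
                                matrix(TRUE, 20, 20), spacing = c(1, 1, 1))
  expect_equal(volume_ml(cube), 8.0)
})

test_that("every measure matches brute-force enumeration on random masks", {
  set.seed(42)
  for (i in 1:30) {
    seg <- random_compartment(ny = sample(4:10, 1), nz = sample(3:8, 1),
                              nx = sample(4:12, 1))
    expect_equal(unclass(compute_all_measures(seg)), oracle_measures(seg),
                 tolerance = 1e-12)
  }
})

test_that("measures are equivariant under joint and meniscus-only shifts", {
  set.seed(101)
  shift_men <- function(seg, k) {
    d <- dim(seg$meniscus)
    men <- array(FALSE, dim = d + c(0, 0, k))
    men[, , seq_len(d[3]) + k] <- seg$meniscus
    plat <- cbind(seg$plateau, matrix(FALSE, d[1], k))
    segmented_compartment(men, plat, spacing = seg$spacing)
  }
  shift_both <- function(seg, k) {
    d <- dim(seg$meniscus)
    men <- array(FALSE, dim = d + c(0, 0, k))
    men[, , seq_len(d[3]) + k] <- seg$meniscus
    plat <- matrix(FALSE, d[1], d[3] + k)
    plat[, seq_len(d[3]) + k] <- seg$plateau
    segmented_compartment(men, plat, spacing = seg$spacing)
  }
  for (i in 1:10) {
    seg <- random_compartment()
    k <- sample(1:3, 1)
    m0 <- compute_all_measures(seg)
    mb <- compute_all_measures(shift_both(seg, k))
    expect_equal(unclass(mb), unclass(m0), tolerance = 1e-12)

    mm <- compute_all_measures(shift_men(seg, k))
    dx <- k * unname(seg$spacing["x"])
    for (f in c("mean_extrusion_mm", "max_extrusion_mm",
                "mean_extrusion_central5_mm", "mean_extrusion_central1_mm"))
      expect_equal(mm[[f]], m0[[f]] + dx, tolerance = 1e-12)
    expect_gte(mm[["extrusion_area_pct"]], m0[["extrusion_area_pct"]] - 1e-12)
    # shape-only measures unchanged
    for (f in c("width_mean_mm", "height_mean_mm", "height_max_mm", "volume_ml"))
      expect_equal(mm[[f]], m0[[f]], tolerance = 1e-12)
  }
})

test_that("aggregate orderings hold on random masks", {
  set.seed(7)
  for (i in 1:15) {
    seg <- random_compartment()
    m <- compute_all_measures(seg)
    ex <- vapply(intersect(menisq:::meniscus_slices(seg),
                           menisq:::plateau_slices(seg)),
                 function(y) extrusion_distance_slice(seg, y), numeric(1))
    expect_gte(m[["max_extrusion_mm"]], m[["mean_extrusion_mm"]])
    expect_gte(m[["mean_extrusion_mm"]], min(ex))
    expect_gte(m[["height_max_mm"]], m[["height_mean_mm"]])
    uncovered <- 100 * sum(seg$plateau &
                           !meniscus_tibial_footprint(seg)) / sum(seg$plateau)
    expect_equal(m[["coverage_pct"]] + uncovered, 100, tolerance = 1e-12)
  }
})
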