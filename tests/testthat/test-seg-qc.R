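test_that("QC mask of a ball contains the ball grown by the net margin", {
  dims <- c(70, 70, 70); sp <- c(2, 2, 2)
  heart <- make_ball(dims, c(35, 35, 35), 40, sp)
  qm <- build_qc_mask(heart, sp, qc_params(15, 35, 1))
  expect_false(attr(qm, "eroded_empty"))
  expect_true(all(qm[heart]))                       # original fully inside
  inner <- make_ball(dims, c(35, 35, 35), 58, sp)   # 60 mm minus one voxel
  expect_true(all(qm[inner]))
  outer_ <- make_ball(dims, c(35, 35, 35), 62, sp)
  expect_true(all(!qm[!outer_]))                    # and not much beyond
})

test_that("largest-component step discards the smaller of two distant balls", {
  dims <- c(80, 40, 40); sp <- c(2, 2, 2)
  big <- make_ball(dims, c(20, 20, 20), 30, sp)
  small <- make_ball(dims, c(60, 20, 20), 20, sp)   # 80 mm apart
  heart <- big | small
  qm <- build_qc_mask(heart, sp, qc_params(15, 35, 1))
  # remnant of the small ball (radius 5 mm) is dropped, so the QC mask is
  # the big remnant grown 35 mm: it cannot reach the far side of the small
  # ball (center 80 mm away from the big center, remnant radius 15 mm)
  far_point <- c(69, 10, 10)                        # (138, 20, 20) mm
  expect_false(qm[far_point[1], far_point[2], far_point[3]])
  near_point <- c(24, 10, 10)                       # inside big + 35 mm
  expect_true(qm[near_point[1], near_point[2], near_point[3]])
  rep_ <- qc_check(heart, heart, sp, qc_params(15, 35, 1))
  expect_true(rep_$flagged)                          # small ball is outside
  expect_gt(rep_$outside_volume_ml, 1)
})

test_that("a heart that vanishes under erosion is flagged as degenerate", {
  sv <- array(FALSE, c(16, 16, 16)); sv[8, 8, 8] <- TRUE
  qm <- build_qc_mask(sv, c(1, 1, 1), qc_params(15, 35, 0))
  expect_true(attr(qm, "eroded_empty"))
  expect_false(any(qm))
  rep_ <- qc_check(sv, sv, c(1, 1, 1))
  expect_true(rep_$flagged)
  expect_true(rep_$eroded_empty)
  expect_error(build_qc_mask(array(FALSE, c(4, 4, 4)), c(1, 1, 1)), "empty")
})

test_that("erode-then-dilate containment holds for convex but not all shapes", {
  sp <- c(1.5, 1.5, 1.5); e <- 6
  ball <- make_ball(c(24, 24, 24), c(12, 12, 12), 12, sp)
  # a one-voxel dilation margin absorbs boundary discretisation
  opened <- dilate_mm(erode_mm(ball, sp, e), sp, e + 1.5)
  expect_identical(opened,
                   brute_dilate(brute_erode(ball, sp, e), sp, e + 1.5))
  expect_true(all(opened[ball]))
  # dumbbell: two balls joined by a thin bridge; the bridge and the smaller
  # lobe do not survive opening
  dumb <- make_ball(c(40, 16, 16), c(10, 8, 8), 9, sp) |
    make_ball(c(40, 16, 16), c(32, 8, 8), 5, sp)
  dumb[14:28, 8, 8] <- TRUE
  opened2 <- dilate_mm(erode_mm(dumb, sp, e), sp, e)
  expect_identical(opened2, brute_dilate(brute_erode(dumb, sp, e), sp, e))
  expect_false(all(opened2[dumb]))
})

test_that("a convex heart checked against itself never flags", {
  sp <- c(1, 1, 2)
  for (r in c(25, 35)) {
    ball <- make_ball(c(64, 64, 32), c(32, 32, 16), r, sp)
    rep_ <- qc_check(ball, ball, sp, qc_params(15, 35, 0))
    expect_identical(rep_$outside_volume_ml, 0)
    expect_false(rep_$flagged)
  }
  ell <- generate_cardiac_phantom(small_cardiac(radii = c(22, 20, 18)), 0,
                                  seed = 1)
  rep2 <- qc_check(ell$truth$pericardium_mask, ell$truth$pericardium_mask,
                   ell$volume$spacing, qc_params(15, 35, 0))
  expect_identical(rep2$outside_volume_ml, 0)
})

test_that("outside volume is monotone in the morphological radii", {
  sh <- small_cardiac(radii = c(22, 20, 18))
  ph <- generate_cardiac_phantom(sh, 0, seed = 4)
  heart <- ph$truth$pericardium_mask
  sp <- ph$volume$spacing
  bad <- inject_segmentation_failure(heart,
    failure_spec("add_blob", 1.5, offset_mm = 6), sp)
  out_d <- sapply(c(16, 25, 35), function(d)
    qc_check(bad, heart, sp, qc_params(14, d, 1))$outside_volume_ml)
  expect_gt(out_d[1], 0)
  expect_true(all(diff(out_d) <= 1e-12))
  out_e <- sapply(c(5, 10, 14), function(e)
    qc_check(bad, heart, sp, qc_params(e, 20, 1))$outside_volume_ml)
  expect_true(all(diff(out_e) >= -1e-12))
})

test_that("well-separated multi-ml blobs are flagged and intact phantoms are not", {
  sh <- cardiac_shape_params(grid_dim = c(96L, 96L, 128L),
                             spacing = c(1.5, 1.5, 1.5),
                             outer_radii_mm = c(30, 27, 25),
                             chest_wall_mm = 6)
  params <- qc_params(15, 35, 1)
  for (i in 1:4) {
    ph <- generate_cardiac_phantom(sh, noise_sd_hu = 10, seed = 100 + i)
    heart <- ph$truth$pericardium_mask
    sp <- ph$volume$spacing
    bad <- inject_segmentation_failure(heart,
      failure_spec("add_blob", 4 + i, offset_mm = 50 + 2 * i), sp)
    expect_true(qc_check(bad, heart, sp, params)$flagged)
    expect_false(qc_check(heart, heart, sp, params)$flagged)
  }
})
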