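test_that("cardiac phantom is bit-reproducible per seed", {
  sh <- small_cardiac()
  a <- generate_cardiac_phantom(sh, noise_sd_hu = 12, seed = 5)
  b <- generate_cardiac_phantom(sh, noise_sd_hu = 12, seed = 5)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth, b$truth)
  c_ <- generate_cardiac_phantom(sh, noise_sd_hu = 12, seed = 6)
  expect_false(identical(a$volume$data, c_$volume$data))
})

test_that("phantom truth is conserved under brute-force voxel recount", {
  sh <- small_cardiac()
  ph <- generate_cardiac_phantom(sh, noise_sd_hu = 8, seed = 3)
  fat <- ph$truth$pericardium_mask & !ph$truth$chamber_mask
  expect_identical(fat, ph$truth$fat_mask)
  expect_identical(ph$truth$true_eatv_ml,
                   sum(fat) * prod(ph$volume$spacing) / 1000)
  expect_true(all(ph$truth$pericardium_mask[ph$truth$chamber_mask]))
})

test_that("noiseless phantom attenuation equals the painted fat value", {
  ph <- generate_cardiac_phantom(small_cardiac(), noise_sd_hu = 0, seed = 1,
                                 fat_center_hu = -70)
  expect_identical(ph$truth$true_eata_hu, -70)
  q <- quantify_eat(ph$volume, ph$truth$pericardium_mask,
                    ph$truth$chamber_mask)
  expect_identical(q$median_hu, -70)
  expect_identical(q$volume_ml, ph$truth$true_eatv_ml)
})

test_that("discretised shell volume approaches the analytic ellipsoid shell", {
  radii <- c(18, 16, 15); scale <- 0.85
  analytic <- ellipsoid_shell_ml(radii, radii * scale)
  errs <- sapply(c(2, 1, 0.5), function(h) {
    n <- ceiling(48 / h)
    sh <- cardiac_shape_params(grid_dim = rep(n, 3), spacing = rep(h, 3),
                               outer_radii_mm = radii, inner_scale = scale,
                               chest_wall_mm = 0)
    ph <- generate_cardiac_phantom(sh, noise_sd_hu = 0, seed = 1)
    abs(ph$truth$true_eatv_ml - analytic)
  })
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3] / analytic, 0.01)
})

test_that("impossible geometry is rejected", {
  expect_error(cardiac_shape_params(grid_dim = c(32, 32, 32),
                                    outer_radii_mm = c(40, 40, 40)),
               "invalid geometry")
  expect_error(abdominal_shape_params(grid_dim = c(64, 64), r_vat_mm = 30,
                                      wall_mm = c(30, 34), r_sat_mm = 40),
               "invalid geometry")
})

test_that("add_blob changes mask volume by the requested amount", {
  sh <- small_cardiac()
  ph <- generate_cardiac_phantom(sh, noise_sd_hu = 0, seed = 2)
  heart <- ph$truth$pericardium_mask
  sp <- ph$volume$spacing
  voxvol_ml <- prod(sp) / 1000
  for (mag in c(1, 5)) {
    bad <- inject_segmentation_failure(heart,
      failure_spec("add_blob", mag, offset_mm = 8), sp)
    delta <- compute_volume_ml(bad, sp) - compute_volume_ml(heart, sp)
    expect_lte(abs(delta - mag), voxvol_ml)
    expect_true(all(bad[heart]))         # union: original untouched
  }
  # zero offset still yields a valid corruption
  touching <- inject_segmentation_failure(heart,
    failure_spec("add_blob", 0.5, offset_mm = 0), sp)
  expect_gt(sum(touching), sum(heart))
})

test_that("delete_wedge removes the requested volume and refuses to overdraw", {
  sh <- small_cardiac()
  ph <- generate_cardiac_phantom(sh, noise_sd_hu = 0, seed = 2)
  heart <- ph$truth$pericardium_mask
  sp <- ph$volume$spacing
  carved <- inject_segmentation_failure(heart,
    failure_spec("delete_wedge", 3), sp)
  expect_lte(abs((compute_volume_ml(heart, sp) -
                    compute_volume_ml(carved, sp)) - 3), prod(sp) / 1000)
  expect_true(all(heart[carved]))        # subset of the original
  total <- compute_volume_ml(heart, sp)
  expect_error(inject_segmentation_failure(heart,
    failure_spec("delete_wedge", total + 1), sp), "cannot delete")
})

test_that("blob that cannot fit in the grid is a placement error", {
  m <- array(FALSE, c(12, 12, 12)); m[5:8, 5:8, 5:8] <- TRUE
  expect_error(inject_segmentation_failure(m,
    failure_spec("add_blob", 5, offset_mm = 50), c(1, 1, 1)),
    "placement error")
})

test_that("abdominal phantom truth areas equal pixel-count arithmetic", {
  ph <- generate_abdominal_phantom(seed = 9)
  tr <- ph$truth
  px <- prod(ph$slice$spacing) / 100
  expect_identical(tr$true_vat_cm2, sum(tr$vat_mask) * px)
  expect_identical(tr$true_sat_cm2, sum(tr$sat_mask) * px)
  expect_false(any(tr$fat_mask & tr$lean_wall_mask))
  # zero-width SAT annulus
  sh0 <- abdominal_shape_params(r_vat_mm = 40, wall_mm = c(40, 46),
                                r_sat_mm = 46)
  ph0 <- generate_abdominal_phantom(sh0, seed = 1)
  expect_identical(ph0$truth$true_sat_cm2, 0)
  # determinism
  expect_identical(generate_abdominal_phantom(seed = 4)$slice$data,
                   generate_abdominal_phantom(seed = 4)$slice$data)
})

test_that("open lean wall with enclosed visceral fat is rejected", {
  expect_error(abdominal_shape_params(wall_gap_deg = 30),
               "open lean wall")
  # an open wall with no VAT disc is legitimate
  sh <- abdominal_shape_params(r_vat_mm = 0, wall_mm = c(40, 46),
                               r_sat_mm = 60, wall_gap_deg = 30)
  ph <- generate_abdominal_phantom(sh, seed = 1)
  expect_identical(ph$truth$true_vat_cm2, 0)
})
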