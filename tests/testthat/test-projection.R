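test_that("MIP matches its definition on simple volumes", {
  vol <- ct_volume(array(0, c(5, 4, 6)))
  expect_true(all(project_mip(vol, "anterior_posterior")$values == 0))

  arr <- array(-1000, c(5, 4, 6))
  arr[2, 3, 4] <- 3000
  vol <- ct_volume(arr)
  img <- project_mip(vol, "anterior_posterior")
  expect_equal(dim(img$values), c(6, 5))      # rows z, cols x
  expect_equal(sum(img$values == 3000), 1)
  expect_equal(sum(img$values == -1000), 29)
  expect_equal(img$values[6 - 4 + 1, 2], 3000)  # head-up row flip
})

test_that("average projection is the ray mean", {
  vol <- ct_volume(array(100, c(3, 3, 3)))
  expect_true(all(project_average(vol, "lateral")$values == 100))
  arr <- array(0, c(2, 3, 2))
  arr[1, , 1] <- c(-1000, 0, 1000)
  img <- project_average(ct_volume(arr), "anterior_posterior")
  expect_equal(img$values[2, 1], 0)
})

test_that("selective minIP skips masked voxels and sentinels empty rays", {
  ph <- generate_phantom(standard_fixtures()$body_with_gas)
  mask <- ph$truth$exterior_air_mask
  img <- project_minip_selective(ph$volume, mask, "anterior_posterior")
  gas_fp <- oracle_footprint(ph$truth$interior_gas_mask, "anterior_posterior")
  expect_true(all(img$values[gas_fp] == -800))
  body_fp <- oracle_footprint(!mask, "anterior_posterior")
  expect_true(all(img$values[!body_fp] == MINIP_SENTINEL_HU))

  all_masked <- array(TRUE, dim(ph$volume$voxels))
  img2 <- project_minip_selective(ph$volume, all_masked, "anterior_posterior")
  expect_true(all(img2$values == MINIP_SENTINEL_HU))

  expect_error(
    project_minip_selective(ph$volume, array(TRUE, c(2, 2, 2)), "lateral"),
    "shape"
  )
})

test_that("all three projections match brute-force ray loops", {
  for (seed in 1:3) {
    vol <- random_hu_volume(c(9, 11, 8), seed = 100 + seed)
    set.seed(200 + seed)
    mask <- array(runif(prod(dim(vol$voxels))) < 0.4, dim(vol$voxels))
    for (view in c("anterior_posterior", "lateral")) {
      expect_identical(project_mip(vol, view)$values,
                       oracle_project(vol$voxels, view, max))
      expect_equal(project_average(vol, view)$values,
                   oracle_project(vol$voxels, view, mean), tolerance = 1e-9)
      expect_identical(project_minip_selective(vol, mask, view)$values,
                       oracle_project(vol$voxels, view, min, mask = mask))
      # empty mask reduces the selective minIP to the plain minimum
      none <- array(FALSE, dim(vol$voxels))
      expect_identical(project_minip_selective(vol, none, view)$values,
                       oracle_project(vol$voxels, view, min))
      # ray ordering: min <= mean <= max
      expect_true(all(
        oracle_project(vol$voxels, view, min) <=
          project_average(vol, view)$values + 1e-9))
      expect_true(all(
        project_average(vol, view)$values <=
          project_mip(vol, view)$values + 1e-9))
    }
  }
})

test_that("isotropic resampling preserves constants, ramps and value range", {
  const <- projection_image(matrix(7, 10, 8), c(2, 1), "lateral", "average")
  out <- resample_isotropic(const)
  expect_equal(out$pixel_spacing, c(1, 1))
  expect_equal(nrow(out$values), 19)          # double row count (+/- 1)
  expect_true(all(out$values == 7))

  iso <- projection_image(matrix(rnorm(20), 4, 5), c(1.5, 1.5),
                          "lateral", "mip")
  expect_identical(resample_isotropic(iso), iso)

  # linear ramp along the resampled axis interpolates exactly
  ramp <- projection_image(matrix(rep(seq(0, 900, by = 100), 2), 10, 2),
                           c(3, 1), "anterior_posterior", "average")
  out <- resample_isotropic(ramp)
  pos <- (seq_len(nrow(out$values)) - 1) * 1  # mm along rows
  expect_equal(out$values[, 1], pos / 3 * 100, tolerance = 1e-9)
  expect_true(min(out$values) >= 0 && max(out$values) <= 900)
})
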