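test_that("corner seeds are exactly the eight volume corners", {
  vol <- ct_volume(array(-1000, c(10, 10, 10)))
  s <- corner_seeds(vol)
  expect_equal(nrow(s), 8L)
  expect_true(all(s[, 1] %in% c(1L, 10L)))
  expect_equal(nrow(unique(s)), 8L)

  vol2 <- ct_volume(array(-1000, c(2, 2, 2)))
  expect_equal(nrow(unique(corner_seeds(vol2))), 8L)  # every voxel a corner

  vol3 <- ct_volume(array(-1000, c(5, 7, 3)))
  s3 <- corner_seeds(vol3)
  want <- as.matrix(expand.grid(i = c(1L, 5L), j = c(1L, 7L), k = c(1L, 3L),
                                KEEP.OUT.ATTRS = FALSE))
  expect_setequal(apply(s3, 1, paste, collapse = ","),
                  apply(want, 1, paste, collapse = ","))
})

test_that("region growing floods connected air and respects the -200 boundary", {
  vol <- ct_volume(array(-1000, c(6, 6, 6)))
  mask <- region_grow_exterior(vol, corner_seeds(vol))
  expect_true(all(mask))

  # a voxel at exactly -200 HU is absorbed; -199 never is
  arr <- array(-1000, c(6, 6, 6))
  arr[3, 3, 3] <- -200
  arr[4, 4, 4] <- -199
  vol <- ct_volume(arr)
  mask <- region_grow_exterior(vol, corner_seeds(vol))
  expect_true(mask[3, 3, 3])
  expect_false(mask[4, 4, 4])
  expect_false(any(vol$voxels[mask] > -200))
})

test_that("gas enclosed by the body is never flagged", {
  ph <- generate_phantom(standard_fixtures()$body_with_gas)
  mask <- region_grow_exterior(ph$volume, corner_seeds(ph$volume))
  expect_false(any(mask[ph$truth$interior_gas_mask]))
  expect_identical(mask, ph$truth$exterior_air_mask)
})

test_that("region growing matches an independent flood fill on random volumes", {
  for (seed in 1:4) {
    vol <- random_hu_volume(c(14, 12, 16), seed = seed)
    seeds <- corner_seeds(vol)
    for (conn in c("face", "face+edge+corner")) {
      cfg <- pmct_config(connectivity = conn)
      got <- region_grow_exterior(vol, seeds, cfg)
      want <- oracle_flood_fill(vol$voxels, seeds, -200, conn)
      expect_identical(got, want)
    }
  }
})

test_that("lowering the air threshold never adds flagged voxels", {
  vol <- random_hu_volume(c(12, 12, 12), seed = 9)
  seeds <- corner_seeds(vol)
  prev <- NULL
  for (thr in c(-150, -200, -300, -500)) {
    m <- region_grow_exterior(vol, seeds, pmct_config(air_threshold_hu = thr))
    if (!is.null(prev)) expect_false(any(m & !prev))  # subset of previous
    prev <- m
  }
})

test_that("seeds on tissue are skipped and an empty seed list warns", {
  vol <- ct_volume(array(40, c(4, 4, 4)))  # solid tissue, corners included
  mask <- region_grow_exterior(vol, corner_seeds(vol))
  expect_false(any(mask))
  expect_warning(
    m0 <- region_grow_exterior(vol, matrix(integer(0), ncol = 3)),
    "empty seed"
  )
  expect_false(any(m0))
  expect_error(region_grow_exterior(vol, rbind(c(9L, 1L, 1L))), "bounds")
})

test_that("table seeding finds hollow cavities, ignores solid tables and bodies", {
  fx <- standard_fixtures()
  cfg <- pmct_config()

  ph <- generate_phantom(fx$body_with_hollow_table)
  seeds <- table_seeds(ph$volume, cfg)
  expect_gt(nrow(seeds), 0)
  expect_true(all(ph$labels[seeds] == 2L))  # all seeds in the cavity

  ph_solid <- generate_phantom(fx$body_with_solid_table)
  expect_equal(nrow(table_seeds(ph_solid$volume, cfg)), 0L)

  ph_none <- generate_phantom(fx$body_with_gas)
  expect_equal(nrow(table_seeds(ph_none$volume, cfg)), 0L)

  cfg_off <- pmct_config(table_seeds_enabled = FALSE)
  expect_equal(nrow(table_seeds(ph$volume, cfg_off)), 0L)
})

test_that("adding table seeds only grows the exterior mask, to the full truth", {
  ph <- generate_phantom(standard_fixtures()$body_with_hollow_table)
  cfg <- pmct_config()
  m_corner <- region_grow_exterior(ph$volume, corner_seeds(ph$volume), cfg)
  ts <- table_seeds(ph$volume, cfg, exterior = m_corner)
  m_both <- m_corner | region_grow_exterior(ph$volume, ts, cfg)
  expect_false(any(m_corner & !m_both))            # superset
  expect_gt(sum(m_both), sum(m_corner))            # cavity added
  expect_identical(m_both, ph$truth$exterior_air_mask)
  # the cavity is unreachable from the corners alone
  expect_false(any(m_corner[ph$labels == 2L]))
})
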