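test_that("an empty spec yields uniform background fully exterior", {
  ph <- generate_phantom(phantom_spec(c(8, 9, 4)))
  expect_true(all(ph$volume$voxels == -1000))
  expect_true(all(ph$truth$exterior_air_mask))
  expect_false(any(ph$truth$interior_gas_mask))
})

test_that("phantom generation is deterministic under a fixed seed", {
  spec <- standard_fixtures()$body_with_gas
  spec$noise_sd <- 15
  spec$rng_seed <- 77L
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$voxels, b$volume$voxels)
  spec$rng_seed <- 78L
  c <- generate_phantom(spec)
  expect_false(identical(a$volume$voxels, c$volume$voxels))
})

test_that("noise is bounded away from every decision threshold", {
  spec <- standard_fixtures()$body_with_gas
  spec$noise_sd <- 15
  ph <- generate_phantom(spec)
  clean <- generate_phantom(standard_fixtures()$body_with_gas)
  expect_true(all(abs(ph$volume$voxels - clean$volume$voxels) <= 45 + 1e-9))
  # the noisy phantom still segments to the exact ground truth
  mask <- region_grow_exterior(ph$volume, corner_seeds(ph$volume))
  expect_identical(mask, ph$truth$exterior_air_mask)
  # sd so large that tissue could cross the air threshold is rejected
  spec$noise_sd <- 100
  expect_error(generate_phantom(spec), "noise_sd")
})

test_that("spec violations are rejected with the constraint named", {
  expect_error(phantom_spec(c(30, 30, 1)), "at least 2")
  expect_error(
    phantom_spec(c(30, 30, 10),
                 body = list(center = c(15, 15, 5), radii = c(20, 5, 3),
                             hu = 40)),
    "outside the volume bounds"
  )
  body <- list(center = c(15, 15, 8), radii = c(10, 10, 6), hu = 40)
  expect_error(
    phantom_spec(c(30, 30, 16), body = body,
                 gas_pockets = list(list(center = c(24, 15, 8), radius = 2,
                                         hu = -800))),
    "strictly inside"
  )
  expect_error(
    phantom_spec(c(30, 30, 16),
                 gas_pockets = list(list(center = c(15, 15, 8), radius = 2,
                                         hu = -800))),
    "require a body"
  )
})

test_that("standard fixtures are valid and their masks disjoint", {
  fx <- standard_fixtures()
  expect_true(all(c("body_only", "body_with_gas", "body_with_metal",
                    "body_with_hollow_table", "open_airway") %in% names(fx)))
  for (name in names(fx)) {
    spec <- fx[[name]]
    expect_s3_class(spec, "phantom_spec")
    expect_true(all(spec$shape <= 64L))
    ph <- generate_phantom(spec)
    t <- ph$truth
    expect_false(any(t$exterior_air_mask & t$interior_gas_mask))
    expect_false(any(t$exterior_air_mask & t$metal_mask))
    expect_false(any(t$interior_gas_mask & t$metal_mask))
  }
})

test_that("the hollow table cavity is watertight and corner-unreachable", {
  ph <- generate_phantom(standard_fixtures()$body_with_hollow_table)
  cavity <- ph$labels == 2L
  expect_gt(sum(cavity), 0)
  m <- oracle_flood_fill(ph$volume$voxels, corner_seeds(ph$volume), -200)
  expect_false(any(m[cavity]))
})

test_that("the open airway connects interior gas to the outside", {
  ph <- generate_phantom(standard_fixtures()$open_airway)
  m <- oracle_flood_fill(ph$volume$voxels, corner_seeds(ph$volume), -200)
  expect_true(all(m[ph$truth$interior_gas_mask]))
})
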