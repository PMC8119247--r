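make_proj <- function(values, kind, view = "anterior_posterior")
  projection_image(values, c(1, 1), view, kind)

test_that("windowing is a clamped linear ramp with half-up rounding", {
  expect_equal(apply_window(c(0, 500, 1000)), c(0L, 128L, 255L))
  expect_equal(apply_window(c(-500, 2000)), c(0L, 255L))
  # agreement with scalar arithmetic across the ramp
  hu <- seq(-100, 1100, by = 7)
  expect_equal(apply_window(hu), as.integer(oracle_window(hu)))
  # monotone non-decreasing
  expect_true(all(diff(apply_window(seq(-300, 1300))) >= 0))
  expect_error(apply_window(0, width_hu = 0), "width")
})

test_that("composite applies the three rules in order", {
  cfg <- pmct_config()
  m <- matrix(c(2801, 3000, 2800, 1000), 2, 2)
  n <- matrix(c(0, -221, -220, 0), 2, 2)
  a <- matrix(0, 2, 2)
  ov <- composite_overview(make_proj(m, "mip"), make_proj(n, "minip"),
                           make_proj(a, "average"), cfg)
  px <- ov$pixels
  expect_equal(px[1, 1, ], c(255L, 0L, 0L))   # MIP 2801 -> red
  expect_equal(px[2, 1, ], c(0L, 0L, 255L))   # blue beats red on conflict
  # thresholds themselves never fire (strict inequalities)
  expect_true(is_gray(px)[1, 2])
  # gray level of blend 0.7*1000 + 0.3*0 = 700 HU, windowed independently
  expect_equal(px[2, 2, 1], as.integer(oracle_window(0.7 * 1000 + 0.3 * 0)))
  expect_equal(px[2, 2, 1], 179L)
})

test_that("red and blue pixel sets follow the threshold set algebra", {
  cfg <- pmct_config()
  for (seed in 1:3) {
    set.seed(300 + seed)
    m <- matrix(runif(120, -1000, 3500), 10, 12)
    n <- matrix(runif(120, -1000, 3071), 10, 12)
    a <- matrix(runif(120, -1000, 1500), 10, 12)
    ov <- composite_overview(make_proj(m, "mip"), make_proj(n, "minip"),
                             make_proj(a, "average"), cfg)
    px <- ov$pixels
    blue_want <- n < cfg$blue_threshold_hu
    red_want <- (m > cfg$red_threshold_hu) & !blue_want
    expect_identical(unname(is_pure_blue(px)), blue_want)
    expect_identical(unname(is_pure_red(px)), red_want)
    # exactly three pixel classes
    expect_true(all(is_gray(px) | is_pure_red(px) | is_pure_blue(px)))
  }
})

test_that("gray levels are monotone in MIP and average values", {
  cfg <- pmct_config()
  n <- matrix(0, 1, 1)
  lvl <- function(mip, avg)
    composite_overview(make_proj(matrix(mip, 1, 1), "mip"),
                       make_proj(n, "minip"),
                       make_proj(matrix(avg, 1, 1), "average"),
                       cfg)$pixels[1, 1, 1]
  mips <- seq(-500, 2000, by = 250)
  expect_true(all(diff(vapply(mips, lvl, numeric(1), avg = 100)) >= 0))
  avgs <- seq(-500, 2000, by = 250)
  expect_true(all(diff(vapply(avgs, lvl, numeric(1), mip = 100)) >= 0))
})

test_that("with full MIP weight the gray channel is the windowed MIP", {
  cfg <- pmct_config(mip_weight = 1, avg_weight = 0)
  set.seed(42)
  m <- matrix(runif(64, -500, 2000), 8, 8)
  a <- matrix(runif(64, -500, 2000), 8, 8)
  ov <- composite_overview(make_proj(m, "mip"),
                           make_proj(matrix(0, 8, 8), "minip"),
                           make_proj(a, "average"), cfg)
  gray <- ov$pixels[, , 1]
  expect_equal(gray[!is_pure_red(ov$pixels) & !is_pure_blue(ov$pixels)],
               apply_window(m)[!is_pure_red(ov$pixels) & !is_pure_blue(ov$pixels)])
})

test_that("composite rejects mismatched inputs", {
  cfg <- pmct_config()
  expect_error(
    composite_overview(make_proj(matrix(0, 2, 2), "mip"),
                       make_proj(matrix(0, 3, 2), "minip"),
                       make_proj(matrix(0, 2, 2), "average"), cfg),
    "shape"
  )
  expect_error(
    composite_overview(make_proj(matrix(0, 2, 2), "mip"),
                       make_proj(matrix(0, 2, 2), "minip", view = "lateral"),
                       make_proj(matrix(0, 2, 2), "average"), cfg),
    "view"
  )
})
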