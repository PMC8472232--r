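# Channel geometry, bead trapping, layout planning and the lubrication
# flow model.

test_that("height_at interpolates linear profiles and honours endpoints", {
  ch <- table1_3a()
  expect_equal(height_at(ch, 0), 7.583)
  expect_equal(height_at(ch, 20000), 2.077)
  # midpoint of the linear interpolation, hand arithmetic
  expect_equal(height_at(ch, 10000), (7.583 + 2.077) / 2)
  expect_error(height_at(ch, -1), "outside")
  expect_error(height_at(ch, 20001), "outside")
})

test_that("measured profiles interpolate piecewise-linearly and monotonically", {
  prof <- data.frame(position_um = c(0, 5000, 12000, 20000),
                     height_um = c(7.6, 6.0, 3.5, 2.1))
  ch <- channel_profile(20000, 3000, 7.6, 2.1, measured = prof)
  expect_equal(height_at(ch, 5000), 6.0)
  expect_equal(height_at(ch, 8500), (6.0 + 3.5) / 2)
  x <- seq(0, 20000, by = 250)
  expect_true(all(diff(height_at(ch, x)) <= 0))
  bad <- prof; bad$height_um <- rev(bad$height_um)
  expect_error(channel_profile(20000, 3000, 7.6, 2.1, measured = bad),
               "non-increasing")
})

test_that("profile invariants are enforced at construction", {
  expect_error(channel_profile(20000, 3000, 2, 2), "inlet_height")
  expect_error(channel_profile(20000, 3000, 2, -1), "inlet_height")
})

test_that("band_position solves height_at(x) = d and encodes tie rules", {
  ch <- table1_3a()
  bp <- band_position(ch, 4.5)
  expect_equal(bp$status, "trapped")
  # oracle: independent bisection on height_at
  lo <- 0; hi <- 20000
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (height_at(ch, mid) > 4.5) lo <- mid else hi <- mid
  }
  expect_equal(bp$position, (lo + hi) / 2, tolerance = 1e-9)
  expect_equal(bp$position, (7.583 - 4.5) / (7.583 - 2.077) * 20000)
  expect_lt(abs(height_at(ch, bp$position) - 4.5), 1e-9)

  expect_equal(band_position(ch, 1.0)$status, "passes_through")
  expect_equal(band_position(ch, 2.077)$status, "passes_through")
  expect_equal(band_position(ch, 7.583)$status, "excluded_at_inlet")
  expect_equal(band_position(ch, 7.583)$position, 0)
})

test_that("trapped diameters round-trip and smaller beads trap further", {
  ch <- table1_3a()
  set.seed(1)
  ds <- sort(runif(25, 2.2, 7.4), decreasing = TRUE)
  xs <- vapply(ds, function(d) band_position(ch, d)$position, numeric(1))
  for (i in seq_along(ds)) {
    expect_lt(abs(height_at(ch, xs[i]) - ds[i]), 1e-9)
  }
  expect_true(all(diff(xs) > 0))
})

test_that("plan_layout places the two-plex panel and flags collisions", {
  ch <- table1_3a()
  beads <- list(bead_spec("IL6", 4.5, fluor_channel = "q525"),
                bead_spec("GFAP", 2.8))
  lay <- plan_layout(ch, beads)
  expect_true(attr(lay, "feasible"))
  expect_equal(lay$position,
               c((7.583 - 4.5) / (7.583 - 2.077) * 20000,
                 (7.583 - 2.8) / (7.583 - 2.077) * 20000))
  expect_gt(diff(lay$position), 500 + 500)

  single <- plan_layout(ch, list(bead_spec("GFAP", 2.8)))
  expect_true(attr(single, "feasible"))
  expect_equal(nrow(single), 1)

  expect_error(plan_layout(ch, list(bead_spec("A", 4.5),
                                    bead_spec("B", 4.5))),
               "collide")
})

test_that("plan_layout flags close bands and non-trapping beads", {
  ch <- table1_3a()
  close_pair <- list(bead_spec("A", 4.5), bead_spec("B", 4.4))
  lay <- plan_layout(ch, close_pair)
  expect_false(attr(lay, "feasible"))
  expect_match(attr(lay, "violations"), "apart", all = FALSE)

  lay2 <- plan_layout(ch, list(bead_spec("A", 4.5), bead_spec("tiny", 1)))
  expect_false(attr(lay2, "feasible"))
  expect_match(attr(lay2, "violations"), "passes through", all = FALSE)
})

test_that("capacity follows the floor rule and is monotone", {
  expect_identical(capacity(20000, 500, 500), 20L)
  expect_identical(capacity(1000, 500, 500), 1L)
  expect_identical(capacity(20000, 500, 1500), 10L)
  expect_error(capacity(0, 500, 500), "positive")
  for (bw in c(300, 500, 900)) {
    expect_true(all(diff(vapply(c(500, 1000, 2000), function(sep)
      capacity(20000, bw, sep), integer(1))) <= 0))
  }
})

test_that("flow closed form matches an independent quadrature oracle", {
  set.seed(7)
  for (i in 1:20) {
    hi <- runif(1, 3, 8); ho <- runif(1, 1, 2.5)
    L <- runif(1, 10000, 30000); w <- runif(1, 2000, 4000)
    ch <- channel_profile(L, w, hi, ho)
    q_cf <- flow_rate(ch, 1e4, 1e-3)
    # oracle: direct adaptive quadrature of the resistance integral,
    # written here independently of the package internals
    h <- function(x) (hi + (ho - hi) * x / L) * 1e-6
    I <- integrate(function(x) 1 / h(x)^3, 0, L, rel.tol = 1e-12)$value * 1e-6
    R <- 12 * 1e-3 * I / (w * 1e-6)
    q_oracle <- (1e4 / R) * 6e10
    expect_equal(q_cf, q_oracle, tolerance = 1e-9)
  }
})

test_that("flow is linear in pressure and matches the plane-Poiseuille limit", {
  ch <- table1_3a()
  expect_equal(flow_rate(ch, 2e4, 1e-3), 2 * flow_rate(ch, 1e4, 1e-3))
  q <- flow_rate(ch, 1e4, 1e-3, uniform_height = 2)
  q_slit <- (3000e-6 * (2e-6)^3 * 1e4) / (12 * 1e-3 * 20000e-6) * 6e10
  expect_equal(q, q_slit)
})

test_that("flow rate is dominated by the outlet height", {
  eps <- 1e-4
  for (ho in seq(1, 2.5, length.out = 5)) {
    for (hi in seq(3, 8, length.out = 5)) {
      q <- function(hi_, ho_) flow_rate(channel_profile(20000, 3000, hi_, ho_),
                                        1e4, 1e-3)
      el_o <- (log(q(hi, ho * (1 + eps))) - log(q(hi, ho))) / log(1 + eps)
      el_i <- (log(q(hi * (1 + eps), ho)) - log(q(hi, ho))) / log(1 + eps)
      expect_gt(abs(el_o), abs(el_i))
    }
  }
})

test_that("design_check applies the 1.5 um outlet rule inclusively", {
  expect_length(design_check(channel_profile(20000, 3000, 6.342, 0.963)), 1)
  expect_length(design_check(table1_3a()), 0)
  expect_length(design_check(channel_profile(20000, 3000, 6, 1.5)), 0)
})

test_that("channel geometry round-trips through JSON and CSV", {
  ch <- table1_3a()
  jf <- tempfile(fileext = ".json")
  write_channel(ch, jf)
  ch2 <- read_channel(jf)
  expect_equal(ch2$inlet_height, ch$inlet_height)
  expect_equal(height_at(ch2, 12345), height_at(ch, 12345))

  cf <- tempfile(fileext = ".csv")
  write_channel(ch, cf)
  ch3 <- read_channel(cf, width = 3000)
  expect_equal(height_at(ch3, 10000), height_at(ch, 10000), tolerance = 1e-9)
  unlink(c(jf, cf))
})
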