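# Generative model: bead diameters, binding response, rendering, run-level
# generators, and their determinism/conservation/monotonicity properties.

test_that("bead diameter sampling is truncated-normal and reproducible", {
  sp0 <- bead_spec("x", 2.8, 0, n_beads = 5)
  expect_equal(sample_bead_diameters(sp0, 5, seed = 1), rep(2.8, 5))

  sp <- bead_spec("x", 4.5, 0.05)
  d <- sample_bead_diameters(sp, 10000, seed = 2)
  expect_lt(abs(mean(d) / 4.5 - 1), 0.01)
  expect_true(all(abs(d - 4.5) <= 3 * 0.05 * 4.5))
  expect_identical(sample_bead_diameters(sp, 100, seed = 9),
                   sample_bead_diameters(sp, 100, seed = 9))
})

test_that("mean_response is a monotone saturating curve with exact anchors", {
  bm <- list(response_max = 2000, k_half = 2000, baseline = 50, hill = 1)
  expect_equal(mean_response(0, bm), 50)
  expect_equal(mean_response(2000, bm), 50 + 1000)
  expect_equal(mean_response(20000, bm), 50 + 2000 * 10 / 11)
  cc <- c(0, 10, 100, 1000, 1e4, 1e6)
  expect_true(all(diff(mean_response(cc, bm)) > 0))
  expect_error(mean_response(-1, bm), "non-negative")
  bm2 <- modifyList(bm, list(hill = 1.7))
  expect_true(all(diff(mean_response(cc, bm2)) >= 0))
})

test_that("a degenerate render is exactly the analytic signal", {
  cfg <- clean_config(n_beads = 1)
  fv <- render_fov(cfg, 1, c(GFAP = 2000), fov_seed = 5)
  sig <- mean_response(2000, cfg$binding_model)
  inside <- fv$images$fluor$q585[fv$truth$mask]
  expect_equal(unique(inside),
               sig * cfg$crossover["q585", "q585"] +
                 cfg$autofluorescence["GFAP", "q585"] +
                 cfg$fluor_background)
  expect_equal(unname(fv$truth$true_rfu_per_bead_area["q585"]),
               sig + cfg$autofluorescence["GFAP", "q585"][[1]])
})

test_that("rendering is deterministic and the mask conserves disk area", {
  cfg <- small_config()
  a <- render_fov(cfg, 1, c(GFAP = 500), fov_seed = 3)
  b <- render_fov(cfg, 1, c(GFAP = 500), fov_seed = 3)
  expect_identical(a, b)
  # mask area matches the analytic disk area to ~1 px per bead boundary
  analytic <- sum(pi * (a$truth$beads$diameter / 2 / cfg$pixel_size)^2)
  expect_lt(abs(a$truth$mask_area_px - analytic),
            nrow(a$truth$beads) * 2 * pi * max(a$truth$beads$diameter) /
              2 / cfg$pixel_size)
})

test_that("true band intensity increases with own-analyte concentration", {
  cfg <- small_config()
  rfu <- vapply(c(0, 100, 1000, 10000), function(conc)
    render_fov(cfg, 1, c(GFAP = conc),
               fov_seed = 77)$truth$true_rfu_per_bead_area[["q585"]],
    numeric(1))
  expect_true(all(diff(rfu) > 0))
})

test_that("own channel dominates other channels in every band", {
  cfg <- small_duplex_config()
  sample <- c(IL6 = 25000, GFAP = 10000)
  for (band in c("IL6", "GFAP")) {
    own <- cfg$bead_specs[[band]]$fluor_channel
    tr <- render_fov(cfg, band, sample, fov_seed = 8)$truth
    others <- setdiff(names(tr$true_rfu_per_bead_area), own)
    expect_true(all(tr$true_rfu_per_bead_area[own] >
                      tr$true_rfu_per_bead_area[others]))
  }
})

test_that("crossover gains of zero decouple the channels", {
  cfg <- small_duplex_config(crossover_gain = 0, carryover_fraction = 0)
  t1 <- render_fov(cfg, "IL6", c(IL6 = 1000, GFAP = 0), fov_seed = 4)$truth
  t2 <- render_fov(cfg, "IL6", c(IL6 = 1000, GFAP = 25000), fov_seed = 4)$truth
  expect_identical(t1$true_rfu_per_bead_area, t2$true_rfu_per_bead_area)
})

test_that("carryover obeys its fraction: zero means no foreign beads", {
  cfg <- small_duplex_config(carryover_fraction = 0)
  tr <- render_fov(cfg, "IL6", c(IL6 = 0, GFAP = 0), fov_seed = 6)$truth
  expect_true(all(tr$beads$label == "IL6"))
  cfg2 <- small_duplex_config(carryover_fraction = 0.5)
  tr2 <- render_fov(cfg2, "IL6", c(IL6 = 0, GFAP = 0), fov_seed = 6)$truth
  expect_true(any(tr2$beads$label == "GFAP"))
  # larger beads never lodge in a downstream (smaller-height) band
  tr3 <- render_fov(cfg2, "GFAP", c(IL6 = 0, GFAP = 0), fov_seed = 6)$truth
  expect_true(all(tr3$beads$label == "GFAP"))
})

test_that("overfilled fields of view fail loudly", {
  cfg <- small_config(n_beads = 100000)
  expect_error(render_fov(cfg, 1, c(GFAP = 0), fov_seed = 1), "too large")
})

test_that("standard-curve runs have the stated layout and sub-seeded determinism", {
  cfg <- small_config()
  run <- simulate_standard_curve_run(cfg, c(10000, 5000, 1000, 500, 100, 0),
                                     replicates = 3, n_blanks = 10)
  expect_length(run$fovs, 18)
  expect_length(run$blanks, 10)
  expect_equal(vapply(run$blanks, `[[`, numeric(1), "concentration"),
               rep(0, 10))
  one <- simulate_standard_curve_run(cfg, 100, replicates = 1, n_blanks = 0)
  expect_length(one$fovs, 1)
  run2 <- simulate_standard_curve_run(cfg, c(10000, 5000, 1000, 500, 100, 0),
                                      replicates = 3, n_blanks = 10)
  expect_identical(run$fovs[[7]]$images, run2$fovs[[7]]$images)
})

test_that("multiplex runs render all-zero controls at baseline only", {
  cfg <- small_duplex_config(carryover_fraction = 0)
  run <- simulate_multiplex_run(cfg, c(IL6 = 0, GFAP = 0), n_fov = 1,
                                with_controls = FALSE)
  for (band in names(run$bands)) {
    tr <- run$bands[[band]]$fovs[[1]]$truth
    sig <- unique(tr$beads$signal_rfu)
    expect_equal(sig, cfg$binding_model$baseline)
  }
})

test_that("multiplex runs refuse infeasible layouts", {
  cfg <- small_duplex_config()
  ch <- channel_profile(20000, 3000, 7.583, 2.077)
  ok <- simulate_multiplex_run(cfg, c(IL6 = 100, GFAP = 100),
                               profile = ch, n_fov = 1,
                               with_controls = FALSE)
  expect_s3_class(ok$layout, "band_layout")
  # 1 um beads pass through this outlet: infeasible panel
  cfg3 <- sim_config(image_shape = c(200L, 260L), bead_specs = list(
    bead_spec("IL6", 4.5, 0.03, "q525", n_beads = 25),
    bead_spec("IL8", 1.0, 0.03, "q655", n_beads = 40)))
  expect_error(
    simulate_multiplex_run(cfg3, c(IL6 = 0, IL8 = 0), profile = ch,
                           n_fov = 1),
    "infeasible")
})
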