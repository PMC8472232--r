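# Flat-field and background correction, binarization, the masked
# RFU/Bead-Area statistic, and band aggregation.

test_that("pseudo-flat-field is a fixed point on flat images", {
  img <- matrix(100, 80, 90)
  expect_equal(pseudo_flat_field(img), img, tolerance = 1e-9)
  expect_error(pseudo_flat_field(matrix(0, 10, 10)), "all-zero")
})

test_that("pseudo-flat-field removes a known smooth gradient", {
  base <- matrix(200, 120, 150)
  grad <- outer(seq(0.5, 1.5, length.out = 120),
                seq(1, 1, length.out = 150))
  corrected <- pseudo_flat_field(base * grad)
  expect_lt(diff(range(corrected)) / mean(corrected), 0.02)
  expect_identical(pseudo_flat_field(base * grad),
                   pseudo_flat_field(base * grad))
})

test_that("background correction recovers a disk on constant background", {
  img <- matrix(3, 60, 60)
  mask <- matrix(FALSE, 60, 60)
  yy <- outer(1:60, rep(1, 60)); xx <- t(yy)
  mask[(yy - 30)^2 + (xx - 30)^2 <= 64] <- TRUE
  img[mask] <- img[mask] + 10
  out <- background_correct(img, mask)
  expect_equal(unique(out[mask]), 10)
  expect_equal(unique(out[!mask]), 0)
  # no-mask path: lowest-decile median
  expect_equal(background_correct(matrix(7, 20, 20)), matrix(0, 20, 20))
  expect_equal(background_correct(out, mask), out)
  expect_error(background_correct(img, mask | TRUE), "every pixel")
})

test_that("binarization recovers the true mask at zero noise", {
  cfg <- clean_config(n_beads = 30)
  fv <- render_fov(cfg, 1, c(GFAP = 1000), fov_seed = 9)
  ff <- pseudo_flat_field(fv$images$epi)
  # boundary tolerance: one pixel of perimeter per bead
  perim <- nrow(fv$truth$beads) * 2 * pi * 2.8 / 2 / cfg$pixel_size
  mask <- binarize_epi(ff, method = "otsu", polarity = "beads_dark")
  expect_lt(sum(xor(mask, fv$truth$mask)), perim)
  # local-mean needs an offset above the residual background structure
  mask_lm <- binarize_epi(ff, method = "local_mean",
                          polarity = "beads_dark", offset = 50)
  expect_lt(sum(xor(mask_lm, fv$truth$mask)), perim)
  expect_warning(m0 <- binarize_epi(matrix(5, 30, 30)), "constant")
  expect_equal(sum(m0), 0)
  inverted <- binarize_epi(ff, polarity = "beads_bright")
  expect_lt(sum(inverted & fv$truth$mask) / sum(fv$truth$mask), 0.05)
})

test_that("RFU/Bead-Area matches its definition and a naive loop oracle", {
  mask <- matrix(FALSE, 20, 20); mask[3:12, 3:12] <- TRUE  # 100 px
  fluor <- matrix(0, 20, 20); fluor[mask] <- 5
  ms <- rfu_per_bead_area(mask, fluor)
  expect_equal(ms$b, 100)
  expect_equal(unname(ms$rfu_per_bead_area), 5)
  # off-mask debris of any intensity changes nothing, exactly
  debris <- fluor; debris[15:19, 15:19] <- 1000
  expect_identical(rfu_per_bead_area(mask, debris)$rfu_per_bead_area,
                   ms$rfu_per_bead_area)
  # naive double-loop oracle
  set.seed(3)
  img <- matrix(runif(400), 20, 20)
  f_loop <- 0; b_loop <- 0L
  for (i in 1:20) for (j in 1:20) {
    b_loop <- b_loop + as.integer(mask[i, j])
    f_loop <- f_loop + mask[i, j] * img[i, j]
  }
  ms2 <- rfu_per_bead_area(mask, img)
  expect_identical(ms2$b, b_loop)
  expect_identical(unname(ms2$f), f_loop)
  expect_error(rfu_per_bead_area(matrix(FALSE, 5, 5), matrix(1, 5, 5)),
               "empty")
})

test_that("the statistic is scale-equivariant in fluorescence gain", {
  mask <- matrix(FALSE, 30, 30); mask[5:20, 5:20] <- TRUE
  set.seed(8)
  img <- matrix(0, 30, 30); img[mask] <- runif(sum(mask), 1, 10)
  s1 <- rfu_per_bead_area(mask, img)$rfu_per_bead_area
  s3 <- rfu_per_bead_area(mask, img * 3.5)$rfu_per_bead_area
  expect_equal(s3, 3.5 * s1)
})

test_that("quantification round-trips ground truth within 5% at default noise", {
  cfg <- small_config(n_beads = 60)
  fv <- render_fov(cfg, 1, c(GFAP = 2000), fov_seed = 12)
  st <- quantify_fov(fv$images)
  expect_lt(abs(st$rfu_per_bead_area[["q585"]] /
                  fv$truth$true_rfu_per_bead_area[["q585"]] - 1), 0.05)
})

test_that("band aggregation computes SEM and control subtraction", {
  cfg <- small_config()
  fv <- render_fov(cfg, 1, c(GFAP = 1000), fov_seed = 2)
  bm <- measure_band(list(fv, fv, fv))
  expect_equal(bm$table$sem, rep(0, nrow(bm$table)))
  expect_equal(bm$table$n_fov, rep(3, nrow(bm$table)))
  # controls equal to the measurement: subtracted value is zero
  bm2 <- measure_band(list(fv, fv), control_fovs = list(fv, fv))
  expect_equal(bm2$table$control_subtracted, rep(0, nrow(bm2$table)))
  # mismatched channel sets across FOVs must error
  fv_bad <- fv$images
  names(fv_bad$fluor) <- "q999"
  expect_error(measure_band(list(fv$images, fv_bad)), "differ")
})

test_that("each band's own channel dominates after control subtraction", {
  cfg <- small_duplex_config()
  run <- simulate_multiplex_run(cfg, c(IL6 = 25000, GFAP = 10000),
                                n_fov = 2)
  for (band in names(run$bands)) {
    bd <- run$bands[[band]]
    bm <- measure_band(bd$fovs, bd$control_fovs)
    own <- cfg$bead_specs[[band]]$fluor_channel
    tab <- bm$table
    expect_gt(tab$rfu_per_bead_area[tab$channel == own],
              max(tab$rfu_per_bead_area[tab$channel != own]))
  }
})

test_that("image pairs round-trip through 16-bit TIFF files", {
  skip_if_not_installed("tiff")
  cfg <- small_config(n_beads = 10)
  fv <- render_fov(cfg, 1, c(GFAP = 500), fov_seed = 1)
  dir <- tempfile()
  write_image_pair(fv$images, dir)
  back <- read_image_pair(dir, "GFAP", 1, "q585",
                          pixel_size = cfg$pixel_size)
  expect_equal(dim(back$epi), dim(fv$images$epi))
  # 16-bit quantization: within one grey level
  expect_lt(max(abs(back$fluor$q585 - fv$images$fluor$q585)), 1.0)
  unlink(dir, recursive = TRUE)
})
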