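# Synthetic micrograph generator: bead populations with a saturable binding
# response, spectral crossover between quantum-dot channels, bead carryover
# between detection bands, illumination gradients, untethered debris, and
# camera noise — all with exact ground truth, so the quantification and
# statistics layers can be validated end to end.

# Run expr with a private RNG stream seeded by `seed`, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive a reproducible sub-seed (< 2^31 - 1) for FOV `index` from a master
# seed, so any subset of a run can be regenerated independently.
sub_seed <- function(master, index) {
  ((master %% 2147483647) * 69069 + index * 1013904223) %% 2147483647
}

#' Configuration of the synthetic imaging model
#'
#' Collects every knob of the generative model. Defaults emulate the
#' reference instrument and assay: 1344 x 1100 pixel 16-bit micrographs, a
#' saturable (Hill/Langmuir) binding response, a diagonally dominant
#' spectral crossover matrix, strong 525 nm autofluorescence of the
#' ~2.8 um polymer beads, a smooth multiplicative illumination gradient on
#' the epi image, dark beads on a bright epi background, mixed
#' Gaussian-plus-shot camera noise, a handful of bright untethered debris
#' spots per field of view, and a small carryover probability for smaller
#' beads lodging in upstream bands.
#'
#' @param seed Master seed; every field of view derives its own sub-seed
#'   from it, so runs are bit-reproducible.
#' @param image_shape Image dimensions in pixels, `c(rows, cols)`.
#' @param pixel_size Micrometres per pixel.
#' @param bead_specs List of [bead_spec()]s, one per detection band,
#'   largest diameter first (bands form in that order along the channel).
#' @param binding_model List `(response_max, k_half, baseline, hill)`:
#'   mean on-bead fluorescence is
#'   `baseline + response_max * c^hill / (k_half^hill + c^hill)` RFU at
#'   analyte concentration `c` pg/mL.
#' @param crossover Square matrix, fluorophore x detection channel, of
#'   relative gains (diagonal 1). `NULL` builds a default with
#'   `crossover_gain` off-diagonal.
#' @param crossover_gain Default off-diagonal spectral gain.
#' @param autofluorescence Matrix, bead spec x channel, of additive RFU.
#'   `NULL` builds a default: 5 RFU everywhere, except 150 RFU in channel
#'   `"q525"` for beads of ~2.8 um diameter (their polymer matrix is
#'   strongly autofluorescent near 525 nm).
#' @param illumination Coefficients of the multiplicative illumination
#'   field `1 + cx*u + cy*v + cxx*u^2 + cyy*v^2` with `u, v` in
#'   `[-0.5, 0.5]` across the image.
#' @param epi_contrast List `(background, attenuation)`: epi image level off
#'   beads and the amount by which bead disks are darker.
#' @param fluor_background Uniform additive background in every
#'   fluorescence channel, RFU.
#' @param noise List `(gaussian_sd, poisson_scale)`: pixel noise sd is
#'   `sqrt(gaussian_sd^2 + poisson_scale * intensity)` (Gaussian
#'   approximation to read + shot noise).
#' @param fov_scale_sd Log-sd of a per-FOV multiplicative excitation jitter
#'   applied to all fluorescence signal (drift between fields of view).
#' @param debris List `(count, intensity, radius_px)`: bright fluorescent
#'   spots not tethered to any bead, absent from the epi image.
#' @param carryover_fraction Probability that a bead of a smaller type
#'   lodges in an upstream band while that band forms.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       image_shape = c(1100L, 1344L),
                       pixel_size = 0.325,
                       bead_specs = list(
                         bead_spec("GFAP", 2.8, 0.03, "q585",
                                   n_beads = 1500)),
                       binding_model = list(response_max = 2000, k_half = 2000,
                                            baseline = 50, hill = 1),
                       crossover = NULL, crossover_gain = 0.05,
                       autofluorescence = NULL,
                       illumination = list(cx = 0.3, cy = 0.2,
                                           cxx = 0, cyy = 0),
                       epi_contrast = list(background = 1000,
                                           attenuation = 400),
                       fluor_background = 20,
                       noise = list(gaussian_sd = 10, poisson_scale = 0.5),
                       fov_scale_sd = 0.05,
                       debris = list(count = 5, intensity = c(500, 2000),
                                     radius_px = c(1, 3)),
                       carryover_fraction = 0.02) {
  if (inherits(bead_specs, "bead_spec")) bead_specs <- list(bead_specs)
  stopifnot(length(bead_specs) >= 1,
            carryover_fraction >= 0, carryover_fraction < 1,
            fluor_background >= 0, epi_contrast$background > 0,
            all(unlist(noise) >= 0), debris$count >= 0)
  channels <- unique(vapply(bead_specs, function(b) b$fluor_channel,
                            character(1)))
  labels <- vapply(bead_specs, function(b) b$label, character(1))
  if (anyDuplicated(labels)) stop("bead spec labels must be unique")
  names(bead_specs) <- labels
  if (is.null(crossover)) {
    k <- length(channels)
    crossover <- matrix(crossover_gain, k, k,
                        dimnames = list(channels, channels))
    diag(crossover) <- 1
  }
  stopifnot(all(crossover >= 0),
            all(channels %in% rownames(crossover)),
            all(channels %in% colnames(crossover)))
  if (is.null(autofluorescence)) {
    autofluorescence <- matrix(5, length(bead_specs), length(channels),
                               dimnames = list(labels, channels))
    af28 <- vapply(bead_specs, function(b)
      b$diameter_mean >= 2.5 && b$diameter_mean <= 3.1, logical(1))
    if ("q525" %in% channels && any(af28)) {
      autofluorescence[af28, "q525"] <- 150
    }
  }
  stopifnot(all(autofluorescence >= 0),
            all(labels %in% rownames(autofluorescence)))
  with(binding_model, stopifnot(response_max >= 0, k_half > 0,
                                baseline >= 0, hill > 0))
  structure(
    list(seed = as.integer(seed), image_shape = as.integer(image_shape),
         pixel_size = pixel_size, bead_specs = bead_specs,
         channels = channels, binding_model = binding_model,
         crossover = crossover, autofluorescence = autofluorescence,
         illumination = illumination, epi_contrast = epi_contrast,
         fluor_background = fluor_background, noise = noise,
         fov_scale_sd = fov_scale_sd, debris = debris,
         carryover_fraction = carryover_fraction),
    class = "sim_config")
}

#' Draw bead diameters
#'
#' Diameters follow a normal distribution with mean `diameter_mean` and sd
#' `diameter_cv * diameter_mean`, truncated at three standard deviations
#' (beads far outside the nominal size are removed upstream by the
#' manufacturer and by the channel itself).
#'
#' @param spec A [bead_spec()].
#' @param n Number of draws.
#' @param seed Optional seed for a private, reproducible stream.
#' @return Numeric vector of `n` diameters, micrometres.
#' @export
sample_bead_diameters <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "bead_spec"), n >= 0)
  draw <- function() {
    mu <- spec$diameter_mean
    sd <- spec$diameter_cv * mu
    if (sd == 0 || n == 0) return(rep(mu, n))
    d <- stats::rnorm(n, mu, sd)
    while (any(bad <- abs(d - mu) > 3 * sd)) {
      d[bad] <- stats::rnorm(sum(bad), mu, sd)
    }
    d
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Mean on-bead fluorescence at a given analyte concentration
#'
#' Saturable Hill/Langmuir binding response:
#' `baseline + response_max * c^hill / (k_half^hill + c^hill)`.
#' Monotone non-decreasing in concentration, equal to `baseline` at zero
#' and approaching `baseline + response_max` at saturation.
#'
#' @param concentration Analyte concentration(s), pg/mL (non-negative).
#' @param binding_model List `(response_max, k_half, baseline, hill)`.
#' @return Mean response(s), RFU per unit bead area.
#' @export
mean_response <- function(concentration,
                          binding_model = sim_config()$binding_model) {
  if (any(concentration < 0)) stop("concentration must be non-negative")
  with(binding_model, {
    ch <- concentration^hill
    baseline + response_max * ch / (k_half^hill + ch)
  })
}

# Add disks to `img`; returns list(img, mask). `values` is per-bead additive
# intensity (negative for epi attenuation). Centres/radii in pixels.
draw_disks <- function(img, cx, cy, r, values, mask = NULL) {
  nr <- nrow(img); nc <- ncol(img)
  if (is.null(mask)) mask <- matrix(FALSE, nr, nc)
  for (i in seq_along(cx)) {
    x0 <- max(1L, floor(cx[i] - r[i])); x1 <- min(nc, ceiling(cx[i] + r[i]))
    y0 <- max(1L, floor(cy[i] - r[i])); y1 <- min(nr, ceiling(cy[i] + r[i]))
    if (x0 > x1 || y0 > y1) next
    xs <- x0:x1; ys <- y0:y1
    inside <- outer((ys - cy[i])^2, (xs - cx[i])^2, "+") <= r[i]^2
    block <- img[ys, xs, drop = FALSE]
    block[inside] <- block[inside] + values[i]
    img[ys, xs] <- block
    mb <- mask[ys, xs, drop = FALSE]
    mb[inside] <- TRUE
    mask[ys, xs] <- mb
  }
  list(img = img, mask = mask)
}

# Multiplicative illumination field on the pixel grid, coefficients from
# config$illumination; u, v in [-0.5, 0.5].
illumination_field <- function(shape, coef) {
  v <- (seq_len(shape[1]) - 1) / max(shape[1] - 1, 1) - 0.5
  u <- (seq_len(shape[2]) - 1) / max(shape[2] - 1, 1) - 0.5
  f <- 1 + outer(coef$cy * v + coef$cyy * v^2,
                 coef$cx * u + coef$cxx * u^2, "+")
  if (any(f <= 0)) stop("illumination field must be positive")
  f
}

apply_noise <- function(img, noise) {
  if (noise$gaussian_sd == 0 && noise$poisson_scale == 0) return(img)
  sd <- sqrt(noise$gaussian_sd^2 + noise$poisson_scale * pmax(img, 0))
  pmax(img + stats::rnorm(length(img), 0, sd), 0)
}

# Place n beads on a jittered grid: cells sized to the largest bead so that
# no two beads overlap, cell order randomized, each bead jittered uniformly
# within its cell. Detection bands are densely and fairly regularly packed,
# which this emulates while keeping placement O(n).
place_beads <- function(shape, r_px) {
  n <- length(r_px)
  cell <- 2 * max(r_px) + 2
  nx <- floor((shape[2] - 2) / cell)
  ny <- floor((shape[1] - 2) / cell)
  if (n > nx * ny) {
    stop("bead count too large to place without overlap: ", n, " beads, ",
         nx * ny, " sites; reduce n_beads or enlarge the field of view")
  }
  sites <- sample.int(nx * ny, n)
  ix <- (sites - 1) %% nx
  iy <- (sites - 1) %/% nx
  slack <- pmax(cell / 2 - r_px - 1, 0)
  cx <- 1 + (ix + 0.5) * cell + stats::runif(n, -1, 1) * slack
  cy <- 1 + (iy + 0.5) * cell + stats::runif(n, -1, 1) * slack
  list(cx = cx, cy = cy)
}

#' Render one synthetic field of view
#'
#' Produces a paired epi-illuminated image and one fluorescence image per
#' detection channel for a single detection band, together with full ground
#' truth. The epi image is `illumination * (background - attenuation inside
#' bead disks) + noise` (beads dark). Each fluorescence channel sums, inside
#' every bead disk, the crossover-weighted quantum-dot signal of that bead's
#' fluorophore plus its autofluorescence, then adds a uniform background,
#' bright untethered debris spots (absent from the epi image), and noise.
#' Beads of smaller types appear in this band with probability
#' `carryover_fraction` each.
#'
#' @param config A [sim_config()].
#' @param band Index or label of the bead spec whose band is imaged.
#' @param concentrations Named vector of analyte concentrations, pg/mL;
#'   names must cover every bead spec label.
#' @param fov_seed Seed for this field of view (derive from the master seed
#'   via repeated calls from the run-level generators).
#' @param fov_index Metadata only: index recorded with the images.
#' @return List with `images` (an `image_pair`: `epi`, named list `fluor`,
#'   `pixel_size`, `metadata`) and `truth` (a `ground_truth`: bead table,
#'   logical `mask`, noiseless per-channel `true_rfu_per_bead_area`
#'   computed over the true mask after background removal, and the sample
#'   concentrations).
#' @export
render_fov <- function(config, band = 1L, concentrations,
                       fov_seed = config$seed, fov_index = 1L) {
  stopifnot(inherits(config, "sim_config"))
  specs <- config$bead_specs
  if (is.character(band)) band <- match(band, names(specs))
  if (is.na(band) || band < 1 || band > length(specs)) {
    stop("band not present in config")
  }
  labs <- names(specs)
  if (!all(labs %in% names(concentrations))) {
    stop("concentrations must be named for every analyte: ",
         paste(labs, collapse = ", "))
  }
  with_seed(fov_seed, {
    shape <- config$image_shape
    px <- config$pixel_size
    own <- specs[[band]]

    # bead roster: the band's own beads plus carryover from smaller types
    roster <- data.frame(label = character(0), diameter = numeric(0))
    d_own <- sample_bead_diameters(own, own$n_beads)
    roster <- data.frame(label = rep(own$label, length(d_own)),
                         diameter = d_own, stringsAsFactors = FALSE)
    for (sp in specs) {
      if (sp$label != own$label && sp$diameter_mean < own$diameter_mean &&
          config$carryover_fraction > 0) {
        n_c <- stats::rbinom(1, sp$n_beads, config$carryover_fraction)
        if (n_c > 0) {
          roster <- rbind(roster, data.frame(
            label = rep(sp$label, n_c),
            diameter = sample_bead_diameters(sp, n_c),
            stringsAsFactors = FALSE))
        }
      }
    }
    r_px <- roster$diameter / 2 / px
    pos <- place_beads(shape, r_px)

    illum <- illumination_field(shape, config$illumination)
    fov_scale <- if (config$fov_scale_sd > 0) {
      exp(stats::rnorm(1, 0, config$fov_scale_sd))
    } else 1

    # epi: dark disks on bright background, multiplicative illumination
    epi0 <- matrix(config$epi_contrast$background, shape[1], shape[2])
    dd <- draw_disks(epi0, pos$cx, pos$cy, r_px,
                     rep(-config$epi_contrast$attenuation, nrow(roster)))
    epi <- apply_noise(dd$img * illum, config$noise)
    mask <- dd$mask

    # per-bead fluorophore signal in RFU (before crossover weighting)
    sig <- mean_response(unname(concentrations[roster$label]),
                         config$binding_model)
    fluor_of <- vapply(specs[roster$label], function(s) s$fluor_channel,
                       character(1))

    fluor <- list(); true_rfu <- numeric(0)
    b <- sum(mask)
    for (ch in config$channels) {
      val <- fov_scale * (sig * config$crossover[fluor_of, ch] +
                            config$autofluorescence[roster$label, ch])
      img0 <- matrix(0, shape[1], shape[2])
      img0 <- draw_disks(img0, pos$cx, pos$cy, r_px, val)$img
      true_rfu[ch] <- sum(img0[mask]) / b
      img <- img0 + config$fluor_background
      if (config$debris$count > 0) {
        nd <- config$debris$count
        img <- draw_disks(
          img,
          stats::runif(nd, 1, shape[2]), stats::runif(nd, 1, shape[1]),
          stats::runif(nd, config$debris$radius_px[1],
                       config$debris$radius_px[2]),
          stats::runif(nd, config$debris$intensity[1],
                       config$debris$intensity[2]))$img
      }
      fluor[[ch]] <- apply_noise(img, config$noise)
    }

    images <- structure(
      list(epi = epi, fluor = fluor, pixel_size = px,
           metadata = list(band = own$label, fov = fov_index)),
      class = "image_pair")
    truth <- structure(
      list(beads = cbind(roster, cx_px = pos$cx, cy_px = pos$cy,
                         signal_rfu = sig),
           mask = mask, mask_area_px = b,
           true_rfu_per_bead_area = true_rfu,
           fov_scale = fov_scale,
           concentrations = concentrations[labs]),
      class = "ground_truth")
    list(images = images, truth = truth)
  })
}

#' Simulate a standard-curve imaging run
#'
#' One field of view per concentration x replicate for the first (or named)
#' band, plus a set of blank replicates for limit-of-detection work. The
#' default calibrator series and replicate structure follow standard
#' practice for this assay family: six calibrators from 0 to
#' 10,000 pg/mL, three replicates each, and ten blanks.
#'
#' @param config A [sim_config()].
#' @param concentrations Calibrator concentrations, pg/mL.
#' @param replicates Fields of view per calibrator.
#' @param n_blanks Additional blank (0 pg/mL) fields of view.
#' @param band Which band is imaged (index or label).
#' @return List with `fovs` (each element: `images`, `truth`,
#'   `concentration`, `replicate`) and `blanks` (same shape, concentration
#'   zero), plus the `config` used.
#' @export
simulate_standard_curve_run <- function(config,
                                        concentrations = c(10000, 5000, 1000,
                                                           500, 100, 0),
                                        replicates = 3, n_blanks = 10,
                                        band = 1L) {
  stopifnot(inherits(config, "sim_config"), replicates >= 1, n_blanks >= 0)
  specs <- config$bead_specs
  if (is.character(band)) band <- match(band, names(specs))
  analyte <- names(specs)[band]
  zero <- stats::setNames(rep(0, length(specs)), names(specs))
  counter <- 0L
  fovs <- list()
  for (conc in concentrations) {
    for (rep_i in seq_len(replicates)) {
      counter <- counter + 1L
      cc <- zero; cc[analyte] <- conc
      fv <- render_fov(config, band, cc,
                       fov_seed = sub_seed(config$seed, counter),
                       fov_index = counter)
      fovs[[counter]] <- c(fv, list(concentration = conc, replicate = rep_i))
    }
  }
  blanks <- list()
  for (i in seq_len(n_blanks)) {
    counter <- counter + 1L
    fv <- render_fov(config, band, zero,
                     fov_seed = sub_seed(config$seed, counter),
                     fov_index = counter)
    blanks[[i]] <- c(fv, list(concentration = 0, replicate = i))
  }
  list(fovs = fovs, blanks = blanks, config = config, analyte = analyte)
}

#' Simulate a multiplexed run
#'
#' Renders fields of view for every detection band at the given sample
#' concentrations, optionally alongside a matched control run (all analytes
#' at zero) for control subtraction. When a [channel_profile()] is given,
#' the band layout is checked first with [plan_layout()] and the run aborts
#' if the layout is infeasible.
#'
#' @param config A [sim_config()] with at least two bead specs.
#' @param sample Named vector of analyte concentrations, pg/mL.
#' @param profile Optional [channel_profile()] for a feasibility check.
#' @param n_fov Fields of view per band and condition.
#' @param with_controls Also render the matched all-zero control run.
#' @return List `bands`, one element per bead spec (largest first), each
#'   with `fovs`, `control_fovs` and the band `label`; plus `layout` when a
#'   profile was supplied.
#' @export
simulate_multiplex_run <- function(config, sample, profile = NULL,
                                   n_fov = 5, with_controls = TRUE) {
  stopifnot(inherits(config, "sim_config"), n_fov >= 1)
  specs <- config$bead_specs
  if (length(specs) < 2) stop("a multiplex run needs at least two bead specs")
  if (!all(names(specs) %in% names(sample))) {
    stop("sample must name a concentration for every analyte")
  }
  layout <- NULL
  if (!is.null(profile)) {
    layout <- plan_layout(profile, unname(specs))
    if (!isTRUE(attr(layout, "feasible"))) {
      stop("band layout infeasible: ",
           paste(attr(layout, "violations"), collapse = "; "))
    }
  }
  zero <- stats::setNames(rep(0, length(specs)), names(specs))
  counter <- 0L
  bands <- list()
  for (bi in seq_along(specs)) {
    fovs <- vector("list", n_fov)
    ctrl <- if (with_controls) vector("list", n_fov) else NULL
    for (k in seq_len(n_fov)) {
      counter <- counter + 1L
      fovs[[k]] <- render_fov(config, bi, sample[names(specs)],
                              fov_seed = sub_seed(config$seed, counter),
                              fov_index = k)
      if (with_controls) {
        counter <- counter + 1L
        ctrl[[k]] <- render_fov(config, bi, zero,
                                fov_seed = sub_seed(config$seed, counter),
                                fov_index = k)
      }
    }
    bands[[names(specs)[bi]]] <- list(label = names(specs)[bi],
                                      fovs = fovs, control_fovs = ctrl)
  }
  list(bands = bands, layout = layout, sample = sample, config = config)
}

#' Simulate a bead-sizing acquisition
#'
#' Renders a population of bright bead disks on a dark background, laid out
#' on a grid (as in a mounted slide imaged by confocal), as a small Z-stack
#' in which each bead is in focus in one slice. The maximum-intensity
#' projection of the stack contains every bead at full intensity, which is
#' what the sizing pipeline segments.
#'
#' @param spec A [bead_spec()].
#' @param n Number of beads.
#' @param pixel_size Micrometres per pixel (confocal scans resolve beads
#'   much more finely than the assay camera; default 0.1).
#' @param n_slices Number of Z slices.
#' @param intensity On-bead intensity, arbitrary units.
#' @param noise_sd Gaussian noise sd (0 = noiseless).
#' @param seed Seed for the private stream.
#' @return List with `stack` (list of matrices), `projection` (their
#'   pixelwise maximum), `diameters_um` (ground truth), and `pixel_size`.
#' @export
simulate_bead_projection <- function(spec, n, pixel_size = 0.1,
                                     n_slices = 5, intensity = 1000,
                                     noise_sd = 0, seed = 1L) {
  stopifnot(inherits(spec, "bead_spec"), n >= 1, n_slices >= 1)
  with_seed(seed, {
    d_um <- sample_bead_diameters(spec, n)
    r_px <- d_um / 2 / pixel_size
    cell <- ceiling(2 * max(r_px)) + 6
    ncols <- ceiling(sqrt(n))
    nrows <- ceiling(n / ncols)
    shape <- c(nrows * cell + cell, ncols * cell + cell)
    cx <- cell * ((seq_len(n) - 1) %% ncols) + cell
    cy <- cell * ((seq_len(n) - 1) %/% ncols) + cell
    # sub-pixel jitter so rasterization error is unbiased
    cx <- cx + stats::runif(n) - 0.5
    cy <- cy + stats::runif(n) - 0.5
    slice_of <- sample.int(n_slices, n, replace = TRUE)
    stack <- lapply(seq_len(n_slices), function(s) {
      idx <- which(slice_of == s)
      img <- matrix(0, shape[1], shape[2])
      if (length(idx)) {
        img <- draw_disks(img, cx[idx], cy[idx], r_px[idx],
                          rep(intensity, length(idx)))$img
      }
      if (noise_sd > 0) img <- pmax(img + stats::rnorm(length(img), 0,
                                                       noise_sd), 0)
      img
    })
    list(stack = stack, projection = max_projection(stack),
         diameters_um = d_um, pixel_size = pixel_size)
  })
}
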