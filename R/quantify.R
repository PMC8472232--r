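# Masked-intensity quantification: pseudo-flat-field correction of the epi
# image, background correction of the fluorescence images, binarization of
# the epi image to a bead mask B', and the RFU/Bead-Area statistic
# f/b = sum(B' * fluor) / sum(B'). Because only pixels inside the bead mask
# contribute, fluorescent debris and quantum-dot aggregates not tethered to
# a bead are excluded by construction.

# Separable Gaussian blur via 1-D FFT convolution with linear-extrapolating
# (odd-reflection) padding: pad(-t) = 2 m(1) - m(1 + t). Odd reflection
# continues a linear trend exactly, so blurring a linear illumination ramp
# returns the ramp unchanged — plain mirror padding instead rounds the ramp
# near the edges by ~0.8 sigma x slope, biasing the illumination estimate.
# EBImage's spatial-domain filters require the kernel to fit inside the
# image, which fails at the large sigmas used for illumination estimation;
# frequency-domain convolution has no such limit.
gaussian_blur <- function(img, sigma) {
  blur_rows <- function(m) {
    n <- nrow(m)
    if (n == 1) return(m)
    p <- min(n - 1, ceiling(3 * sigma))
    N <- stats::nextn(n + 2 * p, c(2, 3, 5))
    pb <- N - n - p
    # clamp reflection sources for pads deeper than n - 1; the clamped
    # region then lies > 3 sigma from every retained pixel
    top <- 2 * m[rep(1, p), , drop = FALSE] -
      m[1 + pmin(p:1, n - 1), , drop = FALSE]
    bot <- 2 * m[rep(n, pb), , drop = FALSE] -
      m[n - pmin(seq_len(pb), n - 1), , drop = FALSE]
    padded <- rbind(top, m, bot)
    d <- seq_len(N) - 1
    d <- pmin(d, N - d)
    k <- exp(-d^2 / (2 * sigma^2))
    k <- k / sum(k)
    K <- stats::fft(k)
    out <- Re(stats::mvfft(stats::mvfft(padded) * K, inverse = TRUE)) / N
    out[(p + 1):(p + n), , drop = FALSE]
  }
  t(blur_rows(t(blur_rows(img))))
}

#' Pseudo-flat-field correction
#'
#' Divides the image elementwise by a heavily smoothed (large-sigma
#' Gaussian) copy of itself, removing slowly varying illumination, then
#' rescales so the global mean is preserved. The output is strictly
#' positive wherever the input is positive.
#'
#' @param img Numeric matrix (non-negative intensities).
#' @param sigma Gaussian sigma in pixels; default one quarter of the
#'   smaller image dimension — far above the bead scale, so beads are not
#'   divided out, while the odd-reflection padding of the blur preserves
#'   (and therefore cancels) linear illumination ramps exactly.
#' @return Corrected matrix of the same shape.
#' @export
pseudo_flat_field <- function(img, sigma = NULL) {
  stopifnot(is.matrix(img), length(img) > 0)
  if (all(img == 0)) stop("cannot flat-field an all-zero image")
  if (is.null(sigma)) sigma <- min(dim(img)) / 4
  smooth <- gaussian_blur(img, sigma)
  smooth <- pmax(smooth, .Machine$double.eps)
  corrected <- img / smooth
  corrected * mean(img) / mean(corrected)
}

#' Background correction of a fluorescence image
#'
#' Subtracts a robust scalar background estimate and clamps at zero. With a
#' bead mask, the background is the median of off-mask pixels; without one,
#' the median of the lowest-decile pixels.
#'
#' @param img Numeric matrix.
#' @param mask Optional logical matrix marking bead (foreground) pixels.
#' @return Corrected matrix, non-negative.
#' @export
background_correct <- function(img, mask = NULL) {
  stopifnot(is.matrix(img), length(img) > 0)
  if (is.null(mask)) {
    cutoff <- stats::quantile(img, 0.1, names = FALSE)
    bg <- stats::median(img[img <= cutoff])
  } else {
    stopifnot(identical(dim(mask), dim(img)))
    if (all(mask)) stop("mask covers every pixel; no background to estimate")
    bg <- stats::median(img[!mask])
  }
  pmax(img - bg, 0)
}

#' Binarize the corrected epi image into a bead mask
#'
#' @param img Flat-field-corrected epi image.
#' @param method `"otsu"` (global two-class variance maximization) or
#'   `"local_mean"` (pixel vs. mean of a square window minus `offset`).
#' @param polarity Whether beads are darker or brighter than background in
#'   the epi image.
#' @param window_radius Half-width of the local-mean window, pixels.
#' @param offset Offset subtracted from the local mean before comparison.
#' @return Logical matrix `B'` (`TRUE` = bead pixel). A constant image
#'   yields an empty mask with a warning.
#' @export
binarize_epi <- function(img, method = c("otsu", "local_mean"),
                         polarity = c("beads_dark", "beads_bright"),
                         window_radius = 15, offset = 0) {
  stopifnot(is.matrix(img))
  method <- match.arg(method)
  polarity <- match.arg(polarity)
  rng <- range(img)
  if (diff(rng) == 0) {
    warning("constant image: returning an empty mask")
    return(matrix(FALSE, nrow(img), ncol(img)))
  }
  if (method == "otsu") {
    norm <- (img - rng[1]) / diff(rng)
    th <- EBImage::otsu(norm, range = c(0, 1))
    if (polarity == "beads_dark") norm < th else norm > th
  } else {
    side <- 2 * window_radius + 1
    kern <- matrix(1 / side^2, side, side)
    local_mean <- EBImage::filter2(img, kern, boundary = "replicate")
    # guard against filter2's ~1e-13 FFT ripple on flat regions
    eps <- 1e-9 * diff(rng)
    if (polarity == "beads_dark") img < local_mean - offset - eps
    else img > local_mean + offset + eps
  }
}

#' The masked RFU/Bead-Area statistic
#'
#' For each fluorescence channel, multiplies the bead mask `B'` elementwise
#' with the background-corrected fluorescence image to give `F'`, sums the
#' mask to `b` (bead area in pixels) and `F'` to `f`, and reports `f / b`.
#' Off-mask signal — debris, quantum-dot aggregates — contributes exactly
#' nothing.
#'
#' @param mask Logical matrix `B'`.
#' @param fluor A numeric matrix or named list of matrices (one per
#'   channel), background-corrected.
#' @return A `mask_stats` object: `b`, named vectors `f` and
#'   `rfu_per_bead_area`, and the mask.
#' @export
rfu_per_bead_area <- function(mask, fluor) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  mask <- mask > 0
  if (is.matrix(fluor)) fluor <- list(signal = fluor)
  b <- sum(mask)
  if (b == 0) stop("empty bead mask: RFU/Bead-Area is undefined (b = 0)")
  f <- vapply(fluor, function(ch) {
    stopifnot(identical(dim(ch), dim(mask)))
    sum(ch[mask])
  }, numeric(1))
  structure(list(b = b, f = f, rfu_per_bead_area = f / b, mask = mask),
            class = "mask_stats")
}

#' Quantify one field of view
#'
#' Runs the full per-FOV procedure: pseudo-flat-field correct the epi
#' image, binarize it to the bead mask, background-correct each
#' fluorescence channel against that mask, and compute RFU/Bead-Area.
#'
#' @param image_pair An `image_pair` (see [render_fov()]) or a list with
#'   `epi` and named `fluor` matrices.
#' @param method,polarity,window_radius,offset Passed to [binarize_epi()].
#' @param flat_field_sigma Passed to [pseudo_flat_field()].
#' @return A `mask_stats` object.
#' @export
quantify_fov <- function(image_pair, method = "otsu",
                         polarity = "beads_dark", flat_field_sigma = NULL,
                         window_radius = 15, offset = 0) {
  epi <- pseudo_flat_field(image_pair$epi, sigma = flat_field_sigma)
  mask <- binarize_epi(epi, method = method, polarity = polarity,
                       window_radius = window_radius, offset = offset)
  corrected <- lapply(image_pair$fluor, background_correct, mask = mask)
  rfu_per_bead_area(mask, corrected)
}

#' Aggregate a detection band across fields of view
#'
#' Quantifies every FOV, averages the per-FOV RFU/Bead-Area channelwise,
#' reports the SEM across FOVs, and — when control FOVs are supplied —
#' subtracts the control band mean channelwise (negative values are
#' preserved so downstream statistics stay unbiased).
#'
#' @param fovs List of `image_pair`s, or of [render_fov()] outputs.
#' @param control_fovs Optional matched control (0 pg/mL) FOVs.
#' @param ... Passed to [quantify_fov()].
#' @return A `band_measurement`: data frame `table` (channel, mean, sem,
#'   n_fov, control_subtracted), matrices `per_fov` and
#'   `control_per_fov` (FOV x channel), and the band label.
#' @export
measure_band <- function(fovs, control_fovs = NULL, ...) {
  unwrap <- function(x) if (!is.null(x$images)) x$images else x
  fovs <- lapply(fovs, unwrap)
  stopifnot(length(fovs) >= 1)
  per_fov_stats <- function(lst) {
    chans <- names(lst[[1]]$fluor)
    rows <- lapply(lst, function(ip) {
      if (!identical(names(ip$fluor), chans)) {
        stop("channel sets differ across FOVs")
      }
      quantify_fov(ip, ...)$rfu_per_bead_area
    })
    do.call(rbind, rows)
  }
  per_fov <- per_fov_stats(fovs)
  n <- nrow(per_fov)
  means <- colMeans(per_fov)
  sem <- if (n >= 2) apply(per_fov, 2, stats::sd) / sqrt(n) else
    rep(NA_real_, ncol(per_fov))
  ctrl_per_fov <- NULL
  ctrl_sub <- rep(NA_real_, length(means))
  if (!is.null(control_fovs)) {
    ctrl_per_fov <- per_fov_stats(lapply(control_fovs, unwrap))
    if (!identical(colnames(ctrl_per_fov), colnames(per_fov))) {
      stop("control FOV channels differ from measurement FOV channels")
    }
    ctrl_sub <- means - colMeans(ctrl_per_fov)
  }
  band <- fovs[[1]]$metadata$band
  structure(
    list(band = if (is.null(band)) NA_character_ else band,
         table = data.frame(channel = colnames(per_fov),
                            rfu_per_bead_area = unname(means),
                            sem = unname(sem), n_fov = n,
                            control_subtracted = unname(ctrl_sub)),
         per_fov = per_fov, control_per_fov = ctrl_per_fov),
    class = "band_measurement")
}

#' @export
print.band_measurement <- function(x, ...) {
  cat(sprintf("Detection band '%s' (%d FOVs)\n", x$band, nrow(x$per_fov)))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write / read an image pair as 16-bit TIFFs
#'
#' Files are named `<band>_<fov>_<channel>.tif` (`epi` is a channel name);
#' intensities are stored as 16-bit unsigned integers, clamped to
#' `[0, 65535]`. Requires the `tiff` package.
#'
#' @param image_pair An `image_pair`.
#' @param dir Output directory (created if needed).
#' @return `write_image_pair()` invisibly returns the written paths;
#'   `read_image_pair()` returns an `image_pair`.
#' @export
write_image_pair <- function(image_pair, dir) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF I/O")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  md <- image_pair$metadata
  stem <- sprintf("%s_%s", md$band, md$fov)
  imgs <- c(list(epi = image_pair$epi), image_pair$fluor)
  paths <- character(0)
  for (ch in names(imgs)) {
    path <- file.path(dir, sprintf("%s_%s.tif", stem, ch))
    tiff::writeTIFF(pmin(pmax(imgs[[ch]], 0), 65535) / 65535, path,
                    bits.per.sample = 16)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' @rdname write_image_pair
#' @param band,fov Band label and FOV index identifying the files.
#' @param channels Fluorescence channel names to read.
#' @param pixel_size Micrometres per pixel to record.
#' @export
read_image_pair <- function(dir, band, fov, channels, pixel_size = 0.325) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF I/O")
  }
  rd <- function(ch) {
    tiff::readTIFF(file.path(dir, sprintf("%s_%s_%s.tif", band, fov, ch))) *
      65535
  }
  structure(
    list(epi = rd("epi"),
         fluor = stats::setNames(lapply(channels, rd), channels),
         pixel_size = pixel_size,
         metadata = list(band = band, fov = fov)),
    class = "image_pair")
}
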