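# Bead diameter characterization from confocal Z-stacks: maximum-intensity
# projection, local thresholding, particle analysis, and equivalent-circle
# diameter statistics.

#' Maximum-intensity Z-projection
#'
#' @param zstack List of numeric matrices of identical shape (the slices).
#' @return Matrix of pixelwise maxima.
#' @export
max_projection <- function(zstack) {
  if (length(zstack) == 0) stop("empty Z-stack")
  dims <- lapply(zstack, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("all slices must share the same shape")
  }
  Reduce(pmax, zstack)
}

# Merge 4-connected labels that touch diagonally, giving 8-connectivity.
# EBImage::bwlabel is 4-connected; a union-find pass over the two diagonal
# shift directions joins components that meet only at corners.
merge_diagonal_labels <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  if (nr < 2 || nc < 2 || max(lab) == 0) return(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc])))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) == 0) return(lab)
  parent <- seq_len(max(lab))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_along(parent), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Segment particles in a projection image
#'
#' Local-mean thresholding (bright particles on a dark background) followed
#' by connected-component labelling and size/edge filters — the standard
#' particle-analysis recipe for sizing mounted beads.
#'
#' @param projection Numeric matrix (maximum-intensity projection).
#' @param pixel_size Micrometres per pixel.
#' @param window_radius Half-width of the local-mean window, pixels.
#' @param offset Pixel must exceed the local mean by this much.
#' @param min_area Drop particles smaller than this, square micrometres.
#' @param exclude_edges Drop particles touching the image border.
#' @param connectivity 8 (default) or 4.
#' @return Numeric vector of particle areas in square micrometres (may be
#'   empty).
#' @export
segment_particles <- function(projection, pixel_size = 0.1,
                              window_radius = 15, offset = 0,
                              min_area = 0, exclude_edges = TRUE,
                              connectivity = 8) {
  stopifnot(is.matrix(projection), pixel_size > 0,
            connectivity %in% c(4, 8))
  if (diff(range(projection)) == 0) return(numeric(0))
  side <- 2 * window_radius + 1
  kern <- matrix(1 / side^2, side, side)
  local_mean <- EBImage::filter2(projection, kern, boundary = "replicate")
  # filter2 is FFT-based; a tiny floor keeps its ~1e-13 ripple from lifting
  # exact-zero background above the local mean
  eps <- 1e-9 * diff(range(projection))
  mask <- projection > pmax(local_mean + offset, min(projection) + eps)
  if (!any(mask)) return(numeric(0))
  lab <- EBImage::bwlabel(mask)
  if (connectivity == 8) lab <- merge_diagonal_labels(lab)
  keep <- seq_len(max(lab))
  if (exclude_edges) {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    keep <- setdiff(keep, border)
  }
  areas_px <- tabulate(lab[lab > 0], nbins = max(lab))[keep]
  areas_um2 <- areas_px * pixel_size^2
  areas_um2[areas_um2 >= min_area]
}

#' Summarize a particle population as equivalent-circle diameters
#'
#' Converts areas to equivalent-circle diameters `d = 2 sqrt(area / pi)`
#' and reports count, mean, sample (n-1) standard deviation and coefficient
#' of variation. With fewer than two particles the dispersion statistics
#' are reported as `NA`.
#'
#' @param areas Numeric vector of particle areas, square micrometres.
#' @return A `bead_population_stats` object.
#' @export
summarize_diameters <- function(areas) {
  stopifnot(is.numeric(areas), all(areas >= 0))
  d <- 2 * sqrt(areas / pi)
  n <- length(d)
  structure(
    list(areas_um2 = areas, diameters_um = d, n = n,
         mean_diameter = if (n >= 1) mean(d) else NA_real_,
         sd_diameter = if (n >= 2) stats::sd(d) else NA_real_,
         cv_diameter = if (n >= 2 && mean(d) > 0) stats::sd(d) / mean(d)
                       else NA_real_),
    class = "bead_population_stats")
}

#' @export
print.bead_population_stats <- function(x, ...) {
  cat(sprintf("Bead population: n = %d, mean diameter %.3f um, sd %.3f um, CV %.1f%%\n",
              x$n, x$mean_diameter, x$sd_diameter, 100 * x$cv_diameter))
  invisible(x)
}
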