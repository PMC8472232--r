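#' Variable-height channel geometry
#'
#' Construct a description of one variable-height microfluidic channel whose
#' ceiling height decreases monotonically from inlet to outlet. Beads trap at
#' the position where their diameter matches the local channel height, so the
#' height profile determines where each detection band forms.
#'
#' @param length Channel length in micrometres (typical device: 20,000).
#' @param width Channel width in micrometres (typical device: 3,000).
#' @param inlet_height Ceiling height at the inlet, micrometres.
#' @param outlet_height Ceiling height at the outlet, micrometres. Must be
#'   positive and smaller than `inlet_height`.
#' @param measured Optional two-column data frame (`position_um`,
#'   `height_um`) of profilometer samples. When supplied, `height_at()`
#'   interpolates the measured profile piecewise-linearly instead of using
#'   the straight line between inlet and outlet; the samples must be ordered
#'   by position, span `[0, length]` and be monotone non-increasing.
#'
#' @return An object of class `channel_profile`.
#' @examples
#' ch <- channel_profile(20000, 3000, inlet_height = 7.583, outlet_height = 2.077)
#' height_at(ch, 10000)
#' @export
channel_profile <- function(length, width, inlet_height, outlet_height,
                            measured = NULL) {
  stopifnot(is.numeric(length), length > 0, is.numeric(width), width > 0)
  if (!(inlet_height > outlet_height && outlet_height > 0)) {
    stop("channel heights must satisfy inlet_height > outlet_height > 0")
  }
  kind <- "linear"
  if (!is.null(measured)) {
    measured <- as.data.frame(measured)
    if (!all(c("position_um", "height_um") %in% names(measured))) {
      stop("measured profile needs columns position_um and height_um")
    }
    pos <- measured$position_um
    h <- measured$height_um
    if (is.unsorted(pos, strictly = TRUE)) {
      stop("measured positions must be strictly increasing")
    }
    if (any(diff(h) > 0)) {
      stop("measured heights must be monotone non-increasing")
    }
    if (pos[1] > 0 || pos[base::length(pos)] < length) {
      stop("measured profile must span [0, length]")
    }
    tol <- 0.05 * (inlet_height - outlet_height)
    if (abs(h[1] - inlet_height) > tol ||
        abs(h[base::length(h)] - outlet_height) > tol) {
      stop("measured endpoint heights disagree with inlet/outlet heights")
    }
    kind <- "measured"
  }
  structure(
    list(length = length, width = width,
         inlet_height = inlet_height, outlet_height = outlet_height,
         profile_kind = kind, measured = measured),
    class = "channel_profile"
  )
}

#' @export
print.channel_profile <- function(x, ...) {
  cat(sprintf(
    "Variable-height channel: %.0f x %.0f um, height %.3f -> %.3f um (%s profile)\n",
    x$length, x$width, x$inlet_height, x$outlet_height, x$profile_kind))
  invisible(x)
}

#' Channel height at a position
#'
#' @param profile A [channel_profile()].
#' @param x Position(s) from the inlet, micrometres, in `[0, length]`.
#' @return Height(s) in micrometres. Linear profiles interpolate between the
#'   inlet and outlet heights; measured profiles interpolate the profilometer
#'   samples piecewise-linearly.
#' @export
height_at <- function(profile, x) {
  stopifnot(inherits(profile, "channel_profile"))
  if (any(x < 0 | x > profile$length)) {
    stop("position outside [0, length]")
  }
  if (profile$profile_kind == "linear") {
    profile$inlet_height +
      (profile$outlet_height - profile$inlet_height) * x / profile$length
  } else {
    stats::approx(profile$measured$position_um, profile$measured$height_um,
                  xout = x, rule = 2)$y
  }
}

#' Assay bead specification
#'
#' @param label Analyte name the bead population reports (e.g. `"GFAP"`).
#' @param diameter_mean Mean bead diameter, micrometres.
#' @param diameter_cv Coefficient of variation of the diameter (fraction,
#'   `0 <= cv < 0.5`).
#' @param fluor_channel Detection-channel label of the bead's quantum-dot
#'   reporter (e.g. `"q585"`).
#' @param n_beads Bead count rendered per simulated field of view
#'   (detection bands are densely packed; the default gives a few percent
#'   areal coverage at the default image scale).
#' @return An object of class `bead_spec`.
#' @export
bead_spec <- function(label, diameter_mean, diameter_cv = 0.03,
                      fluor_channel = "q585", n_beads = 1500) {
  stopifnot(diameter_mean > 0, diameter_cv >= 0, diameter_cv < 0.5,
            n_beads >= 0)
  structure(
    list(label = label, diameter_mean = diameter_mean,
         diameter_cv = diameter_cv, fluor_channel = fluor_channel,
         n_beads = n_beads),
    class = "bead_spec"
  )
}

#' Where a bead of a given diameter traps
#'
#' A bead traps at the unique position where the (monotone decreasing)
#' channel height equals its diameter. A bead at least as large as the inlet
#' height cannot enter the channel; a bead no larger than the outlet height
#' is never pinched and passes through.
#'
#' @param profile A [channel_profile()].
#' @param diameter Bead diameter, micrometres.
#' @return A list with `position` (micrometres from the inlet, `NA` when not
#'   trapped, 0 for inlet exclusion) and `status` (one of `"trapped"`,
#'   `"excluded_at_inlet"`, `"passes_through"`).
#' @export
band_position <- function(profile, diameter) {
  stopifnot(inherits(profile, "channel_profile"), diameter > 0)
  if (diameter >= profile$inlet_height) {
    return(list(position = 0, status = "excluded_at_inlet"))
  }
  if (diameter <= profile$outlet_height) {
    return(list(position = NA_real_, status = "passes_through"))
  }
  if (profile$profile_kind == "linear") {
    x <- (profile$inlet_height - diameter) /
      (profile$inlet_height - profile$outlet_height) * profile$length
  } else {
    # monotone profile: bisect height_at to machine precision
    f <- function(p) height_at(profile, p) - diameter
    x <- stats::uniroot(f, c(0, profile$length), tol = 1e-12)$root
  }
  list(position = x, status = "trapped")
}

#' Plan a multiplex band layout
#'
#' Computes trap positions for a panel of bead specifications and flags
#' layout problems: band pairs closer (centre to centre) than one band width
#' plus the minimum separation, beads that cannot trap, and outlet heights
#' below the design rule (see [design_check()]).
#'
#' @param profile A [channel_profile()].
#' @param beads List of [bead_spec()] objects with distinct diameters.
#' @param band_width Nominal width of one detection band, micrometres.
#' @param min_separation Required clear spacing between bands, micrometres.
#' @param diameter_tol Diameters closer than this are treated as colliding,
#'   micrometres.
#' @return A `band_layout`: a data frame (label, diameter, position, status)
#'   ordered by position, with attributes `feasible` (logical) and
#'   `violations` (character vector).
#' @export
plan_layout <- function(profile, beads, band_width = 500,
                        min_separation = 500, diameter_tol = 0.05) {
  stopifnot(inherits(profile, "channel_profile"), length(beads) >= 1)
  if (inherits(beads, "bead_spec")) beads <- list(beads)
  d <- vapply(beads, function(b) b$diameter_mean, numeric(1))
  labels <- vapply(beads, function(b) b$label, character(1))
  if (any(dist(d) < diameter_tol)) {
    pair <- which(as.matrix(dist(d)) < diameter_tol & upper.tri(diag(length(d))),
                  arr.ind = TRUE)[1, ]
    stop(sprintf("bead diameters collide: %s (%.3g um) vs %s (%.3g um)",
                 labels[pair[1]], d[pair[1]], labels[pair[2]], d[pair[2]]))
  }
  pos <- lapply(d, function(di) band_position(profile, di))
  layout <- data.frame(
    label = labels,
    diameter = d,
    position = vapply(pos, function(p) p$position, numeric(1)),
    status = vapply(pos, function(p) p$status, character(1)),
    stringsAsFactors = FALSE
  )
  layout <- layout[order(layout$position, na.last = TRUE), ]
  rownames(layout) <- NULL

  violations <- character(0)
  not_trapped <- layout$status != "trapped"
  if (any(not_trapped)) {
    violations <- c(violations, sprintf(
      "bead '%s' (%.3g um) %s", layout$label[not_trapped],
      layout$diameter[not_trapped],
      ifelse(layout$status[not_trapped] == "passes_through",
             "passes through the outlet", "is excluded at the inlet")))
  }
  trapped <- layout[layout$status == "trapped", ]
  if (nrow(trapped) >= 2) {
    sep <- diff(trapped$position)
    bad <- sep < band_width + min_separation
    if (any(bad)) {
      violations <- c(violations, sprintf(
        "bands '%s' and '%s' are %.0f um apart (< %.0f um required)",
        trapped$label[which(bad)], trapped$label[which(bad) + 1],
        sep[bad], band_width + min_separation))
    }
  }
  violations <- c(violations, design_check(profile))
  structure(layout, class = c("band_layout", "data.frame"),
            feasible = length(violations) == 0, violations = violations,
            band_width = band_width, min_separation = min_separation)
}

#' Multiplexing capacity of a channel
#'
#' Number of detection bands a channel of the given length can hold when
#' each band occupies `band_width` and bands are spaced by `min_separation`:
#' `floor(length / (band_width + min_separation))`.
#'
#' @param length Channel length, micrometres.
#' @param band_width Band width, micrometres (typical trapped band: ~500).
#' @param min_separation Required spacing between bands, micrometres.
#' @return Integer band count.
#' @examples
#' capacity(20000, 500, 500) # 20-plex in a 20 mm channel
#' @export
capacity <- function(length, band_width = 500, min_separation = 500) {
  if (any(c(length, band_width, min_separation) <= 0)) {
    stop("length, band_width and min_separation must be positive")
  }
  as.integer(floor(length / (band_width + min_separation)))
}

# Hydraulic resistance of the channel in SI units (Pa s / m^3), lubrication
# (wide-slit) limit: R = 12 mu int_0^L dx / (w h(x)^3).
channel_resistance <- function(profile, viscosity,
                               method = c("closed_form", "quadrature")) {
  method <- match.arg(method)
  L <- profile$length * 1e-6
  w <- profile$width * 1e-6
  hi <- profile$inlet_height * 1e-6
  ho <- profile$outlet_height * 1e-6
  if (profile$profile_kind == "linear" && method == "closed_form") {
    if (abs(hi - ho) < .Machine$double.eps * hi) {
      return(12 * viscosity * L / (w * hi^3))
    }
    return((6 * viscosity * L / w) * (1 / ho^2 - 1 / hi^2) / (hi - ho))
  }
  integrand <- function(x_um) 1 / (height_at(profile, x_um) * 1e-6)^3
  # integrate over position in um, convert dx to metres afterwards
  I <- stats::integrate(integrand, 0, profile$length,
                        rel.tol = 1e-12, abs.tol = 0,
                        subdivisions = 500L)$value * 1e-6
  12 * viscosity * I / w
}

#' Volumetric flow rate through a variable-height channel
#'
#' Pressure-driven flow in the lubrication (wide-slit, `width >> height`)
#' regime: `Q = dP / R` with hydraulic resistance
#' `R = 12 mu \int dx / (w h(x)^3)`. For a linear height profile the
#' integral has the closed form
#' `R = (6 mu L / w) (1/h_o^2 - 1/h_i^2) / (h_i - h_o)`, which reduces to
#' the plane-Poiseuille slit formula `12 mu L / (w h^3)` as
#' `h_i -> h_o`. Because resistance is dominated by the narrowest part of
#' the channel (the `h^-3` weighting), flow rate is controlled mainly by
#' the outlet height; widening the inlet does little.
#'
#' @param profile A [channel_profile()]. A degenerate profile cannot be
#'   constructed (heights must strictly decrease); to model a uniform slit,
#'   pass `uniform_height`.
#' @param pressure_drop Applied pressure difference, Pa.
#' @param viscosity Dynamic viscosity, Pa s (water: ~1e-3).
#' @param method `"closed_form"` (linear profiles; exact) or
#'   `"quadrature"` (adaptive numerical integration of the resistance
#'   integral; required for measured profiles).
#' @param uniform_height If supplied (micrometres), ignore `profile` and use
#'   a uniform slit of this height with `profile`'s length and width — the
#'   degenerate equal-heights limit.
#' @return Flow rate in microlitres per minute.
#' @export
flow_rate <- function(profile, pressure_drop, viscosity,
                      method = c("closed_form", "quadrature"),
                      uniform_height = NULL) {
  stopifnot(pressure_drop > 0, viscosity > 0)
  method <- match.arg(method)
  if (!is.null(uniform_height)) {
    stopifnot(uniform_height > 0)
    L <- profile$length * 1e-6; w <- profile$width * 1e-6
    h <- uniform_height * 1e-6
    R <- 12 * viscosity * L / (w * h^3)
  } else {
    stopifnot(inherits(profile, "channel_profile"))
    R <- channel_resistance(profile, viscosity, method)
  }
  q_m3s <- pressure_drop / R
  q_m3s * 1e9 * 60  # m^3/s -> uL/min
}

#' Check a channel against the band-formation design rules
#'
#' The one hard rule: the outlet height should be at least 1.5 micrometres.
#' Narrower outlets throttle the flow (resistance scales as the inverse
#' cube of the local height, so the outlet dominates), slowing band
#' formation and risking bead aggregation and wall adsorption.
#'
#' @param profile A [channel_profile()].
#' @param min_outlet Minimum acceptable outlet height, micrometres.
#' @return Character vector of violations (empty when the design passes).
#' @export
design_check <- function(profile, min_outlet = 1.5) {
  stopifnot(inherits(profile, "channel_profile"))
  out <- character(0)
  if (profile$outlet_height < min_outlet) {
    out <- c(out, sprintf(
      paste0("outlet height %.3f um is below %.1f um: flow is throttled by ",
             "the outlet, so bands form slowly and beads risk aggregating ",
             "or adsorbing to the walls"),
      profile$outlet_height, min_outlet))
  }
  out
}

#' Read or write channel geometry
#'
#' JSON files carry `{length_um, width_um, inlet_um, outlet_um}`; CSV files
#' carry a measured profile with columns `position_um, height_um`.
#'
#' @param path File path (`.json` or `.csv`).
#' @param profile A [channel_profile()] (for writing).
#' @param ... For CSV reads: `width` (micrometres), required since a profile
#'   trace carries no width.
#' @return `read_channel()` returns a [channel_profile()];
#'   `write_channel()` returns `path` invisibly.
#' @export
read_channel <- function(path, ...) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    channel_profile(j$length_um, j$width_um, j$inlet_um, j$outlet_um)
  } else {
    prof <- utils::read.csv(path)
    args <- list(...)
    if (is.null(args$width)) stop("reading a CSV profile requires width=")
    n <- nrow(prof)
    channel_profile(prof$position_um[n], args$width,
                    prof$height_um[1], prof$height_um[n], measured = prof)
  }
}

#' @rdname read_channel
#' @export
write_channel <- function(profile, path) {
  stopifnot(inherits(profile, "channel_profile"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(length_um = profile$length, width_um = profile$width,
           inlet_um = profile$inlet_height, outlet_um = profile$outlet_height),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    prof <- profile$measured
    if (is.null(prof)) {
      x <- seq(0, profile$length, length.out = 101)
      prof <- data.frame(position_um = x, height_um = height_at(profile, x))
    }
    utils::write.csv(prof, path, row.names = FALSE)
  }
  invisible(path)
}
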