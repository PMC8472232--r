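# Assay statistics: monotone standard curves, limits of detection,
# intra- and inter-assay coefficients of variation, the crossover
# false-positive t-test, and method comparison against a reference assay.

#' Fit a standard curve
#'
#' Default model is the four-parameter logistic (4PL)
#' `r(c) = d + (a - d) / (1 + (c / c0)^b)` — the workhorse of sandwich
#' immunoassay calibration — fitted by Levenberg-Marquardt least squares;
#' `a` is the zero-concentration asymptote, `d` the saturation asymptote,
#' `c0` the inflection concentration and `b` the slope factor. A
#' linear-in-log10-concentration fallback is available for sparse curves.
#' Fits that are not monotone non-decreasing are refused.
#'
#' @param concentrations Calibrator concentrations, pg/mL (replicates
#'   allowed; 4PL needs >= 4 distinct values including 0, linear_log >= 2
#'   distinct nonzero values).
#' @param responses Matching responses (RFU/Bead-Area).
#' @param model `"four_parameter_logistic"` or `"linear_log"`.
#' @return A `standard_curve`: model name, named `params`, per-calibrator
#'   means and SEMs, and `residual_sd`.
#' @export
fit_standard_curve <- function(concentrations, responses,
                               model = c("four_parameter_logistic",
                                         "linear_log")) {
  model <- match.arg(model)
  stopifnot(length(concentrations) == length(responses),
            all(concentrations >= 0))
  agg <- stats::aggregate(responses,
                          by = list(concentration = concentrations), mean)
  names(agg)[2] <- "mean_response"
  sem <- stats::aggregate(responses,
                          by = list(concentration = concentrations),
                          function(v) if (length(v) >= 2)
                            stats::sd(v) / sqrt(length(v)) else NA_real_)
  agg$sem <- sem$x

  if (model == "four_parameter_logistic") {
    if (length(unique(concentrations)) < 4 || !any(concentrations == 0)) {
      stop("4PL needs at least 4 distinct concentrations including 0")
    }
    df <- data.frame(c = concentrations, r = responses)
    start <- list(a = min(agg$mean_response), d = max(agg$mean_response),
                  c0 = stats::median(concentrations[concentrations > 0]),
                  b = 1)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        r ~ d + (a - d) / (1 + (c / c0)^b), data = df, start = start,
        lower = c(a = -Inf, d = -Inf, c0 = 1e-9, b = 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) stop(
        "4PL fit did not converge (start: ",
        paste(sprintf("%s=%.4g", names(start), unlist(start)),
              collapse = ", "),
        "; bounds: c0 > 0, b > 0): ", conditionMessage(e)))
    p <- stats::coef(fit)
    if (!(p[["d"]] > p[["a"]] && p[["b"]] > 0)) {
      stop("fitted 4PL is not monotone non-decreasing in concentration")
    }
    resid_sd <- stats::sigma(fit)
    params <- p
  } else {
    pos <- concentrations > 0
    if (any(!pos)) {
      warning("linear_log drops zero-concentration calibrators")
    }
    if (length(unique(concentrations[pos])) < 2) {
      stop("linear_log needs at least 2 distinct nonzero concentrations")
    }
    lf <- stats::lm(responses[pos] ~ log10(concentrations[pos]))
    co <- stats::coef(lf)
    if (co[2] < 0) {
      stop("fitted linear_log curve is decreasing in concentration")
    }
    params <- c(intercept = unname(co[1]), slope = unname(co[2]))
    resid_sd <- stats::sigma(lf)
  }
  structure(
    list(model = model, params = params, calibrators = agg,
         residual_sd = resid_sd,
         range = range(concentrations)),
    class = "standard_curve")
}

#' Predicted response of a fitted standard curve
#'
#' @param object A `standard_curve`.
#' @param concentration Concentration(s), pg/mL.
#' @param ... Unused.
#' @return Predicted response(s).
#' @export
predict.standard_curve <- function(object, concentration, ...) {
  p <- object$params
  if (object$model == "four_parameter_logistic") {
    unname(p["d"] + (p["a"] - p["d"]) / (1 + (concentration / p["c0"])^p["b"]))
  } else {
    unname(p["intercept"] + p["slope"] * log10(concentration))
  }
}

#' Invert a standard curve: signal to concentration
#'
#' Unique inverse of the monotone fitted model. Signals at or below the
#' blank asymptote are flagged `below_range` (reported `NA`); signals at or
#' above the saturation asymptote are flagged `above_range`.
#'
#' @param curve A `standard_curve`.
#' @param signal Response value(s), RFU/Bead-Area.
#' @return Numeric concentration(s) in pg/mL, `NA` where out of range, with
#'   a `status` attribute (`"ok"`, `"below_range"`, `"above_range"`).
#' @export
inverse_concentration <- function(curve, signal) {
  stopifnot(inherits(curve, "standard_curve"))
  p <- curve$params
  if (curve$model == "four_parameter_logistic") {
    a <- p[["a"]]; d <- p[["d"]]; c0 <- p[["c0"]]; b <- p[["b"]]
    status <- ifelse(signal <= a, "below_range",
                     ifelse(signal >= d, "above_range", "ok"))
    conc <- ifelse(status == "ok",
                   c0 * ((a - signal) / (signal - d))^(1 / b), NA_real_)
  } else {
    status <- rep("ok", length(signal))
    conc <- 10^((signal - p[["intercept"]]) / p[["slope"]])
  }
  structure(conc, status = status)
}

#' Limit of detection
#'
#' Signal LOD is the blank mean plus three standard deviations (sample sd);
#' the concentration LOD is obtained by inverting the standard curve at
#' that signal. Ten blank replicates is the conventional sample size; other
#' counts are accepted with a warning.
#'
#' @param blank_signals Blank (0 pg/mL) responses, >= 2 values.
#' @param curve Optional `standard_curve` for the concentration-unit LOD.
#' @return A `lod_result`: `blank_mean`, `blank_sd`, `n_blank`,
#'   `signal_lod`, `concentration_lod` (`NA` without a curve or when out of
#'   the curve's range) and `status`.
#' @export
lod <- function(blank_signals, curve = NULL) {
  n <- length(blank_signals)
  if (n < 2) stop("LOD needs at least 2 blank replicates")
  if (n != 10) warning("LOD conventionally uses 10 blanks; got ", n)
  m <- mean(blank_signals)
  s <- stats::sd(blank_signals)
  signal_lod <- m + 3 * s
  conc <- NA_real_; status <- "no_curve"
  if (!is.null(curve)) {
    cl <- inverse_concentration(curve, signal_lod)
    conc <- as.numeric(cl)
    status <- attr(cl, "status")
  }
  structure(list(blank_mean = m, blank_sd = s, n_blank = n,
                 signal_lod = signal_lod, concentration_lod = conc,
                 status = status),
            class = "lod_result")
}

#' @export
print.lod_result <- function(x, ...) {
  cat(sprintf("LOD: signal %.4g (blank %.4g + 3 x sd %.4g, n = %d)",
              x$signal_lod, x$blank_mean, x$blank_sd, x$n_blank))
  if (!is.na(x$concentration_lod)) {
    cat(sprintf("; concentration %.4g pg/mL", x$concentration_lod))
  }
  cat("\n")
  invisible(x)
}

#' Intra-assay coefficient of variation
#'
#' Sample sd divided by the mean of same-day replicates of one sample.
#'
#' @param replicates Replicate responses (>= 2).
#' @return CV as a fraction (`NA` if the mean is zero).
#' @export
intra_assay_cv <- function(replicates) {
  if (length(replicates) < 2) stop("intra-assay CV needs >= 2 replicates")
  m <- mean(replicates)
  if (m == 0) return(NA_real_)
  stats::sd(replicates) / m
}

#' Inter-assay coefficient of variation
#'
#' Arithmetic mean of the per-day CVs of the same sample across days
#' (conventionally three).
#'
#' @param per_day_cvs One CV per day, as fractions.
#' @return Mean CV as a fraction.
#' @export
inter_assay_cv <- function(per_day_cvs) {
  if (length(per_day_cvs) < 2) {
    warning("inter-assay CV conventionally uses >= 2 days; got ",
            length(per_day_cvs))
  }
  mean(per_day_cvs)
}

#' Crossover false-positive test
#'
#' Two-sample two-tailed t-test comparing a detection band's responses
#' between two conditions (e.g. a co-analyte present vs. absent, with the
#' band's own analyte at zero in both). A non-significant result indicates
#' that bead carryover into the band does not generate a false positive.
#'
#' @param band_values_a,band_values_b Per-FOV responses under each
#'   condition (>= 2 each).
#' @param var_equal Pooled-variance Student's t (default) or Welch.
#' @return List with `t`, `df`, `p_value` and `method`.
#' @export
crossover_test <- function(band_values_a, band_values_b, var_equal = TRUE) {
  stopifnot(length(band_values_a) >= 2, length(band_values_b) >= 2)
  if (stats::sd(band_values_a) == 0 && stats::sd(band_values_b) == 0) {
    stop("both groups have zero variance; t-test undefined")
  }
  ht <- stats::t.test(band_values_a, band_values_b, var.equal = var_equal,
                      alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, method = ht$method)
}

#' Compare a test method against a reference method
#'
#' Ordinary least-squares trend of test vs. reference concentrations over
#' paired samples, plus the mean bias relative to the identity line. A
#' slope below one with negative bias is the signature of a test assay that
#' systematically underestimates the reference (for example when it detects
#' only a subset of the analyte forms the reference detects).
#'
#' @param reference_concs Reference-method concentrations, pg/mL.
#' @param test_concs Paired test-method concentrations, pg/mL (>= 3 pairs).
#' @return List with `slope`, `intercept`, `mean_bias`
#'   (`mean(test - reference)`), `r_squared` and the `lm` fit.
#' @export
method_comparison <- function(reference_concs, test_concs) {
  stopifnot(length(reference_concs) == length(test_concs),
            length(reference_concs) >= 3)
  fit <- stats::lm(test_concs ~ reference_concs)
  co <- stats::coef(fit)
  list(slope = unname(co[2]), intercept = unname(co[1]),
       mean_bias = mean(test_concs - reference_concs),
       r_squared = suppressWarnings(summary(fit)$r.squared), fit = fit)
}
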