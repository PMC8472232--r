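# Reagent stoichiometry for adding an analyte to the multiplex panel. Every
# assay in the panel uses one fixed ratio chain relative to the highest
# analyte amount the assay must resolve: 5x molar excess of capture
# antibody, 10x molar excess of detection antibody, and 2x molar excess of
# quantum dots over detection antibody.

#' Design the reagent recipe for one assay
#'
#' Computes the maximum analyte amount in moles from the top-of-range
#' concentration and sample volume, applies the fixed molar-excess chain
#' (capture 5x, detection 10x, quantum dot 2x detection = 20x analyte),
#' and, where stock concentrations are given, converts moles to pipettable
#' volumes.
#'
#' @param analyte Analyte name.
#' @param max_concentration Highest analyte concentration the assay must
#'   resolve, pg/mL.
#' @param sample_volume Sample volume per reaction, microlitres.
#' @param analyte_molar_mass Analyte molar mass, g/mol (required).
#' @param capture_stock_mg_ml,detection_stock_mg_ml Antibody stock
#'   concentrations, mg/mL (optional; volumes reported when given).
#' @param antibody_molar_mass Antibody molar mass, g/mol. Defaults to
#'   150,000 (intact IgG); the output flags when the default was used.
#' @param qdot_stock_um Quantum-dot stock molarity, micromolar (optional).
#' @return An `assay_recipe`: moles of analyte and of each reagent, the
#'   ratio chain, and volumes (microlitres) where stocks were supplied.
#' @examples
#' design_recipe("GFAP", max_concentration = 10000, sample_volume = 100,
#'               analyte_molar_mass = 50000)
#' @export
design_recipe <- function(analyte, max_concentration, sample_volume,
                          analyte_molar_mass,
                          capture_stock_mg_ml = NULL,
                          detection_stock_mg_ml = NULL,
                          antibody_molar_mass = 150000,
                          qdot_stock_um = NULL) {
  if (missing(analyte_molar_mass) || is.null(analyte_molar_mass) ||
      is.na(analyte_molar_mass)) {
    stop("analyte_molar_mass is required (g/mol)")
  }
  stopifnot(max_concentration > 0, sample_volume > 0,
            analyte_molar_mass > 0, antibody_molar_mass > 0)
  # pg/mL x uL -> g: conc * (vol/1000) pg = conc * vol * 1e-15 g
  analyte_g <- max_concentration * sample_volume * 1e-15
  analyte_mol <- analyte_g / analyte_molar_mass
  capture_mol <- 5 * analyte_mol
  detection_mol <- 10 * analyte_mol
  qdot_mol <- 2 * detection_mol

  vol_ab_ul <- function(mol, stock_mg_ml) {
    if (is.null(stock_mg_ml)) return(NA_real_)
    stopifnot(stock_mg_ml > 0)
    mol * antibody_molar_mass * 1e6 / stock_mg_ml  # g -> mg/(mg/mL) -> uL
  }
  qdot_vol_ul <- if (is.null(qdot_stock_um)) NA_real_ else {
    stopifnot(qdot_stock_um > 0)
    qdot_mol * 1e12 / qdot_stock_um  # mol / (uM * 1e-6 mol/L) -> L -> uL
  }
  structure(
    list(analyte = analyte,
         max_concentration_pg_ml = max_concentration,
         sample_volume_ul = sample_volume,
         analyte_mol = analyte_mol,
         capture_mol = capture_mol,
         detection_mol = detection_mol,
         qdot_mol = qdot_mol,
         ratios = c(capture_to_analyte = 5, detection_to_analyte = 10,
                    qdot_to_detection = 2),
         capture_volume_ul = vol_ab_ul(capture_mol, capture_stock_mg_ml),
         detection_volume_ul = vol_ab_ul(detection_mol,
                                         detection_stock_mg_ml),
         qdot_volume_ul = qdot_vol_ul,
         antibody_molar_mass = antibody_molar_mass,
         antibody_molar_mass_defaulted =
           missing(antibody_molar_mass)),
    class = "assay_recipe")
}

#' @export
print.assay_recipe <- function(x, ...) {
  cat(sprintf("Assay recipe for %s (top of range %.4g pg/mL in %.4g uL)\n",
              x$analyte, x$max_concentration_pg_ml, x$sample_volume_ul))
  cat(sprintf("  analyte:   %.3e mol\n", x$analyte_mol))
  cat(sprintf("  capture:   %.3e mol (5x analyte)%s\n", x$capture_mol,
              if (!is.na(x$capture_volume_ul))
                sprintf(" -> %.3g uL", x$capture_volume_ul) else ""))
  cat(sprintf("  detection: %.3e mol (10x analyte)%s\n", x$detection_mol,
              if (!is.na(x$detection_volume_ul))
                sprintf(" -> %.3g uL", x$detection_volume_ul) else ""))
  cat(sprintf("  quantum dot: %.3e mol (2x detection)%s\n", x$qdot_mol,
              if (!is.na(x$qdot_volume_ul))
                sprintf(" -> %.3g uL", x$qdot_volume_ul) else ""))
  if (x$antibody_molar_mass_defaulted) {
    cat("  note: antibody molar mass defaulted to 150 kDa (intact IgG)\n")
  }
  invisible(x)
}
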