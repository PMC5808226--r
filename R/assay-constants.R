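#' Physical constants of the oocyte swelling assay
#'
#' Bundles the five constants that convert an initial rate of relative volume
#' change into a membrane permeability: the initial oocyte volume `v0`
#' (cm^3), the oocyte surface area `s` (cm^2), the molar volume of water `vw`
#' (cm^3/mol), and the internal/external osmolalities `osm_in` / `osm_out`
#' (mmol/kg). Defaults are the standard values for stage V-VI Xenopus laevis
#' oocytes transferred into a 3-fold dilution of 1X Ringer's solution:
#' v0 = 9e-4 cm^3, s = 0.045 cm^2, vw = 18 cm^3/mol, osm_in = 202 mmol/kg,
#' osm_out = 59 mmol/kg.
#'
#' Osmolalities are bridged to molar concentrations assuming 1 kg of water
#' occupies 1000 cm^3, so 1 mmol/kg = 1e-6 mol/cm^3.
#'
#' @param v0 Initial oocyte volume, cm^3. Strictly positive.
#' @param s Oocyte surface area, cm^2. Strictly positive.
#' @param vw Molar volume of water, cm^3/mol. Strictly positive.
#' @param osm_in Initial internal osmolality, mmol/kg. Strictly positive.
#' @param osm_out Bath osmolality, mmol/kg. Strictly positive.
#'
#' @return An object of class `assay_constants`: a named list with the five
#'   fields above.
#' @examples
#' assay_constants()
#' assay_constants(osm_out = 202) # isotonic bath (no osmotic gradient)
#' @export
assay_constants <- function(v0 = 9e-4, s = 0.045, vw = 18,
                            osm_in = 202, osm_out = 59) {
  vals <- c(v0 = v0, s = s, vw = vw, osm_in = osm_in, osm_out = osm_out)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    bad <- names(vals)[!is.finite(vals) | vals <= 0]
    stop("assay constants must be finite and strictly positive; offending: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(v0 = v0, s = s, vw = vw, osm_in = osm_in, osm_out = osm_out),
            class = "assay_constants")
}

#' @export
print.assay_constants <- function(x, ...) {
  cat("Oocyte swelling assay constants\n")
  cat(sprintf("  v0      %.3g cm^3\n", x$v0))
  cat(sprintf("  s       %.3g cm^2\n", x$s))
  cat(sprintf("  vw      %.3g cm^3/mol\n", x$vw))
  cat(sprintf("  osm_in  %.4g mmol/kg\n", x$osm_in))
  cat(sprintf("  osm_out %.4g mmol/kg\n", x$osm_out))
  invisible(x)
}

# mmol/kg -> mol/cm^3 under the 1 kg water = 1000 cm^3 convention
.osm_to_mol_cm3 <- function(osm_mmol_kg) osm_mmol_kg * 1e-6

.check_constants <- function(constants) {
  if (!inherits(constants, "assay_constants")) {
    stop("`constants` must be created with assay_constants()", call. = FALSE)
  }
  constants
}
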