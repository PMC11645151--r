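#' Constants of the Gomez intraglomerular model
#'
#' The Gomez equations back out intraglomerular quantities from measured
#' GFR, renal plasma flow, hematocrit, total protein and mean arterial
#' pressure under stated assumptions: a fixed Bowman-space hydrostatic
#' pressure `P_Bow`, a whole-kidney glomerular ultrafiltration coefficient
#' `K_FG`, and a conversion factor of 1328 from mmHg.s/mL to
#' dyne.s.cm^-5 for the arteriolar resistances.
#'
#' @param P_Bow Bowman space pressure, mmHg (default 10).
#' @param K_FG Ultrafiltration coefficient, mL/s/mmHg (default 0.1012; a
#'   disease-specific value may be supplied).
#' @param resistance_conversion Factor to dyne.s.cm^-5 (default 1328).
#' @param pah_extraction Default PAH extraction fraction (0.85).
#' @return A list of class `gomez_constants`.
#' @export
gomez_constants <- function(P_Bow = 10, K_FG = 0.1012,
                            resistance_conversion = 1328,
                            pah_extraction = 0.85) {
  vals <- c(P_Bow, K_FG, resistance_conversion, pah_extraction)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all Gomez constants must be positive")
  structure(list(P_Bow = P_Bow, K_FG = K_FG,
                 resistance_conversion = resistance_conversion,
                 pah_extraction = pah_extraction),
            class = "gomez_constants")
}

#' Gomez intraglomerular hemodynamic profile
#'
#' Computes filtration fraction FF = GFR/RPF, renal blood flow
#' RBF = RPF/(1 - Hct), transglomerular pressure difference
#' dP_F = GFR / K_FG (flows in mL/s), mean intracapillary plasma protein
#' concentration C_M = (TP/FF) ln(1/(1 - FF)), glomerular oncotic pressure
#' pi_G = 5 (C_M - 2), intraglomerular pressure
#' P_GLO = dP_F + P_Bow + pi_G, and the afferent/efferent arteriolar
#' resistances R_A = ((MAP - P_GLO)/RBF) x 1328 and
#' R_E = (GFR / (K_FG (RBF - GFR))) x 1328 (flows in mL/s inside the
#' resistance expressions; results in dyne.s.cm^-5). Renal vascular
#' resistance RVR = MAP/RBF (mmHg.min/mL) is included.
#'
#' @param gfr GFR, mL/min.
#' @param rpf Renal plasma flow, mL/min.
#' @param map_pressure Mean arterial pressure, mmHg.
#' @param hct Hematocrit as a fraction in (0, 1).
#' @param total_protein Plasma total protein, g/dL.
#' @param constants A [gomez_constants()] object.
#' @return An object of class `hemodynamic_profile` with all inputs,
#'   intermediates and outputs.
#' @examples
#' gomez_profile(gfr = 147, rpf = 600, map_pressure = 93,
#'               hct = 0.42, total_protein = 7.0)
#' @export
gomez_profile <- function(gfr, rpf, map_pressure, hct, total_protein,
                          constants = gomez_constants()) {
  stopifnot(inherits(constants, "gomez_constants"))
  if (gfr < 0 || rpf <= 0) stop("GFR must be >= 0 and RPF > 0")
  if (hct <= 0 || hct >= 1) stop("hematocrit must be a fraction in (0, 1)")
  ff <- gfr / rpf
  if (ff <= 0 || ff >= 1)
    stop("filtration fraction GFR/RPF must lie in (0, 1); got ",
         signif(ff, 4))
  rbf <- rpf / (1 - hct)
  if (rbf <= gfr) stop("renal blood flow must exceed GFR")
  gfr_s <- gfr / 60
  rbf_s <- rbf / 60
  dpf <- gfr_s / constants$K_FG
  cm <- (total_protein / ff) * log(1 / (1 - ff))
  pi_g <- 5 * (cm - 2)
  p_glo <- dpf + constants$P_Bow + pi_g
  if (map_pressure <= p_glo)
    stop("mean arterial pressure must exceed intraglomerular pressure ",
         sprintf("(MAP %.1f <= P_GLO %.1f mmHg)", map_pressure, p_glo))
  ra <- ((map_pressure - p_glo) / rbf_s) * constants$resistance_conversion
  re <- (gfr_s / (constants$K_FG * (rbf_s - gfr_s))) *
    constants$resistance_conversion
  structure(list(GFR = gfr, RPF = rpf, FF = ff, RBF = rbf,
                 dP_F = dpf, C_M = cm, pi_G = pi_g, P_GLO = p_glo,
                 R_A = ra, R_E = re,
                 RVR = compute_rvr(map_pressure, rbf),
                 MAP = map_pressure, Hct = hct,
                 total_protein = total_protein,
                 constants = constants),
            class = "hemodynamic_profile")
}

#' @export
print.hemodynamic_profile <- function(x, ...) {
  cat("Gomez intraglomerular hemodynamic profile\n")
  cat(sprintf("  GFR %.1f  RPF %.1f  RBF %.1f mL/min   FF %.3f\n",
              x$GFR, x$RPF, x$RBF, x$FF))
  cat(sprintf("  dP_F %.2f  pi_G %.2f  P_GLO %.2f mmHg (P_Bow %.1f)\n",
              x$dP_F, x$pi_G, x$P_GLO, x$constants$P_Bow))
  cat(sprintf("  R_A %.0f  R_E %.0f dyne.s.cm-5   RVR %.4f mmHg.min/mL\n",
              x$R_A, x$R_E, x$RVR))
  invisible(x)
}

#' Renal vascular resistance
#'
#' RVR = mean arterial pressure / renal blood flow.
#'
#' @param map_pressure Mean arterial pressure, mmHg.
#' @param rbf Renal blood flow, mL/min.
#' @return RVR in mmHg.min/mL.
#' @export
compute_rvr <- function(map_pressure, rbf) {
  if (!is.finite(rbf) || rbf <= 0) stop("renal blood flow must be > 0")
  map_pressure / rbf
}
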