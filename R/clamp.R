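#' M-value from a hyperinsulinemic-euglycemic clamp stage
#'
#' The M-value is the mean glucose infusion rate (GIR, mg/kg/min) over the
#' steady-state window of an insulin stage; it indexes whole-body insulin
#' sensitivity. With `normalization = "lean"` the rate is re-expressed per
#' kg of lean mass (mg/lean kg/min).
#'
#' @param times GIR sampling times, minutes from stage start.
#' @param gir GIR values, mg/kg/min (per kg total body weight).
#' @param steady_window Length-2 window in minutes; default the final 30
#'   minutes of the series.
#' @param normalization "total" or "lean".
#' @param weight,lean_mass Body weight and lean mass in kg (needed for lean
#'   normalization).
#' @return M-value in mg/kg/min (or mg/lean kg/min).
#' @examples
#' m_value(seq(0, 120, 5), rep(10, 25))
#' @export
m_value <- function(times, gir, steady_window = NULL,
                    normalization = c("total", "lean"),
                    weight = NULL, lean_mass = NULL) {
  normalization <- match.arg(normalization)
  if (length(times) != length(gir)) stop("times and gir differ in length")
  if (is.null(steady_window))
    steady_window <- c(max(times) - 30, max(times))
  sel <- times >= steady_window[1L] & times <= steady_window[2L]
  if (sum(sel) < 3L)
    stop("need at least 3 GIR samples inside the steady-state window")
  m <- mean(gir[sel])
  if (normalization == "lean") {
    if (is.null(weight) || is.null(lean_mass) || weight <= 0 ||
        lean_mass <= 0)
      stop("lean normalization requires positive weight and lean_mass")
    m <- m * weight / lean_mass
  }
  m
}

#' Percent suppression of nonesterified fatty acids under insulin
#'
#' 100 (baseline - steady) / baseline; attenuated suppression marks adipose
#' insulin resistance. Negative values (a rise under insulin) are allowed.
#'
#' @param baseline,steady NEFA concentrations (uM); baseline must be > 0.
#' @return Suppression in percent.
#' @export
nefa_suppression <- function(baseline, steady) {
  if (!is.finite(baseline) || baseline <= 0)
    stop("baseline NEFA must be > 0")
  100 * (baseline - steady) / baseline
}

#' Muscle mass from appendicular lean mass
#'
#' Linear calibration muscle = a x ALM + b applied to DXA appendicular lean
#' mass (sum of arm and leg lean mass, kg). The additive constant is -0.63
#' kg; the multiplier belongs to the cited external calibration family and
#' must be chosen deliberately (default 1.13), so both coefficients are
#' echoed in the result.
#'
#' @param appendicular_lean ALM in kg, > 0.
#' @param a,b Calibration coefficients.
#' @return Muscle mass (kg) with attribute `"coefficients"`.
#' @export
muscle_mass <- function(appendicular_lean, a = 1.13, b = -0.63) {
  if (appendicular_lean <= 0) stop("appendicular lean mass must be > 0")
  structure(a * appendicular_lean + b, coefficients = c(a = a, b = b))
}
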