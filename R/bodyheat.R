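#' Body surface area (Mosteller)
#'
#' `sqrt(height_cm * mass_kg / 3600)`.
#'
#' @param height_cm Height in cm, > 0.
#' @param mass_kg Body mass in kg, > 0.
#' @return Body surface area in m^2.
#' @examples
#' bsa_mosteller(179, 79.5) # ~2.0 m^2
#' @export
bsa_mosteller <- function(height_cm, mass_kg) {
  if (any(height_cm <= 0) || any(mass_kg <= 0)) {
    stop("height and mass must be > 0", call. = FALSE)
  }
  sqrt(height_cm * mass_kg / 3600)
}

#' Whole-body sweat loss from mass balance
#'
#' Change in nude body mass from pre- to post-exercise, corrected for fluid
#' intake and urine output, with 1 kg of mass change equated to 1 L. A
#' negative result (net mass gain) is returned as-is with a warning.
#'
#' @param mass_pre,mass_post Nude body mass before/after exercise (kg).
#' @param fluid_in Fluid intake during exercise (L).
#' @param urine_out Urine output during exercise (L).
#' @return Sweat loss in litres.
#' @export
wbsl <- function(mass_pre, mass_post, fluid_in = 0, urine_out = 0) {
  if (any(c(mass_pre, mass_post, fluid_in, urine_out) < 0)) {
    stop("masses and volumes must be >= 0", call. = FALSE)
  }
  out <- (mass_pre - mass_post) + fluid_in - urine_out
  if (any(out < 0)) {
    warning("negative sweat loss (net mass gain); check inputs",
            call. = FALSE)
  }
  out
}

#' Whole-body sweat rate
#'
#' Sweat loss divided by exercise duration, expressed per hour.
#'
#' @param wbsl Sweat loss (L).
#' @param duration Exercise duration (min), > 0.
#' @return Sweat rate in L/h.
#' @examples
#' wbsr(1.67, 82.8) # ~1.21 L/h
#' @export
wbsr <- function(wbsl, duration) {
  if (any(duration <= 0)) stop("duration must be > 0", call. = FALSE)
  wbsl / (duration / 60)
}

#' Metabolic heat production from oxygen uptake
#'
#' Partitional-calorimetry estimate of metabolic rate from oxygen uptake and
#' the respiratory exchange ratio, using the non-protein energy equivalents
#' of oxygen (21.13 kJ/L for carbohydrate at RER 1.0, 19.62 kJ/L for fat at
#' RER 0.7, linearly interpolated). External work on a graded treadmill is
#' `mass * g * speed * grade` (small-angle approximation `sin(theta) ~
#' grade`; at a 2 percent grade the error is negligible). Net heat production
#' is metabolic rate minus external work; both are reported, absolute and per
#' unit body surface area.
#'
#' @param vo2 Oxygen uptake (L/min), > 0.
#' @param rer Respiratory exchange ratio; values outside \[0.7, 1.0\] are
#'   clamped with a warning.
#' @param mass_kg Body mass (kg).
#' @param speed_kmh Treadmill speed (km/h); the standard test uses 5.
#' @param grade Fractional grade (0.02 for the standard test), >= 0.
#' @param bsa Body surface area (m^2) for normalisation.
#' @return A one-row `data.frame` with `metabolic_rate` (W), `external_work`
#'   (W), `net_heat_production` (W) and `per_bsa` (W/m^2, net per BSA).
#' @examples
#' metabolic_heat_production(2.0, 1.0, 80, 5, 0.02, 2.0)
#' @export
metabolic_heat_production <- function(vo2, rer, mass_kg, speed_kmh = 5,
                                      grade = 0.02, bsa) {
  if (any(vo2 <= 0)) stop("vo2 must be > 0", call. = FALSE)
  if (any(grade < 0)) stop("grade must be >= 0", call. = FALSE)
  if (any(rer < 0.7) || any(rer > 1.0)) {
    warning("RER outside [0.7, 1.0]; clamped", call. = FALSE)
    rer <- pmin(pmax(rer, 0.7), 1.0)
  }
  e_o2 <- ((rer - 0.7) / 0.3) * 21.13 + ((1 - rer) / 0.3) * 19.62 # kJ/L
  metabolic_rate <- vo2 * e_o2 * 1000 / 60                        # W
  external_work <- mass_kg * 9.81 * (speed_kmh / 3.6) * grade     # W
  net <- metabolic_rate - external_work
  data.frame(metabolic_rate = metabolic_rate,
             external_work = external_work,
             net_heat_production = net,
             per_bsa = net / bsa)
}

#' Relative exercise intensity
#'
#' Oxygen uptake as a percentage of maximal oxygen uptake.
#'
#' @param vo2_rel Exercise oxygen uptake (mL/min/kg).
#' @param vo2max Maximal oxygen uptake (mL/min/kg), > 0.
#' @return Percent of maximum.
#' @export
relative_intensity <- function(vo2_rel, vo2max) {
  if (any(vo2max <= 0)) stop("vo2max must be > 0", call. = FALSE)
  100 * vo2_rel / vo2max
}

#' Pre-exercise hydration screening from urine specific gravity
#'
#' Participants are cleared for exercise below 1.020, asked to drink 500 mL
#' of water and be rechecked in the 1.020--1.025 band (boundaries inclusive),
#' and rescheduled above 1.025.
#'
#' @param usg Urine specific gravity, in \[1.000, 1.060\].
#' @return One of `"cleared"`, `"drink_and_recheck"`, `"reschedule"`
#'   (vectorised).
#' @examples
#' hydration_screen(c(1.015, 1.022, 1.030))
#' @export
hydration_screen <- function(usg) {
  if (any(usg < 1.000) || any(usg > 1.060)) {
    stop("usg must lie in [1.000, 1.060]", call. = FALSE)
  }
  ifelse(usg < 1.020, "cleared",
         ifelse(usg <= 1.025, "drink_and_recheck", "reschedule"))
}
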