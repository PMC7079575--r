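#' Packaged pelvic limb muscle roster
#'
#' The 33 pelvic limb musculotendon actuators of the model with their
#' volumes (cm^3), pennation angles (deg), optimal fiber lengths (cm),
#' tendon slack lengths (cm), and maximum isometric forces (N). Values
#' are subject-specific CT-derived and literature-scaled parameters for
#' a 5.4 kg Dachshund; left and right limbs share one parameter set.
#'
#' @return A tibble with one row per muscle.
#' @export
#' @examples
#' canine_muscles()
canine_muscles <- function() {
  path <- system.file("extdata", "table2_muscles.csv", package = "caninegait")
  as_tibble(read.csv(path, check.names = FALSE))
}

#' Scale optimal fiber length and tendon slack length to the subject
#'
#' Literature reference fiber and tendon slack lengths are scaled by the
#' ratio of the subject's bony segment length to the reference segment
#' length: `f = f_ref * l / l_ref` and `TSL = TSL_ref * l / l_ref`.
#'
#' @param f_ref,tsl_ref Reference optimal fiber / tendon slack length (cm).
#' @param l Subject segment length (cm).
#' @param l_ref Reference segment length (cm); must be > 0.
#' @return Scaled length (cm); vectorized.
#' @export
#' @examples
#' scale_fiber_length(4.0, l = 6, l_ref = 8)  # 3.0
scale_fiber_length <- function(f_ref, l, l_ref) {
  if (any(l_ref <= 0)) {
    abort("`l_ref` must be > 0.", class = "caninegait_invalid_input")
  }
  f_ref * l / l_ref
}

#' @rdname scale_fiber_length
#' @export
scale_tendon_slack <- function(tsl_ref, l, l_ref) {
  if (any(l_ref <= 0)) {
    abort("`l_ref` must be > 0.", class = "caninegait_invalid_input")
  }
  tsl_ref * l / l_ref
}

#' Adjust fiber and tendon slack lengths to the mid-stance MTU length
#'
#' Distributes the gap between the mid-stance musculotendon unit length
#' and the scaled `f + TSL` proportionally:
#' `f_adj = (MTU - f - TSL) * f / (f + TSL) + f` and analogously for
#' `TSL_adj`. By construction `f_adj + TSL_adj = MTU` and the
#' fiber:tendon split `f/TSL` is preserved.
#'
#' @param f Scaled optimal fiber length (cm).
#' @param tsl Scaled tendon slack length (cm).
#' @param mtu Musculotendon unit length at mid-stance (cm).
#' @return Tibble with columns `f_adj` and `tsl_adj` (cm); vectorized.
#' @export
#' @examples
#' adjust_fiber_and_tendon(2, 2, 6)  # f_adj = tsl_adj = 3
adjust_fiber_and_tendon <- function(f, tsl, mtu) {
  if (any(f + tsl <= 0)) {
    abort("`f + tsl` must be > 0.", class = "caninegait_invalid_input")
  }
  if (any(mtu <= 0)) {
    abort("`mtu` must be > 0.", class = "caninegait_invalid_input")
  }
  gap <- mtu - f - tsl
  tibble(
    f_adj = gap * f / (f + tsl) + f,
    tsl_adj = gap * tsl / (f + tsl) + tsl
  )
}

#' Maximum isometric muscle force from volume-based PCSA
#'
#' `F_iso = T * Vol * cos(alpha) / f`, i.e. specific tension times the
#' physiological cross-sectional area (muscle volume over optimal fiber
#' length) with the pennation angle projecting fiber force onto the
#' tendon line of action.
#'
#' Note on the pennation term: the projection of pennate fiber force
#' onto the tendon is the cosine of the pennation angle, and the
#' packaged muscle roster's printed forces are reproduced by the cosine
#' form (a sine term would, e.g., give 14 N instead of 202 N for the
#' adductor magnus et brevis). This function therefore uses
#' `cos(alpha)`; zero-pennation muscles reduce to `T * Vol / f`.
#'
#' @param volume_cm3 Muscle volume (cm^3).
#' @param pennation_deg Pennation angle (degrees, `0 <= alpha < 90`).
#' @param fiber_cm (Adjusted) optimal fiber length (cm); must be > 0.
#' @param specific_tension Muscle specific tension (N/cm^2, default 22.5).
#' @return Maximum isometric force (N); vectorized.
#' @export
#' @examples
#' max_isometric_force(35.1, 4, 3.9)   # ~202 N
#' max_isometric_force(15.6, 0, 6.3)   # ~55.7 N
max_isometric_force <- function(volume_cm3, pennation_deg, fiber_cm,
                                specific_tension = 22.5) {
  if (any(fiber_cm <= 0)) {
    abort("`fiber_cm` must be > 0.", class = "caninegait_invalid_input")
  }
  if (any(volume_cm3 < 0)) {
    abort("`volume_cm3` must be >= 0.", class = "caninegait_invalid_input")
  }
  if (any(pennation_deg < 0 | pennation_deg >= 90)) {
    abort("`pennation_deg` must be in [0, 90).",
          class = "caninegait_invalid_input")
  }
  specific_tension * volume_cm3 * cos(deg2rad(pennation_deg)) / fiber_cm
}
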