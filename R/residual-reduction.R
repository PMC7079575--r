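#' Simplified residual reduction
#'
#' A two-step stand-in for a full tracking-controller residual
#' reduction: (1) the kinematic coordinate series is re-filtered at
#' 6 Hz (zero-phase Butterworth); (2) the torso point-mass COM is
#' shifted horizontally (cranial-caudal x) to null the mean pelvis
#' residual z-moment over stance. Because the residual moment is
#' exactly linear in the shift (the torso weight is constant), the
#' nulling shift is found from a two-point evaluation of the residual
#' slope. The shift is clamped to an anatomical bound (a fraction of
#' pelvis length) and only applied if the residual-moment RMS does not
#' increase; before/after RMS values are always reported.
#'
#' @param coords Coordinate series (long or wide, see
#'   [inverse_dynamics()]).
#' @param model An [msk_model()] containing a `torso` segment.
#' @param grf Ground reaction tibble (see [inverse_dynamics()]).
#' @param stance_window Optional length-2 time window over which the
#'   mean residual is nulled (e.g. the stance phase); defaults to the
#'   whole trial.
#' @param torso_segment Name of the torso segment.
#' @param max_shift_frac Clamp on |shift| as a fraction of pelvis
#'   length (default 0.30).
#' @param pelvis_length_mm Pelvis segment length used for the clamp.
#' @param cutoff,filter_order Re-filtering controls (6 Hz, 4th order).
#' @param ... Passed to [inverse_dynamics()].
#' @return List of class `rra_result`: `model` (adjusted), `coords`
#'   (re-filtered), `shift_mm` (applied torso COM x-shift),
#'   `shift_requested_mm`, `applied`, `clamped`, `rms_before`,
#'   `rms_after` (residual moment RMS, N m), and `residuals_after`.
#' @export
reduce_residuals <- function(coords, model, grf,
                             stance_window = NULL,
                             torso_segment = "torso",
                             max_shift_frac = 0.30,
                             pelvis_length_mm = NULL,
                             cutoff = 6, filter_order = 4, ...) {
  if (!torso_segment %in% model$segments$name) {
    abort("Model has no torso segment to adjust.",
          class = "caninegait_invalid_input")
  }
  qw <- coords_to_wide(coords)
  rate <- 1 / stats::median(diff(qw$time))
  cn <- setdiff(names(qw), "time")
  for (cc in cn) {
    qw[[cc]] <- butterworth_lowpass(qw[[cc]], cutoff = cutoff, rate = rate,
                                    order = filter_order)
  }

  if (is.null(pelvis_length_mm)) {
    root <- model$segments$name[is.na(model$segments$parent_idx)]
    pelvis_length_mm <- model$segments$length_mm[
      match(root, model$segments$name)] %||% 80
    if (is.na(pelvis_length_mm)) pelvis_length_mm <- 80
  }

  shifted <- function(dx) {
    m2 <- model
    i <- match(torso_segment, m2$segments$name)
    m2$segments$cx[i] <- m2$segments$cx[i] + dx
    m2
  }
  resid_z <- function(dx) {
    id <- inverse_dynamics(qw, shifted(dx), grf, ...)
    r <- id$residuals
    if (!is.null(stance_window)) {
      r <- filter(r, .data$time >= stance_window[1],
                  .data$time <= stance_window[2])
    }
    list(mean_mz = mean(r$mz_nm),
         rms = sqrt(mean(r$mx_nm^2 + r$my_nm^2 + r$mz_nm^2)),
         residuals = id$residuals)
  }

  base <- resid_z(0)
  probe <- resid_z(1)          # 1 mm probe: residual moment is linear in dx
  slope <- probe$mean_mz - base$mean_mz
  requested <- if (abs(slope) < 1e-12) 0 else -base$mean_mz / slope
  bound <- max_shift_frac * pelvis_length_mm
  clamped <- abs(requested) > bound
  if (clamped) {
    warn(sprintf("Requested torso COM shift %.1f mm exceeds the anatomical bound %.1f mm; not applied.",
                 requested, bound))
  }
  shift <- if (clamped) 0 else requested
  after <- if (shift == 0) base else resid_z(shift)
  applied <- after$rms <= base$rms + 1e-12
  if (!applied) {   # keep the original model if the shift did not help
    shift <- 0
    after <- base
  }

  structure(
    list(model = shifted(shift), coords = qw,
         shift_mm = shift, shift_requested_mm = requested,
         applied = applied && shift != 0, clamped = clamped,
         rms_before = base$rms, rms_after = after$rms,
         residuals_after = after$residuals),
    class = "rra_result"
  )
}

#' @export
print.rra_result <- function(x, ...) {
  cat(sprintf("<rra_result> torso COM shift %.2f mm (requested %.2f%s), residual moment RMS %.4f -> %.4f N m\n",
              x$shift_mm, x$shift_requested_mm,
              if (x$clamped) ", clamped" else "", x$rms_before, x$rms_after))
  invisible(x)
}

#' @describeIn reduce_residuals One-row summary of the reduction.
#' @param x,object An `rra_result`.
#' @param ... Unused.
#' @method glance rra_result
#' @export
glance.rra_result <- function(x, ...) {
  tibble(shift_mm = x$shift_mm, shift_requested_mm = x$shift_requested_mm,
         applied = x$applied, clamped = x$clamped,
         rms_before = x$rms_before, rms_after = x$rms_after)
}
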