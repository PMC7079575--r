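#' Tune muscle fiber operating ranges over a gait cycle
#'
#' Rescales each muscle's adjusted optimal fiber length and tendon
#' slack length (multiplicatively, preserving their proportional
#' split) so that the normalized fiber length stays between 0.8 and
#' 1.2 at mid-stance and between 0.5 and 1.5 over the whole gait
#' cycle. The update is a damped multiplicative iteration (damping
#' 0.5, at most `max_iter` passes) toward the scale factor that
#' satisfies the currently most-violated band constraint; muscles for
#' which no scale factor can satisfy all bands are flagged as
#' untunable rather than silently accepted. Maximum isometric forces
#' are recomputed from the tuned fiber lengths.
#'
#' @param model An [msk_model()] with muscles and paths.
#' @param coords Gait-cycle coordinate series (long or wide).
#' @param midstance_time Time (s) of mid-stance; defaults to 30% of
#'   the series (mid-stance of a 60% stance fraction).
#' @param band_midstance,band_cycle Normalized-length bands.
#' @param damping Damping of the multiplicative update (default 0.5).
#' @param max_iter Iteration cap per muscle (default 50).
#' @return List with `model` (tuned) and `report`: per-muscle tibble
#'   of the scale factor, mid-stance and cycle min/max normalized
#'   lengths before and after, and `tuned`/`converged` flags.
#' @export
tune_fiber_operating_range <- function(model, coords,
                                       midstance_time = NULL,
                                       band_midstance = c(0.8, 1.2),
                                       band_cycle = c(0.5, 1.5),
                                       damping = 0.5, max_iter = 50) {
  if (is.null(model$muscles)) {
    abort("Model has no muscles.", class = "caninegait_invalid_input")
  }
  qw <- coords_to_wide(coords)
  times <- qw$time
  if (is.null(midstance_time)) {
    midstance_time <- times[1] + 0.3 * (times[length(times)] - times[1])
  }
  ms_idx <- which.min(abs(times - midstance_time))
  cn <- setdiff(names(qw), "time")

  mus <- model$muscles
  mtu <- matrix(NA_real_, length(times), nrow(mus),
                dimnames = list(NULL, mus$muscle))
  for (f in seq_along(times)) {
    q <- setNames(as.numeric(qw[f, cn]), cn)
    ml <- musculotendon_length(model, q)
    mtu[f, ] <- ml$mtu_cm[match(mus$muscle, ml$muscle)]
  }

  report <- purrr::map_dfr(seq_len(nrow(mus)), function(j) {
    f0 <- mus$f_adj_cm[j]; t0 <- mus$tsl_adj_cm[j]
    cosa <- cos(deg2rad(mus$pennation_deg[j]))
    lnorm_at <- function(k) (mtu[, j] - k * t0) / (k * f0 * cosa)
    band_state <- function(k) {
      ln <- lnorm_at(k)
      list(ms = ln[ms_idx], lo = min(ln), hi = max(ln))
    }
    # scale factor solving lnorm_ms = target:
    # (MTU_ms - k t0) / (k f0 cosa) = target  =>  k = MTU_ms / (target f0 cosa + t0)
    k_for <- function(mtu_ref, target) mtu_ref / (target * f0 * cosa + t0)
    in_band <- function(s) {
      s$ms >= band_midstance[1] && s$ms <= band_midstance[2] &&
        s$lo >= band_cycle[1] && s$hi <= band_cycle[2]
    }
    k <- 1
    s <- band_state(k)
    converged <- in_band(s)
    it <- 0
    while (!converged && it < max_iter) {
      it <- it + 1
      # most violated constraint decides the target scale
      margin <- 0.02   # aim slightly inside a band edge
      k_target <- if (s$hi > band_cycle[2]) {
        k_for(max(mtu[, j]), band_cycle[2] - margin)
      } else if (s$lo < band_cycle[1]) {
        k_for(min(mtu[, j]), band_cycle[1] + margin)
      } else if (s$ms > band_midstance[2]) {
        k_for(mtu[ms_idx, j], band_midstance[2] - margin)
      } else {
        k_for(mtu[ms_idx, j], band_midstance[1] + margin)
      }
      k <- k * (1 - damping) + k_target * damping
      s <- band_state(k)
      converged <- in_band(s)
    }
    s0 <- band_state(1)
    tibble(muscle = mus$muscle[j], scale = k,
           ms_lnorm_before = s0$ms, ms_lnorm_after = s$ms,
           min_lnorm_after = s$lo, max_lnorm_after = s$hi,
           tuned = abs(k - 1) > 1e-9, converged = converged,
           iterations = it)
  })

  if (any(!report$converged)) {
    warn(paste0("Untunable muscle(s): ",
                paste(report$muscle[!report$converged], collapse = ", ")))
  }

  tuned <- model
  keep <- report$converged
  sc <- ifelse(keep, report$scale, 1)
  tuned$muscles$f_adj_cm <- tuned$muscles$f_adj_cm * sc
  tuned$muscles$tsl_adj_cm <- tuned$muscles$tsl_adj_cm * sc
  if (all(c("volume_cm3", "pennation_deg") %in% names(tuned$muscles))) {
    tuned$muscles$f_iso_n <- max_isometric_force(
      tuned$muscles$volume_cm3, tuned$muscles$pennation_deg,
      tuned$muscles$f_adj_cm)
  }
  list(model = tuned, report = report)
}
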