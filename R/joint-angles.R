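#' Included angle between two vectors (degrees)
#'
#' The arccos of the normalized dot product, the primitive behind the
#' marker-based hip, stifle and tarsal flexion-extension angles.
#'
#' @param a,b Numeric length-3 vectors or n x 3 matrices (rowwise).
#' @return Angle(s) in degrees in \[0, 180\].
#' @export
included_angle <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, 1)
  if (is.null(dim(b))) b <- matrix(b, 1)
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  if (any(na < 1e-12) || any(nb < 1e-12)) {
    abort("Zero-length axis vector.", class = "caninegait_degenerate_frame")
  }
  cosv <- pmin(1, pmax(-1, rowSums(a * b) / (na * nb)))
  rad2deg(acos(cosv))
}

marker_mat <- function(markers, name) {
  df <- filter(markers, .data$marker == name) %>% arrange(.data$time)
  if (nrow(df) == 0) {
    abort(sprintf("Marker `%s` required for joint angles is missing.", name),
          class = "caninegait_invalid_input")
  }
  as.matrix(df[, c("x", "y", "z")])
}

#' Marker-based sagittal joint angles
#'
#' Computes the hip, stifle and tarsal flexion-extension angles from
#' surface marker trajectories as included angles between segment axis
#' vectors:
#'
#' * hip: angle between the pelvis cranial (x) axis - from the
#'   ischiatic tuberosity to the iliac crest marker - and the femur
#'   proximal-distal (y) axis from the lateral femoral condyle to the
#'   greater trochanter;
#' * stifle: angle between the femur y axis and the tibia y axis from
#'   the lateral malleolus to the lateral femoral condyle;
#' * tarsus: angle between the tibia y axis and the tarsus y axis from
#'   the distal 5th metatarsal to the calcaneus.
#'
#' Being built from dot products of marker difference vectors, the
#' angles are invariant under any global rigid transformation of the
#' marker cloud.
#'
#' @param markers Long marker tibble (`time`, `marker`, `x`, `y`, `z`)
#'   containing the markers named above (side suffix `_L` by default).
#' @param side Which limb's markers to use (suffix on limb marker names).
#' @return Tibble with columns `time`, `joint` (hip/stifle/tarsus) and
#'   `angle_deg` (included angle, 0-180 deg).
#' @export
joint_angles <- function(markers, side = "L") {
  sfx <- paste0("_", side)
  tt <- sort(unique(markers$time))
  ic <- marker_mat(markers, paste0("iliac_crest", sfx))
  it <- marker_mat(markers, paste0("ischiatic_tuberosity", sfx))
  gt <- marker_mat(markers, paste0("greater_trochanter", sfx))
  lfc <- marker_mat(markers, paste0("lateral_femoral_condyle", sfx))
  lm_ <- marker_mat(markers, paste0("lateral_malleolus", sfx))
  cal <- marker_mat(markers, paste0("calcaneus", sfx))
  mt5 <- marker_mat(markers, paste0("distal_5th_metatarsal", sfx))

  x_p <- ic - it          # pelvis cranial axis
  y_f <- gt - lfc         # femur proximal-distal axis
  y_t <- lfc - lm_        # tibia proximal-distal axis
  y_tr <- cal - mt5       # tarsus proximal-distal axis

  bind_rows(
    tibble(time = tt, joint = "hip", angle_deg = included_angle(x_p, y_f)),
    tibble(time = tt, joint = "stifle", angle_deg = included_angle(y_f, y_t)),
    tibble(time = tt, joint = "tarsus", angle_deg = included_angle(y_t, y_tr))
  )
}

#' Joint angle series over the normalized gait cycle
#'
#' Resamples marker-based joint angles onto the 100-point cycle and
#' adds angular velocity (deg/s) by central differences consistent with
#' the cycle duration.
#'
#' @param markers Long marker tibble covering exactly one gait cycle.
#' @param n Cycle points (default 100).
#' @inheritParams joint_angles
#' @return Tibble with `cycle_pct`, `joint`, `angle_deg`,
#'   `velocity_dps`.
#' @export
joint_angle_series <- function(markers, side = "L", n = 100) {
  ang <- joint_angles(markers, side = side)
  duration <- diff(range(ang$time))
  ang %>%
    group_by(.data$joint) %>%
    group_split() %>%
    purrr::map_dfr(function(df) {
      rs <- resample_cycle(df[, c("time", "angle_deg")], n = n)
      dt <- duration / (n - 1)
      rs$velocity_dps <- finite_diff(rs$angle_deg, dt)
      rs$joint <- df$joint[1]
      rs
    }) %>%
    select("cycle_pct", "joint", "angle_deg", "velocity_dps")
}

# central differences with one-sided ends
finite_diff <- function(x, dt) {
  n <- length(x)
  if (n < 2) return(rep(0, n))
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  if (n > 2) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d
}
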