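#' Hill-type muscle characteristic curves
#'
#' Dimensionless force-length and force-velocity factors of the
#' musculotendon actuators:
#'
#' * active force-length: Gaussian `exp(-(l - 1)^2 / width^2)`, peak 1
#'   at normalized fiber length 1;
#' * passive force-length: zero at or below optimal length, exponential
#'   above, reaching 1 (one maximal isometric force) at strain
#'   `passive_strain`;
#' * force-velocity: Hill hyperbola on the concentric side (factor 1 at
#'   zero velocity, 0 at maximal shortening velocity), saturating
#'   eccentric branch with plateau `ecc_max`.
#'
#' Velocities are normalized by `vmax` optimal fiber lengths per
#' second; positive normalized velocity is shortening.
#'
#' @param width Active curve width (default 0.45).
#' @param passive_strain Strain above optimal length at which passive
#'   force reaches one F_iso (default 0.6).
#' @param passive_k Passive exponential shape factor (default 4).
#' @param af Hill force-velocity curvature `a/F_iso` (default 0.25).
#' @param ecc_max Eccentric plateau (default 1.4).
#' @param vmax Maximal shortening velocity in fiber lengths/s
#'   (default 10).
#' @return List of vectorized functions `fl(lnorm)`, `fp(lnorm)`,
#'   `fv(vnorm)` plus the parameters.
#' @export
hill_curves <- function(width = 0.45, passive_strain = 0.6, passive_k = 4,
                        af = 0.25, ecc_max = 1.4, vmax = 10) {
  fl <- function(lnorm) exp(-((lnorm - 1)^2) / width^2)
  fp <- function(lnorm) {
    ifelse(lnorm <= 1, 0,
           (exp(passive_k * (lnorm - 1) / passive_strain) - 1) /
             (exp(passive_k) - 1))
  }
  fv <- function(vnorm) {
    v <- pmin(vnorm, 1)  # beyond vmax the fiber produces no active force
    con <- pmax(0, (1 - v) / (1 + v / af))
    ecc <- ecc_max - (ecc_max - 1) / (1 - 4 * pmin(vnorm, 0))
    ifelse(vnorm >= 0, con, ecc)
  }
  list(fl = fl, fp = fp, fv = fv, width = width,
       passive_strain = passive_strain, passive_k = passive_k, af = af,
       ecc_max = ecc_max, vmax = vmax)
}

#' Musculotendon unit length for a pose
#'
#' Polyline length of the muscle line of action from origin through via
#' points to insertion, with all attachment points mapped to the world
#' frame.
#'
#' @param model An [msk_model()] with muscle paths.
#' @param q Named coordinate vector (see [forward_kinematics()]).
#' @param muscle Muscle name(s); default all.
#' @return Tibble with columns `muscle` and `mtu_cm`.
#' @export
musculotendon_length <- function(model, q = NULL, muscle = NULL) {
  if (is.null(model$paths)) {
    abort("Model has no muscle paths.", class = "caninegait_invalid_input")
  }
  paths <- model$paths
  if (!is.null(muscle)) {
    paths <- filter(paths, .data$muscle %in% !!muscle)
    if (nrow(paths) == 0) {
      abort("Unknown muscle.", class = "caninegait_invalid_input")
    }
  }
  fk <- forward_kinematics(model, q)
  world <- matrix(NA_real_, nrow(paths), 3)
  for (i in seq_len(nrow(paths))) {
    s <- paths$segment[i]
    world[i, ] <- fk$p[s, ] + fk$R[[s]] %*%
      c(paths$x[i], paths$y[i], paths$z[i])
  }
  paths$wx <- world[, 1]; paths$wy <- world[, 2]; paths$wz <- world[, 3]
  paths %>%
    group_by(.data$muscle) %>%
    summarise(
      mtu_cm = sum(sqrt(diff(.data$wx)^2 + diff(.data$wy)^2 +
                          diff(.data$wz)^2)) / 10,
      .groups = "drop"
    )
}

#' Muscle moment arm by tendon excursion
#'
#' `r = -d(MTU length)/d(theta)`: the change of musculotendon length
#' per radian of a generalized coordinate, estimated by central
#' differences with a 0.1 degree perturbation. A positive arm means
#' the muscle shortens as the coordinate increases (it generates a
#' positive moment about that coordinate). Muscles not spanning the
#' joint have zero arm.
#'
#' @inheritParams musculotendon_length
#' @param coord Generalized coordinate name (e.g. `"stifle_L_rz"`).
#' @param delta_deg Perturbation size (default 0.1 deg).
#' @return Tibble with columns `muscle` and `arm_cm`.
#' @export
moment_arm <- function(model, q = NULL, muscle = NULL, coord,
                       delta_deg = 0.1) {
  if (!coord %in% model$coords$coord) {
    abort(sprintf("Unknown coordinate `%s`.", coord),
          class = "caninegait_invalid_input")
  }
  pose <- model$default_pose
  if (!is.null(q)) pose[names(q)] <- q
  qp <- pose; qp[coord] <- pose[coord] + delta_deg
  qm <- pose; qm[coord] <- pose[coord] - delta_deg
  lp <- musculotendon_length(model, qp, muscle)
  lm_ <- musculotendon_length(model, qm, muscle)
  tibble(
    muscle = lp$muscle,
    arm_cm = -(lp$mtu_cm - lm_$mtu_cm) / (2 * deg2rad(delta_deg))
  )
}

#' Rigid-tendon musculotendon force
#'
#' `F = F_iso * (a * fl(lnorm) * fv(vnorm) + fp(lnorm)) * cos(alpha)`:
#' tendon force under the rigid-tendon assumption, where the fiber
#' length is the musculotendon length minus the tendon slack length
#' projected along the pennation angle. The characteristic curves are
#' defined on the whole real line, so out-of-range fiber lengths simply
#' produce (near-)zero active force; activation outside \[0, 1\] is
#' clamped with a warning.
#'
#' @param a Activation in \[0, 1\].
#' @param lnorm Normalized fiber length (fiber length / optimal fiber
#'   length).
#' @param vnorm Normalized fiber velocity (shortening positive, in
#'   fractions of `vmax`).
#' @param f_iso_n Maximum isometric force (N).
#' @param pennation_deg Pennation angle (deg).
#' @param curves Output of [hill_curves()].
#' @return Tendon force (N); vectorized.
#' @export
tendon_force <- function(a, lnorm, vnorm = 0, f_iso_n, pennation_deg = 0,
                         curves = hill_curves()) {
  if (any(a < -1e-9 | a > 1 + 1e-9)) {
    warn("Activation outside [0, 1]; clamping.")
  }
  a <- pmin(1, pmax(0, a))
  f_iso_n * (a * curves$fl(lnorm) * curves$fv(vnorm) + curves$fp(lnorm)) *
    cos(deg2rad(pennation_deg))
}

# rigid-tendon fiber state from an MTU length series
fiber_state <- function(mtu_cm, f_adj_cm, tsl_adj_cm, pennation_deg,
                        dt = NULL, vmax = 10) {
  cosa <- cos(deg2rad(pennation_deg))
  fiber <- (mtu_cm - tsl_adj_cm) / cosa
  lnorm <- fiber / f_adj_cm
  vnorm <- rep(0, length(mtu_cm))
  if (!is.null(dt) && length(mtu_cm) > 2) {
    dfiber <- finite_diff(fiber, dt)           # cm/s
    vnorm <- -dfiber / (vmax * f_adj_cm)       # shortening positive
  }
  tibble(fiber_cm = fiber, lnorm = lnorm, vnorm = vnorm)
}
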