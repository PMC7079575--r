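coords_to_wide <- function(coords) {
  if ("coord" %in% names(coords) && "value" %in% names(coords)) {
    coords <- tidyr::pivot_wider(coords, names_from = "coord",
                                 values_from = "value")
  }
  arrange(coords, .data$time)
}

# average (anti-alias) or interpolate a GRF channel onto kinematic times
align_grf <- function(grf, times) {
  dt <- stats::median(diff(times))
  grf_rate <- 1 / stats::median(diff(grf$time))
  num <- setdiff(names(grf)[vapply(grf, is.numeric, logical(1))], "time")
  out <- tibble(time = times)
  if (grf_rate > 1.5 / dt) {
    bins <- findInterval(grf$time, c(times - dt / 2, times[length(times)] + dt / 2))
    ok <- bins >= 1 & bins <= length(times)
    for (cc in num) {
      agg <- tapply(grf[[cc]][ok], bins[ok], mean)
      v <- rep(NA_real_, length(times))
      v[as.integer(names(agg))] <- agg
      # frames with no force sample (outside plate record) are unloaded
      v[is.na(v)] <- 0
      out[[cc]] <- v
    }
  } else {
    for (cc in num) {
      out[[cc]] <- approx(grf$time, grf[[cc]], xout = times, rule = 2)$y
    }
  }
  out
}

#' Inverse dynamics over the segment tree
#'
#' Distal-to-proximal Newton-Euler recursion: per frame, segment
#' angular velocities/accelerations and COM accelerations are estimated
#' by central differences of the forward-kinematics trajectories, the
#' measured ground reaction force is applied to the paw segment at the
#' center of pressure (with the vertical free torque), and joint forces
#' and torques are propagated up the tree. The unbalanced wrench at the
#' root (pelvis) is reported as the residual force and moment - what
#' the pelvis residual actuators would have to supply.
#'
#' Joint moments are reported work-conjugate to each rotational
#' generalized coordinate (power = moment x coordinate rate), so
#' flexion - the positive sense of every `_rz` coordinate - is
#' positive; extension-positive curves are sign flips.
#'
#' @param coords Coordinate series from [inverse_kinematics()]
#'   ([tidy()] long form or wide with one column per coordinate), on an
#'   evenly sampled time base.
#' @param model An [msk_model()].
#' @param grf Optional ground reaction tibble: `time`, `fx`, `fy`, `fz`
#'   (N, world axes), `tv` (vertical free torque, N m), `copx`, `copy`,
#'   `copz` (center of pressure, m). Sampled faster than the kinematics
#'   it is block-averaged (anti-aliased) onto kinematic frames; COP is
#'   only used on loaded frames.
#' @param grf_segment Segment receiving the ground reaction.
#' @param load_threshold Vertical force (N) below which a frame counts
#'   as unloaded (no external force applied).
#' @param gravity Gravity vector in m/s^2.
#' @return An object of class `id_result`: `moments` (tibble `time`,
#'   `coord`, `moment_nm` for every rotational DOF), `residuals`
#'   (per-frame pelvis residual force N and moment N m), `model`.
#' @export
inverse_dynamics <- function(coords, model, grf = NULL,
                             grf_segment = "phalanges_L",
                             load_threshold = 0.5,
                             gravity = c(0, -9.81, 0)) {
  qw <- coords_to_wide(coords)
  times <- qw$time
  nf <- length(times)
  if (nf < 3) {
    abort("Need at least 3 frames for acceleration estimates.",
          class = "caninegait_invalid_input")
  }
  dt <- diff(times)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1]) {
    abort("Coordinate series must be evenly sampled.",
          class = "caninegait_invalid_input")
  }
  dt <- dt[1]
  segs <- model$segments
  ns <- nrow(segs)
  if (!is.null(grf) && !grf_segment %in% segs$name) {
    abort("`grf_segment` is not a model segment.",
          class = "caninegait_invalid_input")
  }

  # FK for all frames
  Rarr <- array(NA_real_, c(3, 3, ns, nf))
  com <- array(NA_real_, c(nf, ns, 3))
  jnt <- array(NA_real_, c(nf, ns, 3))
  cn <- setdiff(names(qw), "time")
  for (f in seq_len(nf)) {
    q <- setNames(as.numeric(qw[f, cn]), cn)
    fk <- forward_kinematics(model, q)
    for (s in seq_len(ns)) {
      Rarr[, , s, f] <- fk$R[[s]]
      jnt[f, s, ] <- fk$p[s, ] / 1000
      com[f, s, ] <- (fk$p[s, ] + fk$R[[s]] %*%
                        c(segs$cx[s], segs$cy[s], segs$cz[s])) / 1000
    }
  }

  # angular velocity / acceleration and COM acceleration (central diff,
  # endpoint values copied from the nearest interior frame)
  omega <- array(0, c(nf, ns, 3))
  for (f in 2:(nf - 1)) {
    for (s in seq_len(ns)) {
      Rdot <- (Rarr[, , s, f + 1] - Rarr[, , s, f - 1]) / (2 * dt)
      W <- Rdot %*% t(Rarr[, , s, f])
      omega[f, s, ] <- c(W[3, 2], W[1, 3], W[2, 1])
    }
  }
  omega[1, , ] <- omega[2, , ]; omega[nf, , ] <- omega[nf - 1, , ]
  alpha <- array(0, c(nf, ns, 3))
  acc <- array(0, c(nf, ns, 3))
  for (f in 2:(nf - 1)) {
    alpha[f, , ] <- (omega[f + 1, , ] - omega[f - 1, , ]) / (2 * dt)
    acc[f, , ] <- (com[f + 1, , ] - 2 * com[f, , ] + com[f - 1, , ]) / dt^2
  }
  alpha[1, , ] <- alpha[2, , ]; alpha[nf, , ] <- alpha[nf - 1, , ]
  acc[1, , ] <- acc[2, , ]; acc[nf, , ] <- acc[nf - 1, , ]

  ext <- if (!is.null(grf)) align_grf(grf, times) else NULL
  if (!is.null(ext)) {
    needed <- c("fx", "fy", "fz")
    if (!all(needed %in% names(ext))) {
      abort("GRF table needs columns fx, fy, fz.",
            class = "caninegait_invalid_input")
    }
    loaded <- abs(ext$fy) > load_threshold
    has_cop <- all(c("copx", "copy", "copz") %in% names(ext))
    if (any(loaded) && !has_cop) {
      abort("COP columns (copx, copy, copz) are required on loaded frames.",
            class = "caninegait_invalid_input")
    }
  }

  children <- lapply(seq_len(ns), function(i) which(segs$parent_idx == i))
  rev_order <- rev(seq_len(ns))
  rot_coords <- filter(model$coords, .data$kind == "rotation")

  moments_out <- vector("list", nf)
  resid_out <- vector("list", nf)
  grf_idx <- if (!is.null(grf)) match(grf_segment, segs$name) else NA_integer_

  for (f in seq_len(nf)) {
    Fj <- matrix(0, ns, 3)   # joint force on segment from its parent
    Tj <- matrix(0, ns, 3)   # joint torque on segment from its parent
    for (s in rev_order) {
      m <- segs$mass_kg[s]
      Rw <- Rarr[, , s, f]
      Iw <- Rw %*% segs$inertia[[s]] %*% t(Rw)
      om <- omega[f, s, ]
      f_ext <- c(0, 0, 0); t_ext <- c(0, 0, 0); r_cop <- c(0, 0, 0)
      if (!is.null(ext) && s == grf_idx && loaded[f]) {
        f_ext <- c(ext$fx[f], ext$fy[f], ext$fz[f])
        if ("tv" %in% names(ext)) t_ext <- c(0, ext$tv[f], 0)
        r_cop <- c(ext$copx[f], ext$copy[f], ext$copz[f])
      }
      fs <- m * acc[f, s, ] - m * gravity - f_ext
      ts <- as.numeric(Iw %*% alpha[f, s, ]) + cross3(om, as.numeric(Iw %*% om)) -
        t_ext - cross3(r_cop - com[f, s, ], f_ext)
      for (c_ in children[[s]]) {
        fs <- fs + Fj[c_, ]
        ts <- ts + Tj[c_, ] + cross3(jnt[f, c_, ] - com[f, s, ], Fj[c_, ])
      }
      ts <- ts - cross3(jnt[f, s, ] - com[f, s, ], fs)
      Fj[s, ] <- fs
      Tj[s, ] <- ts
    }

    # project joint torques onto the rotation axes of each coordinate
    qf <- setNames(as.numeric(qw[f, cn]), cn)
    mom <- purrr::map_dbl(seq_len(nrow(rot_coords)), function(k) {
      seg <- rot_coords$segment[k]
      s <- match(seg, segs$name)
      if (is.na(segs$parent_idx[s])) return(NA_real_)  # root handled as residual
      coord <- rot_coords$coord[k]
      Rp <- Rarr[, , segs$parent_idx[s], f]
      axis <- coord_axis_world(coord, Rp, Rarr[, , s, f], qf)
      sum(Tj[s, ] * axis)
    })
    keep <- !is.na(mom)
    moments_out[[f]] <- tibble(time = times[f],
                               coord = rot_coords$coord[keep],
                               moment_nm = mom[keep])
    root <- which(is.na(segs$parent_idx))
    resid_out[[f]] <- tibble(
      time = times[f],
      fx_n = Fj[root, 1], fy_n = Fj[root, 2], fz_n = Fj[root, 3],
      mx_nm = Tj[root, 1], my_nm = Tj[root, 2], mz_nm = Tj[root, 3]
    )
  }

  structure(
    list(moments = bind_rows(moments_out), residuals = bind_rows(resid_out),
         times = times, model = model),
    class = "id_result"
  )
}

# world direction of the rotation axis a generalized coordinate acts about
coord_axis_world <- function(coord, Rp, Rs, q) {
  if (endsWith(coord, "_rz")) {
    Rp[, 3]
  } else if (endsWith(coord, "_rx")) {
    rz <- q[sub("_rx$", "_rz", coord)]
    (Rp %*% rot_z(deg2rad(rz)))[, 1]
  } else { # _ry: after Rz Rx the y axis equals the child frame y axis
    Rs[, 2]
  }
}

#' @export
print.id_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<id_result> %d frames, %d moment DOFs, residual force RMS %.3f N, residual moment RMS %.4f N m\n",
              g$n_frames, g$n_dofs, g$resid_force_rms_n, g$resid_moment_rms_nm))
  invisible(x)
}

#' @describeIn inverse_dynamics Long joint-moment series.
#' @param x,object An `id_result`.
#' @param ... Unused.
#' @method tidy id_result
#' @export
tidy.id_result <- function(x, ...) x$moments

#' @describeIn inverse_dynamics One-row summary with residual RMS values.
#' @method glance id_result
#' @export
glance.id_result <- function(x, ...) {
  r <- x$residuals
  tibble(
    n_frames = length(x$times),
    n_dofs = length(unique(x$moments$coord)),
    resid_force_rms_n = sqrt(mean(r$fx_n^2 + r$fy_n^2 + r$fz_n^2)),
    resid_moment_rms_nm = sqrt(mean(r$mx_nm^2 + r$my_nm^2 + r$mz_nm^2))
  )
}

#' Joint power from moments and angular velocities
#'
#' Elementwise product of the net joint moment and the joint angular
#' velocity, with deg/s converted to rad/s. Positive power is energy
#' generation, negative is absorption.
#'
#' @param moments Tibble with columns (`time` or `cycle_pct`), `coord`
#'   (or `joint`), and `moment_nm`.
#' @param velocities Tibble with the same key columns and
#'   `velocity_dps`.
#' @return The joined tibble with a `power_w` column.
#' @export
joint_power <- function(moments, velocities) {
  keys <- intersect(intersect(names(moments), names(velocities)),
                    c("time", "cycle_pct", "coord", "joint"))
  if (!length(keys)) {
    abort("No shared key columns between moments and velocities.",
          class = "caninegait_invalid_input")
  }
  out <- dplyr::inner_join(moments, velocities, by = keys)
  if (nrow(out) != nrow(moments)) {
    abort("Moment and velocity series are not aligned.",
          class = "caninegait_invalid_input")
  }
  mutate(out, power_w = .data$moment_nm * deg2rad(.data$velocity_dps))
}
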