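# Exact active-set solver for min x'x + (m - B x)' W (m - B x), 0 <= x <= 1.
# Convex QP with positive-definite Hessian H = 2 I + 2 B' W B; bounds are
# activated/released until the KKT conditions hold.
solve_box_qp <- function(B, m, W, tol = 1e-12, max_pass = 100) {
  n <- ncol(B)
  H <- 2 * diag(n) + 2 * t(B) %*% W %*% B
  g <- -2 * t(B) %*% W %*% m          # gradient at x = 0 is g
  x <- rep(0, n)
  lower <- rep(FALSE, n); upper <- rep(FALSE, n)
  for (pass in seq_len(max_pass)) {
    free <- !(lower | upper)
    xf <- rep(0, n); xf[upper] <- 1
    if (any(free)) {
      rhs <- -(g[free] + H[free, !free, drop = FALSE] %*% xf[!free])
      xf[free] <- solve(H[free, free, drop = FALSE], rhs)
    }
    # activate violated bounds
    viol_lo <- free & xf < -tol
    viol_hi <- free & xf > 1 + tol
    if (any(viol_lo) || any(viol_hi)) {
      lower[viol_lo] <- TRUE
      upper[viol_hi] <- TRUE
      next
    }
    # release bounds whose multiplier has the wrong sign
    grad <- as.numeric(H %*% pmin(pmax(xf, 0), 1) + g)
    release_lo <- lower & grad < -tol
    release_hi <- upper & grad > tol
    if (any(release_lo) || any(release_hi)) {
      lower[release_lo] <- FALSE
      upper[release_hi] <- FALSE
      next
    }
    x <- pmin(pmax(xf, 0), 1)
    return(x)
  }
  warn("Activation QP active-set iteration limit reached.")
  x
}

#' Single-frame activation distribution
#'
#' Distributes net joint moments into muscle activations by minimizing
#' the sum of squared activations plus a quadratic reserve penalty,
#'
#' `min_a sum_j a_j^2 + sum_i (reserve_i / reserve_opt)^2`
#' subject to `sum_j r_ij F_j(a_j) + reserve_i = M_i`, `0 <= a_j <= 1`,
#'
#' where `F_j(a) = c_j a + d_j` is the rigid-tendon muscle force (so
#' the problem is a convex quadratic program with a unique solution).
#' Reserves are eliminated algebraically, leaving a box-constrained QP
#' solved exactly by an active-set method; the moment balance then
#' holds to machine precision with the reserves absorbing the
#' remainder.
#'
#' @param arms Matrix (DOFs x muscles) of moment arms in meters.
#' @param gain Numeric vector (muscles): active force per unit
#'   activation `c_j` in N (i.e. `F_iso * fl * fv * cos(alpha)`).
#' @param passive Numeric vector (muscles): activation-independent
#'   force `d_j` in N.
#' @param moments Numeric vector (DOFs): net joint moments in N m.
#' @param reserve_opt Reserve actuator optimal moment (N m, default 1):
#'   the reserve moment that costs as much as one fully activated
#'   muscle, making reserves expensive.
#' @return List with `activation` (muscles), `force_n`, `reserve_nm`
#'   (DOFs), and `objective` (sum of squared activations plus reserve
#'   cost).
#' @export
solve_activation_frame <- function(arms, gain, passive, moments,
                                   reserve_opt = 1) {
  arms <- rbind(arms)
  nd <- nrow(arms)
  B <- arms * rep(gain, each = nd)           # moment per unit activation
  m <- moments - as.numeric(arms %*% passive)
  W <- diag(1 / reserve_opt^2, nd)
  a <- solve_box_qp(B, m, W)
  force <- gain * a + passive
  reserve <- moments - as.numeric(arms %*% force)
  list(activation = a, force_n = force, reserve_nm = reserve,
       objective = sum(a^2) + sum((reserve / reserve_opt)^2))
}

#' Static optimization over a gait cycle
#'
#' Runs [solve_activation_frame()] at every frame of a joint-moment
#' series: per frame, muscle moment arms, rigid-tendon fiber states and
#' force-length-velocity factors are evaluated at the corresponding
#' pose, then the activation QP distributes the net moments of the
#' requested DOFs across the muscles, with per-DOF reserve actuators
#' absorbing what the muscles cannot produce.
#'
#' @param moments Joint-moment series: tibble `time`, `coord`,
#'   `moment_nm` (as produced by [inverse_dynamics()]).
#' @param model An [msk_model()] with muscles and paths; the muscle
#'   table needs `muscle`, `f_iso_n`, `pennation_deg`, `f_adj_cm`,
#'   `tsl_adj_cm`.
#' @param coords Coordinate series aligned with `moments` (long or
#'   wide).
#' @param dofs Coordinates to balance (default: every coordinate
#'   present in `moments` that at least one muscle spans).
#' @param curves Hill curves from [hill_curves()].
#' @param reserve_opt Reserve optimal moment (N m).
#' @return Object of class `activation_solution`: `states` (tibble
#'   `time` x `muscle`: `activation`, `force_n`, `mtu_cm`, `lnorm`,
#'   `vnorm`), `reserves` (tibble `time` x `coord`: `reserve_nm`,
#'   `moment_nm`), `objective` per frame, and `model`.
#' @export
static_optimization <- function(moments, model, coords, dofs = NULL,
                                curves = hill_curves(),
                                reserve_opt = 1) {
  if (is.null(model$muscles) || is.null(model$paths)) {
    abort("Model has no muscles.", class = "caninegait_invalid_input")
  }
  qw <- coords_to_wide(coords)
  times <- qw$time
  dt <- if (length(times) > 1) stats::median(diff(times)) else NULL
  cn <- setdiff(names(qw), "time")
  mus <- model$muscles
  nm <- nrow(mus)

  # MTU lengths for all frames and muscles
  mtu <- matrix(NA_real_, length(times), nm,
                dimnames = list(NULL, mus$muscle))
  for (f in seq_along(times)) {
    q <- setNames(as.numeric(qw[f, cn]), cn)
    mtu[f, ] <- musculotendon_length(model, q)$mtu_cm[
      match(mus$muscle, sort(unique(model$paths$muscle)))]
  }

  state <- purrr::map(seq_len(nm), function(j) {
    fiber_state(mtu[, j], mus$f_adj_cm[j], mus$tsl_adj_cm[j],
                mus$pennation_deg[j], dt = dt, vmax = curves$vmax)
  })
  lnorm <- vapply(state, function(s) s$lnorm, numeric(length(times)))
  vnorm <- vapply(state, function(s) s$vnorm, numeric(length(times)))
  lnorm <- rbind(lnorm); vnorm <- rbind(vnorm)

  mom_w <- tidyr::pivot_wider(moments, names_from = "coord",
                              values_from = "moment_nm") %>%
    arrange(.data$time)
  if (!isTRUE(all.equal(mom_w$time, times))) {
    abort("Moment and coordinate series are not aligned in time.",
          class = "caninegait_invalid_input")
  }
  mom_cols <- setdiff(names(mom_w), "time")

  if (is.null(dofs)) dofs <- mom_cols
  missing <- setdiff(dofs, mom_cols)
  if (length(missing)) {
    abort(paste0("Moments missing for DOFs: ", paste(missing, collapse = ", ")),
          class = "caninegait_invalid_input")
  }

  # moment arms per frame (tendon excursion at each pose)
  arms <- array(0, c(length(times), length(dofs), nm),
                dimnames = list(NULL, dofs, mus$muscle))
  for (f in seq_along(times)) {
    q <- setNames(as.numeric(qw[f, cn]), cn)
    for (d in seq_along(dofs)) {
      ma <- moment_arm(model, q, coord = dofs[d])
      arms[f, d, ] <- ma$arm_cm[match(mus$muscle, ma$muscle)] / 100  # m
    }
  }

  # drop DOFs no muscle spans
  spans <- apply(abs(arms) > 1e-9, 2, any)
  if (!all(spans)) dofs <- dofs[spans]
  arms <- arms[, spans, , drop = FALSE]

  states_out <- vector("list", length(times))
  reserves_out <- vector("list", length(times))
  objective <- numeric(length(times))
  cosa <- cos(deg2rad(mus$pennation_deg))
  for (f in seq_along(times)) {
    gain <- mus$f_iso_n * curves$fl(lnorm[f, ]) * curves$fv(vnorm[f, ]) * cosa
    passive <- mus$f_iso_n * curves$fp(lnorm[f, ]) * cosa
    Mf <- as.numeric(mom_w[f, dofs])
    Af <- matrix(arms[f, , ], nrow = length(dofs), ncol = nm)
    sol <- solve_activation_frame(Af, gain, passive, Mf,
                                  reserve_opt = reserve_opt)
    states_out[[f]] <- tibble(
      time = times[f], muscle = mus$muscle,
      activation = sol$activation, force_n = sol$force_n,
      mtu_cm = mtu[f, ], lnorm = lnorm[f, ], vnorm = vnorm[f, ]
    )
    reserves_out[[f]] <- tibble(time = times[f], coord = dofs,
                                moment_nm = Mf, reserve_nm = sol$reserve_nm)
    objective[f] <- sol$objective
  }

  structure(
    list(states = bind_rows(states_out), reserves = bind_rows(reserves_out),
         objective = tibble(time = times, objective = objective),
         dofs = dofs, model = model),
    class = "activation_solution"
  )
}

#' @export
print.activation_solution <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<activation_solution> %d frames x %d muscles, peak activation %.3f, reserve RMS %.4f N m\n",
              g$n_frames, g$n_muscles, g$peak_activation, g$reserve_rms_nm))
  invisible(x)
}

#' @describeIn static_optimization Long activation/force series.
#' @param x,object An `activation_solution`.
#' @param ... Unused.
#' @method tidy activation_solution
#' @export
tidy.activation_solution <- function(x, ...) x$states

#' @describeIn static_optimization One-row solution summary.
#' @method glance activation_solution
#' @export
glance.activation_solution <- function(x, ...) {
  tibble(
    n_frames = nrow(x$objective),
    n_muscles = length(unique(x$states$muscle)),
    peak_activation = max(x$states$activation),
    mean_objective = mean(x$objective$objective),
    reserve_rms_nm = sqrt(mean(x$reserves$reserve_nm^2))
  )
}

#' Peak activations, forces and their timing
#'
#' Per muscle, the peak activation and peak force over the normalized
#' gait cycle and the cycle percentage at which each occurs, plus the
#' mean activation across all muscles during stance and swing.
#'
#' @param solution An `activation_solution` (or its [tidy()] states
#'   tibble with a `cycle_pct` or `time` column).
#' @param stance_fraction Stance end as a fraction of the cycle, used
#'   to split stance/swing means (default 0.6).
#' @return List with `peaks` (tibble: muscle, peak activation/force and
#'   timings in % cycle) and `phase_means` (stance/swing mean
#'   activation across muscles).
#' @export
summarize_peaks <- function(solution, stance_fraction = 0.6) {
  states <- if (inherits(solution, "activation_solution")) {
    solution$states
  } else {
    solution
  }
  if (nrow(states) == 0) {
    abort("Empty solution.", class = "caninegait_invalid_input")
  }
  tcol <- if ("cycle_pct" %in% names(states)) "cycle_pct" else "time"
  tt <- states[[tcol]]
  pct <- if (tcol == "cycle_pct") tt else
    (tt - min(tt)) / (max(tt) - min(tt)) * 100
  states$.pct <- pct
  peaks <- states %>%
    group_by(.data$muscle) %>%
    summarise(
      peak_activation = max(.data$activation),
      activation_peak_pct = .data$.pct[which.max(.data$activation)],
      peak_force_n = max(.data$force_n),
      force_peak_pct = .data$.pct[which.max(.data$force_n)],
      .groups = "drop"
    )
  phase_means <- states %>%
    mutate(phase = ifelse(.data$.pct <= stance_fraction * 100,
                          "stance", "swing")) %>%
    group_by(.data$phase) %>%
    summarise(mean_activation = mean(.data$activation), .groups = "drop")
  list(peaks = peaks, phase_means = phase_means)
}
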