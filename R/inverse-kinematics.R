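#' Marker-based inverse kinematics
#'
#' Solves, frame by frame, for the generalized coordinates that
#' minimize the weighted least-squares error between measured marker
#' positions and the model's virtual markers:
#' `min_q sum_m w_m || virtual_m(q) - measured_m ||^2`,
#' using Levenberg-Marquardt nonlinear least squares with a numeric
#' Jacobian. Frames are solved in order, each warm-started from the
#' previous solution; the first frame starts from the model default
#' pose with the root translation initialized from the pelvis marker
#' centroid.
#'
#' Coordinates that no measured marker can inform (joints of segments
#' that neither bear markers nor lead to segments that do) are locked
#' at their default-pose values and reported as such.
#'
#' @param markers Long marker tibble (`time`, `marker`, `x`, `y`, `z`,
#'   optional `visible`); marker names must match the model's virtual
#'   markers. At least 3 non-collinear markers should be visible.
#' @param model An [msk_model()] with virtual markers.
#' @param weights Optional named vector of per-marker tracking weights
#'   (default 1 for every marker; a weight of 0 removes a marker).
#' @param init Optional named vector: starting pose for the first frame.
#' @param ftol,ptol,maxiter Levenberg-Marquardt controls.
#' @return An object of class `ik_fit` with elements `coords` (tibble
#'   `time` x `coord` x `value`; rotations deg, translations mm),
#'   `frames` (per-frame RMS marker error in mm, convergence flag,
#'   marker count), `residuals` (per frame and marker, mm),
#'   `locked_coords`, and `model`.
#' @export
inverse_kinematics <- function(markers, model, weights = NULL, init = NULL,
                               ftol = 1e-12, ptol = 1e-12, maxiter = 100) {
  if (is.null(model$markers)) {
    abort("Model has no virtual markers.", class = "caninegait_invalid_input")
  }
  if (!"visible" %in% names(markers)) markers$visible <- TRUE
  markers <- filter(markers, .data$marker %in% model$markers$marker)
  if (nrow(markers) == 0) {
    abort("No measured markers match the model's virtual markers.",
          class = "caninegait_invalid_input")
  }
  w <- setNames(rep(1, nrow(model$markers)), model$markers$marker)
  if (!is.null(weights)) w[names(weights)] <- weights

  # coordinates observable through the marker set
  seg_tbl <- model$segments
  marker_segs <- unique(model$markers$segment[
    model$markers$marker %in% unique(markers$marker)])
  observable <- character(0)
  for (s in marker_segs) {
    while (!is.na(s)) {
      observable <- c(observable, s)
      s <- seg_tbl$parent[match(s, seg_tbl$name)]
    }
  }
  free <- model$coords$coord[model$coords$segment %in% unique(observable)]
  locked <- setdiff(model$coords$coord, free)

  pose <- model$default_pose
  if (!is.null(init)) pose[names(init)] <- init

  times <- sort(unique(markers$time))
  mk <- markers %>% arrange(.data$time, .data$marker)
  mk_split <- split(mk, mk$time)

  # initialize root translation from the centroid offset of root markers
  root_seg <- seg_tbl$name[is.na(seg_tbl$parent)]
  t_coords <- paste0(root_seg, c("_tx", "_ty", "_tz"))
  if (all(t_coords %in% free) && is.null(init)) {
    first <- mk_split[[1]]
    first <- filter(first, .data$visible)
    pose0 <- pose; pose0[t_coords] <- 0
    virt0 <- fk_markers(model, pose0)
    shared <- intersect(first$marker, rownames(virt0))
    if (length(shared) >= 1) {
      meas_c <- colMeans(as.matrix(first[match(shared, first$marker),
                                         c("x", "y", "z")]))
      pose[t_coords] <- meas_c - colMeans(virt0[shared, , drop = FALSE])
    }
  }

  coords_out <- vector("list", length(times))
  frames_out <- vector("list", length(times))
  resid_out <- vector("list", length(times))
  par <- pose[free]

  for (fi in seq_along(times)) {
    df <- filter(mk_split[[fi]], .data$visible)
    nm <- df$marker
    ww <- w[nm]
    use <- ww > 0
    df <- df[use, ]; nm <- nm[use]; ww <- ww[use]
    meas <- as.matrix(df[, c("x", "y", "z")])
    sw <- sqrt(rep(ww, each = 3))
    resid_fn <- function(p) {
      q <- pose; q[free] <- p
      virt <- fk_markers(model, q)[nm, , drop = FALSE]
      sw * as.numeric(t(virt - meas))
    }
    # central-difference Jacobian with a fixed absolute step: the mixed
    # parameter units (mm translations, degree rotations) make relative
    # steps collapse near zero
    jac_fn <- function(p) {
      h <- 1e-4
      vapply(seq_along(p), function(i) {
        pp <- p; pp[i] <- p[i] + h
        pm <- p; pm[i] <- p[i] - h
        (resid_fn(pp) - resid_fn(pm)) / (2 * h)
      }, numeric(3 * length(nm)))
    }
    fit <- minpack.lm::nls.lm(par = par, fn = resid_fn, jac = jac_fn,
                              control = minpack.lm::nls.lm.control(
                                ftol = ftol, ptol = ptol, maxiter = maxiter))
    par <- fit$par
    q <- pose; q[free] <- par
    virt <- fk_markers(model, q)[nm, , drop = FALSE]
    per_marker <- sqrt(rowSums((virt - meas)^2))
    converged <- fit$info %in% 1:4
    if (!converged) {
      warn(sprintf("IK did not converge at t = %.4f (info = %d: %s)",
                   times[fi], fit$info, fit$message))
    }
    coords_out[[fi]] <- tibble(time = times[fi], coord = names(q),
                               value = unname(q))
    frames_out[[fi]] <- tibble(
      time = times[fi],
      rms_mm = sqrt(mean(per_marker^2)),
      converged = converged, n_markers = length(nm)
    )
    resid_out[[fi]] <- tibble(time = times[fi], marker = nm,
                              resid_mm = unname(per_marker))
  }

  structure(
    list(coords = bind_rows(coords_out), frames = bind_rows(frames_out),
         residuals = bind_rows(resid_out), locked_coords = locked,
         free_coords = free, model = model),
    class = "ik_fit"
  )
}

#' @export
print.ik_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<ik_fit> %d frames, %d free coordinates, RMS marker error %.3f mm\n",
              g$n_frames, g$n_free_coords, g$rms_mm))
  if (g$n_failed > 0) cat(sprintf("%d frame(s) failed to converge\n", g$n_failed))
  invisible(x)
}

#' @describeIn inverse_kinematics Long coordinate series of an IK fit.
#' @param x,object An `ik_fit`.
#' @param ... Unused.
#' @method tidy ik_fit
#' @export
tidy.ik_fit <- function(x, ...) x$coords

#' @describeIn inverse_kinematics One-row IK summary (overall RMS in mm,
#'   frame and failure counts).
#' @method glance ik_fit
#' @export
glance.ik_fit <- function(x, ...) {
  tibble(
    n_frames = nrow(x$frames),
    n_free_coords = length(x$free_coords),
    rms_mm = sqrt(mean(x$residuals$resid_mm^2)),
    max_marker_error_mm = max(x$residuals$resid_mm),
    n_failed = sum(!x$frames$converged)
  )
}

#' Coordinate series of an IK fit in wide form
#'
#' @param fit An `ik_fit`.
#' @return Tibble with `time` and one column per generalized coordinate.
#' @export
ik_coords_wide <- function(fit) {
  tidyr::pivot_wider(fit$coords, names_from = "coord", values_from = "value")
}
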