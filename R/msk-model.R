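#' Assemble a rigid-body musculoskeletal model
#'
#' Builds the segment-tree model used by the kinematics, dynamics and
#' muscle modules. Segments form a tree rooted at the pelvis (a 6-DOF
#' free joint to the ground); each non-root segment connects to its
#' parent through a joint of one of four types:
#'
#' * `free`: 6 DOF (`_tx`,`_ty`,`_tz` in mm, `_rz`,`_rx`,`_ry` in deg) -
#'   the root.
#' * `ball`: 3 rotational DOF (`_rz` flexion, `_rx` adduction, `_ry`
#'   internal rotation) - the hip.
#' * `hinge`: 1 DOF (`_rz` flexion) - the tarsus.
#' * `sliding_hinge`: 1 DOF flexion plus translations prescribed as a
#'   function of the flexion angle (femorotibial coupling) - the stifle.
#'   With no coupling function it is a pure hinge.
#' * `fixed`: 0 DOF - the phalanges and the torso point mass.
#'
#' Each segment's local frame has its origin at the proximal joint
#' center, x cranial, y proximal-distal, z mediolateral in the neutral
#' pose (all coordinates zero), in which all frames are world-aligned.
#'
#' @param segments Tibble with columns `name`, `parent` (NA for root),
#'   `joint_type`, `jx`,`jy`,`jz` (joint center in the parent frame,
#'   mm), `mass_kg`, `cx`,`cy`,`cz` (COM in the segment frame, mm),
#'   `inertia` (list column of 3x3 kg m^2 tensors about the COM in
#'   segment axes), and optionally `coupling` (list column of functions
#'   `angle_deg -> c(dx, dy, dz)` mm for sliding hinges) and `length_mm`.
#' @param markers Tibble with columns `marker`, `segment`, `x`, `y`, `z`
#'   (virtual marker placements in segment frames, mm).
#' @param muscles Tibble of musculotendon parameters (one row per
#'   muscle; needs at least `muscle`, `f_iso_n`, `pennation_deg`,
#'   `f_adj_cm`, `tsl_adj_cm`).
#' @param paths Tibble with columns `muscle`, `point` (ordering index),
#'   `segment`, `x`, `y`, `z`: origin, via and insertion points of each
#'   muscle line of action in segment frames (mm).
#' @param default_pose Named numeric vector of generalized coordinates
#'   defining the reference (e.g. standing) posture; missing coordinates
#'   default to 0.
#' @param body_mass_kg Total body mass of the subject (kg), used by the
#'   torso mass rule and for body-weight normalization.
#' @return An object of class `msk_model`.
#' @export
msk_model <- function(segments, markers = NULL, muscles = NULL,
                      paths = NULL, default_pose = NULL,
                      body_mass_kg = NA_real_) {
  segments <- as_tibble(segments)
  needed <- c("name", "parent", "joint_type", "jx", "jy", "jz",
              "mass_kg", "cx", "cy", "cz", "inertia")
  missing <- setdiff(needed, names(segments))
  if (length(missing)) {
    abort(paste0("`segments` is missing columns: ",
                 paste(missing, collapse = ", ")),
          class = "caninegait_invalid_input")
  }
  if (anyDuplicated(segments$name)) {
    abort("Segment names must be unique.", class = "caninegait_invalid_input")
  }
  if (!"coupling" %in% names(segments)) {
    segments$coupling <- vector("list", nrow(segments))
  }
  if (!"joint" %in% names(segments)) segments$joint <- segments$name
  ok_types <- c("free", "ball", "hinge", "sliding_hinge", "fixed")
  if (!all(segments$joint_type %in% ok_types)) {
    abort("Unknown joint type.", class = "caninegait_invalid_input")
  }
  root <- which(is.na(segments$parent))
  if (length(root) != 1) {
    abort("Exactly one root segment (parent = NA) is required.",
          class = "caninegait_invalid_input")
  }
  # topological order (parents before children); also detects cycles/orphans
  order <- integer(0)
  placed <- rep(FALSE, nrow(segments))
  queue <- root
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    order <- c(order, i); placed[i] <- TRUE
    kids <- which(segments$parent %in% segments$name[i])
    queue <- c(queue, kids)
  }
  if (!all(placed)) {
    abort("Segment graph is not a tree rooted at the root segment.",
          class = "caninegait_invalid_input")
  }
  segments <- segments[order, ]
  segments$parent_idx <- match(segments$parent, segments$name)
  if (any(segments$mass_kg <= 0)) {
    abort("Segment masses must be > 0.", class = "caninegait_invalid_input")
  }

  coords <- model_coord_table(segments)
  pose <- setNames(rep(0, nrow(coords)), coords$coord)
  if (!is.null(default_pose)) {
    unknown <- setdiff(names(default_pose), names(pose))
    if (length(unknown)) {
      abort(paste0("Unknown coordinates in `default_pose`: ",
                   paste(unknown, collapse = ", ")),
            class = "caninegait_invalid_input")
    }
    pose[names(default_pose)] <- default_pose
  }

  if (!is.null(markers)) {
    markers <- as_tibble(markers)
    if (!all(markers$segment %in% segments$name)) {
      abort("Marker references a segment not in the model.",
            class = "caninegait_invalid_input")
    }
  }
  if (!is.null(paths)) {
    paths <- as_tibble(paths)
    if (!all(paths$segment %in% segments$name)) {
      abort("Muscle path references a segment not in the model.",
            class = "caninegait_invalid_input")
    }
    pts_per <- table(paths$muscle)
    if (any(pts_per < 2)) {
      abort("Every muscle path needs at least an origin and an insertion.",
            class = "caninegait_invalid_input")
    }
    paths <- arrange(paths, .data$muscle, .data$point)
  }

  structure(
    list(segments = segments, coords = coords, markers = markers,
         muscles = if (!is.null(muscles)) as_tibble(muscles) else NULL,
         paths = paths, default_pose = pose, body_mass_kg = body_mass_kg),
    class = "msk_model"
  )
}

joint_coord_names <- function(type, joint) {
  suffix <- switch(type,
    free = c("_tx", "_ty", "_tz", "_rz", "_rx", "_ry"),
    ball = c("_rz", "_rx", "_ry"),
    hinge = "_rz",
    sliding_hinge = "_rz",
    fixed = character(0)
  )
  if (!length(suffix)) return(character(0))
  paste0(joint, suffix)
}

model_coord_table <- function(segments) {
  purrr::pmap_dfr(
    list(segments$name, segments$joint, segments$joint_type),
    function(seg, joint, type) {
      nm <- joint_coord_names(type, joint)
      if (!length(nm)) return(tibble())
      tibble(coord = nm, segment = seg, joint = joint,
             kind = ifelse(grepl("_t[xyz]$", nm), "translation", "rotation"))
    })
}

#' @export
print.msk_model <- function(x, ...) {
  cat(sprintf("<msk_model> %d segments, %d coordinates, %d markers, %d muscles\n",
              nrow(x$segments), nrow(x$coords),
              if (is.null(x$markers)) 0L else nrow(x$markers),
              if (is.null(x$muscles)) 0L else nrow(x$muscles)))
  if (is.finite(x$body_mass_kg)) {
    cat(sprintf("body mass %.2f kg, modeled mass %.3f kg\n",
                x$body_mass_kg, sum(x$segments$mass_kg)))
  }
  invisible(x)
}

#' @describeIn msk_model Tidy the segment table (one row per segment).
#' @param x,object An `msk_model`.
#' @param ... Unused.
#' @method tidy msk_model
#' @export
tidy.msk_model <- function(x, ...) {
  select(x$segments, "name", "parent", "joint_type", "mass_kg",
         "jx", "jy", "jz", "cx", "cy", "cz")
}

#' @describeIn msk_model One-row model summary.
#' @method glance msk_model
#' @export
glance.msk_model <- function(x, ...) {
  tibble(
    n_segments = nrow(x$segments),
    n_coords = nrow(x$coords),
    n_markers = if (is.null(x$markers)) 0L else nrow(x$markers),
    n_muscles = if (is.null(x$muscles)) 0L else nrow(x$muscles),
    modeled_mass_kg = sum(x$segments$mass_kg),
    body_mass_kg = x$body_mass_kg
  )
}

joint_rotation <- function(type, qj) {
  switch(type,
    free = rot_z(deg2rad(qj[4])) %*% rot_x(deg2rad(qj[5])) %*% rot_y(deg2rad(qj[6])),
    ball = rot_z(deg2rad(qj[1])) %*% rot_x(deg2rad(qj[2])) %*% rot_y(deg2rad(qj[3])),
    hinge = rot_z(deg2rad(qj[1])),
    sliding_hinge = rot_z(deg2rad(qj[1])),
    fixed = diag(3)
  )
}

joint_translation <- function(type, qj, coupling) {
  if (type == "free") return(qj[1:3])
  if (type == "sliding_hinge" && !is.null(coupling)) {
    return(as.numeric(coupling(qj[1])))
  }
  c(0, 0, 0)
}

#' Forward kinematics of a model pose
#'
#' Computes the world rotation matrix and origin of every segment for a
#' single pose. Rotational coordinates are in degrees, translations in
#' mm; segment origins sit at the proximal joint centers.
#'
#' @param model An [msk_model()].
#' @param q Named numeric vector of generalized coordinates (missing
#'   names default to the model's `default_pose`).
#' @return List with `R` (list of 3x3 world rotations, named by
#'   segment) and `p` (matrix of segment origins in mm, segments x 3).
#' @export
forward_kinematics <- function(model, q = NULL) {
  pose <- model$default_pose
  if (!is.null(q)) {
    if (is.null(names(q))) {
      if (length(q) != length(pose)) {
        abort("Unnamed `q` must cover every coordinate.",
              class = "caninegait_invalid_input")
      }
      pose[] <- q
    } else {
      pose[names(q)] <- q
    }
  }
  segs <- model$segments
  ns <- nrow(segs)
  R <- vector("list", ns); names(R) <- segs$name
  p <- matrix(0, ns, 3, dimnames = list(segs$name, c("x", "y", "z")))
  for (i in seq_len(ns)) {
    type <- segs$joint_type[i]
    qj <- pose[joint_coord_names(type, segs$joint[i])]
    Rj <- joint_rotation(type, qj)
    tj <- joint_translation(type, qj, segs$coupling[[i]])
    jloc <- c(segs$jx[i], segs$jy[i], segs$jz[i])
    pi_ <- segs$parent_idx[i]
    if (is.na(pi_)) {
      R[[i]] <- Rj
      p[i, ] <- jloc + tj
    } else {
      R[[i]] <- R[[pi_]] %*% Rj
      p[i, ] <- p[pi_, ] + R[[pi_]] %*% (jloc + tj)
    }
  }
  list(R = R, p = p)
}

#' Virtual marker positions for a pose
#'
#' @inheritParams forward_kinematics
#' @param markers Optional marker placement tibble; defaults to the
#'   model's own virtual markers.
#' @return Matrix (markers x 3) of world positions in mm, rownames are
#'   marker names.
#' @export
fk_markers <- function(model, q = NULL, markers = NULL) {
  markers <- markers %||% model$markers
  if (is.null(markers)) {
    abort("Model has no virtual markers.", class = "caninegait_invalid_input")
  }
  fk <- forward_kinematics(model, q)
  out <- matrix(NA_real_, nrow(markers), 3,
                dimnames = list(markers$marker, c("x", "y", "z")))
  for (i in seq_len(nrow(markers))) {
    s <- markers$segment[i]
    out[i, ] <- fk$p[s, ] + fk$R[[s]] %*% c(markers$x[i], markers$y[i], markers$z[i])
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Femorotibial translation coupling for a sliding-hinge stifle
#'
#' Builds the translation-vs-flexion coupling function of the stifle
#' from user-supplied knots via a natural cubic spline. The default
#' single zero knot yields a pure hinge (zero translation at all
#' flexion angles).
#'
#' @param knots Tibble with columns `angle_deg`, `tx_mm`, `ty_mm`
#'   (cranial/caudal and proximal/distal femorotibial translation at
#'   each flexion angle).
#' @return A function `angle_deg -> c(dx, dy, dz)` (mm).
#' @export
make_stifle_coupling <- function(knots = tibble(angle_deg = 0, tx_mm = 0,
                                                ty_mm = 0)) {
  if (nrow(knots) == 1) {
    tx <- function(a) rep(knots$tx_mm, length(a))
    ty <- function(a) rep(knots$ty_mm, length(a))
  } else {
    tx <- stats::splinefun(knots$angle_deg, knots$tx_mm, method = "natural")
    ty <- stats::splinefun(knots$angle_deg, knots$ty_mm, method = "natural")
  }
  function(angle_deg) c(tx(angle_deg), ty(angle_deg), 0)
}
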