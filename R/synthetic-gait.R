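#' Specification of a synthetic gait trial
#'
#' Collects every tunable of the synthetic canine gait generator with
#' defaults matching the modeled study conditions: a 5.4 kg dog walking
#' at 0.6 m/s, vertical ground reaction with a first peak of 51% body
#' weight at 16% of the gait cycle, braking for the first third of
#' stance then propulsion, a small mediolateral force (5% BW), and
#' 2 mm isotropic Gaussian marker noise. Identical specs (including
#' `seed`) generate bit-identical trials.
#'
#' @param seed Integer seed controlling all randomness.
#' @param body_mass_kg Body mass (kg, default 5.4).
#' @param speed_ms Walking speed (m/s, default 0.6).
#' @param cycle_duration_s Gait cycle duration (s, default 0.7).
#' @param stance_fraction Stance fraction of the cycle (default 0.6).
#' @param rate_hz Marker sampling rate (Hz, default 100).
#' @param grf_rate_hz Force platform rate (Hz, default 1000).
#' @param noise_sd_mm Marker noise SD (mm, default 2).
#' @param grf_peak1_bw First vertical GRF peak as a fraction of body
#'   weight (default 0.51).
#' @param grf_peak1_pct Timing of that peak in % of the gait cycle
#'   (default 16).
#' @param braking_fraction Fraction of stance occupied by the braking
#'   (caudally directed) cranial force (default 1/3).
#' @param ml_amp_bw Mediolateral force amplitude as a fraction of body
#'   weight (default 0.05).
#' @param contralateral `"static"` (right limb held at the default
#'   posture; only the instrumented left limb articulates) or
#'   `"phase_shifted"` (right limb runs the same waveforms half a cycle
#'   out of phase).
#' @return A list of class `gait_spec`.
#' @export
gait_spec <- function(seed = 1L, body_mass_kg = 5.4, speed_ms = 0.6,
                      cycle_duration_s = 0.7, stance_fraction = 0.6,
                      rate_hz = 100, grf_rate_hz = 1000, noise_sd_mm = 2,
                      grf_peak1_bw = 0.51, grf_peak1_pct = 16,
                      braking_fraction = 1 / 3, ml_amp_bw = 0.05,
                      contralateral = c("static", "phase_shifted")) {
  contralateral <- match.arg(contralateral)
  stopifnot_scalar(body_mass_kg, "body_mass_kg", positive = TRUE)
  stopifnot_scalar(speed_ms, "speed_ms", positive = TRUE)
  stopifnot_scalar(cycle_duration_s, "cycle_duration_s", positive = TRUE)
  if (stance_fraction <= 0 || stance_fraction >= 1) {
    abort("`stance_fraction` must be in (0, 1).",
          class = "caninegait_invalid_input")
  }
  structure(
    list(seed = as.integer(seed), body_mass_kg = body_mass_kg,
         speed_ms = speed_ms, cycle_duration_s = cycle_duration_s,
         stance_fraction = stance_fraction, rate_hz = rate_hz,
         grf_rate_hz = grf_rate_hz, noise_sd_mm = noise_sd_mm,
         grf_peak1_bw = grf_peak1_bw, grf_peak1_pct = grf_peak1_pct,
         braking_fraction = braking_fraction, ml_amp_bw = ml_amp_bw,
         contralateral = contralateral),
    class = "gait_spec"
  )
}

# ---- morphology -----------------------------------------------------------

# segment dimension and mass budget for a 5.4 kg dog; masses scale
# linearly with body mass, summing to ~0.9 kg at 5.4 kg so the torso
# point mass closes to 1.8 kg by the half-body-mass rule
segment_budget <- function() {
  tibble(
    base = c("pelvis", "femur", "tibia", "tarsus", "phalanges"),
    length_mm = c(80, 90, 100, 45, 30),
    width_mm = c(50, 25, 20, 15, 20),
    depth_mm = c(40, 25, 20, 15, 15),
    mass_kg_at_ref = c(0.33, 0.145, 0.085, 0.035, 0.02),
    bilateral = c(FALSE, TRUE, TRUE, TRUE, TRUE)
  )
}

# tissue composition of the synthetic segments (fractions of pixels)
tissue_mix <- function() {
  tibble(tissue = c("cortical_bone", "trabecular_bone", "muscle", "fat"),
         fraction = c(0.10, 0.08, 0.70, 0.12))
}

synthetic_tissue_table <- function(body_mass_kg, pixel_mm = 3.25,
                                   slice_mm = 5) {
  budget <- segment_budget()
  mix <- tissue_mix()
  dens <- setNames(tissue_densities()$density_g_cm3, tissue_densities()$tissue)
  scale <- body_mass_kg / 5.4
  rows <- purrr::pmap_dfr(budget, function(base, length_mm, width_mm,
                                           depth_mm, mass_kg_at_ref,
                                           bilateral) {
    segs <- if (bilateral) paste0(base, c("_L", "_R")) else base
    target <- mass_kg_at_ref * scale
    # mean density of the mix sets the total pixel count for the target mass
    mean_rho <- sum(mix$fraction * dens[mix$tissue])
    n_total <- target * 1e6 / (mean_rho * pixel_mm^2 * slice_mm)
    purrr::map_dfr(segs, function(s) {
      tibble(segment = s, tissue = mix$tissue,
             n_pixels = round(n_total * mix$fraction),
             pixel_mm = pixel_mm, slice_mm = slice_mm)
    })
  })
  rows
}

# uniform voxel grid filling a cuboid, for the inertia summation
cuboid_voxels <- function(length_mm, width_mm, depth_mm, pitch_mm = 3.25,
                          slice_mm = 5) {
  xs <- seq(-width_mm / 2 + pitch_mm / 2, width_mm / 2, by = pitch_mm)
  ys <- seq(-length_mm + slice_mm / 2, 0, by = slice_mm)
  zs <- seq(-depth_mm / 2 + pitch_mm / 2, depth_mm / 2, by = pitch_mm)
  g <- expand.grid(x = xs, y = ys, z = zs)
  tibble(x = g$x, y = g$y, z = g$z, tissue = "muscle")
}

# left-limb muscle attachment table: origin, optional via, insertion
# (segment-local mm). Mirrored for the right limb.
muscle_attachments <- function() {
  A <- function(muscle, ...) {
    pts <- list(...)
    purrr::imap_dfr(pts, function(p, i) {
      tibble(muscle = muscle, point = as.integer(i), segment = p[[1]],
             x = p[[2]], y = p[[3]], z = p[[4]])
    })
  }
  bind_rows(
    A("Adductor longus", list("pelvis", -15, -25, -10), list("femur_L", -3, -45, -5)),
    A("Adductor magnus et brevis", list("pelvis", -20, -25, -12), list("femur_L", -5, -55, -5)),
    A("Biceps femoris (patellar)", list("pelvis", -42, -8, -22),
      list("femur_L", 8, -85, -16), list("tibia_L", 12, -12, -8)),
    A("Biceps femoris (tibial)", list("pelvis", -42, -8, -22), list("tibia_L", -8, -25, -10)),
    A("Biceps femoris (calcaneal)", list("pelvis", -42, -8, -22),
      list("tibia_L", -10, -60, -10), list("tarsus_L", -20, 3, -8)),
    A("Extensor digitorum lateralis", list("tibia_L", 2, -40, -12),
      list("tarsus_L", 4, -2, -8), list("tarsus_L", 3, -42, -8)),
    A("Extensor digitorum longus", list("femur_L", 6, -85, -10),
      list("tibia_L", 8, -15, -8), list("tarsus_L", 6, -2, -6),
      list("tarsus_L", 5, -40, -6)),
    A("Flexor digitorum profundus", list("tibia_L", -6, -25, -6),
      list("tarsus_L", -12, -5, -6), list("tarsus_L", -2, -40, -6)),
    A("Flexor digitorum superficialis", list("femur_L", -8, -82, -8),
      list("tarsus_L", -18, 2, -7), list("tarsus_L", -3, -42, -7)),
    A("Gastrocnemius lateralis", list("femur_L", -8, -80, -12), list("tarsus_L", -20, 3, -8)),
    A("Gastrocnemius medialis", list("femur_L", -8, -80, -5), list("tarsus_L", -20, 3, -4)),
    A("Gemelli", list("pelvis", -30, -10, -22), list("femur_L", -6, -12, -10)),
    A("Gluteus medius", list("pelvis", 10, 15, -28), list("femur_L", -8, -10, -12)),
    A("Gluteus profundus", list("pelvis", 0, 5, -28), list("femur_L", -5, -8, -14)),
    A("Gluteus superficialis", list("pelvis", -5, 10, -30), list("femur_L", -6, -20, -12)),
    A("Gracilis", list("pelvis", -20, -28, -10), list("tibia_L", -4, -20, -6)),
    A("Iliopsoas", list("pelvis", 25, -15, -20), list("femur_L", 8, -25, -8)),
    A("Obturator externus", list("pelvis", -25, -20, -15), list("femur_L", -6, -15, -8)),
    A("Obturator internus", list("pelvis", -25, -12, -15), list("femur_L", -6, -15, -10)),
    A("Pectineus", list("pelvis", -22, -28, -12), list("femur_L", 0, -40, -6)),
    A("Peroneus longus", list("tibia_L", 0, -15, -14),
      list("tarsus_L", 2, -2, -10), list("tarsus_L", 0, -38, -10)),
    A("Popliteus", list("femur_L", -5, -85, -10), list("tibia_L", -5, -20, -5)),
    A("Quadratus femoris", list("pelvis", -35, -15, -20), list("femur_L", -8, -20, -8)),
    A("Rectus femoris", list("pelvis", 10, -25, -22),
      list("femur_L", 15, -85, -5), list("tibia_L", 12, -15, -5)),
    A("Sartorius caudalis", list("pelvis", 33, -5, -20), list("tibia_L", 5, -25, -8)),
    A("Sartorius cranialis", list("pelvis", 35, 0, -20), list("tibia_L", 10, -20, -8)),
    A("Semimembranosus (tibial)", list("pelvis", -40, -12, -15), list("tibia_L", -6, -20, -6)),
    A("Semimembranosus (femoral)", list("pelvis", -40, -12, -15), list("femur_L", -8, -70, -5)),
    A("Semitendinosus", list("pelvis", -44, -10, -18), list("tibia_L", -5, -40, -5)),
    A("Tensor fascia lata", list("pelvis", -5, -12, -28), list("femur_L", 6, -40, -15)),
    A("Tibialis cranialis", list("tibia_L", 8, -15, -6),
      list("tarsus_L", 7, -3, -5), list("tarsus_L", 6, -35, -5)),
    A("Vastus lateralis and intermedius", list("femur_L", 8, -20, -10),
      list("femur_L", 15, -85, -5), list("tibia_L", 12, -12, -6)),
    A("Vastus medialis", list("femur_L", 8, -25, -3),
      list("femur_L", 14, -85, -2), list("tibia_L", 12, -12, -4))
  )
}

# marker placements (left limb instrumented; bilateral iliac crests)
marker_placements <- function() {
  tibble::tribble(
    ~marker, ~segment, ~x, ~y, ~z,
    "iliac_crest_L", "pelvis", 40, 10, -25,
    "iliac_crest_R", "pelvis", 40, 10, 25,
    "ischiatic_tuberosity_L", "pelvis", -40, 0, -25,
    "greater_trochanter_L", "femur_L", 0, 5, -12,
    "lateral_femoral_condyle_L", "femur_L", 0, -90, -15,
    "fibular_head_L", "tibia_L", 0, -10, -15,
    "tibial_crest_L", "tibia_L", 12, -15, -5,
    "lateral_malleolus_L", "tibia_L", 0, -100, -12,
    "calcaneus_L", "tarsus_L", -15, 5, -8,
    "distal_5th_metatarsal_L", "tarsus_L", 0, -45, -10,
    "dorsal_paw_L", "phalanges_L", 20, -5, 0
  )
}

default_standing_pose <- function(pelvis_height_mm) {
  c(pelvis_tx = 0, pelvis_ty = pelvis_height_mm, pelvis_tz = 0,
    pelvis_rz = 0, pelvis_rx = 0, pelvis_ry = 0,
    hip_L_rz = 35, hip_L_rx = 0, hip_L_ry = 0,
    stifle_L_rz = -70, tarsus_L_rz = 45,
    hip_R_rz = 35, hip_R_rx = 0, hip_R_ry = 0,
    stifle_R_rz = -70, tarsus_R_rz = 45)
}

#' Generate a synthetic subject morphology
#'
#' Builds the bilateral pelvis + pelvic limb model of a synthetic dog
#' of the given body mass: per-segment tissue voxel tables (coarsened
#' CT-style grids) whose density-weighted masses leave a positive torso
#' point mass under the half-body-mass rule; cuboid voxel grids for the
#' inertia tensors; virtual markers at the ten instrumented sites; and
#' the packaged muscle roster attached along anatomically plausible
#' lines of action, with fiber and tendon slack lengths adjusted to the
#' musculotendon length in the default (mid-stance-like) posture and
#' maximum isometric forces recomputed from the adjusted fiber lengths.
#'
#' @param spec A [gait_spec()].
#' @return List with `model` (an [msk_model()]) and `tissue_table`.
#' @export
generate_morphology <- function(spec = gait_spec()) {
  budget <- segment_budget()
  tt <- synthetic_tissue_table(spec$body_mass_kg)
  masses <- compute_segment_mass(tt)

  seg_mass <- setNames(masses$mass_kg, masses$segment)
  torso_mass <- compute_torso_mass(spec$body_mass_kg, sum(seg_mass))

  inertia_for <- function(base, mass) {
    b <- budget[budget$base == base, ]
    vox <- cuboid_voxels(b$length_mm, b$width_mm, b$depth_mm)
    raw <- compute_segment_inertia(vox, pixel_mm = 3.25, slice_mm = 5)
    raw$inertia_kg_m2 * (mass / raw$mass_kg)   # same shape, target mass
  }

  hip_y <- -20
  seg_rows <- list(
    list(name = "pelvis", parent = NA, joint_type = "free",
         joint = "pelvis", j = c(0, 0, 0), base = "pelvis",
         com = c(0, -10, 0)),
    list(name = "torso", parent = "pelvis", joint_type = "fixed",
         joint = "torso", j = c(40, -10, 0), base = NA,
         com = c(20, -10, 0)),
    list(name = "femur_L", parent = "pelvis", joint_type = "ball",
         joint = "hip_L", j = c(-30, hip_y, -25), base = "femur",
         com = c(0, -45, 0)),
    list(name = "tibia_L", parent = "femur_L", joint_type = "sliding_hinge",
         joint = "stifle_L", j = c(0, -90, 0), base = "tibia",
         com = c(0, -50, 0)),
    list(name = "tarsus_L", parent = "tibia_L", joint_type = "hinge",
         joint = "tarsus_L", j = c(0, -100, 0), base = "tarsus",
         com = c(0, -22, 0)),
    list(name = "phalanges_L", parent = "tarsus_L", joint_type = "fixed",
         joint = "mtp_L", j = c(0, -45, 0), base = "phalanges",
         com = c(15, -8, 0)),
    list(name = "femur_R", parent = "pelvis", joint_type = "ball",
         joint = "hip_R", j = c(-30, hip_y, 25), base = "femur",
         com = c(0, -45, 0)),
    list(name = "tibia_R", parent = "femur_R", joint_type = "sliding_hinge",
         joint = "stifle_R", j = c(0, -90, 0), base = "tibia",
         com = c(0, -50, 0)),
    list(name = "tarsus_R", parent = "tibia_R", joint_type = "hinge",
         joint = "tarsus_R", j = c(0, -100, 0), base = "tarsus",
         com = c(0, -22, 0)),
    list(name = "phalanges_R", parent = "tarsus_R", joint_type = "fixed",
         joint = "mtp_R", j = c(0, -45, 0), base = "phalanges",
         com = c(15, -8, 0))
  )
  segments <- purrr::map_dfr(seg_rows, function(s) {
    if (is.na(s$base)) {  # torso point mass: negligible rotary inertia
      m <- torso_mass
      inert <- diag(1e-6, 3)
      len <- NA_real_
    } else {
      m <- seg_mass[[s$name]]
      inert <- inertia_for(s$base, m)
      len <- budget$length_mm[budget$base == s$base]
    }
    tibble(name = s$name, parent = s$parent, joint_type = s$joint_type,
           joint = s$joint, jx = s$j[1], jy = s$j[2], jz = s$j[3],
           mass_kg = m, cx = s$com[1], cy = s$com[2], cz = s$com[3],
           inertia = list(inert), length_mm = len)
  })

  paths_L <- muscle_attachments()
  paths_R <- paths_L %>%
    mutate(segment = sub("_L$", "_R", .data$segment), z = -.data$z,
           muscle = paste0(.data$muscle, " (R)"))
  paths <- bind_rows(paths_L, paths_R)

  # standing pose: pelvis height puts the paw on the ground
  pose0 <- default_standing_pose(0)
  base_model <- msk_model(segments, markers = marker_placements(),
                         paths = paths_L, default_pose = pose0,
                         body_mass_kg = spec$body_mass_kg)
  fk <- forward_kinematics(base_model)
  paw_y <- fk$p["phalanges_L", 2] - 10   # paw pad 10 mm below the joint
  pose <- default_standing_pose(-paw_y)

  roster <- canine_muscles()
  # left-limb parameters from the roster, adjusted to the model's own
  # mid-stance musculotendon lengths (the right limb shares them)
  model_tmp <- msk_model(segments, markers = marker_placements(),
                         paths = paths_L, default_pose = pose,
                         body_mass_kg = spec$body_mass_kg)
  mtu0 <- musculotendon_length(model_tmp)
  roster <- roster %>%
    left_join(mtu0, by = "muscle") %>%
    mutate(adjust_fiber_and_tendon(.data$optimal_fiber_cm,
                                   .data$tendon_slack_cm, .data$mtu_cm),
           f_iso_n = max_isometric_force(.data$volume_cm3,
                                         .data$pennation_deg, .data$f_adj))
  muscles <- roster %>%
    transmute(muscle = .data$muscle, volume_cm3 = .data$volume_cm3,
              pennation_deg = .data$pennation_deg,
              f_adj_cm = .data$f_adj, tsl_adj_cm = .data$tsl_adj,
              f_iso_n = .data$f_iso_n, mtu_midstance_cm = .data$mtu_cm)

  model <- msk_model(segments, markers = marker_placements(),
                     muscles = muscles, paths = paths_L,
                     default_pose = pose,
                     body_mass_kg = spec$body_mass_kg)
  list(model = model, tissue_table = tt, torso_mass_kg = torso_mass)
}

# ---- trial ----------------------------------------------------------------

# least-squares projection of a periodic target onto a 3-harmonic
# Fourier basis; returns a function of cycle phase in [0, 1)
fourier3 <- function(phases, values) {
  X <- cbind(1, cos(2 * pi * phases), sin(2 * pi * phases),
             cos(4 * pi * phases), sin(4 * pi * phases),
             cos(6 * pi * phases), sin(6 * pi * phases))
  beta <- qr.solve(X, values)
  function(phi) {
    Xp <- cbind(1, cos(2 * pi * phi), sin(2 * pi * phi),
                cos(4 * pi * phi), sin(4 * pi * phi),
                cos(6 * pi * phi), sin(6 * pi * phi))
    as.numeric(Xp %*% beta)
  }
}

# periodic spline through knots, sampled densely, then Fourier-smoothed
waveform_from_knots <- function(knot_phi, knot_val) {
  sp <- stats::splinefun(c(knot_phi, knot_phi[1] + 1),
                         c(knot_val, knot_val[1]), method = "periodic")
  phi <- seq(0, 1, length.out = 201)[-201]
  fourier3(phi, sp(phi))
}

joint_waveforms <- function() {
  list(
    hip_rz = waveform_from_knots(c(0, 0.3, 0.55, 0.8),
                                 c(12, -8, -15, 14)),
    stifle_rz = waveform_from_knots(c(0, 0.15, 0.35, 0.55, 0.75, 0.9),
                                    c(0, -6, -2, -10, -28, -10)),
    tarsus_rz = waveform_from_knots(c(0, 0.2, 0.45, 0.6, 0.8),
                                    c(0, -8, 8, 14, -16)),
    hip_rx = function(phi) 3 * sin(2 * pi * phi),
    hip_ry = function(phi) 2 * cos(2 * pi * phi) - 2,
    pelvis_ty = function(phi) 5 * sin(4 * pi * phi),
    pelvis_rz = function(phi) 1.5 * sin(2 * pi * phi)
  )
}

joint_limits <- function() {
  tibble(coord = c("hip_L_rz", "stifle_L_rz", "tarsus_L_rz"),
         lower = c(-60, -140, -40), upper = c(110, 20, 110))
}

# vertical GRF template on stance phase [0, 1]: first peak of
# `peak1_bw` BW placed exactly at the prescribed stance phase, followed
# by a lower propulsive hump; edge-smoothed. The first-bump center and
# the overall scale are calibrated (deterministically, on a fine grid)
# so the early local maximum sits exactly at `phi1_stance` with value
# `peak1_bw * bw_n` despite the window and second-hump overlap.
grf_vertical <- function(phi_stance, bw_n, peak1_bw, phi1_stance) {
  ramp <- function(u) ifelse(u <= 0, 0, ifelse(u >= 1, 1, u^2 * (3 - 2 * u)))
  shape <- function(phi, c1) {
    win <- ramp(phi / 0.08) * ramp((1 - phi) / 0.12)
    (exp(-((phi - c1) / 0.14)^2) + 0.85 * exp(-((phi - 0.72) / 0.24)^2)) * win
  }
  grid <- seq(0, 1, by = 1e-4)
  early <- grid < 0.5
  c1 <- phi1_stance
  for (i in 1:25) {
    peak_at <- grid[early][which.max(shape(grid[early], c1))]
    if (abs(peak_at - phi1_stance) < 1e-4) break
    c1 <- c1 + (phi1_stance - peak_at)
  }
  scale <- peak1_bw * bw_n / shape(phi1_stance, c1)
  scale * shape(phi_stance, c1)
}

#' Generate a synthetic gait trial
#'
#' Produces a self-consistent gait trial for a synthetic subject:
#' smooth periodic joint-angle waveforms (3-harmonic Fourier series
#' with hip/stifle/tarsus ranges typical of a walking Dachshund) drive
#' the model's forward kinematics; markers at the ten instrumented
#' sites are the forward-kinematic positions plus seeded isotropic
#' Gaussian noise; the ground reaction follows the parameterized
#' double-peak vertical / braking-propulsion cranial template with the
#' center of pressure under the paw; and ground-truth joint moments
#' come from noise-free inverse dynamics. The force record extends past
#' the cycle end into the next paw contact so cycle segmentation has a
#' closing event.
#'
#' @param spec A [gait_spec()].
#' @param model Optional model from [generate_morphology()] (generated
#'   from `spec` if omitted).
#' @return List of class `synthetic_trial`: `markers` (noisy),
#'   `markers_clean`, `grf` (at `grf_rate_hz`), `truth_coords`,
#'   `truth_angles` (the left hip/stifle/tarsus flexion coordinates on
#'   the 100-point cycle), `truth_moments`, `cycle`, `model`, `spec`.
#' @export
generate_trial <- function(spec = gait_spec(), model = NULL) {
  if (is.null(model)) model <- generate_morphology(spec)$model
  Tcyc <- spec$cycle_duration_s
  nf <- round(Tcyc * spec$rate_hz)
  times <- seq(0, nf) / spec$rate_hz
  phi <- (times / Tcyc) %% 1
  phi[length(phi)] <- 1    # closing frame of the cycle
  wf <- joint_waveforms()
  pose <- model$default_pose

  dev <- list(
    hip_L_rz = wf$hip_rz(phi), stifle_L_rz = wf$stifle_rz(phi),
    tarsus_L_rz = wf$tarsus_rz(phi),
    hip_L_rx = wf$hip_rx(phi), hip_L_ry = wf$hip_ry(phi),
    pelvis_ty = wf$pelvis_ty(phi), pelvis_rz = wf$pelvis_rz(phi)
  )
  if (spec$contralateral == "phase_shifted") {
    phi_r <- (phi + 0.5) %% 1
    dev$hip_R_rz <- wf$hip_rz(phi_r)
    dev$stifle_R_rz <- wf$stifle_rz(phi_r)
    dev$tarsus_R_rz <- wf$tarsus_rz(phi_r)
  }

  qw <- tibble(time = times)
  for (cc in names(pose)) qw[[cc]] <- rep(pose[[cc]], length(times))
  for (cc in names(dev)) qw[[cc]] <- qw[[cc]] + dev[[cc]]
  qw$pelvis_tx <- qw$pelvis_tx + spec$speed_ms * 1000 * times

  lim <- joint_limits()
  for (i in seq_len(nrow(lim))) {
    v <- qw[[lim$coord[i]]]
    if (any(v < lim$lower[i] | v > lim$upper[i])) {
      abort(sprintf("Waveform drives %s outside its joint limits.",
                    lim$coord[i]),
            class = "caninegait_joint_limit")
    }
  }

  # clean markers by forward kinematics
  cn <- setdiff(names(qw), "time")
  clean <- purrr::map_dfr(seq_along(times), function(f) {
    q <- setNames(as.numeric(qw[f, cn]), cn)
    mk <- fk_markers(model, q)
    tibble(time = times[f], marker = rownames(mk),
           x = unname(mk[, 1]), y = unname(mk[, 2]), z = unname(mk[, 3]),
           visible = TRUE)
  })
  noisy <- clean
  if (spec$noise_sd_mm > 0) {
    noisy <- withr::with_seed(spec$seed, {
      n <- nrow(clean)
      mutate(clean,
             x = .data$x + stats::rnorm(n, 0, spec$noise_sd_mm),
             y = .data$y + stats::rnorm(n, 0, spec$noise_sd_mm),
             z = .data$z + stats::rnorm(n, 0, spec$noise_sd_mm))
    })
  }

  # ground reaction at the force-plate rate, spanning into the next cycle
  bw <- spec$body_mass_kg * 9.81
  gt <- seq(0, 1.15 * Tcyc, by = 1 / spec$grf_rate_hz)
  phi_c <- (gt / Tcyc) %% 1
  in_stance <- phi_c < spec$stance_fraction
  phi_s <- ifelse(in_stance, phi_c / spec$stance_fraction, NA_real_)
  phi1_s <- (spec$grf_peak1_pct / 100) / spec$stance_fraction
  fy <- ifelse(in_stance,
               grf_vertical(phi_s, bw, spec$grf_peak1_bw, phi1_s), 0)
  brake <- spec$braking_fraction
  fx <- ifelse(in_stance & phi_s < brake,
               -0.08 * bw * sin(pi * phi_s / brake),
               ifelse(in_stance,
                      0.06 * bw * sin(pi * (phi_s - brake) / (1 - brake)), 0))
  fz <- ifelse(in_stance, -spec$ml_amp_bw * bw * sin(pi * phi_s), 0)
  tv <- ifelse(in_stance, 0.002 * bw * sin(2 * pi * phi_s), 0)

  # COP under the paw (stance paw is nearly stationary; use its
  # position at the corresponding kinematic phase)
  paw <- purrr::map_dfr(seq_along(times), function(f) {
    q <- setNames(as.numeric(qw[f, cn]), cn)
    fk <- forward_kinematics(model, q)
    pp <- fk$p["phalanges_L", ] + fk$R[["phalanges_L"]] %*% c(15, -10, 0)
    tibble(time = times[f], px = pp[1] / 1000, pz = pp[3] / 1000)
  })
  copx <- approx(paw$time, paw$px, xout = pmin(gt %% Tcyc, max(paw$time)),
                 rule = 2)$y
  copz <- approx(paw$time, paw$pz, xout = pmin(gt %% Tcyc, max(paw$time)),
                 rule = 2)$y
  grf <- tibble(time = gt, fx = fx, fy = fy, fz = fz, tv = tv,
                copx = ifelse(fy > 0, copx, 0), copy = 0,
                copz = ifelse(fy > 0, copz, 0))

  truth_moments <- inverse_dynamics(qw, model, grf)
  truth_angles <- purrr::map_dfr(
    c(hip = "hip_L_rz", stifle = "stifle_L_rz", tarsus = "tarsus_L_rz"),
    function(cc) {
      rs <- resample_cycle(qw[, c("time", cc)], n = 100)
      tibble(cycle_pct = rs$cycle_pct, angle_deg = rs[[cc]])
    }, .id = "joint")

  structure(
    list(markers = noisy, markers_clean = clean, grf = grf,
         truth_coords = qw, truth_angles = truth_angles,
         truth_moments = truth_moments,
         cycle = tibble(start_time = 0, end_time = Tcyc,
                        stance_fraction = spec$stance_fraction),
         model = model, spec = spec),
    class = "synthetic_trial"
  )
}

#' Corrupt a synthetic trial for recovery experiments
#'
#' Injects known defects whose recovery the pipeline can be tested
#' against: marker occlusion gaps, a constant force-plate bias, and a
#' torso COM offset. The injected truth is recorded in the returned
#' trial.
#'
#' @param trial A `synthetic_trial`.
#' @param gaps Optional tibble `marker`, `start_frame`, `length`:
#'   frames to blank out (coordinates set NA, `visible = FALSE`).
#' @param grf_bias Optional named numeric, e.g. `c(fx = 1, fy = -2)`
#'   (N), added to the force channels over the whole record.
#' @param torso_offset_mm Optional scalar: cranial shift applied to the
#'   model torso COM (the kinematics and forces are untouched, so
#'   residual reduction should recover the shift).
#' @return The modified `synthetic_trial` with an `injected` element.
#' @export
corrupt_trial <- function(trial, gaps = NULL, grf_bias = NULL,
                          torso_offset_mm = NULL) {
  stopifnot(inherits(trial, "synthetic_trial"))
  nf <- length(unique(trial$markers$time))
  if (!is.null(gaps)) {
    for (i in seq_len(nrow(gaps))) {
      if (gaps$start_frame[i] + gaps$length[i] - 1 > nf) {
        abort("Gap extends beyond the trial.",
              class = "caninegait_invalid_input")
      }
      tt <- sort(unique(trial$markers$time))
      frames <- tt[gaps$start_frame[i]:(gaps$start_frame[i] + gaps$length[i] - 1)]
      idx <- trial$markers$marker == gaps$marker[i] &
        trial$markers$time %in% frames
      trial$markers$x[idx] <- NA_real_
      trial$markers$y[idx] <- NA_real_
      trial$markers$z[idx] <- NA_real_
      trial$markers$visible[idx] <- FALSE
    }
  }
  if (!is.null(grf_bias)) {
    for (cc in names(grf_bias)) {
      trial$grf[[cc]] <- trial$grf[[cc]] + grf_bias[[cc]]
    }
  }
  if (!is.null(torso_offset_mm)) {
    i <- match("torso", trial$model$segments$name)
    trial$model$segments$cx[i] <- trial$model$segments$cx[i] + torso_offset_mm
  }
  trial$injected <- list(gaps = gaps, grf_bias = grf_bias,
                         torso_offset_mm = torso_offset_mm)
  trial
}
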