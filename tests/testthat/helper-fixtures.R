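# shared fixtures, built in code

# single hinge pendulum under a massless free root
pendulum_model <- function(mass = 2, com_mm = -150, izz = 0.004) {
  segs <- tibble::tibble(
    name = c("base", "rod"), parent = c(NA, "base"),
    joint_type = c("free", "hinge"), joint = c("base", "hinge"),
    jx = 0, jy = 0, jz = 0, mass_kg = c(1e-9, mass),
    cx = 0, cy = c(0, com_mm), cz = 0,
    inertia = list(diag(1e-12, 3), diag(c(1e-6, 1e-6, izz)))
  )
  msk_model(segs)
}

# three-link planar chain hanging from a (near-massless) free root
chain3_model <- function() {
  segs <- tibble::tibble(
    name = c("base", "link1", "link2", "link3"),
    parent = c(NA, "base", "link1", "link2"),
    joint_type = c("free", "hinge", "hinge", "hinge"),
    joint = c("base", "j1", "j2", "j3"),
    jx = c(0, 0, 0, 0), jy = c(0, 0, -150, -120), jz = 0,
    mass_kg = c(1e-9, 1.2, 0.8, 0.3),
    cx = 0, cy = c(0, -75, -60, -40), cz = 0,
    inertia = list(diag(1e-12, 3), diag(c(1e-6, 1e-6, 3e-3)),
                   diag(c(1e-6, 1e-6, 1.5e-3)), diag(c(1e-6, 1e-6, 4e-4)))
  )
  msk_model(segs)
}

# hinge with a one-muscle "pulley" path (via point fixed on the child)
pulley_model <- function(R_mm = 20) {
  segs <- tibble::tibble(
    name = c("base", "arm"), parent = c(NA, "base"),
    joint_type = c("free", "hinge"), joint = c("base", "hinge"),
    jx = 0, jy = c(0, -150), jz = 0, mass_kg = c(1e-9, 1),
    cx = 0, cy = c(0, -50), cz = 0,
    inertia = list(diag(1e-12, 3), diag(1e-3, 3))
  )
  paths <- tibble::tibble(
    muscle = "puller", point = 1:2,
    segment = c("base", "arm"),
    x = c(-R_mm, -R_mm), y = c(-20, -10), z = 0
  )
  msk_model(segs, paths = paths,
            muscles = tibble::tibble(muscle = "puller", f_iso_n = 100,
                                     pennation_deg = 0, f_adj_cm = 3,
                                     tsl_adj_cm = 10))
}

# planar two-link toy for musculotendon length trigonometry
twolink_muscle_model <- function() {
  segs <- tibble::tibble(
    name = c("base", "upper", "lower"), parent = c(NA, "base", "upper"),
    joint_type = c("free", "hinge", "hinge"),
    joint = c("base", "shoulder", "elbow"),
    jx = 0, jy = c(0, 0, -150), jz = 0, mass_kg = c(1e-9, 1, 1),
    cx = 0, cy = c(0, -75, -75), cz = 0,
    inertia = list(diag(1e-12, 3), diag(1e-3, 3), diag(1e-3, 3))
  )
  paths <- tibble::tibble(
    muscle = "flexor", point = 1:2,
    segment = c("upper", "lower"),
    x = 0, y = c(-100, -50), z = 0
  )
  msk_model(segs, paths = paths,
            muscles = tibble::tibble(muscle = "flexor", f_iso_n = 100,
                                     pennation_deg = 0, f_adj_cm = 4,
                                     tsl_adj_cm = 6))
}

# cached synthetic trials (the generator is deterministic, so caching
# only saves test time)
.trial_cache <- new.env(parent = emptyenv())

cached_morphology <- function() {
  if (!exists("morph", envir = .trial_cache)) {
    assign("morph", generate_morphology(gait_spec()), envir = .trial_cache)
  }
  get("morph", envir = .trial_cache)
}

cached_trial <- function(seed = 1, noise_sd_mm = 2) {
  key <- paste0("s", seed, "_n", noise_sd_mm)
  if (!exists(key, envir = .trial_cache)) {
    trial <- generate_trial(gait_spec(seed = seed, noise_sd_mm = noise_sd_mm),
                            cached_morphology()$model)
    assign(key, trial, envir = .trial_cache)
  }
  get(key, envir = .trial_cache)
}

# signed perpendicular distance (z-plane) from a point to a segment line
perp_distance_z <- function(joint_xy, p1, p2) {
  d <- p2 - p1
  v <- joint_xy - p1[1:2]
  abs(d[1] * v[2] - d[2] * v[1]) / sqrt(sum(d[1:2]^2))
}

cross3_test <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
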