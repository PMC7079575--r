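#' Reference tissue densities for CT-derived segment masses
#'
#' Average densities for the four tissue classes segmented from CT
#' (cortical bone, trabecular bone, muscle, fat), in g/cm^3, as reported
#' for canine tissue.
#'
#' @return A tibble with columns `tissue` and `density_g_cm3`.
#' @export
#' @examples
#' tissue_densities()
tissue_densities <- function() {
  tibble(
    tissue = c("cortical_bone", "trabecular_bone", "muscle", "fat"),
    density_g_cm3 = c(2.003, 1.911, 1.06, 0.95)
  )
}

validate_tissue_table <- function(tissue_table) {
  needed <- c("segment", "tissue", "n_pixels", "pixel_mm", "slice_mm")
  missing <- setdiff(needed, names(tissue_table))
  if (length(missing)) {
    abort(paste0("Tissue table is missing columns: ",
                 paste(missing, collapse = ", ")),
          class = "caninegait_invalid_input")
  }
  if (any(tissue_table$n_pixels < 0, na.rm = TRUE) ||
      any(abs(tissue_table$n_pixels - round(tissue_table$n_pixels)) > 1e-8,
          na.rm = TRUE)) {
    abort("Pixel counts must be non-negative integers.",
          class = "caninegait_invalid_input")
  }
  if (any(tissue_table$pixel_mm <= 0) || any(tissue_table$slice_mm <= 0)) {
    abort("Pixel size and slice thickness must be > 0.",
          class = "caninegait_invalid_input")
  }
  invisible(tissue_table)
}

#' Segment mass from a CT tissue voxel table
#'
#' Mass of each body segment as the density-weighted sum of its tissue
#' voxel volumes: `m = sum_i rho_i * P^2 * S * N_i` over the four tissue
#' classes, where `P` is the pixel width/height (mm), `S` the slice
#' thickness (mm) and `N_i` the pixel count of class `i`. Volumes are
#' converted mm^3 -> cm^3 and masses g -> kg.
#'
#' @param tissue_table Tibble with columns `segment`, `tissue`,
#'   `n_pixels`, `pixel_mm`, `slice_mm` (one row per segment x tissue
#'   class; a zero count is allowed and contributes nothing).
#' @param segment Optional segment name(s) to restrict the result to.
#' @param densities Tissue density lookup, as [tissue_densities()].
#' @return Tibble with columns `segment` and `mass_kg`.
#' @export
#' @examples
#' tt <- tibble::tibble(
#'   segment = "femur_L", tissue = "muscle",
#'   n_pixels = 1e6, pixel_mm = 0.325, slice_mm = 1
#' )
#' compute_segment_mass(tt)  # 0.112 kg
compute_segment_mass <- function(tissue_table, segment = NULL,
                                 densities = tissue_densities()) {
  validate_tissue_table(tissue_table)
  if (any(densities$density_g_cm3 <= 0)) {
    abort("Tissue densities must be > 0.", class = "caninegait_invalid_input")
  }
  out <- tissue_table %>%
    left_join(densities, by = "tissue") %>%
    mutate(
      mass_kg = .data$density_g_cm3 * .data$pixel_mm^2 * .data$slice_mm *
        .data$n_pixels / 1e6
    )
  if (anyNA(out$mass_kg)) {
    bad <- unique(out$tissue[is.na(out$mass_kg)])
    abort(paste0("Unknown tissue class(es): ", paste(bad, collapse = ", ")),
          class = "caninegait_invalid_input")
  }
  out <- out %>%
    group_by(.data$segment) %>%
    summarise(mass_kg = sum(.data$mass_kg), .groups = "drop")
  if (!is.null(segment)) {
    out <- out[match(segment, out$segment), , drop = FALSE]
    if (anyNA(out$segment)) {
      abort("Requested segment not present in tissue table.",
            class = "caninegait_invalid_input")
    }
  }
  out
}

#' Torso point mass from the half-body-mass rule
#'
#' The caudal abdominal mass carried by the pelvic limbs is modeled as a
#' torso point mass equal to half the total body mass minus the mass of
#' all other model segments (the body is assumed evenly supported by the
#' thoracic and pelvic limbs).
#'
#' @param total_mass Total body mass (kg).
#' @param segment_mass_sum Summed mass of all modeled bony segments (kg).
#' @return Torso mass (kg), a single number.
#' @export
#' @examples
#' compute_torso_mass(5.4, 0.9)  # 1.8
compute_torso_mass <- function(total_mass, segment_mass_sum) {
  stopifnot_scalar(total_mass, "total_mass", positive = TRUE)
  stopifnot_scalar(segment_mass_sum, "segment_mass_sum")
  if (segment_mass_sum < 0) {
    abort("`segment_mass_sum` must be >= 0.",
          class = "caninegait_invalid_input")
  }
  torso <- total_mass / 2 - segment_mass_sum
  if (torso <= 0) {
    abort("Segment masses meet or exceed half the body mass; torso mass would be non-positive.",
          class = "caninegait_nonpositive_torso")
  }
  torso
}

#' Segment inertia tensor from a labeled voxel cloud
#'
#' Voxel-wise summation of point-mass inertia contributions about the
#' segment center of mass, expressed in the anatomical axes. Each voxel
#' of tissue class `i` carries mass `rho_i * P^2 * S`; the tensor is the
#' parallel-axis sum `sum m_v (|r|^2 I - r r^T)` with `r` the voxel
#' offset from the COM, optionally rotated into anatomical axes.
#'
#' @param voxels Tibble with voxel center coordinates `x`, `y`, `z` (mm)
#'   and a `tissue` column.
#' @param pixel_mm,slice_mm Voxel in-plane size and slice thickness (mm).
#' @param axes Optional 3x3 orthonormal matrix whose columns are the
#'   anatomical x/y/z axes expressed in the voxel coordinate frame; the
#'   tensor is reported in these axes. Default identity.
#' @param densities Tissue density lookup, as [tissue_densities()].
#' @return List with `inertia_kg_m2` (3x3, about COM, anatomical axes),
#'   `mass_kg`, and `com_mm` (in the voxel frame).
#' @export
compute_segment_inertia <- function(voxels, pixel_mm, slice_mm,
                                    axes = diag(3),
                                    densities = tissue_densities()) {
  if (nrow(voxels) == 0) {
    abort("Empty voxel set.", class = "caninegait_invalid_input")
  }
  stopifnot_scalar(pixel_mm, "pixel_mm", positive = TRUE)
  stopifnot_scalar(slice_mm, "slice_mm", positive = TRUE)
  rho <- setNames(densities$density_g_cm3, densities$tissue)
  if (anyNA(rho[voxels$tissue])) {
    abort("Unknown tissue class in voxel table.",
          class = "caninegait_invalid_input")
  }
  # per-voxel mass in kg: rho [g/cm^3] * volume [mm^3] / 1e6
  m_v <- rho[voxels$tissue] * pixel_mm^2 * slice_mm / 1e6
  mass <- sum(m_v)
  com <- c(sum(m_v * voxels$x), sum(m_v * voxels$y), sum(m_v * voxels$z)) / mass
  # offsets in meters
  rx <- (voxels$x - com[1]) / 1000
  ry <- (voxels$y - com[2]) / 1000
  rz <- (voxels$z - com[3]) / 1000
  ixx <- sum(m_v * (ry^2 + rz^2))
  iyy <- sum(m_v * (rx^2 + rz^2))
  izz <- sum(m_v * (rx^2 + ry^2))
  ixy <- -sum(m_v * rx * ry)
  ixz <- -sum(m_v * rx * rz)
  iyz <- -sum(m_v * ry * rz)
  inertia <- matrix(c(ixx, ixy, ixz,
                      ixy, iyy, iyz,
                      ixz, iyz, izz), 3, 3)
  if (max(abs(crossprod(axes) - diag(3))) > 1e-8) {
    abort("`axes` must be orthonormal.", class = "caninegait_invalid_input")
  }
  inertia <- t(axes) %*% inertia %*% axes
  inertia <- (inertia + t(inertia)) / 2
  list(inertia_kg_m2 = inertia, mass_kg = mass, com_mm = com)
}
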