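#' Anatomical segment coordinate systems from bony landmarks
#'
#' Builds the right-handed orthonormal frame of a pelvis or pelvic limb
#' segment from named bony landmarks, following the model's anatomical
#' conventions: x points cranially, y along the proximal-distal axis,
#' and z completes the right-handed set (z = x cross y). The
#' mediolateral reference (condylar, malleolar, or metatarsal axis) is
#' ordered oppositely for the left and right sides, so left and right
#' frames of a mirrored limb mirror each other.
#'
#' Landmark names: `RIC`/`LIC` right/left cranial dorsal iliac crest,
#' `RIT`/`LIT` ischiatic tuberosity, `COM` pelvis center of mass, `CFH`
#' femoral head center, `LFC`/`MFC` lateral/medial femoral condyle,
#' `MPTC` midpoint of the tibial condyles, `LM`/`MM` lateral/medial
#' malleolus, `MPM` midpoint of the malleoli, `MT5`/`MT2` heads of the
#' 5th/2nd metatarsal, `MP25P`/`MP25D` proximal/distal midpoint of the
#' 2nd and 5th metatarsals, `PCOM` phalangeal center of mass, `MPMT`
#' metatarsal midpoint (left phalanges origin; the published origin
#' naming differs between sides and is followed verbatim).
#'
#' @param landmarks Tibble with columns `name`, `x`, `y`, `z` (mm).
#' @param segment One of `"pelvis"`, `"femur"`, `"tibia"`, `"tarsus"`,
#'   `"phalanges"`.
#' @param side `"right"` or `"left"` (ignored for the pelvis).
#' @return A `segment_frame`: list with `origin` (length-3, mm) and
#'   `axes` (3x3 matrix with columns x, y, z), orthonormal and
#'   right-handed.
#' @export
build_coordinate_system <- function(landmarks, segment,
                                    side = c("right", "left")) {
  side <- match.arg(side)
  segment <- match.arg(segment,
                       c("pelvis", "femur", "tibia", "tarsus", "phalanges"))
  pt <- function(nm) {
    i <- match(nm, landmarks$name)
    if (is.na(i)) {
      abort(sprintf("Landmark `%s` required for the %s %s frame is missing.",
                    nm, side, segment),
            class = "caninegait_invalid_input")
    }
    v <- as.numeric(c(landmarks$x[i], landmarks$y[i], landmarks$z[i]))
    if (any(!is.finite(v))) {
      abort(sprintf("Landmark `%s` has non-finite coordinates.", nm),
            class = "caninegait_invalid_input")
    }
    v
  }

  if (segment == "pelvis") {
    origin <- pt("COM")
    x <- unit_vec(pt("RIC") - pt("RIT"), "pelvis x (RIC-RIT)")
    y <- unit_vec(cross3(x, pt("RIC") - pt("LIC")), "pelvis y")
    z <- cross3(x, y)
  } else if (segment == "femur") {
    origin <- pt("CFH")
    y <- unit_vec(pt("CFH") - pt("MFC"), "femur y (CFH-MFC)")
    condylar <- if (side == "right") pt("LFC") - pt("MFC") else pt("MFC") - pt("LFC")
    x <- unit_vec(cross3(y, condylar), "femur x")
    z <- cross3(x, y)
  } else if (segment == "tibia") {
    origin <- pt("MPTC")
    y <- unit_vec(pt("MPTC") - pt("MPM"), "tibia y (MPTC-MPM)")
    malleolar <- if (side == "right") pt("LM") - pt("MM") else pt("MM") - pt("LM")
    x <- unit_vec(cross3(y, malleolar), "tibia x")
    z <- cross3(x, y)
  } else if (segment == "tarsus") {
    origin <- pt("MPM")
    y <- unit_vec(pt("MP25P") - pt("MP25D"), "tarsus y (MP25P-MP25D)")
    metatarsal <- if (side == "right") pt("MT5") - pt("MT2") else pt("MT2") - pt("MT5")
    x <- unit_vec(cross3(y, metatarsal), "tarsus x")
    z <- cross3(x, y)
  } else { # phalanges
    origin <- if (side == "right") pt("MP25D") else pt("MPMT")
    z <- if (side == "right") {
      unit_vec(pt("MT5") - pt("MT2"), "phalanges z (MT5-MT2)")
    } else {
      unit_vec(pt("MT2") - pt("MT5"), "phalanges z (MT2-MT5)")
    }
    y <- unit_vec(cross3(pt("MP25D") - pt("PCOM"), z), "phalanges y")
    x <- cross3(y, z)
  }

  axes <- cbind(x = x, y = y, z = z)
  gram <- crossprod(axes)
  if (max(abs(gram - diag(3))) > 1e-9) {
    abort("Landmarks produce a degenerate (non-orthonormal) frame.",
          class = "caninegait_degenerate_frame")
  }
  structure(list(origin = origin, axes = axes, segment = segment, side = side),
            class = "segment_frame")
}

#' @export
print.segment_frame <- function(x, ...) {
  cat(sprintf("<segment_frame> %s (%s)\n", x$segment, x$side))
  cat("origin (mm):", format(round(x$origin, 3)), "\n")
  print(round(x$axes, 6))
  invisible(x)
}
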