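Package: caninegait
Title: Canine Pelvic Limb Musculoskeletal Gait Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Subject-specific rigid-body musculoskeletal modeling of the
    canine pelvis and pelvic limbs during walking gait. Builds segment
    masses and inertia tensors from CT-style tissue voxel tables,
    anatomical coordinate systems from bony landmarks, and Hill-type
    musculotendon actuators from muscle volumes, pennation angles, and
    fiber/tendon lengths scaled to the subject. Solves marker-based
    inverse kinematics, Newton-Euler inverse dynamics with pelvis residual
    actuators and a simplified residual-reduction step, and distributes
    net joint moments into muscle activations and forces by static
    optimization (minimum sum of squared activations). Includes
    correlation and residual-standard-deviation validation metrics with
    the conventional validity thresholds, TRC/MOT marker and force-plate
    file I/O, and a seeded synthetic gait generator so the full pipeline
    is testable without motion-capture data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    minpack.lm,
    stats,
    utils,
    withr,
    yaml
Suggests:
    pracma,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
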