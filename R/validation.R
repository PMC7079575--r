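#' Correlation coefficient between model and reference curves
#'
#' Pearson correlation computed from its definitional sums:
#' `r = sum((f - fbar)(g - gbar)) / sqrt(sum((f - fbar)^2) sum((g - gbar)^2))`,
#' where `f` is the model-predicted curve and `g` the reference curve
#' (typically the pointwise mean across experimental trials).
#'
#' @param f,g Numeric series of equal length (>= 3), finite, each with
#'   nonzero variance.
#' @return The correlation coefficient, a single number in \[-1, 1\].
#' @export
correlation_coefficient <- function(f, g) {
  check_pair(f, g)
  fc <- f - mean(f); gc <- g - mean(g)
  den <- sqrt(sum(fc^2) * sum(gc^2))
  if (den == 0) {
    abort("Correlation undefined: a series has zero variance.",
          class = "caninegait_zero_variance")
  }
  sum(fc * gc) / den
}

#' Standard deviation of residuals between model and reference curves
#'
#' The sample standard deviation of the pointwise residuals `f - g`,
#' computed in the numerically stable two-pass form
#' `sqrt(sum((d - dbar)^2) / (n - 1))` with `d = f - g`. This equals
#' the one-pass form
#' `sqrt((n sum(d^2) - (sum d)^2) / (n (n - 1)))` algebraically, and is
#' insensitive to a constant offset between the curves by construction.
#'
#' @inheritParams correlation_coefficient
#' @return The residual standard deviation, in the units of the curves.
#' @export
std_residuals <- function(f, g) {
  check_pair(f, g, min_n = 2)
  d <- f - g
  sqrt(sum((d - mean(d))^2) / (length(d) - 1))
}

check_pair <- function(f, g, min_n = 3) {
  if (length(f) != length(g)) {
    abort("Series must have equal length.", class = "caninegait_invalid_input")
  }
  if (length(f) < min_n) {
    abort(sprintf("Series must have at least %d points.", min_n),
          class = "caninegait_invalid_input")
  }
  if (any(!is.finite(f)) || any(!is.finite(g))) {
    abort("Series must be finite.", class = "caninegait_invalid_input")
  }
  invisible(TRUE)
}

#' Kinematic validity check
#'
#' Applies the validity thresholds to a model-vs-reference comparison:
#' the curves agree if `r >= r_min` (default 0.80) and the residual
#' standard deviation does not exceed `sigma_frac` (default 20%) of the
#' peak reference value.
#'
#' @param r Correlation coefficient.
#' @param sigma_e Residual standard deviation (curve units).
#' @param peak_reference Peak absolute value of the reference curve.
#' @param r_min,sigma_frac Thresholds.
#' @return One-row tibble: `r`, `sigma_e`, `sigma_limit`
#'   (`sigma_frac * peak_reference`), `pass_r`, `pass_sigma`, `pass`.
#' @export
validity_check <- function(r, sigma_e, peak_reference,
                           r_min = 0.80, sigma_frac = 0.20) {
  sigma_limit <- sigma_frac * abs(peak_reference)
  tibble(
    r = r, sigma_e = sigma_e, sigma_limit = sigma_limit,
    pass_r = r >= r_min, pass_sigma = sigma_e <= sigma_limit,
    pass = r >= r_min & sigma_e <= sigma_limit
  )
}

#' Validate model curves against reference curves
#'
#' Tidy wrapper: joins a model curve table and a reference curve table
#' on their shared keys and computes, per curve, the correlation
#' coefficient, residual standard deviation and validity flags.
#'
#' @param data Tibble of model curves with a grouping column (e.g.
#'   `joint`), a position column (`cycle_pct` or `time`) and a value
#'   column.
#' @param reference Tibble of reference curves with the same columns
#'   (reference values typically pointwise means across trials).
#' @param by Grouping column name (default `"joint"`).
#' @param value Value column name (default `"angle_deg"`).
#' @param r_min,sigma_frac Thresholds for [validity_check()].
#' @return Object of class `validation_result`: a tibble with one row
#'   per group (`r`, `sigma_e`, `sigma_limit`, `peak_reference`, pass
#'   flags).
#' @export
validate_curves <- function(data, reference, by = "joint",
                            value = "angle_deg",
                            r_min = 0.80, sigma_frac = 0.20) {
  pos <- intersect(c("cycle_pct", "time"), intersect(names(data),
                                                     names(reference)))
  if (!length(pos)) {
    abort("Curves need a shared `cycle_pct` or `time` column.",
          class = "caninegait_invalid_input")
  }
  pos <- pos[1]
  joined <- dplyr::inner_join(
    select(data, dplyr::all_of(c(by, pos, value))),
    select(reference, dplyr::all_of(c(by, pos, value))),
    by = c(by, pos), suffix = c("_model", "_ref")
  )
  vm <- paste0(value, "_model"); vr <- paste0(value, "_ref")
  out <- joined %>%
    group_by(dplyr::across(dplyr::all_of(by))) %>%
    summarise(
      n = n(),
      r = correlation_coefficient(.data[[vm]], .data[[vr]]),
      sigma_e = std_residuals(.data[[vm]], .data[[vr]]),
      peak_reference = max(abs(.data[[vr]])),
      .groups = "drop"
    ) %>%
    mutate(
      sigma_limit = sigma_frac * .data$peak_reference,
      pass_r = .data$r >= r_min,
      pass_sigma = .data$sigma_e <= .data$sigma_limit,
      pass = .data$pass_r & .data$pass_sigma
    )
  structure(out, class = c("validation_result", class(out)),
            r_min = r_min, sigma_frac = sigma_frac)
}

#' @export
print.validation_result <- function(x, ...) {
  r_min <- attr(x, "r_min"); sf <- attr(x, "sigma_frac")
  cat(sprintf("Kinematic validity (r >= %.2f and sigma_e <= %.0f%% of peak reference):\n",
              r_min, 100 * sf))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-10s r = %.3f, sigma_e = %.2f (where %.0f%% of peak reference value = %.1f) -> %s\n",
                x[[1]][i], x$r[i], x$sigma_e[i], 100 * sf,
                x$sigma_limit[i], if (x$pass[i]) "pass" else "FAIL"))
  }
  invisible(x)
}
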