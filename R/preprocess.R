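#' Zero-phase low-pass Butterworth filter
#'
#' Fourth-order Butterworth low-pass applied forward and backward
#' (zero phase; effective eighth order) with a 6 Hz default cutoff, the
#' standard smoothing for marker and kinematic series. Constant signals
#' pass unchanged.
#'
#' @param x Numeric vector (one signal) without NAs.
#' @param cutoff Cutoff frequency in Hz (default 6).
#' @param rate Sampling rate in Hz; must exceed twice the cutoff.
#' @param order Filter order before the forward-backward pass.
#' @return Filtered numeric vector of the same length.
#' @export
butterworth_lowpass <- function(x, cutoff = 6, rate, order = 4) {
  stopifnot_scalar(cutoff, "cutoff", positive = TRUE)
  stopifnot_scalar(rate, "rate", positive = TRUE)
  if (rate <= 2 * cutoff) {
    abort("Sampling rate must exceed twice the cutoff frequency.",
          class = "caninegait_invalid_input")
  }
  if (anyNA(x)) {
    abort("Signal contains NA; fill gaps before filtering.",
          class = "caninegait_invalid_input")
  }
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  # endpoint detrending plus odd-reflection padding suppresses the
  # forward-backward edge transients; constant and linearly trending
  # signals pass through unchanged
  n <- length(x)
  trend <- x[1] + (x[n] - x[1]) * (seq_len(n) - 1) / max(1, n - 1)
  r <- x - trend
  np <- min(n - 1, max(12, ceiling(3 * rate / cutoff)))
  if (np > 0) {
    left <- 2 * r[1] - r[(np + 1):2]
    right <- 2 * r[n] - r[(n - 1):(n - np)]
    y <- as.numeric(signal::filtfilt(bf, c(left, r, right)))[(np + 1):(np + n)]
  } else {
    y <- as.numeric(signal::filtfilt(bf, r))
  }
  y + trend
}

#' Smooth marker trajectories
#'
#' Applies [butterworth_lowpass()] to every coordinate of every marker
#' in a long marker table.
#'
#' @param markers Tibble with columns `time`, `marker`, `x`, `y`, `z`
#'   (mm) and optionally `visible`.
#' @param cutoff,order Passed to [butterworth_lowpass()].
#' @return The marker tibble with smoothed coordinates.
#' @export
smooth_markers <- function(markers, cutoff = 6, order = 4) {
  rate <- marker_rate(markers)
  markers %>%
    group_by(.data$marker) %>%
    arrange(.data$time, .by_group = TRUE) %>%
    mutate(across(c("x", "y", "z"),
                  ~ butterworth_lowpass(.x, cutoff = cutoff, rate = rate,
                                        order = order))) %>%
    ungroup()
}

marker_rate <- function(markers) {
  tt <- sort(unique(markers$time))
  if (length(tt) < 2) {
    abort("Need at least two frames.", class = "caninegait_invalid_input")
  }
  1 / stats::median(diff(tt))
}

#' Fill short marker gaps with quintic splines
#'
#' Interpolates marker occlusions shorter than 5 frames with a quintic
#' polynomial fitted per coordinate to the three frames on each side of
#' the gap (six support points determine the quintic exactly, so smooth
#' polynomial trajectories are recovered without error). Gaps of 5 or
#' more frames, gaps at the sequence boundary, and gaps with fewer than
#' three support frames on either side are left unfilled and the trial
#' is flagged as unsuccessful (attribute `trial_valid = FALSE`).
#'
#' Gaps must be explicit: rows present with `visible = FALSE` (their
#' coordinates are ignored) or NA coordinates.
#'
#' @param markers Tibble with columns `time`, `marker`, `x`, `y`, `z`
#'   and optionally `visible`.
#' @param max_gap Longest fillable gap in frames (default 4).
#' @return The marker tibble with filled gaps, `visible` updated, and
#'   attributes `trial_valid` (logical) and `unfilled_gaps` (tibble).
#' @export
fill_gaps_quintic <- function(markers, max_gap = 4) {
  if (!"visible" %in% names(markers)) {
    markers$visible <- is.finite(markers$x) & is.finite(markers$y) &
      is.finite(markers$z)
  }
  unfilled <- list()
  out <- markers %>%
    group_by(.data$marker) %>%
    arrange(.data$time, .by_group = TRUE) %>%
    group_split()
  out <- purrr::map(out, function(df) {
    vis <- df$visible
    if (all(vis)) return(df)
    r <- rle(!vis)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      i0 <- starts[k]; i1 <- ends[k]; len <- i1 - i0 + 1
      at_boundary <- i0 == 1 || i1 == nrow(df)
      enough_support <- !at_boundary &&
        i0 - 3 >= 1 && i1 + 3 <= nrow(df) &&
        all(vis[(i0 - 3):(i0 - 1)]) && all(vis[(i1 + 1):(i1 + 3)])
      if (len <= max_gap && enough_support) {
        sup <- c((i0 - 3):(i0 - 1), (i1 + 1):(i1 + 3))
        ts <- df$time[sup] - df$time[i0]
        tg <- df$time[i0:i1] - df$time[i0]
        for (cc in c("x", "y", "z")) {
          fit <- lm(y ~ poly(t, 5, raw = TRUE),
                    data = data.frame(t = ts, y = df[[cc]][sup]))
          df[[cc]][i0:i1] <- predict(fit, newdata = data.frame(t = tg))
        }
        df$visible[i0:i1] <- TRUE
      } else {
        unfilled[[length(unfilled) + 1]] <<- tibble(
          marker = df$marker[1], start_frame = i0, length = len,
          reason = if (len > max_gap) "too_long" else "insufficient_support"
        )
      }
    }
    df
  })
  out <- bind_rows(out) %>% arrange(.data$time, .data$marker)
  unfilled <- if (length(unfilled)) bind_rows(unfilled) else
    tibble(marker = character(), start_frame = integer(),
           length = integer(), reason = character())
  attr(out, "trial_valid") <- nrow(unfilled) == 0
  attr(out, "unfilled_gaps") <- unfilled
  out
}

#' Segment a gait cycle from vertical ground reaction force
#'
#' Paw contact is the first frame at which the vertical force rises
#' above the threshold (default 2% body weight) and stays there for at
#' least the debounce duration (50 ms), rejecting baseline chatter. A
#' full cycle spans one contact to the next ipsilateral contact; the
#' stance fraction is the portion of the cycle during which the force
#' remains above threshold.
#'
#' @param grf Tibble with columns `time` (s) and `fy` (vertical force, N).
#' @param threshold Contact threshold in N; must be > 0. The
#'   conventional default is 2% of body weight.
#' @param min_contact_ms Minimum sustained contact (and flight) duration
#'   for a transition to count, in ms.
#' @return Tibble with one row per detected cycle: `start_time`,
#'   `end_time`, `stance_end_time`, `stance_fraction`, plus the frame
#'   indices. Errors if no contact is found.
#' @export
segment_gait_cycle <- function(grf, threshold, min_contact_ms = 50) {
  stopifnot_scalar(threshold, "threshold")
  if (threshold <= 0) {
    abort("Contact threshold must be > 0 (a zero threshold triggers on baseline chatter).",
          class = "caninegait_invalid_input")
  }
  grf <- arrange(grf, .data$time)
  rate <- 1 / stats::median(diff(grf$time))
  debounce <- max(1L, ceiling(min_contact_ms / 1000 * rate))
  loaded <- grf$fy > threshold
  r <- rle(loaded)
  # drop runs shorter than the debounce window (chatter in either state)
  keep <- r$lengths >= debounce
  if (!any(keep & r$values)) {
    abort("No paw contact found above threshold.",
          class = "caninegait_no_contact")
  }
  # merge chattery short runs into their predecessor state
  state <- inverse.rle(r)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  for (k in seq_along(r$lengths)) {
    if (!keep[k] && k > 1) state[starts[k]:ends[k]] <- state[starts[k] - 1]
  }
  r2 <- rle(state)
  ends2 <- cumsum(r2$lengths); starts2 <- ends2 - r2$lengths + 1
  contact_starts <- starts2[r2$values]
  contact_ends <- ends2[r2$values]
  if (length(contact_starts) < 1) {
    abort("No paw contact found above threshold.",
          class = "caninegait_no_contact")
  }
  n_cycles <- length(contact_starts) - 1
  if (n_cycles < 1) {
    abort("Only one contact found; a full cycle needs the next ipsilateral contact.",
          class = "caninegait_no_contact")
  }
  purrr::map_dfr(seq_len(n_cycles), function(i) {
    s <- contact_starts[i]; e <- contact_starts[i + 1]
    stance_end <- contact_ends[i]
    tibble(
      cycle = i,
      start_frame = s, end_frame = e, stance_end_frame = stance_end,
      start_time = grf$time[s], end_time = grf$time[e],
      stance_end_time = grf$time[stance_end],
      stance_fraction = (grf$time[stance_end] - grf$time[s]) /
        (grf$time[e] - grf$time[s])
    )
  })
}

#' Resample a series onto the normalized gait cycle
#'
#' Linear-in-time interpolation of each numeric column onto `n` evenly
#' spaced points from 0 to 100% of the cycle; endpoint values are
#' preserved exactly.
#'
#' @param data Tibble with a `time` column, or a numeric vector
#'   (assumed evenly spaced over the cycle).
#' @param n Number of cycle points (default 100).
#' @return For a tibble input: tibble with `cycle_pct` plus the
#'   interpolated numeric columns. For a vector: numeric vector of
#'   length `n`.
#' @export
resample_cycle <- function(data, n = 100) {
  if (is.numeric(data) && is.null(dim(data))) {
    if (length(data) < 2) {
      abort("Series must have at least 2 samples.",
            class = "caninegait_invalid_input")
    }
    t0 <- seq(0, 1, length.out = length(data))
    return(approx(t0, data, xout = seq(0, 1, length.out = n))$y)
  }
  if (!"time" %in% names(data)) {
    abort("`data` needs a `time` column.", class = "caninegait_invalid_input")
  }
  if (nrow(data) < 2) {
    abort("Series must have at least 2 samples.",
          class = "caninegait_invalid_input")
  }
  data <- arrange(data, .data$time)
  tt <- data$time
  xout <- seq(tt[1], tt[length(tt)], length.out = n)
  num <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], "time")
  out <- tibble(cycle_pct = seq(0, 100, length.out = n))
  for (cc in num) out[[cc]] <- approx(tt, data[[cc]], xout = xout)$y
  out
}
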