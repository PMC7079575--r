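#' Read and write TRC marker files
#'
#' TRC is the tab-separated marker trajectory format of motion-capture
#' pipelines: a header with the sampling rate, frame count, units and
#' marker names, then one row per frame with frame number, time, and
#' X/Y/Z columns per marker (mm here).
#'
#' @param path File path.
#' @param markers Long marker tibble (`time`, `marker`, `x`, `y`, `z`,
#'   optional `visible`); invisible samples are written blank.
#' @return `read_trc()` returns the long marker tibble with a
#'   `visible` column; `write_trc()` returns `path` invisibly.
#' @export
write_trc <- function(markers, path) {
  if (!"visible" %in% names(markers)) markers$visible <- TRUE
  tt <- sort(unique(markers$time))
  rate <- 1 / stats::median(diff(tt))
  mk_names <- unique(markers$marker)
  wide <- markers %>%
    mutate(across(c("x", "y", "z"), ~ ifelse(.data$visible, .x, NA_real_))) %>%
    select("time", "marker", "x", "y", "z") %>%
    tidyr::pivot_wider(names_from = "marker",
                       values_from = c("x", "y", "z"),
                       names_glue = "{marker}.{.value}")
  # column order: per-marker X, Y, Z triplets
  ord <- as.vector(t(outer(mk_names, c("x", "y", "z"),
                           function(m, c) paste0(m, ".", c))))
  wide <- wide[, c("time", ord)]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("PathFileType\t4\t(X/Y/Z)\t", basename(path)),
    "DataRate\tCameraRate\tNumFrames\tNumMarkers\tUnits\tOrigDataRate\tOrigDataStartFrame\tOrigNumFrames",
    sprintf("%g\t%g\t%d\t%d\tmm\t%g\t1\t%d",
            rate, rate, length(tt), length(mk_names), rate, length(tt)),
    paste(c("Frame#", "Time",
            as.vector(rbind(mk_names, "", ""))), collapse = "\t"),
    paste(c("", "", paste0(rep(c("X", "Y", "Z"), length(mk_names)),
                           rep(seq_along(mk_names), each = 3))),
          collapse = "\t"),
    ""
  ), con)
  body <- cbind(seq_along(tt), wide)
  utils::write.table(body, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_trc
#' @export
read_trc <- function(path) {
  lines <- readLines(path)
  name_row <- strsplit(lines[4], "\t")[[1]]
  mk_names <- name_row[-(1:2)]
  mk_names <- mk_names[mk_names != ""]
  body <- lines[-(1:6)]
  body <- body[nzchar(body)]
  mat <- utils::read.table(text = body, sep = "\t", header = FALSE,
                           na.strings = c("", "NA"))
  out <- purrr::map_dfr(seq_along(mk_names), function(i) {
    cols <- 2 + (i - 1) * 3 + (1:3)
    tibble(time = mat[[2]], marker = mk_names[i],
           x = mat[[cols[1]]], y = mat[[cols[2]]], z = mat[[cols[3]]])
  })
  out %>%
    mutate(visible = is.finite(.data$x) & is.finite(.data$y) &
             is.finite(.data$z)) %>%
    arrange(.data$time, .data$marker)
}

#' Read and write MOT time-series files
#'
#' MOT is the tab-separated time-series format used for force-plate
#' records and joint coordinate/moment series: a small header
#' (`name`, `nRows`, `nColumns`, `inDegrees`, `endheader`) then a
#' header row of column names starting with `time`.
#'
#' @param data Tibble with a `time` column and numeric columns.
#' @param path File path.
#' @param name Record name written into the header.
#' @param in_degrees Whether rotational columns are in degrees.
#' @return `read_mot()` returns a tibble; `write_mot()` returns
#'   `path` invisibly.
#' @export
write_mot <- function(data, path, name = "caninegait",
                      in_degrees = TRUE) {
  if (!"time" %in% names(data)) {
    abort("`data` needs a `time` column.", class = "caninegait_invalid_input")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    name,
    "version=1",
    sprintf("nRows=%d", nrow(data)),
    sprintf("nColumns=%d", ncol(data)),
    sprintf("inDegrees=%s", if (in_degrees) "yes" else "no"),
    "endheader",
    paste(names(data), collapse = "\t")
  ), con)
  utils::write.table(data, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mot
#' @export
read_mot <- function(path) {
  lines <- readLines(path)
  end <- which(trimws(lines) == "endheader")
  if (!length(end)) {
    abort("Not a MOT file: no `endheader` line.",
          class = "caninegait_invalid_input")
  }
  header <- strsplit(lines[end + 1], "\t")[[1]]
  mat <- utils::read.table(text = lines[-(1:(end + 1))], sep = "\t",
                           header = FALSE)
  names(mat) <- header
  as_tibble(mat)
}
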