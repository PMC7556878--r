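# File interchange: TIFF stacks for movies/linescans, CSV for traces and
# cohort tables, JSON sidecars for calibration and ground truth. All time
# columns are seconds, diameters um, velocities mm/s.

#' Write a vessel movie (or linescan) as a TIFF stack with a JSON sidecar
#'
#' Intensities are scaled to the unit interval for 16-bit TIFF storage; the scale,
#' calibration and any ground truth go to `<path>.json` so the stack
#' round-trips losslessly to within 16-bit quantization.
#'
#' @param movie a `vessel_movie` or `linescan_image`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  frames <- if (inherits(movie, "linescan_image")) {
    list(movie$image)
  } else {
    lapply(seq_len(dim(movie$frames)[1]), function(i) movie$frames[i, , ])
  }
  lo <- min(vapply(frames, min, numeric(1)))
  hi <- max(vapply(frames, max, numeric(1)))
  rng <- max(hi - lo, .Machine$double.eps)
  scaled <- lapply(frames, function(f) (f - lo) / rng)
  tiff::writeTIFF(scaled, path, bits.per.sample = 16)
  meta <- movie[setdiff(names(movie), c("frames", "image"))]
  meta$intensity_offset <- lo
  meta$intensity_scale <- rng
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a vessel movie written by [write_movie_tiff()]
#'
#' @param path TIFF path (expects the `.json` sidecar next to it).
#' @return a `vessel_movie` or `linescan_image`, depending on the sidecar.
#' @export
read_movie_tiff <- function(path) {
  if (!file.exists(path))
    stop_invalid("missing input file: ", path)
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- lapply(frames, function(f)
    f * meta$intensity_scale + meta$intensity_offset)
  if (!is.null(meta$line_rate)) {
    structure(list(image = frames[[1]], pixel_size = meta$pixel_size,
                   line_rate = meta$line_rate,
                   convention = meta$convention,
                   ground_truth = meta$ground_truth),
              class = "linescan_image")
  } else {
    arr <- array(0, c(length(frames), nrow(frames[[1]]), ncol(frames[[1]])))
    for (i in seq_along(frames)) arr[i, , ] <- frames[[i]]
    axis_line <- meta$axis_line
    if (!is.null(axis_line))
      axis_line <- lapply(axis_line, function(p) unlist(p))
    new_vessel_movie(arr, meta$pixel_size, meta$frame_rate,
                     meta$vessel_class, roi = unlist(meta$roi),
                     axis_line = axis_line,
                     ground_truth = meta$ground_truth)
  }
}

#' Write a time-series trace as CSV (time_s, value)
#'
#' @param values numeric vector.
#' @param sample_rate Hz.
#' @param path output path.
#' @param value_name column name for the values (e.g. `"diameter_um"`).
#' @param extra optional data.frame of extra columns (e.g. `despiked`).
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(values, sample_rate, path,
                            value_name = "value", extra = NULL) {
  df <- data.frame(time_s = (seq_along(values) - 1) / sample_rate,
                   value = values)
  names(df)[2] <- value_name
  if (!is.null(extra)) df <- cbind(df, extra)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trace CSV written by [write_trace_csv()]
#'
#' @param path CSV path.
#' @return data.frame; `attr(, "sample_rate")` is inferred from the time
#'   column.
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop_invalid("missing input file: ", path)
  df <- read.csv(path)
  if (nrow(df) > 1)
    attr(df, "sample_rate") <- 1 / median(diff(df$time_s))
  df
}

#' Write / read a cohort table CSV
#'
#' Columns: animal_id, vessel_id, vessel_class, d_vehicle_um,
#' d_treatment_um.
#'
#' @param table cohort data.frame.
#' @param path CSV path.
#' @return `path` / the table.
#' @export
write_cohort_csv <- function(table, path) {
  write.csv(table[, c("animal_id", "vessel_id", "vessel_class",
                      "d_vehicle_um", "d_treatment_um")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop_invalid("missing input file: ", path)
  read.csv(path)
}
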