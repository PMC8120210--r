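#' Read a force recording from CSV
#'
#' Expects a header with columns `time_s` and `force_mN` (extra columns such
#' as `stim` or `post_mm` are preserved); gzip-compressed files are accepted.
#' A JSON sidecar (same path plus `.json`), if present, supplies metadata
#' such as the pacing rate and stimulation times.
#'
#' @param path CSV (optionally .gz) file path
#' @return a `force_trace` data frame with sampling metadata attributes
#' @export
read_force_trace <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "force_mN") %in% names(df)))
    stop_eht("expected columns `time_s` and `force_mN` in %s", path)
  if (nrow(df) < 2) stop_eht("trace in %s is empty or degenerate", path)
  dts <- diff(df$time_s)
  if (any(dts <= 0) || diff(range(dts)) > 1e-9 + 1e-6 * stats::median(dts))
    stop_eht("time column must be strictly increasing and uniform")
  if (any(!is.finite(df$force_mN))) stop_eht("non-finite force values")
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list()
  structure(df, sampling_interval = stats::median(dts),
            pacing_rate = meta$pacing_rate,
            stim_times = meta$stim_times,
            class = c("force_trace", "data.frame"))
}

#' Write a force trace as CSV plus a JSON parameter sidecar
#'
#' @param trace a `force_trace` data frame
#' @param path output CSV path; metadata goes to `paste0(path, ".json")`
#' @return `path`, invisibly
#' @export
write_force_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace)[c("time_s", "force_mN")], path,
                   row.names = FALSE)
  meta <- list(sampling_interval = attr(trace, "sampling_interval"),
               pacing_rate = attr(trace, "pacing_rate"),
               stim_times = attr(trace, "stim_times"))
  jsonlite::write_json(meta[!vapply(meta, is.null, TRUE)],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a synthetic tissue image to TIFF plus ground-truth CSV
#'
#' Channels are written as one multi-frame TIFF (frame order dapi, wga,
#' actinin), the label map as a second TIFF, and the ground truth as CSV.
#'
#' @param img result of [generate_tissue_image()]
#' @param prefix output path prefix; files `<prefix>_channels.tif`,
#'   `<prefix>_labels.tif`, `<prefix>_truth.csv` are created
#' @return named character vector of the created paths, invisibly
#' @export
write_tissue_image <- function(img, prefix) {
  ch <- img$channels
  arr <- array(0, c(dim(ch$dapi), 3))
  arr[, , 1] <- ch$dapi; arr[, , 2] <- ch$wga; arr[, , 3] <- ch$actinin
  scale <- max(arr, 1)
  p1 <- paste0(prefix, "_channels.tif")
  p2 <- paste0(prefix, "_labels.tif")
  p3 <- paste0(prefix, "_truth.csv")
  EBImage::writeImage(EBImage::Image(arr / scale), p1, type = "tiff",
                      bits.per.sample = 16L)
  EBImage::writeImage(EBImage::Image(img$labels / max(img$labels, 1)), p2,
                      type = "tiff", bits.per.sample = 16L)
  utils::write.csv(img$truth, p3, row.names = FALSE)
  invisible(c(channels = p1, labels = p2, truth = p3))
}

#' Read a two-column trace CSV (time + value)
#'
#' Convenience reader for calcium-fluorescence or voltage traces stored as
#' `time_s,value` CSV.
#'
#' @param path CSV path
#' @param value_name name for the value column in the result (e.g.
#'   `"intensity"` or `"voltage_mV"`)
#' @return data frame with `time_s` and the value column
#' @export
read_signal_trace <- function(path, value_name = "intensity") {
  df <- utils::read.csv(path)
  if (ncol(df) < 2) stop_eht("expected at least two columns in %s", path)
  out <- data.frame(time_s = df[[1]], v = df[[2]])
  names(out)[2] <- value_name
  out
}
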