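#' Write a TIRF movie as a multi-page TIFF with a JSON sidecar
#'
#' One 32-bit float page per frame (ImageJ-readable).  Intensities are
#' scaled into `[0, 1]` by a recorded `intensity_scale`; the sidecar
#' (`<path>.json`) stores the scale, acquisition geometry, insulin frame
#' and frame times so that [read_movie()] restores the object.
#'
#' @param movie A [tirf_movie()].
#' @param path Output TIFF path.
#' @param extra Optional named list merged into the sidecar (e.g. the
#'   simulation seed).
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path, extra = NULL) {
  stopifnot(inherits(movie, "tirf_movie"))
  sc <- max(movie$frames, 1)
  pages <- lapply(seq_len(dim(movie$frames)[3]),
                  function(f) movie$frames[, , f] / sc)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- c(list(intensity_scale = sc,
                 geometry = unclass(movie$geometry),
                 insulin_frame = movie$insulin_frame,
                 insulin_time = movie$insulin_time,
                 frame_times = movie$frame_times), extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a movie written by [write_movie()]
#'
#' @param path TIFF path (expects `<path>.json` alongside).
#' @return A [tirf_movie()].
#' @export
read_movie <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (f in seq_along(pages))
    frames[, , f] <- pages[[f]] * meta$intensity_scale
  geom <- do.call(acquisition_geometry, meta$geometry)
  tirf_movie(frames, geom, meta$insulin_frame,
             frame_times = meta$frame_times,
             insulin_time = meta$insulin_time)
}

#' Write simulator ground truth as CSV
#'
#' One row per vesicle per frame: `id`, `class`, `frame`, `x_px`, `y_px`,
#' `z_nm`, `amplitude`.
#'
#' @param truth Ground-truth data frame from [simulate_tirf_movie()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}
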