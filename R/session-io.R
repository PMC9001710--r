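#' Write a session to a directory
#'
#' Plain-format session export: gaze and trials as CSV, per-unit spike
#' times as CSV, unit/RF metadata as JSON, stimulus images as PNG and the
#' LFP as a raw little-endian double array with a JSON shape descriptor.
#'
#' @param session an `av_session`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(session$gaze)[c("t", "x", "y")],
                   file.path(dir, "gaze.csv"), row.names = FALSE)
  utils::write.csv(session$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  dir.create(file.path(dir, "spikes"), showWarnings = FALSE)
  for (u in seq_along(session$spikes)) {
    utils::write.csv(data.frame(t = as.numeric(session$spikes[[u]])),
                     file.path(dir, "spikes", sprintf("unit_%03d.csv", u)),
                     row.names = FALSE)
  }
  utils::write.csv(session$units, file.path(dir, "units.csv"),
                   row.names = FALSE)
  jsonlite::write_json(session$rf, file.path(dir, "rf.json"),
                       auto_unbox = TRUE, digits = NA)
  dir.create(file.path(dir, "images"), showWarnings = FALSE)
  for (i in seq_along(session$images)) {
    png::writePNG(session$images[[i]]$image,
                  file.path(dir, "images", sprintf("img_%02d.png", i)))
  }
  con <- file(file.path(dir, "lfp.bin"), "wb")
  writeBin(as.vector(session$lfp$lfp), con, size = 8, endian = "little")
  close(con)
  jsonlite::write_json(list(n_channels = nrow(session$lfp$lfp),
                            n_samples = ncol(session$lfp$lfp),
                            fs = session$lfp$fs,
                            depths_mm = session$lfp$depths_mm),
                       file.path(dir, "lfp.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir session directory.
#' @return an `av_session` (without generator ground truth and with images
#'   as plain matrices wrapped in minimal `stimulus_image` objects).
#' @export
read_session <- function(dir) {
  gz <- utils::read.csv(file.path(dir, "gaze.csv"))
  trials <- utils::read.csv(file.path(dir, "trials.csv"))
  units <- utils::read.csv(file.path(dir, "units.csv"))
  spike_files <- sort(list.files(file.path(dir, "spikes"), full.names = TRUE))
  spikes <- lapply(spike_files, function(f) utils::read.csv(f)$t)
  rf <- jsonlite::read_json(file.path(dir, "rf.json"), simplifyVector = TRUE)
  img_files <- sort(list.files(file.path(dir, "images"), full.names = TRUE))
  meta <- jsonlite::read_json(file.path(dir, "lfp.json"),
                              simplifyVector = TRUE)
  images <- lapply(img_files, function(f) {
    m <- png::readPNG(f)
    if (length(dim(m)) == 3) m <- m[, , 1]
    structure(list(image = m, objects = NULL,
                   ppd = rf$ppd,
                   width_deg = ncol(m) / rf$ppd,
                   height_deg = nrow(m) / rf$ppd),
              class = "stimulus_image")
  })
  con <- file(file.path(dir, "lfp.bin"), "rb")
  v <- readBin(con, "double", n = meta$n_channels * meta$n_samples,
               size = 8, endian = "little")
  close(con)
  structure(list(
    gaze = gaze_record(gz$t, gz$x, gz$y), trials = trials, images = images,
    spikes = spikes, units = units,
    lfp = list(lfp = matrix(v, meta$n_channels, meta$n_samples),
               fs = meta$fs, depths_mm = meta$depths_mm),
    rf = rf_geometry(unlist(rf$offset), rf$diameter, rf$ppd),
    truth = NULL, seed = NA_integer_
  ), class = "av_session")
}
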