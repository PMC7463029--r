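#' Write a velocity cine as a text container
#'
#' One tab-delimited matrix per frame (`frame_001.tsv`, ...), the lumen
#' mask as 0/1 (`mask.tsv`), and a JSON sidecar (`cine.json`) recording
#' the grid shape, pixel spacing in mm, frame interval in ms, declared
#' velocity unit and the frame file names.
#'
#' @param series A `cine_flow` object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the sidecar path.
#' @export
write_cine <- function(series, dir) {
  stopifnot(inherits(series, "cine_flow"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  frame_files <- sprintf("frame_%03d.tsv", seq_along(series$frames))
  for (i in seq_along(series$frames)) {
    write.table(series$frames[[i]], file.path(dir, frame_files[i]),
                quote = FALSE, sep = "\t", row.names = FALSE,
                col.names = FALSE)
  }
  write.table(series$mask * 1L, file.path(dir, "mask.tsv"), quote = FALSE,
              sep = "\t", row.names = FALSE, col.names = FALSE)
  sidecar <- list(shape = dim(series$mask),
                  pixel_spacing_mm = series$pixel_spacing,
                  frame_interval_ms = series$frame_interval_ms,
                  velocity_unit = series$velocity_unit,
                  venc = series$venc,
                  mask_file = "mask.tsv",
                  frames = frame_files)
  path <- file.path(dir, "cine.json")
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a velocity cine text container
#'
#' Reads the sidecar written by [write_cine()] and reconstructs the
#' `cine_flow` object; velocities declared in cm/s are converted to m/s.
#'
#' @param dir Directory containing `cine.json`.
#' @return A `cine_flow` object.
#' @export
read_cine <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "cine.json"),
                                 simplifyVector = TRUE)
  mask <- as.matrix(read.table(file.path(dir, sidecar$mask_file))) > 0
  dimnames(mask) <- NULL
  frames <- lapply(sidecar$frames, function(f) {
    fr <- as.matrix(read.table(file.path(dir, f)))
    dimnames(fr) <- NULL
    fr
  })
  cine_flow(frames, mask, sidecar$pixel_spacing_mm,
            sidecar$frame_interval_ms %||% NA,
            velocity_unit = sidecar$velocity_unit,
            venc = sidecar$venc)
}
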