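#' Frame sequences
#'
#' A frame sequence holds an ordered list of single-channel intensity
#' matrices (one per video frame) together with the acquisition frame rate.
#' Intensities are kept in native sensor units, `0 .. 2^bit_depth - 1`.
#'
#' @param frames List of numeric matrices, all of identical dimensions,
#'   with non-negative intensities.
#' @param fps Frames per second, > 0.
#' @param source_id Free-text provenance label.
#' @param bit_depth Declared sensor bit depth (8 or 16).
#'
#' @return An object of class `matt_frames`: a list with elements
#'   `frames`, `fps`, `source_id`, `bit_depth`.
#' @export
frame_sequence <- function(frames, fps, source_id = "", bit_depth = 8) {
  if (!is.list(frames) || length(frames) == 0L) {
    abort_validation("`frames` must be a non-empty list of matrices.")
  }
  dims <- map(frames, dim)
  if (any(map_lgl(frames, ~ !is.matrix(.x) || !is.numeric(.x)))) {
    abort_validation("Every frame must be a numeric matrix.")
  }
  if (length(unique(map(dims, identity))) > 1L) {
    abort_validation("All frames must share the same height x width.")
  }
  fps <- check_scalar(fps, "fps", positive = TRUE)
  if (!bit_depth %in% c(8, 16)) {
    abort_validation("`bit_depth` must be 8 or 16.")
  }
  max_allowed <- 2^bit_depth - 1
  rng <- range(map_dbl(frames, min), map_dbl(frames, max))
  if (rng[1] < 0 || rng[2] > max_allowed) {
    abort_validation(sprintf(
      "Frame intensities must lie in [0, %d] for bit depth %d.",
      as.integer(max_allowed), as.integer(bit_depth)
    ))
  }
  structure(
    list(frames = frames, fps = fps, source_id = source_id,
         bit_depth = as.integer(bit_depth)),
    class = "matt_frames"
  )
}

#' @export
print.matt_frames <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<matt_frames> %d frames of %dx%d px, %g fps, %d-bit%s\n",
              length(x$frames), d[1], d[2], x$fps, x$bit_depth,
              if (nzchar(x$source_id)) paste0(" [", x$source_id, "]") else ""))
  invisible(x)
}

#' @export
length.matt_frames <- function(x) length(x$frames)

# Rec.601 luma weights: fixed, deterministic reduction of colour input.
luminance <- function(arr) {
  if (length(dim(arr)) == 2L) return(arr)
  if (length(dim(arr)) == 3L) {
    ch <- dim(arr)[3]
    if (ch == 1L) return(arr[, , 1])
    # channels beyond RGB (e.g. alpha) are ignored
    return(0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3])
  }
  abort_validation("Unsupported image array layout.")
}

#' Load a frame sequence from disk
#'
#' Reads a directory of numbered PNG or TIFF frames (lexical filename
#' order defines temporal order).  Colour input is reduced to luminance
#' with fixed Rec.601 weights (0.299 R + 0.587 G + 0.114 B); intensities
#' are rescaled to native units for the declared bit depth.  Container
#' video files (MP4/AVI) are not decodable by this build and raise an
#' I/O error suggesting frame extraction.
#'
#' @param path Directory containing image frames.
#' @param fps Frame rate to attach to the sequence (frames per second).
#' @param bit_depth Sensor bit depth the files encode (8 or 16).
#' @return A [frame_sequence()].
#' @export
load_frames <- function(path, fps = 30, bit_depth = 8) {
  if (!file.exists(path)) {
    abort_io(sprintf("Input path does not exist: '%s'", path))
  }
  if (!dir.exists(path)) {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("mp4", "avi", "mov", "mkv")) {
      abort_io(sprintf(
        "Cannot decode container video '%s': no video decoder is available; extract frames to a PNG/TIFF directory first.",
        path
      ))
    }
    abort_io(sprintf("'%s' is neither a directory of frames nor a readable input.", path))
  }
  files <- list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                      full.names = TRUE)
  files <- sort(files, method = "radix")
  if (length(files) == 0L) {
    abort_io(sprintf("No PNG/TIFF frames found in directory '%s'.", path))
  }
  scale <- 2^bit_depth - 1
  frames <- map(files, function(f) {
    img <- tryCatch(
      if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
      else tiff::readTIFF(f),
      error = function(e) abort_io(sprintf("Unreadable image file '%s': %s", f, conditionMessage(e)))
    )
    luminance(img) * scale
  })
  dims <- unique(map(frames, dim))
  if (length(dims) > 1L) {
    abort_validation(sprintf(
      "Mixed frame shapes in '%s': found %s.", path,
      paste(map(dims, ~ paste(.x, collapse = "x")), collapse = ", ")
    ))
  }
  frame_sequence(frames, fps = fps, source_id = basename(path),
                 bit_depth = bit_depth)
}

#' Write a frame sequence as numbered PNG files
#'
#' Inverse of [load_frames()]: frames are quantized to the sequence's bit
#' depth (8-bit PNG output) and written as `frame_000000.png`, ... so that
#' reloading reproduces the pixel values exactly.
#'
#' @param frames A [frame_sequence()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the written file paths.
#' @export
write_frames <- function(frames, dir) {
  stopifnot(inherits(frames, "matt_frames"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scale <- 2^frames$bit_depth - 1
  paths <- character(length(frames$frames))
  for (i in seq_along(frames$frames)) {
    paths[i] <- file.path(dir, sprintf("frame_%06d.png", i - 1L))
    m <- round(frames$frames[[i]]) / scale
    png::writePNG(pmin(pmax(m, 0), 1), paths[i])
  }
  invisible(paths)
}
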