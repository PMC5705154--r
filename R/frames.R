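#' Frame sequences
#'
#' A `frame_sequence` holds an ordered set of single-channel grayscale frames
#' plus the acquisition frame rate. Frames are stored as numeric matrices in a
#' bottom-left-origin convention: the value of pixel `(x, y)` (0-based, `x`
#' rightward, `y` upward) is `frame[y + 1, x + 1]`, i.e. matrix row 1 is the
#' *bottom* image row. Image files, whose first row is the top of the picture,
#' are flipped on read and unflipped on write so that round trips are
#' bit-exact.
#'
#' @param frames list of numeric matrices, all with identical dimensions.
#' @param fps frames per second (fluoroscopy is typically recorded at 30).
#' @return A `frame_sequence` object (list with elements `frames` and `fps`).
#' @examples
#' fs <- frame_sequence(list(matrix(0, 16, 16), matrix(1, 16, 16)))
#' length(fs$frames)
#' @export
frame_sequence <- function(frames, fps = 30) {
  if (!is.list(frames) || length(frames) == 0) {
    abort("`frames` must be a non-empty list of matrices.")
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("All frames must share the same height and width.")
  }
  ok <- vapply(frames, function(f) is.matrix(f) && all(is.finite(f)), logical(1))
  if (!all(ok)) abort("Frames must be finite numeric matrices.")
  if (!is_scalar_number(fps) || fps <= 0) abort("`fps` must be a positive number.")
  structure(
    list(frames = frames, fps = fps, origin_convention = "bottom-left"),
    class = "frame_sequence"
  )
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_sequence> %d frames of %dx%d px at %g fps (origin %s)\n",
              length(x$frames), d[2], d[1], x$fps, x$origin_convention))
  invisible(x)
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

# Convert a decoded image array (top-left origin, possibly RGB(A)) to a
# bottom-left-origin grayscale matrix. Rec.601 luminance weights.
decode_image_array <- function(a) {
  if (length(dim(a)) == 3) {
    nc <- dim(a)[3]
    if (nc >= 3) {
      a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    } else {
      a <- a[, , 1]
    }
  }
  a[rev(seq_len(nrow(a))), , drop = FALSE]
}

#' Read a frame sequence from a directory of images
#'
#' Reads all `.png`/`.tif`/`.tiff` files in `path` in lexicographic order.
#' Colour images are converted to luminance; rows are flipped so the origin is
#' the bottom-left corner. Image-sequence directories are the canonical
#' bit-exact input; video containers must be exported to frames with an
#' external tool first.
#'
#' @param path directory containing the frame images.
#' @param fps frames per second to attach to the sequence.
#' @return A [frame_sequence()].
#' @export
read_frames <- function(path, fps = 30) {
  if (!dir.exists(path)) {
    if (file.exists(path)) {
      abort(paste0("`path` is a file; video containers are not decoded here. ",
                   "Export the video to a directory of PNG/TIFF frames first."))
    }
    abort(sprintf("Path '%s' does not exist.", path))
  }
  files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0) abort(sprintf("No PNG/TIFF frames found in '%s'.", path))
  frames <- purrr::map(files, function(f) {
    a <- if (grepl("\\.png$", f, ignore.case = TRUE)) {
      png::readPNG(f)
    } else {
      tiff::readTIFF(f)
    }
    decode_image_array(a)
  })
  frame_sequence(frames, fps = fps)
}

#' Write a frame sequence as numbered PNG files
#'
#' @param fs a [frame_sequence()].
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_frames <- function(fs, path) {
  stopifnot(inherits(fs, "frame_sequence"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(fs$frames)) {
    f <- fs$frames[[i]]
    f <- pmin(pmax(f, 0), 1)
    f <- f[rev(seq_len(nrow(f))), , drop = FALSE]  # back to top-left origin
    png::writePNG(f, file.path(path, sprintf("frame_%04d.png", i - 1L)))
  }
  invisible(path)
}

# Pixel lookup helpers (0-based x right, y up).
frame_dim <- function(frame) c(width = ncol(frame), height = nrow(frame))

in_bounds <- function(frame, x, y) {
  x >= 0 & x <= ncol(frame) - 1 & y >= 0 & y <= nrow(frame) - 1
}
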