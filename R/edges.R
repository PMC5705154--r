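#' Sobel edge images
#'
#' Computes the horizontal (`Ex`) and vertical (`Ey`) 3x3 Sobel responses of a
#' grayscale frame. `Ex` responds to intensity changes along x (a vertical
#' step of height `h` gives an interior response of `4h`), `Ey` to changes
#' along y (upward, in the bottom-left-origin convention). Borders use
#' symmetric reflect padding (edge pixel repeated), the same rule applied when
#' template sampling leaves the image.
#'
#' These per-pixel edge characteristics — not raw intensities — are what the
#' template tracker matches between frames, which makes the matching error
#' invariant to global brightness offsets.
#'
#' @param frame numeric matrix (bottom-left-origin grayscale frame).
#' @return List with matrices `Ex` and `Ey`, same shape as `frame`.
#' @examples
#' e <- sobel_edges(matrix(rep(c(0, 0, 1, 1), each = 8), 8, 4))
#' range(e$Ey)
#' @export
sobel_edges <- function(frame) {
  if (!is.matrix(frame) || nrow(frame) < 3 || ncol(frame) < 3) {
    abort("`frame` must be a matrix of at least 3x3 pixels.")
  }
  if (!all(is.finite(frame))) abort("`frame` must be finite.")
  nr <- nrow(frame); nc <- ncol(frame)
  # reflect-pad by one pixel (edge repeated)
  p <- frame[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  sh <- function(dy, dx) p[(2 + dy):(nr + 1 + dy), (2 + dx):(nc + 1 + dx)]
  # rows index y (upward), columns index x (rightward)
  ex <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  ey <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  list(Ex = ex, Ey = ey)
}

# Bilinear sampling with reflect padding at continuous 0-based (x, y)
# coordinates; thin wrapper over the compiled kernel.
bilinear_sample <- function(m, x, y) {
  .bilinear_sample(m, as.numeric(x), as.numeric(y))
}

#' Create a square edge template
#'
#' A template is the square ROI centred on a target point in a reference
#' frame; tracking matches its Sobel edge characteristics against later
#' frames under small rotations and shifts.
#'
#' @param center numeric `(x, y)` target point, 0-based pixel coordinates.
#' @param side odd side length in pixels.
#' @param frame optional reference frame matrix; when given, the template
#'   must lie fully inside it.
#' @return List with `center`, `side` and the integer pixel `offsets`.
#' @export
edge_template <- function(center, side = 41L, frame = NULL) {
  side <- check_odd_side(side, min = 3L, arg = "side")
  if (length(center) != 2 || !all(is.finite(center))) {
    abort("`center` must be a finite (x, y) pair.")
  }
  h <- (side - 1) / 2
  if (!is.null(frame)) {
    if (center[1] - h < 0 || center[1] + h > ncol(frame) - 1 ||
        center[2] - h < 0 || center[2] + h > nrow(frame) - 1) {
      abort("Template ROI falls outside the image at creation.")
    }
  }
  list(center = as.numeric(center), side = side, offsets = roi_offsets(side))
}
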