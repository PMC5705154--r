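# Internal helpers shared across modules.

# Evaluate `expr` with a locally-seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(expr)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_odd_side <- function(side, min = 9L, arg = "roi_side") {
  if (!is_scalar_number(side) || side %% 2 != 1 || side < min) {
    abort(sprintf("`%s` must be an odd integer >= %d, got %s.",
                  arg, min, paste(side, collapse = ",")))
  }
  as.integer(side)
}

deg2rad <- function(deg) deg * pi / 180

# Square-ROI pixel offsets relative to the centre, as a tibble of integer
# (dx, dy) pairs; side must be odd so the centre is a pixel.
roi_offsets <- function(side) {
  side <- check_odd_side(side, min = 3L, arg = "side")
  h <- (side - 1L) / 2L
  g <- expand.grid(dx = -h:h, dy = -h:h)
  tibble::tibble(dx = as.numeric(g$dx), dy = as.numeric(g$dy))
}
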