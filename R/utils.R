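# Shared helpers: rounding, seeding, frame geometry.

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used for all reported percentages (base `round()` uses
#' round-half-even, which disagrees on exact ties).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(2.675, 2) # 2.68, not 2.67
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Fraction -> percentage at 2 decimals (Table-1 convention).
as_pct <- function(frac, digits = 2) round_half_up(100 * frac, digits)

# Deterministic fan-out of a master seed into per-stage seeds.
# Keeps results < 2^31 so they are valid R integers.
derive_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1)
  h <- 0
  for (ch in utf8ToInt(as.character(stage))) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.double(master_seed) * 48271 + h) %% 2147483647)
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s].", name, min, max))
  }
  invisible(x)
}

# Half-open square frames [x, x+size) x [y, y+size), 0-based coordinates.
frames_overlap <- function(x1, y1, s1, x2, y2, s2) {
  (x1 < x2 + s2) & (x2 < x1 + s1) & (y1 < y2 + s2) & (y2 < y1 + s1)
}

frame_iou <- function(x1, y1, s1, x2, y2, s2) {
  ix <- pmax(0, pmin(x1 + s1, x2 + s2) - pmax(x1, x2))
  iy <- pmax(0, pmin(y1 + s1, y2 + s2) - pmax(y1, y2))
  inter <- ix * iy
  inter / (s1 * s1 + s2 * s2 - inter)
}

# Point-in-frame containment (half-open).
frame_contains <- function(fx, fy, size, px, py) {
  px >= fx & px < fx + size & py >= fy & py < fy + size
}

# Crop a `size` x `size` region with top-left (x, y) (0-based) out of a pixel
# matrix, padding out-of-bounds area with `pad`.
crop_padded <- function(pixels, x, y, size, pad) {
  h <- nrow(pixels); w <- ncol(pixels)
  out <- matrix(pad, size, size)
  rows <- (y + 1):(y + size)
  cols <- (x + 1):(x + size)
  rin <- rows >= 1 & rows <= h
  cin <- cols >= 1 & cols <= w
  if (any(rin) && any(cin)) {
    out[rin, cin] <- pixels[rows[rin], cols[cin], drop = FALSE]
  }
  out
}

# Integer-factor block-mean downsampling; trims trailing rows/cols that do
# not fill a complete block.
block_downsample <- function(m, factor) {
  if (factor == 1) return(m)
  h2 <- nrow(m) %/% factor
  w2 <- ncol(m) %/% factor
  if (h2 < 1 || w2 < 1) abort("downsample factor larger than the image")
  m <- m[seq_len(h2 * factor), seq_len(w2 * factor), drop = FALSE]
  # mean over row-blocks, then column-blocks
  a <- array(m, c(factor, h2, w2 * factor))
  m1 <- colMeans(a)                               # h2 x (w2*factor)
  a2 <- array(t(m1), c(factor, w2, h2))
  t(colMeans(a2))                                 # h2 x w2
}
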