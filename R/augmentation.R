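# Training-time augmentation: horizontal/vertical shift, rotation,
# horizontal flip, multiplicative brightness jitter. Applied on the fly to
# training images only; all randomness is driven by an explicit seed.

#' Augmentation policy
#'
#' Magnitudes follow the framework-style fractional convention: shifts are
#' fractions of the image extent (0.1 of 224 px by default; switch
#' `shift_unit` to `"pixels"` for absolute offsets), rotation is the maximum
#' absolute angle in degrees, brightness is the maximum relative change
#' (factor drawn uniformly from `[1 - b, 1 + b]`). Geometric transforms fill
#' uncovered pixels with the nearest edge value, which avoids black borders
#' that would otherwise dominate the block-DCT high-frequency content.
#'
#' @param shift_h,shift_v Maximum horizontal/vertical shift (fraction of the
#'   width/height, or pixels when `shift_unit = "pixels"`). Default 0.1.
#' @param rotation Maximum absolute rotation in degrees, in \[0, 180\].
#'   Default 15.
#' @param hflip Apply a horizontal flip with probability 0.5? Default TRUE.
#' @param brightness Maximum relative brightness change, default 0.2.
#' @param shift_unit `"fraction"` (default) or `"pixels"`.
#' @return An object of class `augmentation_policy`.
#' @export
augmentation_policy <- function(shift_h = 0.1, shift_v = 0.1, rotation = 15,
                                hflip = TRUE, brightness = 0.2,
                                shift_unit = c("fraction", "pixels")) {
  shift_unit <- match.arg(shift_unit)
  if (shift_unit == "fraction" && (shift_h < 0 || shift_h >= 1 ||
                                   shift_v < 0 || shift_v >= 1)) {
    stop("fractional shifts must lie in [0, 1)")
  }
  if (rotation < 0 || rotation > 180) stop("`rotation` must be in [0, 180] degrees")
  if (brightness < 0) stop("`brightness` must be >= 0")
  structure(list(shift_h = shift_h, shift_v = shift_v, rotation = rotation,
                 hflip = isTRUE(hflip), brightness = brightness,
                 shift_unit = shift_unit),
            class = "augmentation_policy")
}

# Clamped bilinear gather at fractional (row, col) coordinates.
sample_bilinear <- function(plane, rr, cc) {
  h <- nrow(plane); w <- ncol(plane)
  rr <- pmin(pmax(rr, 1), h)
  cc <- pmin(pmax(cc, 1), w)
  r0 <- pmin(floor(rr), h - 1L); r0[h == 1L] <- 1L
  c0 <- pmin(floor(cc), w - 1L); c0[w == 1L] <- 1L
  r0 <- pmax(r0, 1L); c0 <- pmax(c0, 1L)
  r1 <- pmin(r0 + 1L, h); c1 <- pmin(c0 + 1L, w)
  fr <- rr - r0; fc <- cc - c0
  plane[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    plane[cbind(r1, c0)] * fr * (1 - fc) +
    plane[cbind(r0, c1)] * (1 - fr) * fc +
    plane[cbind(r1, c1)] * fr * fc
}

#' Apply a seeded random augmentation to an image
#'
#' Draws, in a fixed order governed only by `seed`: a horizontal and a
#' vertical shift (uniform up to the policy magnitudes), a rotation angle
#' (uniform in the +/- range), a flip decision (probability 0.5 when
#' enabled) and a brightness factor (uniform in `[1 - b, 1 + b]`), then
#' applies shift, rotation about the image centre, flip and brightness in
#' that order. The output has the same shape as the input; an all-zero
#' policy with flipping disabled returns the input unchanged.
#'
#' @param img An [rgb_image].
#' @param policy An [augmentation_policy()].
#' @param seed Integer seed driving all randomness.
#' @return The augmented [rgb_image].
#' @export
augment <- function(img, policy = augmentation_policy(), seed = 1L) {
  img <- as_rgb_image(img)
  if (!inherits(policy, "augmentation_policy")) {
    stop("`policy` must be an augmentation_policy")
  }
  d <- dim(img); h <- d[1]; w <- d[2]
  draws <- withr::with_seed(as.integer(seed), stats::runif(5))
  unit_w <- if (policy$shift_unit == "fraction") w else 1
  unit_h <- if (policy$shift_unit == "fraction") h else 1
  dx <- (2 * draws[1] - 1) * policy$shift_h * unit_w
  dy <- (2 * draws[2] - 1) * policy$shift_v * unit_h
  theta <- (2 * draws[3] - 1) * policy$rotation * pi / 180
  flip <- policy$hflip && draws[4] < 0.5
  bfac <- 1 + (2 * draws[5] - 1) * policy$brightness

  out <- unclass(img)
  if (dx != 0 || dy != 0 || theta != 0 || flip) {
    # inverse-map output pixels: undo flip, then rotation, then shift
    rc <- rep(seq_len(h), times = w)
    cc <- rep(seq_len(w), each = h)
    if (flip) cc <- w + 1L - cc
    r0 <- (h + 1) / 2; c0 <- (w + 1) / 2
    ct <- cos(theta); st <- sin(theta)
    rr <- r0 + ct * (rc - r0) - st * (cc - c0)
    cs <- c0 + st * (rc - r0) + ct * (cc - c0)
    rr <- rr - dy
    cs <- cs - dx
    for (ch in 1:3) {
      out[, , ch] <- matrix(sample_bilinear(img[, , ch], rr, cs), h, w)
    }
  }
  rgb_image(out * bfac)
}
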