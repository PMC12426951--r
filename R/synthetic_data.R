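# Seeded generator of three-class leaf-like images with controlled
# spatial-frequency signatures, standing in for a real leaf-disease photo
# collection so the whole pipeline is testable offline. The healthy
# analogue has only low-frequency shading; the rust analogue superimposes
# small sharp speckles (high-frequency texture); the angular-leaf-spot
# analogue superimposes larger smooth-edged blotches (mid-frequency). The
# base leaf (shape, colour, shading, sensor noise) is drawn identically for
# every class at a given seed, so lesions are the only class difference.

synthetic_classes <- c("healthy-analog", "blotch-lesion-analog",
                       "speckle-lesion-analog")

synthetic_label <- function(class) {
  switch(class,
         "healthy-analog" = "Healthy",
         "blotch-lesion-analog" = "Angular Leaf Spot",
         "speckle-lesion-analog" = "Bean Rust",
         stop("unknown synthetic class: ", class))
}

#' Specification of one synthetic leaf image
#'
#' @param class One of `"healthy-analog"`, `"speckle-lesion-analog"`
#'   (small sharp dark spots, rust analogue) or `"blotch-lesion-analog"`
#'   (large smooth brown patches, angular-leaf-spot analogue).
#' @param side Image side in pixels, `>= 32` (default 224).
#' @param density Lesion density in \[0, 1\] scaling the lesion count;
#'   0 degenerates to the healthy analogue. Default 0.3.
#' @param color_jitter Standard deviation of the per-image base-colour
#'   jitter, in intensity units. Default 6.
#' @param seed Integer seed; the image is a pure function of the spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(class = synthetic_classes, side = 224L,
                           density = 0.3, color_jitter = 6, seed = 1L) {
  class <- match.arg(class, synthetic_classes)
  if (side < 32) stop("`side` must be >= 32")
  if (density < 0 || density > 1) stop("`density` must be in [0, 1]")
  structure(list(class = class, side = as.integer(side), density = density,
                 color_jitter = color_jitter, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Paint a disc into the three channel planes. Speckles are hard-edged dots;
# blotches have a short soft edge and concentric ring texture of period
# `ring` pixels, which concentrates their energy in the mid-frequency band.
paint_disc <- function(planes, cx, cy, r, colour, sharp, side, ring = NULL) {
  x0 <- max(1L, floor(cx - r)); x1 <- min(side, ceiling(cx + r))
  y0 <- max(1L, floor(cy - r)); y1 <- min(side, ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(planes)
  xs <- x0:x1; ys <- y0:y1
  d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))
  if (sharp) {
    w <- (d <= r) * 1.0
    tex <- 0
  } else {
    w <- pmin(pmax((r - d) / 1.5, 0), 1)
    tex <- 14 * cos(2 * pi * d / ring)
  }
  for (ch in 1:3) {
    sub <- planes[[ch]][ys, xs, drop = FALSE]
    planes[[ch]][ys, xs] <- sub * (1 - w) + (colour[ch] + tex) * w
  }
  planes
}

#' Generate one synthetic leaf image
#'
#' Builds a smooth green leaf (rotated ellipse on a light background, with
#' low-frequency shading, per-image colour jitter and faint sensor noise),
#' then superimposes the class's lesions inside the leaf mask. The result
#' is a deterministic function of the spec; the healthy analogue and a
#' lesion class at density 0 are pixel-identical at the same seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `image` (an [rgb_image]) and `label` (the
#'   corresponding entry of [leaf_classes()]).
#' @export
generate_leaf_image <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) stop("`spec` must be a synthetic_spec")
  s <- spec$side
  withr::with_seed(spec$seed, {
    # -- base leaf, identical for every class at this seed --
    phi <- stats::runif(1, -pi / 6, pi / 6)
    a <- s * stats::runif(1, 0.36, 0.44)
    b <- s * stats::runif(1, 0.26, 0.33)
    ctr <- (s + 1) / 2
    x <- matrix(rep(seq_len(s), each = s), s, s) - ctr   # column coord
    y <- matrix(rep(seq_len(s), times = s), s, s) - ctr  # row coord
    xr <- cos(phi) * x + sin(phi) * y
    yr <- -sin(phi) * x + cos(phi) * y
    mask <- (xr / a)^2 + (yr / b)^2 <= 1

    base_col <- c(62, 128, 52) + stats::rnorm(3, 0, spec$color_jitter)
    bg_col <- c(236, 233, 228)
    f <- stats::runif(4, 0.5, 2.5)
    ph <- stats::runif(4, 0, 2 * pi)
    shade <- 10 * cos(2 * pi * f[1] * x / s + ph[1]) *
      cos(2 * pi * f[2] * y / s + ph[2]) +
      7 * cos(2 * pi * f[3] * (x + y) / s + ph[3]) +
      5 * cos(2 * pi * f[4] * (x - y) / s + ph[4])
    # sensor noise is drawn here (fixed RNG position, identical across
    # classes at one seed) but added after lesion painting, so lesions add
    # texture instead of erasing the noise floor
    noise <- matrix(stats::rnorm(s * s, 0, 1.0), s, s)
    planes <- lapply(1:3, function(ch) {
      p <- matrix(bg_col[ch], s, s)
      p[mask] <- base_col[ch] + shade[mask]
      p
    })

    # -- class-conditional lesions --
    n_lesions <- switch(spec$class,
                        "healthy-analog" = 0L,
                        "speckle-lesion-analog" =
                          as.integer(round(spec$density * 600 * (s / 224)^2)),
                        "blotch-lesion-analog" =
                          as.integer(round(spec$density * 30 * (s / 224)^2)))
    if (n_lesions > 0L) {
      sharp <- spec$class == "speckle-lesion-analog"
      for (i in seq_len(n_lesions)) {
        if (sharp) {
          r <- stats::runif(1, 1.0, 2.2)
          colour <- c(96, 48, 30) + stats::rnorm(3, 0, 6)
          ring <- NULL
        } else {
          r <- stats::runif(1, 0.04, 0.08) * s
          colour <- c(132, 92, 46) + stats::rnorm(3, 0, 8)
          ring <- stats::runif(1, 5, 9)
        }
        # rejection-sample a centre keeping the whole disc inside the leaf
        repeat {
          cx <- stats::runif(1, 1, s); cy <- stats::runif(1, 1, s)
          xrr <- cos(phi) * (cx - ctr) + sin(phi) * (cy - ctr)
          yrr <- -sin(phi) * (cx - ctr) + cos(phi) * (cy - ctr)
          if ((xrr / (a - r))^2 + (yrr / (b - r))^2 <= 1) break
        }
        planes <- paint_disc(planes, cx, cy, r, colour, sharp, s, ring)
      }
    }
    planes <- lapply(planes, function(p) p + noise)
    img <- rgb_image(array(c(planes[[1]], planes[[2]], planes[[3]]),
                           dim = c(s, s, 3L)))
    list(image = img, label = synthetic_label(spec$class))
  })
}

#' Generate a balanced labelled dataset on disk
#'
#' Writes `n_per_class` PNGs per class under `dir/<class>/`, using
#' per-image seeds derived from `seed`, and returns the scanned manifest.
#' Two runs with the same arguments produce byte-identical files.
#'
#' @param n_per_class Images per class, `>= 1`.
#' @param side Image side in pixels (default 224).
#' @param seed Integer master seed.
#' @param dir Output directory (created if needed).
#' @param density Lesion density passed to [synthetic_spec()].
#' @return The dataset manifest from [scan_dataset()].
#' @export
generate_dataset <- function(n_per_class, side = 224L, seed = 1L,
                             dir = tempfile("leafset"), density = 0.3) {
  if (n_per_class < 1) stop("`n_per_class` must be >= 1")
  dir_names <- c("healthy-analog" = "healthy",
                 "blotch-lesion-analog" = "angular_leaf_spot",
                 "speckle-lesion-analog" = "bean_rust")
  for (cl_i in seq_along(synthetic_classes)) {
    cl <- synthetic_classes[cl_i]
    out_dir <- file.path(dir, dir_names[[cl]])
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
    for (i in seq_len(n_per_class)) {
      img_seed <- (as.integer(seed) %% 100000L) * 17389L + cl_i * 4721L + i
      spec <- synthetic_spec(cl, side = side, density = density,
                             seed = img_seed)
      res <- generate_leaf_image(spec)
      save_image(res$image, file.path(out_dir, sprintf("img_%04d.png", i)))
    }
  }
  scan_dataset(dir)
}

#' Mean high-frequency block-DCT energy of an image
#'
#' Averages the squared per-patch standard 2D DCT coefficients whose radial
#' frequency index exceeds the block side (`k1 + k2 > b`, 0-based) over all
#' blocks and channels — the band the enhancement transform amplifies most.
#' The image is cropped to a block multiple if needed.
#'
#' @param img An [rgb_image].
#' @param b Block side (default 16).
#' @return A single number: the mean high-band coefficient energy.
#' @export
high_band_energy <- function(img, b = 16L) {
  img <- as_rgb_image(img)
  d <- dim(img)
  h <- (d[1] %/% b) * b; w <- (d[2] %/% b) * b
  if (h < b || w < b) stop("image smaller than one block")
  kr <- (seq_len(h) - 1L) %% b
  kc <- (seq_len(w) - 1L) %% b
  mask <- outer(kr, kc, "+") > b
  mean(vapply(1:3, function(ch) {
    co <- plane_block_dct(img[seq_len(h), seq_len(w), ch], b)
    mean(co[mask]^2)
  }, 0))
}
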