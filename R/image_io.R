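# Image container, PNG/JPEG IO, bilinear resize, dataset manifests.

#' RGB image container
#'
#' A thin S3 wrapper around an `H x W x 3` numeric array of intensities on
#' the nominal \[0, 255\] scale (values may leave that range after
#' enhancement; they are only clipped when written to disk).
#'
#' @param x Numeric `H x W x 3` array.
#' @return An object of class `rgb_image`.
#' @export
rgb_image <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L) {
    stop("`x` must be an H x W x 3 array")
  }
  if (dim(x)[1] < 1L || dim(x)[2] < 1L) stop("degenerate image: zero-sized plane")
  if (any(!is.finite(x))) stop("image intensities must be finite")
  structure(x * 1.0, class = "rgb_image")
}

as_rgb_image <- function(x) {
  if (inherits(x, "rgb_image")) return(x)
  rgb_image(x)
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image> %d x %d, range [%.1f, %.1f]\n",
              d[1], d[2], min(x), max(x)))
  invisible(x)
}

#' Canonical class vocabulary of the leaf-disease task
#'
#' The three classes, in the fixed order used for confusion matrices,
#' one-hot encoding and tie-breaking at prediction time.
#'
#' @return Character vector of length 3.
#' @export
leaf_classes <- function() c("Healthy", "Angular Leaf Spot", "Bean Rust")

normalize_label <- function(x) gsub("[ _-]+", " ", tolower(trimws(x)))

match_class <- function(dirname) {
  lut <- stats::setNames(leaf_classes(), normalize_label(leaf_classes()))
  lut[normalize_label(dirname)]
}

#' Load a PNG or JPEG file as an RGB image
#'
#' Decodes the file, promotes grayscale to three identical planes, drops any
#' alpha channel, and scales intensities to \[0, 255\].
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return An [rgb_image].
#' @export
load_image <- function(path) {
  if (length(path) != 1L || !file.exists(path)) {
    stop("cannot read image: file not found: ", path)
  }
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    switch(ext,
           png = png::readPNG(path),
           jpg = ,
           jpeg = jpeg::readJPEG(path),
           stop("unsupported image format '", ext, "' for ", path)),
    error = function(e) stop("failed to decode image ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.matrix(raw)) raw <- array(rep(raw, 3L), dim = c(dim(raw), 3L))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  if (dim(raw)[3] == 2L) {  # gray + alpha
    raw <- array(rep(raw[, , 1L], 3L), dim = c(dim(raw)[1:2], 3L))
  }
  rgb_image(raw * 255)
}

#' Write an RGB image to PNG or JPEG
#'
#' Intensities are clipped to \[0, 255\] and quantised (round half-to-even)
#' to 8 bits. PNG is lossless and preferred for enhanced outputs; JPEG is
#' written at quality 0.95.
#'
#' @param img An [rgb_image].
#' @param path Output path ending in `.png`, `.jpg` or `.jpeg`.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  img <- as_rgb_image(img)
  x <- round(pmin(pmax(unclass(img), 0), 255)) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(x, path),
         jpg = ,
         jpeg = jpeg::writeJPEG(x, path, quality = 0.95),
         stop("unsupported output format '", ext, "'"))
  invisible(path)
}

# Row/column bilinear interpolation weights from n_src to n_dst samples
# (half-pixel centre alignment, edge clamped). Returns an n_dst x n_src
# weight matrix with at most two non-zeros per row.
bilinear_weights <- function(n_dst, n_src) {
  W <- matrix(0, n_dst, n_src)
  scale <- n_src / n_dst
  src <- (seq_len(n_dst) - 0.5) * scale + 0.5  # 1-based source coordinate
  lo <- pmin(pmax(floor(src), 1L), n_src)
  hi <- pmin(lo + 1L, n_src)
  frac <- pmin(pmax(src - lo, 0), 1)
  W[cbind(seq_len(n_dst), lo)] <- 1 - frac
  W[cbind(seq_len(n_dst), hi)] <- W[cbind(seq_len(n_dst), hi)] + frac
  W
}

#' Resize an RGB image to a square side with bilinear interpolation
#'
#' Aspect ratio is not preserved: both axes are resampled to `side` pixels
#' (the convention of patch-based classification backbones, whose inputs
#' are square). Resizing to the current size returns the image unchanged.
#'
#' @param img An [rgb_image].
#' @param side Target side length in pixels, `>= 1`.
#' @return An [rgb_image] of dimension `side x side x 3`.
#' @export
resize_to <- function(img, side = 224L) {
  img <- as_rgb_image(img)
  if (side < 1) stop("`side` must be >= 1")
  side <- as.integer(side)
  d <- dim(img)
  if (d[1] == side && d[2] == side) return(img)
  Wr <- bilinear_weights(side, d[1])
  Wc <- t(bilinear_weights(side, d[2]))
  out <- array(0, dim = c(side, side, 3L))
  for (ch in 1:3) out[, , ch] <- Wr %*% img[, , ch] %*% Wc
  rgb_image(out)
}

#' Scan a directory-per-class dataset into a manifest
#'
#' Expects `root/<class>/<image files>` with class directory names matching
#' the three-class leaf vocabulary (`Healthy`, `Angular Leaf Spot`,
#' `Bean Rust`; case, spaces, `_` and `-` are normalised). Files are listed
#' in sorted order so the manifest is deterministic across runs.
#'
#' @param root Dataset root directory.
#' @return A tibble with columns `path` and `label` (factor over
#'   [leaf_classes()]), with a `class_counts` attribute.
#' @export
scan_dataset <- function(root) {
  if (length(root) != 1L || !dir.exists(root)) {
    stop("dataset root does not exist: ", root)
  }
  dirs <- sort(list.dirs(root, recursive = FALSE))
  if (length(dirs) == 0L) stop("empty dataset root (no class directories): ", root)
  recs <- lapply(dirs, function(d) {
    cls <- match_class(basename(d))
    if (is.na(cls)) {
      stop("unknown class directory '", basename(d), "'; expected one of: ",
           paste(leaf_classes(), collapse = ", "))
    }
    files <- sort(list.files(d, pattern = "\\.(png|jpe?g)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) return(NULL)
    tibble::tibble(path = files, label = unname(cls))
  })
  manifest <- do.call(rbind, recs)
  if (is.null(manifest) || nrow(manifest) == 0L) {
    stop("no images found under ", root)
  }
  manifest$label <- factor(manifest$label, levels = leaf_classes())
  stopifnot(!anyDuplicated(manifest$path))
  attr(manifest, "class_counts") <- table(manifest$label)
  manifest
}

#' Write a manifest as a tab-separated table
#'
#' @param manifest A manifest tibble from [scan_dataset()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
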