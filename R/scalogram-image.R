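#' Min-max normalize a scalogram to the unit interval
#'
#' Linear rescaling `(x - min)/(max - min)` of the magnitude matrix. A
#' constant matrix (max == min) maps to all zeros. Because the rescaling
#' cancels any positive gain on the input beat, rendered images are invariant
#' to amplitude calibration of the recording.
#'
#' @param scalogram A [scalogram()] object or a numeric matrix.
#' @return Numeric matrix with entries in `[0, 1]`.
#' @export
normalize_magnitude <- function(scalogram) {
  m <- if (inherits(scalogram, "scalogram")) scalogram$magnitude else scalogram
  if (!is.matrix(m) || !all(is.finite(m))) {
    stop("scalogram magnitude must be a finite matrix", call. = FALSE)
  }
  lo <- min(m); hi <- max(m)
  if (hi == lo) return(matrix(0, nrow(m), ncol(m)))
  (m - lo) / (hi - lo)
}

# 64-entry jet-like lookup table (blue -> cyan -> yellow -> red), the classic
# default of numerical plotting environments; stored explicitly so rendered
# images are identical across platforms.
jet_table <- function(n = 64L) {
  # piecewise-linear ramps of the classic jet map
  u <- (seq_len(n) - 1) / (n - 1)
  interp <- function(x, xp, yp) stats::approx(xp, yp, x, rule = 2)$y
  r <- interp(u, c(0, 0.35, 0.66, 0.89, 1), c(0, 0, 1, 1, 0.5))
  g <- interp(u, c(0, 0.125, 0.375, 0.64, 0.91, 1), c(0, 0, 1, 1, 0, 0))
  b <- interp(u, c(0, 0.11, 0.34, 0.65, 1), c(0.5, 1, 1, 0, 0))
  cbind(r = r, g = g, b = b)
}

#' Map a unit-interval matrix through a colormap
#'
#' Deterministically maps each value through a 64-entry lookup table with
#' linear interpolation between adjacent table entries. Value 0 yields the
#' first table colour, value 1 the last.
#'
#' @param normalized Numeric matrix with entries in `[0, 1]`.
#' @param colormap `"jet"` (default) for the explicit jet-like table, or
#'   `"gray"` to replicate the value into all three channels.
#' @return Numeric array `nrow x ncol x 3` with entries in `[0, 1]`.
#' @export
apply_colormap <- function(normalized, colormap = c("jet", "gray")) {
  colormap <- match.arg(colormap)
  m <- normalized
  if (!is.matrix(m)) stop("`normalized` must be a matrix", call. = FALSE)
  if (any(!is.finite(m)) || any(m < 0) || any(m > 1)) {
    stop("`normalized` entries must lie in [0, 1]", call. = FALSE)
  }
  out <- array(0, dim = c(nrow(m), ncol(m), 3L))
  if (colormap == "gray") {
    out[, , 1] <- m; out[, , 2] <- m; out[, , 3] <- m
    return(out)
  }
  tab <- jet_table(64L)
  pos <- m * 63 + 1          # fractional index into the table
  lo <- floor(pos); hi <- pmin(lo + 1, 64); frac <- pos - lo
  for (ch in 1:3) {
    out[, , ch] <- tab[lo, ch] * (1 - frac) + tab[hi, ch] * frac
  }
  out
}

#' Bilinear image resize
#'
#' Resizes an H x W x 3 array (or an H x W matrix) to a target size with
#' bilinear interpolation using the align-corners convention: source corner
#' pixels map exactly to target corner pixels, so resizing an image to its own
#' size is the identity. Interpolated values are convex combinations, so the
#' `[0, 1]` range is preserved.
#'
#' @param image Numeric array `H x W x C` or matrix `H x W`, entries in `[0, 1]`.
#' @param target Integer vector `c(H, W)` of the output size (each >= 1).
#' @return Numeric array `target[1] x target[2] x C` (or matrix if the input
#'   was a matrix).
#' @export
resize_image <- function(image, target) {
  is_mat <- is.matrix(image)
  if (is_mat) image <- array(image, dim = c(dim(image), 1L))
  d <- dim(image)
  if (length(d) != 3L) stop("`image` must be H x W x C or a matrix", call. = FALSE)
  if (d[1] < 2L || d[2] < 2L) stop("source image must be at least 2 x 2", call. = FALSE)
  target <- as.integer(target)
  if (length(target) != 2L || any(is.na(target)) || any(target < 1L)) {
    stop("`target` must be two positive integers c(H, W)", call. = FALSE)
  }
  H <- target[1]; W <- target[2]
  src_pos <- function(n_dst, n_src) {
    if (n_dst == 1L) return(list(lo = 1L, hi = 1L, frac = 0))
    p <- (seq_len(n_dst) - 1) * (n_src - 1) / (n_dst - 1) + 1
    lo <- pmin(floor(p), n_src - 1L)
    list(lo = as.integer(lo), hi = as.integer(lo + 1L), frac = p - lo)
  }
  ry <- src_pos(H, d[1]); rx <- src_pos(W, d[2])
  out <- array(0, dim = c(H, W, d[3]))
  wy <- ry$frac; wx <- rx$frac
  for (ch in seq_len(d[3])) {
    ch_src <- image[, , ch]
    tl <- ch_src[ry$lo, rx$lo, drop = FALSE]; tr <- ch_src[ry$lo, rx$hi, drop = FALSE]
    bl <- ch_src[ry$hi, rx$lo, drop = FALSE]; br <- ch_src[ry$hi, rx$hi, drop = FALSE]
    top <- tl * (1 - rep(wx, each = H)) + tr * rep(wx, each = H)
    bot <- bl * (1 - rep(wx, each = H)) + br * rep(wx, each = H)
    out[, , ch] <- top * (1 - wy) + bot * wy
  }
  if (is_mat && d[3] == 1L) out[, , 1] else out
}

#' Render a scalogram as a fixed-size RGB image
#'
#' Normalizes the magnitude, maps it through the colormap and resizes to the
#' target. Rows are ordered with the smallest scale (highest frequency) at
#' the top of the image; set `flip_rows = TRUE` to invert.
#'
#' @param scalogram A [scalogram()] object (or magnitude matrix).
#' @param size Target size `c(H, W)`; `c(224, 224)` for large backbones,
#'   `c(28, 28)` for the small CNN.
#' @param colormap Passed to [apply_colormap()].
#' @param log_magnitude If `TRUE`, compress magnitudes with `log1p` before
#'   normalizing (off by default: magnitudes are mapped linearly).
#' @param flip_rows Put the largest scale at the top instead.
#' @return Numeric array `size[1] x size[2] x 3`, entries in `[0, 1]`.
#' @export
scalogram_image <- function(scalogram, size = c(224L, 224L),
                            colormap = c("jet", "gray"),
                            log_magnitude = FALSE, flip_rows = FALSE) {
  m <- if (inherits(scalogram, "scalogram")) scalogram$magnitude else scalogram
  if (log_magnitude) m <- log1p(m)
  norm <- normalize_magnitude(m)
  if (flip_rows) norm <- norm[rev(seq_len(nrow(norm))), , drop = FALSE]
  resize_image(apply_colormap(norm, colormap), size)
}

#' Write a scalogram image to a PNG file
#'
#' 8-bit-per-channel PNG output; the quantisation is deterministic, so
#' identical beats produce byte-identical files.
#'
#' @param image Numeric `H x W x 3` array in `[0, 1]`.
#' @param path Output file path (conventionally `<subject>_<beat>.png`).
#' @return `path`, invisibly.
#' @export
write_scalogram_png <- function(image, path) {
  png::writePNG(image, target = path)
  invisible(path)
}
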