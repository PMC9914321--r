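#' Enhancement measure (EME)
#'
#' Block-based contrast measure: the image is partitioned into
#' non-overlapping `block_h` x `block_w` cells (3 x 3 by default; trailing
#' partial blocks are dropped rather than padded, which would fabricate
#' border contrast) and the per-block values
#' `20 * log10(I_max / max(I_min, epsilon))` are averaged. Larger EME means
#' stronger local contrast; a constant image scores exactly 0. The decibel
#' convention (log base 10) is used. `epsilon` floors the block minimum so
#' blocks containing true zeros stay finite; a block whose maximum is below
#' `epsilon` contributes 0.
#'
#' @param img A raw-tagged [gray_image] on the 0-255 scale, or a plain
#'   numeric matrix on that scale.
#' @param block_h,block_w Block dimensions (default 3 x 3).
#' @param epsilon Floor for the block minimum, in raw intensity units
#'   (default 1, i.e. one 8-bit gray level).
#' @return Non-negative scalar, in dB.
#' @examples
#' eme(gray_image(matrix(c(50, rep(125, 7), 200), 3, 3), "raw"))  # 20*log10(4)
#' @export
eme <- function(img, block_h = 3L, block_w = 3L, epsilon = 1) {
  x <- metric_pixels(img)
  block_h <- as.integer(block_h); block_w <- as.integer(block_w)
  stopifnot(block_h >= 1L, block_w >= 1L, epsilon > 0)
  nbr <- nrow(x) %/% block_h
  nbc <- ncol(x) %/% block_w
  if (nbr < 1L || nbc < 1L) {
    stop(sprintf("image (%dx%d) is smaller than one %dx%d block",
                 nrow(x), ncol(x), block_h, block_w), call. = FALSE)
  }
  x <- x[seq_len(nbr * block_h), seq_len(nbc * block_w), drop = FALSE]
  # block min/max by folding the block offsets; avoids an R-level block loop
  bmax <- matrix(-Inf, nbr, nbc)
  bmin <- matrix(Inf, nbr, nbc)
  for (i in seq_len(block_h)) {
    ri <- seq.int(i, by = block_h, length.out = nbr)
    for (j in seq_len(block_w)) {
      sub <- x[ri, seq.int(j, by = block_w, length.out = nbc), drop = FALSE]
      bmax <- pmax(bmax, sub)
      bmin <- pmin(bmin, sub)
    }
  }
  contrib <- ifelse(bmax < epsilon, 0,
                    20 * log10(bmax / pmax(bmin, epsilon)))
  mean(contrib)
}

#' Absolute mean brightness error (AMBE)
#'
#' Absolute difference between the mean intensities of two same-sized raw
#' images; small values indicate the processing preserved global
#' brightness. Symmetric in its arguments; by convention the reference is
#' the original source image.
#'
#' @param reference,processed Raw-tagged [gray_image]s (or matrices) of the
#'   same dimensions and scale.
#' @return Non-negative scalar.
#' @export
ambe <- function(reference, processed) {
  a <- metric_pixels(reference); b <- metric_pixels(processed)
  if (!identical(dim(a), dim(b))) {
    stop("reference and processed images differ in shape", call. = FALSE)
  }
  abs(mean(a) - mean(b))
}

#' Shannon entropy of an 8-bit image
#'
#' Pixels are requantized to the 256-level grid (round half up) and the
#' entropy of the resulting histogram is returned in bits: 0 for a constant
#' image, up to 8 when all 256 levels are equally frequent.
#'
#' @inheritParams eme
#' @return Entropy in bits, in \[0, 8\].
#' @export
entropy <- function(img) {
  x <- metric_pixels(img)
  lev <- as.integer(clamp(floor(x + 0.5), 0, 255))
  p <- tabulate(lev + 1L, nbins = 256L) / length(lev)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Population standard deviation of image intensities
#'
#' Divides by N (not N - 1): the image is the whole population of pixels.
#'
#' @inheritParams eme
#' @return Non-negative scalar in raw intensity units.
#' @export
std_dev <- function(img) {
  x <- metric_pixels(img)
  sqrt(mean((x - mean(x))^2))
}

#' Universal image quality index (IQI)
#'
#' Full-reference structural index combining loss of correlation, luminance
#' distortion and contrast distortion: over every `window` x `window`
#' sliding window (stride 1),
#'
#'   Q = 4 * s_xy * mx * my / ((s_x^2 + s_y^2) * (mx^2 + my^2))
#'
#' and the mean of Q over all windows with a nonzero denominator is
#' returned. Q lies in \[-1, 1\]; `iqi(x, x) = 1` for any non-constant
#' image, and structural inversion drives Q negative.
#'
#' @param candidate,reference Raw-tagged [gray_image]s (or matrices) of the
#'   same dimensions.
#' @param window Side of the square sliding window (default 8).
#' @return Scalar in \[-1, 1\].
#' @export
iqi <- function(candidate, reference, window = 8L) {
  x <- metric_pixels(candidate); y <- metric_pixels(reference)
  if (!identical(dim(x), dim(y))) {
    stop("candidate and reference images differ in shape", call. = FALSE)
  }
  w <- as.integer(window)
  if (w > min(dim(x))) {
    stop(sprintf("window %d exceeds the smaller image side %d",
                 w, min(dim(x))), call. = FALSE)
  }
  n <- w * w
  sx  <- window_sums(x, w);      sy  <- window_sums(y, w)
  sxx <- window_sums(x * x, w);  syy <- window_sums(y * y, w)
  sxy <- window_sums(x * y, w)
  mx <- sx / n; my <- sy / n
  vx <- sxx / n - mx^2; vy <- syy / n - my^2
  cxy <- sxy / n - mx * my
  den <- (vx + vy) * (mx^2 + my^2)
  ok <- abs(den) > 1e-12
  if (!any(ok)) {
    stop("IQI undefined: every window has zero variance and zero mean",
         call. = FALSE)
  }
  q <- (4 * cxy * mx * my)[ok] / den[ok]
  mean(q)
}

#' Per-image quality report
#'
#' Bundles the metric suite for one image, optionally against a reference
#' (which enables AMBE and IQI). All metrics are computed on the raw 0-255
#' scale; a normalized image is de-normalized first.
#'
#' @param img Image under assessment ([gray_image]).
#' @param reference Optional reference image for AMBE/IQI (typically the
#'   original source).
#' @param block_h,block_w,epsilon Passed to [eme()].
#' @param window Passed to [iqi()].
#' @return A one-row `data.frame` with columns `E`, `EME`, `AMBE`, `SD`,
#'   `IQI` (`AMBE`/`IQI` are `NA` without a reference).
#' @export
metrics_report <- function(img, reference = NULL,
                           block_h = 3L, block_w = 3L, epsilon = 1,
                           window = 8L) {
  img <- as_raw(img)
  out <- data.frame(
    E   = entropy(img),
    EME = eme(img, block_h, block_w, epsilon),
    AMBE = NA_real_,
    SD  = std_dev(img),
    IQI = NA_real_
  )
  if (!is.null(reference)) {
    reference <- as_raw(reference)
    out$AMBE <- ambe(reference, img)
    # IQI is undefined for a fully constant pair; report NA rather than
    # aborting a batch over a degenerate image
    out$IQI <- tryCatch(iqi(img, reference, window),
                        error = function(e) NA_real_)
  }
  out
}

# -- helpers --------------------------------------------------------------

as_raw <- function(img) {
  if (is_gray_image(img) && img$range == "normalized") denormalize(img) else img
}

# Accept a raw gray_image or bare matrix; reject normalized input, whose
# [0,1] scale would silently change EME/SD/AMBE.
metric_pixels <- function(img) {
  if (is_gray_image(img)) {
    if (img$range != "raw") {
      stop("metrics operate on raw-scale images; call denormalize() first",
           call. = FALSE)
    }
    img$pixels
  } else if (is.matrix(img) && is.numeric(img)) {
    img
  } else {
    stop("expected a gray_image or numeric matrix", call. = FALSE)
  }
}

# Sums over all w x w sliding windows (stride 1) via a padded integral
# image; returns an (H-w+1) x (W-w+1) matrix.
window_sums <- function(x, w) {
  h <- nrow(x); wd <- ncol(x)
  cs <- matrix(0, h + 1L, wd + 1L)
  cs[-1L, -1L] <- x
  cs <- apply(cs, 2L, cumsum)        # cumulative down columns
  cs <- t(apply(cs, 1L, cumsum))     # then across rows
  i <- seq_len(h - w + 1L); j <- seq_len(wd - w + 1L)
  cs[i + w, j + w, drop = FALSE] - cs[i, j + w, drop = FALSE] -
    cs[i + w, j, drop = FALSE] + cs[i, j, drop = FALSE]
}
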