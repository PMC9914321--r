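#' Sigmoid (S-curve) gray-level transform parameters
#'
#' The transform maps a normalized intensity r in \[0, 1\] to
#'
#'   s(r) = alpha + (beta - alpha) / (1 + exp(-(r - gamma) / delta))
#'
#' `alpha` and `beta` are the two asymptote-side constants (s tends to
#' `alpha` as r falls below the center and to `beta` above it), `gamma` is
#' the sigmoid center on the normalized gray axis and `delta` its width:
#' small `delta` means a steep mid-tone stretch. The defaults are the tuned
#' operating point for breast images; note that with them `beta < alpha`,
#' so the default map is a *decreasing* sigmoid, i.e. it inverts intensity
#' while stretching contrast. Use [scurve_invert()] to swap the asymptotes
#' if a non-inverting map is wanted.
#'
#' @param alpha,beta Asymptote-side constants; must differ (equal values
#'   make the transform constant).
#' @param gamma Sigmoid center, normally inside \[0, 1\].
#' @param delta Sigmoid width, strictly positive.
#' @return An object of class `scurve_params`.
#' @examples
#' p <- scurve_params()
#' scurve_value(p$gamma, p)  # midpoint: (alpha + beta) / 2
#' @export
scurve_params <- function(alpha = 0.9642, beta = 8.594e-4,
                          gamma = 0.4962, delta = 0.07598) {
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0) {
    stop("`delta` must be a single positive number", call. = FALSE)
  }
  if (alpha == beta) {
    stop("`alpha` and `beta` must differ (equal values give a constant map)",
         call. = FALSE)
  }
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta),
                 gamma = as.numeric(gamma), delta = as.numeric(delta)),
            class = "scurve_params")
}

#' @rdname scurve_params
#' @param p An `scurve_params` object.
#' @export
scurve_invert <- function(p) {
  stopifnot(inherits(p, "scurve_params"))
  scurve_params(p$beta, p$alpha, p$gamma, p$delta)
}

#' @export
print.scurve_params <- function(x, ...) {
  cat(sprintf("<scurve_params alpha=%g beta=%g gamma=%g delta=%g (%s)>\n",
              x$alpha, x$beta, x$gamma, x$delta,
              if (x$beta < x$alpha) "decreasing" else "increasing"))
  invisible(x)
}

#' Evaluate the S-curve transform
#'
#' Pointwise sigmoid map on normalized intensities; the result is clamped
#' to \[0, 1\] (inert for the default parameters, whose range is roughly
#' (0.0021, 0.9628), but tuned parameters may overshoot).
#'
#' @param r Numeric vector or matrix of normalized intensities in \[0, 1\].
#' @inheritParams scurve_invert
#' @return Transformed intensities, same shape as `r`, in \[0, 1\].
#' @export
scurve_value <- function(r, p = scurve_params()) {
  stopifnot(inherits(p, "scurve_params"))
  s <- p$alpha + (p$beta - p$alpha) / (1 + exp(-(r - p$gamma) / p$delta))
  clamp(s, 0, 1)
}

#' Global S-curve enhancement
#'
#' Applies [scurve_value()] elementwise to a whole normalized image.
#'
#' @param img A normalized [gray_image].
#' @inheritParams scurve_invert
#' @return A normalized [gray_image] of the same shape.
#' @export
scurve_global <- function(img, p = scurve_params()) {
  stopifnot(is_gray_image(img))
  if (img$range != "normalized") {
    stop("scurve_global() needs a normalized image; call normalize() first",
         call. = FALSE)
  }
  gray_image(scurve_value(img$pixels, p), "normalized", img$l_min, img$l_max)
}

#' Local (tiled) S-curve enhancement
#'
#' The image is divided into a `tiles` x `tiles` grid (edge tiles take the
#' ceiling remainder). Within each tile the intensities are renormalized so
#' the tile minimum maps to 0 and the tile maximum to 1, pushed through the
#' sigmoid, and mapped back onto the tile's original min/max span — so each
#' tile gets the full mid-tone stretch regardless of how narrow its local
#' range is. With `blend = TRUE` (default) every pixel is bilinearly
#' interpolated between the mappings of the four nearest tile centers, the
#' same seam-suppression scheme adaptive histogram equalization uses.
#' A constant tile passes through unchanged. With `renormalize = FALSE`
#' the sigmoid is applied to the tile's pixels directly (no per-tile
#' rescaling), in which case `tiles = 1, blend = FALSE` reproduces
#' [scurve_global()] exactly.
#'
#' @inheritParams scurve_global
#' @param tiles Tiles per side (a `tiles` x `tiles` grid); must not exceed
#'   the smaller image side.
#' @param blend Bilinearly blend neighboring tile mappings (default `TRUE`).
#' @param renormalize Rescale each tile to \[0, 1\] before the sigmoid and
#'   restore its span after (default `TRUE`).
#' @return A normalized [gray_image] of the same shape.
#' @export
scurve_local <- function(img, p = scurve_params(), tiles = 8L,
                         blend = TRUE, renormalize = TRUE) {
  stopifnot(is_gray_image(img))
  if (img$range != "normalized") {
    stop("scurve_local() needs a normalized image; call normalize() first",
         call. = FALSE)
  }
  x <- img$pixels
  h <- nrow(x); w <- ncol(x)
  k <- as.integer(tiles)
  if (k < 1L || k > min(h, w)) {
    stop(sprintf("tile grid %dx%d does not fit a %dx%d image", k, k, h, w),
         call. = FALSE)
  }

  # tile index (1..k) of each row/column; ceiling split so edge tiles absorb
  # the remainder
  row_tile <- ceiling(seq_len(h) / h * k)
  col_tile <- ceiling(seq_len(w) / w * k)

  # per-tile min/max (k x k)
  tmin <- matrix(Inf, k, k); tmax <- matrix(-Inf, k, k)
  for (i in seq_len(k)) {
    ri <- which(row_tile == i)
    for (j in seq_len(k)) {
      blk <- x[ri, which(col_tile == j), drop = FALSE]
      tmin[i, j] <- min(blk); tmax[i, j] <- max(blk)
    }
  }

  # mapping of tile (i,j) applied to an arbitrary pixel matrix v
  tile_map <- function(v, lo, hi) {
    if (renormalize) {
      span <- hi - lo
      const <- span <= 0
      span[const] <- 1          # placeholder; constant tiles pass through below
      s <- scurve_value((v - lo) / span, p)
      out <- lo + s * (hi - lo)
      out[const] <- v[const]
      out
    } else {
      scurve_value(v, p)
    }
  }

  if (!blend) {
    lo <- tmin[cbind(rep(row_tile, w), rep(col_tile, each = h))]
    hi <- tmax[cbind(rep(row_tile, w), rep(col_tile, each = h))]
    dim(lo) <- dim(hi) <- c(h, w)
    out <- tile_map(x, lo, hi)
  } else {
    # CLAHE-style blending: interpolate between the mappings of the four
    # tiles whose centers surround the pixel
    centers_r <- vapply(seq_len(k), function(i) mean(which(row_tile == i)),
                        numeric(1))
    centers_c <- vapply(seq_len(k), function(j) mean(which(col_tile == j)),
                        numeric(1))
    pos <- function(coord, centers) {
      # fractional tile position: i0, i1 (neighbor tiles) and weight toward i1
      i1 <- findInterval(coord, centers)        # last center <= coord
      i0 <- pmax(i1, 1L); i1 <- pmin(i1 + 1L, k)
      wgt <- rep(0, length(coord))
      inner <- i0 < i1
      wgt[inner] <- (coord[inner] - centers[i0[inner]]) /
        (centers[i1[inner]] - centers[i0[inner]])
      list(lo = i0, hi = i1, w = wgt)
    }
    pr <- pos(seq_len(h), centers_r)
    pc <- pos(seq_len(w), centers_c)

    # evaluate the four neighbor-tile mappings over the full image
    eval_corner <- function(rt, ct) {
      lo <- tmin[cbind(rep(rt, w), rep(ct, each = h))]
      hi <- tmax[cbind(rep(rt, w), rep(ct, each = h))]
      dim(lo) <- dim(hi) <- c(h, w)
      tile_map(x, lo, hi)
    }
    f00 <- eval_corner(pr$lo, pc$lo)
    f01 <- eval_corner(pr$lo, pc$hi)
    f10 <- eval_corner(pr$hi, pc$lo)
    f11 <- eval_corner(pr$hi, pc$hi)

    wr <- matrix(pr$w, h, w)           # weight toward the lower-index row tile
    wc <- matrix(pc$w, h, w, byrow = TRUE)
    out <- (1 - wr) * ((1 - wc) * f00 + wc * f01) +
           wr * ((1 - wc) * f10 + wc * f11)
  }
  gray_image(clamp(out, 0, 1), "normalized", img$l_min, img$l_max)
}
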