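# Orthonormal scaling filters (17 significant digits). The high-pass
# filter is the alternating flip g[k] = (-1)^k h[F-1-k], and the synthesis
# bank is the transpose of the analysis bank, so perfect reconstruction is
# exact under periodic extension.
WAVELET_FILTERS <- list(
  haar = c(0.70710678118654757, 0.70710678118654757),
  db2  = c(0.48296291314453416, 0.83651630373780794,
           0.22414386804201339, -0.12940952255126037),
  db4  = c(0.23037781330889651, 0.71484657055291567,
           0.63088076792985892, -0.027983769416859854,
           -0.18703481171909309, 0.030841381835560764,
           0.032883011666885197, -0.010597401785069032),
  sym4 = c(0.032223100604042702, -0.012603967262037833,
           -0.099219543576847216, 0.29785779560527736,
           0.80373875180591614, 0.49761866763201545,
           -0.02963552764599851, -0.075765714789273325)
)

wavelet_filter <- function(name) {
  h <- WAVELET_FILTERS[[name]]
  if (is.null(h)) {
    stop(sprintf("unknown wavelet '%s' (supported: %s)", name,
                 paste(names(WAVELET_FILTERS), collapse = ", ")),
         call. = FALSE)
  }
  f <- length(h)
  g <- rev(h) * (-1)^(seq_len(f) - 1L)
  list(h = h, g = g, len = f)
}

# One analysis step along the rows of X (even row count): returns the
# low-pass and high-pass halves. Periodic indexing keeps the filter bank
# orthogonal for every even length, including lengths shorter than the
# filter.
dwt_step <- function(X, filt) {
  n <- nrow(X); half <- n %/% 2L
  A <- matrix(0, half, ncol(X)); D <- A
  base <- 2L * (seq_len(half) - 1L)
  for (k in seq_len(filt$len)) {
    rows <- (base + k - 1L) %% n + 1L
    A <- A + filt$h[k] * X[rows, , drop = FALSE]
    D <- D + filt$g[k] * X[rows, , drop = FALSE]
  }
  list(A = A, D = D)
}

idwt_step <- function(A, D, filt) {
  half <- nrow(A); n <- 2L * half
  X <- matrix(0, n, ncol(A))
  base <- 2L * (seq_len(half) - 1L)
  for (k in seq_len(filt$len)) {
    rows <- (base + k - 1L) %% n + 1L
    X[rows, ] <- X[rows, , drop = FALSE] + filt$h[k] * A + filt$g[k] * D
  }
  X
}

# Replicate-pad the trailing row/column so both sides are even; the
# one-sample half-sample-symmetric extension that periodization then wraps.
pad_even <- function(x) {
  if (nrow(x) %% 2L) x <- rbind(x, x[nrow(x), , drop = FALSE])
  if (ncol(x) %% 2L) x <- cbind(x, x[, ncol(x), drop = FALSE])
  x
}

#' Two-dimensional discrete wavelet decomposition
#'
#' Separable one- or multi-level DWT splitting the image into an
#' approximate sub-band (`ll`, the low-frequency "AC" content) and three
#' detail sub-bands per level (`lh`, `hl`, `hh`, the high-frequency "DC"
#' content). Odd-sized inputs are replicate-padded to even before each
#' split, so level-1 sub-bands measure `ceil(side / 2)`; the recorded
#' pre-pad shapes make [idwt_reconstruct()] an exact inverse for every
#' input size.
#'
#' @param img A [gray_image] (raw or normalized) or numeric matrix, at
#'   least 2 x 2.
#' @param wavelet One of `"haar"`, `"db2"`, `"db4"`, `"sym4"`.
#' @param level Decomposition depth (default 1).
#' @return An object of class `subband_set`: `ll` (matrix), `lh`/`hl`/`hh`
#'   (lists of matrices, finest level first), `wavelet`, `level`.
#' @examples
#' S <- dwt2(matrix(1:16, 4, 4), "haar")
#' dim(S$ll)
#' @export
dwt2 <- function(img, wavelet = "haar", level = 1L) {
  x <- if (is_gray_image(img)) img$pixels else img
  stopifnot(is.matrix(x), is.numeric(x))
  level <- as.integer(level)
  stopifnot(level >= 1L)
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop("image must be at least 2x2 for a wavelet split", call. = FALSE)
  }
  filt <- wavelet_filter(wavelet)
  lh <- hl <- hh <- vector("list", level)
  shapes <- vector("list", level)
  for (j in seq_len(level)) {
    shapes[[j]] <- dim(x)
    x <- pad_even(x)
    cols <- dwt_step(x, filt)            # filter down the columns
    rL <- dwt_step(t(cols$A), filt)      # then along the rows
    rH <- dwt_step(t(cols$D), filt)
    x        <- t(rL$A)                  # LL feeds the next level
    lh[[j]]  <- t(rH$A)                  # low in x, high in y
    hl[[j]]  <- t(rL$D)
    hh[[j]]  <- t(rH$D)
  }
  structure(list(ll = x, lh = lh, hl = hl, hh = hh,
                 wavelet = wavelet, level = level, shapes = shapes),
            class = "subband_set")
}

#' @export
print.subband_set <- function(x, ...) {
  cat(sprintf("<subband_set %s, level %d, ll %dx%d>\n", x$wavelet, x$level,
              nrow(x$ll), ncol(x$ll)))
  invisible(x)
}

#' Inverse two-dimensional wavelet reconstruction
#'
#' Inverts [dwt2()] exactly (synthesis bank = transpose of the analysis
#' bank). The result is cropped — or edge-replicated — to `target_shape`
#' when one is given; otherwise the decomposition's recorded input shape
#' is restored.
#'
#' @param S A `subband_set`.
#' @param target_shape Optional `c(height, width)` for the output.
#' @return A numeric matrix.
#' @export
idwt_reconstruct <- function(S, target_shape = NULL) {
  stopifnot(inherits(S, "subband_set"))
  filt <- wavelet_filter(S$wavelet)
  x <- S$ll
  for (j in rev(seq_len(S$level))) {
    if (!identical(dim(S$lh[[j]]), dim(x)) ||
        !identical(dim(S$hl[[j]]), dim(x)) ||
        !identical(dim(S$hh[[j]]), dim(x))) {
      stop("inconsistent sub-band shapes", call. = FALSE)
    }
    rL <- t(idwt_step(t(x),        t(S$hl[[j]]) , filt))
    rH <- t(idwt_step(t(S$lh[[j]]), t(S$hh[[j]]), filt))
    x <- idwt_step(rL, rH, filt)
    sh <- S$shapes[[j]]
    x <- x[seq_len(min(nrow(x), sh[1])), seq_len(min(ncol(x), sh[2])),
           drop = FALSE]
  }
  if (!is.null(target_shape)) x <- fit_shape(x, target_shape)
  x
}

fit_shape <- function(x, shape) {
  h <- shape[1]; w <- shape[2]
  while (nrow(x) < h) x <- rbind(x, x[nrow(x), , drop = FALSE])
  while (ncol(x) < w) x <- cbind(x, x[, ncol(x), drop = FALSE])
  x[seq_len(h), seq_len(w), drop = FALSE]
}

#' Maximum-rule fusion of two wavelet decompositions
#'
#' Merges two same-shape decompositions coefficient by coefficient.
#' `"plain_max"` (default) takes the literal elementwise maximum on every
#' sub-band. `"abs_max"` keeps, on the detail bands only, whichever signed
#' coefficient has the larger magnitude (so strong negative edges survive),
#' with the plain maximum still used on the approximate band.
#'
#' @param A,B `subband_set`s with identical wavelet, level and shapes.
#' @param mode `"plain_max"` or `"abs_max"`.
#' @return A fused `subband_set`.
#' @export
fuse_max <- function(A, B, mode = c("plain_max", "abs_max")) {
  mode <- match.arg(mode)
  stopifnot(inherits(A, "subband_set"), inherits(B, "subband_set"))
  if (!identical(A$wavelet, B$wavelet) || !identical(A$level, B$level)) {
    stop("cannot fuse decompositions with different wavelets or levels",
         call. = FALSE)
  }
  if (!identical(dim(A$ll), dim(B$ll))) {
    stop("cannot fuse decompositions of different shapes", call. = FALSE)
  }
  pick <- function(a, b) {
    if (mode == "plain_max") pmax(a, b)
    else ifelse(abs(a) >= abs(b), a, b)
  }
  out <- A
  out$ll <- pmax(A$ll, B$ll)
  for (j in seq_len(A$level)) {
    out$lh[[j]] <- pick(A$lh[[j]], B$lh[[j]])
    out$hl[[j]] <- pick(A$hl[[j]], B$hl[[j]])
    out$hh[[j]] <- pick(A$hh[[j]], B$hh[[j]])
  }
  out
}

#' Wavelet-domain fusion of an original and an enhanced image
#'
#' Decomposes both raw images, merges the coefficients under the maximum
#' rule and reconstructs, clamping the result to the display range. Fusing
#' an image with itself returns the image (up to reconstruction
#' round-off), and the operation is symmetric in its two inputs.
#'
#' @param original,enhanced Raw-tagged [gray_image]s of identical shape
#'   and scale.
#' @inheritParams dwt2
#' @inheritParams fuse_max
#' @return A raw-tagged [gray_image] of the input shape.
#' @export
fuse_images <- function(original, enhanced, wavelet = "haar",
                        mode = c("plain_max", "abs_max"), level = 1L) {
  stopifnot(is_gray_image(original), is_gray_image(enhanced))
  if (original$range != "raw" || enhanced$range != "raw") {
    stop("fuse_images() expects raw-scale images", call. = FALSE)
  }
  if (!identical(dim(original$pixels), dim(enhanced$pixels))) {
    stop("original and enhanced images differ in shape", call. = FALSE)
  }
  A <- dwt2(original, wavelet, level)
  B <- dwt2(enhanced, wavelet, level)
  fused <- idwt_reconstruct(fuse_max(A, B, mode), dim(original$pixels))
  gray_image(clamp(fused, original$l_min, original$l_max), "raw",
             original$l_min, original$l_max)
}
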