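#' Grayscale image container
#'
#' A `gray_image` is a numeric matrix (rows = image height) carrying an
#' explicit value-range tag. Pipeline stages are strict about the tag: the
#' S-curve transform operates on `"normalized"` images (pixels in \[0, 1\]),
#' while the quality metrics operate on `"raw"` images (pixels in
#' \[`l_min`, `l_max`\], by default the 8-bit display range \[0, 255\]).
#' Pixels are stored as doubles throughout; quantization to 8-bit integers
#' happens only when an image is written to disk.
#'
#' @param pixels Numeric matrix of intensities, height x width.
#' @param range One of `"raw"` or `"normalized"`.
#' @param l_min,l_max Display range endpoints carried through normalization
#'   so the image can be de-normalized later. Defaults cover 8-bit sources;
#'   set `l_max = 65535` for 16-bit data.
#'
#' @return An object of class `gray_image`.
#' @examples
#' img <- gray_image(matrix(0:255, 16, 16), "raw")
#' range(pixels(img))
#' @export
gray_image <- function(pixels, range = c("raw", "normalized"),
                       l_min = 0, l_max = 255) {
  range <- match.arg(range)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("image dimensions must be at least 1x1", call. = FALSE)
  }
  if (anyNA(pixels)) stop("image contains missing values", call. = FALSE)
  if (!(l_min < l_max)) stop("`l_min` must be smaller than `l_max`", call. = FALSE)
  tol <- 1e-9
  if (range == "normalized") {
    if (min(pixels) < -tol || max(pixels) > 1 + tol) {
      stop("normalized image has pixels outside [0, 1]", call. = FALSE)
    }
  } else {
    if (min(pixels) < l_min - tol || max(pixels) > l_max + tol) {
      stop("raw image has pixels outside [l_min, l_max]", call. = FALSE)
    }
  }
  structure(
    list(pixels = unname(pixels), range = range,
         l_min = as.numeric(l_min), l_max = as.numeric(l_max)),
    class = "gray_image"
  )
}

#' @rdname gray_image
#' @param x A `gray_image`.
#' @export
is_gray_image <- function(x) inherits(x, "gray_image")

#' @rdname gray_image
#' @export
pixels <- function(x) {
  stopifnot(is_gray_image(x))
  x$pixels
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %dx%d, %s", nrow(x$pixels), ncol(x$pixels), x$range))
  if (x$range == "raw") cat(sprintf(" [%g, %g]", x$l_min, x$l_max))
  cat(sprintf(", pixel range %.4g..%.4g>\n", min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

#' Map a raw image onto the unit interval
#'
#' `normalize()` rescales a raw-tagged image linearly so that `l_min` maps to
#' 0 and `l_max` maps to 1; `denormalize()` inverts the map. The pair is an
#' exact round trip (no quantization is applied). Both functions refuse an
#' image already carrying the target tag, which catches double-normalization
#' bugs in pipelines.
#'
#' @param img A `gray_image` with range tag `"raw"` (`normalize`) or
#'   `"normalized"` (`denormalize`).
#' @return A `gray_image` with the opposite range tag; `l_min`/`l_max` are
#'   carried along unchanged.
#' @examples
#' img <- gray_image(matrix(c(0, 128, 255, 64), 2, 2), "raw")
#' normalize(img)
#' @export
normalize <- function(img) {
  stopifnot(is_gray_image(img))
  if (img$range == "normalized") {
    stop("image is already normalized", call. = FALSE)
  }
  px <- (img$pixels - img$l_min) / (img$l_max - img$l_min)
  gray_image(pmin(pmax(px, 0), 1), "normalized", img$l_min, img$l_max)
}

#' @rdname normalize
#' @export
denormalize <- function(img) {
  stopifnot(is_gray_image(img))
  if (img$range == "raw") {
    stop("image is already raw (de-normalized)", call. = FALSE)
  }
  px <- img$l_min + img$pixels * (img$l_max - img$l_min)
  gray_image(px, "raw", img$l_min, img$l_max)
}

# Clamp a numeric matrix into [lo, hi]; used after transforms whose range can
# slightly overshoot the nominal interval.
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
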