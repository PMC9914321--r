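#' Specification for a synthetic mammogram-like phantom
#'
#' The phantom emulates the acquisition conditions that motivate contrast
#' enhancement of breast images — a smooth tissue-like background, faint
#' low-contrast lesion blobs, bright microcalcification specks, and
#' additive Gaussian noise — so every pipeline stage can be exercised
#' reproducibly without any external mammography database. The
#' `"low_contrast"` preset squeezes the dynamic range into roughly
#' \[90, 140\], imitating the poor-contrast, low-entropy inputs the
#' enhancement is aimed at.
#'
#' @param height,width Image size in pixels.
#' @param background_level Mean background intensity on the 0-255 scale.
#' @param tissue_smoothness Correlation length (in pixels, the sigma of
#'   the Gaussian low-pass) of the random background field.
#' @param tissue_amplitude Peak-to-trough scale of the background field.
#' @param n_lesions Number of Gaussian-profile lesion blobs.
#' @param lesion_contrast Additive peak intensity of each lesion.
#' @param lesion_radius Mean lesion radius in pixels (the Gaussian sigma).
#' @param n_microcalcs Number of 1-3 pixel bright specks.
#' @param microcalc_contrast Additive intensity of the specks.
#' @param noise_sigma Standard deviation of the additive Gaussian noise.
#' @param seed Integer seed; identical specs yield identical phantoms.
#' @param preset `"default"`, or `"low_contrast"`, which rescales the
#'   finished scene into the narrow band \[90, 140\].
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 128L, width = 128L,
                         background_level = 100,
                         tissue_smoothness = 12,
                         tissue_amplitude = 25,
                         n_lesions = 3L, lesion_contrast = 20,
                         lesion_radius = 8,
                         n_microcalcs = 10L, microcalc_contrast = 80,
                         noise_sigma = 3,
                         seed = 1L,
                         preset = c("default", "low_contrast")) {
  preset <- match.arg(preset)
  if (preset == "low_contrast") {
    # narrow-band version of the same scene: dim tissue field, faint
    # lesions and specks, then squeezed into [90, 140] after assembly
    background_level <- 115
    tissue_amplitude <- 10
    lesion_contrast <- 8
    microcalc_contrast <- 20
    noise_sigma <- 2
  }
  height <- as.integer(height); width <- as.integer(width)
  stopifnot(height >= 1L, width >= 1L, tissue_smoothness > 0,
            n_lesions >= 0L, n_microcalcs >= 0L, noise_sigma >= 0,
            background_level >= 0, background_level <= 255)
  if (n_lesions > 0L && 2 * lesion_radius > min(height, width)) {
    stop("lesion radius exceeds the image", call. = FALSE)
  }
  structure(list(height = height, width = width,
                 background_level = background_level,
                 tissue_smoothness = tissue_smoothness,
                 tissue_amplitude = tissue_amplitude,
                 n_lesions = as.integer(n_lesions),
                 lesion_contrast = lesion_contrast,
                 lesion_radius = lesion_radius,
                 n_microcalcs = as.integer(n_microcalcs),
                 microcalc_contrast = microcalc_contrast,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 preset = preset),
            class = "phantom_spec")
}

#' Generate a reproducible mammogram-like phantom
#'
#' Builds the scene described by a [phantom_spec]: low-pass-filtered
#' Gaussian noise for the tissue background (filtered in the Fourier
#' domain with a Gaussian kernel of sigma `tissue_smoothness`), additive
#' Gaussian-profile lesions at random interior centers, bright
#' microcalcification specks of 1-3 pixels, then pixelwise Gaussian noise;
#' the result is clamped to \[0, 255\].
#'
#' @param spec A [phantom_spec].
#' @return A list of class `phantom`: `image` (raw [gray_image]),
#'   `lesions` (data.frame of centers, radii, contrasts) and `microcalcs`
#'   (data.frame of coordinates), the ground-truth annotation.
#' @examples
#' ph <- generate_phantom(phantom_spec(height = 64, width = 64, seed = 7))
#' ph$image
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height; w <- spec$width

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed)

  img <- matrix(spec$background_level, h, w)

  # smooth tissue field: white noise low-passed with a Gaussian transfer
  # function, rescaled to the requested amplitude
  if (spec$tissue_amplitude > 0 && h > 1L && w > 1L) {
    z <- matrix(stats::rnorm(h * w), h, w)
    fr <- seq_len(h) - 1L; fr[fr > h / 2] <- fr[fr > h / 2] - h; fr <- fr / h
    fc <- seq_len(w) - 1L; fc[fc > w / 2] <- fc[fc > w / 2] - w; fc <- fc / w
    att <- exp(-2 * (pi * spec$tissue_smoothness)^2 *
                 outer(fr^2, fc^2, `+`))
    field <- Re(stats::fft(stats::fft(z) * att, inverse = TRUE)) / (h * w)
    rng <- max(field) - min(field)
    if (rng > 0) {
      field <- (field - mean(field)) / rng * spec$tissue_amplitude
      img <- img + field
    }
  }

  lesions <- data.frame(row = numeric(0), col = numeric(0),
                        radius = numeric(0), contrast = numeric(0))
  if (spec$n_lesions > 0L) {
    margin <- spec$lesion_radius
    rows <- stats::runif(spec$n_lesions, 1 + margin, h - margin)
    cols <- stats::runif(spec$n_lesions, 1 + margin, w - margin)
    radii <- spec$lesion_radius * stats::runif(spec$n_lesions, 0.7, 1.3)
    ri <- matrix(seq_len(h), h, w)
    ci <- matrix(seq_len(w), h, w, byrow = TRUE)
    for (l in seq_len(spec$n_lesions)) {
      d2 <- (ri - rows[l])^2 + (ci - cols[l])^2
      img <- img + spec$lesion_contrast * exp(-d2 / (2 * radii[l]^2))
    }
    lesions <- data.frame(row = rows, col = cols, radius = radii,
                          contrast = spec$lesion_contrast)
  }

  microcalcs <- data.frame(row = integer(0), col = integer(0))
  if (spec$n_microcalcs > 0L) {
    mr <- sample.int(h, spec$n_microcalcs, replace = TRUE)
    mc <- sample.int(w, spec$n_microcalcs, replace = TRUE)
    for (m in seq_len(spec$n_microcalcs)) {
      sz <- sample.int(3L, 1L)          # speck of 1-3 pixels
      rr <- mr[m]:min(mr[m] + sz %/% 2L, h)
      cc <- mc[m]:min(mc[m] + (sz - 1L) %/% 2L, w)
      img[rr, cc] <- img[rr, cc] + spec$microcalc_contrast
    }
    microcalcs <- data.frame(row = mr, col = mc)
  }

  if (spec$noise_sigma > 0) {
    img <- img + matrix(stats::rnorm(h * w, sd = spec$noise_sigma), h, w)
  }

  if (spec$preset == "low_contrast") {
    rng <- max(img) - min(img)
    if (rng > 0) img <- 90 + (img - min(img)) / rng * 50
  }

  structure(list(image = gray_image(clamp(img, 0, 255), "raw", 0, 255),
                 lesions = lesions, microcalcs = microcalcs, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom %dx%d (%s), %d lesion(s), %d microcalc(s), seed=%d>\n",
              x$spec$height, x$spec$width, x$spec$preset,
              nrow(x$lesions), nrow(x$microcalcs), x$spec$seed))
  invisible(x)
}
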