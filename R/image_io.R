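#' Read a raster image as a raw grayscale image
#'
#' Supports PGM (both plain `P2` and binary `P5`, the native Mini-MIAS
#' format), PNG, TIFF and JPEG. Color inputs are reduced to luminance with
#' the ITU-R BT.601 weights (0.299, 0.587, 0.114); for 8-bit color sources
#' the luma is floored onto the integer grid, matching the usual `uint8`
#' conversion convention, while grayscale inputs are passed through
#' untouched. The result is tagged `"raw"` with `l_min = 0` and `l_max`
#' equal to the format's maximum value (255 for 8-bit, 65535 for 16-bit).
#'
#' @param path Path to a `.pgm`, `.png`, `.tif`/`.tiff`, `.jpg`/`.jpeg` file.
#' @return A raw-tagged [gray_image].
#' @seealso [save_image()]
#' @export
load_image <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read image '%s': file does not exist", path),
         call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    pgm  = read_pgm(path),
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    stop(sprintf("cannot read image '%s': unsupported format '.%s'", path, ext),
         call. = FALSE)
  )
  # png/tiff/jpeg readers return values scaled to [0,1]; PGM returns raw
  # integers plus a maxval attribute.
  if (ext == "pgm") {
    l_max <- attr(arr, "maxval")
    px <- unclass(arr)
    attr(px, "maxval") <- NULL
  } else {
    l_max <- 255
    if (length(dim(arr)) == 3L) {
      if (dim(arr)[3] >= 3L) {
        luma <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
        # floor with a guard against representation error on exact integers
        px <- floor(luma * l_max + 1e-9)
      } else {
        px <- arr[, , 1] * l_max  # gray (+ alpha): keep luminance plane as is
      }
    } else {
      px <- arr * l_max
    }
  }
  if (nrow(px) < 1L || ncol(px) < 1L) {
    stop(sprintf("image '%s' has zero size", path), call. = FALSE)
  }
  gray_image(px, "raw", 0, l_max)
}

#' Write a grayscale image to disk
#'
#' Normalized images are de-normalized first. Pixels are quantized to the
#' 8-bit grid with round-half-up (the only place in the pipeline where
#' quantization happens) and clamped to the display range.
#'
#' @param img A [gray_image].
#' @param path Output path; format chosen by extension (`.pgm`, `.png`,
#'   `.tif`/`.tiff`, `.jpg`/`.jpeg`).
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  stopifnot(is_gray_image(img))
  if (img$range == "normalized") img <- denormalize(img)
  span <- img$l_max - img$l_min
  u <- clamp((img$pixels - img$l_min) / span, 0, 1)
  q <- floor(u * 255 + 0.5)  # round half up onto the 8-bit grid
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    pgm  = write_pgm(q, path),
    png  = png::writePNG(q / 255, path),
    tif  = ,
    tiff = tiff::writeTIFF(q / 255, path, bits.per.sample = 8L),
    jpg  = ,
    jpeg = jpeg::writeJPEG(q / 255, path, quality = 0.95),
    stop(sprintf("cannot write image '%s': unsupported format '.%s'", path, ext),
         call. = FALSE)
  )
  invisible(path)
}

# -- PGM ------------------------------------------------------------------
# Netpbm grayscale maps: plain text "P2" and binary "P5". Header tokens
# (width, height, maxval) may be separated by arbitrary whitespace and
# '#' comments.

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  if (!magic %in% c("P2", "P5")) {
    stop(sprintf("cannot read image '%s': not a PGM (magic '%s')", path, magic),
         call. = FALSE)
  }
  next_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) break
      if (ch == "#") {                      # comment: skip to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) break else next
      }
      tok <- paste0(tok, ch)
    }
    as.integer(tok)
  }
  width <- next_token(); height <- next_token(); maxval <- next_token()
  if (anyNA(c(width, height, maxval)) || width < 1L || height < 1L) {
    stop(sprintf("image '%s' has an invalid PGM header", path), call. = FALSE)
  }
  n <- width * height
  if (magic == "P5") {
    if (maxval < 256L) {
      vals <- as.integer(readBin(con, "raw", n))
    } else {
      vals <- readBin(con, "integer", n, size = 2L, signed = FALSE,
                      endian = "big")
    }
  } else {
    vals <- integer(0)
    while (length(vals) < n) {
      tok <- next_token()
      if (is.na(tok)) break
      vals <- c(vals, tok)
    }
  }
  if (length(vals) < n) {
    stop(sprintf("image '%s' is truncated", path), call. = FALSE)
  }
  m <- matrix(as.numeric(vals[seq_len(n)]), nrow = height, ncol = width,
              byrow = TRUE)
  attr(m, "maxval") <- as.numeric(maxval)
  m
}

write_pgm <- function(q, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n255\n", ncol(q), nrow(q)), con, eos = NULL)
  writeBin(as.raw(as.integer(t(q))), con)
  invisible(path)
}
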