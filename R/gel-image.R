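# Gel image container and raster I/O.
#
# A gel image is a 2-D non-negative intensity matrix in canonical orientation:
# wells at the top, migration distance increasing with row index.  Supported
# raster formats are PNG, JPEG and plain (ASCII, P2) PGM; TIFF is not read
# because no TIFF decoder is available in the supported dependency set.

#' Construct a gel image
#'
#' @param pixels numeric matrix, rows = migration distance, columns = lateral
#'   position. Intensities must be finite and non-negative.
#' @param orientation `"wells_top"` (canonical) or `"wells_bottom"`; a
#'   `wells_bottom` matrix is flipped vertically on construction so stored
#'   pixels are always canonical.
#' @param bit_depth integer bit depth of the source raster (8 or 16); used to
#'   flag saturated pixels and to bound save/load round-trip error.
#' @param source_path provenance string.
#' @return object of class `gel_image` with elements `pixels` (canonical,
#'   scaled to `[0, 1]`), `bit_depth`, `source_path`, `n_saturated`.
#' @export
gel_image <- function(pixels, orientation = c("wells_top", "wells_bottom"),
                      bit_depth = 8L, source_path = NA_character_) {
  orientation <- match.arg(orientation)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    gq_validation_error("`pixels` must be a numeric matrix")
  if (nrow(pixels) < 50L || ncol(pixels) < 50L)
    gq_validation_error(sprintf(
      "gel image must be at least 50x50 pixels, got %dx%d",
      nrow(pixels), ncol(pixels)))
  if (any(!is.finite(pixels)) || any(pixels < 0))
    gq_validation_error("gel intensities must be finite and >= 0")
  if (orientation == "wells_bottom")
    pixels <- pixels[rev(seq_len(nrow(pixels))), , drop = FALSE]
  mx <- max(pixels)
  quantum <- 1 - 1 / (2^bit_depth)  # saturation level after [0,1] scaling
  if (mx > 1) pixels <- pixels / mx
  n_sat <- sum(pixels >= quantum)
  structure(
    list(pixels = pixels, orientation = "wells_top",
         bit_depth = as.integer(bit_depth),
         source_path = source_path, n_saturated = n_sat),
    class = "gel_image")
}

#' @export
print.gel_image <- function(x, ...) {
  cat(sprintf("<gel_image> %d rows x %d cols, %d-bit, %d saturated px\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$n_saturated))
  invisible(x)
}

#' @export
dim.gel_image <- function(x) dim(x$pixels)

read_pgm <- function(path) {
  txt <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (length(txt) < 4L || txt[1] != "P2")
    gq_io_error(sprintf("not a plain (P2) PGM file: %s", path))
  w <- as.integer(txt[2]); h <- as.integer(txt[3])
  maxval <- as.numeric(txt[4])
  vals <- as.numeric(txt[-(1:4)])
  if (length(vals) != w * h)
    gq_io_error(sprintf("PGM pixel count mismatch in %s", path))
  list(pixels = matrix(vals / maxval, nrow = h, ncol = w, byrow = TRUE),
       bit_depth = if (maxval > 255) 16L else 8L)
}

write_pgm <- function(pixels, path, bit_depth = 8L) {
  maxval <- 2^bit_depth - 1
  q <- round(pmin(pmax(pixels, 0), 1) * maxval)
  atomic_write(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con), add = TRUE)
    writeLines(c("P2", paste(ncol(pixels), nrow(pixels)),
                 format(maxval)), con)
    utils::write.table(q, con, row.names = FALSE, col.names = FALSE)
  })
}

rgb_to_luminance <- function(arr) {
  # Rec. 709 luminance; alpha channels (PNG) are ignored.
  if (length(dim(arr)) == 2L) return(arr)
  nc <- dim(arr)[3]
  if (nc == 1L) return(arr[, , 1])
  if (nc >= 3L)
    return(0.2126 * arr[, , 1] + 0.7152 * arr[, , 2] + 0.0722 * arr[, , 3])
  arr[, , 1]
}

#' Load a gel photograph
#'
#' Reads a PNG, JPEG or plain PGM raster, collapses RGB to Rec. 709 luminance
#' (`0.2126 R + 0.7152 G + 0.0722 B`), scales intensities to `[0, 1]` and
#' canonicalizes the orientation so wells sit at the top (migration distance
#' increases with row index).  The caller must declare the orientation; no
#' auto-flip is attempted because a smear gives no reliable cue.
#'
#' @param path raster file (`.png`, `.jpg`/`.jpeg`, `.pgm`).
#' @param orientation where the wells are in the file: `"wells_top"` or
#'   `"wells_bottom"`.
#' @return a [gel_image].
#' @export
load_gel_image <- function(path,
                           orientation = c("wells_top", "wells_bottom")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path))
    gq_io_error(sprintf("gel image file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  res <- switch(ext,
    png = {
      arr <- tryCatch(png::readPNG(path),
                      error = function(e) gq_io_error(sprintf(
                        "cannot decode PNG %s: %s", path, conditionMessage(e))))
      list(pixels = rgb_to_luminance(arr), bit_depth = 8L)
    },
    jpg = ,
    jpeg = {
      arr <- tryCatch(jpeg::readJPEG(path),
                      error = function(e) gq_io_error(sprintf(
                        "cannot decode JPEG %s: %s", path, conditionMessage(e))))
      list(pixels = rgb_to_luminance(arr), bit_depth = 8L)
    },
    pgm = read_pgm(path),
    gq_io_error(sprintf(
      "unsupported image format '.%s' (supported: png, jpg, jpeg, pgm)", ext))
  )
  gel_image(res$pixels, orientation = orientation, bit_depth = res$bit_depth,
            source_path = path)
}

#' Write a gel image to disk
#'
#' PNG (8-bit grayscale) or plain PGM (8- or 16-bit) depending on the file
#' extension.  Pixels are written in the image's canonical wells-top
#' orientation.
#'
#' @param img a [gel_image].
#' @param path output path (`.png` or `.pgm`).
#' @param bit_depth 8 or 16; PNG output is always quantized to 8 bits.
#' @export
write_gel_image <- function(img, path, bit_depth = img$bit_depth) {
  stopifnot(inherits(img, "gel_image"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    atomic_write(path, function(tmp) {
      px <- pmin(pmax(img$pixels, 0), 1)
      png::writePNG(px, tmp)
    })
  } else if (ext == "pgm") {
    write_pgm(img$pixels, path, bit_depth = bit_depth)
  } else {
    gq_io_error(sprintf("unsupported output format '.%s'", ext))
  }
  invisible(path)
}
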