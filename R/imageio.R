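# Image containers and file I/O. PNG via the png package; TIFF via a
# built-in reader/writer for uncompressed 8-bit baseline TIFF (the only
# flavour the pipeline emits; no TIFF package is available as a
# dependency, and pouch cameras produce plain uncompressed frames).

#' Pouch image container
#'
#' An 8-bit RGB image together with its physical scale. The scale is
#' established once per imaging session (e.g. from a ruler placed in the
#' first frame) and carried with every image.
#'
#' @param pixels H x W x 3 integer array with values in 0-255 (an H x W
#'   matrix is accepted and replicated to grey RGB).
#' @param pixels_per_cm Image scale (> 0).
#' @param id Identifier string.
#' @return An object of class `pouch_image`.
#' @export
pouch_image <- function(pixels, pixels_per_cm, id = "") {
  if (is.matrix(pixels)) {
    m <- pixels
    pixels <- array(0L, c(nrow(m), ncol(m), 3))
    pixels[, , 1] <- m; pixels[, , 2] <- m; pixels[, , 3] <- m
  }
  d <- dim(pixels)
  if (length(d) != 3 || d[3] != 3 || d[1] < 1 || d[2] < 1)
    stopf("pixels must be an H x W x 3 array")
  if (min(pixels) < 0 || max(pixels) > 255)
    stopf("pixel values must lie in 0-255")
  if (!is.integer(pixels)) pixels <- array(as.integer(round(pixels)), d)
  if (!is.numeric(pixels_per_cm) || pixels_per_cm <= 0)
    stopf("pixels_per_cm must be > 0")
  structure(list(pixels = pixels, pixels_per_cm = as.numeric(pixels_per_cm),
                 id = as.character(id)),
            class = "pouch_image")
}

#' @export
print.pouch_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<pouch_image> %d x %d px at %.1f px/cm  id='%s'\n",
              d[1], d[2], x$pixels_per_cm, x$id))
  invisible(x)
}

#' Read a pouch image from a PNG or uncompressed TIFF file
#'
#' @param path File path; format chosen by extension (.png, .tif/.tiff).
#' @param pixels_per_cm Image scale to attach (images do not carry it).
#' @return A [pouch_image].
#' @export
read_pouch_image <- function(path, pixels_per_cm) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = {
      a <- png::readPNG(path)
      round(a * 255)
    },
    tif = ,
    tiff = read_tiff8(path),
    stopf("unsupported image extension '%s'", ext)
  )
  if (length(dim(arr)) == 2) {
    m <- arr
  } else if (dim(arr)[3] >= 3) {
    arr <- arr[, , 1:3, drop = FALSE]
    m <- NULL
  } else {
    m <- arr[, , 1]
  }
  img <- if (is.null(m)) pouch_image(arr, pixels_per_cm) else
    pouch_image(m, pixels_per_cm)
  img$id <- basename(path)
  img
}

#' Write a pouch image (or plain array/mask) to PNG or TIFF
#'
#' Masks (logical matrices) are written as 8-bit 0/255 greyscale.
#'
#' @param x A [pouch_image], numeric array, or logical mask matrix.
#' @param path Output path (.png or .tif/.tiff).
#' @return `path`, invisibly.
#' @export
write_pouch_image <- function(x, path) {
  if (inherits(x, "pouch_image")) x <- x$pixels
  if (is.logical(x)) x <- matrix(as.integer(x) * 255L, nrow(x), ncol(x))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(x / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    write_tiff8(x, path)
  } else stopf("unsupported image extension '%s'", ext)
  invisible(path)
}

# --- minimal baseline TIFF (8-bit, uncompressed, single strip) ---------

write_tiff8 <- function(x, path) {
  if (length(dim(x)) == 2) x <- array(x, c(dim(x), 1))
  H <- dim(x)[1]; W <- dim(x)[2]; S <- dim(x)[3]
  if (!S %in% c(1, 3)) stopf("1 or 3 samples per pixel supported")
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w4 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  writeChar("II", con, eos = NULL)
  w2(42L); w4(8L)                       # IFD at byte 8
  ntags <- 9L
  data_off <- 8L + 2L + ntags * 12L + 4L
  extra_off <- data_off                  # BitsPerSample array for RGB
  pix_off <- data_off + if (S == 3) 6L else 0L
  w2(ntags)
  tag <- function(id, type, count, value) { w2(id); w2(type); w4(count); w4(value) }
  tag(256L, 4L, 1L, W)                   # ImageWidth
  tag(257L, 4L, 1L, H)                   # ImageLength
  if (S == 3) tag(258L, 3L, 3L, extra_off) else tag(258L, 3L, 1L, 8L)
  tag(259L, 3L, 1L, 1L)                  # no compression
  tag(262L, 3L, 1L, if (S == 3) 2L else 1L)  # photometric
  tag(273L, 4L, 1L, pix_off)             # StripOffsets
  tag(277L, 3L, 1L, S)                   # SamplesPerPixel
  tag(278L, 4L, 1L, H)                   # RowsPerStrip
  tag(279L, 4L, 1L, H * W * S)           # StripByteCounts
  w4(0L)                                 # next IFD
  if (S == 3) w2(c(8L, 8L, 8L))
  # interleave samples, row-major
  a <- aperm(x, c(3, 2, 1))              # sample, col, row
  writeBin(as.raw(as.integer(a)), con)
  invisible(path)
}

read_tiff8 <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  en <- if (rawToChar(raw[1:2]) == "II") "little" else "big"
  gi <- function(off, size)
    readBin(raw[(off + 1):(off + size)], "integer", size = size,
            endian = en, signed = size == 4)  # offsets stay below 2^31
  ifd <- readBin(raw[5:8], "integer", size = 4, endian = en)
  n <- gi(ifd, 2)
  tags <- list()
  for (k in seq_len(n)) {
    base <- ifd + 2 + (k - 1) * 12
    id <- gi(base, 2); type <- gi(base + 2, 2); count <- gi(base + 4, 4)
    val <- if (type == 3 && count == 1) gi(base + 8, 2) else gi(base + 8, 4)
    tags[[as.character(id)]] <- list(type = type, count = count, val = val)
  }
  need <- function(id) {
    t <- tags[[as.character(id)]]
    if (is.null(t)) stopf("TIFF tag %d missing", id)
    t
  }
  W <- need(256)$val; H <- need(257)$val
  if (need(259)$val != 1) stopf("only uncompressed TIFF supported")
  S <- if (is.null(tags[["277"]])) 1L else tags[["277"]]$val
  off <- need(273)$val
  cnt <- H * W * S
  vals <- as.integer(raw[(off + 1):(off + cnt)])
  a <- array(vals, c(S, W, H))
  aperm(a, c(3, 2, 1))[, , seq_len(S), drop = (S == 1)]
}

# --- trait record ------------------------------------------------------

trait_names <- c("TRL", "TSA", "DIM", "TRV", "TRT", "TSA1", "TSA3",
                 "TRW", "TCA", "RDI", "SOL", "COPM")

#' Root trait record
#'
#' The 12 traits of one plant/image: 7 morphological -- total root
#' length TRL (cm), total surface area TSA (cm^2), mean diameter DIM
#' (mm), total volume TRV (cm^3), tip count TRT, and surface areas of
#' the 0-0.5 mm (TSA1) and 1.0-1.5 mm (TSA3) diameter classes (cm^2) --
#' and 5 architectural: width TRW (cm), convex area TCA (cm^2), root
#' depth index RDI (fraction of surface area in the lower two-thirds of
#' the rooting depth), solidity SOL (root area / convex area), and
#' centre of projected mass COPM (cm below the root/shoot junction).
#'
#' @param ... The 12 named trait values.
#' @return A named numeric vector of class `trait_record`.
#' @export
trait_record <- function(...) {
  v <- c(...)
  miss <- setdiff(trait_names, names(v))
  if (length(miss)) stopf("missing traits: %s", paste(miss, collapse = ", "))
  v <- v[trait_names]
  if (any(!is.finite(v))) stopf("non-finite trait value")
  if (any(v < 0)) stopf("trait values must be non-negative")
  structure(v, class = "trait_record")
}

#' @export
print.trait_record <- function(x, ...) {
  cat(paste(sprintf("%s=%.3g", names(unclass(x)), unclass(x)),
            collapse = " "), "\n")
  invisible(x)
}

#' @export
as.data.frame.trait_record <- function(x, ...) {
  as.data.frame(as.list(unclass(x)))
}
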