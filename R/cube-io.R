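#' @include AllClasses.R AllGenerics.R utils.R
NULL

## ENVI data type codes <-> R read/write settings
.ENVI_DTYPES <- list(
  `1` = list(what = "integer", size = 1L, signed = FALSE),
  `2` = list(what = "integer", size = 2L, signed = TRUE),
  `4` = list(what = "double", size = 4L, signed = TRUE),
  `5` = list(what = "double", size = 8L, signed = TRUE),
  `12` = list(what = "integer", size = 2L, signed = FALSE)
)

.envi_paths <- function(path) {
  if (grepl("\\.hdr$", path, ignore.case = TRUE)) {
    hdr <- path
    dat <- sub("\\.hdr$", "", path, ignore.case = TRUE)
  } else {
    hdr <- paste0(path, ".hdr")
    dat <- path
  }
  list(hdr = hdr, dat = dat)
}

.parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  if (!length(lines) || !grepl("^\\s*ENVI\\s*$", lines[1]))
    .format_error("not an ENVI header (missing 'ENVI' magic line)")
  txt <- paste(lines[-1], collapse = "\n")
  ## keys start at line beginnings; { ... } values may span lines
  pat <- "(?m)^\\s*([a-zA-Z][a-zA-Z0-9 _]*?)\\s*=\\s*"
  m <- gregexpr(pat, txt, perl = TRUE)[[1]]
  if (m[1] == -1L) .format_error("ENVI header contains no fields")
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  keys <- character(length(starts))
  vals <- character(length(starts))
  for (i in seq_along(starts)) {
    key_raw <- substr(txt, starts[i], starts[i] + lens[i] - 1L)
    keys[i] <- tolower(trimws(sub("=\\s*$", "", key_raw)))
    vstart <- starts[i] + lens[i]
    vend <- if (i < length(starts)) starts[i + 1L] - 1L else nchar(txt)
    vals[i] <- trimws(substr(txt, vstart, vend))
  }
  names(vals) <- keys
  as.list(vals)
}

.envi_num <- function(fields, key) {
  v <- fields[[key]]
  if (is.null(v)) .format_error(sprintf("ENVI header missing '%s'", key))
  suppressWarnings(n <- as.numeric(v))
  if (is.na(n)) .format_error(sprintf("ENVI header field '%s' not numeric", key))
  n
}

#' Read a hyperspectral cube
#'
#' Reads an ENVI cube (text \code{.hdr} plus raw binary, BSQ or BIL
#' interleave) or a multi-page TIFF with a YAML wavelength sidecar into an
#' \linkS4class{HSCube}. The wavelength grid comes from the header (ENVI
#' \code{wavelength} block, in nm) or the sidecar; the scale tag is restored
#' from the header when present and defaults to \code{"raw_counts"}.
#'
#' @param path path to the ENVI data file (or its \code{.hdr}) or to the TIFF.
#' @param dialect one of \code{"envi_bsq"}, \code{"envi_bil"}, \code{"tiff"};
#'   for ENVI the interleave recorded in the header wins.
#' @return An \linkS4class{HSCube}.
#' @seealso \code{\link{writeCube}}
#' @export
readCube <- function(path, dialect = c("envi_bsq", "envi_bil", "tiff")) {
  dialect <- match.arg(dialect)
  if (dialect == "tiff") return(.read_cube_tiff(path))
  p <- .envi_paths(path)
  if (!file.exists(p$hdr)) .format_error(paste("header not found:", p$hdr))
  if (!file.exists(p$dat)) .format_error(paste("data file not found:", p$dat))
  f <- .parse_envi_header(p$hdr)
  samples <- as.integer(.envi_num(f, "samples"))
  lines_n <- as.integer(.envi_num(f, "lines"))
  bands <- as.integer(.envi_num(f, "bands"))
  dtype <- as.character(as.integer(.envi_num(f, "data type")))
  interleave <- tolower(if (is.null(f[["interleave"]])) sub("envi_", "", dialect)
                        else f[["interleave"]])
  if (!(interleave %in% c("bsq", "bil")))
    .format_error(paste("unsupported interleave:", interleave))
  byte_order <- if (is.null(f[["byte order"]])) 0L else as.integer(f[["byte order"]])
  endian <- if (byte_order == 0L) "little" else "big"
  spec <- .ENVI_DTYPES[[dtype]]
  if (is.null(spec)) .format_error(paste("unsupported ENVI data type:", dtype))
  wl_raw <- f[["wavelength"]]
  if (is.null(wl_raw))
    .format_error("ENVI header missing wavelength metadata")
  wl_raw <- gsub("[{}]", "", wl_raw)
  wl <- suppressWarnings(as.numeric(trimws(strsplit(wl_raw, ",")[[1]])))
  wl <- wl[!is.na(wl)]
  if (length(wl) != bands)
    .format_error(sprintf(
      "header declares %d bands but lists %d wavelengths", bands, length(wl)))
  n <- as.double(samples) * lines_n * bands
  expected_bytes <- n * spec$size
  actual <- file.info(p$dat)$size
  if (!isTRUE(actual == expected_bytes))
    .format_error(sprintf(
      "data file size %d does not match header dims (%d expected)",
      actual, expected_bytes))
  con <- file(p$dat, "rb")
  on.exit(close(con))
  raw_vec <- readBin(con, what = spec$what, n = n, size = spec$size,
                     signed = spec$signed, endian = endian)
  raw_vec <- as.double(raw_vec)
  if (interleave == "bsq") {
    ## file order: col fastest, then row, then band
    arr <- aperm(array(raw_vec, c(samples, lines_n, bands)), c(2, 1, 3))
  } else {
    ## bil: col fastest, then band, then row
    arr <- aperm(array(raw_vec, c(samples, bands, lines_n)), c(3, 1, 2))
  }
  tag <- f[["scale tag"]]
  if (is.null(tag) || !(tag %in% .SCALE_TAGS)) tag <- "raw_counts"
  HSCube(arr, wl, scaleTag = tag)
}

.read_cube_tiff <- function(path) {
  if (!file.exists(path)) .format_error(paste("file not found:", path))
  sidecar <- paste0(path, ".yml")
  if (!file.exists(sidecar))
    .format_error("TIFF cube requires a YAML sidecar with wavelengths")
  meta <- yaml::read_yaml(sidecar)
  if (is.null(meta$wavelength))
    .format_error("TIFF sidecar missing wavelength metadata")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(meta$wavelength))
    .format_error(sprintf("TIFF has %d pages but sidecar lists %d wavelengths",
                          length(pages), length(meta$wavelength)))
  lo <- as.numeric(meta$scale_min %||% 0)
  hi <- as.numeric(meta$scale_max %||% 1)
  arr <- array(NA_real_, c(dim(pages[[1]]), length(pages)))
  for (b in seq_along(pages)) arr[, , b] <- lo + pages[[b]] * (hi - lo)
  tag <- meta$scale_tag
  if (is.null(tag) || !(tag %in% .SCALE_TAGS)) tag <- "raw_counts"
  HSCube(arr, as.numeric(meta$wavelength), scaleTag = tag)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a hyperspectral cube
#'
#' Writes an \linkS4class{HSCube} as an ENVI header + raw binary pair (BSQ or
#' BIL interleave) or as a multi-page TIFF with a YAML sidecar. ENVI output
#' round-trips bit-exactly (doubles stored as 8-byte floats, integral payloads
#' as 16-bit integers); TIFF pages are min-max scaled into [0, 1] and stored
#' as 32-bit floats with the scale recorded in the sidecar, so the TIFF
#' dialect round-trips to single precision.
#'
#' @param cube an \linkS4class{HSCube}.
#' @param path output path (ENVI: data file; header written as
#'   \code{<path>.hdr}; TIFF: sidecar written as \code{<path>.yml}).
#' @param dialect \code{"envi_bsq"}, \code{"envi_bil"} or \code{"tiff"}.
#' @return \code{path}, invisibly.
#' @export
writeCube <- function(cube, path, dialect = c("envi_bsq", "envi_bil", "tiff")) {
  dialect <- match.arg(dialect)
  stopifnot(is(cube, "HSCube"))
  validObject(cube)
  d <- dim(cube@data)
  if (d[1] < 1L || d[2] < 1L || d[3] < 1L)
    .contract_error("cannot write an empty cube")
  if (dialect == "tiff") return(.write_cube_tiff(cube, path))
  interleave <- sub("envi_", "", dialect)
  vals <- cube@data
  integral <- !anyNA(vals) && all(vals == round(vals)) &&
    max(abs(vals)) <= 32767
  dtype <- if (integral) 2L else 5L
  spec <- .ENVI_DTYPES[[as.character(dtype)]]
  p <- .envi_paths(path)
  hdr <- c(
    "ENVI",
    "description = { hyperLIF cube }",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", dtype),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("scale tag = %s", cube@scaleTag),
    "wavelength units = Nanometers",
    paste0("wavelength = { ",
           paste(format(cube@wavelength, digits = 15, trim = TRUE),
                 collapse = ", "), " }")
  )
  ok <- tryCatch({
    writeLines(hdr, p$hdr)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write header to ", p$hdr)
  vec <- if (interleave == "bsq") as.vector(aperm(vals, c(2, 1, 3)))
         else as.vector(aperm(vals, c(2, 3, 1)))
  con <- file(p$dat, "wb")
  on.exit(close(con))
  if (spec$what == "integer") {
    writeBin(as.integer(vec), con, size = spec$size, endian = "little")
  } else {
    writeBin(as.double(vec), con, size = spec$size, endian = "little")
  }
  invisible(path)
}

.write_cube_tiff <- function(cube, path) {
  vals <- cube@data
  lo <- min(vals, na.rm = TRUE)
  hi <- max(vals, na.rm = TRUE)
  rng <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(vals)[3]), function(b) {
    m <- (vals[, , b] - lo) / rng
    m[is.na(m)] <- 0
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  yaml::write_yaml(list(
    wavelength = as.numeric(cube@wavelength),
    scale_tag = cube@scaleTag,
    scale_min = lo, scale_max = lo + rng
  ), paste0(path, ".yml"))
  invisible(path)
}

#' Calibrate raw counts to relative reflectance
#'
#' Flat-field calibration against white and dark reference frames:
#' \deqn{I_{fc} = (I_{oc} - I_{Dc}) / (I_{Bc} - I_{Dc})}
#' where \eqn{I_{oc}} is the raw cube, \eqn{I_{Dc}} the dark reference and
#' \eqn{I_{Bc}} the white reference. Pixels where the denominator is not
#' positive become the invalid sentinel (\code{NA}); specular glints with
#' reflectance above 1.05 are kept but flagged in
#' \code{metadata$glintMask}. The result is affine-invariant: scaling raw,
#' white and dark by one positive constant leaves the reflectance unchanged.
#'
#' @param raw an \linkS4class{HSCube} with \code{scaleTag "raw_counts"}.
#' @param refs a \linkS4class{ReferenceFrames}; 2-D references are shared
#'   across bands.
#' @return An \linkS4class{HSCube} with \code{scaleTag "reflectance"}.
#' @examples
#' raw <- HSCube(array(150, c(2, 2, 3)), c(450, 550, 650))
#' refs <- referenceFrames(dark = matrix(100, 2, 2), white = matrix(300, 2, 2))
#' range(cubeData(calibrateReflectance(raw, refs)))  # 0.25
#' @export
calibrateReflectance <- function(raw, refs) {
  stopifnot(is(raw, "HSCube"), is(refs, "ReferenceFrames"))
  if (raw@scaleTag != "raw_counts")
    .contract_error("calibrateReflectance expects a raw_counts cube")
  d <- dim(raw@data)
  rd <- dim(refs@dark)
  if (length(rd) == 2L) {
    if (!identical(rd, d[1:2]))
      .contract_error("2-D references must match the cube's spatial shape")
    dark <- array(refs@dark, d)
    white <- array(refs@white, d)
  } else {
    if (!identical(rd, d))
      .contract_error("3-D references must match the cube shape")
    dark <- refs@dark
    white <- refs@white
  }
  den <- white - dark
  out <- (raw@data - dark) / den
  bad <- !is.finite(out) | den <= 0
  out[bad] <- NA_real_
  glint <- apply(out > 1.05 & !is.na(out), c(1, 2), any)
  HSCube(out, raw@wavelength, scaleTag = "reflectance",
         metadata = c(raw@metadata,
                      list(glintMask = glint,
                           invalidCount = sum(bad))))
}

#' @rdname toDecibel
#' @export
setMethod("toDecibel", "numeric", function(x) {
  out <- ifelse(is.na(x) | x <= 0, NA_real_, 20 * log10(x))
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
})

#' @rdname toDecibel
#' @export
setMethod("toDecibel", "array", function(x) {
  out <- 20 * log10(x)
  out[is.na(x) | x <= 0] <- NA_real_
  out
})

#' @rdname toDecibel
#' @export
setMethod("toDecibel", "HSCube", function(x) {
  out <- 20 * log10(x@data)
  out[is.na(x@data) | x@data <= 0] <- NA_real_
  HSCube(out, x@wavelength, scaleTag = "dB", metadata = x@metadata)
})
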