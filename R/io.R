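# Image I/O: uncompressed baseline TIFF, NIfTI-1 (.nii / .nii.gz) and
# MetaImage (.mhd + .raw), all little-endian, with physical spacing metadata.
# The readers are deliberately minimal: single-sample grayscale rasters only,
# which is what micro-CT and MRI exports of single slices/stacks look like
# once converted out of vendor formats.

# ---- TIFF -----------------------------------------------------------------

tiff_type_size <- c(`1` = 1, `2` = 1, `3` = 2, `4` = 4, `5` = 8,
                    `6` = 1, `8` = 2, `9` = 4, `10` = 8, `11` = 4, `12` = 8)

read_tiff_value <- function(raw, offset, type, count, endian) {
  size <- tiff_type_size[[as.character(type)]] * count
  bytes <- if (size <= 4) raw[(offset + 9):(offset + 8 + size)] else {
    off <- readBin(raw[(offset + 9):(offset + 12)], "integer", 1, 4,
                   endian = endian)
    raw[(off + 1):(off + size)]
  }
  switch(as.character(type),
    `3` = readBin(bytes, "integer", count, 2, signed = FALSE, endian = endian),
    `4` = readBin(bytes, "integer", count, 4, endian = endian),
    `5` = { # RATIONAL: numerator/denominator pairs
      v <- readBin(bytes, "integer", 2 * count, 4, endian = endian)
      v[seq(1, 2 * count, 2)] / v[seq(2, 2 * count, 2)]
    },
    readBin(bytes, "integer", count, 1, signed = FALSE, endian = endian))
}

read_tiff <- function(path, slice = NULL) {
  raw <- readBin(path, "raw", file.info(path)$size)
  byte_order <- rawToChar(raw[1:2])
  endian <- if (byte_order == "II") "little" else if (byte_order == "MM")
    "big" else stop("not a TIFF file: ", path)
  ifd_off <- readBin(raw[5:8], "integer", 1, 4, endian = endian)
  pages <- list()
  while (ifd_off > 0) {
    n <- readBin(raw[(ifd_off + 1):(ifd_off + 2)], "integer", 1, 2,
                 signed = FALSE, endian = endian)
    tags <- list()
    for (k in seq_len(n)) {
      e <- ifd_off + 2 + (k - 1) * 12
      id <- readBin(raw[(e + 1):(e + 2)], "integer", 1, 2, signed = FALSE,
                    endian = endian)
      type <- readBin(raw[(e + 3):(e + 4)], "integer", 1, 2, signed = FALSE,
                      endian = endian)
      count <- readBin(raw[(e + 5):(e + 8)], "integer", 1, 4, endian = endian)
      tags[[as.character(id)]] <- read_tiff_value(raw, e, type, count, endian)
    }
    pages[[length(pages) + 1]] <- tags
    ifd_off <- readBin(raw[(ifd_off + 2 + n * 12 + 1):(ifd_off + 2 + n * 12 + 4)],
                       "integer", 1, 4, endian = endian)
  }
  if (length(pages) > 1 && is.null(slice))
    stop("multi-page TIFF: pass an explicit slice index")
  tags <- pages[[if (is.null(slice)) 1 else slice]]
  tag <- function(id, default = NULL) {
    v <- tags[[as.character(id)]]
    if (is.null(v)) default else v
  }
  if (tag(259, 1) != 1) stop("only uncompressed TIFF is supported")
  w <- tag(256); h <- tag(257)
  bits <- tag(258, 8); fmt <- tag(339, 1)
  offs <- tag(273); counts <- tag(279)
  if (is.null(w) || is.null(h) || is.null(offs))
    stop("malformed TIFF: missing required tags")
  buf <- raw(0)
  for (k in seq_along(offs))
    buf <- c(buf, raw[(offs[k] + 1):(offs[k] + counts[k])])
  vals <- if (fmt == 3) {
    readBin(buf, "double", w * h, bits / 8, endian = endian)
  } else if (bits == 8) {
    readBin(buf, "integer", w * h, 1, signed = FALSE, endian = endian)
  } else if (bits == 16) {
    readBin(buf, "integer", w * h, 2, signed = (fmt == 2), endian = endian)
  } else {
    readBin(buf, "integer", w * h, 4, endian = endian)
  }
  px <- matrix(vals, ncol = w, byrow = TRUE)
  res_unit <- tag(296, 2)
  xres <- tag(282); yres <- tag(283)
  spacing <- NULL
  if (!is.null(xres) && xres > 0) {
    per_mm <- switch(as.character(res_unit), `2` = xres / 25.4, `3` = xres / 10,
                     NULL)
    if (!is.null(per_mm))
      spacing <- c(1 / per_mm,
                   1 / (switch(as.character(res_unit), `2` = yres / 25.4,
                               `3` = yres / 10)))
  }
  list(pixels = px, spacing = spacing, n_pages = length(pages))
}

write_tiff <- function(pixels, path, spacing = NULL, type = "float") {
  h <- nrow(pixels); w <- ncol(pixels)
  con <- file(path, "wb")
  on.exit(close(con))
  wle <- function(x, size) writeBin(as.integer(x), con, size, endian = "little")
  bits <- switch(type, uint8 = 8L, uint16 = 16L, float = 32L)
  fmt <- if (type == "float") 3L else 1L
  nbytes <- h * w * bits / 8
  has_res <- !is.null(spacing)
  ntags <- 10L + if (has_res) 3L else 0L
  # layout: header(8) | pixel data | [rationals(16)] | IFD
  data_off <- 8L
  rat_off <- data_off + nbytes
  ifd_off <- rat_off + if (has_res) 16L else 0L
  writeBin(charToRaw("II"), con); wle(42, 2); wle(ifd_off, 4)
  if (type == "float") {
    writeBin(as.numeric(t(pixels)), con, 4, endian = "little")
  } else {
    v <- as.integer(round(t(pixels)))
    if (type == "uint8") writeBin(pmin(pmax(v, 0L), 255L), con, 1)
    else writeBin(pmin(pmax(v, 0L), 65535L), con, 2, endian = "little")
  }
  if (has_res) { # pixels per cm as RATIONALs at rat_off
    wle(round(1e6 * 10 / spacing[1]), 4); wle(1e6, 4)
    wle(round(1e6 * 10 / spacing[2]), 4); wle(1e6, 4)
  }
  entry <- function(id, typ, count, value, is_offset = FALSE) {
    wle(id, 2); wle(typ, 2); wle(count, 4)
    if (typ == 3 && !is_offset) { wle(value, 2); wle(0, 2) } else wle(value, 4)
  }
  wle(ntags, 2)
  entry(256, 4, 1, w); entry(257, 4, 1, h)
  entry(258, 3, 1, bits); entry(259, 3, 1, 1)
  entry(262, 3, 1, 1); entry(273, 4, 1, data_off)
  entry(277, 3, 1, 1); entry(278, 4, 1, h)
  entry(279, 4, 1, nbytes)
  if (has_res) {
    entry(282, 5, 1, rat_off, TRUE); entry(283, 5, 1, rat_off + 8, TRUE)
    entry(296, 3, 1, 3)
  }
  entry(339, 3, 1, fmt)
  wle(0, 4) # no next IFD
  invisible(path)
}

# ---- NIfTI-1 --------------------------------------------------------------

nifti_datatypes <- list(`2` = c("integer", 1), `4` = c("integer", 2),
                        `8` = c("integer", 4), `16` = c("double", 4),
                        `64` = c("double", 8), `512` = c("integer", 2))

read_nifti <- function(path, slice = NULL) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  endian <- "little"
  if (readBin(hdr[1:4], "integer", 1, 4, endian = endian) != 348) {
    endian <- "big"
    if (readBin(hdr[1:4], "integer", 1, 4, endian = endian) != 348)
      stop("not a NIfTI-1 file: ", path)
  }
  dim <- readBin(hdr[41:56], "integer", 8, 2, endian = endian)
  datatype <- readBin(hdr[71:72], "integer", 1, 2, endian = endian)
  pixdim <- readBin(hdr[77:108], "double", 8, 4, endian = endian)
  vox_offset <- readBin(hdr[109:112], "double", 1, 4, endian = endian)
  scl_slope <- readBin(hdr[113:116], "double", 1, 4, endian = endian)
  scl_inter <- readBin(hdr[117:120], "double", 1, 4, endian = endian)
  dt <- nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype: ", datatype)
  nx <- dim[2]; ny <- dim[3]; nz <- max(dim[4], 1L)
  readBin(con, "raw", round(vox_offset) - 348)
  vals <- readBin(con, dt[1], nx * ny * nz, as.integer(dt[2]),
                  signed = !(datatype == 2 || datatype == 512),
                  endian = endian)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  if (nz > 1 && is.null(slice)) stop("3D NIfTI: pass an explicit slice index")
  if (nz > 1) vals <- vals[((slice - 1) * nx * ny + 1):(slice * nx * ny)]
  px <- t(matrix(vals, nrow = nx, ncol = ny))
  sp <- pixdim[2:3]
  list(pixels = px, spacing = if (all(sp > 0)) sp else NULL,
       slice_thickness = if (dim[4] > 1) pixdim[4] else 0)
}

write_nifti <- function(pixels, path, spacing = NULL, slice_thickness = 0) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, 4, endian = "little")
  f32 <- function(x) writeBin(as.numeric(x), con, 4, endian = "little")
  chr <- function(n) writeBin(raw(n), con)
  sp <- if (is.null(spacing)) c(0, 0) else spacing
  w32(348); chr(10); chr(18); w32(0); w16(0); writeBin(charToRaw("r"), con)
  chr(1)
  w16(c(2, ncol(pixels), nrow(pixels), 1, 1, 1, 1, 1))      # dim
  f32(c(0, 0, 0)); w16(0)                                   # intent
  w16(16); w16(32); w16(0)                                  # float32
  f32(c(1, sp[1], sp[2], slice_thickness, 0, 0, 0, 0))      # pixdim
  f32(352); f32(1); f32(0)                                  # vox_offset, scl
  w16(0); chr(1); writeBin(as.raw(2L), con)                 # xyzt_units = mm
  f32(c(0, 0, 0, 0)); w32(0); w32(0)
  chr(80); chr(24)
  w16(0); w16(0)                                            # qform, sform
  f32(rep(0, 6)); f32(rep(0, 12))
  chr(16); writeBin(c(charToRaw("n+1"), raw(1)), con)
  w32(0)                                                    # extension flag
  f32(as.numeric(t(pixels)))
  invisible(path)
}

# ---- MetaImage ------------------------------------------------------------

read_mhd <- function(path, slice = NULL) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
  get <- function(k) if (k %in% keys) vals[match(k, keys)] else NULL
  dims <- as.integer(strsplit(trimws(get("DimSize")), "\\s+")[[1]])
  sp <- get("ElementSpacing")
  sp <- if (is.null(sp)) NULL else
    as.numeric(strsplit(trimws(sp), "\\s+")[[1]])
  etype <- trimws(get("ElementType"))
  dt <- switch(etype,
    MET_UCHAR = c("integer", 1, FALSE), MET_CHAR = c("integer", 1, TRUE),
    MET_SHORT = c("integer", 2, TRUE), MET_USHORT = c("integer", 2, FALSE),
    MET_INT = c("integer", 4, TRUE), MET_FLOAT = c("double", 4, TRUE),
    MET_DOUBLE = c("double", 8, TRUE),
    stop("unsupported MetaImage ElementType: ", etype))
  datafile <- trimws(get("ElementDataFile"))
  rawpath <- file.path(dirname(path), datafile)
  if (!file.exists(rawpath)) stop("raw data file not found: ", rawpath)
  nx <- dims[1]; ny <- dims[2]; nz <- if (length(dims) > 2) dims[3] else 1L
  vals <- readBin(rawpath, dt[1], nx * ny * nz, as.integer(dt[2]),
                  signed = as.logical(dt[3]), endian = "little")
  if (nz > 1 && is.null(slice)) stop("3D MetaImage: pass an explicit slice index")
  if (nz > 1) vals <- vals[((slice - 1) * nx * ny + 1):(slice * nx * ny)]
  px <- t(matrix(vals, nrow = nx, ncol = ny))
  list(pixels = px, spacing = if (!is.null(sp)) sp[1:2] else NULL,
       slice_thickness = if (length(dims) > 2 && length(sp) > 2) sp[3] else 0)
}

write_mhd <- function(pixels, path, spacing = NULL) {
  rawname <- sub("\\.mhd$", ".raw", basename(path))
  sp <- if (is.null(spacing)) c(1, 1) else spacing
  writeLines(c("ObjectType = Image", "NDims = 2", "BinaryData = True",
               "BinaryDataByteOrderMSB = False",
               sprintf("DimSize = %d %d", ncol(pixels), nrow(pixels)),
               sprintf("ElementSpacing = %g %g", sp[1], sp[2]),
               "ElementType = MET_FLOAT",
               sprintf("ElementDataFile = %s", rawname)), path)
  con <- file(file.path(dirname(path), rawname), "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(pixels)), con, 4, endian = "little")
  invisible(path)
}

# ---- public entry points --------------------------------------------------

#' Read a grayscale image with physical spacing
#'
#' Supports uncompressed baseline TIFF (single or multi-page), NIfTI-1
#' (`.nii`, `.nii.gz`) and MetaImage (`.mhd` + `.raw`). Spacing is taken from
#' file metadata; when the file carries none, `spacing_override` must be
#' given, otherwise an error is raised.
#'
#' @param path path to the image file.
#' @param spacing_override optional spacing in mm/pixel (length 1 or 2) used
#'   when the file has no spacing metadata.
#' @param slice 1-based page/slice index, required for multi-page or 3D
#'   content.
#' @param modality modality tag to attach (`"CT_LIKE"`, `"MR_LIKE"`,
#'   `"UNKNOWN"`).
#' @return A [gray_image()].
#' @export
read_image <- function(path, spacing_override = NULL, slice = NULL,
                       modality = "UNKNOWN") {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(sub("^.*?((\\.nii\\.gz)|(\\.[^.]+))$", "\\1", path))
  r <- switch(ext,
    ".tif" = , ".tiff" = read_tiff(path, slice),
    ".nii" = , ".nii.gz" = read_nifti(path, slice),
    ".mhd" = read_mhd(path, slice),
    stop("unsupported image format: ", ext))
  spacing <- r$spacing
  if (is.null(spacing)) {
    if (is.null(spacing_override))
      stop("spacing unknown: file has no spacing metadata and no override ",
           "was given")
    spacing <- spacing_override
  }
  gray_image(r$pixels, spacing,
             slice_thickness = if (is.null(r$slice_thickness)) 0 else
               r$slice_thickness,
             modality = modality)
}

#' Write a grayscale image
#'
#' Format chosen from the file extension (`.tif`/`.tiff`, `.nii`/`.nii.gz`,
#' `.mhd`). Pixel spacing is embedded in the file metadata. TIFF output is
#' 32-bit float by default; pass `type = "uint8"` or `"uint16"` for integer
#' rasters (written bit-exactly).
#'
#' @param image a [gray_image()].
#' @param path output path.
#' @param type TIFF sample type: `"float"`, `"uint8"` or `"uint16"`.
#' @export
write_image <- function(image, path, type = "float") {
  stopifnot(inherits(image, "gray_image"))
  ext <- tolower(sub("^.*?((\\.nii\\.gz)|(\\.[^.]+))$", "\\1", path))
  switch(ext,
    ".tif" = , ".tiff" = write_tiff(image$pixels, path, image$spacing, type),
    ".nii" = , ".nii.gz" = write_nifti(image$pixels, path, image$spacing,
                                       image$slice_thickness),
    ".mhd" = write_mhd(image$pixels, path, image$spacing),
    stop("unsupported image format: ", ext))
  invisible(path)
}
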