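#' @useDynLib trabkit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim lm coef median quantile sd pchisq rnorm runif
#' @importFrom utils write.csv read.csv modifyList
NULL

MODALITIES <- c("CT_LIKE", "MR_LIKE", "UNKNOWN")

#' Create a 2D grayscale image with physical spacing
#'
#' The unit of analysis for the whole toolkit: a 2D raster of finite
#' intensities (arbitrary units) with a physical pixel spacing in mm and a
#' modality tag controlling polarity conventions downstream (in computed
#' tomography bone is bright; in magnetic resonance imaging the bone signal
#' is a void against bright marrow).
#'
#' Coordinate convention: row-major matrix, origin top-left; x runs along
#' columns (rightward), y along rows (downward). Orientation angles are
#' measured counter-clockwise from the +x axis, in degrees modulo 180.
#'
#' @param pixels numeric matrix of intensities (all finite).
#' @param spacing pixel spacing in mm, length 1 (isotropic) or 2 `(x, y)`.
#' @param slice_thickness slice thickness in mm (metadata only; used to
#'   promote areas to volumes in bubble volumetry). Default 0.
#' @param modality one of `"CT_LIKE"`, `"MR_LIKE"`, `"UNKNOWN"`.
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(pixels, spacing, slice_thickness = 0,
                       modality = "UNKNOWN") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (!all(is.finite(pixels))) stop("all intensities must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1) spacing <- c(spacing, spacing)
  if (length(spacing) != 2 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be one or two strictly positive values (mm/pixel)")
  if (slice_thickness < 0) stop("slice_thickness must be >= 0")
  modality <- match.arg(modality, MODALITIES)
  structure(list(pixels = pixels, spacing = spacing,
                 slice_thickness = as.numeric(slice_thickness),
                 modality = modality),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, spacing %.4g x %.4g mm, %s\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing[1], x$spacing[2],
              x$modality))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

check_analysis_image <- function(image) {
  stopifnot(inherits(image, "gray_image"))
  if (any(dim(image$pixels) < 8))
    stop("analysis entry points require images of at least 8 x 8 pixels")
  invisible(image)
}

#' Create a region of interest
#'
#' @param mask logical matrix, same shape as the host image.
#' @param label short text label.
#' @return An object of class `roi`.
#' @export
roi <- function(mask, label = "roi") {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  structure(list(mask = mask, label = as.character(label)), class = "roi")
}

check_roi <- function(r, image = NULL, require_nonempty = TRUE) {
  stopifnot(inherits(r, "roi"))
  if (!is.null(image) && !identical(dim(r$mask), dim(image$pixels)))
    stop("ROI shape does not match image shape")
  if (require_nonempty && !any(r$mask)) stop("ROI is empty")
  invisible(r)
}

full_roi <- function(image) {
  px <- if (inherits(image, "gray_image")) image$pixels else image$labels
  roi(matrix(TRUE, nrow(px), ncol(px)), "full")
}
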