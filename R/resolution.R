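# Resolution degradation by integer block merging: emulates acquiring the
# same field of view at a coarser voxel size, the mechanism behind partial
# volume effects (thin struts mix with marrow inside one coarse voxel).

#' Degrade image resolution by block merging
#'
#' Merges `factor x factor` pixel blocks (the 2D analogue of merging voxels
#' in blocks of `factor^3`) into single pixels using the block mean, which
#' models partial-volume intensity averaging. The pixel spacing is
#' multiplied by `factor`; e.g. 0.051 mm at factor 2 becomes 0.102 mm and at
#' factor 3 becomes 0.153 mm. Trailing rows/columns that do not fill a
#' block are cropped with a warning.
#'
#' @param image a [gray_image()].
#' @param factor integer block size `>= 2` (2 and 3 mirror the usual
#'   degradation experiment).
#' @param aggregator `"mean"` (default) or `"median"`.
#' @return A degraded [gray_image()] with scaled spacing.
#' @export
degrade <- function(image, factor, aggregator = c("mean", "median")) {
  stopifnot(inherits(image, "gray_image"))
  aggregator <- match.arg(aggregator)
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 2) stop("factor must be an integer >= 2")
  px <- image$pixels
  H <- nrow(px); W <- ncol(px)
  Hc <- (H %/% factor) * factor; Wc <- (W %/% factor) * factor
  if (Hc < H || Wc < W) {
    warning(sprintf("cropping %d row(s) and %d column(s) not filling a block",
                    H - Hc, W - Wc))
    px <- px[seq_len(Hc), seq_len(Wc), drop = FALSE]
  }
  if (Hc == 0 || Wc == 0) stop("image smaller than one block")
  # fold rows then columns (mean of block-row means is the block mean)
  a <- array(px, dim = c(factor, Hc / factor, Wc))
  rowm <- apply(a, c(2, 3), if (aggregator == "mean") mean else median)
  b <- array(t(rowm), dim = c(factor, Wc / factor, Hc / factor))
  out <- t(apply(b, c(2, 3), if (aggregator == "mean") mean else median))
  gray_image(out, image$spacing * factor,
             slice_thickness = image$slice_thickness,
             modality = image$modality)
}
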