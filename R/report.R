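# MorphometryReport: one row of histomorphometric results for an image/ROI,
# with the standard column set (BVF dimensionless, lengths in mm, Tb.N in
# 1/mm, orientations in degrees). The secondary orientation may be "ND"
# (not detected).

#' Assemble a morphometry report
#'
#' @param bvf bone volume fraction, in `[0, 1]`.
#' @param tbth trabecular thickness, mm.
#' @param tbsp trabecular spacing, mm.
#' @param tbn trabecular number, 1/mm (defaults to `bvf / tbth`).
#' @param tborp_mean,tborp_sd principal trabecular orientation mean and SD,
#'   degrees.
#' @param tbors secondary trabecular orientation, degrees, or `NA` when not
#'   detected (rendered as `"ND"` on output).
#' @param tbint trabecular interconnectivity, degrees.
#' @param abv air bubble volume, mm^3 (or mm^2 for pure-2D inputs), optional.
#' @return An object of class `morphometry_report`.
#' @export
morphometry_report <- function(bvf, tbth, tbsp, tbn = bvf / tbth,
                               tborp_mean = NA_real_, tborp_sd = NA_real_,
                               tbors = NA_real_, tbint = NA_real_,
                               abv = NA_real_) {
  if (is.na(bvf) || bvf < 0 || bvf > 1) stop("bvf must be in [0, 1]")
  structure(list(bvf = bvf, tbth = tbth, tbsp = tbsp, tbn = tbn,
                 tborp_mean = tborp_mean, tborp_sd = tborp_sd,
                 tbors = tbors, tbint = tbint, abv = abv),
            class = "morphometry_report")
}

#' @export
print.morphometry_report <- function(x, ...) {
  nd <- function(v) if (is.na(v)) "ND" else sprintf("%.3g", v)
  cat(sprintf(
    "<morphometry_report> BVF %.3f  Tb.Th %.3f mm  Tb.Sp %.3f mm  Tb.N %.3f /mm\n",
    x$bvf, x$tbth, x$tbsp, x$tbn))
  cat(sprintf("  Tb.OrP %s +/- %s deg  Tb.OrS %s deg  Tb.Int %s deg\n",
              nd(x$tborp_mean), nd(x$tborp_sd), nd(x$tbors), nd(x$tbint)))
  invisible(x)
}

report_columns <- c("BVF(-)" = "bvf", "Tb.Th(mm)" = "tbth",
                    "Tb.Sp(mm)" = "tbsp", "Tb.N(1/mm)" = "tbn",
                    "Tb.OrP(deg)" = "tborp_mean", "Tb.OrP.SD(deg)" = "tborp_sd",
                    "Tb.OrS(deg)" = "tbors", "Tb.Int(deg)" = "tbint",
                    "Ab.V(mm3)" = "abv")

#' Write a morphometry report to CSV or JSON
#'
#' The CSV carries the standard column set with units in the header; a
#' missing secondary orientation is written as the cell `"ND"`. JSON output
#' (extension `.json`) mirrors the same fields.
#'
#' @param report a [morphometry_report()].
#' @param path output path ending in `.csv` or `.json`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "morphometry_report"))
  if (is.na(report$bvf)) stop("report is missing mandatory BVF")
  vals <- lapply(report_columns, function(f) report[[f]])
  if (grepl("\\.json$", path)) {
    out <- report[unname(report_columns)]
    out$tbors <- if (is.na(report$tbors)) "ND" else report$tbors
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    cells <- vapply(vals, function(v)
      if (is.na(v)) "ND" else format(v, digits = 15), "")
    df <- as.data.frame(as.list(cells), check.names = FALSE)
    names(df) <- names(report_columns)
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a morphometry report written by [write_report()]
#'
#' @param path path to a `.csv` or `.json` report.
#' @return A [morphometry_report()].
#' @export
read_report <- function(path) {
  num <- function(v) {
    if (is.null(v) || (is.character(v) && v == "ND") || is.na(v)) NA_real_
    else as.numeric(v)
  }
  if (grepl("\\.json$", path)) {
    x <- jsonlite::read_json(path)
    vals <- lapply(x[unname(report_columns)], num)
  } else {
    df <- read.csv(path, check.names = FALSE, colClasses = "character")
    vals <- lapply(df[1, names(report_columns)], num)
  }
  names(vals) <- unname(report_columns)
  do.call(morphometry_report, vals)
}
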