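# Segmentation: bone/marrow binarization with an automatic local threshold
# (sliding-window Otsu with bilinearly interpolated thresholds), three-phase
# bone/marrow/air labelling for CT-like images, and air-bubble volumetry.

#' Phase label codes
#'
#' Integer codes used in [phase_mask()] label matrices: `OUTSIDE = 0`,
#' `BONE = 1`, `MARROW = 2`, `AIR = 3`.
#' @export
PHASE <- c(OUTSIDE = 0L, BONE = 1L, MARROW = 2L, AIR = 3L)

#' Create a phase mask
#'
#' Per-pixel phase labels over \{bone, marrow, air, outside-ROI\}, congruent
#' with the source image and inheriting its spacing.
#'
#' @param labels integer matrix over the [PHASE] codes.
#' @param spacing mm/pixel, length 1 or 2.
#' @param slice_thickness slice thickness in mm (for volume promotion).
#' @return An object of class `phase_mask`.
#' @export
phase_mask <- function(labels, spacing, slice_thickness = 0) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (!all(labels %in% PHASE)) stop("labels must be in {0, 1, 2, 3}")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1) spacing <- c(spacing, spacing)
  structure(list(labels = labels, spacing = spacing,
                 slice_thickness = as.numeric(slice_thickness)),
            class = "phase_mask")
}

#' @export
print.phase_mask <- function(x, ...) {
  tab <- table(factor(x$labels, levels = PHASE, labels = names(PHASE)))
  cat(sprintf("<phase_mask> %d x %d px, spacing %.4g x %.4g mm\n",
              nrow(x$labels), ncol(x$labels), x$spacing[1], x$spacing[2]))
  print(tab)
  invisible(x)
}

#' @export
dim.phase_mask <- function(x) dim(x$labels)

phase_area_mm2 <- function(mask, phase) {
  sum(mask$labels == PHASE[[phase]]) * mask$spacing[1] * mask$spacing[2]
}

# Otsu threshold on a numeric vector (256-bin histogram); returns the
# midpoint of the optimal split, or NA for (near-)constant input.
otsu_threshold <- function(v, nbins = 256) {
  rng <- range(v)
  if (diff(rng) <= .Machine$double.eps * max(1, abs(rng[2]))) return(NA_real_)
  h <- as.numeric(tabulate(pmin(pmax(floor((v - rng[1]) / diff(rng) * nbins)
                                     + 1, 1), nbins), nbins))
  w <- cumsum(h)
  mu <- cumsum(h * seq_len(nbins))
  tot_w <- w[nbins]; tot_mu <- mu[nbins]
  # between-class variance for split after bin t
  t <- seq_len(nbins - 1)
  wb <- w[t]; wf <- tot_w - wb
  ok <- wb > 0 & wf > 0
  bcv <- rep(-Inf, nbins - 1)
  bcv[ok] <- (tot_mu * wb[ok] / tot_w - mu[t][ok])^2 /
    (wb[ok] * wf[ok] / tot_w)
  tb <- which.max(bcv)
  rng[1] + tb / nbins * diff(rng)
}

# 3-class Otsu: two thresholds maximizing between-class variance.
otsu_threshold3 <- function(v, nbins = 128) {
  rng <- range(v)
  if (diff(rng) <= .Machine$double.eps * max(1, abs(rng[2])))
    return(c(NA_real_, NA_real_))
  h <- as.numeric(tabulate(pmin(pmax(floor((v - rng[1]) / diff(rng) * nbins)
                                     + 1, 1), nbins), nbins))
  W <- cumsum(h); M <- cumsum(h * seq_len(nbins))
  cw <- function(a, b) if (b < a) 0 else W[b] - if (a > 1) W[a - 1] else 0
  cm <- function(a, b) if (b < a) 0 else M[b] - if (a > 1) M[a - 1] else 0
  best <- -Inf; bt <- c(NA, NA)
  for (t1 in 1:(nbins - 2)) {
    w1 <- cw(1, t1)
    if (w1 == 0) next
    m1 <- cm(1, t1) / w1
    for (t2 in (t1 + 1):(nbins - 1)) {
      w2 <- cw(t1 + 1, t2); w3 <- cw(t2 + 1, nbins)
      if (w2 == 0 || w3 == 0) next
      m2 <- cm(t1 + 1, t2) / w2; m3 <- cm(t2 + 1, nbins) / w3
      mt <- (M[nbins]) / W[nbins]
      v2 <- w1 * (m1 - mt)^2 + w2 * (m2 - mt)^2 + w3 * (m3 - mt)^2
      if (v2 > best) { best <- v2; bt <- c(t1, t2) }
    }
  }
  rng[1] + bt / nbins * diff(rng)
}

#' Binarize bone vs marrow with an automatic local threshold
#'
#' Sliding-window Otsu thresholding: the image is tiled with overlapping
#' windows, an Otsu threshold is computed per window, thresholds are
#' bilinearly interpolated between window centres, and a pixel is labelled
#' bone when its (polarity-adjusted) intensity exceeds the local threshold.
#' Windows whose content is (near-)constant fall back to the global Otsu
#' threshold. A fully constant image yields all-marrow with a warning.
#'
#' The local threshold makes the binarization invariant to smooth shading
#' and to global affine intensity rescaling, which is what makes MR images
#' with strong coil-profile contrast variations segmentable.
#'
#' @param image a [gray_image()].
#' @param window window side in pixels (`>= 8`, `<=` the smaller image
#'   dimension). Default: a quarter of the smaller image dimension.
#' @param polarity `"bone-bright"` or `"bone-dark"`; default inferred from
#'   the modality tag (`MR_LIKE` implies bone-dark).
#' @param roi optional [roi()]; pixels outside are labelled `OUTSIDE`.
#' @param min_component_px speckle cleanup: bone components and marrow holes
#'   smaller than this many pixels are absorbed into the surrounding phase
#'   (0 disables). Noise speckles otherwise contaminate the orientation
#'   distribution and the aperture statistics.
#' @return A [phase_mask()] with BONE/MARROW (and OUTSIDE) labels.
#' @export
binarize_local <- function(image, window = NULL, polarity = NULL, roi = NULL,
                           min_component_px = 4L) {
  check_analysis_image(image)
  px <- image$pixels
  if (is.null(polarity))
    polarity <- if (image$modality == "MR_LIKE") "bone-dark" else "bone-bright"
  polarity <- match.arg(polarity, c("bone-bright", "bone-dark"))
  if (polarity == "bone-dark") px <- -px
  H <- nrow(px); W <- ncol(px)
  if (is.null(window)) window <- max(8L, min(H, W) %/% 4L)
  if (window < 8 || window > min(H, W))
    stop("window must be >= 8 px and <= the smaller image dimension")
  inroi <- if (is.null(roi)) matrix(TRUE, H, W) else {
    check_roi(roi, image); roi$mask
  }
  global_thr <- otsu_threshold(px[inroi])
  if (is.na(global_thr)) {
    warning("constant image: threshold undefined, labelling all MARROW")
    lab <- matrix(PHASE[["MARROW"]], H, W)
    lab[!inroi] <- PHASE[["OUTSIDE"]]
    return(phase_mask(lab, image$spacing, image$slice_thickness))
  }
  # window centres on a half-window grid
  step <- max(window %/% 2L, 1L)
  ci <- unique(pmin(seq(1L + window %/% 2L, H, by = step), H))
  cj <- unique(pmin(seq(1L + window %/% 2L, W, by = step), W))
  thr <- matrix(global_thr, length(ci), length(cj))
  for (a in seq_along(ci)) for (b in seq_along(cj)) {
    i0 <- max(1L, ci[a] - window %/% 2L); i1 <- min(H, ci[a] + window %/% 2L)
    j0 <- max(1L, cj[b] - window %/% 2L); j1 <- min(W, cj[b] + window %/% 2L)
    t <- otsu_threshold(px[i0:i1, j0:j1])
    if (!is.na(t)) thr[a, b] <- t
  }
  tfull <- bilinear_grid(thr, ci, cj, H, W)
  bone <- px > tfull
  if (min_component_px > 0) {
    bone <- drop_small_components(bone, min_component_px)   # speckles
    bone <- !drop_small_components(!bone, min_component_px) # pinholes
  }
  lab <- matrix(PHASE[["MARROW"]], H, W)
  lab[bone] <- PHASE[["BONE"]]
  lab[!inroi] <- PHASE[["OUTSIDE"]]
  phase_mask(lab, image$spacing, image$slice_thickness)
}

drop_small_components <- function(m, min_px) {
  cc <- cpp_label4(m)
  if (max(cc) == 0) return(m)
  sizes <- tabulate(cc[cc > 0])
  m[cc %in% which(sizes < min_px)] <- FALSE
  m
}

# interpolate values known at grid nodes (ci x cj) to the full raster,
# clamped extrapolation at the borders
bilinear_grid <- function(vals, ci, cj, H, W) {
  interp1 <- function(centers, n) {
    # for each 1..n: lower node index and fractional weight
    idx <- findInterval(seq_len(n), centers)
    idx <- pmin(pmax(idx, 1L), length(centers) - 1L)
    if (length(centers) == 1L) return(list(lo = rep(1L, n), w = rep(0, n)))
    lo <- centers[idx]; hi <- centers[idx + 1L]
    w <- (seq_len(n) - lo) / (hi - lo)
    list(lo = idx, w = pmin(pmax(w, 0), 1))
  }
  ri <- interp1(ci, H); rj <- interp1(cj, W)
  if (length(ci) == 1L && length(cj) == 1L)
    return(matrix(vals[1, 1], H, W))
  lo_i <- ri$lo; wi <- ri$w
  lo_j <- rj$lo; wj <- rj$w
  hi_i <- pmin(lo_i + 1L, length(ci)); hi_j <- pmin(lo_j + 1L, length(cj))
  v00 <- vals[cbind(rep(lo_i, W), rep(lo_j, each = H))]
  v10 <- vals[cbind(rep(hi_i, W), rep(lo_j, each = H))]
  v01 <- vals[cbind(rep(lo_i, W), rep(hi_j, each = H))]
  v11 <- vals[cbind(rep(hi_i, W), rep(hi_j, each = H))]
  wi_f <- rep(wi, W); wj_f <- rep(wj, each = H)
  matrix((1 - wi_f) * (1 - wj_f) * v00 + wi_f * (1 - wj_f) * v10 +
           (1 - wi_f) * wj_f * v01 + wi_f * wj_f * v11, H, W)
}

#' Three-phase bone/marrow/air segmentation for CT-like images
#'
#' Two thresholds from a 3-class Otsu split label the darkest mode as AIR,
#' the middle as MARROW and the brightest as BONE (X-ray absorption orders
#' the phases this way). AIR components smaller than `min_air_px` pixels are
#' merged into MARROW. When the image does not carry three distinguishable
#' modes (3-class split degenerate), the function falls back to
#' [binarize_local()] with an empty AIR phase and warns.
#'
#' @param image a CT-like [gray_image()].
#' @param min_air_px minimum AIR connected-component size in pixels.
#' @param roi optional [roi()].
#' @return A [phase_mask()].
#' @export
segment_three_phase <- function(image, min_air_px = 4L, roi = NULL) {
  check_analysis_image(image)
  if (image$modality == "MR_LIKE")
    stop("three-phase segmentation expects a CT-like image")
  px <- image$pixels
  inroi <- if (is.null(roi)) matrix(TRUE, nrow(px), ncol(px)) else {
    check_roi(roi, image); roi$mask
  }
  thr <- otsu_threshold3(px[inroi])
  degenerate <- any(is.na(thr))
  if (!degenerate) {
    # require each class to hold a non-trivial share of ROI pixels,
    # otherwise the "three modes" premise does not hold
    v <- px[inroi]
    shares <- c(mean(v <= thr[1]), mean(v > thr[1] & v <= thr[2]),
                mean(v > thr[2]))
    if (min(shares) < 1e-4) degenerate <- TRUE
  }
  if (degenerate) {
    warning("fewer than three distinguishable intensity modes; falling ",
            "back to two-phase binarization with empty AIR phase")
    return(binarize_local(image, polarity = "bone-bright", roi = roi))
  }
  lab <- matrix(PHASE[["MARROW"]], nrow(px), ncol(px))
  lab[px <= thr[1]] <- PHASE[["AIR"]]
  lab[px > thr[2]] <- PHASE[["BONE"]]
  lab[!inroi] <- PHASE[["OUTSIDE"]]
  # absorb tiny AIR specks into marrow
  if (min_air_px > 1) {
    cc <- cpp_label4(lab == PHASE[["AIR"]])
    if (max(cc) > 0) {
      sizes <- tabulate(cc[cc > 0])
      small <- which(sizes < min_air_px)
      lab[cc %in% small] <- PHASE[["MARROW"]]
    }
  }
  phase_mask(lab, image$spacing, image$slice_thickness)
}

#' Quantify air-bubble volume from a phase mask
#'
#' Absolute air volume is the AIR pixel area times the slice thickness
#' (falling back to area in mm^2, flagged by `unit`, when the thickness is
#' zero/absent). Relative volumes are expressed against a reference initial
#' air volume and against the total marrow volume (defaulting to the
#' AIR+MARROW volume of the same mask).
#'
#' @param mask a [phase_mask()].
#' @param slice_thickness slice thickness in mm; defaults to the mask's.
#' @param reference_initial optional reference initial air volume, mm^3.
#' @param marrow_total optional total marrow volume, mm^3.
#' @return A list of class `bubble_report` with `abv_abs`,
#'   `abv_rel_initial` (%), `abv_rel_marrow` (%) and `unit`.
#' @export
quantify_bubbles <- function(mask, slice_thickness = NULL,
                             reference_initial = NULL, marrow_total = NULL) {
  stopifnot(inherits(mask, "phase_mask"))
  if (is.null(slice_thickness)) slice_thickness <- mask$slice_thickness
  if (!is.null(reference_initial) && reference_initial <= 0)
    stop("reference_initial must be positive")
  if (!is.null(marrow_total) && marrow_total <= 0)
    stop("marrow_total must be positive")
  area <- phase_area_mm2(mask, "AIR")
  thick <- if (slice_thickness > 0) slice_thickness else 1
  unit <- if (slice_thickness > 0) "mm3" else "mm2"
  abv <- area * thick
  marrow <- if (!is.null(marrow_total)) marrow_total else
    (phase_area_mm2(mask, "MARROW") + area) * thick
  rel_init <- if (!is.null(reference_initial)) 100 * abv / reference_initial
  else NA_real_
  rel_marrow <- if (marrow > 0) 100 * abv / marrow else 0
  if (abv == 0) { rel_init <- if (!is.null(reference_initial)) 0 else NA_real_
                  rel_marrow <- 0 }
  structure(list(abv_abs = abv, abv_rel_initial = rel_init,
                 abv_rel_marrow = rel_marrow, unit = unit),
            class = "bubble_report")
}
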