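# Independent brute-force oracles and small fixture builders. The aperture
# oracle deliberately shares no code with the package implementation: the
# radius at each candidate centre is the minimum point-to-square distance
# over all background squares (computed directly from the clamped per-axis
# formula), and diameters are propagated by an explicit scan.

# fg: logical matrix (TRUE = target phase). Background = in-image !fg
# squares; the image border does not limit disks (capped at the diagonal).
oracle_aperture <- function(fg) {
  H <- nrow(fg); W <- ncol(fg)
  bg <- which(!fg, arr.ind = TRUE)
  out <- matrix(0, H, W)
  px <- which(fg, arr.ind = TRUE)
  rcap <- sqrt(H^2 + W^2) / 2
  for (fy in seq(1, H, by = 0.5)) for (fx in seq(1, W, by = 0.5)) {
    r <- if (nrow(bg) == 0) rcap else {
      dy <- pmax(abs(fy - bg[, 1]) - 0.5, 0)
      dx <- pmax(abs(fx - bg[, 2]) - 0.5, 0)
      min(sqrt(min(dy * dy + dx * dx)), rcap)
    }
    if (r <= 0) next
    cov <- (px[, 1] - fy)^2 + (px[, 2] - fx)^2 <= r^2 + 1e-9
    if (!any(cov)) next
    idx <- px[cov, 1] + (px[cov, 2] - 1) * H
    out[idx] <- pmax(out[idx], 2 * r)
  }
  out
}

# random blob mask: block-upsampled uniform noise thresholded at a fill
# fraction, with a sprinkle of single-pixel flips for ragged edges
random_blob_mask <- function(n, seed, fill = 0.4) {
  set.seed(seed)
  nc <- ceiling(n / 4)
  z <- kronecker(matrix(runif(nc * nc), nc, nc), matrix(1, 4, 4))[1:n, 1:n]
  m <- z >= quantile(z, 1 - fill)
  flips <- sample(n * n, max(1, round(0.02 * n * n)))
  m[flips] <- !m[flips]
  m
}

# bar phantom mask: horizontal bars of width w px separated by gap px,
# wrapped in OUTSIDE margins so no band touches the image border
bar_mask <- function(w, gap, n_bars = 4, width = 64, spacing = 1) {
  period <- w + gap
  height <- n_bars * period + 2 * gap
  lab <- matrix(trabkit::PHASE[["OUTSIDE"]], height, width)
  for (k in seq_len(n_bars)) {
    r0 <- gap + (k - 1) * period + 1
    lab[r0:(r0 + w - 1), ] <- trabkit::PHASE[["BONE"]]
    if (k < n_bars)
      lab[(r0 + w):(r0 + period - 1), ] <- trabkit::PHASE[["MARROW"]]
  }
  phase_mask(lab, spacing)
}

expect_matrix_equal <- function(a, b, tol = 1e-8) {
  expect_lt(max(abs(a - b)), tol)
}
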