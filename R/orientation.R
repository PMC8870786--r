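# Orientation analysis. Per-pixel trabecular orientation comes from the
# eigen-decomposition of the multi-scale Hessian of the gray levels; the
# distribution of orientations over bone pixels is fitted with a
# linear-baseline + two-Gaussian model, yielding the principal and secondary
# trabecular orientations and the interconnectivity metric (the angular
# spread of the whole distribution about the principal orientation).
#
# Angles are strut-axis orientations in degrees on [0, 180), measured
# counter-clockwise from the +x (column) axis; all angular arithmetic is
# modulo 180 with minimal-difference wrapping.

wrap180 <- function(a) ((a %% 180) + 180) %% 180

# minimal wrapped difference between axial angles, in [0, 90]
angdiff180 <- function(a, b) {
  d <- abs(wrap180(a) - wrap180(b))
  pmin(d, 180 - d)
}

gauss_kernel <- function(sigma, order = 0) {
  r <- max(1L, ceiling(4 * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  switch(as.character(order),
    `0` = g,
    `1` = -x / sigma^2 * g,
    `2` = (x^2 - sigma^2) / sigma^4 * g)
}

gaussian_blur <- function(px, sigma) {
  if (sigma <= 0) return(px)
  k <- gauss_kernel(sigma)
  cpp_conv1(cpp_conv1(px, k, 1L), k, 2L)
}

#' Per-pixel trabecular orientation from the multi-scale Hessian
#'
#' For each scale `sigma`, the image is convolved with Gaussian-derivative
#' kernels to obtain the Hessian components Ixx, Ixy, Iyy; eigenvalues are
#' gamma-normalized (multiplied by `sigma^2`) and, per pixel, the scale with
#' the largest response magnitude is selected. For a ridge the eigenvector
#' of the dominant eigenvalue is transverse to the strut, so the reported
#' strut-axis angle is that eigenvector's angle plus 90 degrees (mod 180).
#' The dominant eigenvalue is the most negative one for bright struts
#' (CT-like), the most positive one for dark struts (MR-like), and the one
#' of largest magnitude when the modality is unknown.
#'
#' @param image a [gray_image()].
#' @param scales Gaussian scales in pixels (each `>= 0.5`); default `1:5`.
#' @return An object of class `orientation_field`: `theta` (degrees in
#'   `[0, 180)`), `response` (scale-normalized dominant-eigenvalue
#'   magnitude), `scales_used`.
#' @export
hessian_orientation <- function(image, scales = 1:5) {
  check_analysis_image(image)
  if (length(scales) == 0 || any(scales < 0.5))
    stop("scales must be non-empty, each >= 0.5 px")
  px <- image$pixels
  if (min(dim(px)) < 6 * max(scales))
    stop("image smaller than 6 * max(scale)")
  polarity <- switch(image$modality, CT_LIKE = "bright", MR_LIKE = "dark",
                     "either")
  H <- nrow(px); W <- ncol(px)
  best_resp <- matrix(-Inf, H, W)
  best_theta <- matrix(0, H, W)
  for (s in scales) {
    g0 <- gauss_kernel(s, 0); g1 <- gauss_kernel(s, 1); g2 <- gauss_kernel(s, 2)
    # dim 1 = rows (y), dim 2 = cols (x)
    ixx <- cpp_conv1(cpp_conv1(px, g2, 2L), g0, 1L)
    iyy <- cpp_conv1(cpp_conv1(px, g2, 1L), g0, 2L)
    ixy <- cpp_conv1(cpp_conv1(px, g1, 1L), g1, 2L)
    tr2 <- (ixx + iyy) / 2
    disc <- sqrt(((ixx - iyy) / 2)^2 + ixy^2)
    l_hi <- tr2 + disc; l_lo <- tr2 - disc          # algebraic order
    lam <- switch(polarity,
      bright = l_lo,                                # most negative
      dark = l_hi,                                  # most positive
      ifelse(abs(l_hi) >= abs(l_lo), l_hi, l_lo))
    resp <- s^2 * abs(lam)                          # gamma-normalized
    sel <- resp > best_resp
    if (any(sel)) {
      # eigenvector of lam: (ixy, lam - ixx) in (x, y-down) coordinates;
      # fall back to the axis choice when ixy ~ 0
      vx <- ixy[sel]; vy <- (lam - ixx)[sel]
      # when ixy ~ 0 and lam ~ ixx the eigenvector is the x axis (angle 0),
      # which atan2(0, 0) would not give reliably
      deg <- ifelse(abs(vx) + abs(vy) < 1e-12, 0,
                    atan2(-vy, vx) * 180 / pi)      # y-down -> math angle
      best_theta[sel] <- wrap180(deg + 90)          # transverse -> axis
      best_resp[sel] <- resp[sel]
    }
  }
  structure(list(theta = best_theta, response = best_resp,
                 scales_used = scales),
            class = "orientation_field")
}

#' @export
print.orientation_field <- function(x, ...) {
  cat(sprintf("<orientation_field> %d x %d px, scales {%s}\n",
              nrow(x$theta), ncol(x$theta),
              paste(x$scales_used, collapse = ", ")))
  invisible(x)
}

#' Orientation distribution over bone pixels
#'
#' Histogram of per-pixel strut-axis orientations restricted to the BONE
#' phase, normalized to unit mass.
#'
#' @param field an [hessian_orientation()] result.
#' @param mask a [phase_mask()]; only BONE pixels contribute.
#' @param bin_width bin width in degrees (default 1; must divide 180).
#' @param border pixels to exclude along each image edge, where the
#'   convolution's mirror padding corrupts orientations; default twice the
#'   largest Hessian scale.
#' @return An object of class `orientation_distribution`: `bin_centers`,
#'   `density` (weights summing to 1), `n_pixels`, `bin_width`.
#' @export
orientation_distribution <- function(field, mask, bin_width = 1,
                                     border = NULL) {
  stopifnot(inherits(field, "orientation_field"),
            inherits(mask, "phase_mask"))
  if (!identical(dim(field$theta), dim(mask$labels)))
    stop("orientation field and mask shapes differ")
  nb <- round(180 / bin_width)
  if (abs(nb * bin_width - 180) > 1e-9) stop("bin_width must divide 180")
  if (is.null(border)) border <- ceiling(2 * max(field$scales_used))
  keep <- mask$labels == PHASE[["BONE"]]
  H <- nrow(keep); W <- ncol(keep)
  if (border > 0 && H > 4 * border && W > 4 * border) {
    keep[c(seq_len(border), H - seq_len(border) + 1), ] <- FALSE
    keep[, c(seq_len(border), W - seq_len(border) + 1)] <- FALSE
  }
  th <- field$theta[keep]
  if (length(th) == 0) stop("empty bone phase")
  idx <- pmin(floor(wrap180(th) / bin_width), nb - 1) + 1
  counts <- tabulate(idx, nb)
  structure(list(bin_centers = (seq_len(nb) - 0.5) * bin_width,
                 density = counts / sum(counts),
                 n_pixels = length(th), bin_width = bin_width),
            class = "orientation_distribution")
}

#' Build an orientation distribution from raw angles
#'
#' Convenience constructor used for simulation studies and ground-truth
#' bookkeeping: histograms a vector of angles (degrees, wrapped to
#' `[0, 180)`) with optional weights.
#'
#' @param angles numeric vector of angles in degrees.
#' @param bin_width bin width in degrees (must divide 180).
#' @param weights optional non-negative per-angle weights.
#' @return An `orientation_distribution`.
#' @export
orientation_distribution_from_angles <- function(angles, bin_width = 1,
                                                 weights = NULL) {
  nb <- round(180 / bin_width)
  if (abs(nb * bin_width - 180) > 1e-9) stop("bin_width must divide 180")
  idx <- pmin(floor(wrap180(angles) / bin_width), nb - 1) + 1
  w <- if (is.null(weights)) rep(1, length(angles)) else weights
  counts <- vapply(seq_len(nb), function(b) sum(w[idx == b]), 0)
  structure(list(bin_centers = (seq_len(nb) - 0.5) * bin_width,
                 density = counts / sum(counts),
                 n_pixels = length(angles), bin_width = bin_width),
            class = "orientation_distribution")
}

# model: baseline a + m*x plus two Gaussians with free amplitudes,
# evaluated with wrapped angular residuals
dual_gauss_model <- function(x, p) {
  g <- function(mu, sg) exp(-0.5 * (angdiff180(x, mu) / sg)^2) /
    (sg * sqrt(2 * pi))
  p[["a"]] + p[["m"]] * x + p[["A1"]] * g(p[["mu1"]], p[["s1"]]) +
    p[["A2"]] * g(p[["mu2"]], p[["s2"]])
}

#' Fit the dual-Gaussian orientation-mixture model
#'
#' Nonlinear least squares of the model
#' `Y = a + m*x + A1*N(x; mu1, sigma1) + A2*N(x; mu2, sigma2)`
#' to an orientation distribution, where `N` is a unit-area Gaussian
#' evaluated on wrapped angular residuals. Amplitudes are free by default
#' (`strict_printed = TRUE` pins both to 1, the literal printed form, which
#' cannot adapt to a unit-mass histogram and is provided for comparison
#' only). Components are relabelled so that component 1 carries the larger
#' amplitude. The fit restarts from jittered initializations; the secondary
#' component is flagged undetected (the "ND" case) when its amplitude is
#' below 5% of the principal's, when the two means are closer than
#' `2 * max(sigma1, bin width)`, or when the fit fails to converge.
#'
#' @param dist an `orientation_distribution`.
#' @param n_restarts number of jittered restarts after the deterministic
#'   initialization.
#' @param strict_printed logical; pin both amplitudes to 1.
#' @param min_bins minimum number of non-empty bins required (default 20
#'   for real data; ground-truth bookkeeping on discrete per-strut angle
#'   histograms relaxes this).
#' @return An object of class `gaussian_mixture_fit` with fields `a`, `m`,
#'   `mu1`, `sigma1`, `mu2`, `sigma2`, `amp1`, `amp2`, `converged`,
#'   `secondary_detected`, `sse`.
#' @export
fit_dual_gaussian <- function(dist, n_restarts = 5, strict_printed = FALSE,
                              min_bins = 20) {
  stopifnot(inherits(dist, "orientation_distribution"))
  x <- dist$bin_centers; y <- dist$density
  if (sum(y > 0) < min_bins)
    stop("need at least ", min_bins, " non-empty bins to fit the mixture ",
         "model")
  bw <- dist$bin_width
  s_min <- bw
  # robust baseline from the lowest-density quartile
  low <- y <= quantile(y, 0.25)
  base <- tryCatch(coef(lm(y[low] ~ x[low])), error = function(e) c(0, 0))
  a0 <- unname(base[1]); m0 <- unname(base[2])
  if (!is.finite(a0)) a0 <- min(y)
  if (!is.finite(m0)) m0 <- 0
  mode1 <- x[which.max(y)]
  peak <- max(y) - (a0 + m0 * mode1)
  amp0 <- max(peak, 1e-4) * 10 * sqrt(2 * pi)
  # second initialization peak: maximum of the residual after removing the
  # primary component, restricted away from the primary mode
  g1 <- exp(-0.5 * (angdiff180(x, mode1) / 10)^2) / (10 * sqrt(2 * pi))
  resid <- y - (a0 + m0 * x + amp0 * g1)
  far <- angdiff180(x, mode1) > 25
  mode2 <- if (any(far)) x[far][which.max(resid[far])] else
    wrap180(mode1 + 90)
  peak2 <- max(max(resid[far], 0), 1e-4)
  amp2_0 <- peak2 * 10 * sqrt(2 * pi)
  # bounded parameterization: sigmas in (s_min, 90] via logistic (an
  # unbounded sigma degenerates into a second baseline), amplitudes in
  # (0, 2] (the histogram holds unit mass in total)
  s_max <- 90; a_max <- 2
  qlg <- function(v, hi) stats::qlogis(pmin(pmax(v / hi, 1e-6), 1 - 1e-6))
  pack <- function(a, m, mu1, s1, mu2, s2, A1, A2)
    c(a, m, mu1, qlg(s1 - s_min, s_max - s_min), mu2,
      qlg(s2 - s_min, s_max - s_min), qlg(A1, a_max), qlg(A2, a_max))
  unpack <- function(p) list(a = p[1], m = p[2], mu1 = wrap180(p[3]),
                             s1 = s_min + (s_max - s_min) * stats::plogis(p[4]),
                             mu2 = wrap180(p[5]),
                             s2 = s_min + (s_max - s_min) * stats::plogis(p[6]),
                             A1 = a_max * stats::plogis(p[7]),
                             A2 = a_max * stats::plogis(p[8]))
  sse <- function(p) {
    pr <- unpack(p)
    if (strict_printed) { pr$A1 <- 1; pr$A2 <- 1 }
    m <- dual_gauss_model(x, pr)
    # densities are nonnegative: forbid fits that dip below zero (a flat
    # Gaussian offset by a negative baseline would otherwise be feasible)
    sum((y - m)^2) + 1e3 * sum(pmin(m, 0)^2)
  }
  starts <- list(pack(a0, m0, mode1, 10, mode2, 10, amp0, amp2_0),
                 pack(a0, m0, mode1, 10, mode2, 5, amp0, amp2_0),
                 pack(a0, m0, mode1, 15, wrap180(mode1 + 90), 10,
                      amp0, amp0 / 3))
  # jittered restarts use a data-derived seed; global RNG state is restored
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  set.seed(sum(round(1e6 * y[y > 0])) %% .Machine$integer.max)
  for (k in seq_len(n_restarts))
    starts[[k + 3]] <- starts[[1]] +
      c(0, 0, rnorm(1, 0, 10), rnorm(1, 0, 0.3), rnorm(1, 0, 25),
        rnorm(1, 0, 0.3), rnorm(1, 0, 0.5), rnorm(1, 0, 0.5))
  best <- NULL
  for (st in starts) {
    o <- tryCatch({
      o1 <- optim(st, sse, method = "Nelder-Mead",
                  control = list(maxit = 4000, reltol = 1e-12))
      optim(o1$par, sse, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-12))
    }, error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best))
    return(structure(list(a = NA, m = NA, mu1 = NA, sigma1 = NA, mu2 = NA,
                          sigma2 = NA, amp1 = NA, amp2 = NA,
                          converged = FALSE, secondary_detected = FALSE,
                          sse = NA),
                     class = "gaussian_mixture_fit"))
  p <- unpack(best$par)
  if (strict_printed) { p$A1 <- 1; p$A2 <- 1 }
  converged <- is.finite(best$value) && best$convergence %in% c(0, 1)
  # a very broad wrapped Gaussian (SD beyond 60 degrees on a 180-degree
  # domain) is a disguised baseline, not a trabecular orientation band;
  # genuine principal bands fit below ~50 even for highly disordered bone,
  # while baseline surrogates run into the 90-degree bound
  s_real <- 60
  real1 <- p$s1 < s_real && p$A1 > 1e-6
  real2 <- p$s2 < s_real && p$A2 > 1e-6
  if (real2 && !real1) {
    p <- list(a = p$a, m = p$m, mu1 = p$mu2, s1 = p$s2,
              mu2 = p$mu1, s2 = p$s1, A1 = p$A2, A2 = p$A1)
    real1 <- TRUE; real2 <- FALSE
  } else if (real1 && real2) {
    # component 1 = dominant mass; when the two masses are within 20% of
    # each other the broader component is taken as principal (the principal
    # trabecular band is the more dispersed one, and published fits of this
    # model consistently carry the larger SD on the principal component)
    swap <- if (min(p$A1, p$A2) > 0.8 * max(p$A1, p$A2))
      p$s2 > p$s1 else p$A2 > p$A1
    if (swap) p <- list(a = p$a, m = p$m, mu1 = p$mu2, s1 = p$s2,
                        mu2 = p$mu1, s2 = p$s1, A1 = p$A2, A2 = p$A1)
  }
  sep <- angdiff180(p$mu1, p$mu2)
  secondary <- converged && real1 && real2 && p$A2 >= 0.05 * p$A1 &&
    sep >= 2 * max(p$s1, bw) && p$s2 > 0
  structure(list(a = p$a, m = p$m, mu1 = p$mu1, sigma1 = p$s1, mu2 = p$mu2,
                 sigma2 = p$s2, amp1 = p$A1, amp2 = p$A2,
                 converged = converged, secondary_detected = secondary,
                 sse = best$value),
            class = "gaussian_mixture_fit")
}

#' @export
print.gaussian_mixture_fit <- function(x, ...) {
  cat(sprintf("<gaussian_mixture_fit> mu1 %.2f +/- %.2f deg (amp %.3g)\n",
              x$mu1, x$sigma1, x$amp1))
  if (x$secondary_detected)
    cat(sprintf("  mu2 %.2f +/- %.2f deg (amp %.3g)\n", x$mu2, x$sigma2,
                x$amp2))
  else cat("  secondary: ND\n")
  invisible(x)
}

#' Orientation metrics: Tb.OrP, Tb.OrS, Tb.Int
#'
#' The principal orientation Tb.OrP is the mean and SD of the principal
#' fitted Gaussian. The secondary orientation Tb.OrS is reported both as
#' the raw secondary mean (`tbors_mu2`) and as the difference between the
#' absolute secondary mean and the principal mean (`tbors`); it is `NA`
#' ("ND") when no secondary component was detected. The interconnectivity
#' Tb.Int is the angular standard deviation of the whole (bin-level)
#' orientation distribution about the principal mean, with wrapped angular
#' differences capped at 90 degrees.
#'
#' @param dist an `orientation_distribution`.
#' @param fit a `gaussian_mixture_fit` for the same distribution.
#' @return A list with `tborp` (`c(mean, sd)`), `tbors`, `tbors_mu2`,
#'   `tbint` (degrees).
#' @export
compute_orientation_metrics <- function(dist, fit) {
  stopifnot(inherits(dist, "orientation_distribution"),
            inherits(fit, "gaussian_mixture_fit"))
  if (!isTRUE(fit$converged)) stop("mixture fit did not converge")
  tbint <- sqrt(sum(dist$density * angdiff180(dist$bin_centers, fit$mu1)^2))
  if (fit$secondary_detected) {
    tbors <- abs(fit$mu2) - fit$mu1
    tbors_mu2 <- fit$mu2
  } else {
    tbors <- NA_real_
    tbors_mu2 <- NA_real_
  }
  list(tborp = c(mean = fit$mu1, sd = fit$sigma1), tbors = tbors,
       tbors_mu2 = tbors_mu2, tbint = tbint)
}
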