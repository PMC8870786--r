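# Slice-to-stack registration: find the stack slice best matching a moving
# slice and co-register the pair with a 2D affine transform. The similarity
# driving the optimization is mutual information (robust across modalities
# with inverted contrast); the reported score is the Pearson correlation of
# the registered pair after z-normalization.

#' Pearson correlation between two images
#'
#' @param a,b [gray_image()] objects of identical shape.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
correlation_score <- function(a, b) {
  stopifnot(inherits(a, "gray_image"), inherits(b, "gray_image"))
  if (!identical(dim(a$pixels), dim(b$pixels)))
    stop("images must have identical shapes")
  va <- as.vector(a$pixels); vb <- as.vector(b$pixels)
  if (sd(va) == 0 || sd(vb) == 0)
    stop("zero variance: correlation undefined for a constant image")
  stats::cor(va, vb)
}

# bilinear sampling of matrix px at (row, col) positions; outside -> fill
bilinear_sample <- function(px, r, c, fill) {
  H <- nrow(px); W <- ncol(px)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  get <- function(ri, ci) {
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    v <- rep(fill, length(ri))
    v[ok] <- px[cbind(ri[ok], ci[ok])]
    v
  }
  (1 - fr) * (1 - fc) * get(r0, c0) + (1 - fr) * fc * get(r0, c0 + 1) +
    fr * (1 - fc) * get(r0 + 1, c0) + fr * fc * get(r0 + 1, c0 + 1)
}

# affine parameters (tx, ty, rot deg, log-scale, shear) -> 2x3 matrix
# mapping moving pixel coords (x, y) to fixed coords, about the centre
affine_matrix <- function(par, center) {
  th <- par[3] * pi / 180
  sc <- exp(par[4]); sh <- par[5]
  A <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2) %*%
    matrix(c(sc, 0, sh, sc), 2)
  t0 <- center + par[1:2] - A %*% center
  cbind(A, t0)
}

# warp moving image onto the fixed grid under M (moving -> fixed)
warp_affine <- function(moving, M, H, W, fill = NA) {
  A <- M[, 1:2]; t0 <- M[, 3]
  Ai <- solve(A)
  # fixed grid coords (x = col, y = row)
  gx <- rep(seq_len(W), each = H); gy <- rep(seq_len(H), W)
  q <- Ai %*% rbind(gx - t0[1], gy - t0[2])
  v <- bilinear_sample(moving, q[2, ], q[1, ],
                       fill = if (is.na(fill)) mean(moving) else fill)
  matrix(v, H, W)
}

mutual_information <- function(a, b, bins = 32) {
  cut1 <- function(v) {
    r <- range(v)
    if (diff(r) == 0) return(rep(1L, length(v)))
    pmin(pmax(floor((v - r[1]) / diff(r) * bins) + 1L, 1L), bins)
  }
  ia <- cut1(as.vector(a)); ib <- cut1(as.vector(b))
  j <- tabulate(ia + bins * (ib - 1L), bins * bins) / length(ia)
  pa <- tabulate(ia, bins) / length(ia)
  pb <- tabulate(ib, bins) / length(ib)
  pj <- j[j > 0]
  idx <- which(j > 0) - 1L
  sum(pj * log(pj / (pa[idx %% bins + 1L] * pb[idx %/% bins + 1L])))
}

register_affine_pair <- function(fixed_px, moving_px, bins = 32) {
  H <- nrow(fixed_px); W <- ncol(fixed_px)
  center <- c((W + 1) / 2, (H + 1) / 2)
  neg_mi <- function(par) {
    wm <- warp_affine(moving_px, affine_matrix(par, center), H, W)
    -mutual_information(fixed_px, wm, bins)
  }
  # translation-only warm start: integer grid, then a translation polish,
  # then the full 5-parameter affine search
  span <- max(2, round(min(H, W) / 8))
  grid <- expand.grid(tx = seq(-span, span, by = 1),
                      ty = seq(-span, span, by = 1))
  sc <- apply(grid, 1, function(g) neg_mi(c(g[1], g[2], 0, 0, 0)))
  t0 <- as.numeric(grid[which.min(sc), ])
  ot <- optim(t0, function(t) neg_mi(c(t, 0, 0, 0)),
              method = "Nelder-Mead",
              control = list(maxit = 200, reltol = 1e-10))
  p0 <- c(ot$par, 0, 0, 0)
  o <- optim(p0, neg_mi, method = "Nelder-Mead",
             control = list(maxit = 1000, reltol = 1e-12,
                            parscale = c(1, 1, 2, 0.05, 0.05)))
  o <- optim(o$par, neg_mi, method = "Nelder-Mead",
             control = list(maxit = 500, reltol = 1e-12,
                            parscale = c(0.5, 0.5, 1, 0.02, 0.02)))
  if (o$value > ot$value) { # affine stage must not undo a good warm start
    o <- ot
    o$par <- c(ot$par, 0, 0, 0)
  }
  list(par = o$par, mi = -o$value,
       transform = affine_matrix(o$par, center))
}

#' Register a moving slice against a stack of candidate slices
#'
#' For every slice in the stack the moving image is affinely registered
#' (translation, rotation, isotropic scale, shear) by maximizing mutual
#' information, then scored with the Pearson correlation of the registered
#' pair on z-normalized intensities. The stack slice with the highest score
#' is returned together with the affine transform. If the moving image is
#' on a coarser pixel grid than the stack, it is first upscaled to the
#' stack grid (bilinear).
#'
#' @param moving a [gray_image()].
#' @param stack list of [gray_image()] slices sharing one grid.
#' @param bins joint-histogram bins for mutual information.
#' @return An object of class `registration_result`: `best_slice_index`,
#'   `transform` (2x3, pixel coordinates, maps moving to fixed),
#'   `score`, `score_profile`.
#' @export
register_slice <- function(moving, stack, bins = 32) {
  stopifnot(inherits(moving, "gray_image"), length(stack) >= 1)
  fixed_dim <- dim(stack[[1]]$pixels)
  mv <- moving$pixels
  if (!identical(dim(mv), fixed_dim)) {
    # upscale/resize the moving image onto the stack grid
    sr <- (nrow(mv) - 1) / (fixed_dim[1] - 1)
    sc <- (ncol(mv) - 1) / (fixed_dim[2] - 1)
    gx <- rep(seq_len(fixed_dim[2]), each = fixed_dim[1])
    gy <- rep(seq_len(fixed_dim[1]), fixed_dim[2])
    mv <- matrix(bilinear_sample(mv, 1 + (gy - 1) * sr, 1 + (gx - 1) * sc,
                                 fill = mean(mv)),
                 fixed_dim[1], fixed_dim[2])
  }
  zn <- function(m) (m - mean(m)) / max(sd(m), .Machine$double.eps)
  scores <- numeric(length(stack))
  fits <- vector("list", length(stack))
  for (k in seq_along(stack)) {
    fx <- stack[[k]]$pixels
    fit <- register_affine_pair(fx, mv, bins)
    wm <- warp_affine(mv, fit$transform, fixed_dim[1], fixed_dim[2])
    scores[k] <- stats::cor(as.vector(zn(fx)), as.vector(zn(wm)))
    fits[[k]] <- fit
  }
  best <- which.max(abs(scores))
  structure(list(best_slice_index = best,
                 transform = fits[[best]]$transform,
                 score = scores[best], score_profile = scores),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> best slice %d, score %.4f\n",
              x$best_slice_index, x$score))
  invisible(x)
}
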