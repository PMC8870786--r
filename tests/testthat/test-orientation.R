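# Hessian orientation, orientation distribution, dual-Gaussian fit and the
# derived metrics.

fake_fit <- function(mu1, sigma1 = 10, mu2 = NA, sigma2 = NA,
                     secondary = FALSE) {
  structure(list(a = 0, m = 0, mu1 = mu1, sigma1 = sigma1, mu2 = mu2,
                 sigma2 = sigma2, amp1 = 1, amp2 = 0.5, converged = TRUE,
                 secondary_detected = secondary, sse = 0),
            class = "gaussian_mixture_fit")
}

test_that("axis-aligned and rotated bright bars give the nominal angle", {
  img <- matrix(50, 64, 64); img[, 30:34] <- 200       # vertical bar
  fld <- hessian_orientation(gray_image(img, 1, modality = "CT_LIKE"))
  modal <- median(fld$theta[20:44, 31:33])
  expect_lt(abs(modal - 90), 1)
  # bar at 30 degrees via a jitter-free phantom
  ph <- generate_phantom(phantom_spec(width = 96, height = 96, theta_p = 30,
                                      sigma_p = 0, noise_sd = 0, seed = 1))
  fld2 <- hessian_orientation(ph$image)
  d <- orientation_distribution(fld2, ph$truth$mask)
  expect_lt(min(abs(d$bin_centers[which.max(d$density)] - 30),
                180 - abs(d$bin_centers[which.max(d$density)] - 30)), 2)
})

test_that("orientation histogram is equivariant to 90-degree rotation and
           invariant to intensity negation", {
  ph <- generate_phantom(phantom_spec(width = 96, height = 96, theta_p = 40,
                                      sigma_p = 8, seed = 21))
  img <- ph$image; mask <- ph$truth$mask
  d0 <- orientation_distribution(hessian_orientation(img), mask)
  # counter-clockwise quarter turn
  rotpx <- t(img$pixels)[ncol(img$pixels):1, ]
  rotlab <- t(mask$labels)[ncol(mask$labels):1, ]
  d90 <- orientation_distribution(
    hessian_orientation(gray_image(rotpx, 1, modality = "CT_LIKE")),
    phase_mask(rotlab, 1))
  shifted <- c(d90$density[91:180], d90$density[1:90])
  expect_lt(sum(abs(shifted - d0$density)) / 2, 0.02)
  # negated intensities with the polarity convention flipped
  neg <- gray_image(-img$pixels, 1, modality = "MR_LIKE")
  dneg <- orientation_distribution(hessian_orientation(neg), mask)
  expect_equal(dneg$density, d0$density)
})

test_that("orientation distribution normalizes and handles the delta case", {
  d <- orientation_distribution_from_angles(rep(45, 1000))
  expect_equal(sum(d$density), 1)
  expect_equal(d$density[d$bin_centers == 45.5], 1)
  expect_equal(length(d$bin_centers), 180)
  # two equal-count bar families -> two equal modes
  ph1 <- generate_phantom(phantom_spec(width = 128, height = 128,
                                       theta_p = 30, sigma_p = 0,
                                       noise_sd = 0, seed = 3))
  ph2 <- generate_phantom(phantom_spec(width = 128, height = 128,
                                       theta_p = 120, sigma_p = 0,
                                       noise_sd = 0, seed = 3))
  ta1 <- ph1$truth$angle_map; ta1 <- ta1[!is.na(ta1)]
  ta2 <- ph2$truth$angle_map; ta2 <- ta2[!is.na(ta2)]
  n <- min(length(ta1), length(ta2))
  dt <- orientation_distribution_from_angles(c(ta1[1:n], ta2[1:n]),
                                             bin_width = 5)
  m1 <- sum(dt$density[angdiff180(dt$bin_centers, 30) <= 10])
  m2 <- sum(dt$density[angdiff180(dt$bin_centers, 120) <= 10])
  expect_equal(m1 / m2, 1, tolerance = 0.15)
})

test_that("dual-Gaussian fit recovers a seeded two-component mixture", {
  set.seed(1234)
  ang <- c(rnorm(5e4, 67, 12), rnorm(5e4, 95, 6))
  f <- fit_dual_gaussian(orientation_distribution_from_angles(ang))
  expect_true(f$converged)
  expect_true(f$secondary_detected)
  expect_lt(abs(f$mu1 - 67), 1)
  expect_lt(abs(f$mu2 - 95), 1)
  expect_equal(f$sigma1, 12, tolerance = 0.1)
  expect_equal(f$sigma2, 6, tolerance = 0.1)
})

test_that("degenerate inputs do not produce spurious secondary components", {
  set.seed(7)
  one <- fit_dual_gaussian(
    orientation_distribution_from_angles(rnorm(5e4, 90, 10)))
  expect_true(one$converged)
  expect_false(one$secondary_detected)
  expect_lt(abs(one$mu1 - 90), 1)
  unif <- fit_dual_gaussian(
    orientation_distribution_from_angles(runif(5e4, 0, 180)))
  if (unif$converged && unif$secondary_detected) {
    # any detected structure must not be a sharp mode
    expect_gt(unif$sigma2, 1)
  }
  expect_gte(unif$sigma1, 1)   # bounded below by the bin width
})

test_that("orientation metrics follow their closed forms", {
  # all mass at mu1 -> tbint 0
  d1 <- orientation_distribution_from_angles(rep(67.5, 100))
  m1 <- compute_orientation_metrics(d1, fake_fit(67.5))
  expect_equal(m1$tbint, 0)
  expect_true(is.na(m1$tbors))
  # two equal deltas at mu1 +/- d -> tbint = d
  d2 <- orientation_distribution_from_angles(c(rep(40.5, 50), rep(80.5, 50)))
  m2 <- compute_orientation_metrics(d2, fake_fit(60.5))
  expect_equal(m2$tbint, 20)
  # exact equal-weight mixture about mu1 = 67: closed form 21.95
  edges <- 0:180
  mass <- 0.5 * diff(pnorm(edges, 67, 12)) + 0.5 * diff(pnorm(edges, 95, 6))
  d3 <- orientation_distribution_from_angles(edges[-1] - 0.5, weights = mass)
  m3 <- compute_orientation_metrics(
    d3, fake_fit(67, 12, 95, 6, secondary = TRUE))
  expect_equal(m3$tbint, 21.95, tolerance = 0.01)
  expect_equal(m3$tbors, 95 - 67)
  expect_equal(m3$tbors_mu2, 95)
  # tbint is bounded by 90 for any distribution
  du <- orientation_distribution_from_angles(runif(1e4, 0, 180))
  mu <- compute_orientation_metrics(du, fake_fit(0))
  expect_lte(mu$tbint, 90)
})

test_that("zero-jitter phantoms recover theta_p within 2 degrees", {
  for (th in c(20, 75, 140)) {
    ph <- generate_phantom(phantom_spec(width = 128, height = 128,
                                        theta_p = th, sigma_p = 0, seed = th))
    mask <- binarize_local(ph$image)
    d <- orientation_distribution(hessian_orientation(ph$image), mask)
    f <- fit_dual_gaussian(d, min_bins = 5)  # jitter-free: few distinct bins
    expect_true(f$converged)
    expect_lt(angdiff180(f$mu1, th), 2, label = paste("theta", th))
  }
})
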