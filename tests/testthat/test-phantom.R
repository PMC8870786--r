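# Phantom generator: exact geometry, determinism, bubbles.

test_that("axis-aligned jitter-free phantom has exact nominal BVF", {
  # width 4 px struts every 16 px, theta 0, no jitter/noise/blur
  sp <- phantom_spec(width = 64, height = 64, spacing = 1, theta_p = 0,
                     sigma_p = 0, strut_thickness = 4, strut_spacing = 16,
                     noise_sd = 0, psf_sigma = 0, seed = 1)
  ph <- generate_phantom(sp)
  expect_equal(ph$truth$bvf_true, 4 / 16)
  # bvf_true always equals the emitted mask ratio exactly
  expect_equal(ph$truth$bvf_true, mean(ph$truth$mask$labels == PHASE[["BONE"]]))
})

test_that("rotating theta by 90 degrees preserves BVF and shifts truth angle", {
  base <- list(width = 64, height = 64, spacing = 1, sigma_p = 0,
               strut_thickness = 4, strut_spacing = 16, noise_sd = 0,
               psf_sigma = 0, seed = 5)
  a <- generate_phantom(do.call(phantom_spec, c(base, theta_p = 30)))
  b <- generate_phantom(do.call(phantom_spec, c(base, theta_p = 120)))
  expect_equal(a$truth$bvf_true, b$truth$bvf_true, tolerance = 0.02)
  expect_equal(b$truth$theta_p_true, (a$truth$theta_p_true + 90) %% 180)
})

test_that("fixed seed gives a bit-identical phantom", {
  sp <- phantom_spec(width = 96, height = 96, seed = 42,
                     secondary_fraction = 0.3)
  a <- generate_phantom(sp); b <- generate_phantom(sp)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$mask$labels, b$truth$mask$labels)
})

test_that("bubble truth area matches the analytic disk area within 2%", {
  sp <- phantom_spec(width = 96, height = 96, spacing = 0.051, theta_p = 0,
                     sigma_p = 0, noise_sd = 0, psf_sigma = 0, seed = 2,
                     strut_thickness = 0.153, strut_spacing = 2.4,
                     bubbles = list(list(center = c(48, 24), radius = 10 * 0.051)))
  ph <- generate_phantom(sp)
  analytic <- pi * (10 * 0.051)^2
  expect_equal(ph$truth$bubble_volume_true, analytic, tolerance = 0.02)
})

test_that("insert_bubbles identity and blooming contracts hold", {
  sp <- phantom_spec(width = 64, height = 64, spacing = 1, theta_p = 0,
                     sigma_p = 0, strut_thickness = 3, strut_spacing = 16,
                     noise_sd = 0, psf_sigma = 0, seed = 3)
  ph <- generate_phantom(sp)
  img <- ph$image; mask <- ph$truth$mask
  # empty list: unchanged
  out <- insert_bubbles(img, mask, list())
  expect_identical(out$image$pixels, img$pixels)
  # CT-like: void radius equals nominal radius even with bloom_factor > 1
  bub <- list(list(center = c(32, 40), radius = 5))
  ct <- insert_bubbles(img, mask, bub, bloom_factor = 1.5, air_level = -10)
  expect_equal(sum(ct$image$pixels == -10), sum((rep(1:64, each = 64) - 32)^2 +
               (rep(1:64, 64) - 40)^2 <= 25))
  # MR-like: void radius blooms by 1.5, truth mask stays nominal
  mi <- gray_image(img$pixels, 1, modality = "MR_LIKE")
  mr <- insert_bubbles(mi, mask, list(list(center = c(32, 40), radius = 8)),
                       bloom_factor = 1.5, air_level = -10)
  void_px <- sum(mr$image$pixels == -10)
  expect_equal(void_px, sum((rep(1:64, each = 64) - 32)^2 +
               (rep(1:64, 64) - 40)^2 <= 144), tolerance = 0.01)
  air_truth <- sum(mr$mask$labels == PHASE[["AIR"]])
  expect_lte(air_truth, sum((rep(1:64, each = 64) - 32)^2 +
             (rep(1:64, 64) - 40)^2 <= 64))
  expect_gt(air_truth, 0.8 * pi * 64)
})

test_that("phantom spec invariants are enforced", {
  expect_error(phantom_spec(strut_thickness = 1.2, strut_spacing = 1.1),
               "smaller")
  expect_error(phantom_spec(sigma_p = -1), ">= 0")
  expect_error(phantom_spec(secondary_fraction = 1), "secondary_fraction")
  expect_error(phantom_spec(bubbles = list(list(center = c(1, 1),
                                                radius = 99))),
               "radius")
})

test_that("secondary family contributes roughly its nominal pixel share", {
  sp <- phantom_spec(width = 200, height = 200, spacing = 0.051,
                     secondary_fraction = 0.5, sigma_p = 0, noise_sd = 0,
                     psf_sigma = 0, seed = 7)
  ph <- generate_phantom(sp)
  ang <- ph$truth$angle_map
  bone_ang <- ang[!is.na(ang)]
  near2 <- mean(trabkit:::angdiff180(bone_ang, 67 + 90) < 20)
  expect_gt(near2, 0.3); expect_lt(near2, 0.7)
})
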