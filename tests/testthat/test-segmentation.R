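# Grayscale conversion and lesion delineation: Otsu mask geometry, centroid,
# ray-cast margin radius, rotation equivariance.

test_that("to_grayscale applies Rec. 601 luminance", {
  gray <- matrix(runif(64 * 64, 0, 255), 64, 64)
  expect_identical(to_grayscale(gray), gray)

  rgb <- array(0, dim = c(2, 2, 3))
  rgb[1, 1, ] <- c(255, 0, 0)
  rgb[1, 2, ] <- c(10, 20, 30)
  g <- to_grayscale(rgb)
  expect_equal(g[1, 1], 76.245)
  expect_equal(g[1, 2], 18.15)
  expect_error(to_grayscale(array(0, dim = c(2, 2, 2))), "channel count")
})

test_that("a synthetic disk is segmented to the right area and centre", {
  img <- generate_lesion_image(
    lesion_spec(image_size = c(128, 128), base_radius = 50, lesion_level = 80))
  mask <- segment_lesion(img$image)
  expect_lt(abs(sum(mask$mask) - pi * 50^2) / (pi * 50^2), 0.03)
  expect_lt(max(abs(mask$centroid - img$truth$centre)), 0.5)
  expect_true(all(mask$margin_radius > 0))
  # margin periodicity: radius near 0 and near 2*pi agree
  expect_lt(abs(mask$margin_radius[1] - mask$margin_radius[360]), 1.5)
})

test_that("uniform images fail segmentation with an informative error", {
  expect_error(segment_lesion(matrix(120, 64, 64)), "segmentation failure")
})

test_that("ray-cast margin tracks a harmonically perturbed boundary", {
  spec <- small_lesion_spec(boundary_harmonics = data.frame(
    order = 2, amplitude = 0.2, phase = 0.7))
  img <- generate_lesion_image(spec)
  mask <- segment_lesion(img$image)
  truth <- clocksweep:::margin_radius_analytic(spec, mask$angles)
  rms <- sqrt(mean((mask$margin_radius - truth)^2))
  expect_lt(rms, 1.5)
})

test_that("mask and centroid are equivariant under 90-degree rotation", {
  spec <- small_lesion_spec(0.2, boundary_harmonics = data.frame(
    order = 3, amplitude = 0.1, phase = 0.3))
  img <- generate_lesion_image(spec)
  m1 <- segment_lesion(img$image)
  m2 <- segment_lesion(clocksweep:::rotate90_cw(img$image))
  h <- nrow(img$image)
  # (r, c) -> (c, h + 1 - r) under clockwise rotation
  expect_equal(unname(m2$centroid),
               unname(c(m1$centroid[2], h + 1 - m1$centroid[1])))
  expect_identical(clocksweep:::rotate90_cw(m1$mask), m2$mask)
  # margin radius shifts by a quarter turn (90 grid samples of 360)
  shifted <- m1$margin_radius[((0:359 - 90) %% 360) + 1]
  expect_lt(max(abs(m2$margin_radius - shifted)), 1e-8)
})

test_that("fixed thresholds and degenerate inputs are handled", {
  img <- generate_lesion_image(small_lesion_spec())
  m <- segment_lesion(img$image, method = "fixed", threshold = 150)
  expect_equal(m$threshold, 150)
  expect_error(segment_lesion(img$image, method = "fixed"), "threshold")
  expect_error(segment_lesion(matrix(120, 32, 32)), "64 x 64")
})
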