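# Radial profile and clock-sweep statistic: exact constant/sinusoid cases,
# agreement with the generator's analytic profile, rotation and intensity
# invariances.

test_that("a uniform interior yields a constant profile and statistic 0", {
  # analytic mask strictly inside a uniform region isolates the interpolator
  img <- matrix(60, 160, 160)
  mask <- analytic_disk_mask(img, c(80.5, 80.5), 55)
  prof <- radial_profile(img, mask)
  expect_lt(max(abs(prof$values - 60)), 1e-6)
  expect_equal(sweep_statistic(prof)$statistic, 0)
})

test_that("profile matches the generator's analytic angular profile", {
  img <- generate_lesion_image(small_lesion_spec(0.2))
  s <- sweep_image(img$image)
  rel <- abs(s$profile$values - img$truth$profile) / img$truth$profile
  expect_lt(max(rel), 0.01)
})

test_that("sweep_statistic reduces a sinusoidal profile in closed form", {
  th <- clocksweep:::angle_grid(360L)
  res <- sweep_statistic(profile_from_values(100 + 20 * sin(th)))
  expect_equal(res$delta, 40)
  expect_equal(res$mean_brightness, 100)
  expect_equal(res$statistic, 0.4)
  expect_equal(res$brightest_angle, pi / 2)
  expect_equal(res$darkest_angle, 3 * pi / 2)
  # |d/dtheta sin| peaks at 12 and 6 o'clock; the tie breaks toward noon,
  # confirmed by brute-force scan of the central differences
  sm <- clocksweep:::circular_smooth(100 + 20 * sin(th), 5L)
  dm <- abs(sm[c(2:360, 1)] - sm[c(360, 1:359)])
  expect_equal(res$max_variation_angle, th[which.max(dm)])
  expect_equal(res$max_variation_angle, 0)

  expect_equal(sweep_statistic(profile_from_values(rep(7, 90)))$statistic, 0)
  expect_error(sweep_statistic(profile_from_values(rep(0, 90))), "mean")
})

test_that("statistic is invariant under global intensity scaling", {
  img <- generate_lesion_image(small_lesion_spec(0.2))
  s1 <- sweep_image(img$image)
  s2 <- sweep_image(img$image * 0.6)
  expect_equal(s2$result$statistic, s1$result$statistic, tolerance = 1e-9)
})

test_that("90-degree rotation shifts the profile by exactly 90 samples", {
  img <- generate_lesion_image(small_lesion_spec(
    0.2, boundary_harmonics = data.frame(order = 2, amplitude = 0.15,
                                         phase = 1.1)))
  s1 <- sweep_image(img$image)
  s2 <- sweep_image(clocksweep:::rotate90_cw(img$image))
  shifted <- s1$profile$values[((0:359 - 90) %% 360) + 1]
  expect_equal(s2$profile$values, shifted, tolerance = 1e-9)
  expect_equal(s2$result$statistic, s1$result$statistic, tolerance = 1e-9)
})

test_that("statistic is stable under arbitrary modulation phase (rotation)", {
  # phase-shifting the angular modulation is a pure rotation of the lesion
  stats <- vapply(c(0, 0.9, 2.2, 4.5), function(phi) {
    img <- generate_lesion_image(small_lesion_spec(0.2, modulation_phase = phi))
    sweep_image(img$image)$result$statistic
  }, numeric(1))
  expect_lt((max(stats) - min(stats)) / mean(stats), 0.02)
})

test_that("hand angles locate the modulation extremes on real sweeps", {
  img <- generate_lesion_image(small_lesion_spec(0.3))
  res <- sweep_image(img$image)$result
  ang_diff <- function(a, b) min(abs(a - b), 2 * pi - abs(a - b))
  expect_lt(ang_diff(res$brightest_angle, img$truth$brightest_angle), 0.15)
  expect_lt(ang_diff(res$darkest_angle, img$truth$darkest_angle), 0.15)
  # d/dtheta sin(theta) peaks a quarter turn from the extremes
  expect_lt(min(ang_diff(res$max_variation_angle, 0),
                ang_diff(res$max_variation_angle, pi)), 0.15)
})

test_that("degenerate profiles raise errors", {
  img <- matrix(60, 160, 160)
  mask <- analytic_disk_mask(img, c(80.5, 80.5), 55)
  mask$margin_radius[5] <- 0.5
  expect_error(radial_profile(img, mask), "margin radius below 1 px")
})

test_that("whole-lesion mean denominator is available as an alternative", {
  img <- generate_lesion_image(small_lesion_spec(0.2))
  s <- sweep_image(img$image)
  lm <- lesion_mean_intensity(img$image, s$mask)
  alt <- sweep_statistic(s$profile, mean_value = lm)
  expect_equal(alt$mean_brightness, lm)
  expect_equal(alt$statistic, s$result$delta / lm)
  # for radially flat lesions the two denominators nearly coincide
  expect_equal(alt$statistic, s$result$statistic, tolerance = 0.03)
})
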