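# The clock-sweep radar: brightness along the arm from the lesion centroid to
# the peripheral margin, swept clockwise from 12 o'clock, summarized as the
# brightness range (delta) divided by the mean brightness of the angular
# profile. Three "clock hands" mark the darkest angle, the brightest angle and
# the angle of maximum brightness variation.

#' Angular brightness profile of a lesion
#'
#' For each clock angle, averages bilinearly interpolated intensities at
#' points uniformly spaced on the segment from the centroid to the margin
#' (endpoints included). Interpolation is mask-aware: weights are restricted
#' to in-lesion pixels, so the brighter background never contaminates samples
#' near the margin.
#'
#' @param image numeric matrix of intensities.
#' @param mask a [segment_lesion()] result (`lesion_mask`).
#' @param n_angles number of clock angles; defaults to the mask's angle grid.
#' @param samples_per_arm fixed number of samples per arm, or NULL (default)
#'   for `max(32, ceiling(margin_radius))` per angle.
#' @return object of class `angular_profile`: list with `angles` and `values`
#'   (mean arm intensity per angle).
#' @export
radial_profile <- function(image, mask, n_angles = NULL,
                           samples_per_arm = NULL) {
  stopifnot(is.matrix(image), inherits(mask, "lesion_mask"))
  if (is.null(n_angles)) {
    angles <- mask$angles
    radius <- mask$margin_radius
  } else {
    angles <- angle_grid(n_angles)
    radius <- margin_radius_at(mask, angles)
  }
  if (any(radius < 1)) {
    stop("margin radius below 1 px at ", sum(radius < 1), " angle(s); ",
         "profile undefined", call. = FALSE)
  }
  dirs <- angle_direction(angles)
  values <- vapply(seq_along(angles), function(j) {
    ns <- if (is.null(samples_per_arm)) max(32, ceiling(radius[j]))
          else samples_per_arm
    t <- seq(0, 1, length.out = ns)
    v <- bilinear_sample(image,
                         mask$centroid[1] + t * radius[j] * dirs[j, "drow"],
                         mask$centroid[2] + t * radius[j] * dirs[j, "dcol"],
                         mask = mask$mask)
    mean(v, na.rm = TRUE)
  }, numeric(1))
  structure(list(angles = angles, values = values), class = "angular_profile")
}

#' Clock-sweep summary statistic
#'
#' Reduces an angular profile m(theta) to the clock-sweep radar value:
#' `delta = max(m) - min(m)`, `mean_brightness = mean(m)` over the uniform
#' angle grid, and `statistic = delta / mean_brightness`. The three hand
#' angles are the argmin and argmax of m and the angle of maximum absolute
#' central difference of the (circularly smoothed) profile; ties are broken
#' toward the smallest angle, i.e. closest to 12 o'clock going clockwise.
#'
#' @param profile an [radial_profile()] result (`angular_profile`).
#' @param smoothing_window odd circular moving-average window (in samples)
#'   applied before the variation hand is located; default 5.
#' @param mean_value optional denominator override (e.g. the whole-lesion mean
#'   from [lesion_mean_intensity()]); default is the profile mean.
#' @return object of class `clock_sweep`: `delta`, `mean_brightness`,
#'   `statistic`, `darkest_angle`, `brightest_angle`, `max_variation_angle`
#'   (radians, clockwise from 12 o'clock) and the input `profile`.
#' @export
#' @examples
#' th <- 2 * pi * (0:359) / 360
#' p <- structure(list(angles = th, values = 100 + 20 * sin(th)),
#'                class = "angular_profile")
#' sweep_statistic(p)$statistic # 0.4
sweep_statistic <- function(profile, smoothing_window = 5L,
                            mean_value = NULL) {
  stopifnot(inherits(profile, "angular_profile"),
            length(profile$values) > 0)
  m <- profile$values
  th <- profile$angles
  delta <- max(m) - min(m)
  mean_b <- if (is.null(mean_value)) mean(m) else mean_value
  if (mean_b == 0) stop("mean brightness is zero; statistic undefined",
                        call. = FALSE)
  ms <- circular_smooth(m, smoothing_window)
  n <- length(ms)
  dm <- abs(ms[c(2:n, 1)] - ms[c(n, 1:(n - 1))]) / (2 * (2 * pi / n))
  structure(
    list(delta = delta,
         mean_brightness = mean_b,
         statistic = delta / mean_b,
         darkest_angle = th[which.min(m)],
         brightest_angle = th[which.max(m)],
         max_variation_angle = th[which.max(dm)],
         profile = profile),
    class = "clock_sweep"
  )
}

#' Mean intensity over the lesion mask
#'
#' Alternative denominator for [sweep_statistic()]: the plain mean of all
#' in-mask pixel intensities instead of the mean of the angular profile.
#'
#' @param image numeric matrix.
#' @param mask a `lesion_mask`.
#' @return scalar mean intensity.
#' @export
lesion_mean_intensity <- function(image, mask) {
  stopifnot(is.matrix(image), inherits(mask, "lesion_mask"))
  mean(image[mask$mask])
}

#' Segment and sweep in one call
#'
#' Convenience wrapper: grayscale conversion, lesion segmentation, radial
#' profile and clock-sweep statistic.
#'
#' @param image matrix, array, or path to a PNG/TIFF file.
#' @param n_angles clock angles (default 360).
#' @param smoothing_window see [sweep_statistic()].
#' @param ... passed to [segment_lesion()].
#' @return list with `mask`, `profile` and `result` (`clock_sweep`).
#' @export
sweep_image <- function(image, n_angles = 360L, smoothing_window = 5L, ...) {
  if (is.character(image)) image <- read_lesion_image(image)
  gray <- to_grayscale(image)
  mask <- segment_lesion(gray, n_angles = n_angles, ...)
  profile <- radial_profile(gray, mask)
  list(mask = mask, profile = profile,
       result = sweep_statistic(profile, smoothing_window = smoothing_window))
}

clock_hours <- function(theta) (theta %% (2 * pi)) / (2 * pi) * 12

#' @export
print.clock_sweep <- function(x, ...) {
  cat(sprintf("<clock_sweep> delta/mean = %.3f (delta = %.2f, mean = %.2f)\n",
              x$statistic, x$delta, x$mean_brightness))
  cat(sprintf("  darkest %.1f o'clock, brightest %.1f o'clock, max variation %.1f o'clock\n",
              clock_hours(x$darkest_angle), clock_hours(x$brightest_angle),
              clock_hours(x$max_variation_angle)))
  invisible(x)
}
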