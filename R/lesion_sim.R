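# Synthetic dermoscopy-style lesion generator with analytic ground truth.
#
# The generator emulates a roughly elliptical pigmented lesion darker than the
# surrounding skin: a smooth closed margin r(theta) = R0 * (1 + sum_k a_k *
# cos(k*theta + phi_k)), a flat interior level L0 modulated angularly by
# (1 + A*sin(theta + phi)), and optional additive Gaussian pixel noise.
# Because the interior has no radial dependence, the mean brightness along any
# centre-to-margin arm equals the angular profile m(theta) = L0*(1 +
# A*sin(theta + phi)) analytically, so the clock-sweep statistic has closed
# form (max - min)/mean = 2A. Every image therefore carries its own ground
# truth, which downstream segmentation and profiling are tested against.

#' Specify a synthetic lesion image
#'
#' Parameters of a synthetic single-lesion grayscale image: a dark,
#' near-elliptical lesion on a lighter skin-tone background, with a
#' harmonically perturbed margin and sinusoidal angular brightness modulation.
#'
#' @param image_size integer `(height, width)` in pixels (at least 64). The
#'   default 1024 x 1024 emulates the one-megapixel low end of cropped
#'   dermoscopy photographs.
#' @param background_level background (skin) intensity in `[0, 255]`.
#' @param base_radius mean margin radius `R0` in pixels.
#' @param boundary_harmonics data frame (or NULL) with columns `order`
#'   (integer k >= 1), `amplitude` (dimensionless `a_k`) and `phase`
#'   (radians), perturbing the margin radius as
#'   `r(theta) = R0 * (1 + sum a_k cos(k theta + phase_k))`.
#' @param lesion_level interior base intensity `L0` in `[0, 255]`, darker than
#'   the background even at peak modulation.
#' @param modulation_amplitude angular brightness modulation amplitude `A` in
#'   `[0, 1)`; interior intensity is `L0 * (1 + A * sin(theta + phase))`.
#' @param modulation_phase modulation phase in radians.
#' @param noise_sd standard deviation of additive Gaussian pixel noise, in
#'   intensity units (applied inside the lesion, clipped to `[0, 255]`).
#' @param seed integer seed; generation is bit-reproducible for a fixed spec.
#'
#' @return object of class `lesion_spec`.
#' @export
#' @examples
#' spec <- lesion_spec(modulation_amplitude = 0.2)
#' img <- generate_lesion_image(spec)
#' img$truth$delta_over_mean # analytic clock-sweep value, 2A = 0.4
lesion_spec <- function(image_size = c(1024L, 1024L),
                        background_level = 200,
                        base_radius = 350,
                        boundary_harmonics = NULL,
                        lesion_level = 80,
                        modulation_amplitude = 0,
                        modulation_phase = 0,
                        noise_sd = 0,
                        seed = 1L) {
  if (length(image_size) != 2 || any(image_size < 64)) {
    stop("image_size must be (height, width) with both >= 64", call. = FALSE)
  }
  if (!is.null(boundary_harmonics)) {
    boundary_harmonics <- as.data.frame(boundary_harmonics)
    stopifnot(all(c("order", "amplitude", "phase") %in% names(boundary_harmonics)),
              all(boundary_harmonics$order >= 1))
  }
  if (modulation_amplitude < 0 || modulation_amplitude >= 1) {
    stop("modulation_amplitude must lie in [0, 1)", call. = FALSE)
  }
  if (lesion_level * (1 + modulation_amplitude) >= background_level) {
    stop("darker-lesion convention violated: lesion_level * (1 + A) must be ",
         "below background_level", call. = FALSE)
  }
  spec <- structure(
    list(image_size = as.integer(image_size),
         background_level = background_level,
         base_radius = base_radius,
         boundary_harmonics = boundary_harmonics,
         lesion_level = lesion_level,
         modulation_amplitude = modulation_amplitude,
         modulation_phase = modulation_phase,
         noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "lesion_spec"
  )
  # margin must stay positive and keep a 2 px guard band inside the frame
  th <- angle_grid(720L)
  r <- margin_radius_analytic(spec, th)
  if (any(r <= 0)) {
    stop("boundary harmonics make the margin radius non-positive", call. = FALSE)
  }
  if (max(r) >= min(spec$image_size) / 2 - 2) {
    stop("lesion exceeds image bounds: max margin radius ", round(max(r), 1),
         " px does not fit in a ", min(spec$image_size), " px frame", call. = FALSE)
  }
  spec
}

# analytic margin radius r(theta) for a lesion_spec
margin_radius_analytic <- function(spec, theta) {
  r <- rep(1, length(theta))
  bh <- spec$boundary_harmonics
  if (!is.null(bh)) {
    for (i in seq_len(nrow(bh))) {
      r <- r + bh$amplitude[i] * cos(bh$order[i] * theta + bh$phase[i])
    }
  }
  spec$base_radius * r
}

# analytic angular brightness profile m(theta)
angular_profile_analytic <- function(spec, theta) {
  spec$lesion_level *
    (1 + spec$modulation_amplitude * sin(theta + spec$modulation_phase))
}

#' Generate a synthetic lesion image with ground truth
#'
#' Renders the lesion described by a [lesion_spec()]: pixels outside the
#' margin take the background level; pixels inside take
#' `L0 * (1 + A * sin(theta + phase))` plus optional Gaussian noise, clipped
#' to `[0, 255]`. The returned ground-truth record carries the analytic
#' angular profile, the analytic clock-sweep value `2A`, and the analytic
#' brightest/darkest clock angles.
#'
#' @param spec a [lesion_spec()].
#' @return object of class `lesion_image`: list with `image` (numeric matrix,
#'   intensities in `[0, 255]`), `truth` (list of analytic values) and `spec`.
#' @export
generate_lesion_image <- function(spec) {
  stopifnot(inherits(spec, "lesion_spec"))
  h <- spec$image_size[1]
  w <- spec$image_size[2]
  centre <- c((h + 1) / 2, (w + 1) / 2)
  vr <- matrix(seq_len(h) - centre[1], h, w)
  vc <- matrix(seq_len(w) - centre[2], h, w, byrow = TRUE)
  theta <- displacement_angle(vr, vc)
  rad <- sqrt(vr^2 + vc^2)
  inside <- rad <= margin_radius_analytic(spec, theta)

  img <- matrix(spec$background_level, h, w)
  img[inside] <- angular_profile_analytic(spec, theta[inside])
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    img[inside] <- img[inside] + stats::rnorm(sum(inside), sd = spec$noise_sd)
  }
  img <- pmin(pmax(img, 0), 255)

  A <- spec$modulation_amplitude
  phi <- spec$modulation_phase
  grid <- angle_grid(360L)
  truth <- list(
    centre = centre,
    angles = grid,
    profile = angular_profile_analytic(spec, grid),
    margin_radius = margin_radius_analytic(spec, grid),
    delta_over_mean = 2 * A,
    brightest_angle = if (A > 0) (pi / 2 - phi) %% (2 * pi) else NA_real_,
    darkest_angle = if (A > 0) (3 * pi / 2 - phi) %% (2 * pi) else NA_real_
  )
  structure(list(image = img, truth = truth, spec = spec),
            class = "lesion_image")
}

#' @export
print.lesion_image <- function(x, ...) {
  cat(sprintf("<lesion_image> %d x %d px, L0 = %g, A = %g, noise_sd = %g\n",
              nrow(x$image), ncol(x$image), x$spec$lesion_level,
              x$spec$modulation_amplitude, x$spec$noise_sd))
  invisible(x)
}
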