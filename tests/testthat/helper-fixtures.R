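# Small, fast synthetic fixtures shared across test files. Geometry and unit
# tests use a compact 192 px lesion; the end-to-end recovery tests in
# test-acceptance.R use the generator defaults (1 MP, the emulated study
# conditions).

small_lesion_spec <- function(modulation_amplitude = 0, seed = 1L, ...) {
  lesion_spec(image_size = c(192L, 192L), base_radius = 60,
              modulation_amplitude = modulation_amplitude, seed = seed, ...)
}

# analytic disk mask (no segmentation): constant margin radius about a centre
analytic_disk_mask <- function(image, centre, radius, n_angles = 360L) {
  h <- nrow(image)
  w <- ncol(image)
  vr <- matrix(seq_len(h) - centre[1], h, w)
  vc <- matrix(seq_len(w) - centre[2], h, w, byrow = TRUE)
  structure(
    list(mask = sqrt(vr^2 + vc^2) <= radius,
         centroid = c(row = centre[1], col = centre[2]),
         angles = clocksweep:::angle_grid(n_angles),
         margin_radius = rep(radius, n_angles),
         threshold = NA_real_),
    class = "lesion_mask"
  )
}

# profile object from explicit values on the uniform grid
profile_from_values <- function(values) {
  structure(list(angles = clocksweep:::angle_grid(length(values)),
                 values = values),
            class = "angular_profile")
}

# published percentages as plain vectors (reader rows only)
published_columns <- function() {
  tab <- published_reader_summary()
  as.list(tab[tab$reader != "Mean", ])
}
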