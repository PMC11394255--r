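# Lesion delineation: grayscale conversion, Otsu thresholding (lesion =
# darker class), largest 4-connected component with holes filled, binary
# centroid, and the per-angle margin radius the clock sweep needs. The margin
# radius at each clock angle is the distance from the centroid to the LAST
# in-mask sample along the ray, which covers concave borders.

#' Convert a raster to grayscale
#'
#' 3-channel input is mapped by Rec. 601 luminance
#' (`0.299 R + 0.587 G + 0.114 B`); single-channel input passes through.
#'
#' @param image numeric matrix (H x W) or array (H x W x 3), intensities in
#'   `[0, 255]`.
#' @return numeric matrix of intensities.
#' @export
to_grayscale <- function(image) {
  if (is.matrix(image)) return(image)
  if (is.array(image) && length(dim(image)) == 3) {
    ch <- dim(image)[3]
    if (ch == 1) return(image[, , 1])
    if (ch == 3) {
      return(0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3])
    }
    stop("unsupported channel count: ", ch, " (expected 1 or 3)", call. = FALSE)
  }
  stop("image must be a matrix or an H x W x C array", call. = FALSE)
}

#' Segment the lesion in a grayscale image
#'
#' Thresholds the image (Otsu's criterion by default, or a supplied fixed
#' threshold), keeps the lesion as the darker class, retains the largest
#' 4-connected component, fills holes, and measures the binary centroid and
#' the margin radius on a uniform clock-angle grid.
#'
#' @param image numeric matrix, intensities in `[0, 255]`, at least 64 x 64.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param threshold fixed intensity threshold, required when
#'   `method = "fixed"`.
#' @param n_angles number of clock angles for the margin-radius table
#'   (default 360).
#' @return object of class `lesion_mask`: list with `mask` (logical matrix),
#'   `centroid` (`(row, col)`), `angles`, `margin_radius` (px per angle) and
#'   `threshold`.
#' @export
#' @examples
#' img <- generate_lesion_image(lesion_spec())
#' m <- segment_lesion(img$image)
#' m$centroid
segment_lesion <- function(image,
                           method = c("otsu", "fixed"),
                           threshold = NULL,
                           n_angles = 360L) {
  method <- match.arg(method)
  stopifnot(is.matrix(image), all(is.finite(image)))
  if (any(dim(image) < 64)) stop("image must be at least 64 x 64", call. = FALSE)
  if (method == "otsu") {
    threshold <- 255 * EBImage::otsu(EBImage::Image(t(image) / 255))
  } else if (is.null(threshold)) {
    stop("method = \"fixed\" requires a threshold", call. = FALSE)
  }

  mask <- image < threshold
  if (!any(mask) || all(mask)) {
    stop("segmentation failure: threshold ", round(threshold, 2),
         " does not separate a lesion from the background", call. = FALSE)
  }
  lab <- EBImage::bwlabel(mask)          # 4-connected components
  sizes <- tabulate(lab[lab > 0])
  mask <- lab == which.max(sizes)
  mask <- EBImage::fillHull(mask) > 0

  px <- which(mask, arr.ind = TRUE)
  centroid <- colMeans(px)
  names(centroid) <- c("row", "col")
  if (!mask[round(centroid[1]), round(centroid[2])]) {
    stop("segmentation failure: centroid falls outside the mask ",
         "(threshold ", round(threshold, 2), ")", call. = FALSE)
  }

  angles <- angle_grid(n_angles)
  structure(
    list(mask = mask,
         centroid = centroid,
         angles = angles,
         margin_radius = ray_margin_radius(mask, centroid, angles),
         threshold = threshold),
    class = "lesion_mask"
  )
}

# Distance from the centroid to the last in-mask sample along each ray,
# marched at 0.5 px steps with nearest-neighbour mask lookup.
ray_margin_radius <- function(mask, centroid, angles, step = 0.5) {
  h <- nrow(mask)
  w <- ncol(mask)
  max_r <- sqrt(max(centroid[1] - 1, h - centroid[1])^2 +
                max(centroid[2] - 1, w - centroid[2])^2)
  steps <- seq(step, max_r, by = step)
  dirs <- angle_direction(angles)
  # n_steps x n_angles position grids
  rr <- round(centroid[1] + outer(steps, dirs[, "drow"]))
  cc <- round(centroid[2] + outer(steps, dirs[, "dcol"]))
  ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
  inside <- matrix(FALSE, length(steps), length(angles))
  inside[ok] <- mask[cbind(rr[ok], cc[ok])]
  radius <- apply(inside, 2, function(col) {
    hit <- which(col)
    if (!length(hit)) 0 else steps[max(hit)]
  })
  if (any(radius <= 0)) {
    stop("segmentation failure: margin radius vanishes at ",
         sum(radius <= 0), " angle(s)", call. = FALSE)
  }
  radius
}

# linear interpolation of the margin-radius table at arbitrary clock angles
margin_radius_at <- function(mask, theta) {
  stopifnot(inherits(mask, "lesion_mask"))
  n <- length(mask$angles)
  stepw <- 2 * pi / n
  theta <- theta %% (2 * pi)
  i0 <- floor(theta / stepw)
  f <- theta / stepw - i0
  r <- mask$margin_radius
  r[(i0 %% n) + 1] * (1 - f) + r[((i0 + 1) %% n) + 1] * f
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf(paste0("<lesion_mask> %d px area, centroid (%.1f, %.1f), ",
                     "threshold %.1f, %d angles\n"),
              sum(x$mask), x$centroid[1], x$centroid[2], x$threshold,
              length(x$angles)))
  invisible(x)
}
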