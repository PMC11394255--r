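# Annotated overlay: the image with three clock hands drawn from the centroid
# to the margin (blue = darkest angle, green = brightest, red = maximum
# brightness variation), the clock-sweep value printed bottom-right, and the
# optional externally supplied ensemble risk score printed top-left as
# "Risk = x". Text is rasterized with a built-in 5x7 bitmap font so rendering
# is deterministic and device-free.

# 5x7 glyphs; "#" = on. Only the characters the two labels need.
.overlay_font <- list(
  "0" = c(".###.", "#...#", "#..##", "#.#.#", "##..#", "#...#", ".###."),
  "1" = c("..#..", ".##..", "..#..", "..#..", "..#..", "..#..", ".###."),
  "2" = c(".###.", "#...#", "....#", "...#.", "..#..", ".#...", "#####"),
  "3" = c(".###.", "#...#", "....#", "..##.", "....#", "#...#", ".###."),
  "4" = c("...#.", "..##.", ".#.#.", "#..#.", "#####", "...#.", "...#."),
  "5" = c("#####", "#....", "####.", "....#", "....#", "#...#", ".###."),
  "6" = c(".###.", "#....", "#....", "####.", "#...#", "#...#", ".###."),
  "7" = c("#####", "....#", "...#.", "..#..", ".#...", ".#...", ".#..."),
  "8" = c(".###.", "#...#", "#...#", ".###.", "#...#", "#...#", ".###."),
  "9" = c(".###.", "#...#", "#...#", ".####", "....#", "....#", ".###."),
  "." = c(".....", ".....", ".....", ".....", ".....", "..#..", "..#.."),
  "-" = c(".....", ".....", ".....", "#####", ".....", ".....", "....."),
  "=" = c(".....", ".....", "#####", ".....", "#####", ".....", "....."),
  "R" = c("####.", "#...#", "#...#", "####.", "#.#..", "#..#.", "#...#"),
  "i" = c("..#..", ".....", ".##..", "..#..", "..#..", "..#..", ".###."),
  "s" = c(".....", ".....", ".####", "#....", ".###.", "....#", "####."),
  "k" = c("#....", "#....", "#..#.", "#.#..", "##...", "#.#..", "#..#."),
  " " = c(".....", ".....", ".....", ".....", ".....", ".....", ".....")
)

format_statistic_label <- function(statistic) {
  formatC(statistic, format = "f", digits = 2)
}

format_risk_label <- function(risk_score) {
  paste0("Risk = ", formatC(risk_score, format = "f", digits = 2))
}

# stamp `text` onto an H x W x 3 array, top-left glyph corner at (row, col)
draw_text <- function(rgb, text, row, col, scale = 1L, colour = c(1, 1, 0)) {
  chars <- strsplit(text, "")[[1]]
  h <- dim(rgb)[1]
  w <- dim(rgb)[2]
  x <- col
  for (ch in chars) {
    glyph <- .overlay_font[[ch]]
    if (is.null(glyph)) glyph <- .overlay_font[[" "]]
    on <- which(do.call(rbind, lapply(glyph, function(r)
      strsplit(r, "")[[1]] == "#")), arr.ind = TRUE)
    for (i in seq_len(nrow(on))) {
      rr <- row + (on[i, 1] - 1) * scale + seq_len(scale) - 1
      cc <- x + (on[i, 2] - 1) * scale + seq_len(scale) - 1
      rr <- rr[rr >= 1 & rr <= h]
      cc <- cc[cc >= 1 & cc <= w]
      for (k in 1:3) rgb[rr, cc, k] <- colour[k]
    }
    x <- x + 6 * scale
  }
  rgb
}

text_width <- function(text, scale) nchar(text) * 6 * scale - scale

# stamp a straight hand from the centroid along clock angle theta
draw_hand <- function(rgb, centroid, theta, radius, colour, halfwidth = 1L) {
  h <- dim(rgb)[1]
  w <- dim(rgb)[2]
  d <- angle_direction(theta)
  t <- seq(0, radius, by = 0.3)
  rr <- round(centroid[1] + t * d[, "drow"])
  cc <- round(centroid[2] + t * d[, "dcol"])
  off <- -halfwidth:halfwidth
  for (dr in off) for (dc in off) {
    r2 <- rr + dr
    c2 <- cc + dc
    ok <- r2 >= 1 & r2 <= h & c2 >= 1 & c2 <= w
    for (k in 1:3) {
      idx <- cbind(r2[ok], c2[ok], k)
      rgb[idx] <- colour[k]
    }
  }
  rgb
}

#' Render the annotated clock-sweep overlay
#'
#' Draws the three clock hands (blue at the darkest angle, green at the
#' brightest, red at the maximum-variation angle) from the lesion centroid to
#' the margin, prints the clock-sweep value (2 decimals) bottom-right and,
#' when supplied, the ensemble risk score top-left as `"Risk = x"`.
#'
#' @param image grayscale matrix in `[0, 255]` (as analysed).
#' @param mask the `lesion_mask` used for the sweep.
#' @param result the [sweep_statistic()] result.
#' @param risk_score optional externally computed malignancy risk in
#'   `[0, 1]` (e.g. an ensemble-classifier score); displayed only, never
#'   computed here.
#' @return H x W x 3 numeric array in `[0, 1]`, same spatial size as the
#'   input, suitable for [png::writePNG()].
#' @export
render_overlay <- function(image, mask, result, risk_score = NULL) {
  stopifnot(is.matrix(image), inherits(mask, "lesion_mask"),
            inherits(result, "clock_sweep"))
  if (!is.null(risk_score) && (risk_score < 0 || risk_score > 1)) {
    stop("risk_score must lie in [0, 1]", call. = FALSE)
  }
  h <- nrow(image)
  w <- ncol(image)
  rgb <- array(image / 255, dim = c(h, w, 3))
  halfwidth <- max(1L, round(min(h, w) / 256))

  hands <- list(list(result$darkest_angle, c(0, 0, 1)),
                list(result$brightest_angle, c(0, 1, 0)),
                list(result$max_variation_angle, c(1, 0, 0)))
  for (hd in hands) {
    rgb <- draw_hand(rgb, mask$centroid, hd[[1]],
                     margin_radius_at(mask, hd[[1]]), hd[[2]], halfwidth)
  }

  scale <- max(1L, floor(min(h, w) / 128))
  pad <- 4L * scale
  stat_label <- format_statistic_label(result$statistic)
  rgb <- draw_text(rgb, stat_label,
                   row = h - 7 * scale - pad,
                   col = w - text_width(stat_label, scale) - pad,
                   scale = scale)
  if (!is.null(risk_score)) {
    rgb <- draw_text(rgb, format_risk_label(risk_score),
                     row = pad, col = pad, scale = scale)
  }
  rgb
}
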