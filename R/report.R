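# Study-level reporting in the layout of the published ten-reader summary
# table: per-reader sensitivity/specificity in both conditions, their
# increases, d' in both conditions and its increase, plus a Mean row.
#
# Report-parity conventions (chosen to reproduce the published table cell for
# cell, see the methods vignette): percentages are rounded half-up to 1
# decimal per reader; d' is computed FROM the rounded rates and shown to 2
# decimals; increase cells are differences of the rounded condition cells
# (d' increases are differences before the final 2-decimal rounding); the
# Mean row averages the rounded per-reader cells (2 decimals), and the Mean
# of each increase column is the difference of the two condition means.

#' Build the study report table
#'
#' Scores every reader in both conditions and lays the results out as a
#' per-reader table with a final Mean row, with the rounding conventions of a
#' printed clinical summary table (percentages to 1 decimal per reader, 2
#' decimals for means; d' to 2 decimals, computed from the rounded rates for
#' parity with the printed percentages).
#'
#' @param table a response table (paired decisions for every reader/image).
#' @return tibble with columns `reader`, `sens_without`, `spec_without`,
#'   `sens_with`, `spec_with`, `sens_increase`, `spec_increase`,
#'   `dprime_without`, `dprime_with`, `dprime_increase`; the last row is the
#'   Mean row (`reader == "Mean"`).
#' @export
build_study_report <- function(table) {
  scores <- score_readers(table)
  readers <- unique(scores$reader_id)
  rows <- lapply(readers, function(r) {
    wo <- scores[scores$reader_id == r & scores$condition == "without", ]
    wi <- scores[scores$reader_id == r & scores$condition == "with", ]
    n_pos <- wo$hits + wo$misses
    n_neg <- wo$false_alarms + wo$correct_rejections
    sens_wo <- round_half_up(wo$sensitivity, 1)
    spec_wo <- round_half_up(wo$specificity, 1)
    sens_wi <- round_half_up(wi$sensitivity, 1)
    spec_wi <- round_half_up(wi$specificity, 1)
    d_wo <- dprime(sens_wo / 100, spec_wo / 100, n_pos, n_neg)
    d_wi <- dprime(sens_wi / 100, spec_wi / 100, n_pos, n_neg)
    tibble::tibble(
      reader = r,
      sens_without = sens_wo, spec_without = spec_wo,
      sens_with = sens_wi, spec_with = spec_wi,
      sens_increase = round_half_up(sens_wi - sens_wo, 1),
      spec_increase = round_half_up(spec_wi - spec_wo, 1),
      dprime_without = round_half_up(d_wo, 2),
      dprime_with = round_half_up(d_wi, 2),
      dprime_increase = round_half_up(d_wi - d_wo, 2)
    )
  })
  per_reader <- do.call(rbind, rows)
  rbind(per_reader, report_mean_row(per_reader))
}

report_mean_row <- function(per_reader) {
  m <- function(col) round_half_up(mean(per_reader[[col]]), 2)
  tibble::tibble(
    reader = "Mean",
    sens_without = m("sens_without"), spec_without = m("spec_without"),
    sens_with = m("sens_with"), spec_with = m("spec_with"),
    sens_increase = round_half_up(m("sens_with") - m("sens_without"), 2),
    spec_increase = round_half_up(m("spec_with") - m("spec_without"), 2),
    dprime_without = m("dprime_without"), dprime_with = m("dprime_with"),
    dprime_increase = round_half_up(m("dprime_with") - m("dprime_without"), 2)
  )
}

#' Paired ROC points per reader
#'
#' Maps each reader's two (specificity, sensitivity) pairs to ROC space:
#' `(1 - specificity, sensitivity)` in proportions, one red point per reader
#' without cues and one green point with cues, connected by a segment in the
#' rendered figure.
#'
#' @param report a [build_study_report()] table (the Mean row is dropped) or
#'   any tibble with the same percentage columns.
#' @return tibble in long format: `reader`, `condition`, `fpr`, `tpr`.
#' @export
roc_pair_points <- function(report) {
  report <- report[report$reader != "Mean", , drop = FALSE]
  out <- rbind(
    tibble::tibble(reader = report$reader, condition = "without",
                   fpr = 1 - report$spec_without / 100,
                   tpr = report$sens_without / 100),
    tibble::tibble(reader = report$reader, condition = "with",
                   fpr = 1 - report$spec_with / 100,
                   tpr = report$sens_with / 100)
  )
  stopifnot(all(out$fpr >= 0 & out$fpr <= 1), all(out$tpr >= 0 & out$tpr <= 1))
  out
}

#' Plot paired ROC points
#'
#' @param points a [roc_pair_points()] tibble.
#' @return a ggplot: red points (without cues) joined to green points (with
#'   cues) in the ROC unit square.
#' @export
plot_roc_pairs <- function(points) {
  wide <- merge(points[points$condition == "without", c("reader", "fpr", "tpr")],
                points[points$condition == "with", c("reader", "fpr", "tpr")],
                by = "reader", suffixes = c("_without", "_with"))
  ggplot2::ggplot() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_segment(
      data = wide,
      ggplot2::aes(x = .data$fpr_without, y = .data$tpr_without,
                   xend = .data$fpr_with, yend = .data$tpr_with),
      colour = "black") +
    ggplot2::geom_point(
      data = points,
      ggplot2::aes(x = .data$fpr, y = .data$tpr, colour = .data$condition),
      size = 2.5) +
    ggplot2::scale_colour_manual(
      values = c(without = "red", with = "green3"),
      labels = c(without = "without cues", with = "with cues"),
      name = NULL) +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity") +
    ggplot2::theme_minimal()
}

#' Infer per-class denominators from printed percentages
#'
#' Exhaustive search for the split of `n_total` images into melanomas and
#' nevi such that every printed sensitivity percentage is `100 * k / n_pos`
#' for an integer `k` (to the printed decimal) and every printed specificity
#' percentage is likewise consistent with `n_neg = n_total - n_pos`.
#'
#' @param sens_percents,spec_percents printed percentages (1 decimal).
#' @param n_total total images per reader (default 78).
#' @return tibble of all consistent `(n_melanoma, n_nevus)` pairs.
#' @export
#' @examples
#' infer_denominators(c(71.1, 92.1), c(70, 57.5))
infer_denominators <- function(sens_percents, spec_percents, n_total = 78L) {
  consistent <- function(pcts, n) {
    grid <- round_half_up(100 * (0:n) / n, 1)
    all(vapply(pcts, function(p) any(abs(grid - p) < 1e-9), logical(1)))
  }
  hits <- Filter(function(n) consistent(sens_percents, n) &&
                             consistent(spec_percents, n_total - n),
                 seq_len(n_total - 1))
  tibble::tibble(n_melanoma = as.integer(hits),
                 n_nevus = as.integer(n_total - hits))
}

#' Reconstruct a response table from printed percentages
#'
#' Converts each reader's printed sensitivity/specificity percentages back to
#' integer confusion counts (given the per-class denominators) and lays them
#' out as a paired response table. Which individual images are correct is not
#' identifiable from the margins, so correct decisions are assigned to the
#' first images of each class; every marginal statistic (and hence the whole
#' report) is invariant to that assignment.
#'
#' @param summary tibble with columns `reader`, `sens_without`,
#'   `spec_without`, `sens_with`, `spec_with` (percentages; a `reader ==
#'   "Mean"` row is dropped).
#' @param n_melanoma,n_nevus per-class denominators (defaults 38 and 40, see
#'   [infer_denominators()]).
#' @return a response table tibble.
#' @export
reconstruct_response_table <- function(summary, n_melanoma = 38L,
                                       n_nevus = 40L) {
  summary <- summary[summary$reader != "Mean", , drop = FALSE]
  truth <- rep(c("melanoma", "nevus"), c(n_melanoma, n_nevus))
  image_id <- c(sprintf("mel_%02d", seq_len(n_melanoma)),
                sprintf("nev_%02d", seq_len(n_nevus)))
  decisions <- function(sens_pct, spec_pct) {
    hits <- as.integer(round_half_up(sens_pct / 100 * n_melanoma))
    cr <- as.integer(round_half_up(spec_pct / 100 * n_nevus))
    c(rep(c("melanoma", "nevus"), c(hits, n_melanoma - hits)),
      rep(c("nevus", "melanoma"), c(cr, n_nevus - cr)))
  }
  rows <- lapply(seq_len(nrow(summary)), function(i) {
    tibble::tibble(
      reader_id = summary$reader[i],
      image_id = image_id,
      truth = truth,
      decision_without = decisions(summary$sens_without[i],
                                   summary$spec_without[i]),
      decision_with = decisions(summary$sens_with[i], summary$spec_with[i])
    )
  })
  do.call(rbind, rows)
}

#' Published ten-reader study summary
#'
#' The printed accuracy table of a published paired reader study of melanoma
#' versus clinically atypical nevus dermoscopy screening (ten readers, 78
#' images read without and then with imaging-biomarker cues), shipped with
#' the package as reference input data. Columns follow
#' [build_study_report()]; the final row is the printed Mean row.
#'
#' @return tibble with 11 rows (10 readers + Mean) and the printed
#'   percentage, increase and d' columns.
#' @export
#' @examples
#' published_reader_summary()$dprime_without
published_reader_summary <- function() {
  path <- system.file("extdata", "reader_study_summary.csv",
                      package = "clocksweep", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
}
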