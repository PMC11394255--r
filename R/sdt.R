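# Signal-detection scoring of paired reader studies. Melanoma is the positive
# class throughout: sensitivity = hits / melanomas, specificity = correct
# rejections / nevi, and discriminability is the equal-variance Gaussian
# d' = z(hit rate) - z(false-alarm rate).

#' Equal-variance Gaussian discriminability index
#'
#' `d' = z(sensitivity) - z(1 - specificity)` with `z` the standard-normal
#' quantile. Rates of exactly 0 or 1 are replaced by `1/(2n)` or
#' `1 - 1/(2n)` for the corresponding class before transforming (the standard
#' extreme-rate correction); the class size is then required.
#'
#' @param sensitivity,specificity proportions in `[0, 1]` (vectorized).
#' @param n_pos,n_neg class sizes (melanomas / nevi), needed only when the
#'   corresponding rate is exactly 0 or 1.
#' @return numeric vector of d' values.
#' @export
#' @examples
#' dprime(0.711, 0.70) # 1.08
dprime <- function(sensitivity, specificity, n_pos = NULL, n_neg = NULL) {
  stopifnot(all(sensitivity >= 0 & sensitivity <= 1),
            all(specificity >= 0 & specificity <= 1))
  fix_rate <- function(rate, n, what) {
    extreme <- rate == 0 | rate == 1
    if (any(extreme)) {
      if (is.null(n)) {
        stop(what, " of exactly 0 or 1 requires the class size for the ",
             "1/(2n) correction", call. = FALSE)
      }
      rate[extreme] <- pmin(pmax(rate[extreme], 1 / (2 * n)), 1 - 1 / (2 * n))
    }
    rate
  }
  hit <- fix_rate(sensitivity, n_pos, "sensitivity")
  fa <- 1 - fix_rate(specificity, n_neg, "specificity")
  stats::qnorm(hit) - stats::qnorm(fa)
}

# confusion counts for one reader/condition; melanoma = positive class
tally_reader <- function(records, condition) {
  dec <- records[[paste0("decision_", condition)]]
  pos <- records$truth == "melanoma"
  c(hits = sum(pos & dec == "melanoma"),
    misses = sum(pos & dec == "nevus"),
    false_alarms = sum(!pos & dec == "melanoma"),
    correct_rejections = sum(!pos & dec == "nevus"))
}

#' Score one reader in one condition
#'
#' Tallies the confusion counts for a reader against the ground-truth labels
#' and derives sensitivity, specificity (percentages) and d'.
#'
#' @param table a response table (see [simulate_reader_responses()] /
#'   [read_response_table()]).
#' @param reader_id reader to score.
#' @param condition `"without"` or `"with"`.
#' @return one-row tibble: `reader_id`, `condition`, the four counts,
#'   `sensitivity`, `specificity` (in percent), `dprime`.
#' @export
score_reader <- function(table, reader_id, condition = c("without", "with")) {
  condition <- match.arg(condition)
  records <- table[table$reader_id == reader_id, , drop = FALSE]
  if (!nrow(records)) stop("no records for reader ", reader_id, call. = FALSE)
  n <- tally_reader(records, condition)
  n_pos <- n[["hits"]] + n[["misses"]]
  n_neg <- n[["false_alarms"]] + n[["correct_rejections"]]
  sens <- n[["hits"]] / n_pos
  spec <- n[["correct_rejections"]] / n_neg
  tibble::tibble(
    reader_id = reader_id, condition = condition,
    hits = n[["hits"]], misses = n[["misses"]],
    false_alarms = n[["false_alarms"]],
    correct_rejections = n[["correct_rejections"]],
    sensitivity = 100 * sens, specificity = 100 * spec,
    dprime = dprime(sens, spec, n_pos = n_pos, n_neg = n_neg)
  )
}

#' Score all readers in both conditions
#'
#' @param table a response table.
#' @return tibble with one row per reader and condition (see
#'   [score_reader()]).
#' @export
score_readers <- function(table) {
  validate_response_table(table)
  readers <- unique(table$reader_id)
  rows <- lapply(readers, function(r) {
    rbind(score_reader(table, r, "without"), score_reader(table, r, "with"))
  })
  do.call(rbind, rows)
}

#' Matched-sample (paired) t-test over readers
#'
#' Student's t-test on the per-reader with-minus-without differences,
#' `df = n - 1`. The one-sided alternative tests for an increase with cues.
#'
#' @param values_without,values_with equal-length numeric vectors (one value
#'   per reader).
#' @param sidedness `"two"` (default) or `"one"`.
#' @param metric label carried through to the result.
#' @return object of class `paired_comparison`: `metric`, `differences`,
#'   `mean_diff`, `sd_diff` (sample SD), `t_statistic`, `df`, `p_value`,
#'   `sidedness`.
#' @export
#' @examples
#' paired_test(c(10, 12, 9), c(12, 15, 11))$p_value
paired_test <- function(values_without, values_with,
                        sidedness = c("two", "one"), metric = "") {
  sidedness <- match.arg(sidedness)
  stopifnot(length(values_without) == length(values_with),
            length(values_without) >= 2)
  d <- values_with - values_without
  if (stats::sd(d) == 0) {
    stop("degenerate paired test: differences have zero variance",
         call. = FALSE)
  }
  tt <- stats::t.test(values_with, values_without, paired = TRUE,
                      alternative = if (sidedness == "two") "two.sided"
                                    else "greater")
  structure(
    list(metric = metric,
         differences = d,
         mean_diff = mean(d),
         sd_diff = stats::sd(d),
         t_statistic = unname(tt$statistic),
         df = unname(tt$parameter),
         p_value = tt$p.value,
         sidedness = sidedness),
    class = "paired_comparison"
  )
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired_comparison>%s mean diff %.3f (SD %.3f), t(%d) = %.3f, %s-sided p = %.4g\n",
              if (nzchar(x$metric)) paste0(" ", x$metric, ":") else "",
              x$mean_diff, x$sd_diff, x$df, x$t_statistic, x$sidedness,
              x$p_value))
  invisible(x)
}
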