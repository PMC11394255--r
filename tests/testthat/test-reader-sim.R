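# Simulated paired readers under the equal-variance Gaussian evidence model:
# table invariants, closed-form operating points, parameter recovery.

test_that("response tables satisfy the paired-design invariants", {
  spec <- reader_spec(n_readers = 3, n_melanoma = 5, n_nevus = 6, seed = 2L)
  tab <- simulate_reader_responses(spec)
  expect_equal(nrow(tab), 3 * 11)
  expect_equal(anyDuplicated(tab[c("reader_id", "image_id")]), 0L)
  expect_true(all(tab$truth %in% c("melanoma", "nevus")))
  expect_true(all(!is.na(tab$decision_without) & !is.na(tab$decision_with)))
  expect_silent(validate_response_table(tab))
  # truth labels shared across readers
  split_truth <- split(tab$truth, tab$reader_id)
  expect_true(all(vapply(split_truth, identical, logical(1), split_truth[[1]])))
})

test_that("operating points match the closed-form equal-variance model", {
  # chance reader: d' = 0, criterion 0 -> sensitivity = specificity = 50%
  n <- 20000L
  tab <- simulate_reader_responses(reader_spec(
    n_readers = 1, n_melanoma = n, n_nevus = n,
    dprime_without = 0, dprime_with = 0, criterion = 0, seed = 3L))
  sc <- score_reader(tab, "reader_01", "without")
  se <- 100 * sqrt(0.25 / n)
  expect_lt(abs(sc$sensitivity - 50), 3 * se)
  expect_lt(abs(sc$specificity - 50), 3 * se)

  # d' = 3, criterion 1.5 -> sensitivity = specificity = pnorm(1.5) = 0.933
  tab <- simulate_reader_responses(reader_spec(
    n_readers = 1, n_melanoma = n, n_nevus = n,
    dprime_without = 3, dprime_with = 3, criterion = 1.5, seed = 4L))
  sc <- score_reader(tab, "reader_01", "with")
  p <- pnorm(1.5)
  se <- 100 * sqrt(p * (1 - p) / n)
  expect_lt(abs(sc$sensitivity - 100 * p), 3 * se)
  expect_lt(abs(sc$specificity - 100 * p), 3 * se)
})

test_that("estimated d-prime recovers the generating d-prime", {
  # analytic MC standard error of the d' estimator via the delta method
  dprime_se <- function(d, c, n_pos, n_neg) {
    h <- pnorm(d - c)
    f <- pnorm(-c)
    sqrt(h * (1 - h) / (n_pos * dnorm(qnorm(h))^2) +
         f * (1 - f) / (n_neg * dnorm(qnorm(f))^2))
  }
  n <- 10000L
  spec <- reader_spec(n_readers = 4, n_melanoma = n, n_nevus = n,
                      dprime_without = 0.94, dprime_with = 1.41, seed = 5L)
  tab <- simulate_reader_responses(spec)
  sc <- score_readers(tab)
  for (i in 1:4) {
    id <- sprintf("reader_%02d", i)
    est_wo <- sc$dprime[sc$reader_id == id & sc$condition == "without"]
    est_wi <- sc$dprime[sc$reader_id == id & sc$condition == "with"]
    expect_lt(abs(est_wo - 0.94), 3 * dprime_se(0.94, 0.47, n, n))
    expect_lt(abs(est_wi - 1.41), 3 * dprime_se(1.41, 0.47, n, n))
  }
})

test_that("reader specs are validated and recycled", {
  expect_error(reader_spec(n_readers = 0), "n_readers")
  expect_error(reader_spec(dprime_without = -1), "dprime_without")
  spec <- reader_spec(n_readers = 3, dprime_without = c(0.5, 1))
  expect_length(spec$dprime_without, 3)
  expect_equal(spec$criterion, spec$dprime_without / 2)
})
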