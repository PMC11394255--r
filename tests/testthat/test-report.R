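# Study report layout, denominator inference, count reconstruction and
# paired ROC points.

test_that("denominator inference recovers the 38/40 split", {
  cols <- published_columns()
  cand <- infer_denominators(c(cols$sens_without, cols$sens_with),
                             c(cols$spec_without, cols$spec_with))
  expect_equal(nrow(cand), 1)
  expect_equal(cand$n_melanoma, 38L)
  expect_equal(cand$n_nevus, 40L)
  # a coarser percentage set is compatible with several splits
  loose <- infer_denominators(c(50, 75), c(50, 75), n_total = 16)
  expect_gt(nrow(loose), 1)
})

test_that("reconstruction round-trips printed percentages through scoring", {
  tab <- published_reader_summary()
  rt <- reconstruct_response_table(tab)
  expect_silent(validate_response_table(rt))
  expect_equal(nrow(rt), 10 * 78)
  rep <- build_study_report(rt)
  readers <- rep[rep$reader != "Mean", ]
  pub <- tab[tab$reader != "Mean", ]
  for (col in c("sens_without", "spec_without", "sens_with", "spec_with")) {
    expect_equal(readers[[col]], pub[[col]])
  }
})

test_that("report mean row averages the rounded per-reader cells", {
  rt <- reconstruct_response_table(published_reader_summary())
  rep <- build_study_report(rt)
  readers <- rep[rep$reader != "Mean", ]
  mrow <- rep[rep$reader == "Mean", ]
  expect_equal(mrow$sens_without, round(mean(readers$sens_without), 2))
  expect_equal(mrow$dprime_with,
               clocksweep:::round_half_up(mean(readers$dprime_with), 2))
  expect_equal(mrow$sens_increase, mrow$sens_with - mrow$sens_without)
})

test_that("a perfect reader hits the corrected d-prime ceiling", {
  rt <- reconstruct_response_table(
    tibble::tibble(reader = "ace", sens_without = 100, spec_without = 100,
                   sens_with = 100, spec_with = 100))
  rep <- build_study_report(rt)
  ceiling_d <- qnorm(1 - 1 / 76) - qnorm(1 / 80)
  expect_equal(rep$dprime_without[1],
               clocksweep:::round_half_up(ceiling_d, 2))
})

test_that("roc_pair_points maps readers into the ROC unit square", {
  tab <- published_reader_summary()
  pts <- roc_pair_points(tab)
  expect_equal(nrow(pts), 20)
  expect_true(all(pts$fpr >= 0 & pts$fpr <= 1 & pts$tpr >= 0 & pts$tpr <= 1))
  r1 <- pts[pts$reader == tab$reader[1], ]
  expect_equal(r1$fpr[r1$condition == "without"], 0.30)
  expect_equal(r1$tpr[r1$condition == "without"], 0.711)
  expect_equal(r1$fpr[r1$condition == "with"], 0.225)
  expect_equal(r1$tpr[r1$condition == "with"], 0.816)
  # a no-change reader yields a zero-length segment
  same <- roc_pair_points(tibble::tibble(
    reader = "static", sens_without = 70, spec_without = 60,
    sens_with = 70, spec_with = 60))
  expect_equal(same$fpr[1], same$fpr[2])
  expect_equal(same$tpr[1], same$tpr[2])
  expect_s3_class(plot_roc_pairs(pts), "ggplot")
})

test_that("simulated studies flow through the report unchanged", {
  tab <- simulate_reader_responses(reader_spec(n_readers = 3, seed = 9L))
  rep <- build_study_report(tab)
  expect_equal(nrow(rep), 4)
  expect_equal(rep$reader[4], "Mean")
  expect_true(all(rep$sens_without >= 0 & rep$sens_without <= 100))
})
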