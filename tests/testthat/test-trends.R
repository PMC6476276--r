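mk_posts <- function(ts, cls) {
  data.frame(post_id = paste0("p", seq_along(ts)), timestamp = ts,
             text = "x", true_class = cls, predicted_class = NA_character_,
             stringsAsFactors = FALSE)
}

test_that("binning conserves counts and uses right-open bins", {
  cfg <- trend_config(source = "true")
  ten <- mk_posts(seq(0, 9000, 1000), rep("positive", 10))
  bc <- bin_counts(ten, cfg)
  expect_equal(sum(bc$counts), 10)
  expect_equal(as.numeric(bc$counts[1, c("positive", "negative", "neutral")]),
               c(10, 0, 0))
  # boundary post counts in the later bin
  edge <- mk_posts(c(86399, 86400), c("positive", "positive"))
  bc <- bin_counts(edge, cfg)
  expect_equal(as.numeric(bc$counts[, "positive"]), c(1, 1))
  # conservation on a random batch
  set.seed(3)
  n <- 1000
  rnd <- mk_posts(sample(0:(20 * 86400), n, replace = TRUE),
                  sample(default_classes(), n, replace = TRUE))
  expect_equal(sum(bin_counts(rnd, cfg)$counts), n)
  # strict about missing labels
  bad <- rnd; bad$true_class[5] <- NA
  expect_error(bin_counts(bad, cfg), "without a 'true' class")
})

test_that("trailing moving average obeys the prefix rule", {
  expect_equal(moving_average(rep(4, 10), 7), rep(4, 10))
  x <- c(3, 1, 4, 1, 5)
  expect_equal(moving_average(x, 1), x)
  expect_equal(moving_average(c(0, 0, 7), 7)[3], 7 / 3)
  expect_equal(moving_average(x, 3), c(3, 2, 8 / 3, 2, 10 / 3))
})

test_that("rolling ratio is positive over polar with a minimum-count guard", {
  cfg <- trend_config(ratio_window = 3 * 86400, min_polar_count = 1,
                      source = "true")
  P <- c(10, 10, 10, 0, 0); N <- rep(0, 5)
  expect_equal(rolling_ratio(P, N, cfg), rep(1, 5))
  expect_equal(rolling_ratio(c(5, 5, 5), c(5, 5, 5), cfg), rep(0.5, 3))
  expect_equal(rolling_ratio(c(30, 0, 0), c(10, 0, 0), cfg), rep(0.75, 3))
  guarded <- trend_config(ratio_window = 86400, min_polar_count = 10,
                          source = "true")
  r <- rolling_ratio(c(30, 4), c(10, 4), guarded)
  expect_equal(r, c(0.75, NA))
})

test_that("the sentiment index is an exact z-normalization of the ratio", {
  cfg <- trend_config()
  si <- sentiment_index(c(0.2, 0.5, 0.8), cfg)
  expect_equal(si$mu, 0.5)
  expect_equal(si$sigma, sqrt(0.06))
  expect_equal(si$index, c(-1, 0, 1) * 1.22474, tolerance = 1e-5)
  # normalization identity for arbitrary series with gaps
  set.seed(21)
  r <- runif(50); r[c(3, 17)] <- NA
  si <- sentiment_index(r, cfg)
  ok <- !is.na(si$index)
  expect_lt(abs(mean(si$index[ok])), 1e-9)
  expect_lt(abs(sqrt(mean(si$index[ok]^2)) - 1), 1e-9)
  # degenerate constant ratio
  expect_warning(flat <- sentiment_index(rep(0.4, 5), cfg), "constant")
  expect_equal(flat$index, rep(0, 5))
  expect_error(sentiment_index(c(0.5, NA, NA), cfg), "at least 2")
})

test_that("lowess smoothing preserves lines and constants", {
  cfg <- trend_config(lowess_frac = 0.3)
  t <- (0:29) * 86400
  lin <- 0.002 * (0:29) - 1
  expect_equal(lowess_index(lin, t, cfg), lin, tolerance = 1e-6)
  expect_equal(lowess_index(rep(0.7, 30), t, cfg), rep(0.7, 30),
               tolerance = 1e-9)
  expect_error(lowess_index(c(1:5, rep(NA, 25)), t, cfg), "at least 10")
  # NA positions stay NA
  y <- lin; y[4] <- NA
  sm <- lowess_index(y, t, cfg)
  expect_true(is.na(sm[4]) && !anyNA(sm[-4]))
})

test_that("a step in the index is smoothed to a monotone transition", {
  cfg <- trend_config(lowess_frac = 0.2)
  t <- (0:59) * 86400
  step <- c(rep(-1, 30), rep(1, 30))
  sm <- lowess_index(step, t, cfg)
  region <- 21:40
  expect_true(all(diff(sm[region]) >= -1e-9))
  # reference fit at the same span agrees
  ref <- stats::lowess(t, step, f = 0.2, iter = 2)$y
  expect_equal(sm, ref, tolerance = 1e-12)
})

test_that("trend_report chains the stages and writes one CSV row per bin", {
  posts <- generate_stream(stream_config(volume_rate = 120,
                                         duration_days = 40, seed = 13))
  f <- withr::local_tempfile(fileext = ".csv")
  tr <- trend_report(posts, trend_config(source = "true"), csv_path = f)
  csv <- utils::read.csv(f)
  expect_equal(nrow(csv), length(tr$bins))
  expect_equal(names(csv), c("bin_start", "P", "N", "U", "ma_P", "ma_N",
                             "ma_U", "r", "index", "index_smooth"))
  expect_equal(sum(tr$counts), length(posts))
  # no polar posts at all -> undefined ratio everywhere -> error
  neu <- mk_posts((0:49) * 86400, rep("neutral", 50))
  expect_error(trend_report(neu, trend_config(source = "true")),
               "at least 2")
})
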