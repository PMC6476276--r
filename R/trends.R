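#' Configure the trend analytics
#'
#' Defaults mirror a monitoring setup: daily bins, a 1-week moving average
#' of per-class counts, and the positive-among-polar ratio computed over a
#' trailing 1-month window. All windows are trailing (right-aligned), so
#' the analysis is causal and can run prospectively.
#'
#' @param bin_width Bin width in seconds (default 1 day).
#' @param ma_window Moving-average window in seconds (default 7 days); must
#'   be a positive multiple of `bin_width`.
#' @param ratio_window Rolling-ratio window in seconds (default 30 days);
#'   must be a positive multiple of `bin_width`.
#' @param min_polar_count Minimum positive+negative posts in a window for
#'   the ratio to be defined (default 10); guards against empty windows.
#' @param lowess_frac Lowess span as a fraction of points (default 0.1).
#' @param sigma_floor Below this standard deviation the index degenerates
#'   to all zeros (with a warning) instead of dividing by ~0.
#' @param source Which class column drives the counts: `"predicted"`,
#'   `"true"`, or `"auto"` (predicted when available, else true). Posts
#'   without the requested class are an error.
#' @return A list of class `"trend_config"`.
#' @export
trend_config <- function(bin_width = 86400, ma_window = 7 * 86400,
                         ratio_window = 30 * 86400, min_polar_count = 10,
                         lowess_frac = 0.1, sigma_floor = 1e-12,
                         source = c("auto", "predicted", "true")) {
  assert_that(bin_width > 0, "bin_width must be positive")
  assert_that(ma_window %% bin_width == 0 && ma_window >= bin_width,
              "ma_window must be a positive multiple of bin_width")
  assert_that(ratio_window %% bin_width == 0 && ratio_window >= bin_width,
              "ratio_window must be a positive multiple of bin_width")
  assert_that(min_polar_count >= 0, "min_polar_count must be non-negative")
  assert_that(lowess_frac > 0 && lowess_frac <= 1,
              "lowess_frac must be in (0,1]")
  structure(list(bin_width = bin_width, ma_window = ma_window,
                 ratio_window = ratio_window,
                 min_polar_count = min_polar_count,
                 lowess_frac = lowess_frac, sigma_floor = sigma_floor,
                 source = match.arg(source)),
            class = "trend_config")
}

post_class_column <- function(df, source) {
  cls <- switch(source,
                predicted = df$predicted_class,
                true = df$true_class,
                auto = ifelse(!is.na(df$predicted_class),
                              df$predicted_class, df$true_class))
  if (any(is.na(cls))) {
    stop("posts without a '", source, "' class label cannot be binned",
         call. = FALSE)
  }
  cls
}

#' Bin posts into per-class counts
#'
#' Right-open bins `[t, t + bin_width)` aligned to multiples of the bin
#' width; a post exactly on a boundary counts in the later bin. The total
#' count is conserved: every post in range lands in exactly one cell.
#'
#' @param posts List of posts or a [posts_frame()] data.frame.
#' @param config A [trend_config()].
#' @return List with `bins` (bin start times) and `counts` (bins x classes
#'   integer matrix; columns are the classes present plus the three default
#'   classes).
#' @export
bin_counts <- function(posts, config = trend_config()) {
  df <- if (is.data.frame(posts)) posts else posts_frame(posts)
  assert_that(nrow(df) > 0, "no posts to bin")
  cls <- post_class_column(df, config$source)
  w <- config$bin_width
  b0 <- floor(min(df$timestamp) / w)
  b1 <- floor(max(df$timestamp) / w)
  bins <- (b0:b1) * w
  classes <- union(default_classes(), sort(unique(cls)))
  counts <- matrix(0L, length(bins), length(classes),
                   dimnames = list(NULL, classes))
  bi <- floor(df$timestamp / w) - b0 + 1
  for (k in seq_along(bi)) {
    counts[bi[k], cls[k]] <- counts[bi[k], cls[k]] + 1L
  }
  list(bins = bins, counts = counts)
}

#' Trailing moving average
#'
#' Mean over the last `k` bins; the first `k - 1` bins average over the
#' available prefix.
#'
#' @param x Numeric series.
#' @param k Window length in bins (>= 1).
#' @return Smoothed series, same length as `x`.
#' @export
moving_average <- function(x, k) {
  assert_that(k >= 1, "window must be >= 1 bins")
  n <- length(x)
  cs <- cumsum(x)
  lag <- c(rep(0, min(k, n)), cs[seq_len(max(n - k, 0))])
  (cs - lag) / pmin(seq_len(n), k)
}

trailing_sum <- function(x, k) {
  n <- length(x)
  cs <- cumsum(x)
  cs - c(rep(0, min(k, n)), cs[seq_len(max(n - k, 0))])
}

#' Rolling positive-among-polar ratio
#'
#' `r_t = sum(P) / (sum(P) + sum(N))` over the trailing ratio window, where
#' P and N are the per-bin positive and negative counts; neutral posts are
#' excluded by definition. Windows with fewer than `min_polar_count` polar
#' posts leave `r_t` undefined (`NA`), carried as missing downstream.
#'
#' @param P,N Aligned per-bin positive and negative counts.
#' @param config A [trend_config()].
#' @return Numeric series of ratios in \[0, 1\] with `NA` where undefined.
#' @export
rolling_ratio <- function(P, N, config = trend_config()) {
  assert_that(length(P) == length(N), "P and N must be aligned")
  k <- config$ratio_window / config$bin_width
  sp <- trailing_sum(P, k)
  sn <- trailing_sum(N, k)
  tot <- sp + sn
  r <- ifelse(tot >= max(config$min_polar_count, 1), sp / tot, NA_real_)
  as.numeric(r)
}

#' Normalized sentiment index
#'
#' `(r - mu) / sigma` where `mu` and `sigma` are the mean and population
#' standard deviation of the defined ratio values, so over the defined bins
#' the index has mean 0 and population standard deviation 1 — a trend
#' signal invariant to the stream's volume. If `sigma` is at or below the
#' configured floor (a constant ratio), the index is all zeros and a
#' warning is raised.
#'
#' @param r Ratio series from [rolling_ratio()] (`NA` = undefined).
#' @param config A [trend_config()].
#' @return List with `mu`, `sigma`, and the `index` series (NA where `r`
#'   is undefined).
#' @export
sentiment_index <- function(r, config = trend_config()) {
  ok <- !is.na(r)
  assert_that(sum(ok) >= 2, "need at least 2 defined ratio values")
  mu <- mean(r[ok])
  sigma <- sqrt(mean((r[ok] - mu)^2))
  if (sigma <= config$sigma_floor) {
    warning("ratio series is constant (sigma <= floor); index set to 0")
    index <- ifelse(ok, 0, NA_real_)
  } else {
    index <- (r - mu) / sigma
  }
  list(mu = mu, sigma = sigma, index = as.numeric(index))
}

#' Lowess-smoothed index
#'
#' Locally weighted linear regression (tricube weights, 2 robustness
#' iterations) of the index against bin time at span `lowess_frac`,
#' evaluated at every defined bin. Lowess reproduces straight lines
#' exactly, so a linear trend passes through unchanged.
#'
#' @param index Index series (`NA` = undefined bins).
#' @param times Bin start times aligned with `index`.
#' @param config A [trend_config()].
#' @return Smoothed series, `NA` where the index is undefined.
#' @export
lowess_index <- function(index, times, config = trend_config()) {
  assert_that(length(index) == length(times),
              "index and times must be aligned")
  ok <- !is.na(index)
  assert_that(sum(ok) >= 10, "need at least 10 defined index values")
  fit <- stats::lowess(times[ok], index[ok], f = config$lowess_frac,
                       iter = 2)
  out <- rep(NA_real_, length(index))
  # lowess returns values ordered by x; map back to the defined positions
  out[which(ok)[order(times[ok])]] <- fit$y
  out
}

#' Full trend report
#'
#' Runs the whole analytics chain — binning, per-class 1-week moving
#' averages, the 1-month rolling positive-among-polar ratio, the
#' normalized sentiment index and its lowess fit — and optionally writes a
#' tidy CSV (one row per bin) and a stacked-counts + index plot.
#'
#' @param posts List of posts or a [posts_frame()] data.frame.
#' @param config A [trend_config()].
#' @param csv_path Optional output CSV path.
#' @param plot_path Optional output plot path (requires ggplot2).
#' @return A `"sentiment_series"` list: `bins`, `counts`, `ma`, `r`, `mu`,
#'   `sigma`, `index`, `index_smooth`, and the tidy `table`.
#' @export
trend_report <- function(posts, config = trend_config(), csv_path = NULL,
                         plot_path = NULL) {
  bc <- bin_counts(posts, config)
  k_ma <- config$ma_window / config$bin_width
  ma <- apply(bc$counts, 2, moving_average, k = k_ma)
  r <- rolling_ratio(bc$counts[, "positive"], bc$counts[, "negative"],
                     config)
  si <- sentiment_index(r, config)
  smooth <- lowess_index(si$index, bc$bins, config)
  tab <- data.frame(bin_start = bc$bins,
                    P = bc$counts[, "positive"],
                    N = bc$counts[, "negative"],
                    U = bc$counts[, "neutral"],
                    ma_P = ma[, "positive"],
                    ma_N = ma[, "negative"],
                    ma_U = ma[, "neutral"],
                    r = r, index = si$index, index_smooth = smooth)
  out <- structure(list(bins = bc$bins, counts = bc$counts, ma = ma, r = r,
                        mu = si$mu, sigma = si$sigma, index = si$index,
                        index_smooth = smooth, table = tab),
                   class = "sentiment_series")
  if (!is.null(csv_path)) {
    utils::write.csv(tab, csv_path, row.names = FALSE, na = "")
  }
  if (!is.null(plot_path)) plot_sentiment_series(out, plot_path)
  out
}

#' Plot a sentiment series
#'
#' Stacked per-class moving-average counts with the smoothed sentiment
#' index overlaid on a secondary axis.
#'
#' @param series A `"sentiment_series"` from [trend_report()].
#' @param path Output image path (format from the extension).
#' @return `path`, invisibly.
#' @export
plot_sentiment_series <- function(series, path) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tab <- series$table
  long <- data.frame(
    bin_start = rep(tab$bin_start, 3),
    class = rep(c("positive", "negative", "neutral"),
                each = nrow(tab)),
    ma = c(tab$ma_P, tab$ma_N, tab$ma_U))
  scale <- max(long$ma, na.rm = TRUE) / max(abs(tab$index_smooth), 1,
                                            na.rm = TRUE)
  g <- ggplot2::ggplot(long, ggplot2::aes(
    x = bin_start, y = ma, fill = class)) +
    ggplot2::geom_area(position = "stack", alpha = 0.7) +
    ggplot2::geom_line(
      data = tab[!is.na(tab$index_smooth), ],
      ggplot2::aes(x = bin_start, y = index_smooth * scale),
      inherit.aes = FALSE, linewidth = 0.8) +
    ggplot2::scale_y_continuous(
      name = "posts per day (1-week MA)",
      sec.axis = ggplot2::sec_axis(~ . / scale, name = "sentiment index")) +
    ggplot2::labs(x = "time (epoch seconds)", fill = "class")
  ggplot2::ggsave(path, g, width = 9, height = 4, dpi = 150)
  invisible(path)
}
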