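#' Configure a synthetic post stream
#'
#' Defines the statistical structure the downstream analysis assumes: a
#' class mixture that may change over time, day-scale volume variation via
#' an inhomogeneous Poisson process, and bag-of-tokens text whose class
#' signal strength is controlled by the share of class-specific tokens per
#' post. Every post carries one keyword token by default so it passes the
#' keyword filter; `nonmatch_fraction` generates posts without it to
#' exercise the filter's reject branch.
#'
#' @param classes Label classes (default [default_classes()]).
#' @param class_weights Probability vector over `classes` (recycled over
#'   time) or a function `day -> probability vector`.
#' @param volume_rate Expected posts per day: a non-negative scalar or a
#'   function `day -> rate`.
#' @param duration_days Positive integer number of days.
#' @param tokens_per_post Integer range `c(min, max)` of tokens per post.
#' @param class_token_share Fraction of a post's tokens drawn from its
#'   class's private vocabulary; the rest are shared background tokens.
#'   Controls classifier difficulty.
#' @param vocab Optional list with per-class token vectors and a
#'   `background` vector; autogenerated when `NULL`.
#' @param class_vocab_size,background_vocab_size Sizes of the autogenerated
#'   vocabularies.
#' @param keyword_tokens Tokens guaranteed present in matching posts.
#' @param nonmatch_fraction Fraction of posts generated without a keyword
#'   token.
#' @param start_time Epoch seconds of day 0 (00:00 UTC).
#' @param seed Integer RNG seed; identical seeds give byte-identical streams.
#' @return A list of class `"stream_config"`.
#' @export
stream_config <- function(classes = default_classes(),
                          class_weights = c(1, 1, 1) / 3,
                          volume_rate = 200,
                          duration_days = 60,
                          tokens_per_post = c(6, 12),
                          class_token_share = 0.3,
                          vocab = NULL,
                          class_vocab_size = 40,
                          background_vocab_size = 150,
                          keyword_tokens = "vaccine",
                          nonmatch_fraction = 0,
                          start_time = 0,
                          seed = 1) {
  assert_that(length(classes) >= 2, "need at least two classes")
  assert_that(duration_days >= 1, "duration_days must be positive")
  assert_that(is.function(volume_rate) || all(volume_rate >= 0),
              "volume_rate must be non-negative")
  assert_that(length(tokens_per_post) == 2 &&
                tokens_per_post[1] >= 1 &&
                tokens_per_post[2] >= tokens_per_post[1],
              "tokens_per_post must be a valid integer range")
  assert_that(class_token_share >= 0 && class_token_share <= 1,
              "class_token_share must be in [0,1]")
  assert_that(nonmatch_fraction >= 0 && nonmatch_fraction < 1,
              "nonmatch_fraction must be in [0,1)")
  if (is.null(vocab)) {
    vocab <- c(
      stats::setNames(lapply(seq_along(classes), function(i) {
        sprintf("%stok%03d", substr(classes[i], 1, 3), seq_len(class_vocab_size))
      }), classes),
      list(background = sprintf("bg%03d", seq_len(background_vocab_size))))
  }
  assert_that(all(classes %in% names(vocab)) &&
                all(lengths(vocab[classes]) > 0) &&
                length(vocab$background) > 0,
              "vocab must contain non-empty token lists per class plus 'background'")
  wfun <- if (is.function(class_weights)) {
    class_weights
  } else {
    assert_that(length(class_weights) == length(classes),
                "class_weights length must match classes")
    w0 <- class_weights
    function(day) w0
  }
  cfg <- structure(
    list(classes = classes, class_weights = wfun, volume_rate = volume_rate,
         duration_days = as.integer(duration_days),
         tokens_per_post = as.integer(tokens_per_post),
         class_token_share = class_token_share, vocab = vocab,
         keyword_tokens = keyword_tokens,
         nonmatch_fraction = nonmatch_fraction,
         start_time = as.numeric(start_time), seed = as.integer(seed),
         changepoints = list()),
    class = "stream_config")
  check_stream_weights(cfg)
  cfg
}

check_stream_weights <- function(config) {
  for (day in unique(c(0, seq_len(config$duration_days) - 0.5,
                       config$duration_days))) {
    w <- config$class_weights(day)
    assert_that(length(w) == length(config$classes) &&
                  all(w >= 0) && abs(sum(w) - 1) < 1e-9,
                paste0("class_weights(", day, ") is not a probability vector"))
  }
  invisible(TRUE)
}

#' Inject a distribution changepoint into a stream configuration
#'
#' Returns a configuration whose class mixture equals the old one before
#' `time_days` and `new_weights` afterwards, emulating an abrupt shift in
#' the share of posts per sentiment class.
#'
#' @param config A [stream_config()].
#' @param time_days Changepoint time in days since stream start; must lie
#'   within the stream duration.
#' @param new_weights Probability vector over the configured classes.
#' @return The modified `stream_config`.
#' @export
inject_changepoint <- function(config, time_days, new_weights) {
  assert_that(inherits(config, "stream_config"), "config must be a stream_config")
  assert_that(time_days >= 0 && time_days <= config$duration_days,
              "changepoint time outside stream duration")
  assert_that(length(new_weights) == length(config$classes) &&
                all(new_weights >= 0) && abs(sum(new_weights) - 1) < 1e-9,
              "new_weights must be a probability vector over the classes")
  old <- config$class_weights
  config$class_weights <- function(day) {
    if (day < time_days) old(day) else new_weights
  }
  config$changepoints <- c(config$changepoints,
                           list(list(time_days = time_days,
                                     weights = new_weights)))
  config
}

#' Generate a synthetic post stream
#'
#' Post times follow an inhomogeneous Poisson process (per-day Poisson
#' counts, uniform within-day times); each post's latent `true_class` is
#' drawn from the mixture at its time; text is a bag of class tokens,
#' background tokens and (usually) one keyword token. Deterministic given
#' the config seed.
#'
#' @param config A [stream_config()].
#' @return List of posts with `true_class` set, ordered by time.
#' @export
generate_stream <- function(config) {
  assert_that(inherits(config, "stream_config"), "config must be a stream_config")
  rate_at <- if (is.function(config$volume_rate)) config$volume_rate
             else function(day) config$volume_rate
  set.seed(config$seed)
  posts <- list()
  idx <- 0L
  for (day in seq_len(config$duration_days) - 1L) {
    n <- stats::rpois(1L, rate_at(day))
    if (n == 0L) next
    secs <- sort(floor(stats::runif(n) * 86400))
    for (j in seq_len(n)) {
      idx <- idx + 1L
      t_day <- day + secs[j] / 86400
      w <- config$class_weights(t_day)
      cls <- sample(config$classes, 1L, prob = w)
      k <- sample(seq(config$tokens_per_post[1], config$tokens_per_post[2]), 1L)
      n_cls <- round(config$class_token_share * k)
      toks <- c(sample(config$vocab[[cls]], n_cls, replace = TRUE),
                sample(config$vocab$background, k - n_cls, replace = TRUE))
      toks <- sample(toks)
      if (config$nonmatch_fraction == 0 ||
          stats::runif(1) >= config$nonmatch_fraction) {
        kw <- if (length(config$keyword_tokens) == 1L) config$keyword_tokens
              else sample(config$keyword_tokens, 1L)
        pos <- sample(length(toks) + 1L, 1L)
        toks <- append(toks, kw, after = pos - 1L)
      }
      posts[[idx]] <- post(sprintf("p%07d", idx),
                           config$start_time + day * 86400 + secs[j],
                           paste(toks, collapse = " "),
                           true_class = cls)
    }
  }
  posts
}

#' Create a simulated annotator
#'
#' Answers with the true class according to a row-stochastic confusion
#' matrix. When only `accuracy` is given, the confusion matrix has
#' `accuracy` on the diagonal and the remaining mass spread uniformly over
#' the other classes. Each annotator carries a private RNG stream, so its
#' answers are deterministic given its seed and call sequence.
#'
#' @param user_id Annotator id.
#' @param accuracy Probability of reporting the true class.
#' @param confusion Optional row-stochastic matrix (rows = true class,
#'   columns = reported class), overriding `accuracy`.
#' @param classes Class labels the annotator can report.
#' @param seed Integer seed for the annotator's private RNG.
#' @return An environment of class `"simulated_annotator"`.
#' @export
simulated_annotator <- function(user_id, accuracy = 0.9, confusion = NULL,
                                classes = default_classes(), seed = 1) {
  k <- length(classes)
  if (is.null(confusion)) {
    assert_that(accuracy >= 0 && accuracy <= 1, "accuracy must be in [0,1]")
    confusion <- matrix((1 - accuracy) / (k - 1), k, k,
                        dimnames = list(classes, classes))
    diag(confusion) <- accuracy
  } else {
    assert_that(all(dim(confusion) == c(k, k)) &&
                  all(abs(rowSums(confusion) - 1) < 1e-9) &&
                  all(confusion >= 0),
                "confusion must be a row-stochastic classes x classes matrix")
    dimnames(confusion) <- list(classes, classes)
  }
  ann <- new.env(parent = emptyenv())
  ann$user_id <- as.character(user_id)
  ann$classes <- classes
  ann$confusion <- confusion
  ann$seed <- as.integer(seed)
  ann$state <- NULL
  class(ann) <- "simulated_annotator"
  ann
}

#' Draw one simulated annotation
#'
#' @param annotator A [simulated_annotator()].
#' @param true_class The post's latent class; must be in the annotator's
#'   class set.
#' @return The reported class label.
#' @export
annotate_simulated <- function(annotator, true_class) {
  assert_that(inherits(annotator, "simulated_annotator"),
              "annotator must be a simulated_annotator")
  assert_that(true_class %in% annotator$classes,
              paste0("unknown class: ", true_class))
  with_private_rng(annotator, {
    sample(annotator$classes, 1L, prob = annotator$confusion[true_class, ])
  })
}

#' Flatten a post list to a data frame
#'
#' Convenience accessor used by the trend and learning stages: one row per
#' post with scalar fields only.
#'
#' @param posts List of posts.
#' @return data.frame with columns post_id, timestamp, text, true_class,
#'   predicted_class.
#' @export
posts_frame <- function(posts) {
  pick <- function(f) vapply(posts, function(p) p[[f]] %||% NA_character_, "")
  data.frame(
    post_id = vapply(posts, `[[`, "", "post_id"),
    timestamp = vapply(posts, `[[`, 0, "timestamp"),
    text = vapply(posts, `[[`, "", "text"),
    true_class = pick("true_class"),
    predicted_class = pick("predicted_class"),
    stringsAsFactors = FALSE)
}
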