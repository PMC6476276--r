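#' Configure the active learning loop
#'
#' @param strategy How posts are prioritized for labeling:
#'   `"uncertainty"` (pure uncertainty sampling), `"random"` (uniform
#'   control arm), or `"blended"` (uncertainty blended with recency via the
#'   queue's lambda).
#' @param uncertainty_method Passed to [uncertainty()].
#' @param retrain_every Retrain after this many new consensus labels
#'   (default 100). Consensus labels, not raw annotations, are the unit of
#'   training data.
#' @param budget Total number of consensus labels to collect.
#' @param initial_seed_labels Randomly chosen posts labeled before the
#'   first model is trained (default 60).
#' @param test_fraction Held-out fraction, stratified by true class
#'   (default 0.2); test posts are never queued.
#' @param rng_seed Seed for the loop's randomness (splits, random arm).
#' @return A list of class `"al_config"`.
#' @export
al_config <- function(strategy = c("uncertainty", "random", "blended"),
                      uncertainty_method = "least_confidence",
                      retrain_every = 100, budget = 300,
                      initial_seed_labels = 60, test_fraction = 0.2,
                      rng_seed = 1) {
  assert_that(retrain_every >= 1, "retrain_every must be positive")
  assert_that(budget >= 1, "budget must be positive")
  assert_that(initial_seed_labels >= 1, "initial_seed_labels must be positive")
  assert_that(test_fraction > 0 && test_fraction < 1,
              "test_fraction must be in (0,1)")
  structure(list(strategy = match.arg(strategy),
                 uncertainty_method = uncertainty_method,
                 retrain_every = as.integer(retrain_every),
                 budget = as.integer(budget),
                 initial_seed_labels = as.integer(initial_seed_labels),
                 test_fraction = test_fraction,
                 rng_seed = as.integer(rng_seed)),
            class = "al_config")
}

# Collect one consensus label for pool row `i`, using `nc` annotators chosen
# round-robin starting at `rot`. Returns the labeled_example.
collect_consensus <- function(df, i, annotators, rot, seq, nc) {
  n_ann <- length(annotators)
  idx <- ((rot + seq_len(nc) - 2L) %% n_ann) + 1L
  p <- post(df$post_id[i], df$timestamp[i], df$text[i],
            true_class = df$true_class[i])
  rows <- list()
  for (a in annotators[idx]) {
    res <- run_sequence(seq, p, simulated_answer_fn(a, seq, p$true_class),
                        a$user_id)
    if (res$run$completed) rows[[length(rows) + 1L]] <- res$annotations
  }
  consensus_label(do.call(rbind, rows), seq, n_consensus = nc,
                  text = p$text)
}

#' Run the active learning loop on a synthetic stream
#'
#' Repeats: predict the unlabeled pool, enqueue posts by the configured
#' strategy into the bounded priority queue, serve the top items to
#' `n_consensus` simulated annotators through the question sequence,
#' aggregate consensus labels, and retrain the classifier each time
#' `retrain_every` new labels accrue. Held-out accuracy is recorded after
#' the initial fit (checkpoint 0) and after every retrain. Fully
#' deterministic given the config seeds.
#'
#' @param posts Stream of posts with latent `true_class` (from
#'   [generate_stream()]).
#' @param annotators List of [simulated_annotator()]s; must be at least
#'   `n_consensus` of them.
#' @param config An [al_config()].
#' @param queue_cfg A [queue_config()]; its `n_consensus` and `max_size`
#'   govern labeling, its `lambda_uncertainty`/`tau_recency` apply to the
#'   `"blended"` strategy.
#' @param seq A [question_sequence()] (default the relevance/sentiment
#'   sequence).
#' @param classes Model label set.
#' @return List with `history` (one row per checkpoint: checkpoint,
#'   labels_used, train_size, accuracy, model_version), the final `model`,
#'   the collected `examples`, and `train_post_ids` / `test_post_ids`.
#' @export
active_learning_loop <- function(posts, annotators, config = al_config(),
                                 queue_cfg = queue_config(),
                                 seq = default_question_sequence(),
                                 classes = default_classes()) {
  nc <- queue_cfg$n_consensus
  assert_that(length(annotators) >= nc,
              "annotator pool smaller than n_consensus")
  df <- posts_frame(posts)
  assert_that(!any(is.na(df$true_class)),
              "posts must carry latent true classes")
  set.seed(config$rng_seed)
  n <- nrow(df)
  tokens <- lapply(df$text, tokenize_with_bigrams)

  # stratified held-out split, never queued
  test_idx <- integer(0)
  for (cl in unique(df$true_class)) {
    rows <- which(df$true_class == cl)
    test_idx <- c(test_idx, sample(rows, floor(config$test_fraction *
                                                 length(rows))))
  }
  test_idx <- sort(test_idx)
  pool <- setdiff(seq_len(n), test_idx)

  rot <- 1L
  examples <- list()
  labeled_idx <- integer(0)
  label_one <- function(i) {
    ex <- collect_consensus(df, i, annotators, rot, seq, nc)
    rot <<- rot + nc
    labeled_idx <<- c(labeled_idx, i)
    examples[[length(examples) + 1L]] <<- ex
    ex
  }

  # seed labels: random posts; keep drawing until every class is represented
  seed_order <- sample(pool)
  n_seed <- min(config$initial_seed_labels, length(seed_order))
  for (i in seed_order[seq_len(n_seed)]) label_one(i)
  covered <- function() {
    all(classes %in% vapply(examples, `[[`, "", "label"))
  }
  extra <- n_seed
  while (!covered() && extra < length(seed_order)) {
    extra <- extra + 1L
    label_one(seed_order[extra])
  }

  train_df <- function() {
    data.frame(text = vapply(examples, `[[`, "", "text"),
               label = vapply(examples, `[[`, "", "label"),
               stringsAsFactors = FALSE)
  }
  model <- train_bow(train_df(), classes, prev_version = 0L)
  test_truth <- df$true_class[test_idx]
  evaluate <- function(model) {
    probs <- predict_proba_many(model, tokens[test_idx])
    pred <- classes[max.col(probs, ties.method = "first")]
    evaluate_micro(test_truth, pred)$accuracy
  }
  history <- data.frame(checkpoint = 0L, labels_used = 0L,
                        train_size = model$trained_on,
                        accuracy = evaluate(model),
                        model_version = model$version)

  now <- max(df$timestamp) + 1
  lam <- switch(config$strategy, blended = queue_cfg$lambda_uncertainty, 1)
  qc <- queue_config(max_size = queue_cfg$max_size, n_consensus = nc,
                     lambda_uncertainty = lam,
                     tau_recency = queue_cfg$tau_recency)
  labels_used <- 0L
  checkpoint <- 0L
  while (labels_used < config$budget) {
    avail <- setdiff(pool, labeled_idx)
    if (!length(avail)) break
    probs <- predict_proba_many(model, tokens[avail])
    base <- switch(
      config$strategy,
      random = stats::runif(length(avail)),
      apply(probs, 1, uncertainty, method = config$uncertainty_method))
    state <- queue_state(qc)
    ord <- order(-base)  # enqueue best-first; the bounded queue keeps the top
    for (j in ord) {
      state <- enqueue(queue_item(df$post_id[avail[j]], base[j],
                                  df$timestamp[avail[j]]), state, now)
    }
    n_round <- min(config$retrain_every, config$budget - labels_used)
    for (step in seq_len(n_round)) {
      lead <- annotators[[((rot - 1L) %% length(annotators)) + 1L]]
      item <- next_for_user(lead$user_id, state, now)
      if (is.null(item)) break
      i <- match(item$post_id, df$post_id)
      n_ann <- length(annotators)
      idx <- ((rot + seq_len(nc) - 2L) %% n_ann) + 1L
      p <- post(df$post_id[i], df$timestamp[i], df$text[i],
                true_class = df$true_class[i])
      rows <- list()
      for (a in annotators[idx]) {
        res <- run_sequence(seq, p,
                            simulated_answer_fn(a, seq, p$true_class),
                            a$user_id)
        if (res$run$completed) {
          state <- record_done(a$user_id, item$post_id, state)
          rows[[length(rows) + 1L]] <- res$annotations
        }
      }
      assert_that(item$post_id %in% state$completed,
                  "queue did not retire a fully labeled item")
      examples[[length(examples) + 1L]] <-
        consensus_label(do.call(rbind, rows), seq, n_consensus = nc,
                        text = p$text)
      rot <- rot + nc
      labeled_idx <- c(labeled_idx, i)
      labels_used <- labels_used + 1L
    }
    checkpoint <- checkpoint + 1L
    model <- train_bow(train_df(), classes, prev_version = model$version)
    history <- rbind(history, data.frame(
      checkpoint = checkpoint, labels_used = labels_used,
      train_size = model$trained_on, accuracy = evaluate(model),
      model_version = model$version))
  }
  list(history = history, model = model, examples = examples,
       train_post_ids = df$post_id[labeled_idx],
       test_post_ids = df$post_id[test_idx])
}

#' Standard synthetic fixture for active-learning experiments
#'
#' A 3-class stream of roughly `n_posts` posts over `duration_days` days
#' with uniform class mixture and moderate class-token signal — hard enough
#' that 300-odd labels do not saturate the classifier, so differences
#' between query strategies are measurable.
#'
#' @param seed Stream seed.
#' @param n_posts Approximate stream size (sets the daily Poisson rate).
#' @param duration_days Stream length in days.
#' @return A [stream_config()].
#' @export
al_fixture_config <- function(seed = 1, n_posts = 3000, duration_days = 30) {
  stream_config(volume_rate = n_posts / duration_days,
                duration_days = duration_days,
                class_token_share = 0.25,
                tokens_per_post = c(5, 10),
                seed = seed)
}

#' Compare uncertainty sampling against the random control arm
#'
#' Runs paired simulations: for each seed, one synthetic stream and one
#' annotator pool are generated, and the active learning loop is run once
#' per strategy on identical inputs. Accuracy is measured on the same
#' held-out split in both arms.
#'
#' @param n_seeds Number of paired replicates.
#' @param budget,retrain_every,initial_seed_labels Passed to [al_config()].
#' @param strategies Strategies to compare.
#' @param n_annotators,annotator_accuracy Simulated annotator pool.
#' @param base_seed Offset added to all derived seeds.
#' @param stream_fn Function `seed -> stream_config` (default
#'   [al_fixture_config()]).
#' @return data.frame with one row per (seed, strategy, checkpoint):
#'   columns seed, strategy, checkpoint, labels_used, accuracy.
#' @export
compare_strategies <- function(n_seeds = 10, budget = 300,
                               retrain_every = 100,
                               initial_seed_labels = 60,
                               strategies = c("uncertainty", "random"),
                               n_annotators = 5, annotator_accuracy = 0.9,
                               base_seed = 0, stream_fn = al_fixture_config) {
  out <- list()
  for (s in seq_len(n_seeds)) {
    seed <- base_seed + s
    posts <- generate_stream(stream_fn(seed))
    for (strat in strategies) {
      annotators <- lapply(seq_len(n_annotators), function(k) {
        simulated_annotator(paste0("u", k), accuracy = annotator_accuracy,
                            seed = seed * 1000L + k)
      })
      cfg <- al_config(strategy = strat, budget = budget,
                       retrain_every = retrain_every,
                       initial_seed_labels = initial_seed_labels,
                       rng_seed = seed * 7L + 13L)
      res <- active_learning_loop(posts, annotators, cfg)
      h <- res$history
      h$seed <- seed
      h$strategy <- strat
      out[[length(out) + 1L]] <- h
    }
  }
  do.call(rbind, out)[, c("seed", "strategy", "checkpoint", "labels_used",
                          "accuracy")]
}
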