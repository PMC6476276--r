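# Shared fixtures, built in code.

# Perfectly separable two-class training set: disjoint vocabularies.
separable_examples <- function(n_per_class = 12) {
  mk <- function(label, words) {
    lapply(seq_len(n_per_class), function(i) {
      labeled_example(paste0(label, i),
                      paste(sample(words, 5, replace = TRUE), collapse = " "),
                      label, 3, 1.0)
    })
  }
  set.seed(99)
  c(mk("positive", c("great", "good", "glad", "love", "safe")),
    mk("negative", c("bad", "awful", "harm", "fear", "risky")))
}

# Fresh annotator pool with deterministic per-annotator seeds.
make_annotators <- function(n = 5, accuracy = 0.9, seed_base = 1000,
                            classes = default_classes()) {
  lapply(seq_len(n), function(k) {
    simulated_annotator(paste0("u", k), accuracy = accuracy,
                        classes = classes, seed = seed_base + k)
  })
}

# The drift scenario: polar positive share 0.5 -> 0.7 at the midpoint,
# neutral share constant at 1/3.
drift_stream_config <- function(rate = 200, days_each_side = 60, seed = 7) {
  cfg <- stream_config(volume_rate = rate,
                       duration_days = 2 * days_each_side, seed = seed)
  inject_changepoint(cfg, days_each_side,
                     c(0.7 * 2 / 3, 0.3 * 2 / 3, 1 / 3))
}

# Brute-force oracle for the queue's serving rule: argmax of current
# priority over eligible items, ties to newer enqueued_at then smaller id.
oracle_next <- function(state, user_id, now) {
  best <- NULL
  for (it in state$items) {
    if (it$retired || user_id %in% it$users_done) next
    sc <- priority_score(it$base_uncertainty,
                         max(now - it$enqueued_at, 0), state$config)
    if (is.null(best) || sc > best$sc ||
        (sc == best$sc && it$enqueued_at > best$at) ||
        (sc == best$sc && it$enqueued_at == best$at &&
         it$post_id < best$id)) {
      best <- list(sc = sc, at = it$enqueued_at, id = it$post_id)
    }
  }
  if (is.null(best)) NULL else best$id
}
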