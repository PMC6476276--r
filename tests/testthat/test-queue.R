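test_that("priority score blends uncertainty and recency as specified", {
  cfg <- queue_config(lambda_uncertainty = 0.5, tau_recency = 86400)
  expect_equal(priority_score(0.4, 86400, cfg), 0.5 * 0.4 + 0.5 * exp(-1),
               tolerance = 1e-12)
  expect_equal(priority_score(0.4, 86400, cfg), 0.38394, tolerance = 5e-6)
  pure <- queue_config(lambda_uncertainty = 1)
  expect_equal(priority_score(0.73, 1e6, pure), 0.73)
  rec <- queue_config(lambda_uncertainty = 0)
  expect_equal(priority_score(0.2, 0, rec), 1)
  expect_error(priority_score(0.5, -1, cfg), "non-negative")
  # monotonicity
  u <- seq(0, 1, 0.1)
  expect_true(all(diff(priority_score(u, 100, cfg)) > 0))
  ages <- seq(0, 5 * 86400, length.out = 20)
  expect_true(all(diff(priority_score(0.5, ages, cfg)) < 0))
})

test_that("a full queue evicts the lowest-priority item, never beyond max_size", {
  cfg <- queue_config(max_size = 2, lambda_uncertainty = 1)
  st <- queue_state(cfg)
  st <- enqueue(queue_item("a", 0.3, 0), st, 0)
  expect_length(st$items, 1)
  expect_error(enqueue(queue_item("a", 0.5, 0), st, 0), "duplicate")
  st <- enqueue(queue_item("b", 0.6, 10), st, 10)
  # entrant beats the minimum: "a" (0.3) evicted
  st <- enqueue(queue_item("c", 0.9, 20), st, 20)
  expect_setequal(names(st$items), c("b", "c"))
  # entrant below the minimum is itself dropped
  st2 <- enqueue(queue_item("d", 0.1, 30), st, 30)
  expect_setequal(names(st2$items), c("b", "c"))
})

test_that("eviction honors recency decay at eviction time", {
  cfg <- queue_config(max_size = 2, lambda_uncertainty = 0,
                      tau_recency = 100)
  st <- queue_state(cfg)
  st <- enqueue(queue_item("old", 1, 0), st, 0)
  st <- enqueue(queue_item("new", 0, 1000), st, 1000)
  # at t=1000 "old" has decayed to exp(-10) regardless of its uncertainty
  st <- enqueue(queue_item("next", 0, 1000), st, 1000)
  expect_setequal(names(st$items), c("new", "next"))
})

test_that("serving dedups per user and follows the brute-force argmax", {
  cfg <- queue_config(max_size = 50, n_consensus = 2,
                      lambda_uncertainty = 0.7, tau_recency = 3600)
  st <- queue_state(cfg)
  set.seed(14)
  for (i in 1:50) {
    st <- enqueue(queue_item(sprintf("p%02d", i), runif(1),
                             sample(0:5000, 1)), st, 5000)
  }
  it <- next_for_user("u1", st, 6000)
  expect_equal(it$post_id, oracle_next(st, "u1", 6000))
  st <- record_done("u1", it$post_id, st)
  it2 <- next_for_user("u1", st, 6000)
  expect_false(identical(it2$post_id, it$post_id))
  expect_equal(it2$post_id, oracle_next(st, "u1", 6000))
  # u2 still gets the original top item
  expect_equal(next_for_user("u2", st, 6000)$post_id, it$post_id)
})

test_that("items retire at exactly n_consensus distinct users", {
  cfg <- queue_config(n_consensus = 3)
  st <- queue_state(cfg)
  st <- enqueue(queue_item("p1", 0.5, 0), st, 0)
  st <- record_done("u1", "p1", st)
  expect_error(record_done("u1", "p1", st), "already labeled")
  st <- record_done("u2", "p1", st)
  expect_length(st$completed, 0)
  st <- record_done("u3", "p1", st)
  expect_equal(st$completed, "p1")
  expect_length(st$items, 0)
  expect_error(record_done("u4", "p1", st), "unknown")

  one <- queue_state(queue_config(n_consensus = 1))
  one <- enqueue(queue_item("q", 0.1, 0), one, 0)
  one <- record_done("u1", "q", one)
  expect_equal(one$completed, "q")
})

test_that("a labeled-by-user queue with one item serves that user nothing", {
  st <- queue_state(queue_config())
  st <- enqueue(queue_item("p1", 0.9, 0), st, 0)
  st <- record_done("u1", "p1", st)
  expect_null(next_for_user("u1", st, 0))
})

test_that("with lambda = 1 the serving order is descending base uncertainty", {
  cfg <- queue_config(max_size = 30, n_consensus = 1,
                      lambda_uncertainty = 1)
  set.seed(5)
  u <- round(runif(30), 6)
  st <- queue_state(cfg)
  for (i in 1:30) {
    st <- enqueue(queue_item(sprintf("p%02d", i), u[i], i), st, 30)
  }
  served <- character(0)
  repeat {
    it <- next_for_user("u1", st, 30)
    if (is.null(it)) break
    served <- c(served, it$post_id)
    st <- record_done("u1", it$post_id, st)
  }
  expect_equal(served, sprintf("p%02d", order(-u)))
})
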