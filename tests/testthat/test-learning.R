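test_that("disjoint-vocabulary classes are fit to training accuracy 1", {
  ex <- separable_examples()
  model <- train_bow(ex, classes = c("positive", "negative"))
  texts <- vapply(ex, `[[`, "", "text")
  truth <- vapply(ex, `[[`, "", "label")
  probs <- predict_proba_many(model, texts)
  pred <- colnames(probs)[max.col(probs)]
  expect_equal(mean(pred == truth), 1)
  # pure class-A text lands on A
  p <- predict_proba(model, "great good love")
  expect_equal(names(which.max(p)), "positive")
})

test_that("training requires every class and excludes reserved labels", {
  ex <- separable_examples()
  pos_only <- Filter(function(e) e$label == "positive", ex)
  expect_error(train_bow(pos_only, classes = c("positive", "negative")),
               "negative")
  with_unres <- c(ex, list(labeled_example("x", "great bad", "unresolved",
                                           3, 1 / 3)))
  m1 <- train_bow(ex, classes = c("positive", "negative"))
  m2 <- train_bow(with_unres, classes = c("positive", "negative"))
  expect_equal(m1$weights, m2$weights)
  expect_equal(m2$trained_on, length(ex))
})

test_that("duplicating the training set leaves the decision function unchanged", {
  ex <- separable_examples()
  m1 <- train_bow(ex, classes = c("positive", "negative"), min_df = 1)
  m2 <- train_bow(c(ex, ex), classes = c("positive", "negative"), min_df = 1)
  texts <- c("great love risky", "fear harm", "good glad safe bad")
  p1 <- predict_proba_many(m1, texts)
  p2 <- predict_proba_many(m2, texts)
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("predicted probabilities are normalized and OOV-robust", {
  model <- train_bow(separable_examples(), classes = c("positive", "negative"))
  set.seed(8)
  rand <- vapply(1:200, function(i) {
    paste(sample(c(letters, "great", "bad"), 6, replace = TRUE),
          collapse = " ")
  }, "")
  probs <- predict_proba_many(model, rand)
  expect_true(all(abs(rowSums(probs) - 1) < 1e-9))
  # empty / all-OOV text falls back to the bias-only softmax
  bias_p <- exp(model$bias) / sum(exp(model$bias))
  expect_equal(predict_proba(model, ""), bias_p, tolerance = 1e-12)
  expect_equal(predict_proba(model, "zzz qqq xyzzy"), bias_p,
               tolerance = 1e-12)
})

test_that("uncertainty methods hit their closed-form values", {
  onehot <- c(1, 0, 0)
  expect_equal(uncertainty(onehot, "least_confidence"), 0)
  expect_equal(uncertainty(onehot, "entropy"), 0)
  unif <- rep(1 / 3, 3)
  expect_equal(uncertainty(unif, "least_confidence"), 2 / 3)
  expect_equal(uncertainty(unif, "entropy"), 1)
  p <- c(0.5, 0.3, 0.2)
  expect_equal(uncertainty(p, "least_confidence"), 0.5)
  expect_equal(uncertainty(p, "entropy"), 0.9372, tolerance = 1e-4)
  expect_error(uncertainty(c(0.5, 0.4)), "sum to 1")
})

test_that("micro precision equals micro recall equals accuracy", {
  r <- evaluate_micro(c("A", "B", "B"), c("A", "A", "B"))
  expect_equal(r$micro_precision, 2 / 3)
  expect_equal(r$micro_recall, 2 / 3)
  perfect <- evaluate_micro(c("A", "B"), c("A", "B"))
  expect_equal(perfect$micro_precision, 1)
  set.seed(12)
  for (i in 1:20) {
    truth <- sample(LETTERS[1:4], 50, replace = TRUE)
    pred <- sample(LETTERS[1:4], 50, replace = TRUE)
    r <- evaluate_micro(truth, pred)
    expect_equal(r$micro_precision, r$micro_recall)
    expect_equal(r$micro_precision, r$accuracy)
  }
  expect_error(evaluate_micro(character(0), character(0)), "empty")
})

test_that("a model round-trips through its plain-text directory", {
  dir <- withr::local_tempdir()
  model <- train_bow(separable_examples(), classes = c("positive", "negative"))
  save_model(model, dir)
  back <- load_model(dir)
  expect_equal(back$classes, model$classes)
  expect_equal(back$version, model$version)
  texts <- c("great love", "fear harm bad", "hello world")
  expect_equal(predict_proba_many(back, texts),
               predict_proba_many(model, texts), tolerance = 1e-12)
})
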