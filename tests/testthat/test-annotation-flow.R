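two_branch_sequence <- function() default_question_sequence()

test_that("the shipped relevance/sentiment sequence is valid and loads from YAML", {
  expect_length(validate_sequence(two_branch_sequence()), 0)
  f <- system.file("extdata", "question_sequence_demo.yaml",
                   package = "sentistream")
  seq <- read_question_sequence(f)
  expect_length(validate_sequence(seq), 0)
  expect_equal(seq$start, "Q1")
  expect_equal(next_question(seq, "Q1", "a1_1"), "Q2")
  expect_equal(next_question(seq, "Q1", "a1_2"), "END")
})

test_that("validation reports cycles, missing transitions and unreachable parts", {
  seq <- two_branch_sequence()
  cyc <- seq
  cyc$questions$Q2$answers$a2_1[["next"]] <- "Q1"
  expect_match(paste(validate_sequence(cyc), collapse = "; "), "cycle")

  mis <- seq
  mis$questions$Q2$answers$a2_1[["next"]] <- NULL
  expect_match(paste(validate_sequence(mis), collapse = "; "),
               "missing transition.*Q2.*a2_1")

  orphan <- seq
  orphan$questions$Q9 <- list(text = "orphan", answers = list(
    x = list(text = "x", label = NULL, "next" = "END")))
  expect_match(paste(validate_sequence(orphan), collapse = "; "),
               "unreachable question.*Q9")

  noend <- list(questions = list(
    Q1 = list(text = "q", answers = list(
      a = list(text = "a", label = NULL, "next" = "Q1")))), start = "Q1")
  class(noend) <- "question_sequence"
  v <- validate_sequence(noend)
  expect_match(paste(v, collapse = "; "), "cycle")
  expect_match(paste(v, collapse = "; "), "END not reachable")
})

test_that("transitions follow the answer given and reject unknown pairs", {
  seq <- two_branch_sequence()
  expect_equal(next_question(seq, "Q1", "a1_1"), "Q2")
  expect_equal(next_question(seq, "Q2", "a2_2"), "END")
  expect_error(next_question(seq, "Q2", "nope"), "unknown answer")
})

test_that("run_sequence emits one annotation per answered question, in order", {
  seq <- two_branch_sequence()
  p <- post("p1", 50, "some text")
  irr <- run_sequence(seq, p, function(q) "a1_2", "u1")
  expect_true(irr$run$completed)
  expect_equal(nrow(irr$annotations), 1)

  full <- run_sequence(seq, p, function(q) {
    if (q == "Q1") "a1_1" else "a2_3"
  }, "u2")
  expect_true(full$run$completed)
  expect_equal(full$annotations$question_id, c("Q1", "Q2"))
  expect_equal(full$annotations$answer_id, c("a1_1", "a2_3"))
  expect_equal(full$annotations$post_id, c("p1", "p1"))
})

test_that("an aborted run leaves no annotations", {
  seq <- two_branch_sequence()
  p <- post("p1", 50, "some text")
  bad <- run_sequence(seq, p, function(q) {
    if (q == "Q1") "a1_1" else "invalid_answer"
  }, "u1")
  expect_false(bad$run$completed)
  expect_equal(nrow(bad$annotations), 0)
})

test_that("run length never exceeds the number of questions", {
  seq <- two_branch_sequence()
  p <- post("p1", 1, "t")
  set.seed(31)
  for (i in 1:50) {
    af <- function(q) {
      ans <- names(seq$questions[[q]]$answers)
      sample(ans, 1)
    }
    res <- run_sequence(seq, p, af, paste0("u", i))
    expect_lte(nrow(res$annotations), length(seq$questions))
    expect_true(res$run$completed)
  }
})

test_that("strict majority wins, ties are unresolved, agreement is the vote share", {
  seq <- two_branch_sequence()
  mk_ann <- function(user, answers) {
    data.frame(user_id = user, post_id = "p1",
               question_id = c("Q1", "Q2")[seq_along(answers)],
               answer_id = answers, timestamp = 0)
  }
  sent <- function(user, a2) mk_ann(user, c("a1_1", a2))
  unan <- rbind(sent("u1", "a2_1"), sent("u2", "a2_1"), sent("u3", "a2_1"))
  ex <- consensus_label(unan, seq, text = "t")
  expect_equal(ex$label, "positive")
  expect_equal(ex$agreement, 1)

  maj <- rbind(sent("u1", "a2_1"), sent("u2", "a2_1"), sent("u3", "a2_2"))
  ex <- consensus_label(maj, seq, text = "t")
  expect_equal(ex$label, "positive")
  expect_equal(ex$agreement, 2 / 3)

  tie <- rbind(sent("u1", "a2_1"), sent("u2", "a2_2"), sent("u3", "a2_3"))
  ex <- consensus_label(tie, seq, text = "t")
  expect_equal(ex$label, "unresolved")

  # a user routed straight to END votes "irrelevant"
  irr <- rbind(mk_ann("u1", "a1_2"), mk_ann("u2", "a1_2"),
               sent("u3", "a2_1"))
  ex <- consensus_label(irr, seq, text = "t")
  expect_equal(ex$label, "irrelevant")

  expect_error(consensus_label(rbind(sent("u1", "a2_1"), sent("u2", "a2_1")),
                               seq, n_consensus = 3),
               "consensus not reached")
})

test_that("consensus-of-3 recovery matches the binomial closed form (small MC)", {
  p <- 0.8
  annotators <- make_annotators(3, accuracy = p, seed_base = 500)
  seq <- two_branch_sequence()
  n <- 2000
  set.seed(77)
  truth <- sample(default_classes(), n, replace = TRUE)
  hits <- vapply(seq_len(n), function(i) {
    pp <- post(paste0("p", i), 0, "text")
    rows <- do.call(rbind, lapply(annotators, function(a) {
      run_sequence(seq, pp, simulated_answer_fn(a, seq, truth[i]),
                   a$user_id)$annotations
    }))
    consensus_label(rows, seq, text = "t")$label == truth[i]
  }, NA)
  closed <- p^3 + 3 * p^2 * (1 - p)
  expect_lt(abs(mean(hits) - closed), 0.025)
})
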