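`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

#' Default label classes
#'
#' The three sentiment classes used throughout: "positive", "negative" and
#' "neutral". Projects may extend the set (e.g. with "irrelevant");
#' "unresolved" is reserved for failed consensus and is never a model class.
#'
#' @return Character vector of class labels.
#' @export
default_classes <- function() c("positive", "negative", "neutral")

# Reserved labels that never enter classifier training.
reserved_labels <- function() c("unresolved", "irrelevant")

check_prob_vector <- function(p, tol = 1e-9, what = "class_probs") {
  if (!is.numeric(p) || length(p) < 2) {
    stop(what, " must be a numeric vector over >= 2 classes", call. = FALSE)
  }
  if (any(p < -tol)) stop(what, " has negative entries", call. = FALSE)
  if (abs(sum(p) - 1) > max(tol, 1e-9)) {
    stop(what, " must sum to 1 (got ", format(sum(p), digits = 12), ")",
         call. = FALSE)
  }
  invisible(TRUE)
}

# Evaluate `expr` under an RNG stream private to environment `env` (which
# carries a `seed` and, after first use, a `state`). The caller's global RNG
# state is untouched, so simulated annotators are deterministic given their
# own seed and call sequence regardless of surrounding code.
with_private_rng <- function(env, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  if (is.null(env$state)) {
    set.seed(env$seed)
  } else {
    assign(".Random.seed", env$state, envir = globalenv())
  }
  res <- force(expr)
  env$state <- get(".Random.seed", envir = globalenv())
  res
}
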