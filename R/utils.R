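#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so generators are deterministic without clobbering
#' the session stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

assert_scalar_finite <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (x < lo || x > hi)
    stop(sprintf("`%s` must be in [%s, %s]", name, lo, hi), call. = FALSE)
  invisible(x)
}

#' Planted ground truth of a synthetic dataset
#'
#' Light container recording the parameters actually realized by a
#' synthetic generator (not just the nominal request), so recovery tests
#' can compare estimates against what was drawn.
#'
#' @param kind one of `"stack"`, `"photoactivation"`, `"spine"`,
#'   `"profile"`, `"calcium"`, `"proteome"`.
#' @param params named list of planted values.
#' @param seed integer seed used by the generator.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(kind, params, seed) {
  kind <- match.arg(kind, c("stack", "photoactivation", "spine",
                            "profile", "calcium", "proteome"))
  num <- Filter(function(p) is.numeric(p) && !is.matrix(p) && !is.array(p), params)
  bad <- vapply(num, function(p) any(!is.finite(p)), logical(1))
  if (any(bad))
    stop("non-finite planted value in ground truth: ",
         paste(names(num)[bad], collapse = ", "))
  structure(list(kind = kind, params = params, seed = as.integer(seed)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>", x$kind, " seed:", x$seed, "\n")
  nm <- names(x$params)
  for (i in seq_along(x$params)) {
    p <- x$params[[i]]
    if (is.numeric(p) && length(p) <= 8 && is.null(dim(p))) {
      cat("  ", nm[i], ": ", paste(signif(p, 5), collapse = " "), "\n", sep = "")
    } else {
      cat("  ", nm[i], ": <", class(p)[1], " length ", length(p), ">\n", sep = "")
    }
  }
  invisible(x)
}
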