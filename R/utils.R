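# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporarily seeded RNG
#'
#' Seeds the generator for reproducible bootstrap/simulation draws and
#' restores the caller's RNG state afterwards, so library calls never
#' disturb user-level random streams.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_semioloc <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "semioloc_error")))
}

assert_prob_vector <- function(p, what, tol = 1e-9) {
  if (any(p < -tol)) {
    stop_semioloc(sprintf("%s has negative entries", what), "semioloc_config_error")
  }
  if (abs(sum(p) - 1) > tol) {
    stop_semioloc(sprintf("%s must sum to 1 (got %.12g)", what, sum(p)),
                  "semioloc_config_error")
  }
  invisible(p)
}

#' Percentile interval of a bootstrap sample
#' @noRd
percentile_ci <- function(x, level = 0.95) {
  alpha <- (1 - level) / 2
  q <- stats::quantile(x, probs = c(alpha, 1 - alpha), names = FALSE,
                       na.rm = TRUE, type = 7)
  c(ci_low = q[1], ci_high = q[2])
}
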