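# Internal helpers shared across modules.

#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom Rcpp sourceCpp
#' @useDynLib pharmboost, .registration = TRUE
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stopf <- function(fmt, ..., class = "pharmboost_error") {
  abort(sprintf(fmt, ...), class = class)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stopf("`%s` must be a finite number in [%s, %s]", name,
          format(lower), format(upper), class = "pharmboost_argument_error")
  }
  invisible(x)
}
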