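#' @importFrom methods is as
#' @importFrom stats rbinom rnorm runif rexp rpois rgamma rmultinom
#'   quantile median cor sd pnorm pbinom dhyper p.adjust wilcox.test
#'   setNames ave
#' @importFrom utils head
NULL

## Evaluate `code` under a temporary RNG state so simulation helpers are
## reproducible without clobbering the caller's random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

## Deterministic sub-seed for an independent generator stream. Adding a new
## stream id never perturbs existing streams. Result stays below 2^31 - 1.
sub_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((as.double(seed) %% 2147483647 * 48271 + stream * 69621) %% 2147483629)
}

stop_invalid_config <- function(...) {
  stop(structure(
    class = c("invalid_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "))
  }
  invisible(df)
}
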