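#' @importFrom stats cor cor.test kruskal.test wilcox.test median pnorm
#'   quantile rhyper rlnorm rmultinom rnorm runif rbinom qnbinom qpois sd
#'   setNames complete.cases
#' @importFrom utils read.table write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run `expr` under a private RNG stream: the caller's .Random.seed is
## untouched, and the same `seed` always yields the same draws.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stopf("%s is missing column(s): %s", what, paste(miss, collapse = ", "))
  invisible(df)
}

## Total length of the union of 1-based inclusive intervals.
interval_union_length <- function(from, to) {
  if (length(from) == 0L) return(0L)
  stopifnot(length(from) == length(to))
  if (any(to < from)) stopf("interval end before start")
  sum(IRanges::width(IRanges::reduce(IRanges::IRanges(start = from, end = to))))
}
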