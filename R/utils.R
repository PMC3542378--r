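#' @importFrom stats approx coef cor cor.test lm median pbeta pnorm qbeta
#'   qnorm rbeta rbinom rlnorm rnorm runif sd setNames binom.test p.adjust
#'   predict var
#' @importFrom utils read.delim write.table head modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run `expr` under a fixed RNG seed without clobbering the caller's stream.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Spawn a reproducible child seed (< 2^31) from a master seed.
childSeed <- function(seed, index) {
  (as.integer(seed) * 48271L + as.integer(index) * 16807L) %% 2147480009L
}

assertColumns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stopf("%s is missing required column(s): %s", what,
          paste(miss, collapse = ", "))
  invisible(df)
}
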