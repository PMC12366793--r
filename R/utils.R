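#' @importFrom stats cor cor.test pnorm pchisq pt qchisq rnorm runif rgamma
#'   rmultinom sd setNames uniroot lm coef vcov quantile ecdf smooth.spline
#'   predict qexp median mad aggregate as.formula dist hclust cutree rbinom
#' @importFrom utils head read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a named substream seed from a root seed
#'
#' All randomness in the package flows from one root seed; each generator or
#' stochastic stage draws from its own substream so that adding a stage never
#' perturbs the random numbers of another.
#'
#' @param seed Integer root seed.
#' @param name Character substream name (e.g. `"otu"`, `"spectra"`).
#' @return An integer seed below 2^31, deterministic in `(seed, name)`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  code <- utf8ToInt(name)
  h <- sum(code * seq_along(code)) %% 1000003
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483629)
}

# Run `expr` under a fixed seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stop_invalid <- function(...) {
  stop(paste0(...), call. = FALSE)
}

assert_positive_int <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x)) {
    stop_invalid("`", name, "` must be a positive integer, got: ",
                 paste(format(x), collapse = ", "))
  }
  invisible(as.integer(x))
}
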