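#' @importFrom stats pchisq qchisq pt pnorm rexp rbinom rlnorm runif rnorm
#'   dhyper glm anova binomial lm coef cor.test complete.cases predict
#'   smooth.spline uniroot var sd quantile setNames p.adjust update
#'   binom.test
#' @importFrom methods new validObject is slot
#' @importFrom utils read.delim write.table head combn
NULL

# Derive an independent RNG substream seed from (seed, label).  Each generator
# draws from its own substream so adding a generator never shifts another's
# draws.  Plain polynomial string hash folded into [0, 2^31 - 2].
deriveSeed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- as.double(seed %% 2147483647)
  for (ch in utf8ToInt(label)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

assertProbability <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

assertCount <- function(x, name = deparse(substitute(x)), min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x)) {
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

geometricMean <- function(x) exp(mean(log(x)))

# Rank with average ties, largest value first (rank 1 = top).
rankDesc <- function(x) rank(-x, ties.method = "average")
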