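#' Named, reproducible random substreams
#'
#' Every stochastic element of the model (arrival thinning, each service
#' task, routing, zone/acuity mixes) draws from its own named substream so
#' that scenarios sharing a seed also share random numbers (common random
#' numbers, CRN). A substream is an independent Mersenne-Twister state
#' seeded deterministically from `(seed, id, rep)`; identical triples
#' reproduce identical variate sequences, distinct ids give streams that
#' are independent for practical purposes.
#'
#' @param seed integer master seed.
#' @param id character label of the stochastic element, e.g. `"triage"`.
#' @param rep replication index (0-based offset folded into the seed).
#' @return an object of class `random_stream` holding its own RNG state.
#' @examples
#' s1 <- random_stream(42, "triage")
#' s2 <- random_stream(42, "triage")
#' identical(stream_runif(s1, 5), stream_runif(s2, 5))
#' @export
random_stream <- function(seed, id = "default", rep = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(id))
  st <- new.env(parent = emptyenv())
  st$seed <- as.integer(seed)
  st$id <- id
  st$rep <- as.integer(rep)
  old <- .save_rng()
  set.seed(.derive_seed(seed, id, rep))
  st$state <- get(".Random.seed", envir = globalenv())
  .restore_rng(old)
  class(st) <- "random_stream"
  st
}

# 31-based string hash folded with seed and rep, kept below 2^31 - 1.
.derive_seed <- function(seed, id, rep) {
  h <- (as.double(seed) %% 2147483647) + 1
  for (ch in utf8ToInt(id)) h <- (h * 31 + ch) %% 2147483647
  h <- (h + as.double(rep) * 97003 + 1) %% 2147483647
  as.integer(h)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Evaluate an expression under a stream's RNG state
#'
#' Swaps the stream's saved state into the session RNG, evaluates `expr`,
#' then stores the advanced state back and restores the session RNG.
#'
#' @param stream a [random_stream()].
#' @param expr expression drawing random numbers.
#' @return the value of `expr`.
#' @export
with_stream <- function(stream, expr) {
  stopifnot(inherits(stream, "random_stream"))
  old <- .save_rng()
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    .restore_rng(old)
  })
  expr
}

#' @rdname with_stream
#' @param n number of uniforms to draw.
#' @export
stream_runif <- function(stream, n = 1) with_stream(stream, stats::runif(n))

#' @export
print.random_stream <- function(x, ...) {
  cat(sprintf("<random_stream seed=%d id=%s rep=%d>\n", x$seed, x$id, x$rep))
  invisible(x)
}
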