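#' Erlang-C mean waiting time for the M/M/c queue
#'
#' Closed-form expected waiting time in queue for Poisson arrivals at
#' rate `lambda`, exponential service at rate `mu`, and `c` servers;
#' the analytic benchmark against which the simulator's single-stage
#' reduction is checked.
#'
#' @param lambda arrival rate (per minute).
#' @param mu service rate per server (per minute).
#' @param c number of servers (`lambda < c * mu` required).
#' @return list `p_wait` (probability of waiting) and `wq` (mean wait
#'   in queue, minutes).
#' @examples
#' erlang_c_wait(lambda = 1 / 12, mu = 1 / 20, c = 2)
#' @export
erlang_c_wait <- function(lambda, mu, c) {
  stopifnot(lambda > 0, mu > 0, c >= 1, c == round(c))
  a <- lambda / mu                      # offered load (Erlangs)
  if (a >= c) stop("unstable queue: lambda >= c * mu")
  k <- 0:(c - 1)
  # log-scale Erlang-C probability of waiting
  lterms <- k * log(a) - lfactorial(k)
  ltail <- c * log(a) - lfactorial(c) + log(c / (c - a))
  lmax <- max(lterms, ltail)
  p_wait <- exp(ltail - lmax) / (sum(exp(lterms - lmax)) + exp(ltail - lmax))
  list(p_wait = p_wait, wq = p_wait / (c * mu - lambda))
}
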