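#' Service-time distribution specifications
#'
#' Service times in the scenario configuration are written in the compact
#' simulation-textbook notation used by commercial DES tools, e.g.
#' `"TRI (2, 3, 5)"`, `"1 + 2 * Gamma (0.1, 2.5, 2.5)"`,
#' `"LogNORM (1.3, 2, 1)"` or `"1.7 * TRIA (1, 0.3, 10.1)"`.
#' [parse_distribution()] turns such a string into a canonical
#' `dist_spec`; [dist_sample()] draws seeded variates from it and
#' [dist_moments()] gives its closed-form mean and variance.
#'
#' Parameter conventions (commercial-DES-tool style):
#' \describe{
#'   \item{triangular}{`(min, mode, max)`, minutes. Ill-ordered triples
#'     are sorted into order with a warning.}
#'   \item{gamma}{`(shape, scale[, min])` — the optional third parameter
#'     is a minimum shift added to the variate.}
#'   \item{lognormal}{`(log-mean, log-sd[, min])` — third parameter again
#'     a minimum shift.}
#'   \item{exponential}{`(mean)`, minutes.}
#'   \item{constant}{`(value)`; a bare number parses as a constant.}
#' }
#' An affine wrapper `b + a * FAMILY(...)` (or `a * FAMILY(...) + b`)
#' stores `a` as `scale` and `b` as `shift`; sampled values are
#' `a * X + b`, truncated at zero (durations cannot be negative).
#'
#' @param text distribution string, case-insensitive, whitespace-free or
#'   not; the unicode asterisk is accepted.
#' @return `parse_distribution()`: an object of class `dist_spec` with
#'   fields `family`, `params`, `scale`, `shift`.
#' @examples
#' parse_distribution("TRI (2, 3, 5)")
#' parse_distribution("1 + 2 * Gamma (0.1, 2.5, 2.5)")
#' dist_moments(parse_distribution("LogNORM (1.3, 2, 1)"))
#' @export
parse_distribution <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  raw <- text
  s <- gsub("∗|×", "*", text)   # unicode asterisk / times sign
  s <- gsub("[[:space:]]+", "", s)
  if (!nzchar(s)) stop("empty distribution string")

  shift <- 0; scale <- 1
  num_re <- "[-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?"

  # bare number -> constant
  if (grepl(paste0("^", num_re, "$"), s)) {
    return(new_dist_spec("constant", as.numeric(s), 1, 0, raw))
  }
  # leading "b + rest"
  m <- regmatches(s, regexec(paste0("^(", num_re, ")\\+(.*[A-Za-z].*)$"), s))[[1]]
  if (length(m)) { shift <- as.numeric(m[2]); s <- m[3] }
  # trailing "rest + b"
  m <- regmatches(s, regexec(paste0("^(.*[)])\\+(", num_re, ")$"), s))[[1]]
  if (length(m)) { shift <- shift + as.numeric(m[3]); s <- m[2] }
  # leading "a * rest"
  m <- regmatches(s, regexec(paste0("^(", num_re, ")\\*(.+)$"), s))[[1]]
  if (length(m)) { scale <- as.numeric(m[2]); s <- m[3] }

  m <- regmatches(s, regexec("^([A-Za-z]+)\\(([^)]*)\\)$", s))[[1]]
  if (!length(m))
    stop("malformed distribution string near ", sQuote(s), " in ", sQuote(raw))
  fam_tok <- toupper(m[2])
  params <- suppressWarnings(as.numeric(strsplit(m[3], ",", fixed = TRUE)[[1]]))
  if (!length(params) || anyNA(params))
    stop("cannot parse parameters ", sQuote(m[3]), " in ", sQuote(raw))

  family <- switch(fam_tok,
    TRI = , TRIA = , TRIANGULAR = "triangular",
    GAMMA = "gamma",
    LOGNORM = , LNORM = , LOGNORMAL = "lognormal",
    EXP = , EXPO = , EXPONENTIAL = "exponential",
    CONST = , CONSTANT = "constant",
    stop("unknown distribution family ", sQuote(fam_tok), " in ", sQuote(raw))
  )

  if (family == "triangular") {
    if (length(params) != 3)
      stop("triangular needs 3 parameters, got ", length(params))
    if (is.unsorted(params)) {
      warning("ill-ordered triangular parameters (", paste(params, collapse = ", "),
              ") sorted into (min, mode, max)")
      params <- sort(params)
    }
    if (params[1] == params[3])                       # degenerate -> constant
      return(new_dist_spec("constant", params[1], scale, shift, raw))
  } else if (family == "gamma") {
    if (!length(params) %in% 2:3) stop("gamma needs 2 or 3 parameters")
    if (params[1] <= 0 || params[2] <= 0)
      stop("gamma shape and scale must be positive")
    if (length(params) == 2) params <- c(params, 0)
  } else if (family == "lognormal") {
    if (!length(params) %in% 2:3) stop("lognormal needs 2 or 3 parameters")
    if (params[2] <= 0) stop("lognormal sigma must be positive")
    if (length(params) == 2) params <- c(params, 0)
  } else if (family == "exponential") {
    if (length(params) != 1) stop("exponential needs 1 parameter (mean)")
    if (params[1] <= 0) stop("exponential mean must be positive")
  } else if (family == "constant") {
    if (length(params) != 1) stop("constant needs 1 parameter")
  }
  new_dist_spec(family, params, scale, shift, raw)
}

new_dist_spec <- function(family, params, scale, shift, source = NULL) {
  structure(list(family = family, params = as.numeric(params),
                 scale = scale, shift = shift, source = source),
            class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(format_distribution(x), "\n")
  invisible(x)
}

#' Canonical text form of a distribution spec
#'
#' Inverse of [parse_distribution()] up to canonicalization:
#' `parse(format(parse(text)))` equals `parse(text)`.
#'
#' @param spec a `dist_spec`.
#' @return a single string in the config grammar.
#' @export
format_distribution <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  fam <- switch(spec$family, triangular = "TRIA", gamma = "GAMMA",
                lognormal = "LOGNORM", exponential = "EXPO",
                constant = "CONST")
  core <- sprintf("%s(%s)", fam, paste(format(spec$params, trim = TRUE),
                                       collapse = ", "))
  if (spec$scale != 1) core <- paste0(format(spec$scale), " * ", core)
  if (spec$shift != 0) core <- paste0(format(spec$shift), " + ", core)
  core
}

#' Draw service-time variates from a distribution spec
#'
#' Variates are `scale * X + shift`, truncated at 0; the number of
#' truncated draws is attached as attribute `"truncated"`. With a
#' `stream`, repeated calls on a fresh copy of the same stream reproduce
#' the same sequence.
#'
#' @param spec a `dist_spec` from [parse_distribution()].
#' @param n number of draws.
#' @param stream optional [random_stream()]; defaults to the session RNG.
#' @return numeric vector of `n` nonnegative durations (minutes).
#' @export
dist_sample <- function(spec, n = 1, stream = NULL) {
  stopifnot(inherits(spec, "dist_spec"))
  draw <- function() .dist_draw(spec, n)
  x <- if (is.null(stream)) draw() else with_stream(stream, draw())
  x <- spec$scale * x + spec$shift
  neg <- x < 0
  x[neg] <- 0
  structure(x, truncated = sum(neg))
}

.dist_draw <- function(spec, n) {
  p <- spec$params
  switch(spec$family,
    constant = rep(p[1], n),
    triangular = .rtri(n, p[1], p[2], p[3]),
    gamma = stats::rgamma(n, shape = p[1], scale = p[2]) + p[3],
    lognormal = stats::rlnorm(n, meanlog = p[1], sdlog = p[2]) + p[3],
    exponential = stats::rexp(n, rate = 1 / p[1])
  )
}

# inverse-CDF triangular sampler
.rtri <- function(n, a, b, c) {
  u <- stats::runif(n)
  fc <- (b - a) / (c - a)
  ifelse(u < fc,
         a + sqrt(u * (c - a) * (b - a)),
         c - sqrt((1 - u) * (c - a) * (c - b)))
}

#' Closed-form mean and variance of a distribution spec
#'
#' Moments include the affine `scale`/`shift` wrapper but ignore the
#' zero-truncation applied by [dist_sample()] (negligible for the service
#' laws in use, all of which have nonnegative support before shifting).
#'
#' @param spec a `dist_spec`.
#' @return named numeric vector `c(mean = , variance = )` in minutes and
#'   squared minutes.
#' @export
dist_moments <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  p <- spec$params
  mv <- switch(spec$family,
    constant = c(p[1], 0),
    triangular = c((p[1] + p[2] + p[3]) / 3,
                   (p[1]^2 + p[2]^2 + p[3]^2 -
                    p[1] * p[2] - p[1] * p[3] - p[2] * p[3]) / 18),
    gamma = c(p[1] * p[2] + p[3], p[1] * p[2]^2),
    lognormal = c(exp(p[1] + p[2]^2 / 2) + p[3],
                  (exp(p[2]^2) - 1) * exp(2 * p[1] + p[2]^2)),
    exponential = c(p[1], p[1]^2),
    stop("no closed-form moments for family ", spec$family)
  )
  c(mean = spec$scale * mv[1] + spec$shift,
    variance = spec$scale^2 * mv[2])
}
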