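#' Fit an interaction regression to DOE responses
#'
#' Ordinary least squares on raw factor units (capacity counts), the
#' parameterization in which the case-study equations are printed:
#' main effects plus all two-way interactions by default, plus the
#' three-way interaction with `order = 3`. Coded (-1/0/+1) units are
#' available behind `coded = TRUE`.
#'
#' @param responses a `response_table` from [run_design()] or
#'   [response_table()].
#' @param response response column name, e.g. `"LOS"` or `"AtD"`.
#' @param order highest interaction order: 1 (main effects), 2 or 3.
#' @param coded fit on centered/scaled -1/0/+1 levels instead of raw
#'   units.
#' @param point_means average replications to point means before
#'   fitting (affects R-squared, not coefficients, on balanced designs).
#' @return object of class `regression_fit`: coefficients, standard
#'   errors, t values, `r2`/`adj_r2` (percent), residual df and SS, the
#'   term labels and the design matrix used.
#' @examples
#' des <- full_factorial(default_factors("adult"))
#' y <- with(des, 10 - 2 * ZoneNurse + 0.5 * ZoneBed)
#' rt <- response_table(des, data.frame(LOS = y))
#' coef(fit_ols(rt, "LOS"))
#' @export
fit_ols <- function(responses, response = "LOS", order = 2,
                    coded = FALSE, point_means = FALSE) {
  stopifnot(inherits(responses, "response_table"),
            response %in% names(responses), order %in% 1:3)
  nms <- attr(responses, "factor_names")
  df <- as.data.frame(responses)
  if (point_means) {
    sp <- split(df, df$point)
    df <- do.call(rbind, lapply(sp, function(g) {
      g1 <- g[1, , drop = FALSE]
      g1[[response]] <- mean(g[[response]])
      g1
    }))
  }
  vals <- df[nms]
  if (coded) {
    vals <- as.data.frame(lapply(vals, function(v) {
      lv <- sort(unique(v))
      2 * (v - min(lv)) / (max(lv) - min(lv)) - 1
    }))
  }
  terms <- .interaction_terms(nms, order)
  X <- cbind(`(Intercept)` = 1,
             vapply(terms, function(tt)
               Reduce(`*`, vals[tt]), numeric(nrow(vals))))
  colnames(X) <- c("(Intercept)", vapply(terms, paste, character(1),
                                         collapse = ":"))
  y <- df[[response]]
  if (anyNA(y)) stop("response contains missing values")

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular design: aliased term(s) ",
         paste(aliased, collapse = ", "))
  }
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  df_res <- length(y) - ncol(X)
  sigma2 <- if (df_res > 0) rss / df_res else NA_real_
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(pmax(diag(XtXinv), 0) * sigma2)
  names(se) <- colnames(X)
  r2 <- if (tss > 0) 100 * (1 - rss / tss) else 100
  adj <- if (tss > 0 && df_res > 0)
    100 * (1 - (rss / df_res) / (tss / (length(y) - 1))) else r2

  structure(list(
    coefficients = beta, se = se, t = beta / se,
    r2 = r2, adj_r2 = adj, rss = rss, tss = tss, df_res = df_res,
    terms = colnames(X)[-1], term_vars = terms,
    X = X, y = y, factor_names = nms, response = response,
    coded = coded, point_means = point_means
  ), class = "regression_fit")
}

.interaction_terms <- function(nms, order) {
  terms <- as.list(nms)
  if (order >= 2 && length(nms) >= 2)
    terms <- c(terms, combn(nms, 2, simplify = FALSE))
  if (order >= 3 && length(nms) >= 3)
    terms <- c(terms, combn(nms, 3, simplify = FALSE))
  terms
}

#' @export
coef.regression_fit <- function(object, ...) object$coefficients

#' @export
print.regression_fit <- function(x, ...) {
  cat(equation_text(x), "\n")
  cat(sprintf("R-sq = %.2f%%   R-sq (adj) = %.2f%%   residual df = %d\n",
              x$r2, x$adj_r2, x$df_res))
  invisible(x)
}

#' Equation text in the reporting style of the case study
#'
#' @param fit a [fit_ols()] result.
#' @param digits significant digits per coefficient.
#' @return single string, e.g.
#'   `"LOS = -35.0 + 15.04 ZoneNurse + ..."`.
#' @export
equation_text <- function(fit, digits = 4) {
  stopifnot(inherits(fit, "regression_fit"))
  b <- fit$coefficients
  lab <- gsub(":", " x ", names(b)[-1])
  parts <- sprintf("%s %s %s",
                   ifelse(b[-1] < 0, "-", "+"),
                   vapply(abs(signif(b[-1], digits)), format,
                          character(1), trim = TRUE),
                   lab)
  paste(fit$response, "=", format(signif(b[1], digits)),
        paste(parts, collapse = " "))
}

#' Partial-F ANOVA for a DOE regression
#'
#' Per-term F statistics from full-vs-reduced residual sums of squares
#' (partial, Type III-style tests; on a balanced orthogonal factorial
#' the usual sum-of-squares types coincide), plus the overall model
#' test. A noiseless (zero residual) fit is flagged `degenerate` with
#' infinite F rather than an error; a saturated model (zero residual
#' df) is an error.
#'
#' @param fit a [fit_ols()] result.
#' @return object of class `anova_table`: data.frame with columns
#'   `term`, `df`, `ss`, `F`, `p` (first row is the overall model);
#'   attribute `degenerate`.
#' @export
effects_anova <- function(fit) {
  stopifnot(inherits(fit, "regression_fit"))
  if (fit$df_res == 0)
    stop("saturated model: zero residual degrees of freedom")
  X <- fit$X; y <- fit$y
  rss_full <- fit$rss
  degenerate <- rss_full <= 1e-10 * max(fit$tss, 1)
  mse <- rss_full / fit$df_res

  drop_rss <- function(keep) {
    q <- qr(X[, keep, drop = FALSE])
    sum(qr.resid(q, y)^2)
  }
  term_rows <- lapply(seq_along(fit$terms), function(j) {
    keep <- setdiff(seq_len(ncol(X)), j + 1L)
    ss <- drop_rss(keep) - rss_full
    Fv <- if (degenerate) Inf else (ss / 1) / mse
    data.frame(term = fit$terms[j], df = 1L, ss = max(ss, 0), F = Fv,
               p = if (degenerate) 0 else stats::pf(Fv, 1, fit$df_res,
                                                    lower.tail = FALSE))
  })
  ss_model <- sum((drop(X %*% fit$coefficients) - mean(y))^2)
  df_model <- length(fit$terms)
  F_model <- if (degenerate) Inf else (ss_model / df_model) / mse
  model_row <- data.frame(
    term = "Model", df = df_model, ss = ss_model, F = F_model,
    p = if (degenerate) 0 else stats::pf(F_model, df_model, fit$df_res,
                                         lower.tail = FALSE))
  out <- rbind(model_row, do.call(rbind, term_rows))
  rownames(out) <- NULL
  structure(out, class = c("anova_table", "data.frame"),
            degenerate = degenerate, df_res = fit$df_res)
}

#' @export
print.anova_table <- function(x, ...) {
  y <- as.data.frame(x)
  y$p <- ifelse(y$p < 0.001, "<0.001", formatC(y$p, digits = 3,
                                               format = "f"))
  print.data.frame(y, digits = 4)
  if (isTRUE(attr(x, "degenerate")))
    cat("note: zero residual variance; F statistics are degenerate\n")
  invisible(x)
}

#' Standardized effects, main-effect and interaction summaries
#'
#' Standardized effect of a term is |t| = |coefficient| / SE from the
#' replication-level fit; the Pareto table ranks terms by it. Main-effect
#' tables give the mean response at each factor level; interaction
#' tables give cell means for each factor pair (plot-ready data).
#'
#' @param responses the `response_table` the fit was computed on.
#' @param fit a [fit_ols()] result.
#' @return object of class `effect_summary`: list with elements
#'   `pareto` (term, effect, rank), `main_effects` (factor, level,
#'   mean), `interactions` (factor_a, level_a, factor_b, level_b, mean).
#' @export
effect_summaries <- function(responses, fit) {
  stopifnot(inherits(responses, "response_table"),
            inherits(fit, "regression_fit"))
  nms <- fit$factor_names
  df <- as.data.frame(responses)
  y <- df[[fit$response]]

  counts <- table(df[nms])
  if (length(unique(as.vector(counts))) != 1)
    warning("unbalanced design: level means are weighted by occupancy")

  eff <- abs(fit$t[-1])
  if (fit$tss <= 1e-12 * max(mean(fit$y)^2, 1))  # constant response
    eff[] <- 0
  pareto <- data.frame(term = fit$terms, effect = unname(eff))
  pareto <- pareto[order(-pareto$effect), , drop = FALSE]
  pareto$rank <- seq_len(nrow(pareto))
  rownames(pareto) <- NULL

  main <- do.call(rbind, lapply(nms, function(f) {
    m <- tapply(y, df[[f]], mean)
    data.frame(factor = f, level = as.numeric(names(m)),
               mean = as.numeric(m))
  }))
  rownames(main) <- NULL

  inter <- if (length(nms) >= 2) do.call(rbind, apply(
    combn(nms, 2), 2, function(pr) {
      m <- tapply(y, list(df[[pr[1]]], df[[pr[2]]]), mean)
      grid <- expand.grid(level_a = as.numeric(rownames(m)),
                          level_b = as.numeric(colnames(m)))
      data.frame(factor_a = pr[1], factor_b = pr[2], grid,
                 mean = as.vector(m))
    })) else NULL
  if (!is.null(inter)) rownames(inter) <- NULL

  structure(list(pareto = pareto, main_effects = main,
                 interactions = inter, response = fit$response),
            class = "effect_summary")
}

#' @export
print.effect_summary <- function(x, ...) {
  cat("Pareto of standardized effects (", x$response, ")\n", sep = "")
  print.data.frame(x$pareto, digits = 3)
  cat("\nMain-effect level means\n")
  print.data.frame(x$main_effects, digits = 4)
  invisible(x)
}

#' @export
plot.effect_summary <- function(x, which = c("pareto", "main"), ...) {
  which <- match.arg(which)
  if (which == "pareto") {
    graphics::barplot(rev(x$pareto$effect), names.arg = rev(x$pareto$term),
                      horiz = TRUE, las = 1,
                      xlab = "standardized effect |t|",
                      main = paste("Pareto of effects:", x$response))
  } else {
    me <- x$main_effects
    facs <- unique(me$factor)
    old <- graphics::par(mfrow = c(1, length(facs)))
    on.exit(graphics::par(old))
    for (f in facs) {
      m <- me[me$factor == f, ]
      graphics::plot(m$level, m$mean, type = "b", xlab = f,
                     ylab = paste("mean", x$response))
    }
  }
  invisible(x)
}
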