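#' Define a calibration problem
#'
#' Free parameters are applied to a base scenario through `apply_par`, a
#' function `(config, values) -> config`, so any configuration field
#' (arrival scale, a service-time string, a capacity) can be tuned. The
#' default discrepancy is the sum of squared signed percentage
#' differences over the KPIs named in `target` — the same currency the
#' validation table uses; `discrepancy = "quantile"` compares LOS
#' quantiles instead.
#'
#' @param config base [scenario_config()].
#' @param free data.frame with columns `name`, `init`, `lower`, `upper`.
#' @param target data.frame `variable, real_minutes` of reference KPIs.
#' @param apply_par function `(config, named numeric) -> scenario_config`.
#' @param discrepancy `"kpi_pct"` (default) or `"quantile"`.
#' @param stratum passed to [compute_kpis()].
#' @return object of class `calibration_problem`.
#' @export
calibration_problem <- function(config, free, target, apply_par,
                                discrepancy = c("kpi_pct", "quantile"),
                                stratum = "zone") {
  stopifnot(inherits(config, "scenario_config"), is.function(apply_par),
            all(c("name", "init", "lower", "upper") %in% names(free)))
  if (any(free$init < free$lower | free$init > free$upper))
    stop("initial values must lie within bounds")
  discrepancy <- match.arg(discrepancy)
  structure(list(config = config, free = free, target = target,
                 apply_par = apply_par, discrepancy = discrepancy,
                 stratum = stratum),
            class = "calibration_problem")
}

.cal_objective <- function(problem) {
  tgt <- problem$target
  function(theta) {
    names(theta) <- problem$free$name
    cfg <- problem$apply_par(problem$config, theta)
    logs <- run_scenario(cfg)     # same seed every call: CRN objective
    kp <- compute_kpis(logs, stratum = problem$stratum)
    if (problem$discrepancy == "kpi_pct") {
      vt <- validate_kpis(kp, tgt)
      sum(vt$pct_diff^2)
    } else {
      stop("quantile discrepancy requires a reference event log; ",
           "use qq_pp() directly")
    }
  }
}

#' Calibrate free model parameters against reference KPIs
#'
#' Derivative-free minimization of the discrepancy by Nelder-Mead with
#' box projection and restarts, within an evaluation budget. Every
#' simulator evaluation reuses the scenario seed (common random
#' numbers), making the objective quasi-deterministic. A run that
#' exhausts its budget without meeting the tolerance returns
#' `converged = FALSE` rather than an error.
#'
#' @param problem a [calibration_problem()].
#' @param budget maximum objective evaluations (>= 10).
#' @param seed seed for the search's own randomness (restart jitter).
#' @param tol absolute objective tolerance for convergence.
#' @param restarts maximum restarts after stagnation.
#' @return object of class `calibration_result`: `par` (named fitted
#'   values), `value`, `initial_value`, `trace` (best-so-far per
#'   evaluation, non-increasing), `evaluations`, `converged`.
#' @export
calibrate <- function(problem, budget = 200, seed = 1, tol = 1e-6,
                      restarts = 2) {
  stopifnot(inherits(problem, "calibration_problem"))
  free <- problem$free
  if (nrow(free) == 0) {
    v <- .cal_objective(problem)(numeric(0))
    return(structure(list(par = numeric(0), value = v, initial_value = v,
                          trace = v, evaluations = 1L, converged = TRUE),
                     class = "calibration_result"))
  }
  if (budget < 10) stop("budget must be at least 10")
  obj <- .cal_objective(problem)
  lower <- free$lower; upper <- free$upper
  proj <- function(x) pmin(pmax(x, lower), upper)

  evals <- 0L
  best_val <- Inf; best_par <- proj(free$init); trace <- numeric(0)
  f <- function(x) {
    if (evals >= budget) return(NA_real_)
    evals <<- evals + 1L
    v <- obj(proj(x))
    if (v < best_val) { best_val <<- v; best_par <<- proj(x) }
    trace[evals] <<- best_val
    v
  }

  rng <- random_stream(seed, "calibrate")
  x0 <- proj(free$init)
  v0 <- f(x0)
  initial_value <- v0
  attempt <- 0L
  while (evals < budget && best_val > tol && attempt <= restarts) {
    start <- if (attempt == 0L) x0 else
      proj(best_par + with_stream(rng, stats::rnorm(length(x0))) *
             (upper - lower) * 0.1)
    .nelder_mead_box(f, start, lower, upper,
                     max_eval = budget - evals, tol = tol)
    attempt <- attempt + 1L
  }
  structure(list(par = stats::setNames(best_par, free$name),
                 value = best_val, initial_value = initial_value,
                 trace = trace, evaluations = evals,
                 converged = best_val <= tol ||
                   (length(trace) > 5 &&
                    abs(trace[length(trace)] -
                        trace[max(1, length(trace) - 5)]) < tol)),
            class = "calibration_result")
}

# Nelder-Mead with box projection; mutates the budget through `f`'s
# closure (f returns NA when the budget is gone).
.nelder_mead_box <- function(f, x0, lower, upper, max_eval, tol) {
  n <- length(x0)
  step <- pmax(0.1 * (upper - lower), 1e-8)
  simplex <- rbind(x0, t(sapply(seq_len(n), function(i) {
    x <- x0; x[i] <- min(x[i] + step[i], upper[i])
    if (x[i] == x0[i]) x[i] <- max(x0[i] - step[i], lower[i])
    x
  })))
  vals <- apply(simplex, 1, f)
  if (anyNA(vals)) return(invisible(NULL))
  for (it in seq_len(10 * max_eval)) {
    ord <- order(vals)
    simplex <- simplex[ord, , drop = FALSE]; vals <- vals[ord]
    if (diff(range(vals)) < tol) break
    centroid <- colMeans(simplex[-nrow(simplex), , drop = FALSE])
    worst <- simplex[nrow(simplex), ]
    try_pt <- function(coef) pmin(pmax(centroid + coef * (centroid - worst),
                                       lower), upper)
    xr <- try_pt(1); vr <- f(xr); if (is.na(vr)) break
    if (vr < vals[1]) {
      xe <- try_pt(2); ve <- f(xe); if (is.na(ve)) break
      if (ve < vr) { simplex[nrow(simplex), ] <- xe; vals[length(vals)] <- ve }
      else { simplex[nrow(simplex), ] <- xr; vals[length(vals)] <- vr }
    } else if (vr < vals[length(vals) - 1]) {
      simplex[nrow(simplex), ] <- xr; vals[length(vals)] <- vr
    } else {
      xc <- try_pt(-0.5); vc <- f(xc); if (is.na(vc)) break
      if (vc < vals[length(vals)]) {
        simplex[nrow(simplex), ] <- xc; vals[length(vals)] <- vc
      } else {                                   # shrink toward best
        for (i in 2:nrow(simplex)) {
          simplex[i, ] <- (simplex[1, ] + simplex[i, ]) / 2
          vals[i] <- f(simplex[i, ])
          if (is.na(vals[i])) return(invisible(NULL))
        }
      }
    }
  }
  invisible(NULL)
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Calibration result\n")
  if (length(x$par))
    cat("  par:", paste(names(x$par), signif(x$par, 5),
                        sep = "=", collapse = " "), "\n")
  cat(sprintf("  discrepancy %.6g (from %.6g), %d evaluations, %s\n",
              x$value, x$initial_value, x$evaluations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Distribution-fit diagnostics: histogram, P-P and Q-Q pairs
#'
#' Compares two duration samples (e.g. simulated vs reference
#' arrival-to-doctor times): Q-Q pairs at equally spaced probe
#' probabilities, P-P pairs via each sample's empirical CDF on the
#' pooled support, shared-break histogram counts, and the maximum
#' absolute quantile gap.
#'
#' @param a,b numeric duration samples (minutes), non-empty.
#' @param probes number of probe probabilities; reduced with a warning
#'   if either sample is smaller.
#' @return object of class `fit_diagnostics`: `qq` (p, q_a, q_b),
#'   `pp` (x, F_a, F_b), `histogram` (breaks, counts_a, counts_b),
#'   `max_quantile_gap`.
#' @export
qq_pp <- function(a, b, probes = 100) {
  stopifnot(length(a) > 0, length(b) > 0)
  n <- min(length(a), length(b))
  if (n < probes) {
    warning("samples smaller than probe count; using ", n, " probes")
    probes <- n
  }
  p <- (seq_len(probes) - 0.5) / probes
  qa <- stats::quantile(a, p, names = FALSE, type = 7)
  qb <- stats::quantile(b, p, names = FALSE, type = 7)
  pooled <- sort(unique(c(a, b)))
  Fa <- stats::ecdf(a)(pooled)
  Fb <- stats::ecdf(b)(pooled)
  breaks <- pretty(range(c(a, b)), n = 30)
  structure(list(
    qq = data.frame(p = p, q_a = qa, q_b = qb),
    pp = data.frame(x = pooled, F_a = Fa, F_b = Fb),
    histogram = list(breaks = breaks,
                     counts_a = graphics::hist(a, breaks = breaks,
                                               plot = FALSE)$counts,
                     counts_b = graphics::hist(b, breaks = breaks,
                                               plot = FALSE)$counts),
    max_quantile_gap = max(abs(qa - qb))
  ), class = "fit_diagnostics")
}

#' @export
print.fit_diagnostics <- function(x, ...) {
  cat(sprintf("fit diagnostics: %d Q-Q probes, max quantile gap %.4g\n",
              nrow(x$qq), x$max_quantile_gap))
  invisible(x)
}

#' @export
plot.fit_diagnostics <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::plot(x$qq$q_a, x$qq$q_b, xlab = "sample a quantiles",
                 ylab = "sample b quantiles", main = "Q-Q")
  graphics::abline(0, 1, lty = 2)
  graphics::plot(x$pp$F_a, x$pp$F_b, type = "l", xlab = "F_a",
                 ylab = "F_b", main = "P-P")
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
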