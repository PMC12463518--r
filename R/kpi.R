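#' Compute ED key performance indicators from event logs
#'
#' Pools per-patient durations across replications after warm-up
#' filtering and returns means with standard errors for:
#' \describe{
#'   \item{AtT}{arrival-to-triage, minutes;}
#'   \item{AtD}{arrival-to-doctor (door-to-doctor), minutes;}
#'   \item{LOS1, LOS2}{length of stay in the two strata defined by
#'     `stratum` (default: LOS1 = adult zone, LOS2 = pediatric zone);}
#'   \item{LOS}{pooled length of stay.}
#' }
#'
#' @param logs an `ed_event_log` or a list of them (one per replication).
#' @param warmup_days patients arriving before this are dropped; default
#'   taken from the logs' `warmup` flag.
#' @param stratum how LOS1/LOS2 are defined: `"zone"` (adult/peds),
#'   `"esi"` (3/4) or `"status"` (discharge status).
#' @return object of class `kpi_set`: data.frame with columns
#'   `variable`, `mean`, `se`, `n` and attribute `stratum`.
#' @examples
#' cfg <- scenario_config(horizon_days = 1, warmup_days = 0,
#'                        replications = 1)
#' compute_kpis(run_scenario(cfg))
#' @export
compute_kpis <- function(logs, warmup_days = NULL, stratum = "zone") {
  if (inherits(logs, "ed_event_log")) logs <- list(logs)
  stopifnot(length(logs) > 0,
            all(vapply(logs, inherits, logical(1), "ed_event_log")))
  stratum <- match.arg(stratum, c("zone", "esi", "status"))
  df <- do.call(rbind, lapply(logs, as.data.frame))
  keep <- if (is.null(warmup_days)) !df$warmup else
    df$arrive >= warmup_days * 1440
  df <- df[keep, , drop = FALSE]
  if (!nrow(df))
    stop("no patients remain after warm-up filtering")

  strat <- switch(stratum,
    zone = factor(df$zone, levels = c("adult", "peds")),
    esi = factor(df$esi, levels = c(3, 4)),
    status = factor(df$status))
  levs <- levels(strat)
  if (length(levs) < 2) levs <- c(levs, NA)

  att <- df$triage - df$arrive
  atd <- df$doc - df$arrive
  los <- df$discharge - df$arrive
  msd <- function(x) {
    x <- x[!is.na(x)]
    n <- length(x)
    c(mean = if (n) mean(x) else NA_real_,
      se = if (n > 1) stats::sd(x) / sqrt(n) else 0,
      n = n)
  }
  rows <- rbind(
    AtT = msd(att), AtD = msd(atd),
    LOS1 = msd(los[strat == levs[1]]),
    LOS2 = msd(los[strat == levs[2]]),
    LOS = msd(los)
  )
  out <- data.frame(variable = rownames(rows), rows, row.names = NULL)
  structure(out, class = c("kpi_set", "data.frame"),
            stratum = stratum,
            stratum_levels = stats::setNames(levs[1:2], c("LOS1", "LOS2")),
            replications = length(logs))
}

#' Signed percentage difference between simulated and reference values
#'
#' `(simulated - real) / real * 100`, unrounded and signed; any rounding
#' is a reporting concern handled by [validate_kpis()].
#'
#' @param simulated,real numeric vectors (minutes); `real` must be
#'   positive.
#' @return percentage difference(s).
#' @examples
#' percentage_difference(91, 80)   # 13.75
#' percentage_difference(15, 15)   # 0
#' @export
percentage_difference <- function(simulated, real) {
  stopifnot(is.numeric(simulated), is.numeric(real))
  if (any(real <= 0)) stop("reference values must be positive")
  (simulated - real) / real * 100
}

#' Validate simulated KPIs against reference statistics
#'
#' One row per shared KPI label with the signed percentage difference;
#' `reported` applies the integer-rounding display convention while
#' `pct_diff` keeps the raw value. The overall `pass` attribute is TRUE
#' when every LOS row's absolute percentage difference is at or below
#' `threshold`.
#'
#' @param sim a `kpi_set` (or data.frame with `variable`, `mean`).
#' @param reference a `kpi_set` or data.frame `variable, real_minutes`
#'   (also accepts a `mean` column).
#' @param threshold pass threshold on |LOS percentage difference|,
#'   percent; default 5.
#' @return object of class `validation_table`: data.frame with columns
#'   `variable`, `real`, `simulated`, `pct_diff`, `reported`.
#' @examples
#' ref <- data.frame(variable = c("AtT", "AtD", "LOS1", "LOS2"),
#'                   real_minutes = c(15, 80, 184, 224))
#' sim <- data.frame(variable = c("AtT", "AtD", "LOS1", "LOS2"),
#'                   mean = c(15, 91, 193, 225))
#' validate_kpis(sim, ref)
#' @export
validate_kpis <- function(sim, reference, threshold = 5) {
  sim <- as.data.frame(sim); reference <- as.data.frame(reference)
  if (!"variable" %in% names(sim) || !"mean" %in% names(sim))
    stop("sim must have columns 'variable' and 'mean'")
  real_col <- intersect(c("real_minutes", "mean"), names(reference))[1]
  if (!"variable" %in% names(reference) || is.na(real_col))
    stop("reference must have columns 'variable' and 'real_minutes'")
  labels <- reference$variable
  if (!all(labels %in% sim$variable))
    stop("KPI labels missing from sim: ",
         paste(setdiff(labels, sim$variable), collapse = ", "))
  real <- reference[[real_col]]
  simulated <- sim$mean[match(labels, sim$variable)]
  pd <- percentage_difference(simulated, real)
  out <- data.frame(variable = labels, real = real, simulated = simulated,
                    pct_diff = pd, reported = round(pd))
  is_los <- grepl("^LOS", labels)
  structure(out, class = c("validation_table", "data.frame"),
            threshold = threshold,
            pass = all(abs(pd[is_los]) <= threshold))
}

#' @export
print.validation_table <- function(x, ...) {
  cat("KPI validation (signed percentage difference)\n")
  print.data.frame(x, digits = 4)
  cat(sprintf("LOS rows within %.3g%%: %s\n", attr(x, "threshold"),
              if (isTRUE(attr(x, "pass"))) "yes" else "no"))
  invisible(x)
}

#' @export
print.kpi_set <- function(x, ...) {
  cat(sprintf("KPI set (%d replication(s), stratum by %s)\n",
              attr(x, "replications"), attr(x, "stratum")))
  print.data.frame(x, digits = 4)
  invisible(x)
}
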