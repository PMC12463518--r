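#' Scenario configuration for the ED simulator
#'
#' Bundles everything one simulation scenario needs: resource capacities,
#' service-time laws per task, the 24-hour arrival-rate profile, routing
#' probabilities and run control (horizon, warm-up, replications, seed).
#'
#' Resource pools and their default capacities: the experimental factors
#' (`bed_triage` 1, `nurse_adult` 7, `nurse_peds` 5, `bed_adult` 20,
#' `bed_peds` 8) take the baseline ("current situation") levels of the
#' case study; the remaining pools (`physician_adult` 4, `physician_peds`
#' 2, `triage_nurse` 2, `reg_agent` 2, `technician` 2) are not published
#' and default to values that keep the baseline stable — they are meant
#' to be calibrated, not asserted.
#'
#' Service tasks (all strings in the [parse_distribution()] grammar):
#' registration, triage, triage nurse notes, physician consultation
#' (notes + exam), zone nurse notes, tests (CT / X-ray / Lab plus a
#' result delay), reassessment (physician exam + notes + nurse notes) and
#' the discharge process (nurse notes + discharge + delay).
#'
#' @param capacities named list overriding default pool capacities.
#' @param service named list overriding default service-time strings.
#' @param arrival_profile numeric length-24 vector of hourly arrival
#'   rates (patients/hour); default a smooth mid-day-peaked profile from
#'   [generate_arrival_profile()] totalling `72` patients/day.
#' @param arrival_scale multiplier applied to the profile (calibration
#'   handle), default 1.
#' @param p_peds probability an arrival is pediatric, default 0.3.
#' @param p_esi3 probability of acuity level 3 (vs 4), default 0.5.
#' @param p_tests routing probabilities `c(ct, xray, lab, none)`,
#'   default `c(0.25, 0.25, 0.30, 0.20)`; must sum to 1.
#' @param p_reassess_loop probability of an extra reassessment pass after
#'   the first (everyone gets one pass), default 0.
#' @param horizon_days simulated horizon, default 14.
#' @param warmup_days initial interval discarded by KPI computation,
#'   default 1.
#' @param replications number of replications, default 10.
#' @param seed master seed, default 1.
#' @param queue_warn_cap queue length that triggers an unbounded-queue
#'   warning, default 1000.
#' @return object of class `scenario_config`.
#' @examples
#' cfg <- scenario_config(replications = 2, horizon_days = 2)
#' cfg$capacities$nurse_adult
#' @export
scenario_config <- function(capacities = list(), service = list(),
                            arrival_profile = NULL, arrival_scale = 1,
                            p_peds = 0.3, p_esi3 = 0.5,
                            p_tests = c(ct = 0.25, xray = 0.25,
                                        lab = 0.30, none = 0.20),
                            p_reassess_loop = 0,
                            horizon_days = 14, warmup_days = 1,
                            replications = 10, seed = 1,
                            queue_warn_cap = 1000) {
  caps <- list(
    reg_agent = 2, triage_nurse = 2, bed_triage = 1, technician = 2,
    physician_adult = 4, physician_peds = 2,
    nurse_adult = 7, nurse_peds = 5,
    bed_adult = 20, bed_peds = 8
  )
  unknown <- setdiff(names(capacities), names(caps))
  if (length(unknown)) stop("unknown capacity pool(s): ",
                            paste(unknown, collapse = ", "))
  caps[names(capacities)] <- capacities
  bad <- vapply(caps, function(x) !is.numeric(x) || length(x) != 1 ||
                  x < 0 || x != round(x), logical(1))
  if (any(bad)) stop("capacities must be nonnegative integers: ",
                     paste(names(caps)[bad], collapse = ", "))

  svc <- list(
    registration      = "TRI (2, 3, 5)",
    triage            = "1 + 2 * Gamma (0.1, 2.5, 2.5)",
    triage_notes      = "1.7 * TRIA (1, 0.3, 10.1)",
    consult_notes     = "LogNORM (1.3, 2, 1)",
    consult_exam      = "LogNORM (0.5, 1, 5.5)",
    nurse_notes       = "Gamma (0.77, 0.4667, 13.24)",
    test_ct           = "TRIA (5, 10, 15)",
    test_delay        = "Gamma (0.77, 0.446, 14)",
    test_xray         = "TRIA (5, 7, 10)",
    test_lab          = "TRIA (5, 7, 10)",
    reassess_exam     = "LogNORM (0.5, 1, 5.5)",
    reassess_notes    = "LogNORM (0.1, 1, 2)",
    reassess_nn       = "Gamma (0.77, 0.4667, 13.24)",
    discharge_nn      = "LogNORM (0.1, 1, 2)",
    discharge_proc    = "TRIA (10, 20, 30)",
    discharge_delay   = "LogNORM (1, 2, 4.5)"
  )
  unknown <- setdiff(names(service), names(svc))
  if (length(unknown)) stop("unknown service task(s): ",
                            paste(unknown, collapse = ", "))
  svc[names(service)] <- service
  specs <- suppressWarnings(lapply(svc, parse_distribution))

  if (is.null(arrival_profile))
    arrival_profile <- generate_arrival_profile(72, peak_hour = 11, ratio = 3)
  stopifnot(length(arrival_profile) == 24, all(arrival_profile >= 0),
            arrival_scale >= 0)
  if (length(p_tests) != 4 || any(p_tests < 0) ||
      abs(sum(p_tests) - 1) > 1e-8)
    stop("p_tests must be 4 nonnegative probabilities summing to 1")
  names(p_tests) <- c("ct", "xray", "lab", "none")
  stopifnot(p_peds >= 0, p_peds <= 1, p_esi3 >= 0, p_esi3 <= 1,
            p_reassess_loop >= 0, p_reassess_loop < 1,
            horizon_days > warmup_days, warmup_days >= 0,
            replications >= 1)

  structure(list(
    capacities = caps, service = svc, specs = specs,
    arrival_profile = as.numeric(arrival_profile),
    arrival_scale = arrival_scale,
    p_peds = p_peds, p_esi3 = p_esi3, p_tests = p_tests,
    p_reassess_loop = p_reassess_loop,
    horizon_days = horizon_days, warmup_days = warmup_days,
    replications = as.integer(replications), seed = as.integer(seed),
    queue_warn_cap = queue_warn_cap
  ), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("ED scenario configuration\n")
  cat("  capacities:",
      paste(names(x$capacities), unlist(x$capacities),
            sep = "=", collapse = " "), "\n")
  cat(sprintf("  arrivals: %.1f/day x scale %.3g, peak hour %d\n",
              sum(x$arrival_profile), x$arrival_scale,
              which.max(x$arrival_profile) - 1L))
  cat(sprintf("  horizon %g d, warm-up %g d, %d replication(s), seed %d\n",
              x$horizon_days, x$warmup_days, x$replications, x$seed))
  invisible(x)
}

#' Stable hash of a scenario configuration
#'
#' Identifies which configuration produced an event log (run metadata).
#' Not cryptographic; a 32-bit polynomial hash of the deparsed config.
#'
#' @param config a [scenario_config()].
#' @return character scalar hash.
#' @export
config_hash <- function(config) {
  s <- paste(deparse(unclass(config)[setdiff(names(unclass(config)),
                                             "specs")]), collapse = "")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Read / write scenario configurations as JSON
#'
#' Distribution specs travel as strings in the grammar of
#' [parse_distribution()]; everything else is plain JSON.
#'
#' @param config a [scenario_config()].
#' @param path file path.
#' @return `read_scenario_config()` returns a `scenario_config`;
#'   `write_scenario_config()` returns `path` invisibly.
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  x <- unclass(config)
  x$specs <- NULL
  x$p_tests <- as.list(x$p_tests)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  scenario_config(
    capacities = as.list(x$capacities), service = as.list(x$service),
    arrival_profile = x$arrival_profile, arrival_scale = x$arrival_scale,
    p_peds = x$p_peds, p_esi3 = x$p_esi3,
    p_tests = unlist(x$p_tests), p_reassess_loop = x$p_reassess_loop,
    horizon_days = x$horizon_days, warmup_days = x$warmup_days,
    replications = x$replications, seed = x$seed,
    queue_warn_cap = x$queue_warn_cap
  )
}
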