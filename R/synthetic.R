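#' Smooth 24-hour arrival-rate profile with a daytime peak
#'
#' Raised-cosine profile over hours 0-23: the rate is maximal at
#' `peak_hour`, minimal 12 hours away, with max/min ratio exactly
#' `ratio`, and the hourly values sum to `total` patients/day.
#'
#' @param total patients per day (> 0).
#' @param peak_hour hour of the maximum, 0-23.
#' @param ratio peak-to-trough ratio (>= 1); 1 gives a constant profile.
#' @return numeric length-24 vector of hourly rates (patients/hour).
#' @examples
#' prof <- generate_arrival_profile(240, peak_hour = 11, ratio = 3)
#' sum(prof)            # 240
#' which.max(prof) - 1  # 11
#' @export
generate_arrival_profile <- function(total, peak_hour = 11, ratio = 3) {
  stopifnot(total > 0, ratio >= 1, peak_hour %in% 0:23)
  h <- 0:23
  w <- 1 + (ratio - 1) * (1 + cos(2 * pi * (h - peak_hour) / 24)) / 2
  total * w / sum(w)
}

#' Generate a synthetic timestamp event log with known ground truth
#'
#' Runs the simulator, one replication after another, until `n` patients
#' have been discharged (or `max_reps` is hit), emulating the
#' minute-stamped milestone logs of a hospital information system. The
#' ground truth records the generating configuration, seed and realized
#' KPI means, so downstream KPI, validation, DOE and calibration code
#' can be tested without any external data.
#'
#' @param config a [scenario_config()].
#' @param n number of discharged-patient rows wanted (>= 0).
#' @param seed overrides `config$seed` when given.
#' @param max_reps safety cap on replications consumed.
#' @return list with elements `log` (an `ed_event_log` of exactly `n`
#'   rows, earliest discharges first) and `truth` (list: `seed`,
#'   `config_hash`, `n`, `capacities`, `arrival_per_day`, `kpis` —
#'   realized means over the emitted rows — and `service_means`, the
#'   closed-form mean of every service law).
#' @export
generate_event_log <- function(config, n, seed = NULL, max_reps = 50L) {
  stopifnot(inherits(config, "scenario_config"), n >= 0)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  pieces <- list(); got <- 0L; rep <- 0L
  while (got < n && rep < max_reps) {
    rep <- rep + 1L
    lg <- run_replication(config, rep)
    pieces[[rep]] <- lg
    got <- got + nrow(lg)
  }
  log1 <- if (length(pieces)) do.call(rbind, lapply(pieces, as.data.frame))
          else as.data.frame(run_replication(config, 1L))[0, ]
  log1 <- log1[order(log1$replication, log1$discharge), , drop = FALSE]
  log1 <- utils::head(log1, n)
  rownames(log1) <- NULL
  log1 <- structure(log1, class = c("ed_event_log", "data.frame"),
                    seed = config$seed, config_hash = config_hash(config))
  kp <- if (nrow(log1)) {
    with(log1, c(AtT = mean(triage - arrive), AtD = mean(doc - arrive),
                 LOS = mean(discharge - arrive)))
  } else c(AtT = NA_real_, AtD = NA_real_, LOS = NA_real_)
  truth <- list(
    seed = config$seed, config_hash = config_hash(config), n = n,
    capacities = config$capacities,
    arrival_per_day = sum(config$arrival_profile) * config$arrival_scale,
    kpis = as.list(kp),
    service_means = lapply(config$specs,
                           function(s) unname(dist_moments(s)["mean"]))
  )
  list(log = log1, truth = truth)
}

.TABLE2_HEADER <- c("Arrive", "Reg", "Triage", "Bed", "Doc", "Discharge",
                    "Room", "Discharge status")
.T0 <- as.POSIXct("2022-01-04 00:00:00", tz = "UTC")   # log epoch

#' Read and write timestamp event logs (hospital CSV schema)
#'
#' The CSV carries the columns
#' `Arrive,Reg,Triage,Bed,Doc,Discharge,Room,Discharge status`.
#' The default `"table2"` dialect stamps times as `MM/DD HH:MM`
#' (minute resolution, information-losing, as hospital logs print
#' them); the `"minutes"` dialect writes lossless decimal minutes from
#' simulation start and is what KPI tests use. Zone labels are
#' `"Zone A"` (adult) and `"PEDS"` (pediatric).
#'
#' @param log an `ed_event_log`.
#' @param path CSV file path.
#' @param dialect `"table2"` or `"minutes"`.
#' @return `write_event_log()` returns `path` invisibly;
#'   `read_event_log()` returns an `ed_event_log` (times in minutes;
#'   minute-resolution times when the file was in the `"table2"`
#'   dialect).
#' @export
write_event_log <- function(log, path, dialect = c("table2", "minutes")) {
  dialect <- match.arg(dialect)
  df <- as.data.frame(log)
  fmt <- function(m) {
    if (dialect == "minutes") format(m, trim = TRUE, digits = 15)
    else format(.T0 + floor(m) * 60, "%m/%d %H:%M", tz = "UTC")
  }
  out <- data.frame(
    Arrive = fmt(df$arrive), Reg = fmt(df$reg), Triage = fmt(df$triage),
    Bed = fmt(df$bed), Doc = fmt(df$doc), Discharge = fmt(df$discharge),
    Room = ifelse(df$zone == "peds", "PEDS", "Zone A"),
    check.names = FALSE
  )
  out[["Discharge status"]] <- df$status
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  if (!identical(names(df), .TABLE2_HEADER))
    stop("unexpected event-log header: ", paste(names(df), collapse = ","))
  n <- nrow(df)
  parse_col <- function(x) {
    if (!n) return(numeric(0))
    if (all(grepl("^[0-9.eE+-]+$", x))) as.numeric(x)
    else as.numeric(difftime(as.POSIXct(paste0("2022/", x),
                                        format = "%Y/%m/%d %H:%M",
                                        tz = "UTC"),
                             .T0, units = "mins"))
  }
  out <- data.frame(
    patient = seq_len(n),
    zone = ifelse(df$Room == "PEDS", "peds", "adult"),
    esi = rep(NA_integer_, n),
    arrive = parse_col(df$Arrive), reg = parse_col(df$Reg),
    triage = parse_col(df$Triage), bed = parse_col(df$Bed),
    doc = parse_col(df$Doc), discharge = parse_col(df$Discharge),
    status = df[["Discharge status"]],
    warmup = rep(FALSE, n), replication = rep(1L, n)
  )
  structure(out, class = c("ed_event_log", "data.frame"))
}
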