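#' Generate arrivals from a non-homogeneous Poisson process
#'
#' Arrival epochs are drawn by thinning against the profile maximum; the
#' hourly profile is treated as piecewise-constant over the 24-hour day
#' and repeats for the whole horizon. Zone (adult/pediatric) and acuity
#' (ESI 3/4) are drawn independently from the configured mixes.
#'
#' @param config a [scenario_config()]; uses `arrival_profile`,
#'   `arrival_scale`, `p_peds`, `p_esi3`, `horizon_days` and `seed`.
#' @param rep replication index (selects the random substream).
#' @return data.frame with columns `time` (minutes from start, strictly
#'   increasing), `zone` (`"adult"`/`"peds"`), `esi` (3 or 4).
#' @export
generate_arrivals <- function(config, rep = 1L) {
  stopifnot(inherits(config, "scenario_config"))
  prof <- config$arrival_profile * config$arrival_scale
  horizon <- config$horizon_days * 1440
  lmax <- max(prof) / 60                    # per-minute ceiling rate
  if (lmax <= 0 || horizon <= 0) {
    return(data.frame(time = numeric(0), zone = character(0),
                      esi = integer(0)))
  }
  s_arr <- random_stream(config$seed, "arrivals", rep)
  times <- with_stream(s_arr, {
    out <- numeric(0); t <- 0
    repeat {
      gaps <- stats::rexp(2048, lmax)
      cand <- t + cumsum(gaps)
      keep <- cand[cand < horizon]
      if (length(keep)) {
        rate <- prof[(floor(keep / 60) %% 24) + 1] / 60
        out <- c(out, keep[stats::runif(length(keep)) * lmax < rate])
      }
      t <- t + sum(gaps)
      if (t >= horizon) break
    }
    out
  })
  n <- length(times)
  s_mix <- random_stream(config$seed, "mix", rep)
  u <- with_stream(s_mix, stats::runif(2 * n))
  data.frame(
    time = times,
    zone = ifelse(u[seq_len(n)] < config$p_peds, "peds", "adult"),
    esi = ifelse(u[n + seq_len(n)] < config$p_esi3, 3L, 4L)
  )
}

# resource pool index map (fixed order)
.POOLS <- c("reg_agent", "triage_nurse", "bed_triage", "technician",
            "physician_adult", "physician_peds",
            "nurse_adult", "nurse_peds", "bed_adult", "bed_peds")

#' Run one replication of the ED pathway
#'
#' Executes the patient pathway: registration and triage proceed as
#' parallel branches after arrival (registration may finish after triage
#' has started), both must complete before a zone bed is requested; the
#' bed is held from assignment until discharge completes. Consultation
#' (physician + zone nurse), nurse notes, an optional test (zone nurse +
#' technician), one or more reassessment passes (physician + zone nurse,
#' bed held) and the discharge process (zone nurse, bed held) follow.
#' All service durations and routing decisions are pre-assigned to the
#' patient at arrival from named per-task, per-zone substreams, so that
#' scenarios sharing a seed see common random numbers.
#'
#' @param config a [scenario_config()].
#' @param rep replication index (1-based).
#' @return an `ed_event_log` data.frame of discharged patients with
#'   columns `patient`, `zone`, `esi`, `arrive`, `reg`, `triage`, `bed`,
#'   `doc`, `discharge` (minutes from start), `status`, `warmup`,
#'   `replication`; attributes `n_arrivals`, `n_in_system`, `seed`,
#'   `config_hash`, `queue_warning`.
#' @examples
#' cfg <- scenario_config(horizon_days = 1, warmup_days = 0,
#'                        replications = 1, seed = 7)
#' log1 <- run_replication(cfg)
#' head(log1)
#' @export
run_replication <- function(config, rep = 1L) {
  stopifnot(inherits(config, "scenario_config"))
  arr <- generate_arrivals(config, rep)
  horizon <- config$horizon_days * 1440

  res_cap <- unlist(config$capacities)[.POOLS]
  res_busy <- numeric(length(.POOLS))
  names(res_busy) <- .POOLS
  pool_id <- stats::setNames(seq_along(.POOLS), .POOLS)

  # --- event calendar (grow-on-demand slot vectors) -----------------
  cal_cap <- 512L
  cal_time <- rep(NA_real_, cal_cap)
  cal_fun <- vector("list", cal_cap)
  free_idx <- rev(seq_len(cal_cap))
  now <- 0

  schedule <- function(t, fun) {
    if (!length(free_idx)) {
      add <- length(cal_time)
      cal_time <<- c(cal_time, rep(NA_real_, add))
      cal_fun <<- c(cal_fun, vector("list", add))
      free_idx <<- rev(add + seq_len(add))
    }
    i <- free_idx[length(free_idx)]
    free_idx <<- free_idx[-length(free_idx)]
    cal_time[i] <<- t
    cal_fun[[i]] <<- fun
    invisible(i)
  }

  # --- resource seize/release with a FIFO pending queue -------------
  pend <- vector("list", 64L)
  pend_head <- 1L; pend_tail <- 0L
  queue_warning <- FALSE

  request <- function(pools, fun) {
    pend_tail <<- pend_tail + 1L
    if (pend_tail > length(pend)) pend <<- c(pend, vector("list", length(pend)))
    pend[[pend_tail]] <<- list(pools = pool_id[pools], fun = fun)
    if (pend_tail - pend_head + 1L > config$queue_warn_cap)
      queue_warning <<- TRUE
    dispatch()
  }

  dispatch <- function() {
    i <- pend_head
    while (i <= pend_tail) {
      r <- pend[[i]]
      if (!is.null(r)) {
        ix <- r$pools
        if (all(res_busy[ix] < res_cap[ix])) {
          res_busy[ix] <<- res_busy[ix] + 1
          pend[i] <<- list(NULL)
          r$fun()
        }
      }
      i <- i + 1L
    }
    while (pend_head <= pend_tail && is.null(pend[[pend_head]]))
      pend_head <<- pend_head + 1L
    if (pend_head > 4096L && pend_head > pend_tail) {   # compact
      pend <<- vector("list", 64L); pend_head <<- 1L; pend_tail <<- 0L
    }
    invisible(NULL)
  }

  release <- function(pools) {
    ix <- pool_id[pools]
    res_busy[ix] <<- res_busy[ix] - 1
    stopifnot(all(res_busy >= 0))
    dispatch()
  }

  # --- per-(task, zone) service streams; durations pre-assigned -----
  streams <- new.env(parent = emptyenv())
  svc <- function(task, zone, n = 1) {
    id <- paste0(task, ".", zone)
    if (is.null(streams[[id]]))
      streams[[id]] <- random_stream(config$seed, id, rep)
    as.numeric(dist_sample(config$specs[[task]], n, streams[[id]]))
  }
  s_route <- random_stream(config$seed, "routing", rep)

  draw_patient <- function(zone) {
    u <- with_stream(s_route, stats::runif(2))
    p_cum <- cumsum(config$p_tests)
    test <- c("ct", "xray", "lab", "none")[findInterval(u[1], p_cum) + 1L]
    loops <- if (config$p_reassess_loop > 0)
      sum(with_stream(s_route,
        stats::rgeom(1, 1 - config$p_reassess_loop))) else 0L
    passes <- 1L + loops
    list(
      test = test, passes = passes,
      registration = svc("registration", zone),
      triage = svc("triage", zone) + svc("triage_notes", zone),
      consult = svc("consult_notes", zone) + svc("consult_exam", zone),
      nurse_notes = svc("nurse_notes", zone),
      test_dur = if (test == "none") 0 else
        svc(paste0("test_", test), zone) + svc("test_delay", zone),
      reassess = svc("reassess_exam", zone, passes) +
        svc("reassess_notes", zone, passes) + svc("reassess_nn", zone, passes),
      discharge = svc("discharge_nn", zone) + svc("discharge_proc", zone) +
        svc("discharge_delay", zone)
    )
  }

  # --- output accumulators ------------------------------------------
  n_arr <- nrow(arr)
  out_n <- 0L
  o_id <- integer(n_arr); o_zone <- character(n_arr); o_esi <- integer(n_arr)
  o_arrive <- o_reg <- o_triage <- o_bed <- o_doc <- o_disch <- numeric(n_arr)

  # --- patient pathway as chained closures --------------------------
  start_patient <- function(id, zone, esi) {
    p <- new.env(parent = emptyenv())
    p$arrive <- now; p$branches <- 2L
    p$reg <- p$triage <- p$bed <- p$doc <- NA_real_
    d <- draw_patient(zone)
    phys <- paste0("physician_", zone)
    nurse <- paste0("nurse_", zone)
    bed <- paste0("bed_", zone)

    finish <- function() {
      out_n <<- out_n + 1L
      o_id[out_n] <<- id; o_zone[out_n] <<- zone; o_esi[out_n] <<- esi
      o_arrive[out_n] <<- p$arrive; o_reg[out_n] <<- p$reg
      o_triage[out_n] <<- p$triage; o_bed[out_n] <<- p$bed
      o_doc[out_n] <<- p$doc; o_disch[out_n] <<- now
    }
    do_discharge <- function() {
      request(nurse, function() {
        schedule(now + d$discharge, function() {
          release(c(nurse, bed))
          finish()
        })
      })
    }
    do_reassess <- function(pass) {
      request(c(phys, nurse), function() {
        schedule(now + d$reassess[pass], function() {
          release(c(phys, nurse))
          if (pass < d$passes) do_reassess(pass + 1L) else do_discharge()
        })
      })
    }
    do_tests <- function() {
      if (d$test == "none") return(do_reassess(1L))
      request(c(nurse, "technician"), function() {
        schedule(now + d$test_dur, function() {
          release(c(nurse, "technician"))
          do_reassess(1L)
        })
      })
    }
    do_consult <- function() {
      request(c(phys, nurse), function() {
        p$doc <- now
        schedule(now + d$consult, function() {
          release(c(phys, nurse))
          request(nurse, function() {        # post-consult nurse notes
            schedule(now + d$nurse_notes, function() {
              release(nurse)
              do_tests()
            })
          })
        })
      })
    }
    branch_done <- function() {
      p$branches <- p$branches - 1L
      if (p$branches == 0L) {
        request(bed, function() {
          p$bed <- now
          do_consult()
        })
      }
    }
    request("reg_agent", function() {
      schedule(now + d$registration, function() {
        release("reg_agent")
        p$reg <- now
        branch_done()
      })
    })
    request(c("bed_triage", "triage_nurse"), function() {
      p$triage <- now
      schedule(now + d$triage, function() {
        release(c("bed_triage", "triage_nurse"))
        branch_done()
      })
    })
  }

  for (k in seq_len(n_arr)) {
    local({
      kk <- k
      schedule(arr$time[kk], function()
        start_patient(kk, arr$zone[kk], arr$esi[kk]))
    })
  }

  # --- main loop ----------------------------------------------------
  repeat {
    i <- which.min(cal_time)
    if (!length(i)) break
    t <- cal_time[i]
    f <- cal_fun[[i]]
    cal_time[i] <- NA_real_
    cal_fun[i] <- list(NULL)
    free_idx[length(free_idx) + 1L] <- i
    now <- t
    f()
  }

  if (queue_warning)
    warning("pending-request queue exceeded ", config$queue_warn_cap,
            " (likely an unserved zero-capacity pool)")

  keep <- seq_len(out_n)
  log1 <- data.frame(
    patient = o_id[keep], zone = o_zone[keep], esi = o_esi[keep],
    arrive = o_arrive[keep], reg = o_reg[keep], triage = o_triage[keep],
    bed = o_bed[keep], doc = o_doc[keep], discharge = o_disch[keep],
    status = rep("Discharged with approval", out_n),
    warmup = o_arrive[keep] < config$warmup_days * 1440,
    replication = rep(as.integer(rep), out_n)
  )
  log1 <- log1[order(log1$arrive), , drop = FALSE]
  rownames(log1) <- NULL
  structure(log1,
            class = c("ed_event_log", "data.frame"),
            n_arrivals = n_arr, n_in_system = n_arr - out_n,
            seed = config$seed, replication = as.integer(rep),
            config_hash = config_hash(config),
            queue_warning = queue_warning)
}

#' Run all replications of a scenario
#'
#' Replications differ only in their substream offsets; warm-up filtering
#' is applied downstream by [compute_kpis()], not here.
#'
#' @param config a [scenario_config()].
#' @return list of `ed_event_log`, one per replication.
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  lapply(seq_len(config$replications),
         function(r) run_replication(config, r))
}
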