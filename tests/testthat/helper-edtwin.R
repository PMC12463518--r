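# shared fixtures: all simulation configs here are scaled down from the
# 14-day x 10-replication defaults to keep the suite fast; statistical
# assertions use standard errors computed at the scale actually run.

# small but congested scenario: everything finite, runs in ~0.2 s
fast_config <- function(seed = 1, reps = 1, days = 1, warmup = 0,
                        per_day = 48, ...) {
  scenario_config(
    arrival_profile = generate_arrival_profile(per_day, 11, 3),
    horizon_days = days, warmup_days = warmup,
    replications = reps, seed = seed, ...
  )
}

# all service laws collapsed to distinct constants; ample resources
# so no queueing: path durations are hand-computable
const_service <- list(
  registration = "CONST(3)", triage = "CONST(5)", triage_notes = "CONST(2)",
  consult_notes = "CONST(7)", consult_exam = "CONST(4)",
  nurse_notes = "CONST(6)",
  test_ct = "CONST(10)", test_delay = "CONST(8)",
  test_xray = "CONST(9)", test_lab = "CONST(11)",
  reassess_exam = "CONST(5)", reassess_notes = "CONST(3)",
  reassess_nn = "CONST(6)",
  discharge_nn = "CONST(2)", discharge_proc = "CONST(12)",
  discharge_delay = "CONST(4)"
)

ample_caps <- list(reg_agent = 999, triage_nurse = 999, bed_triage = 999,
                   technician = 999, physician_adult = 999,
                   physician_peds = 999, nurse_adult = 999,
                   nurse_peds = 999, bed_adult = 999, bed_peds = 999)

# single-stage M/M/c reduction: only the consultation draws time and
# only the adult physician pool is finite
mmc_config <- function(lambda_per_hour, mean_service, c_servers,
                       days = 14, reps = 10, seed = 5) {
  svc <- const_service
  svc[] <- "CONST(0)"
  svc$consult_notes <- sprintf("EXPO(%g)", mean_service)
  caps <- ample_caps
  caps$physician_adult <- c_servers
  scenario_config(
    capacities = caps, service = svc,
    arrival_profile = rep(lambda_per_hour, 24),
    p_peds = 0, p_tests = c(0, 0, 0, 1),
    horizon_days = days, warmup_days = 1,
    replications = reps, seed = seed
  )
}

# independent brute-force OLS oracle: explicit normal equations
ols_oracle <- function(X, y) solve(t(X) %*% X, t(X) %*% y)

# build the raw-unit design matrix for a 3-factor model independently
# of the package (main effects + 2-way [+ 3-way] interactions)
oracle_design_matrix <- function(des, three_way = FALSE) {
  tb <- des$TriageBed; zn <- des$ZoneNurse; zb <- des$ZoneBed
  X <- cbind(1, tb, zn, zb, tb * zn, tb * zb, zn * zb)
  if (three_way) X <- cbind(X, tb * zn * zb)
  X
}
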