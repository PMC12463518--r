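test_that("zero arrival profile yields no arrivals, not an error", {
  cfg <- scenario_config(arrival_profile = rep(0, 24), horizon_days = 1,
                         warmup_days = 0, replications = 1)
  expect_identical(nrow(generate_arrivals(cfg)), 0L)
  expect_identical(nrow(run_replication(cfg)), 0L)
})

test_that("NHPP arrival counts match the Poisson closed form", {
  # constant 6/h over 24 h -> count ~ Poisson(144); average over seeds
  n_seeds <- 200
  counts <- vapply(seq_len(n_seeds), function(s) {
    cfg <- scenario_config(arrival_profile = rep(6, 24), horizon_days = 1,
                           warmup_days = 0, replications = 1, seed = s)
    nrow(generate_arrivals(cfg))
  }, numeric(1))
  expect_lt(abs(mean(counts) - 144), 3 * sqrt(144 / n_seeds))
})

test_that("thinning places no arrivals in zero-rate hours", {
  prof <- c(rep(0, 8), rep(10, 8), rep(0, 8))   # daytime-only
  cfg <- scenario_config(arrival_profile = prof, horizon_days = 3,
                         warmup_days = 0, replications = 1, seed = 2)
  arr <- generate_arrivals(cfg)
  hr <- floor(arr$time / 60) %% 24
  expect_true(all(hr >= 8 & hr < 16))
  expect_true(all(diff(arr$time) > 0))
})

test_that("constant service times and ample resources give the hand-computed path sum", {
  cfg <- scenario_config(capacities = ample_caps, service = const_service,
                         arrival_profile = rep(2, 24),
                         p_tests = c(1, 0, 0, 0),   # CT for everyone
                         horizon_days = 1, warmup_days = 0,
                         replications = 1, seed = 4)
  log1 <- as.data.frame(run_replication(cfg))
  expect_gt(nrow(log1), 0)
  # branch: max(reg 3, triage 5 + notes 2); then consult 7+4, nurse 6,
  # CT 10 + delay 8, reassessment 5+3+6, discharge 2+12+4
  expect_equal(log1$discharge - log1$arrive,
               rep(7 + 11 + 6 + 18 + 14 + 18, nrow(log1)))
  expect_equal(log1$doc - log1$arrive, rep(7, nrow(log1)))
  expect_equal(log1$triage - log1$arrive, rep(0, nrow(log1)))
  expect_equal(log1$reg - log1$arrive, rep(3, nrow(log1)))
})

test_that("per-patient milestones are monotone and conservation holds", {
  cfg <- fast_config(seed = 8, days = 2, per_day = 60)
  log1 <- run_replication(cfg)
  df <- as.data.frame(log1)
  expect_true(all(df$arrive <= df$triage))
  expect_true(all(df$triage <= df$bed))
  expect_true(all(df$bed <= df$doc))
  expect_true(all(df$doc <= df$discharge))
  expect_true(all(df$reg >= df$arrive))
  expect_true(all(df$esi %in% c(3L, 4L)))
  expect_identical(attr(log1, "n_arrivals"),
                   nrow(df) + attr(log1, "n_in_system"))
})

test_that("replications are deterministic, distinct, and share a config hash", {
  cfg <- fast_config(seed = 6, reps = 3)
  logs1 <- run_scenario(cfg)
  logs2 <- run_scenario(cfg)
  expect_identical(lapply(logs1, as.data.frame), lapply(logs2, as.data.frame))
  expect_identical(as.data.frame(logs1[[1]]),
                   as.data.frame(run_replication(cfg, 1L)))
  hashes <- vapply(logs1, attr, character(1), "config_hash")
  expect_identical(length(unique(hashes)), 1L)
  expect_false(identical(as.data.frame(logs1[[1]]),
                         as.data.frame(logs1[[2]])))
})

test_that("a zero-capacity required pool triggers the unbounded-queue warning", {
  cfg <- scenario_config(capacities = list(reg_agent = 0),
                         arrival_profile = rep(4, 24), horizon_days = 1,
                         warmup_days = 0, replications = 1,
                         queue_warn_cap = 10)
  expect_warning(log1 <- run_replication(cfg), "queue")
  expect_identical(nrow(log1), 0L)   # nobody ever discharges
})

test_that("adding zone nurses does not increase mean LOS (paired CRN)", {
  # scaled down: 5 replications x 2 days at moderate load
  base <- list(seed = 21, reps = 5, days = 2, warmup = 0.25, per_day = 60)
  run_at <- function(nurses) {
    cfg <- fast_config(seed = base$seed, reps = base$reps,
                       days = base$days, warmup = base$warmup,
                       per_day = base$per_day,
                       capacities = list(nurse_adult = nurses))
    sapply(run_scenario(cfg), function(l) {
      d <- as.data.frame(l); d <- d[!d$warmup & d$zone == "adult", ]
      mean(d$discharge - d$arrive)
    })
  }
  lo <- run_at(5); hi <- run_at(9)
  d <- lo - hi                       # paired by common random numbers
  noise <- 3 * stats::sd(d) / sqrt(length(d))
  expect_gt(mean(d), -noise)         # LOS must not rise beyond MC noise
})
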