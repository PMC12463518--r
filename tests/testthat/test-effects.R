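# published case-study equations (raw factor units); names follow the
# package's term labels.  Adult models: main effects + 2-way terms.
# Pediatric models add the 3-way term.
published_equations <- list(
  AtD_adult = list(
    three_way = FALSE, zone = "adult", response = "AtD",
    beta = c(`(Intercept)` = 10.71, TriageBed = 43.77, ZoneNurse = -0.375,
             ZoneBed = 0.490, `TriageBed:ZoneNurse` = -1.937,
             `TriageBed:ZoneBed` = -0.9792, `ZoneNurse:ZoneBed` = 0.1563)),
  LOS_adult = list(
    three_way = FALSE, zone = "adult", response = "LOS",
    beta = c(`(Intercept)` = -35.0, TriageBed = 52.6, ZoneNurse = 15.04,
             ZoneBed = 4.68, `TriageBed:ZoneNurse` = -2.563,
             `TriageBed:ZoneBed` = -1.062, `ZoneNurse:ZoneBed` = -0.365)),
  AtD_peds = list(
    three_way = TRUE, zone = "peds", response = "AtD",
    beta = c(`(Intercept)` = 86.5, TriageBed = 1.8, ZoneNurse = -6.17,
             ZoneBed = -2.56, `TriageBed:ZoneNurse` = -0.42,
             `TriageBed:ZoneBed` = -0.09, `ZoneNurse:ZoneBed` = 0.303,
             `TriageBed:ZoneNurse:ZoneBed` = 0.026)),
  LOS_peds = list(
    three_way = TRUE, zone = "peds", response = "LOS",
    beta = c(`(Intercept)` = 192, TriageBed = 4.2, ZoneNurse = -9.8,
             ZoneBed = 0.2, `TriageBed:ZoneNurse` = -0.89,
             `TriageBed:ZoneBed` = -0.26, `ZoneNurse:ZoneBed` = -0.09,
             `TriageBed:ZoneNurse:ZoneBed` = 0.060))
)

responses_from <- function(eq, noise = 0, reps = 1, seed = 1) {
  des <- full_factorial(default_factors(eq$zone))
  X <- oracle_design_matrix(des, eq$three_way)
  y0 <- drop(X %*% eq$beta)
  y <- rep(y0, each = reps)
  if (noise > 0)
    y <- y + with_stream(random_stream(seed, "noise"),
                         stats::rnorm(length(y), 0, noise))
  rt <- response_table(des, stats::setNames(data.frame(y), eq$response),
                       replications = reps)
  list(design = des, rt = rt)
}

test_that("noiseless refits recover every published equation exactly", {
  for (nm in names(published_equations)) {
    eq <- published_equations[[nm]]
    rr <- responses_from(eq)
    fit <- fit_ols(rr$rt, eq$response, order = if (eq$three_way) 3 else 2)
    expect_equal(coef(fit)[names(eq$beta)], eq$beta, tolerance = 1e-8,
                 info = nm)
    expect_equal(fit$r2, 100, tolerance = 1e-8, info = nm)
  }
})

test_that("fit_ols equals the explicit normal-equations oracle", {
  eq <- published_equations$LOS_adult
  rr <- responses_from(eq, noise = 5, reps = 2, seed = 3)
  fit <- fit_ols(rr$rt, "LOS", order = 2)
  des_rep <- as.data.frame(rr$rt)
  X <- oracle_design_matrix(des_rep, three_way = FALSE)
  beta_oracle <- as.numeric(ols_oracle(X, des_rep$LOS))
  expect_equal(unname(coef(fit)), beta_oracle, tolerance = 1e-8)
})

test_that("constant response gives zero slopes and intercept = constant", {
  des <- full_factorial(default_factors("adult"))
  rt <- response_table(des, data.frame(LOS = rep(42, 27)))
  fit <- fit_ols(rt, "LOS")
  expect_equal(unname(coef(fit)["(Intercept)"]), 42)
  expect_equal(unname(coef(fit)[-1]), rep(0, 6), tolerance = 1e-10)
})

test_that("R-squared is invariant to affine rescaling of the response", {
  eq <- published_equations$LOS_adult
  rr <- responses_from(eq, noise = 10, reps = 3, seed = 5)
  f1 <- fit_ols(rr$rt, "LOS")
  rt2 <- rr$rt; rt2$LOS <- 1.8 * rt2$LOS + 32    # minutes -> odd units
  f2 <- fit_ols(rt2, "LOS")
  expect_equal(f1$r2, f2$r2, tolerance = 1e-10)
  expect_equal(f1$adj_r2, f2$adj_r2, tolerance = 1e-10)
})

test_that("coefficients under noise are recovered within 4 SE (MC)", {
  # 100 simulations, 10 reps/point, known linear truth
  eq <- published_equations$AtD_adult
  hits <- 0; sims <- 100
  for (s in seq_len(sims)) {
    rr <- responses_from(eq, noise = 8, reps = 10, seed = s)
    fit <- fit_ols(rr$rt, "AtD")
    z <- abs(coef(fit)[names(eq$beta)] - eq$beta) / fit$se[names(eq$beta)]
    hits <- hits + all(z < 4)
  }
  expect_gt(hits / sims, 0.95)
})

test_that("main-effect coefficient signs agree with level-mean differences", {
  des <- full_factorial(default_factors("adult"))
  y <- with(as.data.frame(des), 100 - 6 * ZoneNurse + 2 * ZoneBed +
              0.1 * TriageBed)
  rt <- response_table(des, data.frame(LOS = y))
  fit <- fit_ols(rt, "LOS", order = 1)
  df <- as.data.frame(rt)
  for (f in c("TriageBed", "ZoneNurse", "ZoneBed")) {
    m <- tapply(df$LOS, df[[f]], mean)
    expect_equal(sign(unname(coef(fit)[f])),
                 sign(unname(m[length(m)] - m[1])), info = f)
  }
})

test_that("partial-F ANOVA flags degenerate fits and rejects saturated ones", {
  eq <- published_equations$LOS_adult
  rr <- responses_from(eq)                   # noiseless
  fit <- fit_ols(rr$rt, "LOS")
  at <- effects_anova(fit)
  expect_true(attr(at, "degenerate"))
  expect_true(all(is.infinite(at$F)))

  # saturated: 3 points, 3 coefficients
  des1 <- full_factorial(list(doe_factor("A", c(1, 2, 4))))
  rt1 <- response_table(des1, data.frame(LOS = c(1, 2, 3)))
  fit1 <- fit_ols(rt1, "LOS", order = 2)     # intercept + A on 3 pts: df=1
  des2 <- structure(des1[1:2, ], factors = attr(des1, "factors"),
                    class = class(des1))
  rt2 <- response_table(des2, data.frame(LOS = c(1, 2)))
  expect_error(effects_anova(fit_ols(rt2, "LOS", order = 1)), "saturated")
})

test_that("a single dominant factor wins the power test and the Pareto", {
  des <- full_factorial(default_factors("adult"))
  reps <- 10; sigma <- 4
  zn <- rep(des$ZoneNurse, each = reps)
  y <- 200 - 10 * sigma / 2 * (zn - 9) / 2 +   # ~10-sigma planted effect
    with_stream(random_stream(77, "pw"), stats::rnorm(27 * reps, 0, sigma))
  rt <- response_table(des, data.frame(LOS = y), replications = reps)
  fit <- fit_ols(rt, "LOS")
  at <- effects_anova(fit)
  expect_lt(at$p[at$term == "ZoneNurse"], 0.001)
  es <- effect_summaries(rt, fit)
  expect_identical(es$pareto$term[1], "ZoneNurse")
  # balanced design: factor-level means average to the grand mean
  me <- es$main_effects
  for (f in unique(me$factor))
    expect_equal(mean(me$mean[me$factor == f]), mean(y), tolerance = 1e-10)
})

test_that("additive truth yields parallel interaction cell means", {
  des <- full_factorial(default_factors("adult"))
  y <- with(as.data.frame(des), 50 + 3 * ZoneNurse - 1.5 * ZoneBed)
  rt <- response_table(des, data.frame(LOS = y))
  fit <- fit_ols(rt, "LOS", order = 1)
  es <- effect_summaries(rt, fit)
  cells <- es$interactions
  pr <- cells[cells$factor_a == "ZoneNurse" & cells$factor_b == "ZoneBed", ]
  m <- with(pr, tapply(mean, list(level_a, level_b), identity))
  # parallel profiles: column differences constant across rows
  expect_equal(max(abs(diff(t(apply(m, 1, diff))))), 0, tolerance = 1e-10)

  # constant response -> all standardized effects zero-ish (0/0 guarded)
  rt0 <- response_table(des, data.frame(LOS = rep(7, 27)))
  es0 <- effect_summaries(rt0, fit_ols(rt0, "LOS"))
  expect_true(all(is.na(es0$pareto$effect) | es0$pareto$effect < 1e-6))
})

test_that("singular designs raise an explicit aliased-term error", {
  des <- full_factorial(default_factors("adult"))
  sub <- des[des$TriageBed == 1, ]
  rt <- structure(cbind(sub, replication = 1L,
                        LOS = stats::rnorm(nrow(sub))),
                  factor_names = c("TriageBed", "ZoneNurse", "ZoneBed"),
                  class = c("response_table", "data.frame"))
  expect_error(fit_ols(rt, "LOS"), "singular design.*TriageBed")
})

test_that("equation text renders in reporting style", {
  des <- full_factorial(default_factors("adult"))
  y <- with(as.data.frame(des), -35 + 15 * ZoneNurse)
  rt <- response_table(des, data.frame(LOS = y))
  txt <- equation_text(fit_ols(rt, "LOS", order = 1))
  expect_match(txt, "^LOS = -35")
  expect_match(txt, "\\+ 15 ZoneNurse")
})
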