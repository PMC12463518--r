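#' Experimental factors for the resource study
#'
#' A factor names a resource pool and its ordered candidate capacities
#' (Level 0 = current, higher levels = added capacity). The default
#' three-factor, three-level set per zone mirrors the case study:
#' TriageBed (1, 2, 3), ZoneNurse (adult 7, 9, 11; peds 5, 7, 9) and
#' ZoneBed (adult 20, 26, 32; peds 8, 10, 12).
#'
#' @param name factor label, e.g. `"ZoneNurse"`.
#' @param levels ordered numeric capacities (>= 2 distinct, increasing).
#' @param resource capacity key in [scenario_config()] this factor sets,
#'   e.g. `"nurse_adult"`.
#' @return object of class `doe_factor`.
#' @export
doe_factor <- function(name, levels, resource = name) {
  stopifnot(is.character(name), length(levels) >= 2)
  levels <- as.numeric(levels)
  if (any(diff(levels) <= 0)) stop("levels must be strictly increasing")
  structure(list(name = name, levels = levels, resource = resource),
            class = "doe_factor")
}

#' @rdname doe_factor
#' @param zone `"adult"` or `"peds"`.
#' @export
default_factors <- function(zone = c("adult", "peds")) {
  zone <- match.arg(zone)
  if (zone == "adult") list(
    doe_factor("TriageBed", c(1, 2, 3), "bed_triage"),
    doe_factor("ZoneNurse", c(7, 9, 11), "nurse_adult"),
    doe_factor("ZoneBed", c(20, 26, 32), "bed_adult")
  ) else list(
    doe_factor("TriageBed", c(1, 2, 3), "bed_triage"),
    doe_factor("ZoneNurse", c(5, 7, 9), "nurse_peds"),
    doe_factor("ZoneBed", c(8, 10, 12), "bed_peds")
  )
}

#' Enumerate a full-factorial design
#'
#' Cartesian product of all factor levels in deterministic lexicographic
#' order (first factor slowest, last factor fastest). A design over k
#' three-level factors has exactly 3^k points and each level of each
#' factor appears in 3^(k-1) of them.
#'
#' @param factors list of [doe_factor()].
#' @return data.frame with column `point` and one column per factor
#'   (raw capacity units); attribute `factors` keeps the definitions.
#' @examples
#' nrow(full_factorial(default_factors("adult")))  # 27
#' @export
full_factorial <- function(factors) {
  stopifnot(length(factors) >= 1,
            all(vapply(factors, inherits, logical(1), "doe_factor")))
  nms <- vapply(factors, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate factor names: ",
                               paste(nms[duplicated(nms)], collapse = ", "))
  grid <- rev(expand.grid(rev(lapply(factors, `[[`, "levels")),
                          KEEP.OUT.ATTRS = FALSE))
  names(grid) <- nms
  out <- cbind(point = seq_len(nrow(grid)), grid)
  structure(out, factors = factors, class = c("doe_design", "data.frame"))
}

#' Run a designed experiment over the simulator
#'
#' Each design point is simulated with the same master seed so all
#' points share common random numbers (identical arrival epochs and
#' entity-level service draws), which sharpens between-point contrasts.
#' Responses are post-warm-up per-replication KPI means for the chosen
#' zone.
#'
#' @param design a [full_factorial()] design.
#' @param base_config base [scenario_config()]; factor columns override
#'   its capacities point by point.
#' @param zone which zone's responses to record (`"adult"`/`"peds"`).
#' @param replications per point; default from `base_config`.
#' @param seed master seed; default from `base_config`.
#' @return `response_table` data.frame: `point`, factor columns,
#'   `replication`, `AtD`, `LOS` (minutes); attributes `factor_names`,
#'   `zone`.
#' @export
run_design <- function(design, base_config, zone = "adult",
                       replications = NULL, seed = NULL) {
  stopifnot(inherits(design, "doe_design"),
            inherits(base_config, "scenario_config"))
  zone <- match.arg(zone, c("adult", "peds"))
  factors <- attr(design, "factors")
  nms <- vapply(factors, `[[`, character(1), "name")
  reps <- if (is.null(replications)) base_config$replications
          else as.integer(replications)
  seed <- if (is.null(seed)) base_config$seed else as.integer(seed)

  rows <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    caps <- as.list(base_config$capacities)
    for (f in factors) {
      lev <- design[i, f$name]
      if (lev < 0) stop("infeasible capacity at point ", design$point[i],
                        ": ", f$name, " = ", lev)
      caps[[f$resource]] <- lev
    }
    cfg <- scenario_config(
      capacities = caps, service = base_config$service,
      arrival_profile = base_config$arrival_profile,
      arrival_scale = base_config$arrival_scale,
      p_peds = base_config$p_peds, p_esi3 = base_config$p_esi3,
      p_tests = base_config$p_tests,
      p_reassess_loop = base_config$p_reassess_loop,
      horizon_days = base_config$horizon_days,
      warmup_days = base_config$warmup_days,
      replications = reps, seed = seed,
      queue_warn_cap = base_config$queue_warn_cap
    )
    logs <- run_scenario(cfg)
    resp <- do.call(rbind, lapply(seq_along(logs), function(r) {
      df <- as.data.frame(logs[[r]])
      df <- df[!df$warmup & df$zone == zone, , drop = FALSE]
      data.frame(replication = r,
                 AtD = mean(df$doc - df$arrive),
                 LOS = mean(df$discharge - df$arrive))
    }))
    rows[[i]] <- cbind(point = design$point[i],
                       design[i, nms, drop = FALSE], resp,
                       row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("response_table", "data.frame"),
            factor_names = nms, zone = zone, seed = seed)
}

#' Assemble a response table from externally computed responses
#'
#' Used by the analysis layer and in tests where responses come from a
#' known function of the factors rather than the simulator.
#'
#' @param design a [full_factorial()] design.
#' @param responses data.frame of response columns, `nrow(design) * reps`
#'   rows, point-major order.
#' @param replications replications per point.
#' @return a `response_table`.
#' @export
response_table <- function(design, responses, replications = 1L) {
  stopifnot(inherits(design, "doe_design"))
  nms <- vapply(attr(design, "factors"), `[[`, character(1), "name")
  idx <- rep(seq_len(nrow(design)), each = replications)
  out <- cbind(point = design$point[idx], design[idx, nms, drop = FALSE],
               replication = rep(seq_len(replications), nrow(design)),
               as.data.frame(responses), row.names = NULL)
  rownames(out) <- NULL
  structure(out, class = c("response_table", "data.frame"),
            factor_names = nms, zone = NA_character_)
}
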