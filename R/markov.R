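#' Canonical health states
#'
#' The model distinguishes absence of cancer, three undetected tumor stages
#' (<1 cm, >1 cm, advanced/regional), the corresponding detected states (one
#' cycle, during which work-up and treatment costs fall), two post-treatment
#' states (after simple vs intensive therapy) and death. Internally the
#' undetected and post-treatment states are expanded into yearly sub-states
#' that track time since onset (stage dwell) and time since treatment
#' (mortality cut-off); [aggregate_occupancy()] folds them back onto this
#' canonical set.
#'
#' @return Character vector of the ten canonical state names.
#' @export
health_states <- function() {
  c("HEALTHY", "UNDET_SMALL", "UNDET_LARGE", "UNDET_ADV",
    "DET_SMALL", "DET_LARGE", "DET_ADV",
    "POST_SIMPLE", "POST_INTENSIVE", "DEAD")
}

# ---- internal engine -------------------------------------------------------
# Precomputes everything both the cohort propagation and the individual-level
# microsimulation need, so the two consume one transition logic.
build_engine <- function(strategy, params, life_table, exam_price = NULL,
                         horizon_cycles = params$horizon_years) {
  strategy <- match_strategy(strategy)
  p <- params
  ds <- as.integer(p$dwell_small); dl <- as.integer(p$dwell_large)
  pk <- p$post_mort_years
  npost <- if (is.finite(pk)) as.integer(pk) + 1L else 1L

  nm <- c("HEALTHY",
          paste0("UNDET_SMALL_", seq_len(ds)),
          paste0("UNDET_LARGE_", seq_len(dl)),
          "UNDET_ADV", "DET_SMALL", "DET_LARGE", "DET_ADV",
          paste0("POST_SIMPLE_", seq_len(npost)),
          paste0("POST_INT_L_", seq_len(npost)),
          paste0("POST_INT_A_", seq_len(npost)),
          "DEAD")
  ns <- length(nm)
  iH <- 1L
  iUS <- 1L + seq_len(ds)
  iUL <- 1L + ds + seq_len(dl)
  iUA <- 2L + ds + dl
  iDS <- iUA + 1L; iDL <- iUA + 2L; iDA <- iUA + 3L
  iPS <- iDA + seq_len(npost)
  iPIL <- iDA + npost + seq_len(npost)
  iPIA <- iDA + 2L * npost + seq_len(npost)
  iDEAD <- ns

  cls <- classification_probabilities(strategy, p)
  se <- cls[["p_detect_given_cancer"]]
  p_fp <- cls[["p_fp_given_healthy"]]
  esc <- p$p_nplus_large + (1 - p$p_nplus_large) * (1 - p$p_r0_large)

  util <- rep(p$u_healthy, ns)
  util[c(iDS, iDL, iDA)] <- c(p$u_det_small, p$u_det_large, p$u_det_advanced)
  util[iPS] <- p$u_post_simple
  util[c(iPIL, iPIA)] <- p$u_post_intensive
  util[iDEAD] <- p$u_dead

  q_undet <- annualize_risk(p$p_death_undetected_10y, 10)
  qtum <- numeric(ns)
  qtum[c(iUS, iUL, iUA)] <- q_undet
  qtum[c(iDS, iDL, iDA)] <- c(p$q_det_small, p$q_det_large, p$q_det_advanced)
  if (is.finite(pk)) {
    if (pk > 0) {
      k <- seq_len(as.integer(pk))
      qtum[iPS[k]] <- p$q_det_small
      qtum[iPIL[k]] <- p$q_det_large
      qtum[iPIA[k]] <- p$q_det_advanced
    }
  } else { # stage-specific mortality persists for the whole horizon
    qtum[iPS] <- p$q_det_small
    qtum[iPIL] <- p$q_det_large
    qtum[iPIA] <- p$q_det_advanced
  }

  h <- as.integer(horizon_cycles)
  q_bg <- if (p$background_mortality == "entry_age_constant") {
    q0 <- if (!is.na(p$q_background)) p$q_background
          else annual_death_probability(life_table, p$start_age)
    rep(q0, h)
  } else {
    base <- if (!is.na(p$q_background))
      p$q_background / annual_death_probability(life_table, p$start_age)
    else 1
    pmin(1, base * annual_death_probability(life_table, p$start_age + 0:(h - 1)))
  }
  p_die <- 1 - outer(1 - q_bg, 1 - qtum) # h x ns matrix, competing risks
  p_die[, iDEAD] <- 0

  list(strategy = strategy, params = p, horizon = h, ns = ns, state_names = nm,
       iH = iH, iUS = iUS, iUL = iUL, iUA = iUA, iDS = iDS, iDL = iDL,
       iDA = iDA, iPS = iPS, iPIL = iPIL, iPIA = iPIA, iDEAD = iDEAD,
       se = se, p_fp = p_fp, esc = esc,
       exam_price = if (is.null(exam_price)) p$cost_exam[[strategy]] else exam_price,
       fp_cost = expected_workup_cost(strategy, "healthy", p),
       tp_cost = expected_workup_cost(strategy, "cancer", p),
       treat = c(small = p$cost_treat_small, large = p$cost_treat_large,
                 advanced = p$cost_treat_advanced),
       util = util, p_die = p_die,
       interval = as.integer(p$screening_interval),
       u_fp = p$u_fp_decrement, incidence = p$incidence_annual)
}

engine_initial_occupancy <- function(eng) {
  occ <- numeric(eng$ns)
  occ[eng$iH] <- 1 - eng$params$pretest_prob
  occ[eng$iUS[1L]] <- eng$params$pretest_prob
  names(occ) <- eng$state_names
  occ
}

# One model cycle. Event order (deaths take effect at cycle end):
#   1. screening round (if due): exam charge, false positives, detection with
#      work-up + one-off treatment cost; large tumors escalate to the advanced
#      pathway with probability p_nplus + (1-p_nplus)(1-p_r0)
#   2. QALY accrual: full-year state membership of everyone alive after the
#      screen (detected women accrue the detected-state utility in the
#      detection year), minus the false-positive decrement
#   3. death: background and stage-specific risks combined as independent
#      competing risks
#   4. disease onset among surviving healthy women (skipped at cycle 0, where
#      the pre-test prevalence forms the initial undetected mass)
#   5. stage progression of previously undetected tumors; detected states move
#      on to their post-treatment chains
engine_step <- function(eng, occ, cycle) {
  cost <- 0; fp_mass <- 0
  det <- c(small = 0, large = 0, advanced = 0)
  if (cycle %% eng$interval == 0L) {
    alive <- 1 - unname(occ[eng$iDEAD])
    cost <- cost + eng$exam_price * alive
    fp_mass <- unname(occ[eng$iH]) * eng$p_fp
    cost <- cost + fp_mass * eng$fp_cost
    d_s <- sum(occ[eng$iUS]) * eng$se
    d_l <- sum(occ[eng$iUL]) * eng$se
    d_a <- unname(occ[eng$iUA]) * eng$se
    occ[eng$iUS] <- occ[eng$iUS] * (1 - eng$se)
    occ[eng$iUL] <- occ[eng$iUL] * (1 - eng$se)
    occ[eng$iUA] <- occ[eng$iUA] * (1 - eng$se)
    occ[eng$iDS] <- occ[eng$iDS] + d_s
    occ[eng$iDL] <- occ[eng$iDL] + d_l * (1 - eng$esc)
    occ[eng$iDA] <- occ[eng$iDA] + d_a + d_l * eng$esc
    det <- c(small = d_s, large = d_l * (1 - eng$esc),
             advanced = d_a + d_l * eng$esc)
    cost <- cost + (d_s + d_l + d_a) * eng$tp_cost +
      det[["small"]] * eng$treat[["small"]] +
      det[["large"]] * eng$treat[["large"]] +
      det[["advanced"]] * eng$treat[["advanced"]]
  }
  qaly <- sum(occ * eng$util) - eng$u_fp * fp_mass
  # death
  pd <- eng$p_die[cycle + 1L, ]
  dead_new <- sum(occ * pd)
  occ <- occ * (1 - pd)
  occ[eng$iDEAD] <- occ[eng$iDEAD] + dead_new
  # onset
  onset <- if (cycle > 0L) unname(occ[eng$iH]) * eng$incidence else 0
  occ[eng$iH] <- occ[eng$iH] - onset
  # undetected stage progression (new onset enters afterwards)
  chain <- c(eng$iUS, eng$iUL, eng$iUA)
  v <- occ[chain]
  nl <- length(v)
  shifted <- c(0, v[-nl])
  shifted[nl] <- shifted[nl] + v[nl]
  occ[chain] <- shifted
  occ[eng$iUS[1L]] <- occ[eng$iUS[1L]] + onset
  # detected -> post-treatment chains (which advance one sub-state per cycle)
  advance <- function(idx, inflow) {
    w <- occ[idx]; k <- length(w)
    w2 <- c(inflow, w[-k]); w2[k] <- w2[k] + w[k]
    occ[idx] <<- w2
  }
  advance(eng$iPS, occ[eng$iDS])
  advance(eng$iPIL, occ[eng$iDL])
  advance(eng$iPIA, occ[eng$iDA])
  occ[c(eng$iDS, eng$iDL, eng$iDA)] <- 0
  list(occupancy = occ, cost = cost, qaly = qaly, fp = unname(fp_mass),
       detections = det)
}

# ---- public surface --------------------------------------------------------

#' Initial cohort occupancy
#'
#' The cohort enters at `start_age` with the pre-test prevalence as
#' undetected small tumors and the remainder healthy.
#'
#' @param params `screen_params`.
#' @param life_table A `life_table` (defines the expanded state space only
#'   through the engine; occupancies do not depend on it).
#' @return Named occupancy vector over the expanded state space.
#' @export
initial_occupancy <- function(params, life_table = default_life_table()) {
  engine_initial_occupancy(build_engine("DBT", params, life_table))
}

#' Advance the cohort one cycle
#'
#' Applies one model cycle to an occupancy vector (expanded state space, as
#' returned by [initial_occupancy()]): screening round if due, QALY accrual,
#' death, disease onset, stage progression, detected-to-post transitions.
#' See [run_cohort()] for the event-order convention.
#'
#' @param occupancy Named occupancy vector; must be non-negative and sum to 1.
#' @param cycle Cycle index, `>= 0` (cycle 0 is the prevalence screen).
#' @param strategy `"DBT"` or `"AB_MRI"`.
#' @param params `screen_params`.
#' @param life_table A `life_table`.
#' @return List with `occupancy` (after the cycle), `cost` and `qaly`
#'   (undiscounted accruals of the cycle), `fp` (false-positive mass) and
#'   `detections` (newly detected mass by treatment pathway).
#' @export
transition_update <- function(occupancy, cycle, strategy, params,
                              life_table = default_life_table()) {
  eng <- build_engine(strategy, params, life_table,
                      horizon_cycles = max(params$horizon_years, cycle + 1L))
  if (length(occupancy) != eng$ns)
    stop("occupancy must have length ", eng$ns, " (expanded state space)")
  if (any(occupancy < 0)) stop("occupancy has negative mass")
  if (abs(sum(occupancy) - 1) > 1e-8)
    stop("occupancy must sum to 1 (got ", format(sum(occupancy)), ")")
  if (cycle < 0) stop("cycle must be >= 0")
  engine_step(eng, occupancy, as.integer(cycle))
}

#' Propagate the cohort over the model horizon
#'
#' Runs the Markov cohort model for one strategy: starting from the pre-test
#' occupancy, iterates the per-cycle update for `horizon_cycles` annual
#' cycles, recording state occupancies and undiscounted cost and QALY
#' accruals. Deterministic.
#'
#' Conventions: screening rounds fall on cycles `0, interval, ...` and every
#' woman alive attends; treatment cost is charged once, at detection; QALYs
#' value full state membership each cycle with deaths effective at cycle end
#' (no half-cycle correction); background and tumor-specific mortality act as
#' independent competing risks.
#'
#' @param strategy `"DBT"` or `"AB_MRI"`.
#' @param params `screen_params`.
#' @param life_table A `life_table`.
#' @param horizon_cycles Number of annual cycles (default `horizon_years`).
#' @param exam_price Optional override of `cost_exam[strategy]`, used by the
#'   price-threshold and cost-grid analyses.
#' @return An object of class `"cohort_trajectory"`: list with `strategy`,
#'   `occupancy` (matrix, `horizon+1` rows), `cost`, `qaly`, `fp`,
#'   `detections`, `ages`.
#' @examples
#' traj <- run_cohort("DBT", default_parameters())
#' discounted_totals(traj, 0.03)
#' @export
run_cohort <- function(strategy, params, life_table = default_life_table(),
                       horizon_cycles = params$horizon_years,
                       exam_price = NULL) {
  h <- as.integer(horizon_cycles)
  if (h < 1L) stop("horizon_cycles must be >= 1")
  eng <- build_engine(strategy, params, life_table, exam_price, h)
  occ <- engine_initial_occupancy(eng)
  occm <- matrix(0, h + 1L, eng$ns, dimnames = list(0:h, eng$state_names))
  occm[1L, ] <- occ
  cost <- qaly <- fp <- numeric(h)
  dets <- matrix(0, h, 3L, dimnames = list(NULL, c("small", "large", "advanced")))
  for (t in 0:(h - 1L)) {
    st <- engine_step(eng, occ, t)
    occ <- st$occupancy
    occm[t + 2L, ] <- occ
    cost[t + 1L] <- st$cost
    qaly[t + 1L] <- st$qaly
    fp[t + 1L] <- st$fp
    dets[t + 1L, ] <- st$detections
  }
  structure(list(strategy = eng$strategy, occupancy = occm, cost = cost,
                 qaly = qaly, fp = fp, detections = dets,
                 ages = params$start_age + 0:h),
            class = "cohort_trajectory")
}

#' Fold expanded occupancies onto the canonical states
#'
#' @param traj A `cohort_trajectory` (or an expanded occupancy matrix/vector).
#' @return Matrix with one column per [health_states()] entry.
#' @export
aggregate_occupancy <- function(traj) {
  m <- if (inherits(traj, "cohort_trajectory")) traj$occupancy
       else if (is.matrix(traj)) traj
       else matrix(traj, 1L, dimnames = list(NULL, names(traj)))
  canon <- sub("^(UNDET_SMALL|UNDET_LARGE|POST_SIMPLE)_[0-9]+$", "\\1", colnames(m))
  canon <- sub("^POST_INT_[LA]_[0-9]+$", "POST_INTENSIVE", canon)
  out <- sapply(health_states(), function(s)
    rowSums(m[, canon == s, drop = FALSE]))
  if (is.null(dim(out))) out <- matrix(out, 1L, dimnames = list(NULL, health_states()))
  out
}

#' Discounted cumulative cost and effect
#'
#' Sums the per-cycle accruals of a trajectory with annual discounting,
#' `sum(x_t / (1+rate)^t)`, cycle 0 undiscounted.
#'
#' @param traj A `cohort_trajectory`.
#' @param rate Annual discount rate, `>= 0`.
#' @return List of class `"ce_result"` with `cost` (US-$), `effect` (QALYs)
#'   and `strategy`.
#' @export
discounted_totals <- function(traj, rate = 0.03) {
  stopifnot(inherits(traj, "cohort_trajectory"))
  if (rate < 0) stop("rate must be >= 0")
  structure(list(cost = discount_sum(traj$cost, rate),
                 effect = discount_sum(traj$qaly, rate),
                 strategy = traj$strategy),
            class = "ce_result")
}

discount_sum <- function(x, rate) {
  sum(x / (1 + rate)^(seq_along(x) - 1L))
}

#' Export a cohort trajectory as CSV
#'
#' One row per cycle: `cycle`, `age`, one column per canonical state mass,
#' `cost_accrued`, `qaly_accrued` (accruals are `NA` on the final row, which
#' only carries the terminal occupancy).
#'
#' @param traj A `cohort_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  agg <- aggregate_occupancy(traj)
  df <- data.frame(cycle = 0:(nrow(agg) - 1L), age = traj$ages,
                   agg, check.names = FALSE)
  df$cost_accrued <- c(traj$cost, NA)
  df$qaly_accrued <- c(traj$qaly, NA)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
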