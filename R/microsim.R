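#' Individual-level microsimulation of the screening model
#'
#' Simulates `n` women through the identical probabilistic structure the
#' cohort engine propagates in expectation: the same per-cycle event
#' probabilities, event order, cost schedule and QALY conventions, realized
#' as individual Bernoulli draws. It is the package's brute-force oracle --
#' with growing `n` the mean discounted cost and QALYs converge to the
#' cohort values, validating the propagation arithmetic rather than a
#' reimplementation of the disease model.
#'
#' @param strategy `"DBT"` or `"AB_MRI"`.
#' @param params `screen_params`.
#' @param life_table A `life_table`.
#' @param n Number of simulated women, `>= 1`.
#' @param seed Integer RNG seed; identical seeds give identical trajectories.
#' @return List of class `"microsim_result"`: `states` (n x horizon+1 integer
#'   matrix of expanded-state indices at the start of each cycle),
#'   `state_names`, per-cycle accrual matrices `cost` and `qaly`
#'   (n x horizon), event flag matrices `screened`, `fp`, `detected`,
#'   `ages`, and summary statistics `mean_cost`, `se_cost`, `mean_qaly`,
#'   `se_qaly` of the per-woman discounted totals.
#' @examples
#' ms <- simulate_individuals("DBT", default_parameters(), n = 200, seed = 1)
#' ms$mean_qaly
#' @export
simulate_individuals <- function(strategy, params,
                                 life_table = default_life_table(),
                                 n = 1000L, seed = 1L) {
  if (n < 1L) stop("n must be >= 1")
  set.seed(seed)
  eng <- build_engine(strategy, params, life_table)
  h <- eng$horizon
  disc <- (1 + params$discount_rate)^-(0:(h - 1L))

  state <- integer(n)
  init <- stats::runif(n) < params$pretest_prob
  state[init] <- eng$iUS[1L]
  state[!init] <- eng$iH

  states <- matrix(0L, n, h + 1L)
  states[, 1L] <- state
  cost <- qaly <- matrix(0, n, h)
  screened <- fp <- detected <- matrix(FALSE, n, h)

  for (t in 0:(h - 1L)) {
    j <- t + 1L
    alive <- state != eng$iDEAD
    if (t %% eng$interval == 0L) {
      screened[alive, j] <- TRUE
      cost[alive, j] <- cost[alive, j] + eng$exam_price
      # false positives among the healthy
      ih <- which(state == eng$iH)
      is_fp <- ih[stats::runif(length(ih)) < eng$p_fp]
      fp[is_fp, j] <- TRUE
      cost[is_fp, j] <- cost[is_fp, j] + eng$fp_cost
      # detection of undetected tumors
      iu <- which(state %in% c(eng$iUS, eng$iUL, eng$iUA))
      hit <- iu[stats::runif(length(iu)) < eng$se]
      if (length(hit)) {
        detected[hit, j] <- TRUE
        was_small <- state[hit] %in% eng$iUS
        was_large <- state[hit] %in% eng$iUL
        new_state <- integer(length(hit))
        new_state[was_small] <- eng$iDS
        esc_draw <- stats::runif(length(hit)) < eng$esc
        new_state[was_large & !esc_draw] <- eng$iDL
        new_state[was_large & esc_draw] <- eng$iDA
        new_state[!was_small & !was_large] <- eng$iDA
        state[hit] <- new_state
        treat <- ifelse(new_state == eng$iDS, eng$treat[["small"]],
                 ifelse(new_state == eng$iDL, eng$treat[["large"]],
                        eng$treat[["advanced"]]))
        cost[hit, j] <- cost[hit, j] + eng$tp_cost + treat
      }
    }
    # QALY accrual: full-year membership, deaths effective at cycle end
    qaly[, j] <- eng$util[state] - eng$u_fp * fp[, j]
    # death (competing background and tumor-specific risks)
    pd <- eng$p_die[j, state]
    dies <- stats::runif(n) < pd
    state[dies] <- eng$iDEAD
    # onset among surviving healthy women
    if (t > 0L) {
      ih <- which(state == eng$iH)
      onset <- ih[stats::runif(length(ih)) < eng$incidence]
      onset_flag <- logical(n); onset_flag[onset] <- TRUE
    } else onset_flag <- logical(n)
    # stage progression of previously undetected tumors
    chain <- c(eng$iUS, eng$iUL, eng$iUA)
    iu <- which(state %in% chain & !onset_flag)
    pos <- match(state[iu], chain)
    state[iu] <- chain[pmin(pos + 1L, length(chain))]
    state[onset_flag] <- eng$iUS[1L]
    # detected -> post-treatment chains; post chains advance
    advance_post <- function(det_idx, post_idx) {
      ip <- which(state %in% post_idx)
      pos <- match(state[ip], post_idx)
      state[ip] <<- post_idx[pmin(pos + 1L, length(post_idx))]
      state[state == det_idx] <<- post_idx[1L]
    }
    advance_post(eng$iDS, eng$iPS)
    advance_post(eng$iDL, eng$iPIL)
    advance_post(eng$iDA, eng$iPIA)
    states[, j + 1L] <- state
  }
  dcost <- as.vector(cost %*% disc)
  dqaly <- as.vector(qaly %*% disc)
  structure(list(
    strategy = eng$strategy, states = states, state_names = eng$state_names,
    cost = cost, qaly = qaly, screened = screened, fp = fp,
    detected = detected, ages = params$start_age + 0:h,
    n = n, seed = seed,
    discounted_cost = dcost, discounted_qaly = dqaly,
    mean_cost = mean(dcost), se_cost = stats::sd(dcost) / sqrt(n),
    mean_qaly = mean(dqaly), se_qaly = stats::sd(dqaly) / sqrt(n)),
    class = "microsim_result")
}

#' Export individual trajectories as CSV
#'
#' One row per woman-cycle: `id`, `cycle`, `age`, `state` (canonical state
#' name), `screened`, `fp`, `detected`, `cost`, `qaly`.
#'
#' @param ms A `microsim_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_trajectories <- function(ms, path) {
  stopifnot(inherits(ms, "microsim_result"))
  n <- ms$n; h <- ncol(ms$cost)
  canon <- sub("^(UNDET_SMALL|UNDET_LARGE|POST_SIMPLE)_[0-9]+$", "\\1",
               ms$state_names)
  canon <- sub("^POST_INT_[LA]_[0-9]+$", "POST_INTENSIVE", canon)
  df <- data.frame(
    id = rep(seq_len(n), times = h),
    cycle = rep(0:(h - 1L), each = n),
    age = rep(ms$ages[1:h], each = n),
    state = canon[as.vector(ms$states[, 1:h])],
    screened = as.integer(as.vector(ms$screened)),
    fp = as.integer(as.vector(ms$fp)),
    detected = as.integer(as.vector(ms$detected)),
    cost = as.vector(ms$cost),
    qaly = as.vector(ms$qaly))
  df <- df[order(df$id, df$cycle), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
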