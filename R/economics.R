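#' Cohort run plus discounting in one call
#'
#' @param strategy `"DBT"` or `"AB_MRI"`.
#' @param params `screen_params`.
#' @param life_table A `life_table`.
#' @param exam_price Optional exam-price override.
#' @return A `ce_result`.
#' @export
run_ce <- function(strategy, params, life_table = default_life_table(),
                   exam_price = NULL) {
  discounted_totals(run_cohort(strategy, params, life_table,
                               exam_price = exam_price),
                    params$discount_rate)
}

#' Incremental comparison of two strategies
#'
#' Computes incremental cost and effect of the intervention over the
#' comparator, classifies dominance, and -- when neither strategy dominates
#' and the effect difference is non-zero -- the incremental
#' cost-effectiveness ratio on unrounded values.
#'
#' @param intervention,comparator `ce_result` objects.
#' @return List of class `"comparison_result"` with `delta_cost`,
#'   `delta_effect`, `icer` (`NA` when undefined) and `dominance`, one of
#'   `"none"`, `"intervention_dominant"`, `"comparator_dominant"`,
#'   `"equivalent"`.
#' @export
compare_strategies <- function(intervention, comparator) {
  stopifnot(inherits(intervention, "ce_result"), inherits(comparator, "ce_result"))
  dc <- intervention$cost - comparator$cost
  de <- intervention$effect - comparator$effect
  if (!is.finite(dc) || !is.finite(de)) stop("non-finite cost or effect")
  dominance <-
    if (dc == 0 && de == 0) "equivalent"
    else if (dc <= 0 && de >= 0) "intervention_dominant"
    else if (dc >= 0 && de <= 0) "comparator_dominant"
    else "none"
  icer <- if (dominance == "none" && de != 0) dc / de else NA_real_
  structure(list(delta_cost = dc, delta_effect = de, icer = icer,
                 dominance = dominance,
                 intervention = intervention$strategy,
                 comparator = comparator$strategy),
            class = "comparison_result")
}

#' Base-case cost-effectiveness table
#'
#' Runs both strategies at current parameters and assembles the base-case
#' table: discounted cumulative costs and QALYs per strategy, incremental
#' cost and effect of AB-MRI over DBT, and the ICER (or dominance label).
#'
#' @param params `screen_params`.
#' @param life_table A `life_table`.
#' @return List with `table` (data frame, one row per strategy) and
#'   `comparison` (a `comparison_result`).
#' @export
base_case <- function(params = default_parameters(),
                      life_table = default_life_table()) {
  dbt <- run_ce("DBT", params, life_table)
  ab <- run_ce("AB_MRI", params, life_table)
  cmp <- compare_strategies(ab, dbt)
  tab <- data.frame(
    strategy = c("DBT", "AB_MRI"),
    cum_cost = c(dbt$cost, ab$cost),
    inc_cost = c(NA, cmp$delta_cost),
    cum_qaly = c(dbt$effect, ab$effect),
    inc_qaly = c(NA, cmp$delta_effect),
    icer = c(NA, if (cmp$dominance == "intervention_dominant") -Inf else cmp$icer))
  list(table = tab, comparison = cmp)
}

#' Sensitivity of cumulative cost to the exam price
#'
#' The discounted cumulative cost of a strategy is affine in its exam price;
#' the slope equals the discounted expected number of attended screening
#' rounds. Estimated by a finite difference of step `h` and verified by a
#' three-point collinearity check (an error here would indicate a model
#' nonlinearity bug).
#'
#' @param strategy `"DBT"` or `"AB_MRI"`.
#' @param params `screen_params`.
#' @param life_table A `life_table`.
#' @param h Price step in US-$ (default 20).
#' @return Slope in cumulative $ per $ of exam price.
#' @export
exam_cost_slope <- function(strategy, params, life_table = default_life_table(),
                            h = 20) {
  p0 <- params$cost_exam[[match_strategy(strategy)]]
  c0 <- run_ce(strategy, params, life_table, exam_price = p0)$cost
  c1 <- run_ce(strategy, params, life_table, exam_price = p0 + h)$cost
  c2 <- run_ce(strategy, params, life_table, exam_price = p0 + 2 * h)$cost
  if (abs((c2 - c1) - (c1 - c0)) > 1e-6 * max(1, abs(c1 - c0)))
    stop("cumulative cost is not affine in the exam price of ", strategy,
         " (three-point collinearity failed)")
  (c1 - c0) / h
}

#' Solve the AB-MRI examination-price threshold
#'
#' Finds the AB-MRI exam price at which the strategy becomes cost-saving
#' (incremental cost zero) or exactly meets a willingness-to-pay threshold
#' (ICER equal to `wtp`). Uses the affine dependence of cumulative cost on
#' the exam price (incremental effect does not depend on it), then verifies
#' by re-running the cohort at the solved price: the cost-saving residual
#' must be below $0.01 and the WTP-mode ICER within $1/QALY.
#'
#' @param params `screen_params`.
#' @param life_table A `life_table`.
#' @param mode `"cost_saving"` or `"wtp"`.
#' @param wtp Willingness-to-pay threshold in $/QALY (default `params$wtp`).
#' @return Threshold price per examination, US-$.
#' @export
solve_price_threshold <- function(params, life_table = default_life_table(),
                                  mode = c("cost_saving", "wtp"),
                                  wtp = params$wtp) {
  mode <- match.arg(mode)
  p0 <- params$cost_exam[["AB_MRI"]]
  dbt <- run_ce("DBT", params, life_table)
  ab <- run_ce("AB_MRI", params, life_table)
  de <- ab$effect - dbt$effect
  if (mode == "wtp" && de <= 0)
    stop("wtp mode requires a positive incremental effect at base parameters")
  slope <- exam_cost_slope("AB_MRI", params, life_table)
  dc0 <- ab$cost - dbt$cost
  target_dc <- if (mode == "cost_saving") 0 else wtp * de
  p_star <- p0 + (target_dc - dc0) / slope
  if (p_star < 0 || p_star > 10 * p0)
    stop("no threshold price in [0, ", 10 * p0, "]")
  # verification re-run at the solved price
  ab_star <- run_ce("AB_MRI", params, life_table, exam_price = p_star)
  dc_star <- ab_star$cost - dbt$cost
  if (mode == "cost_saving") {
    if (abs(dc_star) >= 0.01)
      stop("threshold verification failed: |delta cost| = ", abs(dc_star))
  } else {
    if (abs(dc_star / de - wtp) >= 1)
      stop("threshold verification failed: ICER off by ", dc_star / de - wtp)
  }
  p_star
}

#' Cost grid over examination prices
#'
#' Re-runs both cohorts over a grid of exam prices and reports discounted
#' cumulative costs and the resulting cost-effectiveness of AB-MRI vs DBT
#' per cell. Cells where AB-MRI dominates (cheaper, at least as effective)
#' are labelled `"cost-saving"`.
#'
#' @param ab_prices,dbt_prices Exam prices (US-$) for AB-MRI (rows) and DBT
#'   (columns).
#' @param params `screen_params`.
#' @param life_table A `life_table`.
#' @return Data frame of class `"cost_grid"`: one row per (ab_price,
#'   dbt_price) pair with `cost_dbt`, `cost_ab`, `icer`, `label`.
#' @export
cost_grid <- function(ab_prices, dbt_prices, params,
                      life_table = default_life_table()) {
  if (any(ab_prices < 0) || any(dbt_prices < 0)) stop("prices must be >= 0")
  dbt_runs <- lapply(dbt_prices, function(p)
    run_ce("DBT", params, life_table, exam_price = p))
  ab_runs <- lapply(ab_prices, function(p)
    run_ce("AB_MRI", params, life_table, exam_price = p))
  rows <- list()
  for (i in seq_along(ab_prices)) for (j in seq_along(dbt_prices)) {
    cmp <- compare_strategies(ab_runs[[i]], dbt_runs[[j]])
    rows[[length(rows) + 1L]] <- data.frame(
      ab_price = ab_prices[i], dbt_price = dbt_prices[j],
      cost_dbt = dbt_runs[[j]]$cost, cost_ab = ab_runs[[i]]$cost,
      icer = cmp$icer,
      label = if (cmp$dominance == "intervention_dominant") "cost-saving"
              else formatC(cmp$icer, format = "f", digits = 2))
  }
  structure(do.call(rbind, rows), class = c("cost_grid", "data.frame"))
}

#' Export a cost grid as CSV
#'
#' Layout mirrors the published table: one row per AB-MRI price, one column
#' per DBT price, each cell `"C_DBT,C_AB,ICER"` (or `cost-saving`).
#'
#' @param grid A `cost_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cost_grid <- function(grid, path) {
  ab <- sort(unique(grid$ab_price))
  dbt <- sort(unique(grid$dbt_price))
  m <- matrix("", length(ab), length(dbt),
              dimnames = list(ab, format(dbt)))
  for (k in seq_len(nrow(grid))) {
    cell <- sprintf("%.2f,%.2f,%s", grid$cost_dbt[k], grid$cost_ab[k],
                    grid$label[k])
    m[match(grid$ab_price[k], ab), match(grid$dbt_price[k], dbt)] <- cell
  }
  df <- data.frame(ab_mri_price = ab, m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
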