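#' Default one-way sensitivity ranges
#'
#' Plus/minus 20% of the base value for every parameter that carries a PSA
#' distribution (probabilities and utilities capped at 1), except the AB-MRI
#' examination price, which spans the published cost scenario range
#' \[180, 350\]. The starting age is varied by +/- 2 years.
#'
#' @param params `screen_params`.
#' @param life_table A `life_table` (resolves the background-mortality mean).
#' @return Named list of `c(low, high)` ranges keyed by parameter path.
#' @export
default_dsa_ranges <- function(params, life_table = default_life_table()) {
  prob_like <- function(nm) {
    grepl("^(sens|spec|u_|p_|q_|pretest|incidence)", nm)
  }
  out <- list()
  for (nm in names(params$distributions)) {
    base <- param_get(params, nm)
    if (nm == "q_background" && is.na(base))
      base <- annual_death_probability(life_table, params$start_age)
    if (nm == "cost_exam[AB_MRI]") {
      out[[nm]] <- c(180, 350)
    } else if (nm == "start_age") {
      out[[nm]] <- c(base - 2, base + 2)
    } else {
      lo <- 0.8 * base; hi <- 1.2 * base
      if (prob_like(nm)) hi <- min(1, hi)
      out[[nm]] <- c(lo, hi)
    }
  }
  out
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' For each parameter, re-runs the full two-strategy comparison with the
#' parameter at its low and at its high value, everything else held at base,
#' and records the resulting incremental cost-effectiveness ratio. A
#' negative ratio means AB-MRI is cost-saving at that input. Entries come
#' back sorted by span (|ICER_high - ICER_low|), the tornado ordering.
#'
#' @param params `screen_params`.
#' @param life_table A `life_table`.
#' @param ranges Named list of `c(low, high)`, default
#'   [default_dsa_ranges()].
#' @return Data frame of class `"tornado"`: `parameter`, `low`, `high`,
#'   `icer_low`, `icer_high`, `span`, sorted by decreasing span.
#' @export
one_way_dsa <- function(params, life_table = default_life_table(),
                        ranges = default_dsa_ranges(params, life_table)) {
  icer_at <- function(nm, value) {
    p <- tryCatch(validate_parameters(param_set(params, nm, value)),
                  error = function(e)
                    stop("invalid range for '", nm, "': ",
                         conditionMessage(e), call. = FALSE))
    dbt <- run_ce("DBT", p, life_table)
    ab <- run_ce("AB_MRI", p, life_table)
    (ab$cost - dbt$cost) / (ab$effect - dbt$effect)
  }
  rows <- lapply(names(ranges), function(nm) {
    r <- ranges[[nm]]
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2])
      stop("invalid range for '", nm, "'")
    il <- icer_at(nm, r[1]); ih <- icer_at(nm, r[2])
    data.frame(parameter = nm, low = r[1], high = r[2],
               icer_low = il, icer_high = ih, span = abs(ih - il))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$span), ]
  rownames(out) <- NULL
  structure(out, class = c("tornado", "data.frame"))
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n_iter` joint parameter samples via [draw_psa_sample()] (all
#' parameters with a distribution tag, independently), runs both cohorts per
#' draw and records the incremental cost and effect of AB-MRI over DBT.
#' Deterministic given `seed`. Draws for which beta moment-matching is
#' infeasible are redrawn; more than 1% infeasible draws is an error.
#'
#' @param params `screen_params`.
#' @param life_table A `life_table`.
#' @param n_iter Number of Monte Carlo iterations, `>= 1`.
#' @param seed Integer RNG seed.
#' @return List of class `"psa_result"`: `draws` (data frame `iteration`,
#'   `delta_cost`, `delta_effect`), `n_iter`, `seed`, `n_redraws`.
#' @export
run_psa <- function(params, life_table = default_life_table(),
                    n_iter = 1000L, seed = 1L) {
  if (n_iter < 1L) stop("n_iter must be >= 1")
  set.seed(seed)
  dc <- de <- numeric(n_iter)
  n_redraws <- 0L
  for (i in seq_len(n_iter)) {
    repeat {
      ps <- tryCatch(draw_psa_sample(params, life_table),
                     error = function(e) e)
      if (!inherits(ps, "error")) break
      n_redraws <- n_redraws + 1L
      if (n_redraws > max(10, 0.01 * n_iter))
        stop("more than 1% of PSA draws infeasible: ",
             conditionMessage(ps))
    }
    dbt <- run_ce("DBT", ps, life_table)
    ab <- run_ce("AB_MRI", ps, life_table)
    dc[i] <- ab$cost - dbt$cost
    de[i] <- ab$effect - dbt$effect
  }
  structure(list(draws = data.frame(iteration = seq_len(n_iter),
                                    delta_cost = dc, delta_effect = de),
                 n_iter = n_iter, seed = seed, n_redraws = n_redraws),
            class = "psa_result")
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA iterations whose
#' net monetary benefit `wtp * delta_effect - delta_cost` is non-negative.
#' All iterations enter the denominator.
#'
#' @param psa A `psa_result`.
#' @param wtp_grid Willingness-to-pay values in $/QALY.
#' @return Data frame of class `"ceac_curve"`: `wtp`,
#'   `fraction_cost_effective`.
#' @export
ceac <- function(psa, wtp_grid) {
  stopifnot(inherits(psa, "psa_result"))
  if (length(wtp_grid) == 0L) stop("wtp_grid must be non-empty")
  frac <- vapply(wtp_grid, function(l)
    mean(l * psa$draws$delta_effect - psa$draws$delta_cost >= 0), numeric(1))
  structure(data.frame(wtp = wtp_grid, fraction_cost_effective = frac),
            class = c("ceac_curve", "data.frame"))
}

#' Export PSA scatter, CEAC and tornado tables
#'
#' CSV writers with fixed schemas: scatter (`iteration`, `delta_cost`,
#' `delta_effect`, `nmb_at_wtp`), CEAC (`wtp`, `fraction_cost_effective`),
#' tornado (`parameter`, `low`, `high`, `icer_low`, `icer_high`, `span`).
#'
#' @param psa A `psa_result`.
#' @param path Output path.
#' @param wtp WTP used for the `nmb_at_wtp` column.
#' @return `path`, invisibly.
#' @export
write_psa <- function(psa, path, wtp = 100000) {
  df <- psa$draws
  df$nmb_at_wtp <- wtp * df$delta_effect - df$delta_cost
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_psa
#' @param curve A `ceac_curve`.
#' @export
write_ceac <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_psa
#' @param tornado A `tornado` data frame.
#' @export
write_tornado <- function(tornado, path) {
  utils::write.csv(as.data.frame(tornado), path, row.names = FALSE)
  invisible(path)
}
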