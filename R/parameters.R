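#' Model strategies
#'
#' The two screening strategies compared by the model: digital breast
#' tomosynthesis (`"DBT"`) and abbreviated breast MRI (`"AB_MRI"`).
#' All strategy-indexed parameter maps cover exactly these two names.
#'
#' @return Character vector of the two strategy names.
#' @export
strategies <- function() c("DBT", "AB_MRI")

#' Default model parameterization
#'
#' Returns the full base-case parameter set for the two-yearly screening
#' comparison of DBT and AB-MRI in women with dense breasts: diagnostic test
#' performances, short- and long-term costs (US-$), health-state utilities,
#' transition probabilities, discounting, and the natural-history calibration
#' (undetected stage dwell times, post-treatment mortality cut-off).
#'
#' Probabilities are annual unless stated otherwise. `p_death_undetected_10y`
#' is a 10-year cumulative risk and is converted to an annual probability by
#' [annualize_risk()] inside the engine.
#'
#' `q_background` is `NA` by default, meaning the background (other-cause)
#' annual death probability is taken from the life table. With
#' `background_mortality = "entry_age_constant"` (the default) the life-table
#' value at `start_age` is applied as a constant annual risk over the whole
#' horizon; `"age_specific"` looks the risk up at the attained age each cycle.
#'
#' @param overrides Named list of fields to override (see Details in
#'   [load_parameters()] for nested strategy-indexed fields).
#' @return A list of class `"screen_params"`.
#' @examples
#' p <- default_parameters()
#' p$sens[["AB_MRI"]]  # 0.957
#' @export
default_parameters <- function(overrides = list()) {
  p <- list(
    # epidemiology
    pretest_prob       = 0.0159, # prevalence of undetected malignancy at first screen
    incidence_annual   = 0.0040, # annual incidence, women with dense breasts
    start_age          = 55L,
    horizon_years      = 30L,
    cycle_length       = 1L,
    screening_interval = 2L,
    # economics
    discount_rate      = 0.03,
    wtp                = 100000,
    # diagnostic test performance
    sens = c(DBT = 0.391, AB_MRI = 0.957),
    spec = c(DBT = 0.974, AB_MRI = 0.867),
    spec_full_mrm              = 0.94, # full-protocol MRM work-up of AB-MRI positives
    sens_full_mrm_confirmation = 1.0,  # full MRM assumed to confirm every referred cancer
    # short-term costs (US-$)
    cost_exam     = c(DBT = 214.20, AB_MRI = 314.00),
    cost_full_mrm = 314.00,
    cost_biopsy   = 1536.00,
    # long-term (treatment) costs, charged once at detection
    cost_treat_small    = 60637,
    cost_treat_large    = 82121,
    cost_treat_advanced = 129387,
    # utilities (QALY weights per year)
    u_healthy        = 1.00,
    u_det_small      = 0.87,
    u_det_large      = 0.74,
    u_det_advanced   = 0.62,
    u_post_simple    = 0.99,
    u_post_intensive = 0.95,
    u_dead           = 0.00,
    u_fp_decrement   = 0.004, # one-off QALY loss per false-positive episode
    # mortality
    p_death_undetected_10y = 0.10,   # cumulative over 10 years while undetected
    q_det_small            = 0.0011, # annual, from detection of a <1 cm tumor
    q_det_large            = 0.0078,
    q_det_advanced         = 0.0181,
    q_background           = NA_real_, # NA: take from life table
    background_mortality   = "entry_age_constant",
    # surgical/pathology outcomes wiring the large-tumor escalation
    p_r0_small   = 1.00,
    p_r0_large   = 0.90,
    p_nplus_small = 0.00,
    p_nplus_large = 0.40,
    # natural-history calibration
    dwell_small     = 3L, # years a tumor stays <1 cm while undetected
    dwell_large     = 4L, # further years >1 cm before advancing
    post_mort_years = 0L  # years the stage-specific death risk persists after the detection year
  )
  p$distributions <- default_distributions(p)
  p <- apply_overrides(p, overrides)
  validate_parameters(p)
}

#' Default PSA distribution assignments
#'
#' One [distribution_spec()] per uncertain parameter, following the
#' distribution families of the input table: beta for probabilities and
#' utilities, gamma for costs, normal for the starting age. Dispersions are
#' not reported in the source material; the default policy is a coefficient
#' of variation of 0.10 for every beta/gamma parameter and an SD of 2 years
#' for the age. All are configurable.
#'
#' @param p Parameter list (used for means where the spread is relative).
#' @return Named list of `distribution_spec` objects keyed by parameter path.
#' @export
default_distributions <- function(p) {
  cv <- 0.10
  b <- function() distribution_spec("beta", cv)
  g <- function() distribution_spec("gamma", cv)
  list(
    pretest_prob       = b(),
    start_age          = distribution_spec("normal", 2 / p$start_age), # SD = 2 years
    incidence_annual   = b(),
    `sens[DBT]`        = b(),
    `spec[DBT]`        = b(),
    `sens[AB_MRI]`     = b(),
    `spec[AB_MRI]`     = b(),
    spec_full_mrm      = b(),
    `cost_exam[DBT]`   = g(),
    `cost_exam[AB_MRI]` = g(),
    cost_full_mrm      = g(),
    cost_biopsy        = g(),
    cost_treat_small    = g(),
    cost_treat_large    = g(),
    cost_treat_advanced = g(),
    u_det_small      = b(),
    u_det_large      = b(),
    u_det_advanced   = b(),
    u_post_simple    = b(),
    u_post_intensive = b(),
    q_background           = b(),
    p_death_undetected_10y = b(),
    q_det_small            = b(),
    q_det_large            = b(),
    q_det_advanced         = b(),
    p_r0_large    = b(),
    p_nplus_large = b()
  )
}

#' PSA distribution specification
#'
#' @param family One of `"beta"`, `"gamma"`, `"normal"`, `"fixed"`.
#' @param dispersion Coefficient of variation (SD as a fraction of the mean),
#'   `>= 0`. Zero gives a degenerate draw at the mean.
#' @return A list of class `"distribution_spec"`.
#' @export
distribution_spec <- function(family = c("beta", "gamma", "normal", "fixed"),
                              dispersion = 0.10) {
  family <- match.arg(family)
  if (!is.numeric(dispersion) || length(dispersion) != 1L || dispersion < 0)
    stop("dispersion must be a single non-negative number")
  structure(list(family = family, dispersion = dispersion),
            class = "distribution_spec")
}

# parameter paths addressable by "name" or "name[STRATEGY]"
param_get <- function(p, path) {
  m <- regmatches(path, regexec("^([^\\[]+)\\[([^]]+)\\]$", path))[[1]]
  if (length(m) == 3L) p[[m[2]]][[m[3]]] else p[[path]]
}
param_set <- function(p, path, value) {
  m <- regmatches(path, regexec("^([^\\[]+)\\[([^]]+)\\]$", path))[[1]]
  if (length(m) == 3L) p[[m[2]]][[m[3]]] <- value else p[[path]] <- value
  p
}

apply_overrides <- function(p, overrides) {
  if (length(overrides) == 0L) return(p)
  if (is.null(names(overrides)) || any(names(overrides) == ""))
    stop("parameter overrides must be named")
  for (k in seq_along(overrides)) { # positional: later duplicates win
    nm <- names(overrides)[k]
    v <- overrides[[k]]
    if (nm %in% c("sens", "spec", "cost_exam")) {
      # strategy-indexed map: merge
      v <- unlist(v)
      bad <- setdiff(names(v), strategies())
      if (length(bad)) stop("unknown strategy in '", nm, "': ", bad[1])
      p[[nm]][names(v)] <- v
    } else if (nm == "distributions") {
      for (dn in names(v)) {
        d <- v[[dn]]
        if (!inherits(d, "distribution_spec"))
          d <- distribution_spec(d$family, d$dispersion)
        p$distributions[[dn]] <- d
      }
    } else if (grepl("\\[", nm)) {
      p <- param_set(p, nm, v)
    } else {
      if (!nm %in% names(p)) stop("unknown parameter: '", nm, "'")
      p[[nm]] <- v
    }
  }
  p
}

#' Validate a parameter set
#'
#' Checks range and consistency constraints: probabilities and utilities in
#' \[0, 1\], costs non-negative, horizon and screening interval positive
#' integer multiples of the cycle length. Returns the (classed) parameter set
#' invisibly usable in a pipeline; errors name the offending field and bound.
#'
#' @param p Parameter list.
#' @return `p`, with class `"screen_params"`.
#' @export
validate_parameters <- function(p) {
  chk_prob <- function(x, nm) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
      stop("parameter '", nm, "' must lie in [0,1]", call. = FALSE)
  }
  chk_pos <- function(x, nm, strict = FALSE) {
    if (any(!is.finite(x)) || any(if (strict) x <= 0 else x < 0))
      stop("parameter '", nm, "' must be ", if (strict) "> 0" else ">= 0",
           call. = FALSE)
  }
  for (nm in c("pretest_prob", "incidence_annual", "spec_full_mrm",
               "sens_full_mrm_confirmation", "p_death_undetected_10y",
               "q_det_small", "q_det_large", "q_det_advanced",
               "p_r0_small", "p_r0_large", "p_nplus_small", "p_nplus_large",
               "u_healthy", "u_det_small", "u_det_large", "u_det_advanced",
               "u_post_simple", "u_post_intensive", "u_dead"))
    chk_prob(p[[nm]], nm)
  for (s in strategies()) {
    chk_prob(p$sens[[s]], sprintf("sens[%s]", s))
    chk_prob(p$spec[[s]], sprintf("spec[%s]", s))
    chk_pos(p$cost_exam[[s]], sprintf("cost_exam[%s]", s))
  }
  if (!setequal(names(p$sens), strategies()) ||
      !setequal(names(p$spec), strategies()) ||
      !setequal(names(p$cost_exam), strategies()))
    stop("sens/spec/cost_exam must be indexed by exactly the strategies ",
         paste(strategies(), collapse = ", "), call. = FALSE)
  for (nm in c("cost_full_mrm", "cost_biopsy", "cost_treat_small",
               "cost_treat_large", "cost_treat_advanced", "u_fp_decrement",
               "discount_rate", "wtp"))
    chk_pos(p[[nm]], nm)
  if (!is.na(p$q_background)) chk_prob(p$q_background, "q_background")
  if (!p$background_mortality %in% c("entry_age_constant", "age_specific"))
    stop("background_mortality must be 'entry_age_constant' or 'age_specific'",
         call. = FALSE)
  chk_pos(p$start_age, "start_age", strict = TRUE)
  for (nm in c("horizon_years", "screening_interval", "cycle_length",
               "dwell_small", "dwell_large")) {
    chk_pos(p[[nm]], nm, strict = TRUE)
    if (abs(p[[nm]] - round(p[[nm]])) > 1e-9)
      stop("parameter '", nm, "' must be an integer number of years",
           call. = FALSE)
  }
  if (p$horizon_years %% p$cycle_length != 0)
    stop("horizon_years must be a positive integer multiple of cycle_length",
         call. = FALSE)
  if (p$screening_interval %% p$cycle_length != 0)
    stop("screening_interval must be a positive integer multiple of cycle_length",
         call. = FALSE)
  if (!(is.numeric(p$post_mort_years) && length(p$post_mort_years) == 1L &&
        (is.infinite(p$post_mort_years) ||
         (p$post_mort_years >= 0 && abs(p$post_mort_years - round(p$post_mort_years)) < 1e-9))))
    stop("post_mort_years must be a non-negative integer or Inf", call. = FALSE)
  class(p) <- "screen_params"
  p
}

#' Load parameters from a YAML configuration
#'
#' Reads a YAML (or, equivalently, JSON) file whose keys are the field names
#' of [default_parameters()]. Missing keys take the documented defaults, so an
#' empty file yields the base case. Strategy-indexed fields use nested maps
#' (`sens: {DBT: 0.391, AB_MRI: 0.957}`) or flat `sens[DBT]` keys. Scalar
#' overrides supplied programmatically win over the file.
#'
#' @param path Path to a YAML config, or `NULL` for pure defaults.
#' @param overrides Named list applied after the file (e.g.
#'   `list("cost_exam[AB_MRI]" = 250)`).
#' @return Validated `screen_params`.
#' @export
load_parameters <- function(path = NULL, overrides = list()) {
  file_over <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    file_over <- tryCatch(
      yaml::read_yaml(path),
      error = function(e) stop("config parse failure in '", path, "': ",
                               conditionMessage(e), call. = FALSE))
    if (is.null(file_over)) file_over <- list()
    if (!is.list(file_over)) stop("config must be a mapping of parameter names")
  }
  default_parameters(c(file_over, overrides))
}

#' Serialize parameters to YAML
#'
#' Writes a config that [load_parameters()] reads back field-exactly
#' (distribution specs included).
#'
#' @param p `screen_params`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(p, path) {
  out <- unclass(p)
  out$distributions <- lapply(out$distributions, unclass)
  out$sens <- as.list(out$sens); out$spec <- as.list(out$spec)
  out$cost_exam <- as.list(out$cost_exam)
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' Convert a cumulative risk to an annual probability
#'
#' Constant-hazard conversion: the annual probability `q` such that the
#' cumulative probability over `years` years equals `p_total`:
#' `q = 1 - (1 - p_total)^(1/years)`.
#'
#' @param p_total Cumulative probability over the period, in `[0, 1)`.
#' @param years Length of the period in years, `> 0`.
#' @return Annual probability.
#' @examples
#' annualize_risk(0.10, 10) # 0.0104807...
#' @export
annualize_risk <- function(p_total, years) {
  if (any(!is.finite(p_total)) || any(p_total < 0) || any(p_total >= 1))
    stop("p_total must lie in [0, 1): a certain event has no finite hazard")
  if (any(!is.finite(years)) || any(years <= 0)) stop("years must be > 0")
  1 - (1 - p_total)^(1 / years)
}

# method-of-moments shape parameters
beta_moments <- function(mean, sd, name = "parameter") {
  if (mean <= 0 || mean >= 1) stop("beta mean must lie in (0,1) for '", name, "'")
  v <- sd^2
  if (v >= mean * (1 - mean))
    stop("beta moment-matching infeasible for '", name,
         "': variance >= mean*(1-mean)")
  k <- mean * (1 - mean) / v - 1
  c(shape1 = mean * k, shape2 = (1 - mean) * k)
}
gamma_moments <- function(mean, sd, name = "parameter") {
  if (mean <= 0) stop("gamma mean must be > 0 for '", name, "'")
  c(shape = (mean / sd)^2, scale = sd^2 / mean)
}

#' Draw one probabilistic-sensitivity-analysis parameter sample
#'
#' Replaces every parameter that carries a non-fixed [distribution_spec()] by
#' a random draw whose distribution is moment-matched to the base-case mean
#' and the spec's dispersion (SD = dispersion x mean): beta via
#' `shape1 = m(m(1-m)/s^2 - 1)`, `shape2 = (1-m)(m(1-m)/s^2 - 1)`; gamma via
#' `shape = (m/s)^2`, `scale = s^2/m`. Parameters with dispersion 0 (or family
#' `"fixed"`) are returned unchanged. Draws use R's global RNG stream, so they
#' are reproducible under `set.seed()`.
#'
#' The `start_age` draw is rounded to an integer (it indexes the life table)
#' and `q_background`'s mean is resolved from `life_table` when the base value
#' is `NA`.
#'
#' @param p Base-case `screen_params`.
#' @param life_table Life table used to resolve the background-mortality mean.
#' @return A new validated `screen_params` with sampled values.
#' @export
draw_psa_sample <- function(p, life_table = default_life_table()) {
  q <- p
  for (nm in names(p$distributions)) {
    spec <- p$distributions[[nm]]
    if (spec$family == "fixed" || spec$dispersion == 0) next
    m <- param_get(p, nm)
    if (nm == "q_background" && is.na(m))
      m <- annual_death_probability(life_table, p$start_age)
    s <- spec$dispersion * m
    val <- switch(spec$family,
      beta = {
        sh <- beta_moments(m, s, nm)
        stats::rbeta(1L, sh[["shape1"]], sh[["shape2"]])
      },
      gamma = {
        sh <- gamma_moments(m, s, nm)
        stats::rgamma(1L, shape = sh[["shape"]], scale = sh[["scale"]])
      },
      normal = stats::rnorm(1L, m, s))
    if (nm == "start_age") val <- max(1L, as.integer(round(val)))
    q <- param_set(q, nm, val)
  }
  validate_parameters(q)
}
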