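# Shared fixtures built in code.

# flat life table: constant annual background death probability
flat_life_table <- function(q = 0.003, ages = 30:110) life_table(ages, rep(q, length(ages)))

# parameters with all chance events switched off: nobody sick, nobody dies
degenerate_params <- function(...) {
  default_parameters(c(list(
    pretest_prob = 0, incidence_annual = 0,
    p_death_undetected_10y = 0, q_det_small = 0, q_det_large = 0,
    q_det_advanced = 0, q_background = 0,
    spec = list(DBT = 1, AB_MRI = 1)), list(...)))
}

# strategies made literally identical (test performance, exam price and the
# work-up cascade all equalized)
symmetric_params <- function() {
  default_parameters(list(
    sens = list(DBT = 0.7, AB_MRI = 0.7),
    spec = list(DBT = 0.9, AB_MRI = 0.9),
    cost_exam = list(DBT = 250, AB_MRI = 250),
    cost_full_mrm = 0, spec_full_mrm = 0, sens_full_mrm_confirmation = 1))
}

# discounted annuity over cycles 0..(n-1)
annuity <- function(n, rate = 0.03) sum((1 + rate)^-(0:(n - 1)))

# random but valid parameter variation for property sweeps
random_params <- function() {
  default_parameters(list(
    pretest_prob = runif(1, 0, 0.05),
    incidence_annual = runif(1, 0, 0.01),
    sens = list(DBT = runif(1, 0.2, 1), AB_MRI = runif(1, 0.2, 1)),
    spec = list(DBT = runif(1, 0.7, 1), AB_MRI = runif(1, 0.7, 1)),
    p_death_undetected_10y = runif(1, 0, 0.3),
    q_det_small = runif(1, 0, 0.01), q_det_large = runif(1, 0, 0.02),
    q_det_advanced = runif(1, 0, 0.05),
    dwell_small = sample(1:4, 1), dwell_large = sample(1:4, 1),
    post_mort_years = sample(c(0L, 1L, 3L, Inf), 1),
    u_fp_decrement = runif(1, 0, 0.01),
    background_mortality = sample(c("entry_age_constant", "age_specific"), 1)))
}
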