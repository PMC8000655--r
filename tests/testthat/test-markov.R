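test_that("the dead state is absorbing with zero accrual", {
  p <- default_parameters()
  occ <- initial_occupancy(p)
  occ[] <- 0
  occ[length(occ)] <- 1 # DEAD
  st <- transition_update(occ, 5, "DBT", p)
  expect_equal(unname(st$occupancy[length(occ)]), 1)
  expect_equal(st$cost, 0)
  expect_equal(st$qaly, 0)
})

test_that("a non-screening cycle applies onset to survivors after death", {
  lt <- flat_life_table(0.003)
  p <- default_parameters(list(pretest_prob = 0, incidence_annual = 0.004,
                               p_death_undetected_10y = 0))
  occ <- initial_occupancy(p, lt)
  # zero-mortality variant: HEALTHY 0.996 / UNDET_SMALL 0.004, full QALY
  p0 <- default_parameters(list(pretest_prob = 0, incidence_annual = 0.004,
                                q_background = 0, p_death_undetected_10y = 0))
  st <- transition_update(occ, 1, "DBT", p0, lt)
  agg <- aggregate_occupancy(st$occupancy)
  expect_equal(unname(agg[1, "HEALTHY"]), 0.996, tolerance = 1e-12)
  expect_equal(unname(agg[1, "UNDET_SMALL"]), 0.004, tolerance = 1e-12)
  expect_equal(st$cost, 0)
  expect_equal(st$qaly, 1.0)
  # with background mortality 0.003 the onset acts on the 0.997 survivors
  st <- transition_update(occ, 1, "DBT", p, lt)
  agg <- aggregate_occupancy(st$occupancy)
  expect_equal(unname(agg[1, "DEAD"]), 0.003, tolerance = 1e-12)
  expect_equal(unname(agg[1, "UNDET_SMALL"]), 0.997 * 0.004, tolerance = 1e-12)
})

test_that("transition_update validates its occupancy argument", {
  p <- default_parameters()
  occ <- initial_occupancy(p)
  expect_error(transition_update(occ * 2, 0, "DBT", p), "sum to 1")
  occ2 <- occ; occ2[1] <- -occ2[1]
  expect_error(transition_update(occ2, 0, "DBT", p), "negative")
})

test_that("occupancy mass is conserved at every cycle across random models", {
  set.seed(21)
  for (i in 1:30) {
    p <- random_params()
    traj <- run_cohort(sample(strategies(), 1), p)
    sums <- rowSums(traj$occupancy)
    expect_lt(max(abs(sums - 1)), 1e-12)
    expect_true(all(traj$occupancy >= -1e-15))
  }
})

test_that("degenerate no-disease no-death run hits the closed-form annuities", {
  p <- degenerate_params()
  traj <- run_cohort("DBT", p)
  ce <- discounted_totals(traj, 0.03)
  screens <- sum((1.03)^-(seq(0, 28, by = 2)))     # 10.2434
  expect_equal(ce$cost, 214.20 * screens, tolerance = 1e-9)
  expect_equal(ce$effect, annuity(30, 0.03), tolerance = 1e-9)
  expect_equal(sum(traj$qaly), 30)                  # undiscounted person-years
  # one lifetime screen when the interval exceeds the horizon
  p1 <- degenerate_params(screening_interval = 30L)
  expect_equal(discounted_totals(run_cohort("DBT", p1), 0.03)$cost, 214.20,
               tolerance = 1e-9)
})

test_that("discounted QALYs never exceed the 30-cycle annuity bound", {
  bound <- annuity(30, 0.03)
  set.seed(33)
  for (i in 1:20) {
    p <- random_params()
    for (s in strategies())
      expect_lte(discounted_totals(run_cohort(s, p), 0.03)$effect,
                 bound + 1e-12)
  }
})

test_that("discounting matches hand values and rate zero is a plain sum", {
  traj <- structure(list(cost = c(0, 100, 0), qaly = c(1, 1, 1),
                         strategy = "DBT"), class = "cohort_trajectory")
  expect_equal(discounted_totals(traj, 0.03)$cost, 100 / 1.03, tolerance = 1e-12)
  expect_equal(discounted_totals(traj, 0)$cost, 100)
  traj30 <- structure(list(cost = numeric(30), qaly = rep(1, 30),
                           strategy = "DBT"), class = "cohort_trajectory")
  expect_equal(discounted_totals(traj30, 0.03)$effect,
               (1 - 1.03^-30) / (1 - 1.03^-1), tolerance = 1e-9)
})

test_that("identical strategies produce exactly identical trajectories", {
  p <- symmetric_params()
  a <- run_cohort("DBT", p)
  b <- run_cohort("AB_MRI", p)
  expect_identical(a$cost, b$cost)
  expect_identical(a$qaly, b$qaly)
  expect_identical(unname(a$occupancy), unname(b$occupancy))
})

test_that("raising a strategy's sensitivity never lowers its QALYs", {
  qalys <- vapply(seq(0.1, 1, by = 0.1), function(se) {
    p <- default_parameters(list(sens = list(DBT = se)))
    discounted_totals(run_cohort("DBT", p), 0.03)$effect
  }, numeric(1))
  expect_true(all(diff(qalys) >= -1e-12))
})

test_that("stage at detection follows the dwell clock", {
  # single woman-mass with certain detection: a tumor arising right after a
  # screen is small at the next screen; left undetected it is found large,
  # then advanced, at subsequent screens
  p <- degenerate_params(pretest_prob = 1, sens = list(DBT = 1))
  traj <- run_cohort("DBT", p)
  expect_equal(unname(traj$detections[1, ]), c(1, 0, 0)) # prevalence screen
  # with Se = 0 nothing is ever detected and the dwell clock runs free
  never <- run_cohort("DBT", degenerate_params(pretest_prob = 1,
                                               sens = list(DBT = 0)))
  expect_equal(sum(never$detections), 0)
  agg <- aggregate_occupancy(never$occupancy)
  expect_equal(agg[3, "UNDET_SMALL"], 1)  # start of cycle 2
  expect_equal(agg[4, "UNDET_LARGE"], 1)  # start of cycle 3
  expect_equal(agg[8, "UNDET_ADV"], 1)    # after dwell_large more years
})

test_that("trajectory export has the documented schema", {
  p <- default_parameters()
  traj <- run_cohort("DBT", p)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, f)
  df <- read.csv(f, check.names = FALSE)
  expect_equal(nrow(df), 31)
  expect_equal(names(df), c("cycle", "age", health_states(),
                            "cost_accrued", "qaly_accrued"))
  expect_equal(sum(df$cost_accrued, na.rm = TRUE), sum(traj$cost),
               tolerance = 1e-6)
})
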