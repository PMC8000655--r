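test_that("defaults carry the published base-case values", {
  p <- default_parameters()
  expect_equal(p$sens[["AB_MRI"]], 0.957)
  expect_equal(p$sens[["DBT"]], 0.391)
  expect_equal(p$spec[["DBT"]], 0.974)
  expect_equal(p$spec[["AB_MRI"]], 0.867)
  expect_equal(p$cost_biopsy, 1536.00)
  expect_equal(p$cost_exam[["DBT"]], 214.20)
  expect_equal(p$cost_exam[["AB_MRI"]], 314.00)
  expect_equal(p$discount_rate, 0.03)
  expect_equal(p$wtp, 100000)
  expect_equal(p$pretest_prob, 0.0159)
  expect_equal(p$incidence_annual, 0.0040)
})

test_that("overrides change only the requested field", {
  p0 <- default_parameters()
  p1 <- default_parameters(list("cost_exam[AB_MRI]" = 250))
  expect_equal(p1$cost_exam[["AB_MRI"]], 250)
  p1$cost_exam[["AB_MRI"]] <- p0$cost_exam[["AB_MRI"]]
  expect_equal(p1, p0)
  # nested map form
  p2 <- default_parameters(list(cost_exam = list(AB_MRI = 250)))
  expect_equal(p2$cost_exam[["AB_MRI"]], 250)
  expect_equal(p2$cost_exam[["DBT"]], 214.20)
  expect_error(default_parameters(list(nonsense = 1)), "unknown parameter")
})

test_that("validation rejects out-of-range values and names the field", {
  expect_error(default_parameters(list(spec = list(DBT = 1.2))), "spec\\[DBT\\]")
  expect_error(default_parameters(list(cost_biopsy = -1)), "cost_biopsy")
  expect_error(default_parameters(list(u_det_small = 1.5)), "u_det_small")
  expect_error(default_parameters(list(horizon_years = 2.5)), "horizon_years")
  expect_error(default_parameters(list(screening_interval = 0)), "screening_interval")
})

test_that("YAML config loading defaults missing keys and applies overrides", {
  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", cfg)
  p <- load_parameters(cfg)
  expect_equal(p, default_parameters())
  writeLines(c("cost_exam:", "  AB_MRI: 250.0", "incidence_annual: 0.005"), cfg)
  p <- load_parameters(cfg)
  expect_equal(p$cost_exam[["AB_MRI"]], 250)
  expect_equal(p$incidence_annual, 0.005)
  expect_equal(p$sens[["AB_MRI"]], 0.957)
  # programmatic override wins over the file
  p <- load_parameters(cfg, overrides = list(incidence_annual = 0.006))
  expect_equal(p$incidence_annual, 0.006)
  writeLines("spec: {DBT: 1.2}", cfg)
  expect_error(load_parameters(cfg), "spec\\[DBT\\]")
})

test_that("serialization round-trips field-exactly", {
  p <- default_parameters(list(
    "cost_exam[AB_MRI]" = 287.35, start_age = 57L,
    distributions = list(cost_biopsy = distribution_spec("gamma", 0.25))))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(p, f)
  expect_equal(load_parameters(f), p)
})

test_that("annualize_risk matches the constant-hazard closed form", {
  expect_equal(annualize_risk(0.10, 10), 1 - 0.9^0.1, tolerance = 1e-12)
  expect_equal(annualize_risk(0.10, 10), 0.0104807, tolerance = 1e-5)
  expect_equal(annualize_risk(0, 10), 0)
  expect_equal(annualize_risk(0.37, 1), 0.37)
  expect_error(annualize_risk(1, 10), "hazard")
  # inverse identity and monotonicity across a grid
  ps <- seq(0.01, 0.95, by = 0.07)
  for (y in c(0.5, 1, 10)) {
    q <- annualize_risk(ps, y)
    expect_equal(1 - (1 - q)^y, ps, tolerance = 1e-12)
    expect_true(all(diff(q) > 0))
  }
})

test_that("method-of-moments shapes match hand-derived values", {
  sh <- screenCEA:::beta_moments(0.957, 0.02)
  expect_equal(unname(sh), c(97.4968, 4.38070), tolerance = 1e-4)
  sh <- screenCEA:::gamma_moments(1536, 153.6)
  expect_equal(unname(sh), c(100, 15.36), tolerance = 1e-12)
  expect_error(screenCEA:::beta_moments(0.5, 0.6, "x"), "infeasible")
})

test_that("PSA draws are reproducible, degenerate at zero dispersion, and mean-correct", {
  p <- default_parameters()
  set.seed(11); a <- draw_psa_sample(p)
  set.seed(11); b <- draw_psa_sample(p)
  expect_identical(a, b)
  # zero dispersion returns the input set
  p0 <- p
  for (nm in names(p0$distributions)) p0$distributions[[nm]]$dispersion <- 0
  set.seed(1)
  expect_equal(draw_psa_sample(p0), p0)
  # sample means sit within 3 standard errors of the configured means
  set.seed(99)
  n <- 4000
  draws <- replicate(n, {
    d <- draw_psa_sample(p)
    c(d$sens[["DBT"]], d$cost_biopsy, d$u_det_small, d$incidence_annual)
  })
  means <- c(p$sens[["DBT"]], p$cost_biopsy, p$u_det_small, p$incidence_annual)
  for (k in 1:4) {
    se <- sd(draws[k, ]) / sqrt(n)
    expect_lt(abs(mean(draws[k, ]) - means[k]), 3 * se)
  }
})
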