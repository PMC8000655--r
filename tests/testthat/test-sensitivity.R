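test_that("tornado entries are sorted and zero-width ranges give zero span", {
  p <- default_parameters()
  ranges <- list("cost_exam[AB_MRI]" = c(314, 314),
                 incidence_annual = c(0.004, 0.004),
                 "sens[DBT]" = c(0.391, 0.391))
  tor <- one_way_dsa(p, ranges = ranges)
  expect_equal(tor$span, rep(0, 3))
  tor2 <- one_way_dsa(p, ranges = list(
    "cost_exam[AB_MRI]" = c(180, 350),
    incidence_annual = c(0.0032, 0.0048)))
  expect_true(all(diff(tor2$span) <= 0))
  expect_error(one_way_dsa(p, ranges = list("spec[DBT]" = c(0.9, 1.2))),
               "spec\\[DBT\\]")
})

test_that("the AB-MRI price arm of the tornado matches the affine cost relation", {
  p <- default_parameters()
  tor <- one_way_dsa(p, ranges = list("cost_exam[AB_MRI]" = c(180, 350)))
  dbt <- run_ce("DBT", p); ab <- run_ce("AB_MRI", p)
  slope <- exam_cost_slope("AB_MRI", p)
  de <- ab$effect - dbt$effect
  pred_low <- (ab$cost - dbt$cost + (180 - 314) * slope) / de
  pred_high <- (ab$cost - dbt$cost + (350 - 314) * slope) / de
  expect_equal(tor$icer_low, pred_low, tolerance = 1e-6)
  expect_equal(tor$icer_high, pred_high, tolerance = 1e-6)
  expect_lt(tor$icer_low, 0)   # cost-saving region at $180
})

test_that("PSA is reproducible and collapses to the base case at zero dispersion", {
  p <- default_parameters()
  a <- run_psa(p, n_iter = 5, seed = 7)
  b <- run_psa(p, n_iter = 5, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, run_psa(p, n_iter = 5, seed = 8)))
  p0 <- p
  for (nm in names(p0$distributions)) p0$distributions[[nm]]$dispersion <- 0
  psa0 <- run_psa(p0, n_iter = 4, seed = 1)
  dbt <- run_ce("DBT", p0); ab <- run_ce("AB_MRI", p0)
  expect_equal(psa0$draws$delta_cost, rep(ab$cost - dbt$cost, 4))
  expect_equal(psa0$draws$delta_effect, rep(ab$effect - dbt$effect, 4))
})

test_that("PSA draws stay centred on the base case", {
  p <- default_parameters()
  psa <- run_psa(p, n_iter = 400, seed = 13)
  dbt <- run_ce("DBT", p); ab <- run_ce("AB_MRI", p)
  se <- sd(psa$draws$delta_cost) / sqrt(psa$n_iter)
  expect_lt(abs(mean(psa$draws$delta_cost) - (ab$cost - dbt$cost)), 3 * se)
  expect_true(all(psa$draws$delta_effect > -1)) # sanity on scale
})

test_that("the CEAC is the NMB exceedance fraction with the expected properties", {
  draws <- data.frame(iteration = 1:4,
                      delta_cost = c(-50, 100, 200, 700),
                      delta_effect = c(0.01, 0.002, 0.004, 0.005))
  psa <- structure(list(draws = draws, n_iter = 4, seed = 1, n_redraws = 0),
                   class = "psa_result")
  cc <- ceac(psa, c(0, 5e4, 1e5, 2e5))
  expect_equal(cc$fraction_cost_effective[1], mean(draws$delta_cost <= 0))
  expect_equal(cc$fraction_cost_effective[3],
               mean(1e5 * draws$delta_effect - draws$delta_cost >= 0))
  # all delta_effect > 0 makes the curve non-decreasing
  expect_true(all(diff(cc$fraction_cost_effective) >= 0))
  # order invariance: shuffling iterations reproduces the curve exactly
  psa2 <- psa; psa2$draws <- psa2$draws[c(3, 1, 4, 2), ]
  expect_equal(ceac(psa2, c(0, 5e4, 1e5, 2e5))$fraction_cost_effective,
               cc$fraction_cost_effective)
  # exact tie at the threshold counts as cost-effective (NMB >= 0)
  one <- structure(list(draws = data.frame(iteration = 1:2,
                                           delta_cost = c(5, -5),
                                           delta_effect = c(5e-5, -5e-5)),
                        n_iter = 2, seed = 1, n_redraws = 0),
                   class = "psa_result")
  expect_equal(ceac(one, 1e5)$fraction_cost_effective, 1)
})

test_that("sensitivity exports carry their documented columns", {
  p <- default_parameters()
  psa <- run_psa(p, n_iter = 3, seed = 2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_psa(psa, f1, wtp = 1e5)
  df <- read.csv(f1)
  expect_equal(names(df), c("iteration", "delta_cost", "delta_effect", "nmb_at_wtp"))
  expect_equal(df$nmb_at_wtp, 1e5 * df$delta_effect - df$delta_cost)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_ceac(ceac(psa, c(0, 1e5)), f2)
  expect_equal(names(read.csv(f2)), c("wtp", "fraction_cost_effective"))
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_tornado(one_way_dsa(p, ranges = list(incidence_annual = c(0.003, 0.005))), f3)
  expect_equal(names(read.csv(f3)),
               c("parameter", "low", "high", "icer_low", "icer_high", "span"))
})
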