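# Cohort engine: lifespan density, single-cohort stepping, equilibration,
# consumption curves and derived turnover quantities.

test_that("lifespan density has the lognormal closed form and unit mass", {
  # at the median, dlnorm(ls; ln ls, sd) = 1 / (ls * sd * sqrt(2 pi))
  expect_equal(lifespan_density(105, 105, 0.18), 1 / (105 * 0.18 * sqrt(2 * pi)),
               tolerance = 1e-12)
  # hourly Riemann sum over a long horizon recovers the unit normalization
  expect_equal(sum(lifespan_density(1:1000, 105, 0.18)), 1, tolerance = 1e-3)
  # far tail vanishes
  expect_lt(lifespan_density(5000, 105, 0.18), 1e-12)
  expect_error(lifespan_density(-1, 105, 0.18), "non-negative")
  expect_error(lifespan_density(10, 105, 0), "point-mass")
})

test_that("parameter validation enforces the admissible ranges", {
  expect_error(kinetic_params(-1, 105, 0.18, 20), "rd")
  expect_error(kinetic_params(100, 105, 0.18, 20), "rd")
  expect_error(kinetic_params(1, 0, 0.18, 20), "ls")
  expect_error(kinetic_params(1, 105, -0.1, 20), "sd")
  expect_error(kinetic_params(1, 105, 0.18, -5), "pr")
  expect_s3_class(kinetic_params(0, 105, 0, 0), "kinetic_params")
})

test_that("stepping a cohort matches closed-form geometric decay when the lifespan term is idle", {
  p <- kinetic_params(1, 1e6, 0, 10)  # lifespan far beyond any age reached
  s <- cohort_state(0, 10)
  for (h in 1:100) s <- step_cohort(s, p, h)
  expect_equal(s$P, 10 * 0.99^100, tolerance = 1e-12)
  expect_equal(s$CRD, 10 * (1 - 0.99^100), tolerance = 1e-12)
  # no consumption at all
  p0 <- kinetic_params(0, 1e6, 0, 10)
  s0 <- step_cohort(cohort_state(0, 10), p0, 1)
  expect_identical(s0$P, 10)
  # geometric decay dominates a long-lifespan lognormal regime at early ages
  pw <- kinetic_params(4.21, 150, 0.18, 24.3)
  sw <- cohort_state(0, 24.3)
  for (h in 1:24) sw <- step_cohort(sw, pw, h)
  expect_equal(sw$P / 24.3, (1 - 0.0421)^24, tolerance = 1e-3)
  expect_error(step_cohort(cohort_state(5, 1), pw, 5), "birth hour")
})

test_that("iterated step_cohort reproduces the population engine's trajectory", {
  p <- fast_params()
  pop <- platelet_population(p, equilibration_hr = 100, consumption_hr = 10)
  s <- cohort_state(0, p$pr)
  for (h in 1:50) {
    s <- step_cohort(s, p, h)
    expect_equal(s$P, pop$trajectory$P[h + 1], tolerance = 1e-12)
    expect_equal(s$CRD, pop$trajectory$CRD[h + 1], tolerance = 1e-12)
  }
})

test_that("pure-random equilibration matches geometric-series closed forms", {
  pop <- platelet_population(kinetic_params(1, 1e6, 0, 10),
                             equilibration_hr = 500, consumption_hr = 20)
  # equilibrium count -> PR / (RD/100) under the age-0 counting convention
  expect_equal(pop$eq_counts[500], 10 * (1 - 0.99^500) / 0.01, tolerance = 1e-12)
  # e = (1 - q^(n/2)) / (1 - q^n)
  expect_equal(equilibration_metric(pop), (1 - 0.99^250) / (1 - 0.99^500),
               tolerance = 1e-9)
  # survival curve = 100 * (1 - RD/100)^t
  crv <- consumption_curve(pop)
  expect_equal(crv$percent_remaining, 100 * 0.99^(0:20), tolerance = 1e-9)
})

test_that("zero production yields an empty population", {
  pop <- platelet_population(kinetic_params(1, 50, 0.2, 0),
                             equilibration_hr = 50, consumption_hr = 5)
  expect_true(all(pop$eq_counts == 0))
  expect_error(equilibration_metric(pop), "undefined")
  expect_error(turnover_rate(pop), "no platelets")
})

test_that("per-cohort conservation holds exactly and P never increases", {
  for (p in list(fast_params(), kinetic_params(0.1, 60, 0.5, 5),
                 kinetic_params(4.2, 150, 0.18, 24.4),
                 kinetic_params(1.16, 105, 0.18, 20.5))) {
    pop <- platelet_population(p, equilibration_hr = 240, consumption_hr = 60)
    tr <- pop$trajectory
    expect_equal(tr$P + tr$CRD + tr$cumLSDC, rep(p$pr, length(tr$P)),
                 tolerance = 1e-12)
    expect_true(all(diff(tr$P) <= 1e-12))
    expect_true(all(tr$P >= 0))
    # population count is non-increasing once production ceases
    expect_true(all(diff(pop$cons_counts) <= 1e-12))
  }
})

test_that("the age distribution sums to the count at the end of equilibration", {
  pop <- platelet_population(fast_params(), 150, 20)
  ad <- age_distribution(pop)
  expect_equal(sum(ad$count_kul), pop$eq_counts[150], tolerance = 1e-12)
  expect_true(all(ad$count_kul >= 0))
  expect_equal(nrow(ad), 150)
})

test_that("raising RD lowers and raising LS raises the consumption curve", {
  base <- platelet_population(kinetic_params(1, 80, 0.44, 1), 500, 80)
  hi_rd <- platelet_population(kinetic_params(2, 80, 0.44, 1), 500, 80)
  hi_ls <- platelet_population(kinetic_params(1, 120, 0.44, 1), 500, 80)
  expect_true(all(hi_rd$curve[-1] < base$curve[-1]))
  expect_true(all(hi_ls$curve[-1] > base$curve[-1]))
  expect_equal(base$curve[1], 100)
})

test_that("turnover and its random share behave at the extremes", {
  none <- platelet_population(kinetic_params(0, 1e5, 0, 10), 100, 5)
  expect_lt(turnover_rate(none)["percent_per_hr"], 1e-12)
  expect_equal(random_fraction_of_turnover(none), 0)
  pure <- platelet_population(kinetic_params(2, 1e5, 0, 10), 300, 5)
  expect_equal(unname(turnover_rate(pure)["percent_per_hr"]), 2, tolerance = 1e-9)
  expect_equal(random_fraction_of_turnover(pure), 100, tolerance = 1e-9)
})

test_that("the cdf-difference density variant conserves mass and tracks the pdf mode", {
  p <- fast_params()
  a <- platelet_population(p, 300, 60, density_mode = "pdf")
  b <- platelet_population(p, 300, 60, density_mode = "cdf-diff")
  expect_equal(a$curve, b$curve, tolerance = 0.02)
  # with cdf differences the lifespan mass sums exactly to 1, so a cohort is
  # fully consumed well past the lifespan scale
  tr <- b$trajectory
  expect_lt(tr$P[300], 1e-6)
})

test_that("the stored cohort matrix is consistent with the population counts", {
  pop <- platelet_population(fast_params(), 60, 10, keep_matrix = TRUE)
  expect_equal(dim(pop$matrix), c(70, 60))
  expect_equal(unname(rowSums(pop$matrix)[60]), pop$eq_counts[60], tolerance = 1e-12)
  expect_equal(unname(rowSums(pop$matrix)[70]), pop$cons_counts[11], tolerance = 1e-12)
  # upper triangle: a cohort does not exist before its birth hour
  expect_equal(pop$matrix[1, 2], 0)
})

test_that("consumption_curve warns on an inadequately equilibrated source", {
  pop <- platelet_population(kinetic_params(0.1, 300, 0.05, 1), 100, 10)
  expect_lt(pop$e, 0.95)
  expect_warning(consumption_curve(pop), "0.95")
})
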