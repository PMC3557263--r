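# Grafting a donor equilibrium into a recipient environment.

test_that("grafting under unchanged parameters is the identity", {
  donor <- platelet_population(fast_params(pr = 20), 300, 60)
  g <- graft(donor, donor$params, consumption_hr = 60)
  rel <- abs(g$curve - donor$curve) / pmax(donor$curve, 1e-9)
  expect_lt(max(rel), 1e-12)
  expect_equal(g$cons_counts[1], donor$cons_counts[1], tolerance = 1e-13)
})

test_that("the grafted total equals the donor equilibrium count exactly", {
  donor <- platelet_population(kinetic_params(4.2, 150, 0.18, 24.4), 500, 10)
  g <- graft(donor, kinetic_params(2.28, 106, 0.231), consumption_hr = 10)
  expect_equal(g$cons_counts[1], donor$eq_counts[500], tolerance = 1e-12)
  expect_equal(age_distribution(g), age_distribution(donor))
})

test_that("donor age structure shapes lifespan-dependent consumption in the recipient", {
  # a high donor RD skews the equilibrium age distribution young; under equal
  # recipient parameters its lifespan-dependent losses must be uniformly
  # smaller than those of an old-skewed (low donor RD) population
  young <- platelet_population(kinetic_params(8, 40, 0.2, 1), 300, 1)
  old <- platelet_population(kinetic_params(0.5, 40, 0.2, 1), 300, 1)
  recip <- kinetic_params(1, 40, 0.2)
  # assessed over the first 15 h, while the age-structure contrast (rather
  # than exhaustion of the old population's senescent cohorts) drives losses
  gy <- graft(young, recip, consumption_hr = 15)
  go <- graft(old, recip, consumption_hr = 15)
  lsdc_y <- (-diff(gy$cons_counts) - gy$random_cons) / gy$cons_counts[1]
  lsdc_o <- (-diff(go$cons_counts) - go$random_cons) / go$cons_counts[1]
  expect_true(all(lsdc_y < lsdc_o))
})

test_that("first-hour turnover of a graft is floored by the random rate", {
  donor <- platelet_population(fast_params(), 300, 1)
  for (rd in c(0.5, 2, 6)) {
    g <- graft(donor, kinetic_params(rd, 40, 0.2), consumption_hr = 2)
    expect_gte(turnover_rate(g)["percent_per_hr"], rd - 1e-9)
  }
})

test_that("grafting refuses unsuitable donors", {
  donor <- platelet_population(fast_params(), 300, 5)
  g <- graft(donor, fast_params())
  expect_error(graft(g, fast_params()), "grafted")
  poor <- platelet_population(kinetic_params(0.1, 300, 0.05, 1), 100, 5)
  expect_warning(graft(poor, fast_params()), "0.95")
})

test_that("allogeneic fitting recovers recipient parameters from grafted curves", {
  donor <- platelet_population(kinetic_params(4.2, 60, 0.2, 24.4), 500, 5)
  truth <- kinetic_params(2.28, 60, 0.25)
  dat <- simulate_consumption(truth, donor = donor, n_subjects = 4,
                              noise_sd = 0, equilibration_hr = 500)
  sp <- search_space(rd = c(1.28, 3.28), ls = c(50, 70), sd = c(0.15, 0.35),
                     points = 5)
  fit <- platelet_fit(dat, sp, donor = donor, equilibration_hr = 500,
                      refine = 0)
  expect_equal(unname(fit$par), c(2.28, 60, 0.25))
  expect_lt(abs(fit$ss), 1e-6)
  # fitting the donor's own parameters as truth puts the minimum there too
  dat2 <- simulate_consumption(donor$params, donor = donor, n_subjects = 4,
                               noise_sd = 0, equilibration_hr = 500)
  sp2 <- search_space(rd = c(3.2, 5.2), ls = c(50, 70), sd = c(0.1, 0.3),
                      points = 5)
  fit2 <- platelet_fit(dat2, sp2, donor = donor, equilibration_hr = 500,
                       refine = 0)
  expect_equal(unname(fit2$par), c(4.2, 60, 0.2))
})

test_that("cis/trans contrasts reproduce the reference arithmetic", {
  r <- trans_effect_ratios(rd_11 = 1.16, rd_12 = 1.55, rd_22 = 4.20,
                           rd_21 = 2.28)
  expect_equal(unname(r["trans_on_strain2_platelets"]), 84)
  expect_equal(unname(r["trans_on_strain1_platelets"]), 34)
  same <- trans_effect_ratios(1, 1, 1, 1)
  expect_true(all(same == 0))
  expect_error(trans_effect_ratios(0, 1, 1, 1), "denominator")
})
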