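# Grid-search least squares: SS evaluation, plane local minima, the
# local-minimum line, the global minimum, refinement and verification.

test_that("sum of squared residuals is plain pooled arithmetic", {
  crv <- data.frame(hour = 0:10, percent_remaining = 100 * 0.99^(0:10))
  dat <- data.frame(subject_id = "a", time_hr = c(2, 5),
                    percent_remaining = 100 * 0.99^c(2, 5) + c(1, 2))
  expect_equal(sum_squared_residuals(crv, dat), 5, tolerance = 1e-12)
  # points exactly on the curve contribute nothing
  on_curve <- data.frame(subject_id = "b", time_hr = 7,
                         percent_remaining = 100 * 0.99^7)
  expect_equal(sum_squared_residuals(crv, rbind(dat, on_curve)), 5,
               tolerance = 1e-12)
  exact <- data.frame(subject_id = "c", time_hr = c(1, 4),
                      percent_remaining = 100 * 0.99^c(1, 4))
  expect_equal(sum_squared_residuals(crv, exact), 0, tolerance = 1e-12)
  # non-integer times interpolate linearly between hourly values
  mid <- data.frame(subject_id = "d", time_hr = 2.5,
                    percent_remaining = mean(100 * 0.99^c(2, 3)))
  expect_equal(sum_squared_residuals(crv, mid), 0, tolerance = 1e-12)
  beyond <- data.frame(subject_id = "e", time_hr = 11, percent_remaining = 50)
  expect_error(sum_squared_residuals(crv, beyond), "horizon")
})

test_that("a plane's local minimum equals brute-force enumeration", {
  dat <- fast_node_data()
  sp <- fast_space(points = 4)
  lm_ <- plane_local_minimum(2, sp, dat, equilibration_hr = 300)
  # independent route: build each candidate population and score its curve
  brute <- expand.grid(ls = sp$ls, sd = sp$sd)
  brute$ss <- mapply(function(ls, sd) {
    pop <- platelet_population(kinetic_params(2, ls, sd, 1), 300, 80)
    sum_squared_residuals(pop, dat)
  }, brute$ls, brute$sd)
  expect_equal(lm_$ss, min(brute$ss), tolerance = 1e-8)
  k <- which.min(brute$ss)
  expect_equal(lm_$ls, brute$ls[k])
  expect_equal(lm_$sd, brute$sd[k])
})

test_that("the global minimum equals exhaustive enumeration on a small grid", {
  dat <- simulate_consumption(fast_params(), n_subjects = 4, noise_sd = 4,
                              seed = 7, equilibration_hr = 300)
  sp <- fast_space(points = 5)
  fit <- platelet_fit(dat, sp, equilibration_hr = 300, refine = 0,
                      keep_grid = TRUE)
  # exhaustive oracle over all 125 points via the public one-curve route
  grid <- expand.grid(rd = sp$rd, ls = sp$ls, sd = sp$sd)
  grid$ss <- mapply(function(rd, ls, sd) {
    pop <- platelet_population(kinetic_params(rd, ls, sd, 1), 300, 80)
    sum_squared_residuals(pop, dat)
  }, grid$rd, grid$ls, grid$sd)
  k <- which.min(grid$ss)
  expect_equal(unname(fit$par), unname(c(grid$rd[k], grid$ls[k], grid$sd[k])))
  expect_equal(fit$ss, grid$ss[k], tolerance = 1e-8)
  expect_lte(fit$ss, min(fit$grid$ss) + 1e-12)
  # the dense grid agrees with the oracle pointwise
  merged <- merge(fit$grid, grid, by = c("rd", "ls", "sd"))
  expect_equal(merged$ss.x, merged$ss.y, tolerance = 1e-8)
})

test_that("noiseless data generated at a grid node is recovered exactly", {
  fit <- platelet_fit(fast_node_data(), fast_space(), equilibration_hr = 300,
                      refine = 0)
  expect_equal(unname(fit$par), c(2, 40, 0.2))
  expect_lt(abs(fit$ss), 1e-8)
  # refinement of an exact optimum leaves it unchanged
  fit2 <- platelet_fit(fast_node_data(), fast_space(), equilibration_hr = 300,
                       refine = 1)
  expect_equal(fit2$par, fit$par)
})

test_that("the search is deterministic for identical inputs", {
  dat <- simulate_consumption(fast_params(), n_subjects = 4, noise_sd = 3,
                              seed = 11, equilibration_hr = 300)
  f1 <- platelet_fit(dat, fast_space(), equilibration_hr = 300, refine = 1)
  f2 <- platelet_fit(dat, fast_space(), equilibration_hr = 300, refine = 1)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$ss, f2$ss)
  expect_identical(f1$lml, f2$lml)
})

test_that("the LML is normalized to 100% at the global minimum", {
  dat <- simulate_consumption(fast_params(), n_subjects = 4, noise_sd = 3,
                              seed = 3, equilibration_hr = 300)
  fit <- platelet_fit(dat, fast_space(), equilibration_hr = 300, refine = 0)
  expect_equal(min(fit$lml$ss_pct_of_min), 100)
  expect_true(all(fit$lml$ss_pct_of_min >= 100))
  expect_true(all(fit$lml$rd_pct_of_turnover >= 0 &
                  fit$lml$rd_pct_of_turnover <= 100 + 1e-9))
})

test_that("refinement never increases SS and tightens the grid", {
  dat <- simulate_consumption(fast_params(), n_subjects = 4, noise_sd = 3,
                              seed = 5, equilibration_hr = 300)
  coarse <- platelet_fit(dat, fast_space(8), equilibration_hr = 300, refine = 0)
  refined <- platelet_fit(dat, fast_space(8), equilibration_hr = 300, refine = 2)
  expect_lte(refined$ss, coarse$ss)
  if (length(refined$refinements)) {
    hist_ss <- vapply(refined$refinements, function(h) h$gm$ss, numeric(1))
    expect_true(all(diff(c(coarse$ss, hist_ss)) <= 0))
    # refined RD spacing is the one-cell neighbourhood split into 7 steps
    sp1 <- refined$refinements[[1]]$space
    expect_equal(sp1$rd[2] - sp1$rd[1],
                 2 * (fast_space(8)$rd[2] - fast_space(8)$rd[1]) / 7,
                 tolerance = 1e-10)
  }
})

test_that("axis spacing follows the equally-spaced 20-point convention", {
  sp <- search_space(rd = c(0.96, 1.35), ls = c(96, 115), sd = c(0, 0.3))
  expect_length(sp$rd, 20)
  expect_equal(sp$rd[2] - sp$rd[1], (1.35 - 0.96) / 19, tolerance = 1e-12)
  expect_equal(sp$rd[2] - sp$rd[1], 0.0205, tolerance = 0.01)
})

test_that("the equilibration map matches the population metric pointwise", {
  sp <- search_space(rd = c(1, 3), ls = c(30, 50), sd = c(0.1, 0.3), points = 3)
  map <- verify_equilibration(sp, equilibration_hr = 200)
  for (i in c(1, 9, 27)) {
    pop <- platelet_population(kinetic_params(map$rd[i], map$ls[i], map$sd[i], 1),
                               equilibration_hr = 200, consumption_hr = 1)
    expect_equal(map$e[i], equilibration_metric(pop), tolerance = 1e-12)
  }
  expect_true(attr(map, "verified"))
})

test_that("volumes that accumulate platelets for the whole phase fail verification", {
  sp <- search_space(rd = c(0, 0.5), ls = c(400, 500), sd = c(0.01, 0.1),
                     points = 3)
  map <- verify_equilibration(sp, equilibration_hr = 100)
  expect_false(attr(map, "verified"))
  # and fitting inside such a volume is refused, carrying the map as evidence
  dat <- fast_node_data()
  cond <- tryCatch(
    platelet_fit(dat, sp, equilibration_hr = 100),
    plateletkin_unverified_space = function(c) c)
  expect_s3_class(cond$map, "equilibration_map")
})

test_that("minima on the plane boundary are flagged", {
  # truth far outside the LS range forces the LM onto the plane edge
  dat <- fast_node_data()
  sp <- search_space(rd = c(1, 3), ls = c(10, 25), sd = c(0.1, 0.3), points = 4)
  fit <- platelet_fit(dat, sp, equilibration_hr = 300, refine = 0)
  expect_true(any(fit$lml$boundary))
  expect_true(fit$boundary)
})
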