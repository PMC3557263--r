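# Core discrete-time cohort engine.
#
# Every cohort is produced at size PR and evolves independently as a function
# of its age only, so one trajectory indexed by age describes all cohorts of
# a syngeneic population; population counts are rolling sums over it.
# Grafted populations (heterogeneous starting states) are evolved cohort-wise.

# Evolve a single cohort from birth for `horizon` hours.
# Returns P[age + 1], CRD[age + 1], cumulative LSDC, and the number of hours
# at which lifespan destruction had to be truncated to keep P >= 0.
cohort_trajectory <- function(rd, ls, sd, pr, horizon,
                              density_mode = "pdf") {
  w <- lifespan_weights(ls, sd, horizon, density_mode)
  r <- rd / 100
  point_mass <- sd == 0
  P <- numeric(horizon + 1L)
  CRD <- numeric(horizon + 1L)
  cumLSDC <- numeric(horizon + 1L)
  P[1L] <- pr
  clamped <- 0L
  for (a in seq_len(horizon)) {
    rda <- r * P[a]
    crd <- CRD[a] + rda
    avail <- P[a] - rda
    lsdc <- if (point_mass) {
      if (a >= ls) avail else 0
    } else {
      w[a] * (pr - crd)
    }
    if (lsdc > avail) {
      lsdc <- avail
      clamped <- clamped + 1L
    }
    P[a + 1L] <- avail - lsdc
    CRD[a + 1L] <- crd
    cumLSDC[a + 1L] <- cumLSDC[a] + lsdc
  }
  list(P = P, CRD = CRD, cumLSDC = cumLSDC, clamped = clamped)
}

#' Single-cohort state
#'
#' The state of one hourly-born platelet cohort: its birth hour, remaining
#' concentration `P` (K/ul) and cumulative random destruction `CRD` (K/ul).
#'
#' @param birth_hour Hour index at which the cohort was produced.
#' @param P Remaining concentration, K/ul.
#' @param CRD Cumulative random destruction, K/ul.
#' @return An object of class `"cohort_state"`.
#' @seealso [step_cohort()]
#' @export
cohort_state <- function(birth_hour, P, CRD = 0) {
  stopifnot(P >= 0, CRD >= 0)
  structure(list(birth_hour = birth_hour, P = P, CRD = CRD),
            class = "cohort_state")
}

#' Advance one cohort by one hour
#'
#' Applies one hour of consumption to a cohort: random destruction
#' `(rd/100) * P` is removed and added to `CRD`; lifespan-dependent
#' consumption, `lifespan_density(age) * (pr - CRD)` with the updated `CRD`,
#' is then removed. If the lifespan term would drive `P` below zero it is
#' truncated so that `P = 0` (`CRD` is never reduced). With `sd = 0` the
#' lifespan distribution degenerates to a point mass: the whole remainder of
#' the cohort is consumed in the first hour at which its age reaches `ls`.
#'
#' @param state A [cohort_state()].
#' @param params A [kinetic_params()] object.
#' @param current_hour The hour being stepped into; must exceed
#'   `state$birth_hour`. The cohort age used for the lifespan density is
#'   `current_hour - birth_hour`.
#' @param density_mode `"pdf"` (density x 1 hr, the default construction) or
#'   `"cdf-diff"` (exact lifespan probability mass per hour).
#' @return The updated `cohort_state`, with attribute `"clamped"` set to
#'   `TRUE` when truncation occurred.
#' @examples
#' s <- cohort_state(birth_hour = 0, P = 20.5)
#' step_cohort(s, kinetic_params(1.16, 105, 0.18, 20.5), current_hour = 1)
#' @export
step_cohort <- function(state, params, current_hour, density_mode = "pdf") {
  stopifnot(inherits(state, "cohort_state"))
  params <- as_kinetic_params(params)
  density_mode <- match_density_mode(density_mode)
  age <- current_hour - state$birth_hour
  if (age < 1) stop("'current_hour' must exceed the cohort's birth hour")
  rda <- params$rd / 100 * state$P
  crd <- state$CRD + rda
  avail <- state$P - rda
  lsdc <- if (params$sd == 0) {
    if (age >= params$ls) avail else 0
  } else {
    w <- if (density_mode == "pdf") {
      stats::dlnorm(age, log(params$ls), params$sd)
    } else {
      stats::plnorm(age, log(params$ls), params$sd) -
        stats::plnorm(age - 1, log(params$ls), params$sd)
    }
    w * (params$pr - crd)
  }
  clamped <- lsdc > avail
  if (clamped) lsdc <- avail
  out <- cohort_state(state$birth_hour, avail - lsdc, crd)
  attr(out, "clamped") <- clamped
  out
}

#' Equilibrate a platelet cohort population
#'
#' Builds the cohort matrix: one cohort of size `pr` is produced per hour for
#' `equilibration_hr` hours, every live cohort being consumed hourly by the
#' random and lifespan-dependent processes; production then ceases and
#' consumption continues for `consumption_hr` further hours, generating the
#' normalized consumption (survival) curve. The final equilibration row gives
#' the population age distribution with its per-cohort cumulative random
#' destruction ledger.
#'
#' @param params A [kinetic_params()] object (or list with `rd`, `ls`, `sd`,
#'   `pr`).
#' @param equilibration_hr Length `n` of the equilibration phase, hours
#'   (number of cohorts produced). Default 240, the mouse-scale choice; 500
#'   is used for equilibration surveys.
#' @param consumption_hr Length `c` of the post-production consumption phase,
#'   hours. Default 125.
#' @param density_mode See [step_cohort()].
#' @param keep_matrix If `TRUE`, the full `(n + c) x n` matrix of cohort
#'   concentrations is stored in the result (`$matrix`).
#' @return An object of class `"platelet_population"` with, among others,
#'   `eq_counts` (population count at hours `1..n`), `cons_counts` (count at
#'   consumption hours `0..c`), `age` (the equilibrium age distribution with
#'   `CRD`), and the normalized consumption curve. Use the accessors
#'   [consumption_curve()], [equilibration_metric()], [turnover_rate()],
#'   [random_fraction_of_turnover()], [age_distribution()].
#' @examples
#' wt <- platelet_population(kinetic_params(1.16, 105, 0.180, 20.5))
#' equilibration_metric(wt)
#' turnover_rate(wt)
#' @export
platelet_population <- function(params, equilibration_hr = 240,
                                consumption_hr = 125,
                                density_mode = c("pdf", "cdf-diff"),
                                keep_matrix = FALSE) {
  params <- as_kinetic_params(params)
  density_mode <- match.arg(density_mode)
  n <- as.integer(equilibration_hr)
  cc <- as.integer(consumption_hr)
  if (n < 2L) stop("'equilibration_hr' must be at least 2")
  if (cc < 1L) stop("'consumption_hr' must be at least 1")
  m <- n + cc
  tr <- cohort_trajectory(params$rd, params$ls, params$sd, params$pr, m,
                          density_mode)
  S <- cumsum(tr$P)
  eq_counts <- S[seq_len(n)]
  cons_counts <- c(S[n], S[(n + 1L):m] - S[seq_len(cc)])
  random_cons <- params$rd / 100 * cons_counts[seq_len(cc)]
  e <- if (S[n] > 0) S[n %/% 2L] / S[n] else NA_real_
  curve <- if (cons_counts[1L] > 0) 100 * cons_counts / cons_counts[1L]
           else rep(NA_real_, cc + 1L)
  age <- data.frame(age_hr = 0:(n - 1L),
                    count_kul = tr$P[seq_len(n)],
                    crd_kul = tr$CRD[seq_len(n)])
  out <- list(params = params, n = n, c = cc, density_mode = density_mode,
              grafted = FALSE, pr = params$pr,
              eq_counts = eq_counts, cons_counts = cons_counts,
              random_cons = random_cons, curve = curve, age = age,
              e = e, clamped = tr$clamped, trajectory = tr)
  if (keep_matrix) {
    mat <- matrix(0, nrow = m, ncol = n)
    for (j in seq_len(n)) {
      rows <- j:m
      mat[rows, j] <- tr$P[rows - j + 1L]
    }
    dimnames(mat) <- list(hour = seq_len(m), cohort = seq_len(n))
    out$matrix <- mat
  }
  structure(out, class = "platelet_population")
}

#' @export
print.platelet_population <- function(x, ...) {
  cat(if (x$grafted) "Grafted platelet population\n"
      else "Equilibrated platelet population\n")
  cat("  ", format(x$params), "\n", sep = "")
  if (x$grafted)
    cat(sprintf("  donor PR: %.4g K/ul/hr, %d grafted cohorts\n", x$pr, x$n))
  cat(sprintf("  phases: %s%d h consumption; count at production cessation %.4g K/ul\n",
              if (x$grafted) "" else sprintf("%d h equilibration + ", x$n), x$c,
              x$cons_counts[1L]))
  cat(sprintf("  equilibration metric e = %.4f%s\n", x$e,
              if (is.na(x$e) || x$e > 0.95) "" else "  (below 0.95: inadequately equilibrated)"))
  invisible(x)
}

#' @export
plot.platelet_population <- function(x, which = c("curve", "age", "equilibration"),
                                     ...) {
  which <- match.arg(which)
  if (which == "curve") {
    graphics::plot(0:x$c, x$curve, type = "l", xlab = "hours after production ceases",
                   ylab = "% of platelets remaining", ylim = c(0, 100), ...)
  } else if (which == "age") {
    graphics::plot(x$age$age_hr, x$age$count_kul, type = "h",
                   xlab = "platelet age (hr)", ylab = "concentration (K/ul)", ...)
  } else {
    if (x$grafted) stop("a grafted population has no equilibration phase")
    graphics::plot(seq_along(x$eq_counts), x$eq_counts, type = "l",
                   xlab = "hour", ylab = "platelet count (K/ul)", ...)
  }
  invisible(x)
}

#' Normalized post-production consumption curve
#'
#' The model survival curve: the population count at each hour after platelet
#' production ceases, as a percentage of the count at cessation. Warns when
#' the source population's equilibration metric is at or below 0.95, since
#' the curve is then contaminated by incomplete equilibration.
#'
#' @param pop A `"platelet_population"` (from [platelet_population()] or
#'   [graft()]).
#' @return A data frame with columns `hour` (0..c) and `percent_remaining`
#'   (100 at hour 0, non-increasing).
#' @export
consumption_curve <- function(pop) {
  stopifnot(inherits(pop, "platelet_population"))
  if (!is.na(pop$e) && pop$e <= 0.95)
    warning(sprintf("equilibration metric e = %.3f <= 0.95: curve may be unreliable",
                    pop$e))
  data.frame(hour = 0:pop$c, percent_remaining = pop$curve)
}

#' Equilibration metric
#'
#' The population count at the equilibration midpoint (`floor(n/2)`) divided
#' by the count at the end of the equilibration phase. Values above 0.95
#' certify functionally adequate equilibration.
#'
#' @param pop A `"platelet_population"`. For a grafted population the donor's
#'   metric is returned.
#' @return A fraction in (0, 1].
#' @export
equilibration_metric <- function(pop) {
  stopifnot(inherits(pop, "platelet_population"))
  if (is.na(pop$e))
    stop("equilibration metric undefined: no platelets at the end of the equilibration phase")
  pop$e
}

#' Population turnover rate at production cessation
#'
#' The consumption rate observed in the first interval after platelet
#' production ceases, which at true equilibrium equals the platelet
#' production rate.
#'
#' @param pop A `"platelet_population"`.
#' @return Named numeric: `percent_per_hr` (100 x fraction of the count
#'   consumed in the first post-production hour) and `kul_per_hr` (the same
#'   consumption in absolute K/ul/hr).
#' @export
turnover_rate <- function(pop) {
  stopifnot(inherits(pop, "platelet_population"))
  c0 <- pop$cons_counts[1L]
  c1 <- pop$cons_counts[2L]
  if (c0 <= 0) stop("no platelets present at production cessation")
  c(percent_per_hr = 100 * (c0 - c1) / c0, kul_per_hr = c0 - c1)
}

#' Random destruction as a fraction of turnover
#'
#' The share of first-post-production-hour consumption attributable to the
#' random destruction term (as opposed to lifespan-dependent consumption).
#'
#' @param pop A `"platelet_population"`.
#' @return Percent in `[0, 100]`.
#' @export
random_fraction_of_turnover <- function(pop) {
  stopifnot(inherits(pop, "platelet_population"))
  total <- pop$cons_counts[1L] - pop$cons_counts[2L]
  if (total <= 0) {
    if (pop$params$rd == 0) return(0)
    stop("no consumption in the first post-production hour: fraction undefined")
  }
  100 * pop$random_cons[1L] / total
}

#' Equilibrium age distribution
#'
#' The per-cohort concentrations in the last row of the equilibration phase
#' (or, for a grafted population, at the moment of grafting), paired with
#' each cohort's cumulative random destruction. The concentrations sum to the
#' population count at that row.
#'
#' @param pop A `"platelet_population"`.
#' @return Data frame with columns `age_hr`, `count_kul`, `crd_kul`.
#' @export
age_distribution <- function(pop) {
  stopifnot(inherits(pop, "platelet_population"))
  pop$age
}
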