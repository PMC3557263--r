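# Allogeneic grafting: a donor strain's equilibrium age distribution and CRD
# ledger are transplanted into a fresh matrix and consumed under
# recipient-environment parameters. The donor's production rate, not the
# recipient's, scales the lifespan-dependent term of grafted cohorts.

#' Graft a donor equilibrium population into a recipient environment
#'
#' Initializes a fresh consumption matrix with the donor population's final
#' equilibration row (per-cohort concentrations `P` and cumulative random
#' destruction `CRD`) and consumes it hourly under recipient-environment
#' parameters. Cohort ages continue from their donor values, so the donor's
#' age structure shapes the lifespan-dependent consumption seen in the
#' recipient; the donor's production rate parameterizes the lifespan term.
#' This models transfusion of allogeneic platelets.
#'
#' @param donor An equilibrated `"platelet_population"` (see
#'   [platelet_population()]). Its equilibration metric should exceed 0.95; a
#'   warning is raised otherwise.
#' @param params Recipient-environment [kinetic_params()]. The `pr` element
#'   is ignored (no production occurs and the donor's `pr` scales the
#'   lifespan term).
#' @param consumption_hr Hours of consumption to model. Default 125.
#' @param density_mode See [step_cohort()].
#' @return A `"platelet_population"` with `grafted = TRUE`; the usual
#'   accessors apply ([consumption_curve()], [turnover_rate()],
#'   [random_fraction_of_turnover()], [age_distribution()]).
#' @examples
#' wasp <- platelet_population(kinetic_params(4.20, 150, 0.18, 24.4),
#'                             equilibration_hr = 500)
#' g <- graft(wasp, kinetic_params(2.28, 106, 0.231))
#' turnover_rate(g)
#' @export
graft <- function(donor, params, consumption_hr = 125,
                  density_mode = c("pdf", "cdf-diff")) {
  stopifnot(inherits(donor, "platelet_population"))
  if (donor$grafted) stop("'donor' is itself a grafted population; graft from an equilibrated one")
  params <- as_kinetic_params(params)
  density_mode <- match.arg(density_mode)
  if (!is.na(donor$e) && donor$e <= 0.95)
    warning(sprintf("donor equilibration metric e = %.3f <= 0.95: grafted kinetics may be unreliable",
                    donor$e))
  age0 <- donor$age$age_hr
  P0 <- donor$age$count_kul
  CRD0 <- donor$age$crd_kul
  if (length(P0) != length(CRD0) || length(P0) != length(age0))
    stop("mismatched cohort/CRD lengths in donor age distribution")
  st <- graft_consume(age0, P0, CRD0, donor$pr, params$rd, params$ls, params$sd,
                      as.integer(consumption_hr), density_mode)
  cc <- as.integer(consumption_hr)
  curve <- if (st$counts[1L] > 0) 100 * st$counts / st$counts[1L]
           else rep(NA_real_, cc + 1L)
  structure(list(params = params, n = donor$n, c = cc,
                 density_mode = density_mode, grafted = TRUE, pr = donor$pr,
                 eq_counts = NULL, cons_counts = st$counts,
                 random_cons = st$random, curve = curve,
                 age = donor$age, e = donor$e, clamped = st$clamped,
                 donor_params = donor$params),
            class = "platelet_population")
}

# Vectorized-over-cohorts consumption of a grafted population.
# age0/P0/CRD0: state at grafting; pr: donor production rate.
graft_consume <- function(age0, P0, CRD0, pr, rd, ls, sd, cc,
                          density_mode = "pdf") {
  r <- rd / 100
  point_mass <- sd == 0
  horizon <- max(age0) + cc
  w <- lifespan_weights(ls, sd, horizon, density_mode)
  P <- P0
  CRD <- CRD0
  counts <- numeric(cc + 1L)
  random <- numeric(cc)
  counts[1L] <- sum(P)
  clamped <- 0L
  for (t in seq_len(cc)) {
    age_t <- age0 + t
    rda <- r * P
    CRD <- CRD + rda
    avail <- P - rda
    lsdc <- if (point_mass) ifelse(age_t >= ls, avail, 0) else w[age_t] * (pr - CRD)
    over <- lsdc > avail
    if (any(over)) {
      lsdc[over] <- avail[over]
      clamped <- clamped + sum(over)
    }
    P <- avail - lsdc
    counts[t + 1L] <- sum(P)
    random[t] <- sum(rda)
  }
  list(counts = counts, random = random, clamped = clamped)
}

#' Cis and trans random-destruction contrasts
#'
#' Arithmetic contrasts between four fitted random destruction rates from a
#' two-strain transfusion design (donor strain x recipient strain). Each
#' contrast is reported as `100 * (rd_a / rd_b - 1)`, rounded to integer
#' percent. "Strain 1" is the reference (e.g. wild type) and "strain 2" the
#' mutant; `rd_ij` is the fitted RD for strain-`i` platelets consumed in a
#' strain-`j` recipient.
#'
#' @param rd_11,rd_12,rd_22,rd_21 Fitted RD values (\%/hr), or
#'   `"platelet_fit"` objects from which RD is taken.
#' @return Named numeric vector of integer percents:
#'   `trans_on_strain2_platelets` (strain-2 donors, strain-2 vs strain-1
#'   recipients), `trans_on_strain1_platelets` (strain-1 donors, strain-2 vs
#'   strain-1 recipients), `cis_in_strain1_recipients` (strain-2 vs strain-1
#'   donors in strain-1 recipients), `cis_in_strain2_recipients` (the same in
#'   strain-2 recipients).
#' @examples
#' trans_effect_ratios(rd_11 = 1.16, rd_12 = 1.55, rd_22 = 4.20, rd_21 = 2.28)
#' @export
trans_effect_ratios <- function(rd_11, rd_12, rd_22, rd_21) {
  g <- function(x) if (inherits(x, "platelet_fit")) unname(x$par["rd"]) else as.numeric(x)
  rd_11 <- g(rd_11); rd_12 <- g(rd_12); rd_22 <- g(rd_22); rd_21 <- g(rd_21)
  if (any(c(rd_11, rd_12, rd_21) == 0))
    stop("zero denominator RD: ratios undefined")
  round(c(trans_on_strain2_platelets = 100 * (rd_22 / rd_21 - 1),
          trans_on_strain1_platelets = 100 * (rd_12 / rd_11 - 1),
          cis_in_strain1_recipients = 100 * (rd_21 / rd_11 - 1),
          cis_in_strain2_recipients = 100 * (rd_22 / rd_12 - 1)))
}
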