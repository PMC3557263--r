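#' Kinetic parameters for platelet consumption
#'
#' Bundles the three consumption parameters and the production rate that
#' govern one platelet consumption regime: `rd`, the random destruction rate
#' (percent of circulating platelets per hour); `ls`, the median of the
#' lognormal intrinsic-lifespan distribution (hours); `sd`, the standard
#' deviation of ln(lifespan) (dimensionless); and `pr`, the platelet
#' production rate (thousand platelets per microlitre per hour).
#'
#' `sd = 0` denotes the degenerate point-mass lifespan: every platelet not
#' consumed at random dies exactly at age `ls`.
#'
#' @param rd Random destruction rate, \%/hr. Must satisfy `0 <= rd < 100`.
#' @param ls Median lifespan, hours. Must be positive.
#' @param sd Standard deviation of ln(lifespan). Must be non-negative.
#' @param pr Production rate, K/ul/hr. Must be non-negative.
#'
#' @return An object of class `"kinetic_params"`: a named list with elements
#'   `rd`, `ls`, `sd`, `pr`.
#' @examples
#' kinetic_params(rd = 1.16, ls = 105, sd = 0.180, pr = 20.5)
#' @export
kinetic_params <- function(rd, ls, sd, pr = 1) {
  stopifnot(is.numeric(rd), length(rd) == 1L, is.finite(rd),
            is.numeric(ls), length(ls) == 1L, is.finite(ls),
            is.numeric(sd), length(sd) == 1L, is.finite(sd),
            is.numeric(pr), length(pr) == 1L, is.finite(pr))
  if (rd < 0 || rd >= 100)
    stop("'rd' must be in [0, 100): a cohort cannot lose more than itself per hour")
  if (ls <= 0) stop("'ls' must be positive")
  if (sd < 0) stop("'sd' must be non-negative")
  if (pr < 0) stop("'pr' must be non-negative")
  structure(list(rd = rd, ls = ls, sd = sd, pr = pr), class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Platelet kinetic parameters\n")
  cat(sprintf("  RD: %.4g %%/hr   LS: %.4g hr   SD(ln LS): %.4g   PR: %.4g K/ul/hr\n",
              x$rd, x$ls, x$sd, x$pr))
  invisible(x)
}

#' @export
format.kinetic_params <- function(x, ...) {
  sprintf("RD=%.4g %%/hr, LS=%.4g hr, SD=%.4g, PR=%.4g K/ul/hr",
          x$rd, x$ls, x$sd, x$pr)
}

as_kinetic_params <- function(x) {
  if (inherits(x, "kinetic_params")) return(x)
  if (is.list(x) || is.numeric(x)) {
    x <- as.list(x)
    nm <- tolower(names(x))
    names(x) <- nm
    if (all(c("rd", "ls", "sd") %in% nm))
      return(kinetic_params(x$rd, x$ls, x$sd, if ("pr" %in% nm) x$pr else 1))
  }
  stop("cannot interpret 'x' as kinetic parameters (need rd, ls, sd[, pr])")
}

#' Per-hour lifespan-dependent destruction density
#'
#' The probability density of the lognormal intrinsic-lifespan distribution
#' evaluated at a cohort age. The log-scale location is `ln(ls)` and the
#' log-scale scale is `sd`, so `ls` is the median lifespan. Multiplied by one
#' hour and by the unconsumed remainder of a cohort (`pr - crd`), it gives
#' the cohort's lifespan-dependent consumption in that hour.
#'
#' @param age Cohort age in hours (non-negative; the model evaluates it at
#'   integer ages `>= 1`).
#' @param ls Median lifespan, hours (positive).
#' @param sd Standard deviation of ln(lifespan); must be strictly positive
#'   here. The degenerate point-mass case `sd = 0` is handled by
#'   [step_cohort()], not by the density.
#' @return Density value(s) in 1/hr; non-negative, integrating to 1 over age.
#' @examples
#' lifespan_density(105, ls = 105, sd = 0.18)  # 1/(105 * 0.18 * sqrt(2*pi))
#' @export
lifespan_density <- function(age, ls, sd) {
  if (any(age < 0)) stop("'age' must be non-negative")
  if (ls <= 0) stop("'ls' must be positive")
  if (sd <= 0)
    stop("'sd' must be strictly positive; sd = 0 is the degenerate ",
         "point-mass lifespan handled by step_cohort()")
  stats::dlnorm(age, meanlog = log(ls), sdlog = sd)
}

# Hourly lifespan-destruction weights at integer ages 1..horizon.
# "pdf": density * 1 hr, as in the spreadsheet construction.
# "cdf-diff": exact probability mass of the lifespan falling in (age-1, age].
lifespan_weights <- function(ls, sd, horizon, density_mode = "pdf") {
  if (sd == 0) return(numeric(horizon))
  ages <- seq_len(horizon)
  if (density_mode == "pdf") {
    stats::dlnorm(ages, log(ls), sd)
  } else {
    stats::plnorm(ages, log(ls), sd) - stats::plnorm(ages - 1, log(ls), sd)
  }
}

match_density_mode <- function(density_mode) {
  match.arg(density_mode, c("pdf", "cdf-diff"))
}
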