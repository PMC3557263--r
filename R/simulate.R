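# Synthetic consumption datasets with the statistical structure of murine
# labeled-platelet survival studies: a T0 anchor plus a handful of post-T0
# percent-remaining measurements per recipient, Gaussian measurement noise
# around a model-generated curve.

# Run `expr` under a temporary RNG state when `seed` is given, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic platelet consumption dataset
#'
#' For each recipient and measurement time, the percent of T0-labeled
#' platelets remaining is the model consumption curve value plus additive
#' Gaussian noise, floored at zero. With `donor` supplied the noiseless
#' curve comes from the donor equilibrium population grafted into the
#' environment described by `params` (an allogeneic design); otherwise
#' `params` describes a syngeneic regime equilibrated from scratch.
#'
#' Defaults mirror the murine study designs the model targets: 13-30
#' recipients, four post-T0 time points within 125 h, a few percent
#' measurement noise.
#'
#' @param params True [kinetic_params()] (recipient-environment values when
#'   `donor` is given).
#' @param n_subjects Number of recipients. Default 30.
#' @param times Post-T0 measurement times, hours. Default `c(5, 24, 48, 72)`;
#'   `c(5, 24, 48, 89)` matches the alternative design.
#' @param noise_sd Gaussian measurement noise, percent-of-T0 units. Default 3.
#' @param seed Optional integer seed; identical design + seed gives an
#'   identical dataset, and the caller's RNG stream is left untouched.
#' @param donor Optional equilibrated `"platelet_population"` donor.
#' @param equilibration_hr Equilibration length for the syngeneic curve.
#' @param density_mode See [step_cohort()].
#' @param dropout Per-measurement probability of a missing observation
#'   (default 0).
#' @param include_t0 Emit the T0 anchor rows (100 at time 0).
#' @param donor_strain,recipient_strain Optional labels carried into the
#'   dataset.
#' @return A data frame in the standard measurement format, with attribute
#'   `"truth"` recording the generating design.
#' @examples
#' d <- simulate_consumption(kinetic_params(2, 40, 0.2), n_subjects = 4,
#'                           noise_sd = 0, seed = 1, equilibration_hr = 300)
#' head(d)
#' @export
simulate_consumption <- function(params, n_subjects = 30,
                                 times = c(5, 24, 48, 72), noise_sd = 3,
                                 seed = NULL, donor = NULL,
                                 equilibration_hr = 240,
                                 density_mode = c("pdf", "cdf-diff"),
                                 dropout = 0, include_t0 = TRUE,
                                 donor_strain = NULL, recipient_strain = NULL) {
  params <- as_kinetic_params(params)
  density_mode <- match.arg(density_mode)
  stopifnot(n_subjects >= 1, length(times) >= 1, all(times > 0),
            noise_sd >= 0, dropout >= 0, dropout < 1)
  cc <- as.integer(ceiling(max(times)))
  pop <- if (is.null(donor)) {
    platelet_population(params, equilibration_hr, cc, density_mode)
  } else {
    if (equilibration_metric(donor) <= 0.95)
      stop("donor population is not adequately equilibrated (e <= 0.95)")
    graft(donor, params, cc, density_mode)
  }
  crv <- pop$curve
  v <- stats::approx(0:cc, crv, xout = times)$y
  ids <- sprintf("S%0*d", nchar(as.character(n_subjects)), seq_len(n_subjects))
  out <- with_seed(seed, {
    y <- pmax(0, rep(v, n_subjects) +
                 stats::rnorm(length(times) * n_subjects, sd = noise_sd))
    df <- data.frame(subject_id = rep(ids, each = length(times)),
                     time_hr = rep(times, n_subjects),
                     percent_remaining = y)
    if (dropout > 0)
      df <- df[stats::runif(nrow(df)) >= dropout, , drop = FALSE]
    df
  })
  if (include_t0) {
    t0 <- data.frame(subject_id = ids, time_hr = 0, percent_remaining = 100)
    out <- rbind(t0, out)
    out <- out[order(out$subject_id, out$time_hr), , drop = FALSE]
  }
  if (!is.null(donor_strain)) out$donor_strain <- donor_strain
  if (!is.null(recipient_strain)) out$recipient_strain <- recipient_strain
  rownames(out) <- NULL
  attr(out, "truth") <- list(params = params, allogeneic = !is.null(donor),
                             donor_params = if (!is.null(donor)) donor$params,
                             noise_sd = noise_sd, times = times,
                             n_subjects = n_subjects, dropout = dropout,
                             seed = seed)
  out
}
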