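# Standard modelling-object methods for "platelet_fit".

#' @export
print.platelet_fit <- function(x, digits = 4, ...) {
  cat("Platelet consumption fit (grid-search least squares)\n")
  cat("Call: ", paste(deparse(x$call), collapse = " "), "\n", sep = "")
  cat(sprintf("%d subjects, %d measurements%s\n", x$n_subjects, nrow(x$data),
              if (is.null(x$donor)) "" else " (allogeneic: grafted donor population)"))
  co <- coef(x)
  cat("Coefficients:\n")
  cat(sprintf("  RD = %s %%/hr   LS = %s hr   SD = %s\n",
              format(co["rd"], digits = digits),
              if (is.na(co["ls"])) "n/a" else format(co["ls"], digits = digits),
              if (is.na(co["sd"])) "n/a" else format(co["sd"], digits = digits)))
  cat(sprintf("SS = %s; classification: %s\n",
              format(x$ss, digits = digits), x$classification))
  invisible(x)
}

#' Extract fitted consumption parameters
#'
#' Returns the fitted (RD, LS, SD) triple. For fits classified as
#' pure-random the lifespan parameters carry no information and are returned
#' as `NA` (the raw grid optimum remains available as `object$par`).
#'
#' @param object A `"platelet_fit"`.
#' @param ... Unused.
#' @return Named numeric vector `c(rd, ls, sd)`.
#' @export
coef.platelet_fit <- function(object, ...) {
  par <- object$par
  if (object$classification == "pure-random") par[c("ls", "sd")] <- NA_real_
  par
}

#' Predicted percent remaining
#'
#' Evaluates the fitted model consumption curve at arbitrary times (hours
#' after production cessation / T0), interpolating linearly between hourly
#' model values.
#'
#' @param object A `"platelet_fit"`.
#' @param times Hours; default the observed measurement times.
#' @param ... Unused.
#' @return Numeric vector of percent-of-T0 values.
#' @export
predict.platelet_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$data$time_hr
  if (any(times < 0)) stop("'times' must be non-negative")
  if (max(times) > max(object$curve$hour))
    stop("'times' beyond the fitted curve horizon (",
         max(object$curve$hour), " h)")
  stats::approx(object$curve$hour, object$curve$percent_remaining,
                xout = times)$y
}

#' @export
fitted.platelet_fit <- function(object, ...) {
  predict(object, object$data$time_hr)
}

#' @export
residuals.platelet_fit <- function(object, ...) {
  object$data$percent_remaining - fitted(object)
}

#' @export
summary.platelet_fit <- function(object, jackknife = NULL, ...) {
  res <- residuals(object)
  out <- list(fit = object,
              coef = coef(object),
              se = if (!is.null(jackknife)) jackknife$se,
              rmse = sqrt(mean(res^2)),
              turnover = object$turnover,
              random_fraction = object$random_fraction,
              classification = object$classification,
              semilog = object$semilog,
              lml = object$lml)
  class(out) <- "summary.platelet_fit"
  out
}

#' @export
print.summary.platelet_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("RMSE: %s %%; turnover: %s %%/hr; random destruction: %s %% of turnover\n",
              format(x$rmse, digits = digits),
              format(x$turnover["percent_per_hr"], digits = digits),
              format(x$random_fraction, digits = digits)))
  if (!is.null(x$se))
    cat("Jackknife SE: ", paste(sprintf("%s = %s", names(x$se),
                                        format(x$se, digits = digits)),
                                collapse = ", "), "\n", sep = "")
  if (!is.null(x$semilog))
    cat(sprintf("Semi-log regression through T0=100%%: slope %s /hr (implied RD %s %%/hr, R2 %s)\n",
                format(x$semilog$slope_per_hr, digits = digits),
                format(x$semilog$implied_rd, digits = digits),
                format(x$semilog$r_squared, digits = digits)))
  cat("Local-minimum line (one LM per RD plane):\n")
  print(format(x$lml, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
plot.platelet_fit <- function(x, ...) {
  graphics::plot(x$data$time_hr, x$data$percent_remaining,
                 xlab = "hours post T0", ylab = "% of T0 remaining",
                 ylim = c(0, max(100, x$data$percent_remaining)), ...)
  graphics::lines(x$curve$hour, x$curve$percent_remaining)
  invisible(x)
}

#' Simulate datasets from a fitted model
#'
#' Draws synthetic consumption datasets from the fitted curve with additive
#' Gaussian measurement noise (default: the residual standard deviation),
#' matching the observed design (subjects and time grid) unless overridden.
#'
#' @param object A `"platelet_fit"`.
#' @param nsim Number of datasets.
#' @param seed Optional integer seed.
#' @param n_subjects,times,noise_sd Design overrides.
#' @param ... Unused.
#' @return A list of `nsim` data frames in the standard measurement format.
#' @export
simulate.platelet_fit <- function(object, nsim = 1, seed = NULL,
                                  n_subjects = NULL, times = NULL,
                                  noise_sd = NULL, ...) {
  if (is.null(times)) times <- sort(unique(object$data$time_hr))
  if (is.null(n_subjects)) n_subjects <- object$n_subjects
  if (is.null(noise_sd)) noise_sd <- stats::sd(residuals(object))
  curve_v <- predict(object, times)
  with_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      y <- pmax(0, rep(curve_v, n_subjects) +
                   stats::rnorm(length(times) * n_subjects, sd = noise_sd))
      data.frame(subject_id = rep(sprintf("sim%d_%02d", i, seq_len(n_subjects)),
                                  each = length(times)),
                 time_hr = rep(times, n_subjects),
                 percent_remaining = y)
    })
  })
}
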