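# Consumption-dataset validation. The canonical unit for remaining label is
# percent of the T0 measurement (0-100 scale); fraction-scale input is
# auto-detected and rescaled. T0 itself is the implicit 100% anchor at t = 0.

#' Validate a labeled-platelet consumption dataset
#'
#' Checks and normalizes per-recipient percent-remaining measurements. The
#' required columns are `subject_id`, `time_hr` and `percent_remaining`;
#' `donor_strain` and `recipient_strain` are carried through when present.
#' Values on the 0-1 fraction scale (maximum at or below 1.5) are rescaled to
#' percent with a warning. Rows at `time_hr == 0` must read 100 (the T0
#' anchor) and are removed from the residual set. Subjects measured on
#' differing time grids are accepted but flagged via the `"ragged"`
#' attribute.
#'
#' @param data A data frame of measurements.
#' @return The validated data frame (T0 rows dropped), with attributes
#'   `"ragged"` and `"times"` (sorted unique measurement times).
#' @export
as_consumption_data <- function(data) {
  data <- as.data.frame(data)
  req <- c("subject_id", "time_hr", "percent_remaining")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (!is.numeric(data$time_hr) || !is.numeric(data$percent_remaining))
    stop("'time_hr' and 'percent_remaining' must be numeric")
  if (anyNA(data$time_hr) || anyNA(data$percent_remaining))
    stop("missing values in 'time_hr' or 'percent_remaining'")
  if (any(data$time_hr < 0)) stop("negative measurement times")
  if (any(data$percent_remaining < 0)) stop("negative 'percent_remaining' values")
  if (anyDuplicated(data[c("subject_id", "time_hr")]))
    stop("duplicate (subject_id, time_hr) pairs")
  if (max(data$percent_remaining) <= 1.5) {
    warning("'percent_remaining' looks fraction-scaled (max <= 1.5); rescaling to percent")
    data$percent_remaining <- 100 * data$percent_remaining
  }
  t0 <- data$time_hr == 0
  if (any(t0)) {
    if (any(abs(data$percent_remaining[t0] - 100) > 1e-8))
      stop("rows at time 0 must read 100 (the T0 anchor)")
    data <- data[!t0, , drop = FALSE]
  }
  if (!nrow(data)) stop("no post-T0 measurements present")
  grids <- tapply(data$time_hr, data$subject_id, function(t) paste(sort(t), collapse = ","))
  ragged <- length(unique(grids)) > 1L
  if (ragged)
    message("subjects are measured on differing time grids (ragged dataset)")
  rownames(data) <- NULL
  attr(data, "ragged") <- ragged
  attr(data, "times") <- sort(unique(data$time_hr))
  data
}

# Pooled per-time sufficient statistics for fast SS evaluation:
# SS(curve) = sum_j [ syy_j - 2 v_j sy_j + m_j v_j^2 ],  v_j = curve(t_j).
data_summaries <- function(data) {
  f <- factor(data$time_hr)
  times <- as.numeric(levels(f))
  list(times = times,
       m = as.numeric(tabulate(f)),
       sy = as.numeric(tapply(data$percent_remaining, f, sum)),
       syy = as.numeric(tapply(data$percent_remaining^2, f, sum)),
       n_obs = nrow(data))
}

#' Sum of squared residuals between a model curve and observed data
#'
#' Squared residuals are computed for every data point against the model
#' consumption curve, the curve being evaluated at each measurement time by
#' linear interpolation between adjacent hourly values, and summed over all
#' subjects and time points (no per-subject weighting).
#'
#' @param curve A `"platelet_population"`, or a data frame with columns
#'   `hour` and `percent_remaining` (as returned by [consumption_curve()]).
#' @param data A consumption dataset (see [as_consumption_data()]).
#' @return The sum of squared residuals, in squared percentage points.
#' @examples
#' crv <- data.frame(hour = 0:10, percent_remaining = 100 * 0.99^(0:10))
#' dat <- data.frame(subject_id = "a", time_hr = c(2, 5),
#'                   percent_remaining = 100 * 0.99^c(2, 5) + c(1, 2))
#' sum_squared_residuals(crv, dat)  # 1^2 + 2^2 = 5
#' @export
sum_squared_residuals <- function(curve, data) {
  if (inherits(curve, "platelet_population")) curve <- consumption_curve(curve)
  stopifnot(is.data.frame(curve), all(c("hour", "percent_remaining") %in% names(curve)))
  data <- as_consumption_data(data)
  if (max(data$time_hr) > max(curve$hour))
    stop("data contain times beyond the curve horizon")
  v <- stats::approx(curve$hour, curve$percent_remaining,
                     xout = data$time_hr)$y
  sum((data$percent_remaining - v)^2)
}
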