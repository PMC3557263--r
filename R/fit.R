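# Grid-search least-squares fit: SS over an RD x LS x SD grid, one local
# minimum (LM) per RD-defined plane, the local-minimum line (LML) across
# planes, the global minimum (GM) along it, and high-resolution refinement
# of the GM within re-verified volumes. Ties in SS break deterministically
# toward the smallest RD, then LS, then SD.

unverified_space_condition <- function(map, where) {
  structure(class = c("plateletkin_unverified_space", "error", "condition"),
            list(message = sprintf(
                   "search volume not equilibration-verified (%s): min e = %.4f <= 0.95",
                   where, min(map$e)),
                 call = NULL, map = map))
}

# One full grid pass. Returns the LML table, GM, and optionally the dense
# SS grid. `dsum` are pooled per-time data summaries; `donor_state` switches
# to grafted-population curves.
grid_pass <- function(space, dsum, n, density_mode, donor_state = NULL,
                      keep_grid = FALSE) {
  cols <- space_columns(space)
  H <- max(1L, as.integer(ceiling(max(dsum$times))))
  horizon <- if (is.null(donor_state)) n + H else max(donor_state$age0) + H
  w_mat <- column_weights(cols, horizon, density_mode)
  tf <- as.integer(floor(dsum$times))
  frac <- dsum$times - tf
  nrd <- length(space$rd)
  K <- nrow(cols)
  lml <- data.frame(rd = space$rd, ls = NA_real_, sd = NA_real_,
                    ss = NA_real_, boundary = FALSE,
                    rd_pct_of_turnover = NA_real_)
  grid <- if (keep_grid) vector("list", nrd)
  gm <- NULL
  ls_edges <- range(space$ls)
  sd_edges <- range(space$sd)
  for (p in seq_len(nrd)) {
    rd <- space$rd[p]
    counts <- if (is.null(donor_state)) {
      plane_eval(rd, cols, w_mat, n, H, density_mode)$counts
    } else {
      plane_eval_graft(rd, cols, w_mat, donor_state, H)
    }
    pct <- 100 * sweep(counts, 2L, counts[1L, ], "/")
    # curve at each data time by linear interpolation between hourly values
    v <- pct[tf + 1L, , drop = FALSE] * (1 - frac) +
         pct[pmin(tf + 2L, H + 1L), , drop = FALSE] * frac
    ss <- colSums(dsum$syy - 2 * v * dsum$sy + dsum$m * v^2)
    k <- which.min(ss)
    to_first <- (counts[1L, k] - counts[2L, k]) / counts[1L, k]
    lml$ls[p] <- cols$ls[k]
    lml$sd[p] <- cols$sd[k]
    lml$ss[p] <- ss[k]
    lml$boundary[p] <-
      (length(space$ls) > 1L && cols$ls[k] %in% ls_edges) ||
      (length(space$sd) > 1L && cols$sd[k] %in% sd_edges)
    lml$rd_pct_of_turnover[p] <- if (to_first > 0) (rd / 100) / to_first * 100
                                 else NA_real_
    if (keep_grid)
      grid[[p]] <- data.frame(rd = rd, ls = cols$ls, sd = cols$sd, ss = ss)
    if (is.null(gm) || ss[k] < gm$ss)
      gm <- list(rd = rd, ls = cols$ls[k], sd = cols$sd[k], ss = ss[k],
                 boundary = lml$boundary[p] ||
                   (length(space$rd) > 1L && rd %in% range(space$rd)))
  }
  lml$ss_pct_of_min <- 100 * lml$ss / gm$ss
  list(lml = lml, gm = gm,
       grid = if (keep_grid) do.call(rbind, grid))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# +/- one coarse grid cell around the GM, clipped to admissible values.
shrink_space <- function(space, gm) {
  ax <- function(v, g, lo_min, hi_max = Inf) {
    if (length(v) == 1L) return(v)
    step <- v[2] - v[1]
    c(max(lo_min, g - step), min(hi_max, g + step))
  }
  search_space(rd = ax(space$rd, gm$rd, 0, 99.999),
               ls = ax(space$ls, gm$ls, 1e-3),
               sd = ax(space$sd, gm$sd, 0),
               points = lengths(space))
}

# Shift the axes on which the GM sits on a boundary outward by one range
# width (the "adjacent volume" re-search).
shift_space <- function(space, gm) {
  ax <- function(v, g, lo_min, hi_max = Inf) {
    if (length(v) == 1L) return(v)
    rng <- range(v)
    wid <- diff(rng)
    if (g <= rng[1] + 1e-12 && rng[1] > lo_min) {
      c(max(lo_min, rng[1] - wid), rng[1])
    } else if (g >= rng[2] - 1e-12) {
      c(rng[2], min(hi_max, rng[2] + wid))
    } else v[c(1, length(v))]
  }
  search_space(rd = ax(space$rd, gm$rd, 0, 99.999),
               ls = ax(space$ls, gm$ls, 1e-3),
               sd = ax(space$sd, gm$sd, 0),
               points = lengths(space))
}

fit_core <- function(space, dsum, n, density_mode, donor_state = NULL,
                     refine = 2, verify = TRUE, keep_grid = FALSE,
                     boundary_shifts = 0L) {
  if (verify) {
    emap <- verify_equilibration(space, n, density_mode)
    if (!attr(emap, "verified"))
      stop(unverified_space_condition(emap, "coarse search"))
  } else emap <- NULL
  pass <- grid_pass(space, dsum, n, density_mode, donor_state, keep_grid)
  gm <- pass$gm
  shifts <- 0L
  while (gm$boundary && shifts < boundary_shifts) {
    shifts <- shifts + 1L
    space2 <- shift_space(space, gm)
    if (verify) {
      emap2 <- verify_equilibration(space2, n, density_mode)
      if (!attr(emap2, "verified")) break
    }
    pass2 <- grid_pass(space2, dsum, n, density_mode, donor_state, FALSE)
    if (pass2$gm$ss < gm$ss) {
      space <- space2
      pass <- pass2
      gm <- pass2$gm
    } else break
  }
  history <- list()
  round <- 0L
  while (round < refine) {
    round <- round + 1L
    rspace <- shrink_space(space, gm)
    if (verify) {
      remap <- verify_equilibration(rspace, n, density_mode)
      if (!attr(remap, "verified")) {
        warning("refined search volume not equilibration-verified; refinement stopped")
        break
      }
    }
    rpass <- grid_pass(rspace, dsum, n, density_mode, donor_state, FALSE)
    rgm <- rpass$gm
    if (rgm$boundary)
      warning("refined optimum lies on the refined range boundary")
    if (rgm$ss >= gm$ss) break   # previous optimum retained: SS never increases
    moved <- max(abs(rgm$rd - gm$rd), abs(rgm$ls - gm$ls), abs(rgm$sd - gm$sd))
    history[[round]] <- list(space = rspace, gm = rgm, lml = rpass$lml)
    space <- rspace
    gm <- rgm
    if (moved == 0) break
  }
  list(gm = gm, lml = pass$lml, coarse_grid = pass$grid,
       refinements = history, final_space = space, e_map = emap)
}

#' Fit platelet consumption parameters by grid-search least squares
#'
#' Finds the parameter triple (RD, LS, SD) whose model consumption curve
#' minimizes the sum of squared residuals against observed labeled-platelet
#' survival data. The search evaluates every point of an
#' equilibration-verified grid, records the local minimum of each RD-defined
#' plane, follows these across planes (the local-minimum line), takes the
#' global minimum along the line, and refines it on progressively narrower,
#' re-verified grids centred on the optimum. Fits whose random destruction
#' term accounts for more than 99\% of turnover are classified as
#' `"pure-random"`: the data carry no lifespan information, LS and SD are
#' reported as not estimable, and a semi-log linear regression through
#' T0 = 100\% is reported as corroboration.
#'
#' With `donor` supplied, model curves come from the donor equilibrium
#' population grafted into the candidate recipient environment (see
#' [graft()]), so the fitted parameters describe the recipient environment
#' acting on donor-aged platelets.
#'
#' @param data Consumption measurements (see [as_consumption_data()] for the
#'   required columns).
#' @param space A [search_space()]. The default volume (RD 0-5 \%/hr, LS
#'   10-84 hr, SD 0.01-0.7, 20 points per axis) is equilibration-verified at
#'   the default 500 h equilibration.
#' @param donor Optional equilibrated `"platelet_population"` for allogeneic
#'   fits.
#' @param equilibration_hr Equilibration phase length used both for model
#'   curves and for volume verification. Default 500.
#' @param consumption_hr Consumption horizon of the stored fitted curve.
#' @param density_mode See [step_cohort()].
#' @param pr Optional production rate (K/ul/hr) used only to report absolute
#'   turnover; normalized curve shapes are production-rate invariant.
#' @param refine Number of refinement rounds (default 2). Each round shrinks
#'   the grid to the one-cell neighbourhood of the optimum at unchanged
#'   point counts (resolution about 5\% of the refined range per axis).
#' @param verify If `TRUE` (default), every searched volume must satisfy
#'   `e > 0.95` at all grid points; an unverified volume is an error whose
#'   condition carries the e map.
#' @param boundary_shifts Number of adjacent-volume re-searches allowed when
#'   the optimum falls on the search-volume boundary (default 0; the
#'   boundary is flagged either way).
#' @param keep_grid Keep the dense coarse SS grid in the result.
#' @return An object of class `"platelet_fit"`; see [coef.platelet_fit()],
#'   [predict.platelet_fit()], `summary()`, `plot()`, `residuals()`,
#'   [simulate.platelet_fit()]. Key elements: `par` (the optimum triple),
#'   `ss`, `lml` (the local-minimum line with SS as \% of the minimum and RD
#'   as \% of turnover), `classification`, `turnover`, `random_fraction`.
#' @examples
#' \donttest{
#' truth <- kinetic_params(rd = 2, ls = 40, sd = 0.2)
#' dat <- simulate_consumption(truth, n_subjects = 6, noise_sd = 0,
#'                             equilibration_hr = 300)
#' sp <- search_space(c(1, 3), c(30, 50), c(0.1, 0.3), points = 5)
#' fit <- platelet_fit(dat, sp, equilibration_hr = 300, refine = 1)
#' coef(fit)
#' }
#' @export
platelet_fit <- function(data, space = NULL, donor = NULL,
                         equilibration_hr = 500, consumption_hr = 125,
                         density_mode = c("pdf", "cdf-diff"), pr = NULL,
                         refine = 2, verify = TRUE, boundary_shifts = 0L,
                         keep_grid = FALSE) {
  cl <- match.call()
  density_mode <- match.arg(density_mode)
  data <- as_consumption_data(data)
  if (is.null(space))
    space <- search_space(rd = c(0, 5), ls = c(10, 84), sd = c(0.01, 0.7))
  stopifnot(inherits(space, "search_space"))
  n <- as.integer(equilibration_hr)
  donor_state <- NULL
  if (!is.null(donor)) {
    stopifnot(inherits(donor, "platelet_population"))
    if (donor$grafted) stop("'donor' must be an equilibrated (non-grafted) population")
    if (!is.na(donor$e) && donor$e <= 0.95)
      warning("donor equilibration metric <= 0.95")
    donor_state <- list(age0 = donor$age$age_hr, P0 = donor$age$count_kul,
                        CRD0 = donor$age$crd_kul, pr = donor$pr)
  }
  dsum <- data_summaries(data)
  core <- fit_core(space, dsum, n, density_mode, donor_state,
                   refine = refine, verify = verify, keep_grid = keep_grid,
                   boundary_shifts = boundary_shifts)
  gm <- core$gm
  par <- c(rd = gm$rd, ls = gm$ls, sd = gm$sd)
  gm_params <- kinetic_params(gm$rd, gm$ls, gm$sd, pr %||% 1)
  pop <- if (is.null(donor)) {
    platelet_population(gm_params, n, consumption_hr, density_mode)
  } else {
    graft(donor, gm_params, consumption_hr, density_mode)
  }
  to <- turnover_rate(pop)
  rf <- random_fraction_of_turnover(pop)
  classification <- if (rf > 99) "pure-random" else "mixed"
  semilog <- NULL
  if (classification == "pure-random") {
    ok <- data$percent_remaining > 0
    sl <- stats::lm(log(percent_remaining / 100) ~ 0 + time_hr,
                    data = data[ok, , drop = FALSE])
    b <- unname(stats::coef(sl)[1])
    semilog <- list(slope_per_hr = b,
                    implied_rd = 100 * (1 - exp(b)),
                    r_squared = summary(sl)$r.squared,
                    n_dropped_nonpositive = sum(!ok))
  }
  fitted_curve <- data.frame(hour = 0:pop$c, percent_remaining = pop$curve)
  structure(list(par = par, ss = gm$ss, boundary = gm$boundary,
                 classification = classification,
                 random_fraction = rf,
                 turnover = c(percent_per_hr = unname(to["percent_per_hr"]),
                              kul_per_hr = if (is.null(pr)) NA_real_
                                           else unname(to["kul_per_hr"])),
                 pr = pr, semilog = semilog,
                 lml = core$lml, refinements = core$refinements,
                 grid = core$coarse_grid, e_map = core$e_map,
                 space = space, final_space = core$final_space,
                 population = pop, curve = fitted_curve,
                 data = data, donor = donor, n_subjects = length(unique(data$subject_id)),
                 settings = list(equilibration_hr = n,
                                 consumption_hr = as.integer(consumption_hr),
                                 density_mode = density_mode,
                                 refine = refine, verify = verify),
                 call = cl),
            class = "platelet_fit")
}

#' Local minimum of one RD-defined plane
#'
#' Evaluates the sum of squared residuals at every (LS, SD) grid point of a
#' single RD plane and returns the minimizing point, flagging minima that
#' fall on the plane boundary (for which no interior minimum exists at this
#' RD).
#'
#' @param rd The RD value defining the plane (\%/hr).
#' @param space A [search_space()] supplying the LS and SD axes.
#' @param data Consumption measurements.
#' @param donor Optional donor population (allogeneic curves).
#' @param equilibration_hr,density_mode As in [platelet_fit()].
#' @return A one-row data frame: `rd`, `ls`, `sd`, `ss`, `boundary`,
#'   `rd_pct_of_turnover`.
#' @export
plane_local_minimum <- function(rd, space, data, donor = NULL,
                                equilibration_hr = 500,
                                density_mode = c("pdf", "cdf-diff")) {
  density_mode <- match.arg(density_mode)
  data <- as_consumption_data(data)
  plane <- search_space(rd = rd, ls = range(space$ls), sd = range(space$sd),
                        points = c(1L, length(space$ls), length(space$sd)))
  plane$ls <- space$ls
  plane$sd <- space$sd
  donor_state <- if (!is.null(donor))
    list(age0 = donor$age$age_hr, P0 = donor$age$count_kul,
         CRD0 = donor$age$crd_kul, pr = donor$pr)
  pass <- grid_pass(plane, data_summaries(data), as.integer(equilibration_hr),
                    density_mode, donor_state, keep_grid = FALSE)
  pass$lml[, c("rd", "ls", "sd", "ss", "boundary", "rd_pct_of_turnover")]
}

#' Classify a fit as mixed or purely exponential
#'
#' A fitted consumption regime in which the random destruction term accounts
#' for more than 99\% of the first post-production-hour turnover is
#' indistinguishable from a pure exponential decay: the lifespan parameters
#' are not estimable from such data.
#'
#' @param fit A `"platelet_fit"`.
#' @return `"pure-random"` or `"mixed"`.
#' @export
degenerate_exponential_check <- function(fit) {
  stopifnot(inherits(fit, "platelet_fit"))
  fit$classification
}
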