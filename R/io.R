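# File formats and the pipeline driver. Tabular outputs are TSV, parameter
# outputs JSON; every output file carries the run's config checksum and seed
# in a header comment so a result can be matched to the run that made it.

#' Read a consumption dataset from CSV
#'
#' Expects a header row with at least `subject_id`, `time_hr` and
#' `percent_remaining`; `donor_strain`/`recipient_strain` are kept when
#' present. Validation and unit handling are as in [as_consumption_data()].
#'
#' @param path CSV file path.
#' @return A validated consumption data frame.
#' @export
read_consumption_csv <- function(path) {
  as_consumption_data(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a consumption dataset to CSV
#'
#' @param data A consumption data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_consumption_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# 32-bit polynomial checksum of a deparsed object; enough to match outputs
# to the configuration that produced them.
config_checksum <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 4294967296
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

write_tsv_with_header <- function(df, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pipeline run configuration
#'
#' Reads a YAML (`.yml`/`.yaml`) or JSON configuration file into a list. See
#' [run_pipeline()] for the recognized fields.
#'
#' @param path Configuration file path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else stop("config must be .yaml/.yml or .json")
}

config_space <- function(cfg) {
  search_space(rd = as.numeric(cfg$rd), ls = as.numeric(cfg$ls),
               sd = as.numeric(cfg$sd),
               points = if (is.null(cfg$points)) 20 else cfg$points)
}

#' Run the full consumption-analysis pipeline
#'
#' Executes verify -> fit (syngeneic or grafted) -> refine -> classify ->
#' optional jackknife from a single configuration, writing the fitted
#' parameters (JSON), the fitted consumption curve, the equilibrium age
#' distribution and the local-minimum line (TSV) to an output directory.
#' An unverified search volume aborts with an error after writing the
#' diagnostic equilibration contour map.
#'
#' Recognized configuration fields: `data` (CSV path) or `simulate` (a list
#' with `rd`, `ls`, `sd`, `pr`, `n_subjects`, `times`, `noise_sd`);
#' `space` (list with `rd`, `ls`, `sd` ranges and `points`); `donor` (list
#' with `rd`, `ls`, `sd`, `pr` and optionally `equilibration_hr` for
#' allogeneic fits); `equilibration_hr`, `consumption_hr`, `density_mode`,
#' `refine`, `pr`, `jackknife` (logical or points-per-axis), `seed`,
#' `output_dir`.
#'
#' @param config A named list or a path to a YAML/JSON file.
#' @param output_dir Output directory; overrides `config$output_dir`.
#' @return Invisibly, a list with the fit, the optional jackknife result and
#'   the written file paths.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(is.list(config))
  out_dir <- output_dir %||% config$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  stamp <- c(sprintf("plateletkin run; config checksum %s; seed %s",
                     config_checksum(config),
                     if (is.null(seed)) "none" else seed))
  n_eq <- config$equilibration_hr %||% 500
  cc <- config$consumption_hr %||% 125
  mode <- config$density_mode %||% "pdf"

  donor <- NULL
  if (!is.null(config$donor)) {
    dp <- config$donor
    donor <- platelet_population(kinetic_params(dp$rd, dp$ls, dp$sd, dp$pr %||% 1),
                                 dp$equilibration_hr %||% n_eq, cc, mode)
  }
  data <- if (!is.null(config$data)) {
    read_consumption_csv(config$data)
  } else if (!is.null(config$simulate)) {
    sm <- config$simulate
    simulate_consumption(kinetic_params(sm$rd, sm$ls, sm$sd, sm$pr %||% 1),
                         n_subjects = sm$n_subjects %||% 30,
                         times = as.numeric(sm$times %||% c(5, 24, 48, 72)),
                         noise_sd = sm$noise_sd %||% 3, seed = seed,
                         donor = donor, equilibration_hr = n_eq,
                         density_mode = mode)
  } else stop("config must provide 'data' (a CSV path) or 'simulate'")

  space <- if (!is.null(config$space)) config_space(config$space)
  fit <- tryCatch(
    platelet_fit(data, space = space, donor = donor,
                 equilibration_hr = n_eq, consumption_hr = cc,
                 density_mode = mode, pr = config$pr,
                 refine = config$refine %||% 2),
    plateletkin_unverified_space = function(cond) {
      map_path <- file.path(out_dir, "equilibration_map.tsv")
      write_tsv_with_header(cond$map, map_path, stamp)
      stop("search volume failed equilibration verification; ",
           "contour map written to ", map_path, call. = FALSE)
    })

  jk <- NULL
  if (isTRUE(config$jackknife) || is.numeric(config$jackknife)) {
    jk <- jackknife(fit, points = if (is.numeric(config$jackknife))
                                    config$jackknife else 11)
  }

  files <- list()
  co <- coef(fit)
  params_out <- list(rd = unname(co["rd"]),
                     ls = if (is.na(co["ls"])) "n/a" else unname(co["ls"]),
                     sd = if (is.na(co["sd"])) "n/a" else unname(co["sd"]),
                     ss = fit$ss,
                     turnover_pct_per_hr = unname(fit$turnover["percent_per_hr"]),
                     random_fraction_pct = fit$random_fraction,
                     classification = fit$classification,
                     allogeneic = !is.null(donor),
                     config_checksum = config_checksum(config),
                     seed = seed)
  if (!is.null(jk))
    params_out$jackknife <- list(se = as.list(jk$se), n = jk$n)
  files$params <- file.path(out_dir, "parameters.json")
  jsonlite::write_json(params_out, files$params, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  files$curve <- write_tsv_with_header(
    data.frame(hour = fit$curve$hour,
               percent_remaining = fit$curve$percent_remaining),
    file.path(out_dir, "curve.tsv"), stamp)
  files$age <- write_tsv_with_header(age_distribution(fit$population),
                                     file.path(out_dir, "age_distribution.tsv"),
                                     stamp)
  files$lml <- write_tsv_with_header(fit$lml, file.path(out_dir, "lml.tsv"),
                                     stamp)
  if (!is.null(jk))
    files$jackknife <- write_tsv_with_header(
      data.frame(subject_id = rownames(jk$estimates), jk$estimates,
                 boundary = jk$boundary),
      file.path(out_dir, "jackknife.tsv"), stamp)
  invisible(list(fit = fit, jackknife = jk, files = files, config = config))
}
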