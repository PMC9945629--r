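# File formats and run configuration. CSV is the single interchange
# format (UTF-8, period decimal separator); time units are explicit per
# file (minutes for recirculation, days elsewhere).

ts_required_cols <- c("subject_id", "time", "cell_type", "count")
ts_cell_types <- c("lymphocyte", "T_cell", "B_cell", "NK_cell",
                   "neutrophil", "monocyte", "other")

#' Read a long-format blood-count time-series CSV
#'
#' Schema: columns `subject_id`, `time`, `cell_type`, `count` (cells/uL),
#' optionally `time_unit` (uniform within a file, `minutes` or `days`) and
#' further numeric covariate columns (e.g. `dose_Gy`). Validation rejects
#' duplicate `(subject_id, time, cell_type)` keys and negative counts,
#' naming the offending rows; missing counts must be encoded as `NA`,
#' never 0.
#'
#' @param path CSV file path.
#' @param time_unit Expected time unit; overrides/validates the file's
#'   `time_unit` column. Default `"days"` when the file has none.
#' @return A validated tibble (a `leuco_timeseries`), `time_unit` stored
#'   as an attribute.
#' @export
read_timeseries <- function(path, time_unit = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_timeseries(raw, time_unit = time_unit)
}

#' Validate a long-format blood-count table
#'
#' @param data Data frame following the time-series schema.
#' @inheritParams read_timeseries
#' @return The validated `leuco_timeseries` tibble.
#' @export
validate_timeseries <- function(data, time_unit = NULL) {
  data <- as_tibble(data)
  missing_cols <- setdiff(ts_required_cols, names(data))
  if (length(missing_cols)) {
    abort(sprintf("Missing required column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  if ("time_unit" %in% names(data)) {
    units <- unique(data$time_unit)
    if (length(units) > 1L) {
      abort(sprintf("`time_unit` must be uniform within a file; found: %s.",
                    paste(units, collapse = ", ")))
    }
    if (!is.null(time_unit) && units != time_unit) {
      abort(sprintf("File time unit '%s' does not match expected '%s'.",
                    units, time_unit))
    }
    time_unit <- units
  }
  time_unit <- time_unit %||% "days"
  if (!time_unit %in% c("minutes", "days")) {
    abort("`time_unit` must be 'minutes' or 'days'.")
  }
  bad_ct <- setdiff(unique(data$cell_type), ts_cell_types)
  if (length(bad_ct)) {
    abort(sprintf("Unknown cell_type value(s): %s. Allowed: %s.",
                  paste(bad_ct, collapse = ", "),
                  paste(ts_cell_types, collapse = ", ")))
  }
  neg <- which(!is.na(data$count) & data$count < 0)
  if (length(neg)) {
    abort(sprintf("Negative count in row(s): %s.",
                  paste(head(neg, 10), collapse = ", ")))
  }
  key <- paste(data$subject_id, data$time, data$cell_type, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    abort(sprintf("Duplicate (subject_id, time, cell_type) in row(s): %s.",
                  paste(head(dup, 10), collapse = ", ")))
  }
  out <- data
  attr(out, "time_unit") <- time_unit
  class(out) <- c("leuco_timeseries", class(tibble()))
  out
}

#' Write a blood-count time series to CSV
#'
#' Columns are written in schema order (`subject_id`, `time`, `cell_type`,
#' `count`, `time_unit`, then any covariates); full double precision so
#' that read-write round trips are byte-identical.
#'
#' @param data A validated time-series tibble (see [validate_timeseries()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(data, path) {
  data <- validate_timeseries(data,
                              time_unit = attr(data, "time_unit", exact = TRUE))
  out <- as_tibble(data)
  out$time_unit <- attr(data, "time_unit", exact = TRUE)
  front <- c(ts_required_cols, "time_unit")
  out <- out[, c(front, setdiff(names(out), front))]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and validate a run configuration (YAML or JSON)
#'
#' The configuration drives [run_command()]: a `command` plus input/output
#' paths and per-command blocks (model, estimation, validation, metrics).
#' Unknown top-level keys are rejected before any computation.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return The validated config list (class `run_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config not found: %s", path))
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    abort("Config must be a .yaml/.yml or .json file.")
  }
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  allowed <- c("command", "input", "output_dir", "seed", "model",
               "design", "estimation", "validation", "metrics",
               "recirculation", "screen", "allow_nonconverged")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    abort(sprintf("Unknown config key(s): %s. Allowed: %s.",
                  paste(unknown, collapse = ", "),
                  paste(allowed, collapse = ", ")))
  }
  cmds <- c("simulate", "fit", "select", "screen", "validate", "grade")
  if (is.null(cfg$command) || !cfg$command %in% cmds) {
    abort(sprintf("Config `command` must be one of: %s.",
                  paste(cmds, collapse = ", ")))
  }
  structure(cfg, class = "run_config")
}

#' Execute a configured analysis run
#'
#' Dispatches the configured command (`simulate`, `fit`, `select`,
#' `screen`, `validate`, `grade`) over the package's functions, writes the
#' result artifacts (CSV/JSON) into the output directory together with a
#' run log (seed, package version, config hash, wall time), and returns
#' the exit status: 0 on success, 1 when a fit was flagged non-converged
#' (unless `allow_nonconverged`), 2 on configuration errors.
#'
#' @param config A `run_config` (or path to one).
#' @param seed Overrides the config seed.
#' @param out_dir Overrides the config output directory.
#' @return Invisibly, a list with `status` and the result object(s).
#' @export
run_command <- function(config, seed = NULL, out_dir = NULL) {
  cfg <- tryCatch({
    if (is.character(config)) read_run_config(config) else validate_run_config(config)
  }, error = function(e) e)
  if (inherits(cfg, "error")) {
    warn(paste("Invalid config:", conditionMessage(cfg)))
    return(invisible(list(status = 2L, error = conditionMessage(cfg))))
  }
  seed <- seed %||% cfg$seed %||% 1L
  out_dir <- out_dir %||% cfg$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  status <- 0L

  result <- switch(cfg$command,
    simulate = {
      d <- cfg$design
      des <- simulation_design(
        model = d$model, truth = d$truth,
        n_subjects = d$n_subjects %||% 1,
        iiv_cv = unlist(d$iiv_cv %||% list()),
        sampling_days = unlist(d$sampling_days),
        noise = d$noise %||% list(kind = "lognormal", sigma = 0.1),
        cell_type = d$cell_type %||% "neutrophil",
        seed = seed)
      ds <- generate_dataset(des)
      out <- ds$data
      attr(out, "time_unit") <- "days"
      class(out) <- c("leuco_timeseries", class(tibble()))
      write_timeseries(out, file.path(out_dir, "dataset.csv"))
      jsonlite::write_json(
        list(subject_params = ds$subject_params, design_model = des$model),
        file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
      ds
    },
    fit = ,
    select = {
      ts <- read_timeseries(cfg$input)
      fams <- cfg$model$families %||% growth_family()
      fits <- lapply(fams, function(f)
        fit_growth(ts, f,
                   weighting = cfg$estimation$weighting %||% "none"))
      rk <- select_model(fits, criterion = cfg$estimation$criterion %||% "aic")
      if (!all(rk$converged)) status <- 1L
      readr::write_csv(as_tibble(rk)[, c("family", "n_params", "ssr", "mse",
                                         "aic", "bic", "delta", "rank")],
                       file.path(out_dir, "fit_report.csv"), progress = FALSE)
      base <- cfg$model$baseline %||% ts$count[which.min(ts$time)]
      cls <- classify_recovery(attr(rk, "best"), baseline = base)
      jsonlite::write_json(as.list(cls), file.path(out_dir, "classification.json"),
                           auto_unbox = TRUE, digits = NA)
      rk
    },
    screen = {
      ts <- read_timeseries(cfg$input)
      sc <- screen_variable(ts,
        covariate = cfg$screen$covariate %||% "dose_Gy",
        criterion = cfg$screen$criterion %||% "bic")
      readr::write_csv(sc$ranking, file.path(out_dir, "screen_report.csv"),
                       progress = FALSE)
      sc
    },
    validate = {
      ts <- read_timeseries(cfg$input)
      fam <- cfg$model$family %||% "exponential_rise_to_plateau"
      fit <- fit_growth(ts, fam, weighting = cfg$estimation$weighting %||% "none")
      if (!fit$converged) status <- 1L
      gof <- goodness_of_fit(fit)
      cv <- cross_validate(ts, "growth", family = fam,
                           scheme = cfg$validation$scheme %||% "k_fold_blocked_time",
                           k = cfg$validation$k %||% 5, seed = seed)
      jsonlite::write_json(
        list(goodness_of_fit = as.list(gof),
             cv = list(scheme = cv$scheme, k = cv$k, cv_rmse = cv$cv_rmse,
                       folds = cv$folds)),
        file.path(out_dir, "validation_report.json"), auto_unbox = TRUE,
        digits = NA)
      list(gof = gof, cv = cv)
    },
    grade = {
      counts <- readr::read_csv(cfg$input, show_col_types = FALSE, progress = FALSE)
      res <- add_leucocyte_metrics(counts,
        lmr_threshold = cfg$metrics$lmr_threshold %||% 4.25,
        invert_lmr = isTRUE(cfg$metrics$invert_lmr))
      readr::write_csv(res, file.path(out_dir, "metrics.csv"), progress = FALSE)
      res
    })

  if (status == 1L && !isTRUE(cfg$allow_nonconverged)) {
    warn("A fit was flagged non-converged; exit status 1 (set allow_nonconverged to ignore).")
  } else {
    status <- 0L
  }
  log <- list(command = cfg$command, seed = seed,
              package_version = as.character(utils::packageVersion("leucokin")),
              config_hash = rlang::hash(unclass(cfg)),
              wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
              status = status)
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(status = status, result = result))
}
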