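#' Write / read a trial table
#'
#' Plain CSV, one row per trial.
#'
#' @param trials Tibble from [generate_trials()].
#' @param path File path.
#' @return `read_trials_csv` returns the tibble; the writer returns `path`
#'   invisibly.
#' @export
write_trials_csv <- function(trials, path) {
  readr::write_csv(trials, path)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE) |>
    mutate(group = factor(.data$group, levels = c("control", "case")))
}

#' Write / read an epoch set
#'
#' Long CSV: one row per subject / channel / condition / time sample.
#'
#' @param epochs An `erp_epochs` object.
#' @param path File path.
#' @return `read_epochs_csv` returns an `erp_epochs`; the writer returns
#'   `path` invisibly.
#' @export
write_epochs_csv <- function(epochs, path) {
  readr::write_csv(as_tibble(epochs), path)
  invisible(path)
}

#' @rdname write_epochs_csv
#' @export
read_epochs_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("subject", "group", "channel", "condition", "time_ms", "amplitude")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    abort(paste0("Epoch CSV lacks column(s): ", paste(miss, collapse = ", ")))
  }
  time <- sort(unique(d$time_ms))
  step <- unique(round(diff(time), 9))
  if (length(step) != 1) abort("Epoch CSV time axis is not uniform.")
  wide <- d |>
    arrange(match(.data$time_ms, time)) |>
    tidyr::pivot_wider(id_cols = c("subject", "group", "channel", "condition"),
                       names_from = "time_ms", values_from = "amplitude")
  key <- wide[, 1:4]
  key$group <- factor(key$group, levels = c("control", "case"))
  amp <- as.matrix(wide[, -(1:4)])
  dimnames(amp) <- NULL
  new_erp_epochs(key, amp, time, sampling_rate = 1000 / step)
}

#' Write a full synthetic study to a directory
#'
#' Writes `trials.csv`, `epochs.csv`, `wisc.csv` and `labels.csv` plus a
#' `metadata.yaml` sidecar recording the generator configuration (including
#' the seed), sufficient to regenerate the data.
#'
#' @param study A list from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_trials_csv(study$trials, file.path(dir, "trials.csv"))
  write_epochs_csv(study$epochs, file.path(dir, "epochs.csv"))
  readr::write_csv(study$wisc, file.path(dir, "wisc.csv"))
  readr::write_csv(study$labels, file.path(dir, "labels.csv"))
  cfg <- unclass(study$config)
  cfg$wave_params <- as.data.frame(cfg$wave_params)
  cfg$factor_map <- as.data.frame(cfg$factor_map)
  yaml::write_yaml(cfg, file.path(dir, "metadata.yaml"))
  invisible(dir)
}

#' Write / read a VOI table
#'
#' The header encodes variable metadata
#' (`ERP_<channel>_<window>_<condition>_<measure>`, `BEH_*`, `WISC_*`); the
#' reader validates every column against that convention, errors on
#' duplicated subject ids or unknown columns, and excludes (with a message)
#' subjects carrying any missing value. A column-mapping CSV (columns `from`,
#' `to`) lets an external export (e.g. a spreadsheet's own headers) be
#' renamed into the convention before validation.
#'
#' @param voi VOI tibble.
#' @param path File path.
#' @param mapping Optional path to a `from,to` CSV of column renames.
#' @return `read_voi_csv` returns the VOI tibble; the writer returns `path`
#'   invisibly.
#' @export
write_voi_csv <- function(voi, path) {
  readr::write_csv(voi, path)
  invisible(path)
}

#' @rdname write_voi_csv
#' @export
read_voi_csv <- function(path, mapping = NULL) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(mapping)) {
    mp <- readr::read_csv(mapping, show_col_types = FALSE, progress = FALSE)
    if (!all(c("from", "to") %in% names(mp))) {
      abort("Mapping file needs columns `from` and `to`.")
    }
    hit <- match(names(d), mp$from)
    names(d)[!is.na(hit)] <- mp$to[hit[!is.na(hit)]]
  }
  if (!all(id_cols() %in% names(d))) {
    abort("VOI CSV must carry `subject` and `group` columns (or map them).")
  }
  if (anyDuplicated(d$subject)) {
    abort(paste0("Duplicated subject id(s): ",
                 paste(unique(d$subject[duplicated(d$subject)]),
                       collapse = ", ")))
  }
  vars <- setdiff(names(d), id_cols())
  bad <- vars[!(is_erp_col(vars) | is_beh_col(vars) | is_wisc_col(vars))]
  if (length(bad)) {
    abort(paste0("Column(s) not following the ERP_/BEH_/WISC_ naming ",
                 "convention: ", paste(bad, collapse = ", ")))
  }
  voi_metadata(vars)  # errors on unparseable ERP names
  incomplete <- !stats::complete.cases(d[, vars, drop = FALSE])
  if (any(incomplete)) {
    inform(paste0("Excluding ", sum(incomplete),
                  " subject(s) with missing values: ",
                  paste(d$subject[incomplete], collapse = ", ")))
    d <- d[!incomplete, , drop = FALSE]
  }
  d$group <- factor(d$group, levels = c("control", "case"))
  as_tibble(d)
}

#' Serialize / load a fitted CLV model
#'
#' Writes a text bundle (a directory of CSVs plus a YAML header) holding the
#' variable assignment, loadings and projection weights, training
#' standardization parameters, latent scores and the criterion trace, so a
#' fit can be reloaded and used for projection.
#'
#' @param model A `clv_fit`.
#' @param dir Bundle directory (created if needed).
#' @return `read_clv_model` returns a `clv_fit`; the writer returns `dir`
#'   invisibly.
#' @export
write_clv_model <- function(model, dir) {
  stopifnot(inherits(model, "clv_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(model$assignment, file.path(dir, "assignment.csv"))
  readr::write_csv(model$loadings, file.path(dir, "loadings.csv"))
  readr::write_csv(
    tibble(variable = names(model$center), center = unname(model$center),
           scale = unname(model$scale)),
    file.path(dir, "standardization.csv"))
  sc <- as_tibble(model$scores)
  sc <- bind_cols(tibble(subject = rownames(model$scores)), sc)
  readr::write_csv(sc, file.path(dir, "scores.csv"))
  yaml::write_yaml(list(K = model$K, criterion = model$criterion,
                        trace = model$trace, lambda = model$lambda,
                        n = model$n, p = model$p,
                        iterations = model$iterations,
                        converged = model$converged,
                        dropped = model$dropped),
                   file.path(dir, "meta.yaml"), precision = 15)
  invisible(dir)
}

#' @rdname write_clv_model
#' @export
read_clv_model <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  std <- readr::read_csv(file.path(dir, "standardization.csv"),
                         show_col_types = FALSE, progress = FALSE)
  sc <- readr::read_csv(file.path(dir, "scores.csv"),
                        show_col_types = FALSE, progress = FALSE)
  scores <- as.matrix(sc[, -1, drop = FALSE])
  rownames(scores) <- sc$subject
  structure(list(
    K = meta$K,
    assignment = readr::read_csv(file.path(dir, "assignment.csv"),
                                 show_col_types = FALSE, progress = FALSE),
    scores = scores,
    loadings = readr::read_csv(file.path(dir, "loadings.csv"),
                               show_col_types = FALSE, progress = FALSE),
    lambda = unlist(meta$lambda),
    criterion = meta$criterion,
    trace = unlist(meta$trace),
    center = setNames(std$center, std$variable),
    scale = setNames(std$scale, std$variable),
    dropped = unlist(meta$dropped) %||% character(0),
    iterations = meta$iterations,
    converged = meta$converged,
    n = meta$n, p = meta$p
  ), class = "clv_fit")
}

#' Validate a run configuration
#'
#' Checks a configuration list (typically loaded from YAML via
#' [read_run_config()]) for internal consistency: positive repetition count,
#' test fraction in (0, 1), QC thresholds in range, every channel named by a
#' channel set present in the window table, and every scheduled condition
#' among the declared conditions. Missing fields are filled with the
#' documented defaults; all problems are reported together.
#'
#' @param config A named list; recognised fields: `reps`, `test_fraction`,
#'   `k_range`, `restarts`, `seed`, `ac_min`, `tradeoff_sd`, `conditions`,
#'   `windows` (data frame like [default_windows()]), `schedule` (like
#'   [default_schedule()]), `channel_sets` (like [channel_sets_default()]).
#' @return The validated, default-filled configuration (classed
#'   `run_config`).
#' @export
validate_run_config <- function(config = list()) {
  defaults <- list(
    reps = 100, test_fraction = 0.2, k_range = 1:6, restarts = 50,
    seed = 1L, ac_min = 0.70, tradeoff_sd = 2,
    conditions = c("all", "no", "neutral", "spatial", "congruent",
                   "incongruent")
  )
  for (f in names(defaults)) config[[f]] <- config[[f]] %||% defaults[[f]]
  if (is.null(config$channel_sets)) config$channel_sets <- channel_sets_default()
  if (is.null(config$windows)) {
    config$windows <- default_windows(
      unique(unlist(config$channel_sets$channels)))
  }
  if (is.null(config$schedule)) config$schedule <- default_schedule()

  problems <- character(0)
  if (config$reps < 1) problems <- c(problems, "`reps` must be >= 1.")
  if (config$test_fraction <= 0 || config$test_fraction >= 1) {
    problems <- c(problems, "`test_fraction` must lie in (0, 1).")
  }
  if (any(config$k_range < 1)) {
    problems <- c(problems, "`k_range` entries must be >= 1.")
  }
  if (config$ac_min <= 0 || config$ac_min > 1) {
    problems <- c(problems, "`ac_min` must lie in (0, 1].")
  }
  if (config$tradeoff_sd <= 0) {
    problems <- c(problems, "`tradeoff_sd` must be > 0.")
  }
  known_ch <- unique(config$windows$channel)
  for (i in seq_len(nrow(config$channel_sets))) {
    dangling <- setdiff(config$channel_sets$channels[[i]], known_ch)
    if (length(dangling)) {
      problems <- c(problems, paste0(
        "Channel set ", config$channel_sets$id[i],
        " references channel(s) absent from the window table: ",
        paste(dangling, collapse = ", ")))
    }
  }
  dangling_cond <- setdiff(config$schedule$condition, config$conditions)
  if (length(dangling_cond)) {
    problems <- c(problems, paste0(
      "Schedule references unknown condition(s): ",
      paste(dangling_cond, collapse = ", ")))
  }
  if (length(problems)) {
    abort(paste0("Invalid run configuration:\n- ",
                 paste(problems, collapse = "\n- ")))
  }
  structure(config, class = "run_config")
}

#' @rdname validate_run_config
#' @param path Path to a YAML configuration file.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (f in c("windows", "schedule")) {
    if (!is.null(cfg[[f]])) cfg[[f]] <- as_tibble(as.data.frame(cfg[[f]]))
  }
  if (!is.null(cfg$channel_sets)) {
    cs <- cfg$channel_sets
    cfg$channel_sets <- tibble(
      id = purrr::map_int(cs, ~ as.integer(.x$id)),
      label = purrr::map_chr(cs, ~ as.character(.x$label %||% .x$id)),
      channels = purrr::map(cs, ~ as.character(unlist(.x$channels))),
      include_behavior = purrr::map_lgl(cs, ~ isTRUE(.x$include_behavior)),
      include_wisc = purrr::map_lgl(cs, ~ isTRUE(.x$include_wisc))
    )
  }
  validate_run_config(cfg)
}
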