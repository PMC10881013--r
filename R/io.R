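#' Canonical column schemas for the pipeline's CSV files
#'
#' The pipeline defines its own tidy CSV schemas; supplementary files with
#' different native headers attach through a column mapping (see
#' [read_trials()]). Times are seconds from session start, temperatures degC,
#' concentrations unitless fractions.
#'
#' @return Named list of required canonical columns per file kind.
#' @export
canonical_schemas <- function() {
  list(
    trials = c("session_id", "dog", "odor", "condition", "trial_index",
               "presented_step", "presented_fraction", "outcome",
               "latency_s", "mean_inter_box_s", "t_start_s",
               "termination_reason", "session_duration_min"),
    temperature = c("session_id", "minute", "temp_c", "valid"),
    voc = c("odor", "condition", "replicate", "total_voc_ppm")
  )
}

# Rename native columns to canonical names. mapping: named character vector,
# names = canonical fields, values = native column names.
apply_mapping <- function(df, mapping, kind) {
  required <- canonical_schemas()[[kind]]
  if (is.null(mapping)) {
    missing <- setdiff(required, names(df))
    if (length(missing)) {
      stop(sprintf("missing required column(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    return(df)
  }
  if (anyDuplicated(names(mapping))) {
    stop("each canonical field must be mapped exactly once", call. = FALSE)
  }
  missing_map <- setdiff(required, union(names(mapping), names(df)))
  if (length(missing_map)) {
    stop(sprintf("unmapped required column(s): %s",
                 paste(missing_map, collapse = ", ")), call. = FALSE)
  }
  for (canon in names(mapping)) {
    native <- mapping[[canon]]
    if (!native %in% names(df)) {
      stop(sprintf("native column '%s' not found in file", native),
           call. = FALSE)
    }
    names(df)[names(df) == native] <- canon
  }
  df
}

#' Write session trial logs to the canonical CSV schema
#'
#' One row per trial, with the session header fields (labels, termination
#' reason, duration) repeated on every row so the file is self-contained.
#'
#' @param sessions List of `session_result` objects (or an `odor_simulation`,
#'   whose sessions are used).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(sessions, path) {
  if (inherits(sessions, "odor_simulation")) sessions <- sessions$sessions
  rows <- do.call(rbind, lapply(seq_along(sessions), function(i) {
    s <- sessions[[i]]
    id <- if (!is.null(names(sessions)) && nzchar(names(sessions)[i])) {
      names(sessions)[i]
    } else paste(s$dog, s$odor, s$condition, sep = "|")
    data.frame(
      session_id = id, dog = s$dog, odor = s$odor, condition = s$condition,
      s$trials,
      termination_reason = s$termination_reason,
      session_duration_min = s$session_duration_min,
      stringsAsFactors = FALSE
    )
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read trial logs into typed sessions
#'
#' Reads a trials CSV (canonical schema, or any schema attached via
#' `mapping`), validates row by row, groups rows into sessions, and replays
#' each session's outcome sequence through the staircase state machine to
#' recover its reversal record. Malformed rows are collected into a reject
#' report attached as `attr(, "rejects")` rather than aborting the read.
#'
#' @param path CSV path.
#' @param mapping Optional named character vector mapping canonical field
#'   names to the file's native column names.
#' @param ladder The [dilution_ladder()] the sessions ran on (used to replay
#'   reversals).
#' @return Named list of `session_result` objects, empty (with a warning)
#'   for an empty file.
#' @export
read_trials <- function(path, mapping = NULL, ladder = default_ladder()) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("cannot parse '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE))
  if (nrow(df) == 0L) {
    warning("empty trials file: ", path)
    out <- list()
    attr(out, "rejects") <- df
    return(out)
  }
  df <- apply_mapping(df, mapping, "trials")

  ok <- !is.na(df$session_id) & !is.na(df$trial_index) &
    df$outcome %in% c("correct", "incorrect", "no_search") &
    is.finite(df$presented_step) &
    df$presented_step >= 1 & df$presented_step <= n_steps(ladder)
  rejects <- df[!ok, , drop = FALSE]
  df <- df[ok, , drop = FALSE]

  sessions <- lapply(split(df, df$session_id), function(g) {
    g <- g[order(g$trial_index), , drop = FALSE]
    state <- staircase_state(ladder)
    for (o in g$outcome) state <- update_state(state, o, ladder)
    structure(list(
      dog = g$dog[1], odor = g$odor[1], condition = g$condition[1],
      trials = data.frame(
        trial_index = g$trial_index,
        presented_step = g$presented_step,
        presented_fraction = g$presented_fraction,
        outcome = g$outcome,
        latency_s = g$latency_s,
        mean_inter_box_s = g$mean_inter_box_s,
        t_start_s = g$t_start_s
      ),
      observed_reversals = state$reversals,
      reversal_directions = state$reversal_directions,
      termination_reason = g$termination_reason[1],
      session_duration_min = g$session_duration_min[1]
    ), class = "session_result")
  })
  attr(sessions, "rejects") <- rejects
  sessions
}

#' Write / read subcutaneous temperature logs
#'
#' @param temps An `odor_simulation`'s `temperatures$table`, or any data.frame
#'   in the canonical temperature schema.
#' @param path CSV path.
#' @return `path` invisibly (writer); named list of per-session series
#'   data.frames (`minute`, `temp_c`, `valid`) with a reject report attribute
#'   (reader).
#' @export
write_temperatures <- function(temps, path) {
  if (inherits(temps, "odor_simulation")) temps <- temps$temperatures$table
  utils::write.csv(temps, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_temperatures
#' @param mapping Optional canonical-to-native column mapping.
#' @export
read_temperatures <- function(path, mapping = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    warning("empty temperature file: ", path)
    out <- list(); attr(out, "rejects") <- df
    return(out)
  }
  df <- apply_mapping(df, mapping, "temperature")
  ok <- !is.na(df$session_id) & is.finite(df$minute) & !is.na(df$valid) &
    (is.finite(df$temp_c) | !as.logical(df$valid))
  rejects <- df[!ok, , drop = FALSE]
  df <- df[ok, , drop = FALSE]
  out <- lapply(split(df, df$session_id), function(g) {
    g <- g[order(g$minute), , drop = FALSE]
    data.frame(minute = g$minute, temp_c = g$temp_c,
               valid = as.logical(g$valid))
  })
  attr(out, "rejects") <- rejects
  out
}

#' Read an odor-availability (VOC) sample table
#'
#' Expects replicate-level total-VOC samples per odor x condition. Ten
#' replicates per cell are expected by the sampling design; deviations are
#' reported with a warning, not an error.
#'
#' @param path CSV path.
#' @param mapping Optional canonical-to-native column mapping.
#' @param expected_replicates Expected replicate count per cell.
#' @return data.frame in the canonical VOC schema.
#' @export
read_voc <- function(path, mapping = NULL, expected_replicates = 10L) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- apply_mapping(df, mapping, "voc")
  ok <- is.finite(df$total_voc_ppm) & df$total_voc_ppm >= 0
  if (any(!ok)) warning(sum(!ok), " malformed VOC row(s) dropped")
  df <- df[ok, , drop = FALSE]
  counts <- table(paste(df$odor, df$condition))
  off <- counts[counts != expected_replicates]
  if (length(off)) {
    warning("replicate count differs from ", expected_replicates,
            " in cell(s): ", paste(names(off), collapse = ", "))
  }
  df
}

#' Write a threshold record table as CSV
#'
#' @param records Threshold table from [threshold_table()] or a simulator.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_thresholds <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Load and validate a run configuration
#'
#' A YAML run configuration can override the dilution ladder, termination
#' rules per experiment, imputation fractions, generator effect parameters,
#' seeds and column mappings. Unknown keys are rejected so typos fail fast.
#'
#' @param path YAML file path; `NULL` returns the defaults.
#' @return A `run_config` list with `ladder`, `rules_exp1`, `rules_exp2`,
#'   `floor_fraction`, `fail_fraction`, `effects`, `seed`, `mappings`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  allowed <- c("ladder", "rules_exp1", "rules_exp2", "floor_fraction",
               "fail_fraction", "effects", "seed", "mappings")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  ladder <- if (!is.null(cfg$ladder)) {
    l <- as.data.frame(lapply(as.data.frame(
      do.call(rbind, cfg$ladder)), unlist))
    dilution_ladder(l$step_number, l$odor_flow, l$clean_flow,
                    l$nominal_fraction)
  } else default_ladder()
  mk_rules <- function(spec, default_rev) {
    do.call(termination_rules,
            utils::modifyList(list(reversals_required = default_rev),
                              if (is.null(spec)) list() else spec))
  }
  effects <- do.call(effect_spec,
                     if (is.null(cfg$effects)) list()
                     else lapply(cfg$effects, function(x) {
                       if (is.list(x) && !is.null(names(x[[1]]))) x
                       else if (is.list(x)) lapply(x, unlist) else unlist(x)
                     }))
  structure(list(
    ladder = ladder,
    rules_exp1 = mk_rules(cfg$rules_exp1, 7L),
    rules_exp2 = mk_rules(cfg$rules_exp2, 4L),
    floor_fraction = cfg$floor_fraction %||% 0.03,
    fail_fraction = cfg$fail_fraction %||% 0.80,
    effects = effects,
    seed = cfg$seed %||% 1L,
    mappings = cfg$mappings
  ), class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
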