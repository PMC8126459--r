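config_fields <- function() {
  c(names(formals(model_params)),
    "output_dir", "format", "sd_grid")
}

default_config <- function() {
  structure(list(params = model_params(),
                 output_dir = ".",
                 format = "csv",
                 sd_grid = c(0, 0.05, 0.1, 0.2, 0.5, 1)),
            class = "instevo_config")
}

#' Load a run configuration file
#'
#' Accepts either flat JSON (`.json`) or a flat TOML-style `key = value`
#' text file (any other extension): one key per line, `#` comments,
#' numbers, `true`/`false`, quoted strings and `[a, b, c]` arrays. Every
#' omitted key falls back to the baseline default (the [model_params()]
#' defaults plus `output_dir = "."`, `format = "csv"` and the default
#' sensitivity grid); every applied default is reported in a startup log
#' line on stderr. Unknown keys are an error naming the key.
#'
#' @param path Path to the configuration file.
#' @param quiet Suppress the defaults log line. Default `FALSE`.
#' @return An object of class `instevo_config`: list with `params` (an
#'   `instevo_params`), `output_dir`, `format` (`"csv"` or `"jsonl"`) and
#'   `sd_grid`.
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  values <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    parse_flat_kv(readLines(path, warn = FALSE))
  }
  as_config(values, quiet = quiet)
}

# minimal flat TOML-style parser: key = value lines
parse_flat_kv <- function(lines) {
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop(sprintf("cannot parse config line (expected key = value): %s", ln),
           call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    out[[key]] <- parse_kv_value(val)
  }
  out
}

parse_kv_value <- function(val) {
  if (grepl("^\\[.*\\]$", val)) {
    inner <- trimws(substr(val, 2, nchar(val) - 1))
    if (!nzchar(inner)) return(numeric(0))
    return(vapply(trimws(strsplit(inner, ",")[[1]]), parse_kv_value,
                  numeric(1), USE.NAMES = FALSE))
  }
  if (val %in% c("true", "TRUE", "True")) return(TRUE)
  if (val %in% c("false", "FALSE", "False")) return(FALSE)
  if (grepl("^\".*\"$|^'.*'$", val)) return(substr(val, 2, nchar(val) - 1))
  num <- suppressWarnings(as.numeric(val))
  if (!is.na(num)) return(num)
  val
}

as_config <- function(values, quiet = FALSE) {
  known <- config_fields()
  unknown <- setdiff(names(values), known)
  if (length(unknown) > 0) {
    stop(sprintf("unknown config key: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  param_names <- names(formals(model_params))
  pv <- values[intersect(names(values), param_names)]
  params <- do.call(model_params, pv)
  cfg <- structure(
    list(params = params,
         output_dir = if (!is.null(values$output_dir)) values$output_dir
                      else ".",
         format = if (!is.null(values$format))
           match.arg(values$format, c("csv", "jsonl")) else "csv",
         sd_grid = if (!is.null(values$sd_grid)) as.numeric(values$sd_grid)
                   else c(0, 0.05, 0.1, 0.2, 0.5, 1)),
    class = "instevo_config")
  if (!quiet) {
    defaulted <- setdiff(known, names(values))
    if (length(defaulted) > 0) {
      log_line("INFO", "config_defaults",
               keys = paste(defaulted, collapse = ","))
    }
  }
  cfg
}

#' Save a run configuration as JSON
#'
#' Writes a flat JSON document that [load_config()] reads back to an
#' identical configuration (lossless round trip).
#'
#' @param config An `instevo_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  flat <- c(unclass(config$params),
            list(output_dir = config$output_dir,
                 format = config$format,
                 sd_grid = config$sd_grid))
  # scalars unboxed, the grid kept as an array
  boxed <- lapply(names(flat), function(k) {
    if (k == "sd_grid") flat[[k]] else jsonlite::unbox(flat[[k]])
  })
  names(boxed) <- names(flat)
  writeLines(jsonlite::toJSON(boxed, pretty = TRUE, digits = NA), path)
  invisible(path)
}

#' @export
print.instevo_config <- function(x, ...) {
  cat(sprintf("Run configuration (output: %s, format %s, sweep grid: %s)\n",
              x$output_dir, x$format, paste(x$sd_grid, collapse = " ")))
  print(x$params)
  invisible(x)
}

trajectory_columns <- c("replicate", "generation", "cooperator_fraction",
                        "punishment_level", "proposal_value",
                        "proposal_accepted", "mean_payoff_cooperator",
                        "mean_payoff_free_rider")

fmt10 <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else formatC(v, digits = 10, format = "g")
  }, character(1))
  out
}

#' Write trajectory records to disk
#'
#' CSV dialect: the exact header
#' `replicate,generation,cooperator_fraction,punishment_level,proposal_value,proposal_accepted,mean_payoff_cooperator,mean_payoff_free_rider`,
#' rows sorted by (replicate, generation), floats at 10 significant digits
#' and missing values as empty fields. The JSON-lines dialect mirrors the
#' same keys, one object per row, with `null` for missing.
#'
#' @param records Trajectory data frame ([run_batch()]`$records`).
#' @param path Output file path.
#' @param format `"csv"` (default) or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(records, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  stopifnot(nrow(records) > 0,
            all(trajectory_columns %in% names(records)))
  records <- records[order(records$replicate, records$generation),
                     trajectory_columns]
  if (format == "csv") {
    cols <- list(
      as.character(records$replicate),
      as.character(records$generation),
      fmt10(records$cooperator_fraction),
      fmt10(records$punishment_level),
      fmt10(records$proposal_value),
      ifelse(is.na(records$proposal_accepted), "",
             ifelse(records$proposal_accepted, "TRUE", "FALSE")),
      fmt10(records$mean_payoff_cooperator),
      fmt10(records$mean_payoff_free_rider))
    lines <- c(paste(trajectory_columns, collapse = ","),
               do.call(paste, c(cols, sep = ",")))
    writeLines(lines, path)
  } else {
    con <- file(path, open = "wt")
    on.exit(close(con))
    for (i in seq_len(nrow(records))) {
      row <- lapply(records[i, ], jsonlite::unbox)
      writeLines(jsonlite::toJSON(row, na = "null", digits = NA), con)
    }
  }
  invisible(path)
}

#' Read trajectory records written by [write_trajectories()]
#'
#' @param path File path; the dialect is detected from the first byte
#'   (`{` means JSON-lines).
#' @return Trajectory data frame with the standard columns; empty/null
#'   fields become `NA`.
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("trajectory file not found: %s", path), call. = FALSE)
  }
  first <- substr(readLines(path, n = 1L, warn = FALSE), 1, 1)
  if (identical(first, "{")) {
    rows <- lapply(readLines(path, warn = FALSE), function(ln) {
      x <- jsonlite::fromJSON(ln)
      x[vapply(x, is.null, logical(1))] <- NA
      as.data.frame(x)
    })
    out <- do.call(rbind, rows)
  } else {
    out <- utils::read.csv(path, na.strings = "",
                           colClasses = c(replicate = "integer",
                                          generation = "integer",
                                          cooperator_fraction = "numeric",
                                          punishment_level = "numeric",
                                          proposal_value = "numeric",
                                          proposal_accepted = "logical",
                                          mean_payoff_cooperator = "numeric",
                                          mean_payoff_free_rider = "numeric"))
  }
  out <- out[, trajectory_columns]
  out$replicate <- as.integer(out$replicate)
  out$generation <- as.integer(out$generation)
  out$proposal_accepted <- as.logical(out$proposal_accepted)
  for (col in setdiff(trajectory_columns,
                      c("replicate", "generation", "proposal_accepted"))) {
    out[[col]] <- as.numeric(out[[col]])
  }
  out
}

#' Canned test configurations
#'
#' Small, fully specified configurations used by the test-suite and the
#' `fixtures` CLI subcommand: `"baseline"` (the full default run),
#' `"smoke"` (a seconds-scale miniature), `"no_voting"` (political game
#' disabled, fine fixed at 0) and `"oracle"` (voting disabled at N = 1000,
#' used to validate the simulator against the deterministic projection).
#'
#' @param name One of `"baseline"`, `"smoke"`, `"no_voting"`, `"oracle"`.
#' @return An `instevo_config`.
#' @export
fixture_config <- function(name = c("baseline", "smoke", "no_voting",
                                    "oracle")) {
  name <- match.arg(name)
  cfg <- default_config()
  cfg$params <- switch(name,
    baseline = model_params(),
    smoke = model_params(group_size = 60, n_generations = 40,
                         n_replicates = 3, master_seed = 1),
    no_voting = model_params(voting = FALSE, fixed_punishment = 0,
                             n_generations = 200, n_replicates = 10),
    oracle = model_params(group_size = 1000, voting = FALSE,
                          fixed_punishment = 0.6, n_generations = 100,
                          n_replicates = 50))
  cfg
}

#' Write all fixture configurations to a directory
#'
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  names <- eval(formals(fixture_config)$name)
  paths <- vapply(names, function(nm) {
    p <- file.path(dir, paste0(nm, ".json"))
    save_config(fixture_config(nm), p)
    p
  }, character(1))
  invisible(paths)
}
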