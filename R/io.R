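# Event-log readers/writers and run configuration.  The canonical trial and
# fixation logs are JSON Lines (one object per line, schema-versioned, as a
# controller would append after every trial); CSV mirrors are a lossy
# convenience export.  Reads are resume-safe: a truncated final line is
# ignored so a rerun can continue from the last complete record.

LOG_SCHEMA_VERSION <- 1L

#' Write a trial or fixation log as JSON Lines
#'
#' One JSON object per line with field names exactly as in the data frame;
#' appends when the file exists so a run can resume.
#'
#' @param records Data frame of trial or fixation records.
#' @param path Output path (conventionally `.jsonl`).
#' @param append Logical; append to an existing log.
#' @return `path`, invisibly.
#' @export
write_log <- function(records, path, append = FALSE) {
  stopifnot(is.data.frame(records))
  con <- file(path, open = if (append) "a" else "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    rec <- as.list(records[i, , drop = FALSE])
    rec$schema_version <- LOG_SCHEMA_VERSION
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null",
                                digits = NA), con)
  }
  invisible(path)
}

#' Read a JSON Lines log
#'
#' Validates that every complete line parses and that required fields are
#' present; an incomplete (truncated) final line is dropped with a warning,
#' matching the resume semantics of [write_log()].  Unknown fields are
#' preserved.
#'
#' @param path Log path.
#' @param required Character vector of fields each record must carry.
#' @return Data frame of records in file order (empty for an empty file).
#' @export
read_log <- function(path, required = character(0)) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) return(data.frame())
  parsed <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
    if (is.null(rec)) {
      if (i == length(lines)) {
        warning("dropping truncated final record (line ", i, ")")
        next
      }
      stop("malformed record at line ", i)
    }
    miss <- setdiff(required, names(rec))
    if (length(miss))
      stop("record at line ", i, " missing field(s): ",
           paste(miss, collapse = ", "))
    parsed[[i]] <- rec
  }
  parsed <- parsed[!vapply(parsed, is.null, logical(1))]
  if (length(parsed) == 0L) return(data.frame())
  cols <- unique(unlist(lapply(parsed, names)))
  out <- lapply(cols, function(cl) {
    vals <- lapply(parsed, function(r) if (is.null(r[[cl]])) NA else r[[cl]])
    unlist(vals, use.names = FALSE)
  })
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Export a log as CSV
#'
#' @param records Data frame.
#' @param path Output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_log_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the seed, configuration digests, timestamps and log paths that
#' fully determine a simulated run, so it can be reproduced end to end.
#'
#' @param run A `homecage_run` from [simulate_homecage()].
#' @param path Output `.yaml` path.
#' @param logs Named list of log file paths.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(run, path, logs = list()) {
  m <- list(schema_version = LOG_SCHEMA_VERSION,
            seed = run$milestones$seed,
            n_trials = run$milestones$n_trials,
            stage = run$task$stage,
            agent_params = unclass(run$params)[
              !vapply(run$params, is.list, logical(1))],
            wall_clock_anchor = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
            logs = logs,
            software_version = as.character(
              utils::packageVersion("homecage")))
  yaml::write_yaml(m, path)
  invisible(path)
}

#' Read a protocol/agent configuration file
#'
#' YAML (or JSON) with one named key per protocol constant; values override
#' the corresponding [agent_params()] defaults.
#'
#' @param path Configuration file path.
#' @return An [agent_params()] object.
#' @export
read_agent_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::fromJSON(path)
  else yaml::read_yaml(path)
  known <- names(formals(agent_params))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    warning("ignoring unknown configuration key(s): ",
            paste(unknown, collapse = ", "))
  do.call(agent_params, cfg[intersect(names(cfg), known)])
}
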