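# Parsers for the three profiling sources: shell level (Unix time), system
# level (gprof flat profile), and code level (stopwatch logs). All are pure
# text -> records; file reading is left to the caller / CLI.

#' Parse Unix `time` output
#'
#' Two dialects are supported: `posix_p` (`time -p`, e.g. `real 135.72`) and
#' `bash_builtin` (e.g. `real 2m15.720s`). Anything else is rejected. No
#' `real = user + sys` constraint is enforced: real time overshoots the sum
#' under competing load and undershoots it under multithreading.
#'
#' @param text Character vector of lines (or one string with newlines).
#' @param dialect `"posix_p"` or `"bash_builtin"`.
#' @return A list of class `time_result` with `real_seconds`,
#'   `user_seconds`, `sys_seconds`.
#' @export
#' @examples
#' parse_time_output(c("real 135.72", "user 130.10", "sys 2.02"))
parse_time_output <- function(text, dialect = c("posix_p", "bash_builtin")) {
  dialect <- match.arg(dialect)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  get <- function(key) {
    pat <- paste0("^\\s*", key, "\\s+(\\S+)\\s*$")
    hit <- grep(pat, lines, value = TRUE)
    if (length(hit) == 0) {
      stop("missing `", key, "` line in time output", call. = FALSE)
    }
    val <- sub(pat, "\\1", hit[1])
    if (dialect == "posix_p") {
      secs <- suppressWarnings(as.numeric(val))
      if (is.na(secs)) stop("cannot parse `", key, "` value: ", val,
                            call. = FALSE)
    } else {
      m <- regmatches(val, regexec("^([0-9]+)m([0-9.]+)s$", val))[[1]]
      if (length(m) != 3) {
        stop("cannot parse `", key, "` value as bash time: ", val,
             call. = FALSE)
      }
      secs <- as.numeric(m[2]) * 60 + as.numeric(m[3])
    }
    if (secs < 0) stop("`", key, "` time is negative", call. = FALSE)
    secs
  }
  structure(
    list(real_seconds = get("real"), user_seconds = get("user"),
         sys_seconds = get("sys")),
    class = "time_result"
  )
}

#' Parse a gprof flat profile
#'
#' Extracts the per-function rows of the flat-profile section: percent of
#' total time, cumulative seconds, self seconds, call count (absent for some
#' rows, which gprof leaves blank), and function name. Rows keep their
#' source order (gprof sorts by self time).
#'
#' @param text Character vector of lines (or one string with newlines).
#' @return Data frame with columns `percent_time`, `cumulative_seconds`,
#'   `self_seconds`, `calls` (NA when absent), `function_name`.
#' @export
parse_gprof_flat <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  start <- grep("^\\s*%\\s+cumulative\\s+self", lines)
  if (length(start) == 0) {
    stop("no gprof flat-profile section found", call. = FALSE)
  }
  body <- lines[(start[1] + 1):length(lines)]
  # second header line ("time seconds seconds calls ...") and blanks skipped;
  # the section ends at the first line that does not parse as a data row
  body <- body[!grepl("^\\s*time\\s+seconds", body)]
  pat <- paste0("^\\s*([0-9.]+)\\s+([0-9.]+)\\s+([0-9.]+)",
                "(?:\\s+([0-9]+)\\s+[0-9.]+\\s+[0-9.]+)?\\s+(\\S.*?)\\s*$")
  rows <- list()
  for (ln in body) {
    if (!nzchar(trimws(ln))) next
    m <- regmatches(ln, regexec(pat, ln, perl = TRUE))[[1]]
    if (length(m) == 0) {
      if (length(rows) > 0) break else next
    }
    rows[[length(rows) + 1]] <- data.frame(
      percent_time = as.numeric(m[2]),
      cumulative_seconds = as.numeric(m[3]),
      self_seconds = as.numeric(m[4]),
      calls = if (nzchar(m[5])) as.numeric(m[5]) else NA_real_,
      function_name = m[6]
    )
  }
  if (length(rows) == 0) {
    stop("gprof flat-profile section contains no data rows", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  if (any(out$percent_time < 0 | out$percent_time > 100)) {
    stop("gprof percent time outside [0, 100]", call. = FALSE)
  }
  out
}

#' Parse a stopwatch (code-level profiling) log
#'
#' The built-in BLAST profiling module writes one text file per process with
#' one stopwatch reading per line. The line format is configurable as a
#' regular expression with exactly two capture groups (label, seconds); the
#' default expects `<label><TAB><seconds>`. Duplicate labels are preserved
#' in order.
#'
#' @param text Character vector of lines (or one string with newlines).
#' @param pattern Regex with two capture groups.
#' @return Data frame with columns `label`, `seconds` (zero rows, with a
#'   warning, if nothing matches).
#' @export
parse_blastprof_log <- function(text,
                                pattern = "^(.+)\t([0-9.eE+-]+)\\s*$") {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  hits <- regmatches(lines, regexec(pattern, lines))
  ok <- lengths(hits) == 3
  if (!any(ok)) {
    if (length(lines) > 0 && any(nzchar(lines))) {
      warning("no stopwatch lines matched the pattern", call. = FALSE)
    }
    return(data.frame(label = character(0), seconds = numeric(0)))
  }
  out <- data.frame(
    label = vapply(hits[ok], `[`, character(1), 2),
    seconds = as.numeric(vapply(hits[ok], `[`, character(1), 3))
  )
  if (anyNA(out$seconds) || any(out$seconds < 0)) {
    stop("stopwatch seconds must be non-negative numbers", call. = FALSE)
  }
  out
}
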