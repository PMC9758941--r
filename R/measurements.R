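# Measurement tables: the tabular interchange format between profiling
# parsers, the surface fitter, and the synthetic generator. TSV with the
# fixed header: node_type, database_size, query_size, threads, component,
# runtime_seconds, replicate.

MEASUREMENT_COLUMNS <- c("node_type", "database_size", "query_size",
                         "threads", "component", "runtime_seconds",
                         "replicate")

validate_measurements <- function(df, allow_negative_runtime = FALSE) {
  missing <- setdiff(MEASUREMENT_COLUMNS, names(df))
  if (length(missing) > 0) {
    stop("measurement table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[MEASUREMENT_COLUMNS]
  for (col in c("database_size", "query_size", "threads",
                "runtime_seconds", "replicate")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      stop("non-numeric `", col, "` at row ",
           which(is.na(v))[1], call. = FALSE)
    }
    df[[col]] <- v
  }
  checks <- list(
    c("database_size", "database_size >= 1"),
    c("query_size", "query_size >= 1"),
    c("threads", "threads >= 1"),
    c("runtime_seconds", "runtime_seconds >= 0")
  )
  for (ch in checks) {
    if (ch[1] == "runtime_seconds" && allow_negative_runtime) next
    bound <- if (ch[1] == "runtime_seconds") 0 else 1
    bad <- which(df[[ch[1]]] < bound)
    if (length(bad) > 0) {
      stop("invalid value (", ch[2], " violated) at row ", bad[1],
           call. = FALSE)
    }
  }
  bad <- which(!df$component %in% MEASUREMENT_COMPONENTS)
  if (length(bad) > 0) {
    stop("unknown component `", df$component[bad[1]], "` at row ", bad[1],
         call. = FALSE)
  }
  keys <- df[c("node_type", "database_size", "query_size", "threads",
               "component", "replicate")]
  dup <- which(duplicated(keys))
  if (length(dup) > 0) {
    stop("duplicate measurement key at row ", dup[1], call. = FALSE)
  }
  df
}

#' Read / write measurement tables (TSV)
#'
#' The schema is fixed: columns `node_type`, `database_size`, `query_size`,
#' `threads`, `component`, `runtime_seconds`, `replicate`, tab-separated
#' with a header. Reading validates types, the component vocabulary
#' ([measurement_components()]), non-negative runtimes, and key uniqueness,
#' reporting the offending row on failure; write-then-read is lossless.
#'
#' @param path File path.
#' @param records Data frame in the measurement schema.
#' @return `read_measurements()`: validated data frame;
#'   `write_measurements()`: `path`, invisibly.
#' @export
read_measurements <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  validate_measurements(df)
}

#' @rdname read_measurements
#' @export
write_measurements <- function(records, path) {
  records <- validate_measurements(as.data.frame(records))
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Known profiled function names -> component labels
GPROF_FUNCTION_MAP <- c(
  "PrintOneResultSet" = "func_a",
  "CLocalBlast::CLocalBlast" = "func_b",
  "CLocalBlast::Run" = "func_c",
  "GetNextSeqBatch" = "func_d",
  "PreFetchSequenceData" = "func_e"
)

STOPWATCH_LABEL_MAP <- c(
  "RunMTBySplitDB" = "overall",
  "stage1_preloop" = "stage1_preloop",
  "stage2_prepare" = "stage2_prepare",
  "stage3_blast" = "stage3_blast",
  "stage4_format" = "stage4_format",
  "stage5_postloop" = "stage5_postloop"
)

#' Convert parsed profiler outputs to measurement records
#'
#' Assembles records in the measurement schema from any combination of the
#' three profiling sources for one (database, query, node type, threads)
#' run: the `time` result yields `time_real`/`time_user`/`time_sys` rows
#' (plus `overall` = real time), stopwatch entries yield stage rows via
#' their labels, and gprof entries yield `func_a`..`func_e` rows with
#' seconds taken from `percent_time` of the overall runtime (gprof self
#' seconds are distorted by instrumentation overhead, so the share, not the
#' absolute, is trusted). Unrecognized function names and labels are
#' skipped.
#'
#' @param node_type,database_size,query_size,threads,replicate Key fields
#'   stamped on every produced row.
#' @param time_result Optional [parse_time_output()] result.
#' @param stopwatch Optional [parse_blastprof_log()] data frame.
#' @param gprof Optional [parse_gprof_flat()] data frame.
#' @param overall_seconds Total runtime used to scale gprof percentages;
#'   defaults to the `time` real seconds.
#' @return Data frame in the measurement schema.
#' @export
profile_to_measurements <- function(node_type, database_size, query_size,
                                    threads = 1, replicate = 1,
                                    time_result = NULL, stopwatch = NULL,
                                    gprof = NULL, overall_seconds = NULL) {
  row <- function(component, seconds) {
    data.frame(node_type = node_type, database_size = database_size,
               query_size = query_size, threads = threads,
               component = component, runtime_seconds = seconds,
               replicate = replicate)
  }
  out <- list()
  if (!is.null(time_result)) {
    stopifnot(inherits(time_result, "time_result"))
    out[[length(out) + 1]] <- row("time_real", time_result$real_seconds)
    out[[length(out) + 1]] <- row("time_user", time_result$user_seconds)
    out[[length(out) + 1]] <- row("time_sys", time_result$sys_seconds)
    out[[length(out) + 1]] <- row("overall", time_result$real_seconds)
    if (is.null(overall_seconds)) overall_seconds <- time_result$real_seconds
  }
  if (!is.null(stopwatch) && nrow(stopwatch) > 0) {
    known <- stopwatch$label %in% names(STOPWATCH_LABEL_MAP)
    for (k in which(known)) {
      comp <- STOPWATCH_LABEL_MAP[[stopwatch$label[k]]]
      if (comp == "overall" && !is.null(time_result)) next  # already present
      out[[length(out) + 1]] <- row(comp, stopwatch$seconds[k])
    }
  }
  if (!is.null(gprof) && nrow(gprof) > 0) {
    if (is.null(overall_seconds)) {
      stop("gprof rows need `overall_seconds` (or a time_result) to scale ",
           "percentages", call. = FALSE)
    }
    known <- gprof$function_name %in% names(GPROF_FUNCTION_MAP)
    for (k in which(known)) {
      comp <- GPROF_FUNCTION_MAP[[gprof$function_name[k]]]
      out[[length(out) + 1]] <- row(comp,
                                    gprof$percent_time[k] / 100 *
                                      overall_seconds)
    }
  }
  if (length(out) == 0) {
    stop("no profiler inputs supplied", call. = FALSE)
  }
  validate_measurements(do.call(rbind, out))
}
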