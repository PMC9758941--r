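#' Build a job manifest from a partition plan
#'
#' Turns a plan plus the materialized FASTA fragments into one command line
#' per sub-job: the Cartesian product of the `m_k` database fragments and
#' `n_k` query fragments of each node type. Every command carries
#' `-dbseqnum` set to the sequence count of the ORIGINAL, pre-split
#' database. This is the segmentation correction: E-values depend on the
#' effective database size, so sub-jobs searching a fragment must still be
#' told the full count.
#'
#' @param plan A `partition_plan` (from [solve_heterogeneous()] or
#'   [as_partition_plan()]).
#' @param db_fragments Database fragment paths: a character vector for a
#'   single-entry plan, or a named list keyed by node type (lengths must
#'   equal the plan's `m_k`).
#' @param query_fragments Query fragment paths, same shape, lengths `n_k`.
#'   Across node types the query fragments must be disjoint files (each type
#'   searches its own query quota).
#' @param dbseqnum Effective database sequence count injected into every
#'   command; defaults to the plan's database total and must never be a
#'   fragment count.
#' @param threads Threads per sub-job (`-num_threads`).
#' @param command_template Template with placeholders `{db}`, `{query}`,
#'   `{dbseqnum}`, `{threads}`, `{out}`.
#' @return An object of class `job_manifest`: list with `entries` (data
#'   frame: `task_id`, `node_type`, `database_fragment_path`,
#'   `query_fragment_path`, `command_line`), `dbseqnum`, `threads`.
#' @seealso [write_manifest()]
#' @export
make_manifest <- function(plan, db_fragments, query_fragments,
                          dbseqnum = plan$database_total, threads = 1L,
                          command_template = paste(
                            "blastn -db {db} -query {query}",
                            "-dbseqnum {dbseqnum} -num_threads {threads}",
                            "-out {out}")) {
  stopifnot(inherits(plan, "partition_plan"))
  stopifnot(is.numeric(dbseqnum), length(dbseqnum) == 1, dbseqnum >= 1)
  entries <- plan$entries
  db_fragments <- normalize_fragment_arg(db_fragments, entries$node_type,
                                         "db_fragments")
  query_fragments <- normalize_fragment_arg(query_fragments,
                                            entries$node_type,
                                            "query_fragments")
  rows <- lapply(seq_len(nrow(entries)), function(k) {
    e <- entries[k, ]
    dbf <- db_fragments[[e$node_type]]
    qf <- query_fragments[[e$node_type]]
    if (length(dbf) != e$m) {
      stop(sprintf("node type %s: %d database fragments supplied, plan needs m=%d",
                   e$node_type, length(dbf), e$m), call. = FALSE)
    }
    if (length(qf) != e$n) {
      stop(sprintf("node type %s: %d query fragments supplied, plan needs n=%d",
                   e$node_type, length(qf), e$n), call. = FALSE)
    }
    grid <- expand.grid(i = seq_len(e$m), j = seq_len(e$n))
    data.frame(
      node_type = e$node_type, i = grid$i, j = grid$j,
      database_fragment_path = dbf[grid$i],
      query_fragment_path = qf[grid$j]
    )
  })
  entries_df <- do.call(rbind, rows)
  entries_df$task_id <- seq_len(nrow(entries_df))
  entries_df$command_line <- vapply(seq_len(nrow(entries_df)), function(k) {
    fill_template(command_template, list(
      db = entries_df$database_fragment_path[k],
      query = entries_df$query_fragment_path[k],
      dbseqnum = format(dbseqnum, scientific = FALSE),
      threads = as.integer(threads),
      out = sprintf("subjob_%05d.out", entries_df$task_id[k])
    ))
  }, character(1))
  cols <- c("task_id", "node_type", "i", "j", "database_fragment_path",
            "query_fragment_path", "command_line")
  structure(
    list(entries = entries_df[cols], dbseqnum = dbseqnum,
         threads = as.integer(threads)),
    class = "job_manifest"
  )
}

normalize_fragment_arg <- function(x, node_types, what) {
  if (is.character(x)) {
    if (length(node_types) != 1) {
      stop("`", what, "` must be a named list keyed by node type for ",
           "multi-type plans", call. = FALSE)
    }
    x <- setNames(list(x), node_types)
  }
  missing <- setdiff(node_types, names(x))
  if (length(missing) > 0) {
    stop("`", what, "` missing node type(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x
}

fill_template <- function(template, values) {
  for (nm in names(values)) {
    template <- gsub(paste0("{", nm, "}"), values[[nm]], template,
                     fixed = TRUE)
  }
  template
}

#' @export
print.job_manifest <- function(x, ...) {
  cat(sprintf("<job_manifest> %d sub-job(s), dbseqnum=%s, %d thread(s)\n",
              nrow(x$entries), format(x$dbseqnum, scientific = FALSE),
              x$threads))
  utils::head(x$entries[c("task_id", "node_type", "command_line")], 5) |>
    print(row.names = FALSE)
  if (nrow(x$entries) > 5) cat("  ...\n")
  invisible(x)
}

#' Write a job manifest to disk
#'
#' Three formats: `sh` (one command per line under `#!/bin/sh`), `sge` (a
#' Grid Engine array-job script dispatching on `SGE_TASK_ID`), and `json`
#' (the full entry table plus metadata).
#'
#' @param manifest A [job_manifest][make_manifest()].
#' @param path Output file.
#' @param format `"sh"`, `"sge"`, or `"json"`.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path, format = c("sh", "sge", "json")) {
  stopifnot(inherits(manifest, "job_manifest"))
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      list(dbseqnum = manifest$dbseqnum, threads = manifest$threads,
           entries = manifest$entries),
      path, auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
    return(invisible(path))
  }
  lines <- if (format == "sh") {
    c("#!/bin/sh", "set -e", manifest$entries$command_line)
  } else {
    n <- nrow(manifest$entries)
    c("#!/bin/sh",
      "#$ -S /bin/sh",
      sprintf("#$ -t 1-%d", n),
      "case \"$SGE_TASK_ID\" in",
      sprintf("  %d) %s ;;", manifest$entries$task_id,
              manifest$entries$command_line),
      "esac")
  }
  writeLines(lines, path)
  invisible(path)
}
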