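# Streaming FASTA record I/O. Files are processed as line chunks through a
# fixed-size buffer so memory use is independent of file size, and sequence
# lines are passed through verbatim (no re-wrapping), which makes
# split-then-concatenate byte-faithful for POSIX text files.

FASTA_CHUNK_LINES <- 65536L

#' Count sequence records in a FASTA file
#'
#' Streams the file and counts header lines (`>`), using constant memory.
#' Sequence lengths are deliberately not inspected: partitioning operates on
#' sequence counts only, the one piece of a priori knowledge assumed about
#' the inputs.
#'
#' @param fasta_path Path to a FASTA file.
#' @return Number of records (0 for an empty file).
#' @export
count_sequences <- function(fasta_path) {
  con <- file(fasta_path, open = "rt")
  on.exit(close(con))
  n <- 0L
  line_no <- 0L
  seen_header <- FALSE
  repeat {
    lines <- readLines(con, n = FASTA_CHUNK_LINES)
    if (length(lines) == 0) break
    is_header <- startsWith(lines, ">")
    if (!seen_header) {
      first_hdr <- which(is_header)[1]
      bad <- which(nzchar(trimws(lines)) & !is_header)
      bad <- bad[is.na(first_hdr) | bad < first_hdr]
      if (length(bad) > 0) {
        stop(sprintf("malformed FASTA: content before first header at line %d",
                     line_no + bad[1]), call. = FALSE)
      }
      seen_header <- !is.na(first_hdr)
    }
    n <- n + sum(is_header)
    line_no <- line_no + length(lines)
  }
  n
}

#' Split a FASTA file into record-count fragments
#'
#' Streams the input once to count records and once to write fragments whose
#' record counts follow [fragment_sizes()] exactly (maximal-uniform ceiling
#' fragments, remainder in the last non-empty fragment). Record order and
#' line content are preserved verbatim, so concatenating the fragments
#' reproduces the source record stream. When `parts` exceeds the record
#' count, the surplus fragments are written as empty files with a warning so
#' that downstream manifest arithmetic stays aligned with the plan.
#'
#' @param fasta_path Input FASTA file.
#' @param parts Number of fragments (>= 1).
#' @param out_dir Output directory (created if needed).
#' @param name_template `sprintf` template receiving the input basename
#'   (without extension) and the fragment index.
#' @return Character vector of the `parts` fragment paths, in order.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' gen_fasta(10, seed = 1, out_path = f)
#' frags <- split_fasta(f, 3, tempdir())
#' sapply(frags, count_sequences)  # 4 4 2
split_fasta <- function(fasta_path, parts, out_dir,
                        name_template = "%s_part%04d.fasta") {
  stopifnot(parts >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  total <- count_sequences(fasta_path)
  stem <- sub("\\.[^.]*$", "", basename(fasta_path))
  paths <- file.path(out_dir, sprintf(name_template, stem, seq_len(parts)))
  if (total == 0) {
    warning("input has no records; writing ", parts, " empty fragment(s)",
            call. = FALSE)
    for (p in paths) file.create(p)
    return(paths)
  }
  sizes <- fragment_sizes(total, parts)
  if (any(sizes == 0)) {
    warning(sum(sizes == 0), " fragment(s) are empty (parts > records)",
            call. = FALSE)
  }
  bounds <- cumsum(sizes)
  con <- file(fasta_path, open = "rt")
  out <- NULL
  on.exit({
    close(con)
    if (!is.null(out)) close(out)
  }, add = TRUE)
  cur <- 0L          # fragment currently open (0 = none)
  rec <- 0L
  repeat {
    lines <- readLines(con, n = FASTA_CHUNK_LINES)
    if (length(lines) == 0) break
    recs <- rec + cumsum(startsWith(lines, ">"))
    frag <- findInterval(recs - 0.5, c(0, bounds))
    rec <- recs[length(recs)]
    for (f in unique(frag)) {
      if (f != cur) {
        # fragments are visited in increasing order, each opened exactly once
        if (!is.null(out)) close(out)
        out <- file(paths[f], open = "wt")
        cur <- f
      }
      writeLines(lines[frag == f], out)
    }
  }
  if (!is.null(out)) close(out)
  out <- NULL
  # materialize fragments that received nothing (zero-size tail)
  for (p in paths[!file.exists(paths)]) file.create(p)
  paths
}
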