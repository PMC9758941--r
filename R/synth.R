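# Synthetic benchmark generators: measurement grids from known surfaces,
# FASTA files, and profiler-output fixtures. Every generator is a pure
# function of (spec, seed), so the whole package builds and tests offline.

#' Default profiling grid sizes
#'
#' The database and query sequence-count grids the profiling campaign uses:
#' six database truncations spanning 8k-260k sequences and fifteen query
#' truncations spanning 18k-1.1M sequences.
#'
#' @return Numeric vector of sequence counts.
#' @export
default_database_sizes <- function() {
  c(8179, 16358, 32716, 65432, 130862, 261725)
}

#' @rdname default_database_sizes
#' @export
default_query_sizes <- function() {
  c(17848, 35695, 53555, 71389, 89258, 107188, 124961, 142778,
    285555, 393022, 480935, 571110, 696210, 821372, 1142220)
}

#' Generate a synthetic measurement grid from a known surface or model
#'
#' Evaluates the surface (or [performance model][quadratic_model()]) on the
#' full Cartesian grid and perturbs each value with multiplicative Gaussian
#' noise, `runtime = T(D, Q) * (1 + N(0, sigma))`. Deterministic under
#' `seed`. The resulting table feeds [fit_surface()] for generate-then-fit
#' parameter-recovery tests.
#'
#' Raw surface values pass through unchanged by default — a fitted log-axis
#' surface can be negative near the domain edge, and round-trip recovery of
#' its coefficients requires the generator not to censor those values. Set
#' `clamp_at_zero = TRUE` to emulate a physical timer, at the cost of
#' biasing fits near zero; note [write_measurements()] always enforces
#' non-negative runtimes on disk.
#'
#' @param x A [quadratic_surface()] or `performance_model`.
#' @param database_sizes,query_sizes Sequence-count grids; default to the
#'   standard profiling grids.
#' @param noise_sigma_fraction Relative noise sd (0 = exact values).
#' @param replicates Replicate observations per grid point.
#' @param seed Integer seed.
#' @param node_type,component,threads Stamped onto every record.
#' @param clamp_at_zero If `TRUE`, negative values are censored to 0.
#' @return Data frame in the measurement schema (see
#'   [read_measurements()]).
#' @export
gen_measurements <- function(x,
                             database_sizes = default_database_sizes(),
                             query_sizes = default_query_sizes(),
                             noise_sigma_fraction = 0,
                             replicates = 1,
                             seed = 1L,
                             node_type = "synthetic",
                             component = "overall",
                             threads = 1,
                             clamp_at_zero = FALSE) {
  stopifnot(all(database_sizes >= 1), all(query_sizes >= 1),
            noise_sigma_fraction >= 0, replicates >= 1)
  grid <- expand.grid(database_size = database_sizes,
                      query_size = query_sizes)
  truth <- if (inherits(x, "quadratic_surface")) {
    evaluate_surface(x, grid$database_size, grid$query_size)
  } else if (inherits(x, "performance_model")) {
    predict_runtime(x, grid$database_size, grid$query_size,
                    threads = threads)
  } else {
    stop("`x` must be a quadratic_surface or performance_model",
         call. = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(replicates), function(r) {
    data.frame(node_type = node_type, database_size = grid$database_size,
               query_size = grid$query_size, threads = threads,
               component = component, runtime_seconds = truth,
               replicate = r)
  }))
  if (noise_sigma_fraction > 0) {
    rng <- local_seed(seed)
    on.exit(rng())
    eps <- rnorm(nrow(out), mean = 0, sd = noise_sigma_fraction)
    out$runtime_seconds <- out$runtime_seconds * (1 + eps)
  }
  if (clamp_at_zero) out$runtime_seconds <- pmax(out$runtime_seconds, 0)
  validate_measurements(out, allow_negative_runtime = !clamp_at_zero)
}

# Run code under a fixed seed without clobbering the caller's RNG state.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Generate a synthetic FASTA file
#'
#' Writes `num_records` records with ordinal headers (`>seq_1` ...),
#' uniform-random sequence lengths within `length_range`, and
#' uniform-random residues over `alphabet`. Content realism is irrelevant
#' here — the package never aligns sequences — so short-read-like defaults
#' (90-150 bp nucleotides) are used. Byte-identical output under the same
#' seed.
#'
#' @param num_records Number of records (0 gives an empty file).
#' @param length_range Length-2 integer range of residues per record.
#' @param alphabet Characters to draw residues from.
#' @param seed Integer seed.
#' @param out_path Output file path.
#' @param line_width Residues per sequence line.
#' @return `out_path`, invisibly.
#' @export
gen_fasta <- function(num_records, length_range = c(90, 150),
                      alphabet = c("A", "C", "G", "T"), seed = 1L,
                      out_path, line_width = 70L) {
  stopifnot(num_records >= 0, length(length_range) == 2,
            length_range[1] >= 1, length_range[1] <= length_range[2],
            line_width >= 1)
  if (num_records == 0) {
    file.create(out_path)
    return(invisible(out_path))
  }
  rng <- local_seed(seed)
  on.exit(rng())
  con <- file(out_path, open = "wt")
  on.exit(close(con), add = TRUE)
  for (i in seq_len(num_records)) {
    len <- sample(length_range[1]:length_range[2], 1)
    seq <- paste(sample(alphabet, len, replace = TRUE), collapse = "")
    lines <- substring(seq, seq(1, len, by = line_width),
                       pmin(seq(1, len, by = line_width) + line_width - 1,
                            len))
    writeLines(c(sprintf(">seq_%d length=%d", i, len), lines), con)
  }
  invisible(out_path)
}

#' Generate mutually consistent profiler-output fixtures
#'
#' Builds the three profiling texts for one synthetic run: Unix `time`
#' output (POSIX `-p` dialect), a stopwatch log with the overall driver
#' time and its five stage times, and a gprof flat profile with the five
#' core functions. The three texts are consistent by construction: stage
#' seconds are `stage_fractions * total`, function percentages are
#' `function_fractions * 100`, and parsing them back recovers the spec.
#'
#' @param total_seconds Overall wall-clock runtime.
#' @param stage_fractions Five fractions (pre-loop, prepare, blast, format,
#'   post-loop) of `total_seconds`; must sum to <= 1.
#' @param function_fractions Five fractions for functions a-e; must sum to
#'   <= 1.
#' @param query_size Call count for function a (it is called once per query
#'   sequence); the other functions are called `batch_calls` times.
#' @param batch_calls Call count for functions b-e.
#' @param user_seconds,sys_seconds Optional `time` components; default to
#'   96% / 1.5% of total.
#' @return List of class `profiler_fixtures` with character-vector elements
#'   `time_text`, `stopwatch_text`, `gprof_text`, plus the input spec.
#' @export
gen_profiler_fixtures <- function(total_seconds = 135.72,
                                  stage_fractions = c(0.0002, 0.1091,
                                                      0.3804, 0.4813,
                                                      0.0001),
                                  function_fractions = c(0.3066, 0.2928,
                                                         0.1700, 0.0972,
                                                         0.0546),
                                  query_size = 53555,
                                  batch_calls = 4,
                                  user_seconds = NULL,
                                  sys_seconds = NULL) {
  stopifnot(total_seconds >= 0, length(stage_fractions) == 5,
            length(function_fractions) == 5,
            all(stage_fractions >= 0), all(function_fractions >= 0))
  if (sum(stage_fractions) > 1 + 1e-9) {
    stop("stage_fractions sum to more than 1", call. = FALSE)
  }
  if (sum(function_fractions) > 1 + 1e-9) {
    stop("function_fractions sum to more than 1", call. = FALSE)
  }
  user_seconds <- user_seconds %||% (0.96 * total_seconds)
  sys_seconds <- sys_seconds %||% (0.015 * total_seconds)

  time_text <- c(sprintf("real %.2f", total_seconds),
                 sprintf("user %.2f", user_seconds),
                 sprintf("sys %.2f", sys_seconds))

  stage_labels <- c("stage1_preloop", "stage2_prepare", "stage3_blast",
                    "stage4_format", "stage5_postloop")
  stopwatch_text <- c(
    sprintf("RunMTBySplitDB\t%.4f", total_seconds),
    sprintf("%s\t%.4f", stage_labels, stage_fractions * total_seconds)
  )

  fn_names <- names(GPROF_FUNCTION_MAP)
  self <- function_fractions * total_seconds
  ord <- order(self, decreasing = TRUE)
  gprof_text <- c(
    "Flat profile:",
    "",
    "Each sample counts as 0.01 seconds.",
    "  %   cumulative   self              self     total",
    " time   seconds   seconds    calls   s/call   s/call  name",
    sprintf(" %5.2f %9.2f %8.2f %8d %8.4f %8.4f  %s",
            function_fractions[ord] * 100, cumsum(self[ord]), self[ord],
            c(query_size, rep(batch_calls, 4))[ord],
            self[ord] / c(query_size, rep(batch_calls, 4))[ord],
            self[ord] / c(query_size, rep(batch_calls, 4))[ord],
            fn_names[ord])
  )
  structure(
    list(time_text = time_text, stopwatch_text = stopwatch_text,
         gprof_text = gprof_text, total_seconds = total_seconds,
         stage_fractions = stage_fractions,
         function_fractions = function_fractions),
    class = "profiler_fixtures"
  )
}
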