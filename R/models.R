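#' Performance models for one node type
#'
#' A performance model predicts the runtime `T_k(D, Q)` of one sub-job of
#' (database, query) size on a node of type `k`. Three kinds are supported:
#'
#' * `quadratic_sum` — the sum of per-component [quadratic
#'   surfaces][quadratic_surface()] (typically the five core functions, or a
#'   single `overall` surface); each component's prediction is clamped at a
#'   small positive floor before summing, so fitted surfaces that dip
#'   negative at the domain edges cannot produce negative runtimes.
#' * `cpm` — constant performance model: node speed is a constant `s`
#'   (sequences/second) and runtime is `D / s`. Query size is ignored.
#' * `fpm` — functional performance model: speed varies with problem size via
#'   a piecewise-constant table, runtime is `D / s(D)`.
#'
#' A thread speed-up table (a named vector mapping thread count to a divisor,
#' e.g. `c("2" = 1.25)`) may be attached to any kind; predictions at
#' `threads > 1` are divided by the matching factor. Threads are not modeled
#' inside the surfaces: empirically multithreading rescales the runtime
#' surface without changing its shape.
#'
#' @param components Named list of [quadratic_surface()] objects, keyed by
#'   component label (see [measurement_components()]).
#' @param node_type Identifier of the node type the model describes.
#' @param clamp_floor Positive seconds; floor for per-surface predictions.
#' @param thread_speedup Optional named numeric vector of speed-up divisors
#'   keyed by thread count.
#' @return An object of class `performance_model`.
#' @seealso [predict_runtime()], [scale_model()], [reference_model()]
#' @export
#' @examples
#' m <- cpm_model(speed = 1000, node_type = "V")
#' predict_runtime(m, database_size = 523449, query_size = 1)
quadratic_model <- function(components, node_type = "unknown",
                            clamp_floor = 0.001, thread_speedup = NULL) {
  if (!is.list(components) || length(components) == 0 ||
      is.null(names(components)) || any(!nzchar(names(components)))) {
    stop("`components` must be a non-empty named list of surfaces",
         call. = FALSE)
  }
  ok <- vapply(components, inherits, logical(1), "quadratic_surface")
  if (!all(ok)) stop("all components must be quadratic_surface objects",
                     call. = FALSE)
  new_performance_model(
    kind = "quadratic_sum", node_type = node_type, components = components,
    clamp_floor = clamp_floor, thread_speedup = thread_speedup
  )
}

#' @rdname quadratic_model
#' @param speed Constant node speed in sequences per second (`cpm`).
#' @export
cpm_model <- function(speed, node_type = "unknown", thread_speedup = NULL) {
  stopifnot(is.numeric(speed), length(speed) == 1, speed > 0)
  new_performance_model(
    kind = "cpm", node_type = node_type, speed_constant = speed,
    thread_speedup = thread_speedup
  )
}

#' @rdname quadratic_model
#' @param speed_table Data frame with columns `size` (problem size upper
#'   knots, sequences) and `speed` (sequences/second); the speed for a
#'   problem of size `D` is the value at the nearest knot interval
#'   (piecewise-constant). Sizes outside `[min(size), max(size)]` are an
#'   error (`fpm`).
#' @export
fpm_model <- function(speed_table, node_type = "unknown",
                      thread_speedup = NULL) {
  if (!is.data.frame(speed_table) ||
      !all(c("size", "speed") %in% names(speed_table)) ||
      nrow(speed_table) < 1 || any(speed_table$speed <= 0)) {
    stop("`speed_table` needs columns size, speed (speed > 0)", call. = FALSE)
  }
  speed_table <- speed_table[order(speed_table$size), c("size", "speed")]
  new_performance_model(
    kind = "fpm", node_type = node_type, speed_table = speed_table,
    thread_speedup = thread_speedup
  )
}

new_performance_model <- function(kind, node_type, components = NULL,
                                  speed_constant = NULL, speed_table = NULL,
                                  clamp_floor = 0.001, thread_speedup = NULL) {
  if (!is.null(thread_speedup)) {
    if (is.null(names(thread_speedup)) || any(thread_speedup <= 0)) {
      stop("`thread_speedup` must be a named vector of positive divisors",
           call. = FALSE)
    }
  }
  stopifnot(is.numeric(clamp_floor), clamp_floor > 0)
  structure(
    list(
      node_type = node_type, kind = kind, components = components,
      speed_constant = speed_constant, speed_table = speed_table,
      clamp_floor = clamp_floor, thread_speedup = thread_speedup
    ),
    class = "performance_model"
  )
}

#' @export
print.performance_model <- function(x, ...) {
  cat(sprintf("<performance_model> node type %s, kind %s\n",
              x$node_type, x$kind))
  if (x$kind == "quadratic_sum") {
    cat("  components:", paste(names(x$components), collapse = ", "), "\n")
    cat("  clamp floor:", x$clamp_floor, "s\n")
  } else if (x$kind == "cpm") {
    cat("  speed:", x$speed_constant, "seq/s\n")
  } else {
    cat("  speed table knots:", nrow(x$speed_table), "\n")
  }
  if (!is.null(x$thread_speedup)) {
    cat("  thread speed-up:",
        paste(sprintf("%s:%.3g", names(x$thread_speedup), x$thread_speedup),
              collapse = " "), "\n")
  }
  invisible(x)
}

#' Predict sub-job runtime under a performance model
#'
#' Dispatches on the model kind (see [quadratic_model()]) and divides by the
#' thread speed-up factor when `threads > 1`.
#'
#' @param model A `performance_model`.
#' @param database_size,query_size Sub-job sequence counts (vectors recycle).
#' @param threads Thread count; values other than 1 must be present in the
#'   model's `thread_speedup` table.
#' @return Predicted seconds (numeric vector).
#' @export
predict_runtime <- function(model, database_size, query_size, threads = 1L) {
  stopifnot(inherits(model, "performance_model"))
  t1 <- switch(
    model$kind,
    quadratic_sum = {
      per <- lapply(model$components, function(s) {
        evaluate_surface(s, database_size, query_size,
                         detail = TRUE, clamp_floor = model$clamp_floor)$clamped
      })
      Reduce(`+`, per)
    },
    cpm = {
      check_sizes(database_size, query_size)
      database_size / model$speed_constant
    },
    fpm = {
      check_sizes(database_size, query_size)
      tab <- model$speed_table
      if (any(database_size < min(tab$size) | database_size > max(tab$size))) {
        stop(sprintf(
          "fpm model for node type %s: database size outside speed-table domain [%g, %g]",
          model$node_type, min(tab$size), max(tab$size)), call. = FALSE)
      }
      sp <- approx(tab$size, tab$speed, xout = database_size,
                   method = "constant", rule = 2)$y
      database_size / sp
    },
    stop("unknown model kind: ", model$kind, call. = FALSE)
  )
  t1 / thread_factor(model, threads)
}

check_sizes <- function(database_size, query_size) {
  if (any(database_size < 1) || any(query_size < 1)) {
    stop("database_size and query_size must be >= 1 sequence", call. = FALSE)
  }
}

thread_factor <- function(model, threads) {
  threads <- as.integer(threads)
  stopifnot(length(threads) == 1, threads >= 1)
  if (threads == 1L) return(1)
  key <- as.character(threads)
  if (is.null(model$thread_speedup) || !key %in% names(model$thread_speedup)) {
    stop(sprintf(
      "model for node type %s has no thread speed-up factor for %d threads",
      model$node_type, threads), call. = FALSE)
  }
  unname(model$thread_speedup[[key]])
}

#' Derive per-component scale factors between two node types
#'
#' The "abstract processor" idea: one node type's runtime behavior is the
#' reference, and every other type is described by the mean ratio of its
#' runtimes to the reference's, per component, over a matched measurement
#' grid. The resulting factors feed [scale_model()] so one fitted model can
#' be transferred to other node types without refitting.
#'
#' @param records_ref,records_other Measurement tables (see
#'   [read_measurements()]) sharing (database_size, query_size, component)
#'   keys; `records_ref` is the reference node type.
#' @return Named numeric vector: component -> mean(other / ref).
#' @export
derive_scale_factors <- function(records_ref, records_other) {
  keys <- c("database_size", "query_size", "component")
  for (df in list(records_ref, records_other)) {
    if (!all(c(keys, "runtime_seconds") %in% names(df))) {
      stop("measurement tables need columns ",
           paste(c(keys, "runtime_seconds"), collapse = ", "), call. = FALSE)
    }
  }
  ref <- stats::aggregate(records_ref["runtime_seconds"],
                          records_ref[keys], FUN = mean)
  oth <- stats::aggregate(records_other["runtime_seconds"],
                          records_other[keys], FUN = mean)
  m <- merge(ref, oth, by = keys, suffixes = c("_ref", "_other"))
  if (nrow(m) == 0) {
    stop("no overlapping (database_size, query_size, component) keys",
         call. = FALSE)
  }
  if (any(m$runtime_seconds_ref <= 0)) {
    stop("reference runtimes must be positive to form ratios", call. = FALSE)
  }
  m$ratio <- m$runtime_seconds_other / m$runtime_seconds_ref
  out <- stats::aggregate(ratio ~ component, data = m, FUN = mean)
  setNames(out$ratio, out$component)
}

#' Rescale a model to another node type
#'
#' Multiplies every coefficient of each component surface by that component's
#' factor; because the quadratic is linear in its coefficients, predictions
#' scale exactly by the factor at every input.
#'
#' @param model A `quadratic_sum` [performance model][quadratic_model()].
#' @param factors Named numeric vector covering every component of the model
#'   (e.g. from [derive_scale_factors()] or [node_type_factors()]).
#' @param node_type Optional new node-type label for the scaled model.
#' @return A new `performance_model`.
#' @export
scale_model <- function(model, factors, node_type = NULL) {
  stopifnot(inherits(model, "performance_model"))
  if (model$kind != "quadratic_sum") {
    stop("scale_model() applies to quadratic_sum models; rescale cpm/fpm ",
         "speeds directly", call. = FALSE)
  }
  missing <- setdiff(names(model$components), names(factors))
  if (length(missing) > 0) {
    stop("no scale factor for component(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(factors <= 0)) stop("scale factors must be > 0", call. = FALSE)
  comps <- model$components
  for (nm in names(comps)) {
    comps[[nm]]$coefficients <- comps[[nm]]$coefficients * factors[[nm]]
  }
  quadratic_model(comps, node_type = node_type %||% model$node_type,
                  clamp_floor = model$clamp_floor,
                  thread_speedup = model$thread_speedup)
}

#' Scan a model for monotonicity violations
#'
#' Runtimes should not decrease when either input grows. Scans a rectangular
#' grid and reports every adjacent pair where the prediction drops as the
#' database or query size increases. Fitted quadratics can violate this near
#' the domain edges; an empty result means the model is monotone on the grid.
#'
#' @param model A `performance_model`.
#' @param d_range,q_range Length-2 numeric ranges (sequences).
#' @param grid_points Number of grid points per axis.
#' @param threads Thread count forwarded to [predict_runtime()].
#' @return Data frame of violations (`database_size`, `query_size`, `axis`,
#'   `drop_seconds`), zero rows if monotone.
#' @export
check_monotonic <- function(model, d_range, q_range, grid_points = 25,
                            threads = 1L) {
  stopifnot(length(d_range) == 2, length(q_range) == 2, grid_points >= 2)
  ds <- unique(round(seq(d_range[1], d_range[2], length.out = grid_points)))
  qs <- unique(round(seq(q_range[1], q_range[2], length.out = grid_points)))
  grid <- expand.grid(database_size = ds, query_size = qs)
  grid$t <- predict_runtime(model, grid$database_size, grid$query_size,
                            threads = threads)
  tmat <- matrix(grid$t, nrow = length(ds), ncol = length(qs))
  out <- list()
  if (length(ds) > 1) {
    dd <- diff(tmat)                       # along database axis
    idx <- which(dd < 0, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      out[[length(out) + 1]] <- data.frame(
        database_size = ds[idx[, 1] + 1], query_size = qs[idx[, 2]],
        axis = "database", drop_seconds = -dd[idx]
      )
    }
  }
  if (length(qs) > 1) {
    dq <- t(diff(t(tmat)))                 # along query axis
    idx <- which(dq < 0, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      out[[length(out) + 1]] <- data.frame(
        database_size = ds[idx[, 1]], query_size = qs[idx[, 2] + 1],
        axis = "query", drop_seconds = -dq[idx]
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(database_size = numeric(0), query_size = numeric(0),
                      axis = character(0), drop_seconds = numeric(0)))
  }
  do.call(rbind, out)
}
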