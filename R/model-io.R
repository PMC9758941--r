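#' Write / read a performance model as JSON
#'
#' The on-disk document stores the kind, node type, clamp floor, thread
#' speed-up table, and — for `quadratic_sum` models — each component's six
#' coefficients in evaluation order with its transform name and log base.
#'
#' @param model A `performance_model`.
#' @param path File path.
#' @return `write_model()` returns `path` invisibly; `read_model()` returns
#'   the reconstructed `performance_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "performance_model"))
  doc <- list(
    kind = model$kind,
    node_type = model$node_type,
    clamp_floor = model$clamp_floor
  )
  if (!is.null(model$thread_speedup)) {
    doc$thread_speedup <- as.list(model$thread_speedup)
  }
  if (model$kind == "quadratic_sum") {
    doc$components <- lapply(model$components, function(s) {
      list(coefficients = unname(s$coefficients),
           x_transform = s$x_transform, log_base = s$log_base)
    })
  } else if (model$kind == "cpm") {
    doc$speed_constant <- model$speed_constant
  } else {
    doc$speed_table <- model$speed_table
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  ts <- if (!is.null(doc$thread_speedup)) unlist(doc$thread_speedup)
  switch(
    doc$kind,
    quadratic_sum = {
      comps <- lapply(doc$components, function(c) {
        quadratic_surface(unlist(c$coefficients), c$x_transform,
                          c$log_base %||% exp(1))
      })
      quadratic_model(comps, node_type = doc$node_type,
                      clamp_floor = doc$clamp_floor %||% 0.001,
                      thread_speedup = ts)
    },
    cpm = cpm_model(doc$speed_constant, node_type = doc$node_type,
                    thread_speedup = ts),
    fpm = fpm_model(as.data.frame(doc$speed_table),
                    node_type = doc$node_type, thread_speedup = ts),
    stop("unknown model kind in ", path, ": ", doc$kind, call. = FALSE)
  )
}

extdata <- function(file) {
  path <- system.file("extdata", file, package = "blastpart")
  if (!nzchar(path)) stop("packaged data file not found: ", file,
                          call. = FALSE)
  path
}

#' Shipped reference surfaces for the five core BLASTN functions
#'
#' The package ships a fitted coefficient set for the five core BLASTN
#' functions (`func_a` .. `func_e`) on the reference node type (Type V,
#' single thread). Functions a and e use a log-transformed database axis;
#' b, c, and d degenerated to planes.
#'
#' @return Named list of [quadratic_surface()] objects.
#' @seealso [reference_model()], [node_type_factors()]
#' @export
reference_surfaces <- function() {
  doc <- jsonlite::read_json(extdata("core_function_surfaces.json"),
                             simplifyVector = TRUE)
  lapply(doc$components, function(c) {
    quadratic_surface(unlist(c$coefficients), c$x_transform, doc$log_base)
  })
}

#' Shipped reference performance model
#'
#' Builds a ready-to-use `quadratic_sum` model from the packaged reference
#' surfaces ([reference_surfaces()]), rescaled to the requested node type via
#' the packaged factors ([node_type_factors()]) and optionally carrying the
#' packaged thread speed-up table.
#'
#' @param node_type One of `"I"` .. `"VI"`.
#' @param query_set `"A"` or `"B"`, selecting the thread speed-up table, or
#'   `NULL` for no thread table.
#' @param clamp_floor Floor passed to [quadratic_model()].
#' @return A `performance_model`.
#' @export
#' @examples
#' m <- reference_model("V")
#' predict_runtime(m, 261725, 35695)
reference_model <- function(node_type = "V", query_set = "A",
                            clamp_floor = 0.001) {
  ts <- if (!is.null(query_set)) thread_speedup_table(query_set)
  base <- quadratic_model(reference_surfaces(), node_type = "V",
                          clamp_floor = clamp_floor, thread_speedup = ts)
  if (identical(node_type, "V")) return(base)
  fac <- node_type_factors(node_type)
  scale_model(base, fac, node_type = node_type)
}

#' Packaged node-type runtime factors
#'
#' Per-function runtime factors of six node types relative to the reference
#' type (Type V): factor f means the function runs f times as long on that
#' type. Used with [scale_model()] to transfer the reference model to other
#' node types, and by [default_performance_factors()] to derive relative
#' node speeds.
#'
#' @param node_type Optional single type (`"I"` .. `"VI"`); if omitted, the
#'   full table is returned.
#' @return Named numeric vector (one type) or a data.frame (all types, one
#'   row per type, one column per component).
#' @export
node_type_factors <- function(node_type = NULL) {
  doc <- jsonlite::read_json(extdata("node_type_factors.json"),
                             simplifyVector = TRUE)
  tab <- do.call(rbind, lapply(doc$factors, function(x) as.data.frame(x)))
  if (is.null(node_type)) return(tab)
  if (!node_type %in% rownames(tab)) {
    stop("unknown node type: ", node_type, call. = FALSE)
  }
  unlist(tab[node_type, , drop = TRUE])
}

#' Packaged multithreading speed-up table
#'
#' @param query_set `"A"` or `"B"`.
#' @return Named numeric vector mapping thread count to speed-up divisor.
#' @export
thread_speedup_table <- function(query_set = "A") {
  doc <- jsonlite::read_json(extdata("thread_speedup.json"),
                             simplifyVector = TRUE)
  if (!query_set %in% names(doc$speedup)) {
    stop("unknown query set: ", query_set, call. = FALSE)
  }
  unlist(doc$speedup[[query_set]])
}

#' Default relative node speeds from the packaged factors
#'
#' A node type's relative speed `s_k` defaults to the reciprocal of the mean
#' of its per-function runtime factors (slower functions => smaller speed),
#' normalized so the reference type has speed 1. These are defaults only:
#' [node_type_profile()] accepts any user-supplied `performance_factor`,
#' which is the recommended route when measured speeds are available.
#'
#' @return Named numeric vector of speeds, one per packaged node type.
#' @export
default_performance_factors <- function() {
  tab <- node_type_factors()
  1 / rowMeans(tab)
}
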