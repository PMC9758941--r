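#' Bivariate quadratic runtime surface
#'
#' A runtime surface predicts the seconds one sub-job of size
#' (`database_size`, `query_size`) takes on one node type, for one timed
#' component. Sizes are expressed in millions of sequences before evaluation,
#' and the database axis may additionally be log-transformed (the query axis
#' never is). With `x = transform(D / 1e6)` and `y = Q / 1e6` the prediction is
#'
#' \deqn{T(D, Q) = c_1 x^2 + c_2 x y + c_3 y^2 + c_4 x + c_5 y + c_6}
#'
#' A surface with `c1 = c2 = c3 = 0` degenerates to a plane, which is how the
#' query-dominated components behave in practice.
#'
#' @param coefficients Numeric vector of length 6, in the order
#'   `c(c1, c2, c3, c4, c5, c6)` = (x^2, x*y, y^2, x, y, intercept).
#' @param x_transform `"identity"` or `"log"`; transform applied to the
#'   database axis after scaling to millions.
#' @param log_base Base of the logarithm when `x_transform = "log"`.
#'   Defaults to the natural log.
#' @return An object of class `quadratic_surface`.
#' @seealso [evaluate_surface()], [fit_surface()]
#' @export
#' @examples
#' s <- quadratic_surface(c(0, 92.8758, 0, 0.1523, 244.7267, 0.4292))
#' evaluate_surface(s, database_size = 261725, query_size = 35695)
quadratic_surface <- function(coefficients,
                              x_transform = c("identity", "log"),
                              log_base = exp(1)) {
  x_transform <- match.arg(x_transform)
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) != 6 || anyNA(coefficients)) {
    stop("`coefficients` must be six finite numbers (c1..c6)", call. = FALSE)
  }
  if (!is.numeric(log_base) || log_base <= 0 || log_base == 1) {
    stop("`log_base` must be a positive number != 1", call. = FALSE)
  }
  structure(
    list(
      coefficients = setNames(coefficients, paste0("c", 1:6)),
      x_transform = x_transform,
      log_base = log_base
    ),
    class = "quadratic_surface"
  )
}

#' @export
print.quadratic_surface <- function(x, ...) {
  cat("<quadratic_surface>\n")
  cat("  x axis:", if (x$x_transform == "log") {
    sprintf("log_%.4g(D / 1e6)", x$log_base)
  } else "D / 1e6", "\n")
  cat("  coefficients:",
      paste(sprintf("%s=%.6g", names(x$coefficients), x$coefficients),
            collapse = " "), "\n")
  invisible(x)
}

surface_inputs <- function(surface, database_size, query_size) {
  if (any(database_size < 1) || any(query_size < 1)) {
    stop("database_size and query_size must be >= 1 sequence", call. = FALSE)
  }
  x <- database_size / 1e6
  if (surface$x_transform == "log") x <- log(x, base = surface$log_base)
  list(x = x, y = query_size / 1e6)
}

#' Evaluate a runtime surface
#'
#' Converts sequence counts to millions, applies the surface's database-axis
#' transform, and evaluates the quadratic. Fitted quadratics can dip below
#' zero at the edges of their domain; when `detail = TRUE` the result also
#' carries a floor-clamped value and a flag, which is what the optimizer
#' consumes (it needs a total order over candidates, not an error).
#'
#' @param surface A [quadratic_surface()].
#' @param database_size,query_size Sequence counts (vectors recycle).
#' @param detail If `TRUE`, return a data.frame with `raw`, `clamped`, and
#'   `was_clamped` columns; otherwise the raw numeric prediction.
#' @param clamp_floor Positive seconds used as the floor when `detail = TRUE`.
#' @return Numeric vector of predicted seconds, or a data.frame when
#'   `detail = TRUE`.
#' @export
evaluate_surface <- function(surface, database_size, query_size,
                             detail = FALSE, clamp_floor = 0.001) {
  stopifnot(inherits(surface, "quadratic_surface"))
  inp <- surface_inputs(surface, database_size, query_size)
  x <- inp$x; y <- inp$y
  cf <- surface$coefficients
  raw <- cf[[1]] * x^2 + cf[[2]] * x * y + cf[[3]] * y^2 +
    cf[[4]] * x + cf[[5]] * y + cf[[6]]
  if (!detail) return(unname(raw))
  clamped <- pmax(raw, clamp_floor)
  data.frame(raw = unname(raw), clamped = unname(clamped),
             was_clamped = unname(raw <= 0))
}

EQ8_TERMS <- c("x^2", "x*y", "y^2", "x", "y", "intercept")

#' Fit a runtime surface to a measurement grid
#'
#' Ordinary least squares on the six-term quadratic design matrix. The
#' measurements must all belong to a single node type and component;
#' replicates at the same (database, query) point are averaged before
#' fitting. At least six distinct (database, query) points are required, and
#' the design must span all six terms (a degenerate grid, e.g. a single
#' database size, is rejected with the deficient term named).
#'
#' @param records Data frame with columns `database_size`, `query_size`,
#'   `runtime_seconds` (a full measurement table works; `node_type` and
#'   `component` must then be constant).
#' @param x_transform,log_base As in [quadratic_surface()].
#' @return A list with elements `surface` (the fitted [quadratic_surface()])
#'   and `report` (class `fit_report`: `residual_sum_of_squares`,
#'   `r_squared`, `n_points`, `condition_warning`, `per_point_residuals`).
#' @export
#' @examples
#' s <- quadratic_surface(c(0, 4429.4587, 0, 57.7969, 94.9201, 0.1854))
#' grid <- gen_measurements(s, noise_sigma_fraction = 0, seed = 1)
#' fit <- fit_surface(grid)
#' all.equal(fit$surface$coefficients, s$coefficients)
fit_surface <- function(records, x_transform = c("identity", "log"),
                        log_base = exp(1)) {
  x_transform <- match.arg(x_transform)
  req <- c("database_size", "query_size", "runtime_seconds")
  if (!all(req %in% names(records))) {
    stop("records must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("node_type", "component")) {
    if (col %in% names(records) && length(unique(records[[col]])) > 1) {
      stop("records mix several values of `", col,
           "`; fit one node type and component at a time", call. = FALSE)
    }
  }
  # average replicates per (D, Q)
  agg <- stats::aggregate(
    runtime_seconds ~ database_size + query_size,
    data = records[req], FUN = mean
  )
  if (nrow(agg) < 6) {
    stop("need >= 6 distinct (database_size, query_size) points, got ",
         nrow(agg), call. = FALSE)
  }
  proto <- quadratic_surface(rep(0, 6), x_transform, log_base)
  inp <- surface_inputs(proto, agg$database_size, agg$query_size)
  X <- cbind(inp$x^2, inp$x * inp$y, inp$y^2, inp$x, inp$y, 1)
  colnames(X) <- EQ8_TERMS
  qrX <- qr(X)
  if (qrX$rank < 6) {
    bad <- EQ8_TERMS[setdiff(seq_len(6), qrX$pivot[seq_len(qrX$rank)])]
    stop("design matrix is singular; deficient term(s): ",
         paste(bad, collapse = ", "),
         " (grid does not vary enough in that direction)", call. = FALSE)
  }
  beta <- qr.coef(qrX, agg$runtime_seconds)
  resid <- agg$runtime_seconds - drop(X %*% beta)
  rss <- sum(resid^2)
  tss <- sum((agg$runtime_seconds - mean(agg$runtime_seconds))^2)
  report <- structure(
    list(
      residual_sum_of_squares = rss,
      r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
      n_points = nrow(agg),
      condition_warning = kappa(X, exact = TRUE) > 1e8,
      per_point_residuals = resid
    ),
    class = "fit_report"
  )
  list(
    surface = quadratic_surface(unname(beta), x_transform, log_base),
    report = report
  )
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf(
    "<fit_report> n=%d  RSS=%.6g  R^2=%s%s\n",
    x$n_points, x$residual_sum_of_squares,
    ifelse(is.na(x$r_squared), "NA", sprintf("%.6f", x$r_squared)),
    if (isTRUE(x$condition_warning)) "  [ill-conditioned design]" else ""
  ))
  invisible(x)
}
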