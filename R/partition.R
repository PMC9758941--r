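#' Job and cluster descriptions
#'
#' `job_spec()` describes one BLAST job by its two total sequence counts.
#' `node_type_profile()` describes one node type in a cluster inventory:
#' how many nodes are available (`count`, `P_k`) and how fast the type is
#' relative to the others (`performance_factor`, `s_k`; higher = faster).
#' A cluster is simply a list of profiles, one per type; [read_cluster()]
#' loads one from JSON.
#'
#' @param database_total,query_total Total sequence counts (>= 1).
#' @return `job_spec()`: an object of class `job_spec`.
#' @export
job_spec <- function(database_total, query_total) {
  stopifnot(database_total >= 1, query_total >= 1)
  structure(list(database_total = as.numeric(database_total),
                 query_total = as.numeric(query_total)),
            class = "job_spec")
}

#' @rdname job_spec
#' @param node_type Identifier.
#' @param count Number of nodes of this type (`P_k`, >= 0).
#' @param performance_factor Relative speed `s_k` (> 0). See
#'   [default_performance_factors()] for the packaged defaults.
#' @param function_scale_factors Optional named component->factor vector
#'   (relative runtimes vs a reference type).
#' @param thread_speedup Optional named thread-count->divisor vector.
#' @return `node_type_profile()`: an object of class `node_type_profile`.
#' @export
node_type_profile <- function(node_type, count, performance_factor = 1,
                              function_scale_factors = NULL,
                              thread_speedup = NULL) {
  stopifnot(count >= 0, performance_factor > 0)
  if (!is.null(function_scale_factors) && any(function_scale_factors <= 0)) {
    stop("function_scale_factors must be > 0", call. = FALSE)
  }
  structure(list(node_type = as.character(node_type),
                 count = as.integer(count),
                 performance_factor = as.numeric(performance_factor),
                 function_scale_factors = function_scale_factors,
                 thread_speedup = thread_speedup),
            class = "node_type_profile")
}

as_cluster <- function(cluster) {
  if (inherits(cluster, "node_type_profile")) cluster <- list(cluster)
  if (!is.list(cluster) || length(cluster) == 0 ||
      !all(vapply(cluster, inherits, logical(1), "node_type_profile"))) {
    stop("`cluster` must be a non-empty list of node_type_profile objects",
         call. = FALSE)
  }
  types <- vapply(cluster, `[[`, character(1), "node_type")
  if (anyDuplicated(types)) stop("duplicate node types in cluster",
                                 call. = FALSE)
  names(cluster) <- types
  cluster
}

#' Read / write a cluster description (JSON)
#'
#' The document is an array of objects with fields `node_type`, `count`,
#' `performance_factor`, and optional `function_scale_factors` /
#' `thread_speedup` maps.
#'
#' @param path File path.
#' @param cluster List of [node_type_profile()] objects.
#' @return `read_cluster()`: named list of profiles; `write_cluster()`:
#'   `path`, invisibly.
#' @export
read_cluster <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  as_cluster(lapply(doc, function(x) {
    node_type_profile(
      x$node_type, x$count, x$performance_factor %||% 1,
      function_scale_factors = if (!is.null(x$function_scale_factors))
        unlist(x$function_scale_factors),
      thread_speedup = if (!is.null(x$thread_speedup))
        unlist(x$thread_speedup)
    )
  }))
}

#' @rdname read_cluster
#' @export
write_cluster <- function(cluster, path) {
  cluster <- as_cluster(cluster)
  doc <- lapply(unname(cluster), function(p) {
    out <- list(node_type = p$node_type, count = p$count,
                performance_factor = p$performance_factor)
    if (!is.null(p$function_scale_factors))
      out$function_scale_factors <- as.list(p$function_scale_factors)
    if (!is.null(p$thread_speedup))
      out$thread_speedup <- as.list(p$thread_speedup)
    out
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Ceiling fragment size
#'
#' Splitting `total` sequences into `parts` fragments assigns each fragment
#' `ceiling(total / parts)` sequences (the last fragment absorbs the
#' shortfall; see [fragment_sizes()]). When `parts > total` the per-fragment
#' size is 1 and the surplus fragments are empty — the caller is responsible
#' for flagging those.
#'
#' @param total Total sequence count (>= 1).
#' @param parts Number of fragments (>= 1).
#' @return Integer-valued fragment size.
#' @export
#' @examples
#' fragment_size(523449, 64)     # 8179
#' fragment_size(73102023, 585)  # 124961
fragment_size <- function(total, parts) {
  stopifnot(total >= 1, parts >= 1)
  ceiling(total / parts)
}

#' Exact fragment sizes
#'
#' Materializes the ceiling rule into per-fragment counts: fragments are
#' filled to `ceiling(total / parts)` until the remainder runs out, then one
#' partial fragment, then zero-size fragments (reported, never dropped) so
#' that the result always has length `parts` and sums exactly to `total`.
#'
#' @inheritParams fragment_size
#' @return Numeric vector of length `parts`, summing to `total`.
#' @export
#' @examples
#' fragment_sizes(10, 3)  # 4 4 2
fragment_sizes <- function(total, parts) {
  stopifnot(total >= 1, parts >= 1)
  s <- fragment_size(total, parts)
  n_full <- total %/% s
  rem <- total - n_full * s
  sizes <- c(rep(s, n_full), if (rem > 0) rem)
  c(sizes, rep(0, parts - length(sizes)))
}

#' Enumerate candidate (m, n) fragmentations for P nodes
#'
#' For every database fragment count `m` in `1..P`, the query fragment count
#' is `n = floor(P / m)`, the most query fragments the node budget allows.
#' This includes all exact divisor pairs (`m * n = P`) plus near-exact pairs
#' that leave a few nodes idle (e.g. `m = 3, n = 1365` for `P = 4096`), which
#' are legitimate candidates: idle nodes are reported in the plan.
#'
#' @param P Node count (>= 1).
#' @return Data frame with columns `m`, `n`, `nodes_used`, `idle_nodes`,
#'   sorted by `m`.
#' @export
#' @examples
#' enumerate_splits(4)
enumerate_splits <- function(P) {
  stopifnot(P >= 1)
  m <- seq_len(P)
  n <- P %/% m
  keep <- n >= 1
  out <- data.frame(m = m[keep], n = n[keep])
  out <- out[!duplicated(out[c("m", "n")]), ]
  out$nodes_used <- out$m * out$n
  out$idle_nodes <- P - out$nodes_used
  out[order(out$m), ]
}

new_split_candidate <- function(m, n, P, database_fragment, query_fragment,
                                predicted_seconds, node_type = NA_character_) {
  structure(
    list(m = m, n = n, nodes_used = m * n, idle_nodes = P - m * n,
         database_fragment = database_fragment,
         query_fragment = query_fragment,
         predicted_seconds = predicted_seconds,
         node_type = node_type),
    class = "split_candidate"
  )
}

#' @export
print.split_candidate <- function(x, ...) {
  cat(sprintf(
    "<split_candidate> m=%d n=%d (%d nodes, %d idle)  fragments (%s, %s)  predicted %.4g s\n",
    x$m, x$n, x$nodes_used, x$idle_nodes,
    format(x$database_fragment, big.mark = ","),
    format(x$query_fragment, big.mark = ","), x$predicted_seconds))
  invisible(x)
}

#' Optimal fragmentation on a homogeneous cluster
#'
#' Evaluates the predicted sub-job runtime `T(ceil(D/m), ceil(Q/n))` for
#' every candidate from [enumerate_splits()] and returns the minimizer.
#' Because all `m x n` sub-jobs on identical nodes share the same fragment
#' sizes, the worst sub-job equals any sub-job, and minimizing the per
#' sub-job prediction minimizes the whole-job turnaround. Ties are broken in
#' favor of larger `n` (smaller query fragments — empirically the more
#' performance-effective direction), then smaller `m`.
#'
#' @param job A [job_spec()].
#' @param P Number of identical nodes.
#' @param model The node type's [performance model][quadratic_model()].
#' @param threads Threads per sub-job, forwarded to [predict_runtime()].
#' @return A `split_candidate` (fields `m`, `n`, `nodes_used`, `idle_nodes`,
#'   `database_fragment`, `query_fragment`, `predicted_seconds`).
#' @export
#' @examples
#' plane <- quadratic_surface(c(0, 0, 0, 1, 1000, 0))
#' m <- quadratic_model(list(overall = plane))
#' solve_homogeneous(job_spec(1000, 1000), P = 4, m)
solve_homogeneous <- function(job, P, model, threads = 1L) {
  stopifnot(inherits(job, "job_spec"), P >= 1)
  cand <- enumerate_splits(P)
  cand$database_fragment <- fragment_size(job$database_total, cand$m)
  cand$query_fragment <- fragment_size(job$query_total, cand$n)
  cand$predicted_seconds <- tryCatch(
    predict_runtime(model, cand$database_fragment, cand$query_fragment,
                    threads = threads),
    error = function(e) {
      stop("model evaluation failed over candidates (m in 1..", P, "): ",
           conditionMessage(e), call. = FALSE)
    }
  )
  bad <- which(!is.finite(cand$predicted_seconds))
  if (length(bad) > 0) {
    stop(sprintf("model evaluation failed for candidate (m=%d, n=%d)",
                 cand$m[bad[1]], cand$n[bad[1]]), call. = FALSE)
  }
  best <- cand[order(cand$predicted_seconds, -cand$n, cand$m), ][1, ]
  new_split_candidate(best$m, best$n, P, best$database_fragment,
                      best$query_fragment, best$predicted_seconds,
                      node_type = model$node_type)
}

#' Accumulated computing power per node type
#'
#' `W_k = s_k * P_k`: a type's relative speed times its node count. Types
#' with zero nodes get zero power and are excluded from quota splitting.
#'
#' @param cluster List of [node_type_profile()] objects.
#' @return Named numeric vector of `W_k` keyed by node type.
#' @export
compute_power <- function(cluster) {
  cluster <- as_cluster(cluster)
  vapply(cluster, function(p) p$performance_factor * p$count, numeric(1))
}

#' Apportion the query among node types by computing power
#'
#' Divides the query so that each type's share is proportional to its
#' accumulated power (`Q_k / W_k` equal across types). The per-node quota is
#' rounded up to whole sequences, `q_k = ceiling(share_k * Q / P_k)`, and the
#' type quota is `Q_k = q_k * P_k`; hence the quotas always cover `Q`, with
#' an overshoot of at most one sequence per node.
#'
#' @param Q Total query sequences.
#' @param cluster List of [node_type_profile()] objects.
#' @return Data frame with one row per participating type: `node_type`,
#'   `count`, `power`, `share`, `per_node_quota` (`q_k`), `type_quota`
#'   (`Q_k`).
#' @export
split_query_by_power <- function(Q, cluster) {
  stopifnot(Q >= 1)
  cluster <- as_cluster(cluster)
  W <- compute_power(cluster)
  if (sum(W) <= 0) stop("total computing power is zero", call. = FALSE)
  if (any(W == 0)) {
    warning("excluding node type(s) with no nodes: ",
            paste(names(W)[W == 0], collapse = ", "), call. = FALSE)
    cluster <- cluster[W > 0]
    W <- W[W > 0]
  }
  share <- W / sum(W)
  P <- vapply(cluster, `[[`, integer(1), "count")
  q <- ceiling(share * Q / P)
  data.frame(
    node_type = names(W), count = unname(P), power = unname(W),
    share = unname(share), per_node_quota = unname(q),
    type_quota = unname(q * P), row.names = NULL
  )
}

#' Optimal fragmentation on a heterogeneous cluster
#'
#' Heuristic two-level solver: the query is apportioned among node types in
#' proportion to their accumulated computing power
#' ([split_query_by_power()]; only the query is divided across types), then
#' each type solves its own homogeneous sub-problem `(D, Q_k)` with
#' [solve_homogeneous()]. The plan's overall cost is the worst per-type
#' predicted sub-job runtime.
#'
#' @param job A [job_spec()].
#' @param cluster List of [node_type_profile()] objects.
#' @param models Named list of performance models keyed by node type; every
#'   type with nonzero power needs one.
#' @param threads Threads per sub-job.
#' @return A `partition_plan`: data frame `entries` (one row per type with
#'   `node_type`, `count`, `power`, `share`, `per_node_quota`, `type_quota`,
#'   `m`, `n`, `nodes_used`, `idle_nodes`, `database_fragment`,
#'   `query_fragment`, `predicted_seconds`), plus `database_total`,
#'   `query_total`, `threads`, and `cost` (seconds, the max of
#'   `predicted_seconds`).
#' @export
solve_heterogeneous <- function(job, cluster, models, threads = 1L) {
  stopifnot(inherits(job, "job_spec"))
  cluster <- as_cluster(cluster)
  quotas <- split_query_by_power(job$query_total, cluster)
  missing <- setdiff(quotas$node_type, names(models))
  if (length(missing) > 0) {
    stop("no performance model for node type(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  # each type solves (D, share_k * Q): the exact proportional share, not the
  # node-rounded quota, so a single-type cluster reduces to the homogeneous
  # solver exactly. With n_k = P_k the resulting query fragment
  # ceil(share_k * Q / P_k) equals the reported per-node quota q_k.
  picks <- lapply(seq_len(nrow(quotas)), function(i) {
    row <- quotas[i, ]
    solve_homogeneous(job_spec(job$database_total,
                               row$share * job$query_total),
                      row$count, models[[row$node_type]], threads = threads)
  })
  entries <- cbind(
    quotas,
    do.call(rbind, lapply(picks, function(p) {
      data.frame(m = p$m, n = p$n, nodes_used = p$nodes_used,
                 idle_nodes = p$idle_nodes,
                 database_fragment = p$database_fragment,
                 query_fragment = p$query_fragment,
                 predicted_seconds = p$predicted_seconds)
    }))
  )
  new_partition_plan(entries, job, threads)
}

new_partition_plan <- function(entries, job, threads) {
  structure(
    list(entries = entries,
         database_total = job$database_total,
         query_total = job$query_total,
         threads = as.integer(threads),
         cost = max(entries$predicted_seconds)),
    class = "partition_plan"
  )
}

#' Promote a single-type result to a partition plan
#'
#' Wraps a `split_candidate` from [solve_homogeneous()] into a one-entry
#' `partition_plan`, so downstream consumers ([make_manifest()],
#' [write_plan()]) handle homogeneous and heterogeneous results uniformly.
#'
#' @param candidate A `split_candidate`.
#' @param job The [job_spec()] it was solved for.
#' @param P Node count used.
#' @param threads Threads per sub-job.
#' @return A `partition_plan`.
#' @export
as_partition_plan <- function(candidate, job, P, threads = 1L) {
  stopifnot(inherits(candidate, "split_candidate"), inherits(job, "job_spec"))
  q <- fragment_size(job$query_total, 1)  # whole query to the single type
  entries <- data.frame(
    node_type = candidate$node_type %||% "default", count = P, power = P,
    share = 1, per_node_quota = NA_real_, type_quota = job$query_total,
    m = candidate$m, n = candidate$n, nodes_used = candidate$nodes_used,
    idle_nodes = candidate$idle_nodes,
    database_fragment = candidate$database_fragment,
    query_fragment = candidate$query_fragment,
    predicted_seconds = candidate$predicted_seconds
  )
  new_partition_plan(entries, job, threads)
}

#' Plan cost: the slowest predicted sub-job
#'
#' The turnaround of a fanned-out job is the runtime of its slowest sub-job,
#' so a plan's cost is the maximum predicted runtime over its entries.
#'
#' @param plan A `partition_plan`.
#' @return Seconds.
#' @export
plan_cost <- function(plan) {
  stopifnot(inherits(plan, "partition_plan"))
  if (nrow(plan$entries) == 0) stop("empty plan", call. = FALSE)
  max(plan$entries$predicted_seconds)
}

#' @export
print.partition_plan <- function(x, ...) {
  cat(sprintf("<partition_plan> D=%s, Q=%s, %d thread(s), cost %.4g s\n",
              format(x$database_total, big.mark = ","),
              format(x$query_total, big.mark = ","), x$threads, x$cost))
  cols <- c("node_type", "count", "share", "per_node_quota", "m", "n",
            "idle_nodes", "database_fragment", "query_fragment",
            "predicted_seconds")
  print(x$entries[, cols], row.names = FALSE)
  invisible(x)
}

#' Write / read a partition plan (JSON)
#'
#' @param plan A `partition_plan`.
#' @param path File path.
#' @return `write_plan()`: `path` invisibly; `read_plan()`: the plan.
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "partition_plan"))
  jsonlite::write_json(
    list(database_total = plan$database_total,
         query_total = plan$query_total, threads = plan$threads,
         cost = plan$cost, entries = plan$entries),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_partition_plan(as.data.frame(doc$entries),
                     job_spec(doc$database_total, doc$query_total),
                     doc$threads)
}
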