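test_that("ceiling fragment sizes match worked examples and stay tight", {
  expect_equal(fragment_size(523449, 64), 8179)
  expect_equal(fragment_size(523449, 1), 523449)
  expect_equal(fragment_size(73102023, 585), 124961)
  expect_equal(fragment_size(10, 3), 4)
  expect_error(fragment_size(0, 3))

  # tightness: k * size covers the total, k * (size - 1) does not
  set.seed(101)
  for (i in 1:1000) {
    total <- sample(1:1e7, 1)
    parts <- sample(1:2000, 1)
    s <- fragment_size(total, parts)
    expect_true(s * parts >= total)
    expect_true((s - 1) * parts < total)
  }
})

test_that("fragment_sizes sums exactly and reports empty tails", {
  expect_equal(fragment_sizes(10, 3), c(4, 4, 2))
  expect_equal(fragment_sizes(7, 1), 7)
  expect_equal(fragment_sizes(523449, 64), c(rep(8179, 63), 8172))
  expect_equal(fragment_sizes(5, 4), c(2, 2, 1, 0))  # zero kept, not dropped
  set.seed(202)
  for (i in 1:300) {
    total <- sample(1:1e6, 1)
    parts <- sample(1:500, 1)
    sz <- fragment_sizes(total, parts)
    expect_length(sz, parts)
    expect_equal(sum(sz), total)
    expect_true(all(sz >= 0))
    expect_true(all(sz <= fragment_size(total, parts)))
  }
})

test_that("enumerate_splits yields divisor and floor pairs", {
  expect_equal(enumerate_splits(1)[, c("m", "n")],
               data.frame(m = 1L, n = 1L))
  got4 <- enumerate_splits(4)
  expect_equal(got4$m, 1:4)
  expect_equal(got4$n, c(4L, 2L, 1L, 1L))
  expect_equal(got4$idle_nodes, c(0L, 0L, 1L, 0L))

  big <- enumerate_splits(4096)
  key <- paste(big$m, big$n)
  for (mn in list(c(3, 1365), c(5, 819), c(6, 682), c(7, 585), c(64, 64))) {
    expect_true(paste(mn[1], mn[2]) %in% key)
  }
  expect_true(all(big$m * big$n <= 4096))
  expect_true(all(diff(big$m) > 0))
})

test_that("solve_homogeneous minimizes the predicted sub-job time", {
  # plane T = 1e-6 * D + 1e-3 * Q: query term dominates, so split the query
  plane <- quadratic_model(
    list(overall = quadratic_surface(c(0, 0, 0, 1, 1000, 0))))
  best <- solve_homogeneous(job_spec(1000, 1000), 4, plane)
  expect_equal(c(best$m, best$n), c(1L, 4L))
  expect_equal(best$database_fragment, 1000)
  expect_equal(best$query_fragment, 250)

  # constant model: tie-break takes the largest n, then smallest m
  const <- quadratic_model(
    list(overall = quadratic_surface(c(0, 0, 0, 0, 0, 9))))
  tie <- solve_homogeneous(job_spec(1e5, 1e5), 16, const)
  expect_equal(c(tie$m, tie$n), c(1L, 16L))

  one <- solve_homogeneous(job_spec(1e5, 1e5), 1, plane)
  expect_equal(c(one$m, one$n), c(1L, 1L))
})

test_that("solver agrees with exhaustive search over random positive planes", {
  set.seed(303)
  for (trial in 1:20) {
    cf <- c(0, 0, 0, runif(1, 0.1, 100), runif(1, 0.1, 100), runif(1, 0, 10))
    model <- quadratic_model(list(overall = quadratic_surface(cf)))
    D <- sample(1e4:1e6, 1); Q <- sample(1e4:1e7, 1)
    P <- sample(c(16, 64), 1)
    best <- solve_homogeneous(job_spec(D, Q), P, model)
    # independent oracle: direct arithmetic over every m in 1..P
    times <- vapply(1:P, function(m) {
      n <- P %/% m
      cf[4] * ceiling(D / m) / 1e6 + cf[5] * ceiling(Q / n) / 1e6 + cf[6]
    }, numeric(1))
    expect_equal(best$predicted_seconds, min(times), tolerance = 1e-12)
  }
})

test_that("computing power and query quotas follow node counts and speeds", {
  expect_equal(
    unname(compute_power(list(node_type_profile("V", 2048, 1)))), 2048)
  cl <- list(node_type_profile("II", 2048, 0.5728),
             node_type_profile("V", 2048, 1.0))
  W <- compute_power(cl)
  expect_equal(unname(W / sum(W)), c(0.3642, 0.6358), tolerance = 1e-4)
  expect_equal(
    unname(compute_power(list(node_type_profile("x", 0, 2),
                              node_type_profile("y", 4, 1)))), c(0, 4))

  # symmetric split
  even <- split_query_by_power(
    1000, list(node_type_profile("a", 1, 1), node_type_profile("b", 1, 1)))
  expect_equal(even$per_node_quota, c(500, 500))

  # single type degenerates to ceil(Q / P) per node
  solo <- split_query_by_power(73102023,
                               list(node_type_profile("V", 2048, 1)))
  expect_equal(solo$per_node_quota, ceiling(73102023 / 2048))
  expect_equal(solo$type_quota, solo$per_node_quota * 2048)

  # coverage property: quotas always cover Q, overshoot < one per node
  set.seed(404)
  for (i in 1:100) {
    k <- sample(1:4, 1)
    cl <- lapply(seq_len(k), function(j) {
      node_type_profile(paste0("t", j), sample(1:100, 1), runif(1, 0.1, 3))
    })
    Q <- sample(1e3:1e8, 1)
    qs <- split_query_by_power(Q, cl)
    expect_true(sum(qs$type_quota) >= Q)
    expect_lt(sum(qs$type_quota) - Q, sum(qs$count))
    expect_equal(qs$type_quota, qs$per_node_quota * qs$count)
  }

  expect_warning(
    split_query_by_power(1000, list(node_type_profile("a", 0, 1),
                                    node_type_profile("b", 2, 1))),
    "no nodes")
})

test_that("heterogeneous solve reduces, balances, and reports max cost", {
  model <- reference_model("V", query_set = NULL)
  job <- job_spec(523449, 73102023)

  # single-type cluster reproduces the homogeneous answer bit-exactly
  plan <- solve_heterogeneous(job, list(node_type_profile("V", 2048, 1)),
                              list(V = model))
  homo <- solve_homogeneous(job, 2048, model)
  expect_equal(plan$entries$m, homo$m)
  expect_equal(plan$entries$n, homo$n)
  expect_identical(plan$entries$predicted_seconds, homo$predicted_seconds)
  expect_equal(plan_cost(plan), homo$predicted_seconds)

  # two identical types: symmetric quotas and equal predicted times
  twin <- solve_heterogeneous(
    job, list(node_type_profile("A", 1024, 1),
              node_type_profile("B", 1024, 1)),
    list(A = model, B = model))
  expect_equal(twin$entries$type_quota[1], twin$entries$type_quota[2])
  expect_equal(twin$entries$predicted_seconds[1],
               twin$entries$predicted_seconds[2])

  # a type twice as slow (model 2x, speed 1/2) finishes at the same time
  # as the fast type, up to quota rounding
  lin <- quadratic_model(
    list(overall = quadratic_surface(c(0, 0, 0, 2, 800, 0))))
  slow <- scale_model(lin, c(overall = 2))
  bal <- solve_heterogeneous(
    job_spec(1e4, 1e7),
    list(node_type_profile("fast", 64, 1),
         node_type_profile("slow", 64, 0.5)),
    list(fast = lin, slow = slow))
  expect_equal(bal$entries$predicted_seconds[1],
               bal$entries$predicted_seconds[2], tolerance = 1e-3)
  expect_equal(plan_cost(bal), max(bal$entries$predicted_seconds))
})

test_that("plan cost is the slowest entry, order-independent", {
  model <- cpm_model(1000)
  plan <- solve_heterogeneous(
    job_spec(1e5, 1e6),
    list(node_type_profile("a", 4, 1), node_type_profile("b", 4, 2)),
    list(a = model, b = model))
  expect_equal(plan_cost(plan), max(plan$entries$predicted_seconds))
  flipped <- plan
  flipped$entries <- flipped$entries[rev(seq_len(nrow(flipped$entries))), ]
  expect_equal(plan_cost(flipped), plan_cost(plan))
})

test_that("plans survive a JSON round trip", {
  dir <- withr::local_tempdir()
  model <- reference_model("V", query_set = NULL)
  plan <- solve_heterogeneous(
    job_spec(523449, 73102023),
    list(node_type_profile("II", 64, 0.5728),
         node_type_profile("V", 64, 1)),
    list(II = reference_model("II", query_set = NULL), V = model))
  path <- file.path(dir, "plan.json")
  write_plan(plan, path)
  back <- read_plan(path)
  expect_equal(back$cost, plan$cost)
  expect_equal(back$entries$m, plan$entries$m)
  expect_equal(back$entries$type_quota, plan$entries$type_quota)
})

test_that("cluster descriptions survive a JSON round trip", {
  dir <- withr::local_tempdir()
  cl <- list(
    node_type_profile("II", 2048, 0.5728,
                      function_scale_factors = c(func_a = 1.4077),
                      thread_speedup = c("2" = 1.12)),
    node_type_profile("V", 2048, 1)
  )
  path <- file.path(dir, "cluster.json")
  write_cluster(cl, path)
  back <- read_cluster(path)
  expect_named(back, c("II", "V"))
  expect_equal(back$II$performance_factor, 0.5728)
  expect_equal(back$II$function_scale_factors, c(func_a = 1.4077))
  expect_equal(back$V$count, 2048L)
})
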