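test_that("surface evaluation matches independent term-by-term arithmetic", {
  # constant surface
  s42 <- quadratic_surface(c(0, 0, 0, 0, 0, 42))
  expect_equal(evaluate_surface(s42, 1, 1), 42)
  expect_equal(evaluate_surface(s42, 5e6, 9e6), 42)

  # plane with four nonzero terms, checked against plain arithmetic
  b <- ref_row_surface("func_b")
  x <- 261725 / 1e6; y <- 35695 / 1e6
  by_hand <- 92.8758 * x * y + 0.1523 * x + 244.7267 * y + 0.4292
  expect_equal(evaluate_surface(b, 261725, 35695), by_hand)
  expect_equal(by_hand, 10.07, tolerance = 1e-3)

  # log-axis surface that dips negative inside the grid: clamping path
  e <- ref_row_surface("func_e")
  xe <- log(130862 / 1e6); ye <- 71389 / 1e6
  e_hand <- -2.0973 * xe^2 + 33.3526 * xe * ye + 2.0294 * ye^2 +
    12.8749 * xe + 181.6523 * ye + 18.8566
  expect_equal(evaluate_surface(e, 130862, 71389), e_hand)
  expect_lt(e_hand, 0)
  det <- evaluate_surface(e, 130862, 71389, detail = TRUE,
                          clamp_floor = 0.001)
  expect_equal(det$raw, e_hand)
  expect_equal(det$clamped, 0.001)
  expect_true(det$was_clamped)

  # purity: identical inputs, bit-identical outputs
  expect_identical(evaluate_surface(e, 130862, 71389),
                   evaluate_surface(e, 130862, 71389))
  expect_error(evaluate_surface(b, 0, 10), "must be >= 1")
})

test_that("noise-free grids round-trip through the fitter", {
  for (nm in names(ref_rows())) {
    r <- ref_rows()[[nm]]
    grid <- small_grid(ref_row_surface(nm))
    fit <- fit_surface(grid, x_transform = r$transform)
    expect_coefs_recovered(fit$surface$coefficients, r$c)
    expect_equal(fit$report$n_points, 90)
    expect_lt(fit$report$residual_sum_of_squares, 1e-12)
  }
  # constant surface: everything but the intercept fits to ~0
  grid <- small_grid(quadratic_surface(c(0, 0, 0, 0, 0, 5)))
  fit <- fit_surface(grid)
  expect_coefs_recovered(fit$surface$coefficients, c(0, 0, 0, 0, 0, 5))
})

test_that("round-trip recovery holds for randomized surfaces", {
  set.seed(42)
  for (trial in 1:20) {
    cf <- round(runif(6, -50, 50), 4)
    tr <- sample(c("identity", "log"), 1)
    s <- quadratic_surface(cf, tr)
    fit <- fit_surface(small_grid(s), x_transform = tr)
    expect_coefs_recovered(fit$surface$coefficients, cf,
                           rel_tol = 1e-8, abs_tol = 1e-7)
  }
})

test_that("replicates are averaged before fitting", {
  s <- ref_row_surface("func_c")
  grid <- small_grid(s)
  # add a replicate with symmetric offsets: mean equals the true value
  up <- grid; up$runtime_seconds <- up$runtime_seconds + 1; up$replicate <- 2
  dn <- grid; dn$runtime_seconds <- dn$runtime_seconds - 1; dn$replicate <- 3
  fit <- fit_surface(rbind(up, dn))
  expect_coefs_recovered(fit$surface$coefficients, ref_rows()$func_c$c)
})

test_that("fitting rejects deficient designs and mixed tables", {
  s <- ref_row_surface("func_b")
  few <- gen_measurements(s, database_sizes = c(1e4, 2e4),
                          query_sizes = c(1e4, 2e4))
  expect_error(fit_surface(few), ">= 6 distinct")
  # a single database size leaves the x-direction unidentifiable
  flat <- gen_measurements(s, database_sizes = 1e5,
                           query_sizes = default_query_sizes())
  expect_error(fit_surface(flat), "singular|deficient")
  mixed <- rbind(
    gen_measurements(s, node_type = "A"),
    gen_measurements(s, node_type = "B")
  )
  expect_error(fit_surface(mixed), "node_type")
})

test_that("predictions dispatch by model kind and thread factor", {
  cpm <- cpm_model(1000, node_type = "k")
  expect_equal(predict_runtime(cpm, 523449, 1), 523.449)

  # cpm and an equivalent plane agree: T = D / s <=> c4 = 1e6 / s
  plane <- quadratic_model(
    list(overall = quadratic_surface(c(0, 0, 0, 1e6 / 1000, 0, 0))))
  for (D in c(8179, 261725, 523449)) {
    expect_equal(predict_runtime(plane, D, 1000),
                 predict_runtime(cpm, D, 1000), tolerance = 1e-9)
  }

  # fpm: piecewise-constant speed, domain enforced
  fpm <- fpm_model(data.frame(size = c(1e4, 1e5, 1e6),
                              speed = c(500, 1000, 2000)))
  expect_equal(predict_runtime(fpm, 1e4, 1), 1e4 / 500)
  expect_equal(predict_runtime(fpm, 5e5, 1), 5e5 / 1000)
  expect_error(predict_runtime(fpm, 5e6, 1), "speed-table domain")

  # thread speed-up is a plain divisor; missing factors are an error
  m2 <- cpm_model(1000, thread_speedup = c("2" = 1.25))
  expect_equal(predict_runtime(m2, 1e5, 1, threads = 2),
               predict_runtime(m2, 1e5, 1) / 1.25)
  expect_error(predict_runtime(m2, 1e5, 1, threads = 4),
               "no thread speed-up factor")

  # quadratic_sum equals the sum of clamped per-component evaluations
  model <- quadratic_model(lapply(names(ref_rows()), ref_row_surface) |>
                             setNames(names(ref_rows())),
                           node_type = "V")
  per <- vapply(names(ref_rows()), function(nm) {
    max(evaluate_surface(ref_row_surface(nm), 261725, 35695), 0.001)
  }, numeric(1))
  expect_equal(predict_runtime(model, 261725, 35695), sum(per))
})

test_that("scale factors derive and apply exactly", {
  s <- ref_row_surface("func_c")
  ref <- gen_measurements(s, component = "func_c", node_type = "V")
  # identical grids: all factors one
  expect_equal(unname(derive_scale_factors(ref, ref)), 1)

  # a uniformly scaled grid returns its scale
  oth <- ref; oth$runtime_seconds <- oth$runtime_seconds * 1.4704
  expect_equal(unname(derive_scale_factors(ref, oth)), 1.4704)

  # randomized grids against a brute-force per-key ratio average
  set.seed(7)
  oth2 <- ref
  oth2$runtime_seconds <- oth2$runtime_seconds * runif(nrow(oth2), 0.5, 2)
  got <- derive_scale_factors(ref, oth2)
  brute <- mean(oth2$runtime_seconds / ref$runtime_seconds)
  expect_equal(unname(got), brute)

  expect_error(
    derive_scale_factors(ref, transform(ref, database_size = database_size + 1)),
    "no overlapping"
  )

  # scale_model: predictions scale exactly, per component
  model <- reference_model("V", query_set = NULL)
  fac <- node_type_factors("III")
  scaled <- scale_model(model, fac, node_type = "III")
  for (pt in list(c(8179, 17848), c(261725, 1142220))) {
    for (nm in names(model$components)) {
      expect_equal(
        evaluate_surface(scaled$components[[nm]], pt[1], pt[2]),
        fac[[nm]] * evaluate_surface(model$components[[nm]], pt[1], pt[2])
      )
    }
  }
  # identity and doubling
  ones <- setNames(rep(1, 5), names(model$components))
  expect_equal(predict_runtime(scale_model(model, ones), 1e5, 1e5),
               predict_runtime(model, 1e5, 1e5))
  one_comp <- quadratic_model(list(func_b = ref_row_surface("func_b")))
  dbl <- scale_model(one_comp, c(func_b = 2))
  set.seed(11)
  for (i in 1:10) {
    D <- sample(1e3:1e6, 1); Q <- sample(1e3:1e6, 1)
    expect_equal(predict_runtime(dbl, D, Q),
                 2 * predict_runtime(one_comp, D, Q))
  }
  expect_error(scale_model(model, c(func_a = 1)), "no scale factor")
})

test_that("monotonicity scan flags decreasing directions only", {
  expect_equal(nrow(check_monotonic(cpm_model(100), c(1e3, 1e6),
                                    c(1e3, 1e6))), 0)
  dec <- quadratic_model(
    list(overall = quadratic_surface(c(0, 0, 0, -1, 0, 100))))
  v <- check_monotonic(dec, c(1e4, 1e6), c(1e4, 1e6))
  expect_gt(nrow(v), 0)
  expect_true(all(v$axis == "database"))
  # the query-dominated plane is monotone over the profiled domain
  c_plane <- quadratic_model(list(func_c = ref_row_surface("func_c")))
  expect_equal(nrow(check_monotonic(c_plane, c(8e3, 262e3), c(18e3, 1.2e6))),
               0)
})

test_that("models survive a JSON round trip", {
  dir <- withr::local_tempdir()
  model <- reference_model("II", query_set = "A")
  path <- file.path(dir, "model.json")
  write_model(model, path)
  back <- read_model(path)
  expect_equal(back$node_type, "II")
  for (pt in list(c(8179, 17848), c(523449, 1142220))) {
    expect_equal(predict_runtime(back, pt[1], pt[2]),
                 predict_runtime(model, pt[1], pt[2]))
  }
  expect_equal(predict_runtime(back, 1e5, 1e5, threads = 2),
               predict_runtime(model, 1e5, 1e5, threads = 2))

  cpm <- cpm_model(123.4, node_type = "Z")
  write_model(cpm, path)
  expect_equal(predict_runtime(read_model(path), 1e5, 1),
               predict_runtime(cpm, 1e5, 1))
})

test_that("packaged reference data are consistent", {
  surfs <- reference_surfaces()
  expect_named(surfs, paste0("func_", letters[1:5]))
  for (nm in names(surfs)) {
    expect_equal(unname(surfs[[nm]]$coefficients), ref_rows()[[nm]]$c)
    expect_equal(surfs[[nm]]$x_transform, ref_rows()[[nm]]$transform)
  }
  fac <- node_type_factors()
  expect_equal(unname(unlist(fac["V", ])), rep(1, 5))
  expect_equal(fac["II", "func_c"], 1.4704)
  sp <- default_performance_factors()
  expect_equal(unname(sp["V"]), 1)
  expect_true(all(sp[c("II", "III", "IV")] < 1))  # slower types
  expect_equal(unname(thread_speedup_table("B")[["2"]]), 1.25)
})
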