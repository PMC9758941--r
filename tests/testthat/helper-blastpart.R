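# Frozen copies of the shipped reference coefficient rows (five core BLASTN
# functions on the reference node type). Tests freeze them independently of
# inst/extdata so an accidental edit of the packaged data is caught.
ref_rows <- function() {
  list(
    func_a = list(c = c(-3.0722, 143.6097, 3.7202, 22.4770, 881.6166,
                        30.0805), transform = "log"),
    func_b = list(c = c(0, 92.8758, 0, 0.1523, 244.7267, 0.4292),
                  transform = "identity"),
    func_c = list(c = c(0, 4429.4587, 0, 57.7969, 94.9201, 0.1854),
                  transform = "identity"),
    func_d = list(c = c(0, 19.2608, 0, -2.6282, 90.1090, 0.2345),
                  transform = "identity"),
    func_e = list(c = c(-2.0973, 33.3526, 2.0294, 12.8749, 181.6523,
                        18.8566), transform = "log")
  )
}

ref_row_surface <- function(name) {
  r <- ref_rows()[[name]]
  quadratic_surface(r$c, r$transform)
}

# coefficient comparison: relative for nonzero generator coefficients,
# absolute for exact zeros
expect_coefs_recovered <- function(fitted, truth, rel_tol = 1e-8,
                                   abs_tol = 1e-6) {
  nz <- truth != 0
  if (any(nz)) {
    expect_lt(max(abs(fitted[nz] - truth[nz]) / abs(truth[nz])), rel_tol)
  }
  if (any(!nz)) {
    expect_lt(max(abs(fitted[!nz])), abs_tol)
  }
}

# small helper grid for fast fits
small_grid <- function(surface, ...) {
  gen_measurements(surface,
                   database_sizes = default_database_sizes(),
                   query_sizes = default_query_sizes(), ...)
}
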