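test_that("srna_rate reproduces transcription-only and equilibrium values", {
  p <- srna_params(mu = 6.798)
  # only transcription acts at n = 0, for any amplification rate
  expect_equal(srna_rate(0, b_now = 0, p), 6.798)
  expect_equal(srna_rate(0, b_now = 1.7, p), 6.798)
  # b = 0 equilibrium at n = mu / d
  expect_equal(srna_rate(67.98, b_now = 0, p), 0, tolerance = 1e-12)
  expect_error(srna_rate(-1, 0, p), "must be >= 0")
  expect_error(srna_rate(1, -0.5, p), "must be >= 0")
})

test_that("steady state is the non-negative fixed point of the rate", {
  p <- srna_params(b = 0.5, mu = 6.798)
  nhat <- steady_state_level(p)
  # independent root-finding on the rate function
  root <- uniroot(function(n) srna_rate(n, p$b, p), c(1, 10 * 67.98),
                  tol = 1e-12)$root
  expect_equal(nhat, root, tolerance = 1e-8)
  expect_equal(nhat, 113.946, tolerance = 1e-4)
  expect_equal(srna_rate(nhat, p$b, p), 0, tolerance = 1e-10)
  # b = 0 limit and extinction without transcription
  expect_equal(steady_state_level(srna_params(mu = 6.798)), 67.98)
  expect_equal(steady_state_level(srna_params(b = 0.05, d = 0.1, mu = 0)), 0)
})

test_that("closed form solves the amplification-free dynamics exactly", {
  p <- srna_params(mu = 6.798)
  expect_equal(closed_form_b0(12, 0, p), 12)
  expect_equal(closed_form_b0(0, 1e6, p), 67.98)
  expect_equal(closed_form_b0(0, 20, p), 58.78, tolerance = 1e-4)
  expect_error(closed_form_b0(0, 1, srna_params(b = 0.2)), "requires b = 0")
})

test_that("adaptive integrator matches the closed form for b = 0", {
  p <- srna_params(mu = 6.798)
  for (n0 in c(0, 30, 120)) {
    tr <- integrate_generation(p, n0 = n0, c_div = 20)
    exact <- closed_form_b0(n0, 0:20, p)
    expect_equal(tr$n, exact, tolerance = 1e-8)
  }
})

test_that("adaptive integrator matches a fixed-step RK4 reference", {
  draws <- withr::with_seed(101, data.frame(
    b = runif(20, 0, 2), d = runif(20, 0.02, 0.5),
    m = runif(20, 1, 10), mu = runif(20, 0, 10),
    n0 = runif(20, 0, 100)))
  for (i in seq_len(nrow(draws))) {
    p <- srna_params(b = draws$b[i], d = draws$d[i], m = draws$m[i],
                     mu = draws$mu[i])
    tr <- integrate_generation(p, n0 = draws$n0[i], c_div = 10)
    ref <- rk4_reference(p, draws$n0[i], 10)
    expect_equal(tr$n, ref, tolerance = 1e-6)
  }
})

test_that("trajectories stay non-negative and approach the steady state monotonically", {
  p <- srna_params(b = 0.5, mu = 6.798)
  nhat <- steady_state_level(p)
  up <- integrate_generation(p, n0 = 0, c_div = 20)
  expect_true(all(diff(up$n) > 0))
  expect_true(all(up$n >= 0))
  expect_true(all(up$n <= nhat))
  down <- integrate_generation(p, n0 = 2 * nhat, c_div = 20)
  expect_true(all(diff(down$n) < 0))
  expect_true(all(down$n >= nhat))
  # starting at the fixed point, the trajectory is flat
  flat <- integrate_generation(p, n0 = nhat, c_div = 20)
  expect_equal(flat$n, rep(nhat, 21), tolerance = 1e-8)
})

test_that("speed scaling compresses time without moving the steady state", {
  base <- srna_params(b = 0.3, mu = 6.798)
  for (f in c(0.75, 2)) {
    scaled <- srna_params(b = 0.3, mu = 6.798, speed = f)
    expect_equal(steady_state_level(scaled), steady_state_level(base))
    # n(t; f) = n_unscaled(f * t) for constant b
    tt <- seq(0, 12, by = 0.75)
    tr_s <- integrate_generation(scaled, n0 = 0, c_div = 12, times = tt)
    tr_u <- integrate_generation(base, n0 = 0, c_div = 12 * f,
                                 times = f * tt)
    expect_equal(tr_s$n, tr_u$n, tolerance = 1e-7)
  }
})

test_that("parametric and function-valued amplification profiles agree", {
  p <- srna_params(mu = 6.798)
  prof <- b_profile(0.05, delta = 0.4, a = 0.15)
  tr1 <- integrate_generation(p, n0 = 0, c_div = 20, b_prof = prof)
  tr2 <- integrate_generation(p, n0 = 0, c_div = 20,
                              b_prof = function(t) profile_value(prof, t))
  expect_equal(tr1$n, tr2$n, tolerance = 1e-7)
  expect_equal(tr1$b_soma, tr2$b_soma)
})

test_that("integration inputs are validated", {
  p <- srna_params()
  expect_error(integrate_generation(p, n0 = -1), "must be >= 0")
  expect_error(integrate_generation(p, n0 = 0, c_div = 0), "positive integer")
  expect_error(integrate_generation(p, n0 = 0, c_div = 20,
                                    times = c(1, 2, 20)),
               "must start at 0")
  expect_error(integrate_generation(p, n0 = 0,
                                    b_prof = function(t) -1),
               "must be >= 0")
})

test_that("trajectories export to TSV with their three columns", {
  tr <- integrate_generation(srna_params(), n0 = 0, c_div = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(tr, path)
  back <- read.delim(path)
  expect_named(back, c("t", "n", "b_soma"))
  expect_equal(back$n, tr$n, tolerance = 1e-10)
})
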