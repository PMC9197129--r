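test_that("parameter domain is validated", {
  expect_error(ddm_params(a = 0), "must be > 0")
  expect_error(ddm_params(a = 1, z = 0), "\\(0, 1\\)")
  expect_error(ddm_params(a = 1, z = 1), "\\(0, 1\\)")
  expect_error(ddm_params(a = 1, t0 = -0.1), ">= 0")
  expect_error(ddm_params(a = 1, sv = -1), ">= 0")
  expect_error(wiener_pdf(0, "lower", ddm_params(a = 1)), "positive")
  expect_error(wiener_pdf(-1, "lower", ddm_params(a = 1)), "positive")
})

test_that("density vanishes up to the non-decision time", {
  p <- ddm_params(a = 2, z = 0.5, t0 = 0.3, v = -2)
  expect_identical(wiener_pdf(0.3, "lower", p), 0)   # t = t0 exactly
  expect_identical(wiener_pdf(0.1, "upper", p), 0)
  expect_gt(wiener_pdf(0.35, "lower", p), 0)
})

test_that("reflection symmetry: lower(v, z) equals upper(-v, 1 - z)", {
  tt <- c(0.05, 0.2, 0.5, 1, 3, 8)
  for (v in c(-2, -0.5, 0, 1.5)) {
    for (z in c(0.3, 0.5, 0.7)) {
      f1 <- wiener_pdf(tt, "lower", ddm_params(a = 1.6, z = z, v = v))
      f2 <- wiener_pdf(tt, "upper", ddm_params(a = 1.6, z = 1 - z, v = -v))
      expect_equal(f1, f2, tolerance = 1e-12)
    }
  }
})

test_that("defective densities integrate to the closed-form choice probabilities", {
  for (v in c(-2, 0, 1)) {
    for (a in c(1, 2.5)) {
      for (z in c(0.35, 0.5)) {
        p <- ddm_params(a = a, z = z, v = v)
        lo <- integrate(function(t) wiener_pdf(t, "lower", p), 0, Inf,
                        rel.tol = 1e-10, abs.tol = 1e-13)$value
        hi <- integrate(function(t) wiener_pdf(t, "upper", p), 0, Inf,
                        rel.tol = 1e-10, abs.tol = 1e-13)$value
        expect_equal(lo, p_lower_oracle(v, a, z), tolerance = 1e-6)
        expect_equal(lo + hi, 1, tolerance = 1e-6)
        expect_equal(wiener_choice_prob("lower", p),
                     p_lower_oracle(v, a, z), tolerance = 1e-10)
      }
    }
  }
})

test_that("strong positive drift rarely absorbs at the lower boundary", {
  p <- wiener_choice_prob("lower", ddm_params(a = 2, z = 0.5, v = 5))
  expect_lt(p, 0.01)
})

test_that("time-shift: t0 only translates the density", {
  p0 <- ddm_params(a = 1.3, z = 0.6, t0 = 0, v = 1.2)
  p1 <- ddm_params(a = 1.3, z = 0.6, t0 = 0.25, v = 1.2)
  tt <- c(0.1, 0.4, 1, 2)
  expect_equal(wiener_pdf(tt + 0.25, "upper", p1),
               wiener_pdf(tt, "upper", p0), tolerance = 1e-14)
})

test_that("sv marginal agrees with brute-force quadrature over the drift", {
  p_sv <- ddm_params(a = 2, z = 0.4, t0 = 0.2, v = -1, sv = 0.8)
  tgrid <- c(0.25, 0.4, 0.8, 1.5, 3, 6)
  f_marg <- wiener_pdf(tgrid, "lower", p_sv)
  f_num <- vapply(tgrid, function(t) {
    integrate(function(u) {
      vapply(u, function(ui)
        wiener_pdf(t, "lower", ddm_params(a = 2, z = 0.4, t0 = 0.2, v = ui)),
        numeric(1)) * dnorm(u, -1, 0.8)
    }, -1 - 8 * 0.8, -1 + 8 * 0.8, rel.tol = 1e-10)$value
  }, numeric(1))
  expect_equal(f_marg, f_num, tolerance = 1e-5)
  # sv choice probability marginalises the closed form
  p_num <- integrate(function(u) {
    vapply(u, function(ui) p_lower_oracle(ui, 2, 0.4), numeric(1)) *
      dnorm(u, -1, 0.8)
  }, -9, 7, rel.tol = 1e-10)$value
  expect_equal(wiener_choice_prob("lower", p_sv), p_num, tolerance = 1e-7)
})

test_that("simulator respects its contracts", {
  p <- ddm_params(a = 2, z = 0.5, t0 = 0.3, v = -2)
  expect_error(simulate_wiener(p, 10, seed = 1, max_t = 0.2),
               "exceed the non-decision time")
  sim <- simulate_wiener(p, 500, seed = 4, max_t = 5)
  expect_true(all(sim$rt > p$t0 & sim$rt <= 5))
  expect_identical(sim, simulate_wiener(p, 500, seed = 4, max_t = 5))
  expect_false(identical(sim, simulate_wiener(p, 500, seed = 5, max_t = 5)))
  # a tight window censors and carries rt = max_t
  sim2 <- simulate_wiener(ddm_params(a = 3, z = 0.5, t0 = 0.3, v = 0), 200,
                          seed = 6, max_t = 0.5)
  expect_true(any(sim2$censored))
  expect_true(all(sim2$rt[sim2$censored] == 0.5))
  expect_true(all(is.na(sim2$boundary[sim2$censored])))
})

test_that("simulated choice fractions match the closed form", {
  # symmetric process
  sim <- simulate_wiener(ddm_params(a = 1, z = 0.5, v = 0), 4000, seed = 8,
                         max_t = 30, dt = 2e-4)
  se <- sqrt(0.25 / 4000)
  expect_lt(abs(mean(sim$boundary == "lower") - 0.5), 3 * se)
  # drifting process against the closed-form oracle (0.9820 here)
  p <- ddm_params(a = 2, z = 0.5, t0 = 0.3, v = -2)
  target <- p_lower_oracle(-2, 2, 0.5)
  sim2 <- simulate_wiener(p, 20000, seed = 9, max_t = 30)
  frac <- mean(sim2$boundary == "lower")
  expect_lt(abs(frac - target), 3 * sqrt(target * (1 - target) / 20000) + 5e-4)
})
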