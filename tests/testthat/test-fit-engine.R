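test_that("preprocessing applies the censor, floor and log-IQR rules", {
  # identical RTs: zero-width fences keep the point mass
  tr <- tiny_trials(rep(0.6, 20), rep("lower", 20))
  pp <- preprocess_trials(tr)
  expect_identical(nrow(pp$trials), 20L)
  expect_identical(pp$report$n_iqr[1], 0L)

  # a 100 ms response falls below the 200 ms floor
  tr2 <- tiny_trials(c(rep(0.6, 19), 0.1), rep("lower", 20))
  pp2 <- preprocess_trials(tr2)
  expect_identical(pp2$report$n_fast[1], 1L)
  expect_identical(nrow(pp2$trials), 19L)

  # censored trials are dropped before any RT rule
  tr3 <- tiny_trials(c(rep(0.6, 18), 5, 5), rep("lower", 20))
  tr3$censored[19:20] <- TRUE
  pp3 <- preprocess_trials(tr3)
  expect_identical(pp3$report$n_censored[1], 2L)
  expect_identical(nrow(pp3$trials), 18L)
})

test_that("implanted slow outliers are removed exactly", {
  cohort <- simulate_cohort(n_ingroup = 1, n_equality = 0, master_seed = 21)
  tr <- cohort$trials[!cohort$trials$censored, ]
  idx <- c(5L, 60L, 150L, 280L)
  tr$rt[idx] <- 20 * median(tr$rt)
  pp <- preprocess_trials(tr)
  expect_identical(pp$report$n_iqr[1], 4L)
  expect_identical(nrow(pp$trials), nrow(tr) - 4L)
  expect_false(any(pp$trials$rt %in% tr$rt[idx]))
})

test_that("empty input yields an empty report with a warning", {
  expect_warning(pp <- preprocess_trials(NULL), "empty")
  expect_identical(nrow(pp$report), 0L)
})

test_that("the likelihood is the sum of per-trial log defective densities", {
  # five-trial hand-built fixture, term-by-term oracle via wiener_pdf()
  tr <- tiny_trials(rt = c(0.45, 0.62, 0.88, 1.2, 0.51),
                    boundary = c("lower", "lower", "upper", "lower", "upper"),
                    stim_type = c(1, 1, 2, 3, 3))
  theta <- c(a = 1.8, t0 = 0.3, v1 = -1.5, v2 = -0.8, v3 = -1.0, z = 0.45)
  m35 <- model_spec(35)
  oracle <- -sum(vapply(seq_len(nrow(tr)), function(i) {
    v <- theta[[paste0("v", tr$stim_type[i])]]
    log(wiener_pdf(tr$rt[i], tr$boundary[i],
                   ddm_params(a = 1.8, z = 0.45, t0 = 0.3, v = v)))
  }, numeric(1)))
  expect_equal(neg_loglik(m35, theta, tr), oracle, tolerance = 1e-10)

  # group-1 fixture: drift from the percent decomposition per trial
  m22 <- model_spec(22)
  theta22 <- c(a = 1.8, t0 = 0.3, b0 = 1.9, b1 = -2.8, b2 = -1.1, z = 0.45)
  v_tr <- drift_value(list(b0 = 1.9, b1 = -2.8, b2 = -1.1), tr, "percent")
  oracle22 <- -sum(vapply(seq_len(nrow(tr)), function(i) {
    log(wiener_pdf(tr$rt[i], tr$boundary[i],
                   ddm_params(a = 1.8, z = 0.45, t0 = 0.3, v = v_tr[i])))
  }, numeric(1)))
  expect_equal(neg_loglik(m22, theta22, tr), oracle22, tolerance = 1e-10)
})

test_that("likelihood contracts: nesting, trial removal, penalization", {
  kept <- quick_kept()
  tr <- kept[kept$subject == 1, ]
  # a single shared drift is nested in the type-varying-drift model:
  # equal per-type drifts reproduce the single-drift likelihood
  th31 <- c(a1 = 2, a2 = 2, a3 = 2, t0 = 0.25, v = -1.2, sv = 0)
  th35 <- c(a = 2, t0 = 0.25, v1 = -1.2, v2 = -1.2, v3 = -1.2, z = 0.5)
  expect_equal(neg_loglik(model_spec(31), th31, tr),
               neg_loglik(model_spec(35), th35, tr), tolerance = 1e-10)
  # removing trials can only lower the negative log-likelihood
  expect_lt(neg_loglik(model_spec(35), th35, tr[1:100, ]),
            neg_loglik(model_spec(35), th35, tr))
  # rt <= t0 is penalized, not raised
  th_bad <- c(a = 2, t0 = 4.9, v1 = -1, v2 = -1, v3 = -1, z = 0.5)
  expect_true(is.finite(neg_loglik(model_spec(35), th_bad, tr)))
  expect_gt(neg_loglik(model_spec(35), th_bad, tr), 1e4)
  # missing parameter names are rejected
  expect_error(neg_loglik(model_spec(35), th31, tr), "free parameters")
})

test_that("fitting is deterministic and satisfies the BIC identity", {
  kept <- quick_kept()
  tr <- kept[kept$subject == 2, ]
  f1 <- fit_subject(model_spec(34), tr, restarts = 3, seed = 7)
  f2 <- fit_subject(model_spec(34), tr, restarts = 3, seed = 7)
  expect_identical(f1, f2)
  expect_equal(f1$bic, f1$k * log(f1$n) - 2 * f1$loglik, tolerance = 1e-12)
  expect_identical(f1$k, model_k(model_spec(34)))
  expect_identical(f1$n, nrow(tr))
  expect_true(f1$converged)
})

test_that("duplicating every trial doubles the log-likelihood, not the estimates", {
  kept <- quick_kept()
  tr <- kept[kept$subject == 1, ]
  f1 <- fit_subject(model_spec(35), tr, restarts = 3, seed = 3)
  tr2 <- rbind(tr, tr)
  f2 <- fit_subject(model_spec(35), tr2, restarts = 3, seed = 3)
  expect_equal(f2$estimates, f1$estimates, tolerance = 0.02)
  expect_equal(f2$loglik, 2 * f1$loglik, tolerance = 0.005)
})

test_that("freeing the starting point can only improve the fit", {
  kept <- quick_kept()
  tr <- kept[kept$subject == 3, ]
  f_fix <- fit_subject(model_spec(36), tr, restarts = 4, seed = 5) # z fixed
  f_free <- fit_subject(model_spec(35), tr, restarts = 4, seed = 5) # z free
  expect_lte(f_fix$loglik, f_free$loglik + 1e-4)
})

test_that("selection picks the lowest mean BIC with the stated tie-breaks", {
  mk_fit <- function(id, bic, subject = 1, converged = TRUE) {
    spec <- model_spec(id)
    structure(list(subject = subject, model = spec, estimates = numeric(),
                   fixed = numeric(), loglik = (spec$k * log(100) - bic) / 2,
                   k = spec$k, n = 100L, bic = bic, converged = converged,
                   n_restarts_used = 1L), class = "ddm_fit")
  }
  # single candidate selects itself
  sel <- select_model(structure(list(mk_fit(35, 300)), class = "ddm_fit_list"))
  expect_identical(sel$selected$standard, 35L)
  # equal BIC: fewer parameters win (36 has k = 5, 35 has k = 6)
  sel2 <- select_model(structure(list(mk_fit(35, 300), mk_fit(36, 300)),
                                 class = "ddm_fit_list"))
  expect_identical(sel2$selected$standard, 36L)
  # cohort means decide, not single subjects
  fits <- structure(list(mk_fit(34, 290, 1), mk_fit(34, 310, 2),
                         mk_fit(35, 320, 1), mk_fit(35, 270, 2)),
                    class = "ddm_fit_list")
  sel3 <- select_model(fits)
  expect_identical(sel3$selected$standard, 35L)
  # non-converged fits are excluded with a warning; all-failed errors
  expect_warning(sel4 <- select_model(structure(
    list(mk_fit(34, 200, converged = FALSE), mk_fit(35, 300)),
    class = "ddm_fit_list")), "non-converged")
  expect_identical(sel4$selected$standard, 35L)
  expect_error(suppressWarnings(select_model(structure(
    list(mk_fit(34, 200, converged = FALSE)), class = "ddm_fit_list"))),
    "no converged")
})
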