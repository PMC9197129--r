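test_that("the strategy rule splits at 50% type-2 compliance, inclusive", {
  mk <- function(subject, frac, n = 50) {
    n_low <- round(frac * n)
    tiny_trials(rep(0.6, n), c(rep("lower", n_low), rep("upper", n - n_low)),
                stim_type = rep(2, n), subject = subject)
  }
  trials <- rbind(mk(1, 0.5), mk(2, 0.52), mk(3, 0.1), mk(4, 1.0))
  cls <- classify_subjects(trials)
  expect_identical(cls$strategy,
                   c("equality_driven", "ingroup_driven", "equality_driven",
                     "ingroup_driven"))
  expect_equal(cls$frac_type2, c(0.5, 0.52, 0.1, 1.0))
})

test_that("classification ignores trial order and non-type-2 trials", {
  base <- tiny_trials(rep(0.6, 40),
                      c(rep("lower", 10), rep("upper", 30)),
                      stim_type = rep(2, 40))
  pad <- tiny_trials(rep(0.7, 30), rep("lower", 30),
                     stim_type = rep(c(1, 3), 15))
  with_pad <- rbind(base, pad)
  shuffled <- with_pad[rev(seq_len(nrow(with_pad))), ]
  expect_identical(classify_subjects(base)$strategy,
                   classify_subjects(with_pad)$strategy)
  expect_identical(classify_subjects(with_pad), classify_subjects(shuffled))
  # no type-2 trials: unclassified with a warning
  expect_warning(cls <- classify_subjects(pad), "no type-2")
  expect_true(is.na(cls$strategy))
})

test_that("behavioural summaries aggregate per subject first", {
  # two subjects with different all-compliant RT levels: the group mean of
  # per-subject means is unweighted even with unequal trial counts
  s1 <- tiny_trials(rep(0.5, 10), rep("lower", 10), stim_type = rep(1, 10),
                    subject = 1)
  s2 <- tiny_trials(rep(1.0, 40), rep("lower", 40), stim_type = rep(1, 40),
                    subject = 2)
  sm <- suppressWarnings(summarize_behavior(rbind(s1, s2)))
  row1 <- sm[sm$stim_type == 1, ]
  expect_equal(row1$p_compliant_mean, 1.0)
  expect_equal(row1$rt_comp_mean, 0.75)   # (0.5 + 1.0) / 2, not pooled
  # with labels, per-group blocks appear
  labels <- data.frame(subject = 1:2,
                       strategy = c("ingroup_driven", "equality_driven"))
  sm2 <- suppressWarnings(summarize_behavior(rbind(s1, s2), labels))
  expect_setequal(unique(sm2$group),
                  c("all participants", "ingroup_driven", "equality_driven"))
})

test_that("the synthetic cohort reproduces the expected compliance ordering", {
  kept <- quick_kept()
  cohort <- quick_cohort()
  labels <- cohort$agents[, c("subject", "strategy")]
  sm <- suppressWarnings(summarize_behavior(kept, labels))
  ing <- sm[sm$group == "ingroup_driven", ]
  expect_gt(ing$p_compliant_mean[ing$stim_type == 1],
            ing$p_compliant_mean[ing$stim_type == 3])
})

test_that("minimum detectable effect size behaves like noncentral-t power", {
  expect_equal(round(min_detectable_d(11, 0.05, 0.80), 2), 0.94)
  # monotone: decreasing in n and alpha, increasing in power
  ns <- c(5, 11, 20, 44)
  ds <- vapply(ns, min_detectable_d, numeric(1))
  expect_true(all(diff(ds) < 0))
  expect_lt(min_detectable_d(11, 0.10, 0.80), min_detectable_d(11, 0.01, 0.80))
  expect_gt(min_detectable_d(11, 0.05, 0.95), min_detectable_d(11, 0.05, 0.50))
  # noncentrality scales with sqrt(n): quadrupling n roughly halves d
  expect_equal(min_detectable_d(44) / min_detectable_d(11), 0.5,
               tolerance = 0.12)
  # as power approaches the significance level, any effect suffices
  expect_lt(min_detectable_d(11, 0.05, 0.051), 0.05)
  expect_error(min_detectable_d(1), "n >= 2")
})

test_that("quantile diagnostics are monotone, exceed t0, and self-consistent", {
  kept <- quick_kept()
  tr <- kept[kept$subject == 1, ]
  fit <- fit_subject(model_spec(35), tr, restarts = 3, seed = 23)
  gof <- quantile_gof(fit, tr)
  expect_true(all(c("stim_type", "prob", "observed", "predicted") %in%
                    names(gof)))
  t0_hat <- fit$estimates[["t0"]]
  expect_true(all(gof$predicted > t0_hat))
  expect_true(all(gof$observed > t0_hat))
  for (tp in unique(gof$stim_type)) {
    expect_true(all(diff(gof$predicted[gof$stim_type == tp]) > 0))
  }
  # simulated at the fitted parameters, observed and predicted agree through
  # the 0.7 quantile up to Monte-Carlo error
  mid <- gof[gof$prob <= 0.7, ]
  expect_lt(median(abs(mid$observed - mid$predicted)), 0.08)
  # group-1 fits produce mixture-based predictions with the same properties
  fit22 <- fit_subject(model_spec(22), tr, restarts = 3, seed = 24)
  gof22 <- quantile_gof(fit22, tr)
  expect_true(all(diff(gof22$predicted[gof22$stim_type == 1]) > 0))
  # non-converged fits are refused
  bad <- fit
  bad$converged <- FALSE
  expect_error(quantile_gof(bad, tr), "converged")
})
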