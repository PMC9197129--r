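#' Behavioural summary by stimulus type
#'
#' Per stimulus type: the proportion of ingroup-compliant choices and the
#' response-time statistics of compliant and non-compliant responses.  All
#' statistics are computed per subject first and then aggregated across
#' subjects (the subject is the unit of analysis): reported means and SDs
#' are of per-subject means, reported medians are means of per-subject
#' medians.  With strategy `labels`, the summary is additionally emitted per
#' strategy group.  A subject contributing no trials to a response category
#' within a type is omitted from that cell with a warning.
#'
#' @param trials preprocessed trial table (columns `subject`, `stim_type`,
#'   `boundary`, `rt`).
#' @param labels optional data.frame with `subject` and `strategy` columns
#'   (e.g. from [classify_subjects()]).
#' @return A data.frame with one row per (group, stimulus type):
#'   compliant-choice proportion mean/SD, and mean/SD/median RTs for
#'   compliant and non-compliant responses.
#' @examples
#' cohort <- simulate_cohort(n_ingroup = 3, n_equality = 1, master_seed = 1)
#' kept <- preprocess_trials(cohort$trials)$trials
#' summarize_behavior(kept)
#' @export
summarize_behavior <- function(trials, labels = NULL) {
  stopifnot(all(c("subject", "stim_type", "boundary", "rt") %in%
                  names(trials)))
  per_subject <- do.call(rbind, lapply(split(trials, trials$subject),
                                       function(tr) {
    do.call(rbind, lapply(sort(unique(tr$stim_type)), function(tp) {
      tt <- tr[tr$stim_type == tp, ]
      comp <- tt$rt[tt$boundary == "lower"]
      nonc <- tt$rt[tt$boundary == "upper"]
      if (length(comp) == 0L || length(nonc) == 0L)
        warning("subject ", tr$subject[1], ", type ", tp,
                ": a response category is empty; cell omitted")
      data.frame(
        subject = tr$subject[1], stim_type = tp,
        p_compliant = mean(tt$boundary == "lower"),
        rt_comp_mean = if (length(comp)) mean(comp) else NA_real_,
        rt_comp_median = if (length(comp)) median(comp) else NA_real_,
        rt_noncomp_mean = if (length(nonc)) mean(nonc) else NA_real_,
        rt_noncomp_median = if (length(nonc)) median(nonc) else NA_real_)
    }))
  }))
  groups <- list(`all participants` = unique(per_subject$subject))
  if (!is.null(labels)) {
    for (g in unique(labels$strategy))
      groups[[g]] <- labels$subject[labels$strategy == g]
  }
  out <- do.call(rbind, lapply(names(groups), function(g) {
    ps <- per_subject[per_subject$subject %in% groups[[g]], ]
    do.call(rbind, lapply(sort(unique(ps$stim_type)), function(tp) {
      pp <- ps[ps$stim_type == tp, ]
      m <- function(x) mean(x, na.rm = TRUE)
      s <- function(x) sd(x, na.rm = TRUE)
      data.frame(
        group = g, stim_type = tp, n_subjects = nrow(pp),
        p_compliant_mean = m(pp$p_compliant),
        p_compliant_sd = s(pp$p_compliant),
        rt_comp_mean = m(pp$rt_comp_mean), rt_comp_sd = s(pp$rt_comp_mean),
        rt_comp_median = m(pp$rt_comp_median),
        rt_noncomp_mean = m(pp$rt_noncomp_mean),
        rt_noncomp_sd = s(pp$rt_noncomp_mean),
        rt_noncomp_median = m(pp$rt_noncomp_median))
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Classify subjects as ingroup driven or equality driven
#'
#' The classification rule uses stimulus type 2 only, where following the
#' ingroup and choosing the near-equal option are mutually exclusive: a
#' subject whose ingroup-compliant fraction on type-2 trials is 50% or less
#' is labelled `"equality_driven"`, otherwise `"ingroup_driven"`.  Subjects
#' without type-2 trials are left unclassified (`NA`) with a warning.
#'
#' @param trials preprocessed trial table.
#' @return A data.frame with `subject`, `frac_type2` (compliant fraction on
#'   type 2) and `strategy`.
#' @examples
#' cohort <- simulate_cohort(n_ingroup = 2, n_equality = 2, master_seed = 1)
#' kept <- preprocess_trials(cohort$trials)$trials
#' classify_subjects(kept)
#' @export
classify_subjects <- function(trials) {
  stopifnot(all(c("subject", "stim_type", "boundary") %in% names(trials)))
  out <- do.call(rbind, lapply(split(trials, trials$subject), function(tr) {
    t2 <- tr[tr$stim_type == 2, ]
    if (nrow(t2) == 0L) {
      warning("subject ", tr$subject[1],
              " has no type-2 trials; unclassified")
      return(data.frame(subject = tr$subject[1], frac_type2 = NA_real_,
                        strategy = NA_character_))
    }
    frac <- mean(t2$boundary == "lower")
    data.frame(subject = tr$subject[1], frac_type2 = frac,
               strategy = if (frac <= 0.5) "equality_driven"
                          else "ingroup_driven")
  }))
  rownames(out) <- NULL
  out
}

#' Minimum detectable effect size of a paired t test
#'
#' Sensitivity power computation: the smallest Cohen's d that a two-sided
#' paired (one-sample) t test with `n` pairs detects at level `alpha` with
#' the target power.  Power is evaluated exactly under the noncentral t
#' distribution with `n - 1` degrees of freedom and noncentrality
#' `d * sqrt(n)`, and inverted by root finding.
#'
#' @param n number of pairs, `>= 2`.
#' @param alpha two-sided significance level.
#' @param power target power.
#' @return The minimum detectable Cohen's d.
#' @examples
#' min_detectable_d(11, alpha = 0.05, power = 0.80)  # 0.94
#' @export
min_detectable_d <- function(n, alpha = 0.05, power = 0.80) {
  stopifnot(n >= 2, alpha > 0, alpha < 1, power > 0, power < 1)
  df <- n - 1
  crit <- qt(1 - alpha / 2, df)
  pow <- function(d) {
    ncp <- d * sqrt(n)
    pt(crit, df, ncp = ncp, lower.tail = FALSE) +
      pt(-crit, df, ncp = ncp)
  }
  if (power <= pow(0))
    return(0)
  if (pow(50) < power)
    stop("target power unattainable at this sample size", call. = FALSE)
  uniroot(function(d) pow(d) - power, c(1e-8, 50), tol = 1e-10)$root
}

# model-implied parameters per stimulus type from a fit
fit_params_by_type <- function(fit) {
  est <- c(fit$estimates, fit$fixed)
  spec <- fit$model
  get1 <- function(p, tp) {
    if (spec$group == "standard" && p %in% spec$varying)
      est[[paste0(p, tp)]]
    else est[[p]]
  }
  lapply(1:3, function(tp) list(
    a = get1("a", tp), t0 = get1("t0", tp), z = est[["z"]],
    sv = est[["sv"]],
    v = if (spec$group == "standard") get1("v", tp) else NULL))
}

#' Observed vs. model-predicted response-time quantiles
#'
#' Goodness-of-fit diagnostic for one subject's fit: for the
#' ingroup-compliant (lower boundary) responses of each stimulus type, the
#' observed RT quantiles and the quantiles predicted by the fitted model,
#' obtained by numerically inverting the fitted defective CDF normalized
#' within the compliant response.  For information-coupled (group 1) models
#' the predicted distribution is the mixture over the subject's trials of
#' that type, each with its own drift.
#'
#' @param fit a converged `ddm_fit`.
#' @param trials the (preprocessed) trials of the same subject.
#' @param probs quantile levels.
#' @param t_max upper limit of the inversion grid in seconds.
#' @return A data.frame with `stim_type`, `prob`, `observed`, `predicted`.
#' @export
quantile_gof <- function(fit, trials, probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                         t_max = 30) {
  stopifnot(inherits(fit, "ddm_fit"))
  if (!fit$converged)
    stop("quantile diagnostics require a converged fit", call. = FALSE)
  spec <- fit$model
  by_type <- fit_params_by_type(fit)
  est <- c(fit$estimates, fit$fixed)
  out <- list()
  for (tp in 1:3) {
    tt <- trials[trials$stim_type == tp, , drop = FALSE]
    comp <- tt$rt[tt$boundary == "lower"]
    if (length(comp) < 2L) next
    prm <- by_type[[tp]]
    grid_t <- seq(prm$t0 + 1e-9, t_max, length.out = 2048L)
    if (spec$group == "standard") {
      dens <- wiener_pdf_cpp(grid_t, prm$a, prm$z, prm$t0,
                             prm$v, prm$sv, TRUE, 1e-7)
    } else {
      v <- drift_value(list(b0 = est[["b0"]], b1 = est[["b1"]],
                            b2 = if (spec$uses_outgroup) est[["b2"]]),
                       tt, spec$info_kind)
      dens <- rowMeans(vapply(v, function(vi)
        wiener_pdf_cpp(grid_t, prm$a, prm$z, prm$t0, vi, prm$sv, TRUE, 1e-7),
        numeric(length(grid_t))))
    }
    cdf <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2 * diff(grid_t)))
    cdf <- cdf / cdf[length(cdf)]   # normalize within the compliant response
    pred <- approx(cdf, grid_t, xout = probs, ties = "ordered")$y
    out[[length(out) + 1L]] <- data.frame(
      stim_type = tp, prob = probs,
      observed = as.numeric(quantile(comp, probs, names = FALSE)),
      predicted = pred)
  }
  do.call(rbind, out)
}
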