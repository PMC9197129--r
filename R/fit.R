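# ---- likelihood -----------------------------------------------------------

# floor for defective densities inside the optimizer: invalid interior
# evaluations are penalized, never raised
DENS_FLOOR <- 1e-300

# precompute everything the objective needs from a preprocessed trial table
build_likelihood_data <- function(spec, trials) {
  stopifnot(all(c("rt", "boundary", "stim_type") %in% names(trials)))
  if (any(trials$censored))
    stop("likelihood data must not contain censored trials; run preprocess_trials() first",
         call. = FALSE)
  is_lower <- trials$boundary == "lower"
  dat <- list(rt = trials$rt, is_lower = is_lower,
              type = as.integer(trials$stim_type), n = nrow(trials),
              min_rt = min(trials$rt))
  if (spec$group == "info") {
    cov <- stimulus_covariates(trials, spec$info_kind)
    dat$X <- cbind(1, cov$ingr, if (spec$uses_outgroup) cov$outgr)
  } else {
    dat$by_type <- lapply(1:3, function(tp) {
      idx <- dat$type == tp
      list(rt = dat$rt[idx], is_lower = dat$is_lower[idx])
    })
  }
  dat
}

negll_eval <- function(theta, spec, dat, eps = 1e-7) {
  z <- if (spec$z_free) theta[["z"]] else 0.5
  sv <- if (spec$sv_free) theta[["sv"]] else 0
  out <- if (spec$group == "info") {
    beta <- theta[c("b0", "b1", if (spec$uses_outgroup) "b2")]
    v <- as.numeric(dat$X %*% beta)
    wiener_negll_cpp(dat$rt, dat$is_lower, theta[["a"]], z, theta[["t0"]],
                     v, sv, eps, DENS_FLOOR)
  } else {
    a <- if ("a" %in% spec$varying) theta[paste0("a", 1:3)] else rep(theta[["a"]], 3)
    t0 <- if ("t0" %in% spec$varying) theta[paste0("t0", 1:3)] else rep(theta[["t0"]], 3)
    v <- if ("v" %in% spec$varying) theta[paste0("v", 1:3)] else rep(theta[["v"]], 3)
    tot <- 0
    for (tp in 1:3) {
      blk <- dat$by_type[[tp]]
      if (length(blk$rt) == 0L) next
      tot <- tot + wiener_negll_cpp(blk$rt, blk$is_lower, a[[tp]], z,
                                    t0[[tp]], v[[tp]], sv, eps, DENS_FLOOR)
    }
    tot
  }
  if (!is.finite(out)) 1e10 else out
}

#' Negative log-likelihood of a model on preprocessed trials
#'
#' Sum of negative log defective densities over trials, with the drift per
#' trial given by the model: group-1 models derive it from the trial's
#' stimulus through the linear decomposition, group-2 models use the
#' stimulus-type-specific parameters.  Fixed parameters (`z = 0.5`,
#' `sv = 0`) are substituted per the specification.  Invalid interior
#' evaluations (e.g. `rt <= t0`) are penalized with a large finite value
#' rather than raising, as the optimizer requires.
#'
#' @param model a `ddm_model_spec` (see [model_spec()]).
#' @param theta named numeric vector covering `model_par_names` of the model.
#' @param trials preprocessed trial table (no censored rows).
#' @param eps density truncation error bound.
#' @return A single number.
#' @examples
#' cohort <- simulate_cohort(n_ingroup = 1, n_equality = 0, master_seed = 1)
#' kept <- preprocess_trials(cohort$trials)$trials
#' m <- model_spec(35)
#' neg_loglik(m, c(a = 2, t0 = 0.3, v1 = -2, v2 = -1.6, v3 = -0.9, z = 0.5),
#'            kept)
#' @export
neg_loglik <- function(model, theta, trials, eps = 1e-7) {
  nm <- model_par_names(model)
  if (!all(nm %in% names(theta)))
    stop("theta must name all free parameters: ",
         paste(nm, collapse = ", "), call. = FALSE)
  dat <- build_likelihood_data(model, trials)
  negll_eval(theta[nm], model, dat, eps)
}

# ---- fitting --------------------------------------------------------------

# box constraints for the optimizer; t0 is bounded above by the fastest kept
# response, as the likelihood requires
par_bounds <- function(spec, min_rt) {
  nm <- model_par_names(spec)
  lower <- upper <- setNames(numeric(length(nm)), nm)
  for (p in nm) {
    if (grepl("^a", p)) { lower[p] <- 0.3; upper[p] <- 5 }
    else if (grepl("^t0", p)) { lower[p] <- 0.05; upper[p] <- max(min_rt - 0.01, 0.051) }
    else if (p == "z") { lower[p] <- 0.05; upper[p] <- 0.95 }
    else if (p == "sv") { lower[p] <- 0; upper[p] <- 5 }
    else { lower[p] <- -20; upper[p] <- 20 } # drift rates and drift weights
  }
  list(lower = lower, upper = upper)
}

# one heuristic start plus seeded uniform draws; drift-like parameters are
# drawn from a moderate range so random restarts begin on a usable
# likelihood surface
start_values <- function(spec, bounds, restarts, seed, min_rt) {
  nm <- names(bounds$lower)
  heuristic <- setNames(numeric(length(nm)), nm)
  for (p in nm) {
    heuristic[p] <-
      if (grepl("^a", p)) 1.5
      else if (grepl("^t0", p)) 0.9 * min_rt
      else if (p == "z") 0.5
      else if (p == "sv") 0.5
      else 0
  }
  starts <- list(heuristic)
  if (restarts > 1L) {
    draws <- with_seed(seed, {
      lapply(seq_len(restarts - 1L), function(i) {
        s <- setNames(numeric(length(nm)), nm)
        for (p in nm) {
          s[p] <- if (grepl("^(a|t0)", p) || p == "z")
            runif(1, bounds$lower[p], bounds$upper[p])
          else if (p == "sv") runif(1, 0, 2)
          else runif(1, -5, 5)
        }
        s
      })
    })
    starts <- c(starts, draws)
  }
  starts
}

#' Fit one model to one subject by maximum likelihood
#'
#' Bounded quasi-Newton minimisation (via [stats::nlminb]) of the negative
#' log-likelihood, from `restarts` start points: one heuristic start and
#' `restarts - 1` seeded uniform draws.  The best converged solution is
#' returned; if no start converges, the best penalized solution is returned
#' with `converged = FALSE`.
#'
#' @param model a `ddm_model_spec`.
#' @param trials preprocessed trial table for a single subject.
#' @param restarts number of optimizer starts.
#' @param seed integer seed for the random restarts.
#' @param eps density truncation error bound.
#'
#' @return An object of class `ddm_fit`: subject, model, named `estimates`,
#'   `loglik`, free-parameter count `k`, trial count `n`,
#'   `bic = k * log(n) - 2 * loglik`, `converged`, `n_restarts_used`.
#' @examples
#' cohort <- simulate_cohort(n_ingroup = 1, n_equality = 0, master_seed = 1)
#' kept <- preprocess_trials(cohort$trials)$trials
#' fit <- fit_subject(model_spec(35), kept, restarts = 2, seed = 1)
#' fit$bic
#' @export
fit_subject <- function(model, trials, restarts = 5, seed = 1, eps = 1e-7) {
  stopifnot(inherits(model, "ddm_model_spec"))
  if (length(unique(trials$subject)) > 1L)
    stop("fit_subject() expects trials from a single subject", call. = FALSE)
  n <- nrow(trials)
  if (n < 50L)
    warning("fewer than 50 trials; estimates may be unstable")
  dat <- build_likelihood_data(model, trials)
  bounds <- par_bounds(model, dat$min_rt)
  starts <- start_values(model, bounds, restarts, seed, dat$min_rt)
  best <- NULL
  best_conv <- NULL
  for (s in starts) {
    opt <- nlminb(s, negll_eval, spec = model, dat = dat, eps = eps,
                  lower = bounds$lower, upper = bounds$upper,
                  control = list(eval.max = 2000, iter.max = 500))
    if (is.null(best) || opt$objective < best$objective) best <- opt
    if (opt$convergence == 0 &&
        (is.null(best_conv) || opt$objective < best_conv$objective))
      best_conv <- opt
  }
  converged <- !is.null(best_conv)
  sol <- if (converged) best_conv else best
  est <- setNames(as.numeric(sol$par), names(bounds$lower))
  loglik <- -sol$objective
  structure(list(
    subject = trials$subject[1],
    model = model,
    estimates = est,
    fixed = c(if (!model$z_free) c(z = 0.5), if (!model$sv_free) c(sv = 0)),
    loglik = loglik,
    k = model$k,
    n = n,
    bic = model$k * log(n) - 2 * loglik,
    converged = converged,
    n_restarts_used = length(starts)
  ), class = "ddm_fit")
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf("Model %d fit, subject %s: loglik = %.3f, k = %d, n = %d, BIC = %.2f%s\n",
              x$model$id, as.character(x$subject), x$loglik, x$k, x$n, x$bic,
              if (x$converged) "" else " (NOT converged)"))
  print(round(x$estimates, 4))
  invisible(x)
}

#' Fit a set of models to every subject
#'
#' @param trials preprocessed trial table (column `subject` identifies
#'   subjects).
#' @param models list of `ddm_model_spec` objects or integer ids.
#' @param restarts,eps passed to [fit_subject()].
#' @param seed master seed; per-(subject, model) restart seeds are derived
#'   from it deterministically.
#' @return A list of `ddm_fit` objects (class `ddm_fit_list`).
#' @export
fit_cohort <- function(trials, models, restarts = 5, seed = 1, eps = 1e-7) {
  if (is.numeric(models)) models <- lapply(models, model_spec)
  subjects <- unique(trials$subject)
  seeds <- with_seed(seed, {
    matrix(sample.int(.Machine$integer.max - 1L,
                      length(subjects) * length(models)),
           nrow = length(subjects))
  })
  fits <- list()
  for (i in seq_along(subjects)) {
    tr <- trials[trials$subject == subjects[i], , drop = FALSE]
    for (j in seq_along(models)) {
      fits[[length(fits) + 1L]] <-
        fit_subject(models[[j]], tr, restarts = restarts,
                    seed = seeds[i, j], eps = eps)
    }
  }
  structure(fits, class = "ddm_fit_list")
}

#' Tabulate fit results
#'
#' One row per (subject, model) with estimates, log-likelihood, `k`, `n`,
#' BIC and convergence — the serialization schema for fitted cohorts.
#'
#' @param fits a `ddm_fit_list` or list of `ddm_fit` objects.
#' @return A data.frame (estimate columns prefixed `est_`).
#' @export
fits_table <- function(fits) {
  all_par <- unique(unlist(lapply(fits, function(f) names(f$estimates))))
  do.call(rbind, lapply(fits, function(f) {
    est <- setNames(rep(NA_real_, length(all_par)), paste0("est_", all_par))
    est[paste0("est_", names(f$estimates))] <- f$estimates
    cbind(data.frame(subject = f$subject, model_id = f$model$id,
                     group = f$model$group, k = f$k, n = f$n,
                     loglik = f$loglik, bic = f$bic,
                     converged = f$converged,
                     n_restarts = f$n_restarts_used),
          as.data.frame(as.list(est)))
  }))
}

#' BIC-based model selection
#'
#' Selects, within each model group present, the model with the lowest BIC.
#' With several subjects per model, per-subject BICs are averaged first
#' (cohort-level selection).  Non-converged fits are excluded with a
#' warning; if nothing converged, selection fails.  Ties are broken by fewer
#' free parameters, then by lower model id.
#'
#' @param fits a `ddm_fit_list` (one subject or a cohort).
#' @return A list with `selected` (named list `info`/`standard` of winning
#'   model ids, `NULL` when a group is absent) and `table` (mean BIC per
#'   model).
#' @export
select_model <- function(fits) {
  conv <- vapply(fits, function(f) f$converged, logical(1))
  if (!all(conv)) {
    warning(sum(!conv), " non-converged fit(s) excluded from selection")
    fits <- fits[conv]
  }
  if (length(fits) == 0L)
    stop("no converged fits: cannot select a model", call. = FALSE)
  df <- data.frame(
    model_id = vapply(fits, function(f) f$model$id, integer(1)),
    group = vapply(fits, function(f) f$model$group, character(1)),
    k = vapply(fits, function(f) f$k, integer(1)),
    bic = vapply(fits, function(f) f$bic, numeric(1))
  )
  tab <- aggregate(bic ~ model_id + group + k, data = df, FUN = mean)
  names(tab)[names(tab) == "bic"] <- "mean_bic"
  tab$n_subjects <- aggregate(bic ~ model_id, data = df, FUN = length)$bic[
    match(tab$model_id, aggregate(bic ~ model_id, data = df, FUN = length)$model_id)]
  tab <- tab[order(tab$model_id), ]
  rownames(tab) <- NULL
  selected <- list(info = NULL, standard = NULL)
  for (g in unique(tab$group)) {
    sub <- tab[tab$group == g, ]
    sub <- sub[order(sub$mean_bic, sub$k, sub$model_id), ]
    selected[[g]] <- sub$model_id[1]
  }
  list(selected = selected, table = tab)
}
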