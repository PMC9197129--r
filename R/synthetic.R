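#' Default parameter boxes for the two agent strategies
#'
#' Simulated participants come in two behavioural strategies.  Ingroup-driven
#' agents drift toward the compliant boundary on all three stimulus types,
#' most strongly on type 1 (negative drifts with `|v1| >= |v2| >= |v3|`).
#' Equality-driven agents drift toward the non-compliant boundary on type 2
#' (where equality and conformity conflict, `v2 > 0`) and toward the
#' compliant boundary elsewhere.  Parameters are drawn uniformly from boxes
#' centred on the fitted subgroup point estimates of the type-varying-drift
#' model; the boxes are configuration, not hard-coded behaviour.
#'
#' @param strategy `"ingroup_driven"` or `"equality_driven"`.
#' @return A named list of `c(min, max)` ranges for `a`, `z`, `t0`, `v1`,
#'   `v2`, `v3`, and the fixed value `sv`.
#' @export
agent_boxes <- function(strategy = c("ingroup_driven", "equality_driven")) {
  strategy <- match.arg(strategy)
  common <- list(a = c(1.7, 2.3), z = c(0.42, 0.55), t0 = c(0.27, 0.40),
                 sv = 0)
  drifts <- if (strategy == "ingroup_driven") {
    list(v1 = c(-2.4, -1.6), v2 = c(-2.0, -1.2), v3 = c(-1.3, -0.5))
  } else {
    list(v1 = c(-0.8, 0.0), v2 = c(0.6, 1.4), v3 = c(-1.6, -0.8))
  }
  c(common, drifts)
}

#' Create a simulated participant
#'
#' Draws one agent's diffusion parameters uniformly within the
#' strategy-specific boxes (see [agent_boxes()]).  `a`, `z`, `t0` and `sv`
#' are shared across stimulus types; the drift is type-specific.  For
#' ingroup-driven agents the three drawn drift magnitudes are ordered so
#' that `|v1| >= |v2| >= |v3|` (all negative).
#'
#' @param strategy `"ingroup_driven"` or `"equality_driven"`.
#' @param seed integer seed (required; same seed, same agent).
#' @param boxes parameter boxes, defaulting to [agent_boxes()] for the
#'   strategy.
#' @param sv across-trial drift SD used in generation (default 0).
#'
#' @return An object of class `ddm_agent`: strategy, seed, and
#'   `params_by_type` (a list of three [ddm_params]).
#' @examples
#' make_agent("equality_driven", seed = 3)
#' @export
make_agent <- function(strategy = c("ingroup_driven", "equality_driven"),
                       seed, boxes = NULL, sv = NULL) {
  strategy <- match.arg(strategy)
  if (is.null(boxes)) boxes <- agent_boxes(strategy)
  if (is.null(sv)) sv <- boxes$sv %||% 0
  draw <- with_seed(seed, {
    u <- function(r) if (length(r) == 1L) r else runif(1, r[1], r[2])
    list(a = u(boxes$a), z = u(boxes$z), t0 = u(boxes$t0),
         v = c(u(boxes$v1), u(boxes$v2), u(boxes$v3)))
  })
  v <- draw$v
  if (strategy == "ingroup_driven") {
    # enforce the difficulty ordering: strongest pull on type 1
    v <- -sort(abs(v), decreasing = TRUE)
  }
  params_by_type <- lapply(1:3, function(tp) {
    ddm_params(a = draw$a, z = draw$z, t0 = draw$t0, v = v[tp], sv = sv)
  })
  structure(list(strategy = strategy, seed = as.integer(seed),
                 kind = "standard", params_by_type = params_by_type),
            class = "ddm_agent")
}

#' Create a simulated participant whose drift follows trial information
#'
#' Alternative agent whose per-trial drift is the linear decomposition
#' `v = b0 + b1 * ingrInfo + b2 * outgrInfo` for a given information coding,
#' with coefficients drawn uniformly from `coef_boxes`.  Used for
#' selection-recovery experiments where the generating model is a group-1
#' (information-coupled) variant.
#'
#' @param seed integer seed.
#' @param kind trial-information kind (default `"percent"`).
#' @param coef_boxes named list of `c(min, max)` ranges (or scalars) for
#'   `a`, `z`, `t0`, `b0`, `b1`, `b2`; defaults centre on the fitted
#'   percent-information model of the aggregated sample.
#' @param sv across-trial drift SD used in generation (default 0).
#' @return An object of class `ddm_agent` with `kind = "info"`.
#' @export
make_info_agent <- function(seed, kind = "percent", coef_boxes = NULL,
                            sv = 0) {
  if (is.null(coef_boxes)) {
    coef_boxes <- list(a = c(1.8, 2.2), z = c(0.44, 0.52),
                       t0 = c(0.28, 0.36), b0 = c(1.7, 2.1),
                       b1 = c(-3.1, -2.5), b2 = c(-1.3, -0.9))
  }
  draw <- with_seed(seed, {
    u <- function(r) if (length(r) == 1L) r else runif(1, r[1], r[2])
    lapply(coef_boxes, u)
  })
  structure(list(strategy = "info", seed = as.integer(seed), kind = "info",
                 info_kind = kind,
                 coeffs = list(b0 = draw$b0, b1 = draw$b1, b2 = draw$b2),
                 base = list(a = draw$a, z = draw$z, t0 = draw$t0, sv = sv)),
            class = "ddm_agent")
}

#' @export
print.ddm_agent <- function(x, ...) {
  if (x$kind == "standard") {
    v <- vapply(x$params_by_type, function(p) p$v, numeric(1))
    p <- x$params_by_type[[1]]
    cat(sprintf("%s agent (seed %d): a = %.3f, z = %.3f, t0 = %.3f, sv = %.2f, v = (%.2f, %.2f, %.2f)\n",
                x$strategy, x$seed, p$a, p$z, p$t0, p$sv, v[1], v[2], v[3]))
  } else {
    cat(sprintf("information-coupled agent (seed %d, %s): a = %.3f, z = %.3f, t0 = %.3f, b0 = %.2f, b1 = %.2f, b2 = %.2f\n",
                x$seed, x$info_kind, x$base$a, x$base$z, x$base$t0,
                x$coeffs$b0, x$coeffs$b1, x$coeffs$b2))
  }
  invisible(x)
}

#' Simulate one participant's session
#'
#' Runs the diffusion process once per trial of the session plan with the
#' agent's (type-specific or information-coupled) parameters, applies the
#' response window (timeouts are censored), and records the lower boundary
#' as the ingroup-compliant response.
#'
#' @param agent a `ddm_agent`.
#' @param session a session plan from [build_session()].
#' @param seed integer seed for the trial noise.
#' @param dt Euler step size in seconds.
#' @param contamination fraction of trials replaced by uniform fast guesses
#'   (response at chance, RT uniform on 0.05-0.195 s); exercises the outlier
#'   filters, default off.
#'
#' @return The session data.frame augmented with `boundary`
#'   (`"lower"`/`"upper"`/`NA`), `response_option` (`"A"`/`"B"`/`NA`), `rt`
#'   and `censored`.
#' @examples
#' agent <- make_agent("ingroup_driven", seed = 1)
#' trials <- simulate_subject(agent, build_session(seed = 2), seed = 3)
#' mean(trials$boundary == "lower", na.rm = TRUE)
#' @export
simulate_subject <- function(agent, session, seed, dt = 1e-4,
                             contamination = 0) {
  stopifnot(inherits(agent, "ddm_agent"))
  window <- attr(session, "response_window") %||% 5
  n <- nrow(session)
  out <- with_seed(seed, {
    boundary <- integer(n); rt <- numeric(n); censored <- logical(n)
    if (agent$kind == "standard") {
      for (tp in 1:3) {
        idx <- which(session$stim_type == tp)
        if (length(idx) == 0L) next
        p <- agent$params_by_type[[tp]]
        sim <- wiener_sim_cpp(length(idx), p$a, p$z, p$t0, p$v, p$sv, dt,
                              window)
        boundary[idx] <- sim$boundary; rt[idx] <- sim$rt
        censored[idx] <- sim$censored
      }
    } else {
      v <- drift_value(agent$coeffs, session, agent$info_kind)
      b <- agent$base
      sim <- wiener_sim_cpp(n, b$a, b$z, b$t0, v, b$sv, dt, window)
      boundary <- sim$boundary; rt <- sim$rt; censored <- sim$censored
    }
    if (contamination > 0) {
      guess <- runif(n) < contamination
      if (any(guess)) {
        boundary[guess] <- sample(0:1, sum(guess), replace = TRUE)
        rt[guess] <- runif(sum(guess), 0.05, 0.195)
        censored[guess] <- FALSE
      }
    }
    list(boundary = boundary, rt = rt, censored = censored)
  })
  trials <- session
  attr(trials, "response_window") <- window
  trials$boundary <- c("lower", "upper")[out$boundary + 1L]
  # lower boundary = compliant response, so the chosen option follows
  trials$response_option <- ifelse(
    is.na(trials$boundary), NA_character_,
    ifelse((trials$boundary == "lower") == (trials$compliant_option == "A"),
           "A", "B"))
  trials$rt <- out$rt
  trials$censored <- out$censored
  trials
}

#' Simulate a full synthetic cohort
#'
#' Generates a cohort of simulated participants in the default 28:11
#' ingroup-driven to equality-driven mix, each with their own randomized
#' session and seeded diffusion noise.  All per-subject seeds derive
#' deterministically from `master_seed`.
#'
#' @param n_ingroup number of ingroup-driven agents.
#' @param n_equality number of equality-driven agents.
#' @param master_seed integer master seed.
#' @param response_window response deadline in seconds.
#' @param dt Euler step size.
#' @param contamination fast-guess contamination rate (default off).
#' @param sv generative across-trial drift SD (default 0).
#'
#' @return A list of class `ddm_cohort`: `trials` (concatenated trial table
#'   with a `subject` column), `agents` (true parameters and strategy per
#'   subject) and `manifest` (seeds and configuration).
#' @examples
#' cohort <- simulate_cohort(n_ingroup = 2, n_equality = 1, master_seed = 1)
#' table(cohort$agents$strategy)
#' @export
simulate_cohort <- function(n_ingroup = 28, n_equality = 11, master_seed = 1,
                            response_window = 5, dt = 1e-4,
                            contamination = 0, sv = 0) {
  stopifnot(n_ingroup >= 0, n_equality >= 0, n_ingroup + n_equality >= 1)
  n <- n_ingroup + n_equality
  strategies <- rep(c("ingroup_driven", "equality_driven"),
                    c(n_ingroup, n_equality))
  seeds <- with_seed(master_seed,
                     matrix(sample.int(.Machine$integer.max - 1L, n * 3L),
                            nrow = n))
  trial_list <- vector("list", n)
  agent_rows <- vector("list", n)
  for (i in seq_len(n)) {
    agent <- make_agent(strategies[i], seed = seeds[i, 1], sv = sv)
    session <- build_session(seed = seeds[i, 2],
                             response_window = response_window)
    tr <- simulate_subject(agent, session, seed = seeds[i, 3], dt = dt,
                           contamination = contamination)
    tr <- cbind(subject = i, tr)
    trial_list[[i]] <- tr
    v <- vapply(agent$params_by_type, function(p) p$v, numeric(1))
    p1 <- agent$params_by_type[[1]]
    agent_rows[[i]] <- data.frame(
      subject = i, strategy = strategies[i], a = p1$a, z = p1$z, t0 = p1$t0,
      v1 = v[1], v2 = v[2], v3 = v[3], sv = p1$sv,
      agent_seed = seeds[i, 1], session_seed = seeds[i, 2],
      sim_seed = seeds[i, 3])
  }
  trials <- do.call(rbind, trial_list)
  attr(trials, "response_window") <- response_window
  structure(list(
    trials = trials,
    agents = do.call(rbind, agent_rows),
    manifest = list(master_seed = as.integer(master_seed),
                    n_ingroup = n_ingroup, n_equality = n_equality,
                    response_window = response_window, dt = dt,
                    contamination = contamination, sv = sv)
  ), class = "ddm_cohort")
}

#' @export
print.ddm_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects (%d ingroup-driven, %d equality-driven), %d trials\n",
              nrow(x$agents), x$manifest$n_ingroup, x$manifest$n_equality,
              nrow(x$trials)))
  invisible(x)
}

#' Parameter- and selection-recovery experiment
#'
#' Runs the full pipeline on data whose ground truth is known: simulate a
#' cohort under a generating model, preprocess, fit a candidate model set to
#' every subject, select by mean BIC, and score the strategy classifier
#' against the true agent labels.  When the generating model's
#' type-varying-drift specification (id 35) is among the candidates, a
#' parameter-recovery table (true vs. estimated per subject) is reported.
#'
#' @param generating `"standard"` (type-specific drifts; the agents of
#'   [make_agent()]) or `"info"` (percent-information coupled drifts; the
#'   agents of [make_info_agent()]).
#' @param n_ingroup,n_equality cohort composition (only `"standard"`
#'   generation distinguishes strategies; `"info"` generation uses
#'   `n_ingroup + n_equality` identical-strategy agents).
#' @param candidates integer vector of candidate model ids.
#' @param master_seed integer master seed.
#' @param restarts optimizer restarts per fit.
#' @param dt Euler step for generation.
#'
#' @return A list of class `ddm_recovery`: `selection` (mean-BIC table and
#'   winning ids), `recovery` (true vs. estimated parameters, or `NULL`),
#'   `classification` (labels and accuracy, or `NULL`), `fits`, and the
#'   cohort `manifest`.
#' @export
recovery_experiment <- function(generating = c("standard", "info"),
                                n_ingroup = 28, n_equality = 11,
                                candidates = c(34, 35, 46),
                                master_seed = 1, restarts = 5, dt = 1e-4) {
  generating <- match.arg(generating)
  n <- n_ingroup + n_equality
  if (generating == "standard") {
    cohort <- simulate_cohort(n_ingroup, n_equality,
                              master_seed = master_seed, dt = dt)
  } else {
    seeds <- with_seed(master_seed,
                       matrix(sample.int(.Machine$integer.max - 1L, n * 3L),
                              nrow = n))
    trial_list <- vector("list", n)
    for (i in seq_len(n)) {
      agent <- make_info_agent(seed = seeds[i, 1])
      session <- build_session(seed = seeds[i, 2])
      tr <- simulate_subject(agent, session, seed = seeds[i, 3], dt = dt)
      trial_list[[i]] <- cbind(subject = i, tr)
    }
    trials <- do.call(rbind, trial_list)
    attr(trials, "response_window") <- 5
    cohort <- list(trials = trials, agents = NULL,
                   manifest = list(master_seed = as.integer(master_seed),
                                   generating = "info", n = n))
  }
  pp <- preprocess_trials(cohort$trials)
  fits <- fit_cohort(pp$trials, candidates, restarts = restarts,
                     seed = master_seed)
  selection <- select_model(fits)

  recovery <- NULL
  if (generating == "standard" && 35 %in% candidates) {
    f35 <- Filter(function(f) f$model$id == 35, fits)
    est <- do.call(rbind, lapply(f35, function(f)
      data.frame(subject = f$subject, t(f$estimates))))
    truth <- cohort$agents[match(est$subject, cohort$agents$subject), ]
    recovery <- data.frame(
      subject = est$subject,
      true_a = truth$a, est_a = est$a,
      true_t0 = truth$t0, est_t0 = est$t0,
      true_z = truth$z, est_z = est$z,
      true_v1 = truth$v1, est_v1 = est$v1,
      true_v2 = truth$v2, est_v2 = est$v2,
      true_v3 = truth$v3, est_v3 = est$v3)
  }

  classification <- NULL
  if (generating == "standard") {
    cls <- classify_subjects(pp$trials)
    truth <- cohort$agents$strategy[match(cls$subject,
                                          cohort$agents$subject)]
    classification <- list(
      labels = cbind(cls, true_strategy = truth),
      accuracy = mean(cls$strategy == truth, na.rm = TRUE))
  }

  structure(list(selection = selection, recovery = recovery,
                 classification = classification, fits = fits,
                 manifest = cohort$manifest,
                 report = pp$report),
            class = "ddm_recovery")
}

#' @export
print.ddm_recovery <- function(x, ...) {
  cat("Recovery experiment\n")
  cat("  selected:",
      paste(names(Filter(Negate(is.null), x$selection$selected)),
            unlist(x$selection$selected), sep = " = ", collapse = ", "),
      "\n")
  if (!is.null(x$recovery)) {
    mae <- sapply(c("a", "t0", "z", "v1", "v2", "v3"), function(p)
      median(abs(x$recovery[[paste0("est_", p)]] -
                   x$recovery[[paste0("true_", p)]])))
    cat("  median |error|:",
        paste(names(mae), sprintf("%.3f", mae), sep = " = ",
              collapse = ", "), "\n")
  }
  if (!is.null(x$classification))
    cat(sprintf("  strategy classification accuracy: %.3f\n",
                x$classification$accuracy))
  invisible(x)
}
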