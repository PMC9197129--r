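#' Outlier handling for trial-level response times
#'
#' Cleans a trial table per subject before fitting: (i) censored trials
#' (no response within the window) are dropped; (ii) trials faster than
#' `min_rt` (default 200 ms) are dropped as anticipations; (iii) on the
#' log-transformed remaining response times, trials lying more than
#' `iqr_mult` (default 3) interquartile ranges outside the first and third
#' quartiles are dropped.  When the IQR is zero the fences collapse onto the
#' point mass and nothing is removed by rule (iii).
#'
#' @param trials data.frame with at least `subject`, `rt` and `censored`
#'   columns (the trial-table schema of [simulate_cohort()] /
#'   [read_trials()]).
#' @param min_rt fast-guess floor in seconds.
#' @param iqr_mult multiplier of the interquartile range for the log-RT
#'   fences.
#'
#' @return A list of class `ddm_preprocess` with elements `trials` (kept
#'   rows) and `report` (per-subject and overall removal counts and
#'   fractions).
#' @examples
#' cohort <- simulate_cohort(n_ingroup = 2, n_equality = 1, master_seed = 1)
#' pp <- preprocess_trials(cohort$trials)
#' pp$report
#' @export
preprocess_trials <- function(trials, min_rt = 0.2, iqr_mult = 3) {
  if (is.null(trials) || nrow(trials) == 0L) {
    warning("empty trial table: nothing to preprocess")
    return(structure(list(trials = trials,
                          report = data.frame()),
                     class = "ddm_preprocess"))
  }
  stopifnot(all(c("subject", "rt", "censored") %in% names(trials)))
  subjects <- unique(trials$subject)
  kept <- vector("list", length(subjects))
  rows <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    tr <- trials[trials$subject == subjects[i], , drop = FALSE]
    n_total <- nrow(tr)
    if (n_total < 10L)
      warning("subject ", subjects[i], " has fewer than 10 trials")
    tr1 <- tr[!tr$censored, , drop = FALSE]
    n_censored <- n_total - nrow(tr1)
    tr2 <- tr1[tr1$rt >= min_rt, , drop = FALSE]
    n_fast <- nrow(tr1) - nrow(tr2)
    n_iqr <- 0L
    tr3 <- tr2
    if (nrow(tr2) > 0L) {
      lrt <- log(tr2$rt)
      q <- quantile(lrt, c(0.25, 0.75), names = FALSE)
      iqr <- q[2] - q[1]
      ok <- lrt >= q[1] - iqr_mult * iqr & lrt <= q[2] + iqr_mult * iqr
      n_iqr <- sum(!ok)
      tr3 <- tr2[ok, , drop = FALSE]
    }
    kept[[i]] <- tr3
    rows[[i]] <- data.frame(
      subject = subjects[i], n_total = n_total, n_censored = n_censored,
      n_fast = n_fast, n_iqr = n_iqr, n_kept = nrow(tr3),
      frac_removed = (n_total - nrow(tr3)) / n_total
    )
  }
  report <- do.call(rbind, rows)
  overall <- data.frame(
    subject = "(overall)", n_total = sum(report$n_total),
    n_censored = sum(report$n_censored), n_fast = sum(report$n_fast),
    n_iqr = sum(report$n_iqr), n_kept = sum(report$n_kept),
    frac_removed = 1 - sum(report$n_kept) / sum(report$n_total)
  )
  structure(list(trials = do.call(rbind, kept),
                 report = rbind(report, overall)),
            class = "ddm_preprocess")
}

#' @export
print.ddm_preprocess <- function(x, ...) {
  n <- nrow(x$report)
  if (n == 0L) {
    cat("empty preprocessing result\n")
    return(invisible(x))
  }
  ov <- x$report[n, ]
  cat(sprintf(
    "Preprocessing: %d of %d trials kept (%.2f%% removed: %d censored, %d fast, %d log-RT outliers)\n",
    ov$n_kept, ov$n_total, 100 * ov$frac_removed, ov$n_censored, ov$n_fast,
    ov$n_iqr))
  invisible(x)
}
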