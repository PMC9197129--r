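#' Read and write trial tables
#'
#' Trial tables are serialized as UTF-8 tab-separated text with a header row
#' and '.' as the decimal mark.  The fixed column schema (one row per trial)
#' is: `subject`, `trial` (0-based), `block`, `block_label`, `delay`,
#' `stim_id`, `stim_type`, `mirrored`, `ing_A`, `ing_B`, `out_A`, `out_B`,
#' `compliant_option`, `equality_option`, `boundary`, `response_option`,
#' `rt`, `censored`.  Count cells are integers; `boundary` is
#' `lower`/`upper` and empty for censored trials.  The response window is
#' carried in a `#window:` comment line.
#'
#' @param trials a trial table (e.g. `simulate_cohort(...)$trials`).
#' @param path file path.
#' @return `write_trials` returns `path` invisibly; `read_trials` returns
#'   the trial data.frame with the response window restored as an attribute.
#' @examples
#' cohort <- simulate_cohort(n_ingroup = 1, n_equality = 0, master_seed = 1)
#' f <- tempfile(fileext = ".tsv")
#' write_trials(cohort$trials, f)
#' identical(dim(read_trials(f)), dim(cohort$trials))
#' @export
write_trials <- function(trials, path) {
  window <- attr(trials, "response_window") %||% 5
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("#window: %.6g", window), con)
  write.table(trials, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  first <- readLines(path, n = 1L)
  window <- if (startsWith(first, "#window:"))
    as.numeric(sub("#window:", "", first)) else 5
  out <- read.delim(path, comment.char = "#", na.strings = "",
                    stringsAsFactors = FALSE)
  if ("censored" %in% names(out)) out$censored <- as.logical(out$censored)
  if ("mirrored" %in% names(out)) out$mirrored <- as.logical(out$mirrored)
  attr(out, "response_window") <- window
  out
}

#' Write a generic delimited result table
#'
#' Convenience wrapper used by the command-line interface: UTF-8,
#' tab-separated, header row, no quoting, empty cells for `NA`.
#'
#' @param x a data.frame.
#' @param path file path.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "", fileEncoding = "UTF-8")
  invisible(path)
}
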