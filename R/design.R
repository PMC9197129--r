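#' The joint-evaluation stimulus design
#'
#' Builds the full factorial stimulus set of the charity-choice task.  Each
#' stimulus is a 2x2 table of donor counts: two charity options (columns) by
#' ingroup/outgroup (rows); each option's column fills to 100 donors.  Three
#' stimulus types vary how strongly the ingroup prefers one option, using
#' ingroup-count ranges (canonical orientation, option A first):
#' type 1 `[92, 98] x [12, 18]`, type 2 `[92, 98] x [52, 58]`,
#' type 3 `[52, 58] x [12, 18]`.  The 7 x 7 grid gives 49 canonical stimuli
#' per type; each is also emitted with the option columns swapped
#' (`mirrored = TRUE`), for 98 per type and 294 in total.
#'
#' Every stimulus carries two codings: `compliant_option`, the option with
#' the strictly larger ingroup/outgroup ratio (the ingroup-compliant
#' response), and `equality_option`, the option with the smaller absolute
#' difference between its ingroup and outgroup counts.  For type 3 the two
#' coincide; for type 2 they always differ; type 1 offers no near-equal
#' option but the minimiser is still reported.
#'
#' @param ranges optional list overriding the per-type ingroup-count ranges;
#'   a list of three lists, each with integer vectors `A` and `B`.  The
#'   default is the canonical design above.
#'
#' @return A data.frame with one row per presented stimulus and columns
#'   `stim_id`, `stim_type`, `mirrored`, `ing_A`, `ing_B`, `out_A`, `out_B`,
#'   `compliant_option`, `equality_option`.
#' @examples
#' stim <- generate_stimuli()
#' nrow(stim)                      # 294
#' table(stim$stim_type)           # 98 per type
#' @export
generate_stimuli <- function(ranges = NULL) {
  if (is.null(ranges)) {
    ranges <- list(list(A = 92:98, B = 12:18),
                   list(A = 92:98, B = 52:58),
                   list(A = 52:58, B = 12:18))
  }
  stopifnot(length(ranges) == 3L)
  out <- vector("list", 6L)
  k <- 0L
  for (type in 1:3) {
    grid <- expand.grid(ing_B = ranges[[type]]$B, ing_A = ranges[[type]]$A)
    canonical <- data.frame(
      stim_type = type,
      mirrored = FALSE,
      ing_A = grid$ing_A, ing_B = grid$ing_B,
      out_A = 100L - grid$ing_A, out_B = 100L - grid$ing_B
    )
    mirrored <- data.frame(
      stim_type = type,
      mirrored = TRUE,
      ing_A = canonical$ing_B, ing_B = canonical$ing_A,
      out_A = canonical$out_B, out_B = canonical$out_A
    )
    out[[k <- k + 1L]] <- canonical
    out[[k <- k + 1L]] <- mirrored
  }
  stim <- do.call(rbind, out)
  stim$stim_id <- seq_len(nrow(stim))
  stim$compliant_option <- code_compliance(stim)
  stim$equality_option <- code_equality(stim)
  stim[, c("stim_id", "stim_type", "mirrored", "ing_A", "ing_B",
           "out_A", "out_B", "compliant_option", "equality_option")]
}

#' Code the ingroup-compliant option of a stimulus
#'
#' The ingroup-compliant option is the one whose ingroup/outgroup donor
#' ratio is strictly larger.  Equal ratios cannot occur in the canonical
#' design and raise an error.
#'
#' @param stimulus a data.frame with columns `ing_A`, `ing_B`, `out_A`,
#'   `out_B` (one row per stimulus).
#' @return A character vector of `"A"`/`"B"`.
#' @examples
#' code_compliance(data.frame(ing_A = 95, ing_B = 13, out_A = 5, out_B = 87))
#' @export
code_compliance <- function(stimulus) {
  ratio_A <- stimulus$ing_A / stimulus$out_A
  ratio_B <- stimulus$ing_B / stimulus$out_B
  if (any(!is.finite(ratio_A) & !is.finite(ratio_B)) ||
      any(ratio_A == ratio_B))
    stop("tied ingroup/outgroup ratios: compliant option undefined",
         call. = FALSE)
  ifelse(ratio_A > ratio_B, "A", "B")
}

#' Code the equality option of a stimulus
#'
#' The equality option minimises the absolute difference between an option's
#' ingroup and outgroup donor counts.  Ties cannot occur in the canonical
#' design and raise an error.
#'
#' @inheritParams code_compliance
#' @return A character vector of `"A"`/`"B"`.
#' @examples
#' # 92/8 vs 54/46: the 54/46 option is the equality option
#' code_equality(data.frame(ing_A = 92, ing_B = 54, out_A = 8, out_B = 46))
#' @export
code_equality <- function(stimulus) {
  d_A <- abs(stimulus$ing_A - stimulus$out_A)
  d_B <- abs(stimulus$ing_B - stimulus$out_B)
  if (any(d_A == d_B))
    stop("tied ingroup-outgroup differences: equality option undefined",
         call. = FALSE)
  ifelse(d_A < d_B, "A", "B")
}

#' Assemble a randomized session plan
#'
#' Shuffles the 294 stimuli into a session of six 49-trial blocks.  Stimulus
#' types are interleaved: the whole stimulus list is shuffled and then cut
#' into blocks.  Block labels are the six charity categories in seeded random
#' order, and each trial receives an inter-trial delay drawn uniformly from
#' 0.2, 0.4 or 0.6 s.  The same seed reproduces the identical plan.
#'
#' @param seed integer seed (required).
#' @param stimuli stimulus table from [generate_stimuli()].
#' @param response_window response deadline in seconds.
#' @param categories character vector of block labels, one per block.
#'
#' @return A data.frame with one row per trial: `trial` (0-based index),
#'   `block`, `block_label`, `delay`, plus all stimulus columns.  The
#'   response window and seed are stored as attributes.
#' @examples
#' plan <- build_session(seed = 7)
#' table(plan$block)
#' @export
build_session <- function(seed, stimuli = generate_stimuli(),
                          response_window = 5,
                          categories = c("cancer", "disabled", "poverty",
                                         "medical", "elderly",
                                         "children's health")) {
  n <- nrow(stimuli)
  n_blocks <- length(categories)
  stopifnot(n %% n_blocks == 0L)
  plan <- with_seed(seed, {
    ord <- sample.int(n)
    labs <- sample(categories)
    delays <- sample(c(0.2, 0.4, 0.6), n, replace = TRUE)
    list(ord = ord, labs = labs, delays = delays)
  })
  out <- stimuli[plan$ord, , drop = FALSE]
  out$trial <- seq_len(n) - 1L
  out$block <- rep(seq_len(n_blocks), each = n / n_blocks)
  out$block_label <- plan$labs[out$block]
  out$delay <- plan$delays
  rownames(out) <- NULL
  out <- out[, c("trial", "block", "block_label", "delay",
                 names(stimuli))]
  attr(out, "response_window") <- response_window
  attr(out, "seed") <- as.integer(seed)
  out
}
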