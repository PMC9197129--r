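#' Trial-information codings
#'
#' Five ways of reducing one row of a stimulus table (the counts `A` and `B`
#' a group contributed to the two options) to a single covariate that can
#' inform the drift rate: `"diff"` = `A - B`, `"reldiff"` = `A / (A - B)`,
#' `"ratio"` = `A / B`, `"percent"` = `A / (A + B)`, and a dichotomous coding
#' (`"dichot"`), which is defined at the level of the whole 2x2 table and is
#' computed by [dichot_info()].
#'
#' @param kind one of `"diff"`, `"reldiff"`, `"ratio"`, `"percent"`.
#' @param A,B non-negative donor counts (vectorised).
#' @return Numeric vector of information values (unitless).
#' @examples
#' trial_info("ratio", 95, 13)    # 7.31 (to 2 dp)
#' trial_info("percent", 95, 13)  # 0.88 (to 2 dp)
#' @export
trial_info <- function(kind = c("diff", "reldiff", "ratio", "percent",
                                "dichot"), A, B) {
  kind <- match.arg(kind)
  if (kind == "dichot")
    stop("the dichotomous coding is table-level; use dichot_info()",
         call. = FALSE)
  stopifnot(is.numeric(A), is.numeric(B), length(A) == length(B))
  if (any(A < 0) || any(B < 0))
    stop("counts must be non-negative", call. = FALSE)
  bad <- function(cond) {
    i <- which(cond)[1]
    stop(sprintf("trial information '%s' undefined for cells A=%s, B=%s",
                 kind, A[i], B[i]), call. = FALSE)
  }
  switch(kind,
    diff = A - B,
    reldiff = { if (any(A == B)) bad(A == B); A / (A - B) },
    ratio = { if (any(B == 0)) bad(B == 0); A / B },
    percent = { if (any(A + B == 0)) bad(A + B == 0); A / (A + B) }
  )
}

#' Dichotomous trial information
#'
#' Table-level coding: the information is 1 if the largest cell of the 2x2
#' stimulus table (the plurality of donors) lies in the queried group's row,
#' else 0.  In the canonical design the maximum is never shared across rows;
#' a shared maximum raises an error.  The outgroup value is the complement of
#' the ingroup value.
#'
#' @param stimulus data.frame with columns `ing_A`, `ing_B`, `out_A`, `out_B`.
#' @param group `"ingroup"` or `"outgroup"`.
#' @return Integer vector of 0/1.
#' @examples
#' s <- data.frame(ing_A = 95, ing_B = 13, out_A = 5, out_B = 87)
#' dichot_info(s, "ingroup")
#' @export
dichot_info <- function(stimulus, group = c("ingroup", "outgroup")) {
  group <- match.arg(group)
  m_ing <- pmax(stimulus$ing_A, stimulus$ing_B)
  m_out <- pmax(stimulus$out_A, stimulus$out_B)
  if (any(m_ing == m_out))
    stop("maximum cell shared across rows: dichotomous coding undefined",
         call. = FALSE)
  ing <- as.integer(m_ing > m_out)
  if (group == "ingroup") ing else 1L - ing
}

# Per-trial drift covariates for a given information kind, oriented by the
# compliant option: within each row (ingroup, outgroup) the "A" cell of the
# information formula is the compliant option's count and "B" the other
# option's.  This orientation makes the drift weights comparable across
# trials regardless of presentation side.
stimulus_covariates <- function(stimulus, kind) {
  comp_A <- stimulus$compliant_option == "A"
  ing_c <- ifelse(comp_A, stimulus$ing_A, stimulus$ing_B)
  ing_o <- ifelse(comp_A, stimulus$ing_B, stimulus$ing_A)
  out_c <- ifelse(comp_A, stimulus$out_A, stimulus$out_B)
  out_o <- ifelse(comp_A, stimulus$out_B, stimulus$out_A)
  if (kind == "dichot") {
    ingr <- dichot_info(stimulus, "ingroup")
    outgr <- dichot_info(stimulus, "outgroup")
  } else {
    ingr <- trial_info(kind, ing_c, ing_o)
    outgr <- trial_info(kind, out_c, out_o)
  }
  data.frame(ingr = as.numeric(ingr), outgr = as.numeric(outgr))
}

#' Linear drift decomposition
#'
#' Computes the per-trial mean drift rate from a stimulus via the linear
#' decomposition `v = beta0 + beta1 * ingrInfo` (ingroup-only) or
#' `v = beta0 + beta1 * ingrInfo + beta2 * outgrInfo` (ingroup and
#' outgroup), where the information values are computed by `kind` on the
#' ingroup and outgroup rows, oriented by the compliant option (see
#' [trial_info()]).  With the `"percent"` coding, negative weights mean
#' evidence accumulation toward the lower (ingroup-compliant) boundary.
#'
#' @param coeffs list with `b0`, `b1` and optionally `b2`.
#' @param stimulus stimulus data.frame rows (see [generate_stimuli()]).
#' @param kind trial-information kind (including `"dichot"`).
#' @return Numeric vector of drift rates.
#' @examples
#' s <- generate_stimuli()[1, ]
#' drift_value(list(b0 = 1.92, b1 = -2.82, b2 = -1.11), s, "percent")
#' @export
drift_value <- function(coeffs, stimulus, kind) {
  stopifnot(!is.null(coeffs$b0), !is.null(coeffs$b1))
  cov <- stimulus_covariates(stimulus, kind)
  v <- coeffs$b0 + coeffs$b1 * cov$ingr
  if (!is.null(coeffs$b2)) v <- v + coeffs$b2 * cov$outgr
  v
}
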