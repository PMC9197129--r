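#' The 51-variant model space
#'
#' Enumerates the candidate drift-diffusion model variants in two groups.
#'
#' Group 1 ("info", ids 1-30) reformulates the drift as a linear function of
#' trial information: for each of the five information kinds (`diff`,
#' `reldiff`, `ratio`, `percent`, `dichot`, in that order) there are three
#' fixation schemes — (i) `z` fixed at 0.5 with `sv` free, (ii) `z` free with
#' `sv` fixed at 0, (iii) both fixed — each without (odd id) and with (even
#' id) the outgroup weight `beta2`.
#'
#' Group 2 ("standard", ids 31-51) is the standard model with parameters
#' varying over the three stimulus types: the varying subsets are, in order,
#' `a`; `v`; `t0`; `a+v`; `a+t0`; `t0+v`; `a+t0+v`, each under the same three
#' fixation schemes (plain id: `z` fixed / parenthesised: `sv` fixed /
#' bracketed: both fixed).
#'
#' @param group `"info"`, `"standard"`, or `"all"`.
#' @return A list of `ddm_model_spec` objects (class `ddm_model_space`).
#' @examples
#' length(model_space("info"))      # 30
#' length(model_space("standard"))  # 21
#' model_space("all")[[22]]
#' @export
model_space <- function(group = c("all", "info", "standard")) {
  group <- match.arg(group)
  schemes <- list(list(z_free = FALSE, sv_free = TRUE),
                  list(z_free = TRUE, sv_free = FALSE),
                  list(z_free = FALSE, sv_free = FALSE))
  specs <- list()
  id <- 0L
  if (group %in% c("all", "info")) {
    for (kind in c("diff", "reldiff", "ratio", "percent", "dichot")) {
      for (sch in schemes) {
        for (uses_outgroup in c(FALSE, TRUE)) {
          id <- id + 1L
          specs[[length(specs) + 1L]] <- new_model_spec(
            id = id, group = "info", info_kind = kind,
            uses_outgroup = uses_outgroup, varying = character(),
            z_free = sch$z_free, sv_free = sch$sv_free)
        }
      }
    }
  }
  if (group %in% c("all", "standard")) {
    id <- 30L
    varying_sets <- list("a", "v", "t0", c("a", "v"), c("a", "t0"),
                         c("t0", "v"), c("a", "t0", "v"))
    for (varying in varying_sets) {
      for (sch in schemes) {
        id <- id + 1L
        specs[[length(specs) + 1L]] <- new_model_spec(
          id = id, group = "standard", info_kind = NA_character_,
          uses_outgroup = FALSE, varying = varying,
          z_free = sch$z_free, sv_free = sch$sv_free)
      }
    }
  }
  structure(specs, class = "ddm_model_space")
}

new_model_spec <- function(id, group, info_kind, uses_outgroup, varying,
                           z_free, sv_free) {
  spec <- structure(
    list(id = id, group = group, info_kind = info_kind,
         uses_outgroup = uses_outgroup, varying = varying,
         z_free = z_free, sv_free = sv_free),
    class = "ddm_model_spec")
  spec$k <- model_k(spec)
  spec
}

#' Retrieve one model specification by id
#'
#' @param id integer in 1-51.
#' @return A `ddm_model_spec` object.
#' @examples
#' model_spec(35)
#' @export
model_spec <- function(id) {
  stopifnot(length(id) == 1L, id %in% 1:51)
  model_space("all")[[id]]
}

# names of the free parameters, in the order the optimizer sees them
model_par_names <- function(spec) {
  if (spec$group == "info") {
    nm <- c("a", "t0", "b0", "b1")
    if (spec$uses_outgroup) nm <- c(nm, "b2")
  } else {
    nm <- character()
    for (p in c("a", "t0", "v")) {
      nm <- c(nm, if (p %in% spec$varying) paste0(p, 1:3) else p)
    }
  }
  if (spec$z_free) nm <- c(nm, "z")
  if (spec$sv_free) nm <- c(nm, "sv")
  nm
}

#' Free-parameter count of a model specification
#'
#' Group-1 models count `a`, `t0`, `beta0`, `beta1`, plus `beta2`, `z` and
#' `sv` where free; group-2 models count `a`, `t0` and `v` (each tripled when
#' varying over stimulus types) plus `z` and `sv` where free.
#'
#' @param spec a `ddm_model_spec`.
#' @return Integer free-parameter count.
#' @export
model_k <- function(spec) {
  length(model_par_names(spec))
}

#' @export
print.ddm_model_spec <- function(x, ...) {
  if (x$group == "info") {
    cat(sprintf("Model %d (group 1): drift ~ %s information%s\n", x$id,
                x$info_kind,
                if (x$uses_outgroup) " (ingroup + outgroup)" else " (ingroup only)"))
  } else {
    cat(sprintf("Model %d (group 2): {%s} vary over stimulus types\n", x$id,
                paste(x$varying, collapse = ", ")))
  }
  cat(sprintf("  z %s, sv %s; %d free parameters: %s\n",
              if (x$z_free) "free" else "= 0.5",
              if (x$sv_free) "free" else "= 0",
              x$k, paste(model_par_names(x), collapse = ", ")))
  invisible(x)
}

#' Tabulate the model space
#'
#' Serializes a model space into a human-readable table: one row per model
#' with its id, group, free parameters, fixed parameters, varying subset and
#' information kind.
#'
#' @param specs a `ddm_model_space` (default: the full space).
#' @return A data.frame.
#' @examples
#' head(format_model_space())
#' @export
format_model_space <- function(specs = model_space("all")) {
  do.call(rbind, lapply(specs, function(s) {
    fixed <- c(if (!s$z_free) "z=0.5", if (!s$sv_free) "sv=0")
    data.frame(
      id = s$id,
      group = s$group,
      free = paste(model_par_names(s), collapse = ","),
      fixed = paste(fixed, collapse = ","),
      varying = paste(s$varying, collapse = "+"),
      info = ifelse(is.na(s$info_kind), "-", s$info_kind),
      k = s$k,
      stringsAsFactors = FALSE
    )
  }))
}
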