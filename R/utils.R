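# Internal helpers shared across modules.

# Scoped RNG: run `expr` under `seed` without disturbing the caller's RNG
# state; a NULL seed uses the current stream.
with_seed_or_current <- function(seed, expr) {
  if (is.null(seed)) {
    expr
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

# Coerce a population labeling to a named character vector covering `ids`.
# Accepts a data frame with (id, population) columns or a named vector.
as_labeling <- function(labeling, ids) {
  if (is.data.frame(labeling)) {
    cols <- intersect(c("id", "population"), names(labeling))
    if (length(cols) < 2L) {
      abort("`labeling` data frame must have columns `id` and `population`.")
    }
    lab <- stats::setNames(as.character(labeling$population),
                           as.character(labeling$id))
  } else if (!is.null(names(labeling))) {
    lab <- stats::setNames(as.character(labeling), names(labeling))
  } else {
    abort("`labeling` must be a data frame (id, population) or a named vector.")
  }
  if (anyDuplicated(names(lab))) {
    abort("`labeling` assigns more than one population to some ids.")
  }
  missing <- setdiff(ids, names(lab))
  if (length(missing) > 0L) {
    abort(paste0("`labeling` is missing ", length(missing),
                 " id(s), e.g. ", paste(head(missing, 3L), collapse = ", "), "."))
  }
  lab[ids]
}

# Stable unique population order: first appearance in the labeling.
population_levels <- function(lab) unique(unname(lab))

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}
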