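# Copying vectors: the proportion of an individual's (or population's)
# genome copied from each of K reference populations. Simplex-valued.

#' Copying vector of a single individual
#'
#' Element k is the share of recipient `id`'s copied chunks that came from
#' donors labeled with population k. The recipient's own zero diagonal
#' contributes nothing; no donor is excluded.
#'
#' @param counts A [chunkcounts] matrix.
#' @param id A recipient id present in `counts`.
#' @param labeling Population labeling of all donors: a data frame with
#'   columns `id` and `population`, or a named vector.
#' @return Named numeric vector over populations (first-appearance order),
#'   summing to 1.
#' @export
copying_vector <- function(counts, id, labeling) {
  ids <- rownames(counts)
  if (!id %in% ids) abort(paste0("unknown individual: ", id))
  lab <- as_labeling(labeling, ids)
  row <- unclass(counts)[id, ]
  tot <- sum(row)
  if (tot <= 0) abort(paste0("individual '", id, "' copied no chunks."))
  v <- vapply(population_levels(lab),
              function(p) sum(row[lab == p]) / tot, numeric(1))
  v
}

# All individual copying vectors at once, as an n x K matrix (rows sum to 1).
copying_matrix <- function(counts, labeling) {
  ids <- rownames(counts)
  lab <- as_labeling(labeling, ids)
  pops <- population_levels(lab)
  agg <- vapply(pops, function(p) {
    rowSums(unclass(counts)[, lab == p, drop = FALSE])
  }, numeric(length(ids)))
  tot <- rowSums(agg)
  zero <- tot <= 0
  if (any(zero)) {
    abort(paste0("individual(s) with zero copied chunks: ",
                 paste(head(ids[zero], 3L), collapse = ", ")))
  }
  m <- agg / tot
  dimnames(m) <- list(ids, pops)
  m
}

#' Per-individual copying vectors as a tibble
#'
#' @inheritParams copying_vector
#' @return A tibble with column `id` and one proportion column per
#'   reference population; each row sums to 1.
#' @export
copying_profiles <- function(counts, labeling) {
  m <- copying_matrix(counts, labeling)
  dplyr::bind_cols(tibble::tibble(id = rownames(m)), tibble::as_tibble(m))
}

#' Population copying vector
#'
#' The copying vector of a population is the unweighted mean over the
#' copying vectors of its member individuals.
#'
#' @inheritParams copying_vector
#' @param population A population label occurring in `labeling`.
#' @return Named numeric vector over populations, summing to 1.
#' @export
population_copying_vector <- function(counts, labeling, population) {
  lab <- as_labeling(labeling, rownames(counts))
  members <- names(lab)[lab == population]
  if (length(members) == 0L) {
    abort(paste0("population '", population, "' has no members."))
  }
  m <- copying_matrix(counts, labeling)
  colMeans(m[members, , drop = FALSE])
}

#' Copying profiles of all populations
#'
#' @inheritParams copying_vector
#' @param reference_labeling Labeling defining the K reference
#'   populations the copying vectors are expressed against; defaults to
#'   `labeling` itself, but may be finer or coarser (the TVD-tree
#'   robustness check varies it independently of the populations being
#'   profiled).
#' @return A tibble with column `population` and one proportion column per
#'   reference population (the K-dimensional population copying vectors).
#' @export
population_profiles <- function(counts, labeling,
                                reference_labeling = labeling) {
  lab <- as_labeling(labeling, rownames(counts))
  m <- copying_matrix(counts, reference_labeling)
  pops <- population_levels(lab)
  prof <- t(vapply(pops, function(p) {
    colMeans(m[names(lab)[lab == p], , drop = FALSE])
  }, numeric(ncol(m))))
  dplyr::bind_cols(tibble::tibble(population = pops), tibble::as_tibble(prof))
}
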