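# PCA on the coancestry matrix, via the transform of Lawson et al.'s
# chromosome-painting framework: set each diagonal entry to its column
# sum, centre columns, and symmetrise by multiplying with the transpose.

#' Coancestry-matrix PCA transform
#'
#' Three steps, in order: (1) replace each diagonal entry with that
#' column's sum; (2) subtract each column's mean (computed after step 1)
#' from its elements; (3) return `X %*% t(X)`, symmetric and positive
#' semidefinite by construction.
#'
#' @param counts A [chunkcounts] matrix.
#' @return A symmetric n x n numeric matrix with the individual ids as
#'   dimnames.
#' @export
lawson_pca_transform <- function(counts) {
  x <- unclass(counts)
  storage.mode(x) <- "double"
  diag(x) <- colSums(x)
  x <- sweep(x, 2L, colMeans(x))
  s <- x %*% t(x)
  (s + t(s)) / 2
}

#' PCA of a coancestry matrix
#'
#' Eigendecomposition of [lawson_pca_transform()]. Scores are the
#' eigenvectors scaled by the square roots of their (nonnegative-clipped)
#' eigenvalues; each component's sign is fixed so that its largest-
#' magnitude loading is positive.
#'
#' @param counts A [chunkcounts] matrix.
#' @param n_components Number of leading components to return
#'   (at most n - 1).
#' @return An object of class `coancestry_pca` with elements `scores`
#'   (tibble: id, PC1..PCk) and `eigenvalues` (all n, nonincreasing).
#' @export
coancestry_pca <- function(counts, n_components = 2) {
  n <- nrow(counts)
  check_number(n_components, "n_components", lower = 1, upper = n - 1)
  s <- lawson_pca_transform(counts)
  if (any(!is.finite(s))) abort("transformed matrix has non-finite entries.")
  e <- eigen(s, symmetric = TRUE)
  k <- as.integer(n_components)
  vals <- pmax(e$values, 0)
  scores <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(vals[seq_len(k)]), k)
  for (j in seq_len(k)) {
    if (scores[which.max(abs(scores[, j])), j] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  out <- list(
    scores = dplyr::bind_cols(tibble::tibble(id = rownames(counts)),
                              tibble::as_tibble(scores)),
    eigenvalues = e$values
  )
  class(out) <- "coancestry_pca"
  out
}

#' @export
print.coancestry_pca <- function(x, ...) {
  k <- ncol(x$scores) - 1L
  pct <- 100 * x$eigenvalues[seq_len(k)] / sum(pmax(x$eigenvalues, 0))
  cat(sprintf("<coancestry_pca: %d individuals, %d components (%s%% of variance)>\n",
              nrow(x$scores), k, paste(sprintf("%.1f", pct), collapse = " + ")))
  invisible(x)
}

#' @describeIn coancestry_pca Per-individual scores as a tibble.
#' @param x A `coancestry_pca` object.
#' @param ... Unused.
#' @method tidy coancestry_pca
#' @export
tidy.coancestry_pca <- function(x, ...) x$scores

#' @describeIn coancestry_pca One row per component: eigenvalue and
#'   variance share.
#' @method glance coancestry_pca
#' @export
glance.coancestry_pca <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    prop_variance = pmax(x$eigenvalues, 0) / sum(pmax(x$eigenvalues, 0))
  )
}

#' @describeIn coancestry_pca Scatter of the first two PCs, optionally
#'   coloured by a population labeling.
#' @param object A `coancestry_pca` object.
#' @param labeling Optional labeling (data frame `id`, `population` or
#'   named vector) used to colour points.
#' @method autoplot coancestry_pca
#' @export
autoplot.coancestry_pca <- function(object, labeling = NULL, ...) {
  df <- object$scores
  if (!is.null(labeling)) {
    lab <- as_labeling(labeling, df$id)
    df$population <- unname(lab[df$id])
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                          colour = .data$population))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2))
  }
  p + ggplot2::geom_point(alpha = 0.8) + ggplot2::theme_minimal()
}
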