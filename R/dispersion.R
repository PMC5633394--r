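# Group dispersion on the PC1-PC2 plane, calibrated by resampling
# equally sized random groups from the same plot.

#' Resampling-calibrated group dispersion on the PC plane
#'
#' The observed statistic is the empirical variance of a group on the
#' plane of the first two principal components: the average squared
#' Euclidean distance of the group's members from the group mean. It is
#' calibrated against the same statistic for `n_resample` random groups
#' of the same size drawn (without replacement, from all scored
#' individuals) from the same plot: the scaled ratio is
#' observed / mean(null), and the empirical p-value the fraction of null
#' statistics less than or equal to the observed one (small p = the
#' group is unusually tight).
#'
#' @param scores A data frame of PC scores with columns `id`, `PC1`,
#'   `PC2` (e.g. `tidy(coancestry_pca(...))`).
#' @param group Character vector of ids forming the group (size >= 2).
#' @param n_resample Number of random same-size groups for the null.
#'   Default 100000.
#' @param seed Integer seed for the resampling.
#' @return An object of class `dispersion` with elements `observed`,
#'   `null` (numeric vector of length `n_resample`), `ratio`,
#'   `p_value`, `group_size`.
#' @export
dispersion_statistic <- function(scores, group, n_resample = 100000,
                                 seed = NULL) {
  scores <- tibble::as_tibble(scores)
  if (!all(c("id", "PC1", "PC2") %in% names(scores))) {
    abort("`scores` must have columns `id`, `PC1`, `PC2`.")
  }
  group <- as.character(group)
  if (length(group) < 2L) abort("`group` must have at least 2 members.")
  missing <- setdiff(group, scores$id)
  if (length(missing) > 0L) {
    abort(paste0("group id(s) not in `scores`: ",
                 paste(head(missing, 3L), collapse = ", ")))
  }
  check_number(n_resample, "n_resample", lower = 1)
  xy <- as.matrix(scores[, c("PC1", "PC2")])
  rownames(xy) <- scores$id
  observed <- mean_sq_dist(xy[group, , drop = FALSE])
  m <- length(group)
  null <- with_seed_or_current(seed, {
    idx <- replicate(n_resample, sample.int(nrow(xy), m))
    gx <- matrix(xy[, 1][idx], nrow = m)
    gy <- matrix(xy[, 2][idx], nrow = m)
    # per-column mean squared distance to the column centroid
    (colMeans(gx^2) - colMeans(gx)^2) + (colMeans(gy^2) - colMeans(gy)^2)
  })
  out <- list(
    observed = observed,
    null = null,
    ratio = observed / mean(null),
    p_value = mean(null <= observed),
    group_size = m
  )
  class(out) <- "dispersion"
  out
}

# Average squared Euclidean distance to the centroid (population variance,
# not the n-1 form; the calibration ratio is invariant to that choice).
mean_sq_dist <- function(xy) {
  ctr <- colMeans(xy)
  mean((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2)
}

#' @export
print.dispersion <- function(x, ...) {
  cat(sprintf(
    "<dispersion: group of %d; observed %.4g; ratio %.3f; empirical p %.4g>\n",
    x$group_size, x$observed, x$ratio, x$p_value))
  invisible(x)
}

#' @describeIn dispersion_statistic One-row summary tibble.
#' @param x A `dispersion` object.
#' @param ... Unused.
#' @method glance dispersion
#' @export
glance.dispersion <- function(x, ...) {
  tibble::tibble(
    group_size = x$group_size,
    observed = x$observed,
    null_mean = mean(x$null),
    ratio = x$ratio,
    p_value = x$p_value,
    n_resample = length(x$null)
  )
}

#' @describeIn dispersion_statistic Null distribution with the observed
#'   value marked (violin-style summary of the calibration).
#' @param object A `dispersion` object.
#' @method autoplot dispersion
#' @export
autoplot.dispersion <- function(object, ...) {
  df <- tibble::tibble(null = object$null)
  ggplot2::ggplot(df, ggplot2::aes(x = "null", y = .data$null)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_hline(yintercept = object$observed, colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "mean squared distance to group centroid",
                  subtitle = sprintf("observed (line) ratio = %.3f, p = %.4g",
                                     object$ratio, object$p_value)) +
    ggplot2::theme_minimal()
}
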