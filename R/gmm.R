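# East/west ancestry assignment: the per-individual log copy-ratio
# statistic and a semi-supervised two-component Gaussian mixture fitted
# by EM, with reference-panel responsibilities held fixed.

#' Log ratio of average eastern vs. western copying
#'
#' For each recipient i the statistic is
#' `x_i = log( mean_j-in-east c_ij / mean_j-in-west c_ij )`
#' where the means run over the eastern and western reference panels. A
#' panel member's own zero diagonal is simply included in its panel's
#' average (the divisor stays the panel size). Natural logarithm.
#'
#' @param counts A [chunkcounts] matrix.
#' @param east_ids,west_ids Disjoint, nonempty id sets of the eastern and
#'   western reference panels; all must be columns of `counts`.
#' @return A tibble with columns `id` and `x`. Individuals whose mean
#'   copying from either panel is zero get `x = NA` (with a message);
#'   exclude them before fitting.
#' @export
log_copy_ratio <- function(counts, east_ids, west_ids) {
  ids <- rownames(counts)
  east_ids <- as.character(east_ids)
  west_ids <- as.character(west_ids)
  if (length(east_ids) == 0L || length(west_ids) == 0L) {
    abort("both panels must be nonempty.")
  }
  if (length(intersect(east_ids, west_ids)) > 0L) {
    abort("panels must be disjoint.")
  }
  unknown <- setdiff(c(east_ids, west_ids), ids)
  if (length(unknown) > 0L) {
    abort(paste0("panel id(s) not in the matrix: ",
                 paste(head(unknown, 3L), collapse = ", ")))
  }
  m <- unclass(counts)
  mean_e <- rowMeans(m[, east_ids, drop = FALSE])
  mean_w <- rowMeans(m[, west_ids, drop = FALSE])
  x <- unname(ifelse(mean_e > 0 & mean_w > 0, log(mean_e / mean_w), NA_real_))
  n_bad <- sum(is.na(x))
  if (n_bad > 0L) {
    inform(sprintf(
      "%d individual(s) with zero mean copying from a panel: x set to NA.",
      n_bad))
  }
  tibble::tibble(id = ids, x = x)
}

#' Fit a semi-supervised two-component Gaussian mixture by EM
#'
#' Individuals with a known component ("E" or "W" reference-panel
#' members) keep responsibilities fixed at their label throughout;
#' unlabeled individuals' responsibilities are recomputed each E-step.
#' The M-step updates both means, both variances (unpooled) and the
#' mixture weight from all responsibilities. Initialisation is from the
#' labeled groups' sample moments, so the fit is deterministic.
#'
#' @param x Numeric vector of finite log copy-ratio values.
#' @param label Character vector aligned with `x`: `"E"`, `"W"` or `NA`
#'   for unlabeled. Both labels must occur.
#' @param tol Stop when the log-likelihood gain falls below this.
#'   Default 1e-8.
#' @param max_iter Maximum EM iterations. Default 1000.
#' @return An object of class `gmm_fit`: parameters `mu_w`, `mu_e`,
#'   `sigma2_w`, `sigma2_e`, `weight_e`, the per-iteration `loglik`
#'   trace, `converged`, and the data (`x`, `label`, posterior `p_east`).
#' @export
fit_semisupervised_gmm <- function(x, label, tol = 1e-8, max_iter = 1000) {
  if (length(x) != length(label)) abort("`x` and `label` lengths differ.")
  if (any(!is.finite(x))) {
    abort("`x` contains non-finite values; exclude them before fitting.")
  }
  label <- as.character(label)
  if (!all(label %in% c("E", "W") | is.na(label))) {
    abort("`label` entries must be \"E\", \"W\" or NA.")
  }
  is_e <- !is.na(label) & label == "E"
  is_w <- !is.na(label) & label == "W"
  if (!any(is_e) || !any(is_w)) abort("both labeled groups must be nonempty.")
  check_number(tol, "tol", lower = 0)
  check_number(max_iter, "max_iter", lower = 1)

  var0 <- function(v) max(mean((v - mean(v))^2), 1e-12)
  mu_e <- mean(x[is_e]); s2_e <- var0(x[is_e])
  mu_w <- mean(x[is_w]); s2_w <- var0(x[is_w])
  w_e <- sum(is_e) / (sum(is_e) + sum(is_w))

  r_e <- numeric(length(x))       # responsibility of component E
  r_e[is_e] <- 1
  unl <- is.na(label)
  loglik <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    de <- w_e * dnorm(x, mu_e, sqrt(s2_e))
    dw <- (1 - w_e) * dnorm(x, mu_w, sqrt(s2_w))
    # E-step (unlabeled only; panel responsibilities stay fixed)
    r_e[unl] <- de[unl] / (de[unl] + dw[unl])
    ll <- sum(log(de[unl] + dw[unl])) + sum(log(de[is_e])) + sum(log(dw[is_w]))
    loglik <- c(loglik, ll)
    if (it > 1L && ll - loglik[it - 1L] < tol) {
      converged <- TRUE
      break
    }
    # M-step
    se <- sum(r_e); sw <- sum(1 - r_e)
    mu_e <- sum(r_e * x) / se
    mu_w <- sum((1 - r_e) * x) / sw
    s2_e <- sum(r_e * (x - mu_e)^2) / se
    s2_w <- sum((1 - r_e) * (x - mu_w)^2) / sw
    if (s2_e < 1e-12 || s2_w < 1e-12) {
      warn("variance collapse: flooring a component variance at 1e-12.")
      s2_e <- max(s2_e, 1e-12)
      s2_w <- max(s2_w, 1e-12)
    }
    w_e <- se / length(x)
  }
  de <- w_e * dnorm(x, mu_e, sqrt(s2_e))
  dw <- (1 - w_e) * dnorm(x, mu_w, sqrt(s2_w))
  structure(list(
    mu_w = mu_w, mu_e = mu_e, sigma2_w = s2_w, sigma2_e = s2_e,
    weight_e = w_e, loglik = loglik, converged = converged,
    x = x, label = label, p_east = de / (de + dw)
  ), class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf(
    "<gmm_fit: W ~ N(%.3f, %.3f), E ~ N(%.3f, %.3f), weight_e = %.3f; %d EM iterations%s>\n",
    x$mu_w, x$sigma2_w, x$mu_e, x$sigma2_e, x$weight_e, length(x$loglik),
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @describeIn fit_semisupervised_gmm Parameter estimates, one row per
#'   component.
#' @param ... Unused.
#' @method tidy gmm_fit
#' @export
tidy.gmm_fit <- function(x, ...) {
  tibble::tibble(
    component = c("W", "E"),
    mean = c(x$mu_w, x$mu_e),
    variance = c(x$sigma2_w, x$sigma2_e),
    weight = c(1 - x$weight_e, x$weight_e)
  )
}

#' @describeIn fit_semisupervised_gmm One-row fit summary.
#' @method glance gmm_fit
#' @export
glance.gmm_fit <- function(x, ...) {
  tibble::tibble(
    loglik = x$loglik[length(x$loglik)],
    n_iter = length(x$loglik),
    converged = x$converged,
    n = length(x$x),
    n_labeled = sum(!is.na(x$label))
  )
}

#' Assign individuals to populations from a fitted mixture
#'
#' Posterior probabilities of the eastern component by Bayes' rule from
#' the two weighted Gaussian densities. The hard label is `E` if
#' `P(E) >= threshold`, `W` if `P(W) >= threshold`, otherwise
#' `uncertain` (an individual below the threshold for both).
#'
#' @param data A data frame with columns `id` and `x` (finite values),
#'   e.g. from [log_copy_ratio()] after dropping `NA`s.
#' @param fit A [fit_semisupervised_gmm()] object.
#' @param threshold Assignment probability threshold in (0.5, 1].
#'   Default 0.8, i.e. individuals under 80% for both populations are
#'   flagged uncertain.
#' @return A tibble: `id`, `x`, `p_east`, `p_west`, `label`.
#' @export
assign_populations <- function(data, fit, threshold = 0.8) {
  data <- tibble::as_tibble(data)
  if (!all(c("id", "x") %in% names(data))) {
    abort("`data` must have columns `id` and `x`.")
  }
  if (!inherits(fit, "gmm_fit")) abort("`fit` must be a gmm_fit object.")
  if (!is.numeric(threshold) || threshold <= 0.5 || threshold > 1) {
    abort("`threshold` must lie in (0.5, 1].")
  }
  x <- data$x
  if (any(!is.finite(x))) abort("`data$x` contains non-finite values.")
  de <- fit$weight_e * dnorm(x, fit$mu_e, sqrt(fit$sigma2_e))
  dw <- (1 - fit$weight_e) * dnorm(x, fit$mu_w, sqrt(fit$sigma2_w))
  p_east <- de / (de + dw)
  tibble::tibble(
    id = data$id, x = x, p_east = p_east, p_west = 1 - p_east,
    label = dplyr::case_when(
      p_east >= threshold ~ "E",
      1 - p_east >= threshold ~ "W",
      .default = "uncertain"
    )
  )
}

#' @describeIn fit_semisupervised_gmm Histogram of x with the two fitted
#'   component densities.
#' @param object A `gmm_fit` object.
#' @method autoplot gmm_fit
#' @export
autoplot.gmm_fit <- function(object, ...) {
  df <- tibble::tibble(x = object$x)
  grid <- seq(min(df$x), max(df$x), length.out = 400)
  dens <- dplyr::bind_rows(
    tibble::tibble(x = grid, component = "W",
                   d = (1 - object$weight_e) *
                     dnorm(grid, object$mu_w, sqrt(object$sigma2_w))),
    tibble::tibble(x = grid, component = "E",
                   d = object$weight_e *
                     dnorm(grid, object$mu_e, sqrt(object$sigma2_e)))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 50, fill = "grey85", colour = "grey60") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(y = .data$d, colour = .data$component)) +
    ggplot2::labs(x = "log E/W copy ratio", y = "density") +
    ggplot2::theme_minimal()
}
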