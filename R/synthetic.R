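# Synthetic cohorts with known ground truth: clustered geography with
# parental coordinates, Dirichlet-multinomial chunkcount matrices whose
# population-level copying means follow a given propensity matrix,
# two-component Gaussian mixtures for the assignment model, and
# Balding-Nichols allele counts at a chosen F_ST.

#' Configuration of a synthetic cohort
#'
#' @param n_individuals Number of individuals.
#' @param cluster_centers A data frame with columns `lat`, `lon` (decimal
#'   degrees) and optionally `population` (labels; default `P1..PK`):
#'   one row per population.
#' @param cluster_spread_km Standard deviation, in km, of the great-circle
#'   distance of a parent's birthplace from its population centre
#'   (isotropic; 0 puts everyone at the centre).
#' @param propensity K x K row-stochastic matrix Q: row p is the expected
#'   copying proportion of a population-p recipient from each donor
#'   population.
#' @param total_chunks Total chunk count T per recipient row.
#' @param dirichlet_concentration Concentration of the Dirichlet spread
#'   of individual copying propensities around their population's Q row
#'   (larger = individuals closer to the population mean).
#' @param pop_weights Optional sampling weights over populations
#'   (default uniform).
#' @param seed Default seed used by the generators (each can override).
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_individuals,
                             cluster_centers,
                             cluster_spread_km = 20,
                             propensity,
                             total_chunks = 1000,
                             dirichlet_concentration = 50,
                             pop_weights = NULL,
                             seed = NULL) {
  check_number(n_individuals, "n_individuals", lower = 1)
  centers <- tibble::as_tibble(cluster_centers)
  if (nrow(centers) == 0L) abort("`cluster_centers` must have >= 1 row.")
  if (!all(c("lat", "lon") %in% names(centers))) {
    abort("`cluster_centers` needs `lat` and `lon` columns.")
  }
  validate_coords(centers$lat, centers$lon)
  if (!"population" %in% names(centers)) {
    centers$population <- paste0("P", seq_len(nrow(centers)))
  }
  k <- nrow(centers)
  q <- as.matrix(propensity)
  if (nrow(q) != k || ncol(q) != k) {
    abort(sprintf("`propensity` must be %d x %d to match the centers.", k, k))
  }
  if (any(q < 0)) abort("`propensity` entries must be nonnegative.")
  if (any(abs(rowSums(q) - 1) > 1e-9)) {
    abort("each `propensity` row must sum to 1 (within 1e-9).")
  }
  if (k < 2L) abort("need K >= 2 populations.")
  dimnames(q) <- list(centers$population, centers$population)
  check_number(cluster_spread_km, "cluster_spread_km", lower = 0)
  check_number(total_chunks, "total_chunks", lower = 1)
  check_number(dirichlet_concentration, "dirichlet_concentration",
               lower = 1e-12)
  if (!is.null(pop_weights)) {
    if (length(pop_weights) != k || any(pop_weights < 0) ||
        sum(pop_weights) <= 0) {
      abort("`pop_weights` must be K nonnegative weights, not all zero.")
    }
  }
  structure(list(
    n_individuals = as.integer(n_individuals),
    cluster_centers = centers,
    cluster_spread_km = cluster_spread_km,
    propensity = q,
    total_chunks = as.integer(total_chunks),
    dirichlet_concentration = dirichlet_concentration,
    pop_weights = pop_weights,
    seed = seed
  ), class = "synthetic_config")
}

# km of one degree of latitude on the 6371 km sphere
KM_PER_DEG <- EARTH_RADIUS_KM * pi / 180

#' Generate a geographically clustered cohort
#'
#' Each individual is assigned a true population (uniformly, or by the
#' config's `pop_weights`); both parents' birthplaces are drawn
#' isotropically around that population's centre so that the standard
#' deviation of their great-circle distance from the centre equals
#' `cluster_spread_km` (radial distances are Rayleigh; km offsets are
#' converted to degrees at the centre's latitude on a spherical Earth).
#' The individual's own coordinates are the mean of the two parents'.
#'
#' @param config A [synthetic_config()].
#' @param seed Seed overriding `config$seed`.
#' @return A tibble: `id`, `latitude`, `longitude`, `father_lat`,
#'   `father_lon`, `mother_lat`, `mother_lon`, `true_population`.
#' @export
generate_geography <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_individuals
  centers <- config$cluster_centers
  k <- nrow(centers)
  # per-axis normal sd giving sd(Rayleigh radius) = cluster_spread_km
  axis_sd <- config$cluster_spread_km / sqrt(2 - pi / 2)
  with_seed_or_current(seed, {
    pop_idx <- sample.int(k, n, replace = TRUE, prob = config$pop_weights)
    draw_parent <- function() {
      dx <- rnorm(n, 0, axis_sd)
      dy <- rnorm(n, 0, axis_sd)
      lat0 <- centers$lat[pop_idx]
      lon0 <- centers$lon[pop_idx]
      list(lat = lat0 + dy / KM_PER_DEG,
           lon = lon0 + dx / (KM_PER_DEG * cos(lat0 * pi / 180)))
    }
    f <- draw_parent()
    m <- draw_parent()
    tibble::tibble(
      id = sprintf("ind%0*d", nchar(n), seq_len(n)),
      father_lat = f$lat, father_lon = f$lon,
      mother_lat = m$lat, mother_lon = m$lon,
      true_population = centers$population[pop_idx]
    ) |> add_mean_parent_coords()
  })
}

#' Generate a chunkcount matrix from a population propensity model
#'
#' For each recipient of population p, an individual copying propensity
#' over donor populations is drawn from a Dirichlet with mean `Q[p, ]`
#' and the configured concentration; `total_chunks` chunks are then
#' allocated multinomially across donor populations and uniformly at
#' random among each donor population's members, excluding the
#' recipient itself (demand that would fall on a self-only population is
#' reallocated to the other populations in proportion to the remaining
#' propensities). Every row sums exactly to `total_chunks` and the
#' diagonal is exactly zero.
#'
#' @param labels Population label per individual: a named character
#'   vector (names = ids) or a data frame with `id` and `population`
#'   columns; values must match the propensity's population names.
#' @param config A [synthetic_config()].
#' @param seed Seed overriding `config$seed`.
#' @return A [chunkcounts] matrix over the labelled individuals.
#' @export
generate_chunkcounts <- function(labels, config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.data.frame(labels)) {
    if ("true_population" %in% names(labels) &&
        !"population" %in% names(labels)) {
      labels <- dplyr::rename(labels, population = "true_population")
    }
    labels <- stats::setNames(as.character(labels$population),
                              as.character(labels$id))
  }
  ids <- names(labels)
  if (is.null(ids)) abort("`labels` must carry individual ids as names.")
  pops <- rownames(config$propensity)
  if (!all(labels %in% pops)) {
    abort("`labels` contain populations absent from the propensity matrix.")
  }
  n <- length(ids)
  t_chunks <- config$total_chunks
  alpha <- config$dirichlet_concentration
  q <- config$propensity
  members <- lapply(pops, function(p) which(labels == p))
  names(members) <- pops
  counts <- matrix(0, n, n, dimnames = list(ids, ids))
  with_seed_or_current(seed, {
    for (i in seq_len(n)) {
      p <- labels[[i]]
      # Dirichlet(alpha * Q[p, ]): zero-mean components stay exactly zero
      g <- rgamma(length(pops), shape = alpha * q[p, ])
      w <- g / sum(g)
      lone <- vapply(pops, function(k) {
        length(setdiff(members[[k]], i)) == 0L
      }, logical(1))
      if (any(lone & w > 0)) {
        w[lone] <- 0
        if (sum(w) <= 0) {
          abort("no eligible donors: a single-member population copying only from itself.")
        }
        w <- w / sum(w)
      }
      m_pop <- as.vector(rmultinom(1L, t_chunks, w))
      for (ki in which(m_pop > 0L)) {
        donors <- setdiff(members[[pops[ki]]], i)
        if (length(donors) == 1L) {
          counts[i, donors] <- counts[i, donors] + m_pop[ki]
        } else {
          counts[i, donors] <- counts[i, donors] +
            as.vector(rmultinom(1L, m_pop[ki], rep(1, length(donors))))
        }
      }
    }
  })
  chunkcounts(counts, ids)
}

#' Generate Balding-Nichols allele counts at a chosen F_ST
#'
#' Ancestral frequencies are uniform on `[0.05, 0.95]`; each
#' population's frequency is Beta(p(1-F)/F, (1-p)(1-F)/F) around the
#' ancestral p (identical across populations when `fst = 0`); per-SNP,
#' per-population alternate-allele counts are binomial from the diploid
#' population sizes.
#'
#' @param labels Population label per individual (named vector or data
#'   frame with `id`/`population`), used only for the population sizes.
#' @param n_snps Number of independent SNPs.
#' @param fst Differentiation parameter in `[0, 1)`.
#' @param seed Integer seed.
#' @return A long allele-count tibble (`snp_id`, `pop`, `n_alt`,
#'   `n_total`) suitable for [hudson_fst()].
#' @export
generate_genotype_counts <- function(labels, n_snps, fst, seed = NULL) {
  check_number(n_snps, "n_snps", lower = 1)
  check_number(fst, "fst", lower = 0, upper = 1 - 1e-12)
  if (is.data.frame(labels)) {
    lab <- as.character(labels$population %||% labels$true_population)
  } else {
    lab <- as.character(labels)
  }
  sizes <- table(lab)
  pops <- names(sizes)
  with_seed_or_current(seed, {
    p_anc <- runif(n_snps, 0.05, 0.95)
    purrr::map_dfr(pops, function(pp) {
      if (fst == 0) {
        p_pop <- p_anc
      } else {
        p_pop <- rbeta(n_snps, p_anc * (1 - fst) / fst,
                       (1 - p_anc) * (1 - fst) / fst)
      }
      n_tot <- 2L * as.integer(sizes[[pp]])
      tibble::tibble(
        snp_id = paste0("snp", seq_len(n_snps)),
        pop = pp,
        n_alt = rbinom(n_snps, n_tot, p_pop),
        n_total = n_tot
      )
    })
  })
}

#' Generate a labelled two-component Gaussian mixture
#'
#' Draws `n` values from `weight_e * N(mu_e, sigma2_e) +
#' (1 - weight_e) * N(mu_w, sigma2_w)`; a `labeled_fraction` of each
#' component (rounded) carries its true label as the reference set, the
#' rest are unlabeled (`NA`).
#'
#' @param n Number of values.
#' @param mu_w,mu_e Component means (western, eastern).
#' @param sigma2_w,sigma2_e Component variances (>= 0; 0 is degenerate).
#' @param weight_e Mixture weight of the eastern component in `[0, 1]`.
#' @param labeled_fraction Fraction of each component labeled, in
#'   `[0, 1]`.
#' @param seed Integer seed.
#' @return A tibble: `id`, `x`, `true_label` ("W"/"E"), `label` (the
#'   observed partial labeling, `NA` where unlabeled).
#' @export
generate_x_mixture <- function(n, mu_w, mu_e, sigma2_w, sigma2_e,
                               weight_e, labeled_fraction, seed = NULL) {
  check_number(n, "n", lower = 1)
  check_number(weight_e, "weight_e", lower = 0, upper = 1)
  check_number(labeled_fraction, "labeled_fraction", lower = 0, upper = 1)
  check_number(sigma2_w, "sigma2_w", lower = 0)
  check_number(sigma2_e, "sigma2_e", lower = 0)
  with_seed_or_current(seed, {
    is_e <- runif(n) < weight_e
    x <- ifelse(is_e, rnorm(n, mu_e, sqrt(sigma2_e)),
                rnorm(n, mu_w, sqrt(sigma2_w)))
    true_label <- ifelse(is_e, "E", "W")
    label <- rep(NA_character_, n)
    for (comp in c("E", "W")) {
      idx <- which(true_label == comp)
      n_lab <- round(labeled_fraction * length(idx))
      if (n_lab > 0L) label[sample(idx, n_lab)] <- comp
    }
    tibble::tibble(id = paste0("ind", seq_len(n)), x = x,
                   true_label = true_label, label = label)
  })
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper: clustered geography plus the matching
#' chunkcount matrix (and, optionally, Balding-Nichols allele counts).
#'
#' @param config A [synthetic_config()].
#' @param n_snps,fst If both given, allele counts are generated too.
#' @param seed Seed overriding `config$seed`.
#' @return A list of class `synthetic_cohort`: `individuals` (tibble),
#'   `chunkcounts`, optional `genotype_counts`, and `config`.
#' @export
generate_cohort <- function(config, n_snps = NULL, fst = NULL,
                            seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  base_seed <- if (is.null(seed)) NULL else as.integer(seed)
  offset <- function(k) if (is.null(base_seed)) NULL else base_seed + k
  individuals <- generate_geography(config, seed = offset(0L))
  labels <- stats::setNames(individuals$true_population, individuals$id)
  cc <- generate_chunkcounts(labels, config, seed = offset(1L))
  out <- list(individuals = individuals, chunkcounts = cc, config = config)
  if (!is.null(n_snps) && !is.null(fst)) {
    out$genotype_counts <- generate_genotype_counts(labels, n_snps, fst,
                                                    seed = offset(2L))
  }
  structure(out, class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort: %d individuals, %d populations%s>\n",
              nrow(x$individuals), nrow(x$config$cluster_centers),
              if (is.null(x$genotype_counts)) "" else ", with allele counts"))
  invisible(x)
}

#' Write cohort metadata as tab-separated text
#'
#' @param individuals The individual table of a cohort.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(individuals, path) {
  readr::write_tsv(tibble::as_tibble(individuals), path)
  invisible(path)
}

#' Write an allele-count table as tab-separated text
#'
#' Columns written: `snp_id`, `pop`, `n_ref`, `n_alt`.
#'
#' @param table A long allele-count tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_allele_counts <- function(table, path) {
  tibble::as_tibble(table) |>
    dplyr::transmute(.data$snp_id, .data$pop,
                     n_ref = .data$n_total - .data$n_alt, .data$n_alt) |>
    readr::write_tsv(path)
  invisible(path)
}

#' Read an allele-count table written by [write_allele_counts()]
#'
#' @param path Path to the tab-separated table.
#' @return A long allele-count tibble (`snp_id`, `pop`, `n_alt`,
#'   `n_total`).
#' @export
read_allele_counts <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE) |>
    dplyr::mutate(n_total = .data$n_ref + .data$n_alt) |>
    dplyr::select("snp_id", "pop", "n_alt", "n_total")
}
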