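# Hudson's pairwise F_ST as a ratio of averages over SNPs, with a
# block-jackknife standard error over contiguous SNP blocks.

#' Per-SNP numerator and denominator of Hudson's F_ST estimator
#'
#' For sample allele frequencies `p1`, `p2` computed from `n1`, `n2`
#' called alleles:
#' numerator `N = (p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
#' denominator `D = p1(1-p2) + p2(1-p1)`. Negative per-SNP numerators
#' are expected when the true differentiation is small; only the ratio
#' of sums is meaningful.
#'
#' @param p1,p2 Sample allele frequencies in `[0, 1]` (vectorised).
#' @param n1,n2 Numbers of called alleles (>= 2) behind each frequency.
#' @return A tibble with columns `numerator` and `denominator`.
#' @export
hudson_components <- function(p1, n1, p2, n2) {
  if (any(n1 <= 1) || any(n2 <= 1)) {
    abort("allele counts must be >= 2 in both populations.")
  }
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1)) {
    abort("allele frequencies must lie in [0, 1].")
  }
  tibble::tibble(
    numerator = (p1 - p2)^2 -
      p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1),
    denominator = p1 * (1 - p2) + p2 * (1 - p1)
  )
}

# Align one pair of populations from a long allele-count table into a
# per-SNP wide tibble (p1, n1, p2, n2), preserving SNP order.
pair_freqs <- function(table, pop_a, pop_b) {
  table <- tibble::as_tibble(table)
  need <- c("snp_id", "pop", "n_alt", "n_total")
  if (!all(need %in% names(table))) {
    abort("allele-count table needs columns snp_id, pop, n_alt, n_total.")
  }
  a <- dplyr::filter(table, .data$pop == pop_a)
  b <- dplyr::filter(table, .data$pop == pop_b)
  if (nrow(a) == 0L || nrow(b) == 0L) {
    abort("both populations must occur in the table.")
  }
  dplyr::inner_join(
    dplyr::select(a, "snp_id", n_alt_1 = "n_alt", n_1 = "n_total"),
    dplyr::select(b, "snp_id", n_alt_2 = "n_alt", n_2 = "n_total"),
    by = "snp_id"
  ) |>
    dplyr::mutate(p1 = .data$n_alt_1 / .data$n_1,
                  p2 = .data$n_alt_2 / .data$n_2)
}

#' Hudson's pairwise F_ST from an allele-count table
#'
#' Ratio of averages: the sum of per-SNP numerators divided by the sum
#' of per-SNP denominators (never the mean of per-SNP ratios). SNPs
#' monomorphic for the same allele in both populations (`D = 0`) are
#' excluded and counted.
#'
#' @param table Long allele-count table: columns `snp_id`, `pop`,
#'   `n_alt` (alternate-allele count), `n_total` (called alleles).
#' @param pop_a,pop_b The two population labels to compare.
#' @return An object of class `fst_result`: `estimate`, `n_snps_used`,
#'   `n_excluded`, and the populations compared.
#' @export
hudson_fst <- function(table, pop_a, pop_b) {
  d <- pair_freqs(table, pop_a, pop_b)
  comp <- hudson_components(d$p1, d$n_1, d$p2, d$n_2)
  use <- comp$denominator > 0
  if (!any(use)) abort("all SNPs are monomorphic in both populations.")
  structure(list(
    estimate = sum(comp$numerator[use]) / sum(comp$denominator[use]),
    n_snps_used = sum(use),
    n_excluded = sum(!use),
    pop_a = pop_a, pop_b = pop_b
  ), class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("<fst_result: %s vs %s, Hudson F_ST = %.4g (%d SNPs, %d monomorphic excluded)>\n",
              x$pop_a, x$pop_b, x$estimate, x$n_snps_used, x$n_excluded))
  invisible(x)
}

#' @describeIn hudson_fst One-row summary tibble.
#' @param x An `fst_result` object.
#' @param ... Unused.
#' @method glance fst_result
#' @export
glance.fst_result <- function(x, ...) {
  tibble::tibble(pop_a = x$pop_a, pop_b = x$pop_b, estimate = x$estimate,
                 n_snps_used = x$n_snps_used, n_excluded = x$n_excluded)
}

#' Block-jackknife standard error of Hudson's F_ST
#'
#' Delete-one-block jackknife over contiguous blocks of SNPs (in table
#' order), recomputing the ratio-of-averages estimate with each block
#' removed and applying the standard jackknife variance formula.
#' Contiguous blocks absorb local linkage disequilibrium.
#'
#' @inheritParams hudson_fst
#' @param block_size_snps Number of consecutive SNPs per block.
#'   Default 100.
#' @return The standard error (a nonnegative number), with the number
#'   of blocks as attribute `n_blocks`.
#' @export
block_jackknife_se <- function(table, pop_a, pop_b, block_size_snps = 100) {
  check_number(block_size_snps, "block_size_snps", lower = 1)
  d <- pair_freqs(table, pop_a, pop_b)
  comp <- hudson_components(d$p1, d$n_1, d$p2, d$n_2)
  use <- comp$denominator > 0
  num <- comp$numerator[use]
  den <- comp$denominator[use]
  n_snps <- length(num)
  if (block_size_snps >= n_snps) {
    abort("block size must be smaller than the number of polymorphic SNPs.")
  }
  block <- (seq_len(n_snps) - 1L) %/% as.integer(block_size_snps)
  bn <- tapply(num, block, sum)
  bd <- tapply(den, block, sum)
  g <- length(bn)
  theta_j <- (sum(bn) - bn) / (sum(bd) - bd)   # leave-one-block-out
  se <- sqrt((g - 1) / g * sum((theta_j - mean(theta_j))^2))
  attr(se, "n_blocks") <- g
  se
}

#' Tally per-population allele counts from a VCF
#'
#' Reads a VCF (via the vcfR package), keeps biallelic SNPs only
#' (multi-allelic sites are skipped with a message), and tallies
#' alternate-allele and called-allele counts per population from the
#' genotype field.
#'
#' @param path Path to a VCF file.
#' @param populations A data frame with columns `id` (sample names as in
#'   the VCF) and `pop`.
#' @return A long allele-count tibble (`snp_id`, `pop`, `n_alt`,
#'   `n_total`) suitable for [hudson_fst()].
#' @export
allele_counts_from_vcf <- function(path, populations) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCFs requires the vcfR package.")
  }
  populations <- tibble::as_tibble(populations)
  if (!all(c("id", "pop") %in% names(populations))) {
    abort("`populations` must have columns `id` and `pop`.")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  biallelic <- !grepl(",", vcfR::getALT(v), fixed = TRUE)
  n_multi <- sum(!biallelic)
  if (n_multi > 0L) {
    inform(sprintf("%d multi-allelic site(s) skipped.", n_multi))
    v <- v[biallelic, ]
  }
  gt <- vcfR::extract.gt(v)
  snp_ids <- rownames(gt)
  if (is.null(snp_ids)) snp_ids <- as.character(seq_len(nrow(gt)))
  samples <- intersect(colnames(gt), populations$id)
  if (length(samples) == 0L) abort("no VCF samples match `populations$id`.")
  popmap <- stats::setNames(populations$pop, populations$id)
  alt_alleles <- function(g) {
    # count ALT alleles and called alleles from e.g. "0/1", "1|1", "./."
    al <- strsplit(gsub("|", "/", g, fixed = TRUE), "/", fixed = TRUE)
    called <- vapply(al, function(a) sum(a %in% c("0", "1")), integer(1))
    alt <- vapply(al, function(a) sum(a == "1", na.rm = TRUE), integer(1))
    c(alt = sum(alt), total = sum(called))
  }
  purrr::map_dfr(unique(popmap[samples]), function(p) {
    cols <- samples[popmap[samples] == p]
    counts <- apply(gt[, cols, drop = FALSE], 1L, alt_alleles)
    tibble::tibble(snp_id = snp_ids, pop = p,
                   n_alt = unname(counts["alt", ]),
                   n_total = unname(counts["total", ]))
  })
}
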