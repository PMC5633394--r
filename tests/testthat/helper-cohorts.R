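# Shared fixtures, all generated in code.

# Two well-separated populations in central/eastern Finland.
two_pop_config <- function(n = 60, diag_q = 0.8, spread = 15, t_chunks = 1000,
                           alpha = 50, seed = NULL) {
  synthetic_config(
    n_individuals = n,
    cluster_centers = data.frame(lat = c(61, 64), lon = c(23, 29),
                                 population = c("W", "E")),
    cluster_spread_km = spread,
    propensity = matrix(c(diag_q, 1 - diag_q, 1 - diag_q, diag_q), 2,
                        byrow = TRUE),
    total_chunks = t_chunks,
    dirichlet_concentration = alpha,
    seed = seed
  )
}

# Four populations in two nested pairs: within-pair TVD of the propensity
# rows is 0.1, between-pair 0.6, so the planted topology is ((A,B),(C,D)).
nested_pair_config <- function(n = 60, t_chunks = 1000, alpha = 50,
                               seed = NULL) {
  q <- rbind(
    c(0.45, 0.35, 0.10, 0.10),
    c(0.35, 0.45, 0.10, 0.10),
    c(0.10, 0.10, 0.45, 0.35),
    c(0.10, 0.10, 0.35, 0.45)
  )
  synthetic_config(
    n_individuals = n,
    cluster_centers = data.frame(lat = c(60.5, 61.5, 63.5, 64.5),
                                 lon = c(23, 24, 28, 29),
                                 population = c("A", "B", "C", "D")),
    cluster_spread_km = 10,
    propensity = q,
    total_chunks = t_chunks,
    dirichlet_concentration = alpha,
    seed = seed
  )
}

cohort_labels <- function(cohort) {
  stats::setNames(cohort$individuals$true_population, cohort$individuals$id)
}

# Balanced labels without geography, for chunkcount-only fixtures.
balanced_labels <- function(per_pop, pops) {
  stats::setNames(rep(pops, each = per_pop),
                  paste0("i", seq_len(per_pop * length(pops))))
}

# A tiny deterministic chunkcount matrix with exact population profiles:
# pop A members copy 70% from A, 30% from B; pop B the reverse.
exact_two_pop_counts <- function() {
  ids <- c("a1", "a2", "b1", "b2")
  m <- rbind(
    c(0, 70, 15, 15),
    c(70, 0, 15, 15),
    c(15, 15, 0, 70),
    c(15, 15, 70, 0)
  )
  dimnames(m) <- list(ids, ids)
  chunkcounts(m)
}

exact_two_pop_labels <- function() {
  c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
}

# Uniform random simplex points (rows), via normalised exponentials.
random_simplex <- function(n, k) {
  g <- matrix(stats::rexp(n * k), n, k)
  g / rowSums(g)
}
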