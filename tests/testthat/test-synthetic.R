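# The synthetic cohort generators and their ground-truth contracts.

test_that("config validation catches malformed inputs", {
  centers <- data.frame(lat = c(61, 64), lon = c(23, 29))
  q <- matrix(c(0.8, 0.2, 0.2, 0.8), 2, byrow = TRUE)
  expect_s3_class(synthetic_config(10, centers, propensity = q),
                  "synthetic_config")
  expect_error(synthetic_config(10, centers[0, ], propensity = q), ">= 1 row")
  expect_error(synthetic_config(10, centers, propensity = q * 1.1), "sum to 1")
  expect_error(synthetic_config(10, centers, propensity = -q), "nonnegative")
  expect_error(synthetic_config(10, centers[1, ],
                                propensity = matrix(1, 1, 1)), "K >= 2")
})

test_that("zero spread collapses everyone onto the cluster centre", {
  cfg <- synthetic_config(
    20, data.frame(lat = c(62, 62), lon = c(26, 26)),
    cluster_spread_km = 0,
    propensity = matrix(c(0.8, 0.2, 0.2, 0.8), 2, byrow = TRUE), seed = 1)
  geo <- generate_geography(cfg)
  expect_true(all(geo$father_lat == 62 & geo$mother_lat == 62))
  expect_true(all(geo$latitude == 62 & geo$longitude == 26))
})

test_that("generators are reproducible under a fixed seed", {
  cfg <- two_pop_config(n = 25, seed = 99)
  expect_identical(generate_geography(cfg), generate_geography(cfg))
  lab <- balanced_labels(10, c("W", "E"))
  expect_identical(unclass(generate_chunkcounts(lab, cfg, seed = 3)),
                   unclass(generate_chunkcounts(lab, cfg, seed = 3)))
  expect_identical(generate_genotype_counts(lab, 100, 0.01, seed = 5),
                   generate_genotype_counts(lab, 100, 0.01, seed = 5))
  expect_identical(generate_x_mixture(50, -1, 1, 0.2, 0.2, 0.5, 0.1, seed = 7),
                   generate_x_mixture(50, -1, 1, 0.2, 0.2, 0.5, 0.1, seed = 7))
})

test_that("the spread parameter is the sd of distance from the centre", {
  cfg <- synthetic_config(
    1000, data.frame(lat = 62, lon = 26, population = "P1") |>
      rbind(data.frame(lat = 62, lon = 26, population = "P2")),
    cluster_spread_km = 10,
    propensity = matrix(c(0.8, 0.2, 0.2, 0.8), 2, byrow = TRUE), seed = 123)
  geo <- generate_geography(cfg)
  d <- great_circle_km(geo$father_lat, geo$father_lon, 62, 26)
  expect_lt(abs(sd(d) - 10) / 10, 0.15)
})

test_that("chunkcount rows conserve the total and the diagonal is zero", {
  cfg <- two_pop_config(n = 30, t_chunks = 500, seed = 15)
  lab <- balanced_labels(15, c("W", "E"))
  cc <- generate_chunkcounts(lab, cfg, seed = 16)
  m <- unclass(cc)
  expect_equal(unname(rowSums(m)), rep(500, 30))
  expect_equal(unname(diag(m)), rep(0, 30))
  expect_true(all(m >= 0))
  expect_true(all(m == round(m)))
})

test_that("population-level copying means follow the propensity matrix", {
  # Q row (0.5, 0.5): mean copying from either population near one half
  cfg <- synthetic_config(
    100, data.frame(lat = c(61, 64), lon = c(23, 29),
                    population = c("P1", "P2")),
    propensity = matrix(0.5, 2, 2), total_chunks = 1000,
    dirichlet_concentration = 50)
  lab <- balanced_labels(50, c("P1", "P2"))
  cc <- generate_chunkcounts(lab, cfg, seed = 20)
  prof <- population_profiles(cc, lab)
  p1_share <- prof$P1[prof$population == "P1"]
  expect_gte(p1_share, 0.48)
  expect_lte(p1_share, 0.52)
  # near-identity propensity: one-hot within 0.02 at large T and alpha
  cfg2 <- two_pop_config(n = 40, diag_q = 1, t_chunks = 10000, alpha = 1000)
  lab2 <- balanced_labels(20, c("W", "E"))
  cc2 <- generate_chunkcounts(lab2, cfg2, seed = 21)
  prof2 <- population_profiles(cc2, lab2)
  expect_equal(prof2$W[prof2$population == "W"], 1, tolerance = 0.02)
  expect_equal(prof2$E[prof2$population == "E"], 1, tolerance = 0.02)
})

test_that("self-copy demand of a lone member is reallocated, or errors", {
  cfg <- two_pop_config(n = 11)
  lab <- c(balanced_labels(10, "W"), lone = "E")
  cc <- generate_chunkcounts(lab, cfg, seed = 22)
  m <- unclass(cc)
  expect_equal(sum(m["lone", ]), 1000)   # all chunks reallocated to W donors
  expect_equal(m["lone", "lone"], 0)
  lab1 <- c(only = "W")
  expect_error(generate_chunkcounts(lab1, cfg, seed = 23), "donors")
})

test_that("identity propensity drives between-population TVD to one", {
  cfg <- two_pop_config(n = 40, diag_q = 1, t_chunks = 10000, alpha = 1000)
  lab <- balanced_labels(20, c("W", "E"))
  cc <- generate_chunkcounts(lab, cfg, seed = 24)
  d <- pairwise_tvd(population_profiles(cc, lab))
  expect_gte(d["W", "E"], 0.95)
  # within-population TVD: split W into halves and compare their profiles
  split_lab <- lab
  w_ids <- names(lab)[lab == "W"]
  split_lab[w_ids[1:10]] <- "W1"
  split_lab[w_ids[11:20]] <- "W2"
  d_in <- pairwise_tvd(population_profiles(cc, split_lab,
                                           reference_labeling = lab))
  expect_lte(d_in["W1", "W2"], 0.05)
})

test_that("genotype counts respect diploid support and the fst=0 limit", {
  lab <- balanced_labels(30, c("A", "B"))
  tab <- generate_genotype_counts(lab, 500, 0.3, seed = 25)
  expect_true(all(tab$n_alt >= 0 & tab$n_alt <= tab$n_total))
  expect_true(all(tab$n_total == 60))
  # allele-count text round trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_allele_counts(tab, path)
  back <- read_allele_counts(path)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)
})

test_that("the x mixture honours degenerate and fully eastern settings", {
  mix0 <- generate_x_mixture(100, -1, 1, 0, 0, 0.4, 0.5, seed = 26)
  expect_true(all(mix0$x %in% c(-1, 1)))
  expect_true(all(mix0$x[mix0$true_label == "E"] == 1))
  mix1 <- generate_x_mixture(50, -1, 1, 0.2, 0.2, 1, 0.5, seed = 27)
  expect_true(all(mix1$true_label == "E"))
  # component sample means close to truth at n = 2000
  mix2 <- generate_x_mixture(2000, -1, 1, 0.25, 0.25, 0.5, 0.1, seed = 28)
  expect_lt(abs(mean(mix2$x[mix2$true_label == "W"]) + 1), 0.05)
  expect_lt(abs(mean(mix2$x[mix2$true_label == "E"]) - 1), 0.05)
  # labeled fraction is honoured per component and labels are true
  n_lab_e <- sum(!is.na(mix2$label) & mix2$true_label == "E")
  expect_equal(n_lab_e, round(0.1 * sum(mix2$true_label == "E")))
  expect_true(all(mix2$label[!is.na(mix2$label)] ==
                    mix2$true_label[!is.na(mix2$label)]))
})

test_that("cohort metadata writes and the chunkcount dialect round-trips", {
  coh <- generate_cohort(two_pop_config(n = 20, seed = 30))
  meta <- withr::local_tempfile(fileext = ".tsv")
  write_metadata(coh$individuals, meta)
  back <- readr::read_tsv(meta, show_col_types = FALSE)
  expect_equal(back$id, coh$individuals$id)
  ccp <- withr::local_tempfile(fileext = ".chunkcounts.out")
  write_chunkcounts(coh$chunkcounts, ccp)
  expect_equal(unclass(read_chunkcounts(ccp)), unclass(coh$chunkcounts))
})
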