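# TVD between copying profiles and the agglomerative TVD-tree.

test_that("tvd evaluates worked values and rejects length mismatch", {
  expect_equal(tvd(c(0.5, 0.3, 0.2), c(0.2, 0.3, 0.5)), 0.3)
  expect_equal(tvd(c(1, 0), c(0, 1)), 1)
  expect_equal(tvd(c(0.4, 0.6), c(0.4, 0.6)), 0)
  expect_error(tvd(c(1, 0), c(1, 0, 0)), "length")
})

test_that("tvd is a metric on random simplex triples", {
  withr::local_seed(17)
  a <- random_simplex(2000, 5)
  b <- random_simplex(2000, 5)
  c_ <- random_simplex(2000, 5)
  d_ab <- 0.5 * rowSums(abs(a - b))
  d_ba <- 0.5 * rowSums(abs(b - a))
  d_ac <- 0.5 * rowSums(abs(a - c_))
  d_cb <- 0.5 * rowSums(abs(c_ - b))
  expect_equal(d_ab, d_ba)
  expect_true(all(d_ab >= 0 & d_ab <= 1))
  expect_true(all(d_ac + d_cb - d_ab >= -1e-12))
  # the vectorised oracle above agrees with the scalar operation
  i <- sample.int(2000, 25)
  expect_equal(vapply(i, function(j) tvd(a[j, ], b[j, ]), numeric(1)),
               d_ab[i])
})

test_that("pairwise TVD is symmetric, zero-diagonal, and matches the scalar op", {
  cfg <- nested_pair_config(n = 40, seed = 19)
  coh <- generate_cohort(cfg)
  prof <- population_profiles(coh$chunkcounts, cohort_labels(coh))
  d <- pairwise_tvd(prof)
  expect_lt(max(abs(d - t(d))), 1e-12)
  expect_equal(unname(diag(d)), rep(0, 4))
  m <- as.matrix(prof[, -1])
  expect_equal(d["A", "C"], tvd(m[prof$population == "A", ],
                                m[prof$population == "C", ]))
  # identical profiles sit at distance zero
  two <- rbind(X = c(0.5, 0.5), Y = c(0.5, 0.5))
  expect_equal(pairwise_tvd(two)["X", "Y"], 0)
})

test_that("a two-population tree is a single merge at the profile TVD", {
  cc <- exact_two_pop_counts()
  lab <- exact_two_pop_labels()
  tree <- build_tvd_tree(cc, lab)
  expect_equal(nrow(tree$merges), 1L)
  # profiles are exactly (0.7, 0.3) and (0.3, 0.7): TVD 0.4
  expect_equal(tree$merges$tvd, 0.4)
  expect_equal(to_newick(tree), "(A:0.4,B:0.4);")
})

test_that("populations sharing a profile merge first at height zero", {
  ids <- paste0("i", 1:6)
  m <- matrix(0, 6, 6, dimnames = list(ids, ids))
  # pops A = {1,2}, B = {3,4} both copy everything from C = {5,6}
  m[1:4, 5] <- 50; m[1:4, 6] <- 50
  m[5, 1] <- 80; m[5, 2] <- 20   # C copies from A
  m[6, 1] <- 80; m[6, 2] <- 20
  lab <- stats::setNames(rep(c("A", "B", "C"), each = 2), ids)
  tree <- suppressMessages(build_tvd_tree(chunkcounts(m), lab))
  expect_equal(tree$merges$left[1], "A")
  expect_equal(tree$merges$right[1], "B")
  expect_equal(tree$merges$tvd[1], 0)
})

test_that("the planted nested-pair topology is recovered", {
  hits <- vapply(1:20, function(s) {
    coh <- generate_cohort(nested_pair_config(n = 60, seed = 400 + s))
    tree <- build_tvd_tree(coh$chunkcounts, cohort_labels(coh))
    m <- tree$merges
    setequal(c(m$left[1], m$right[1], m$left[2], m$right[2]),
             c("A", "B", "C", "D")) &&
      paste(m$left[1], m$right[1]) %in% c("A B", "C D") &&
      paste(m$left[2], m$right[2]) %in% c("A B", "C D")
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("trees are invariant to individual order and label renaming", {
  coh <- generate_cohort(nested_pair_config(n = 40, seed = 23))
  cc <- coh$chunkcounts
  lab <- cohort_labels(coh)
  t1 <- build_tvd_tree(cc, lab)
  perm <- withr::with_seed(2, sample(rownames(cc)))
  t2 <- build_tvd_tree(chunkcounts(unclass(cc)[perm, perm]), lab[perm])
  expect_equal(t1$merges, t2$merges)
  # renaming A<->D only renames the merge table
  ren <- c(A = "D", B = "B", C = "C", D = "A")
  t3 <- build_tvd_tree(cc, stats::setNames(unname(ren[lab]), names(lab)))
  expect_equal(sort(t3$merges$tvd), sort(t1$merges$tvd), tolerance = 1e-12)
})

test_that("duplicating one population's individuals leaves pairwise TVD unchanged", {
  coh <- generate_cohort(nested_pair_config(n = 40, seed = 29))
  cc <- coh$chunkcounts
  lab <- cohort_labels(coh)
  d0 <- pairwise_tvd(population_profiles(cc, lab))
  # duplicate every A member's copying vector and recompute the
  # population profiles as unweighted means over members
  vec <- copying_profiles(cc, lab)
  vec$population <- unname(lab[vec$id])
  dup <- dplyr::bind_rows(vec, vec[vec$population == "A", ])
  prof_dup <- dup |>
    dplyr::summarise(dplyr::across(c("A", "B", "C", "D"), mean),
                     .by = "population")
  d1 <- pairwise_tvd(prof_dup)
  expect_equal(d1[rownames(d0), colnames(d0)], d0)
})

test_that("topology is robust to splitting the reference populations", {
  agree <- vapply(1:10, function(s) {
    coh <- generate_cohort(nested_pair_config(n = 60, seed = 600 + s))
    cc <- coh$chunkcounts
    lab <- cohort_labels(coh)
    # finer reference set: split population A into 4 arbitrary subgroups
    ref <- lab
    a_ids <- names(lab)[lab == "A"]
    ref[a_ids] <- paste0("A", (seq_along(a_ids) - 1L) %% 4 + 1L)
    t_k <- build_tvd_tree(cc, lab)
    t_k3 <- build_tvd_tree(cc, lab, reference_labeling = ref)
    identical(t_k$merges[c("left", "right")], t_k3$merges[c("left", "right")])
  }, logical(1))
  expect_gte(mean(agree), 0.9)
})

test_that("newick export round-trips and clips non-monotone heights", {
  skip_if_not_installed("ape")
  coh <- generate_cohort(nested_pair_config(n = 40, seed = 31))
  tree <- build_tvd_tree(coh$chunkcounts, cohort_labels(coh))
  ph <- ape::read.tree(text = to_newick(tree))
  expect_setequal(ph$tip.label, c("A", "B", "C", "D"))
  # root-to-tip depth equals the root merge TVD for every tip
  depths <- ape::node.depth.edgelength(ph)[seq_along(ph$tip.label)]
  expect_equal(depths, rep(max(tree$merges$tvd), 4), tolerance = 1e-9)
  # first-merging pair is a cherry in the exported tree
  first <- sort(c(tree$merges$left[1], tree$merges$right[1]))
  mrca <- ape::getMRCA(ph, first)
  expect_equal(sort(ape::extract.clade(ph, mrca)$tip.label), first)
  # hand-built non-monotone heights: clipped to zero with a warning
  bad <- structure(list(
    merges = tibble::tibble(step = 1:2, left = c("A", "A"),
                            right = c("B", "C"), tvd = c(0.4, 0.2)),
    leaves = c("A", "B", "C"),
    children = list(NULL, NULL, NULL, c(1L, 2L), c(4L, 3L)),
    heights = c(0, 0, 0, 0.4, 0.2),
    node_label = c("A", "B", "C", NA, NA),
    root = 5L
  ), class = "tvd_tree")
  expect_warning(nk <- to_newick(bad), "clipped")
  expect_false(grepl("-", nk, fixed = TRUE))
  # topology-only export carries no branch lengths
  expect_false(grepl(":", to_newick(tree, scale_branches = FALSE)))
})
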