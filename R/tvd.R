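# Total variation distance between population copying profiles, and the
# agglomerative TVD-tree: K-1 merges of the closest pair, with profiles
# always expressed against the original K reference populations so the
# distance does not depend on population sample sizes.

#' Total variation distance between two copying vectors
#'
#' Half the L1 distance, `0.5 * sum(abs(a - b))`: 0 iff the vectors are
#' equal, 1 iff their supports are disjoint.
#'
#' @param a,b Numeric simplex vectors of equal length.
#' @return A number in `[0, 1]`.
#' @export
tvd <- function(a, b) {
  if (length(a) != length(b)) abort("copying vectors differ in length.")
  0.5 * sum(abs(a - b))
}

# Coerce a profile input (tibble from population_profiles(), or a plain
# numeric matrix) to a populations x K matrix with rownames.
as_profile_matrix <- function(profiles) {
  if (is.data.frame(profiles)) {
    key <- intersect(c("population", "id"), names(profiles))[1]
    if (is.na(key)) abort("`profiles` needs a `population` (or `id`) column.")
    m <- as.matrix(profiles[setdiff(names(profiles), key)])
    rownames(m) <- as.character(profiles[[key]])
  } else {
    m <- as.matrix(profiles)
    if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  }
  storage.mode(m) <- "double"
  m
}

#' Pairwise TVD matrix between population profiles
#'
#' @param profiles Population copying profiles: the tibble returned by
#'   [population_profiles()], or a populations x K numeric matrix.
#' @return A symmetric matrix of TVD values with zero diagonal.
#' @export
pairwise_tvd <- function(profiles) {
  m <- as_profile_matrix(profiles)
  if (nrow(m) < 2L) abort("need at least 2 populations.")
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- tvd(m[i, ], m[j, ])
    }
  }
  d
}

#' Build the agglomerative TVD-tree over populations
#'
#' Starting from one K-dimensional copying profile per population
#' (individual-averaged), repeat K-1 times: compute TVD between every
#' pair of current populations, merge the pair with the smallest TVD
#' (ties broken by the lexicographically smallest label pair), and
#' replace it by a population whose profile is the unweighted mean over
#' all member individuals' copying vectors. Profiles stay K-dimensional
#' throughout, so distances never depend on how many populations remain.
#'
#' @param counts A [chunkcounts] matrix.
#' @param labeling Population labeling (data frame `id`, `population`
#'   or named vector) with K >= 2 nonempty populations.
#' @param reference_labeling Labeling defining the reference populations
#'   the copying vectors are expressed against; defaults to `labeling`.
#'   The merge distances are always computed in this fixed reference
#'   dimension, whatever the current number of populations.
#' @return An object of class `tvd_tree`: `merges` (tibble: step, left,
#'   right, tvd), `leaves`, and internal child/height bookkeeping used
#'   by [to_newick()].
#' @export
build_tvd_tree <- function(counts, labeling, reference_labeling = labeling) {
  lab <- as_labeling(labeling, rownames(counts))
  pops <- sort(population_levels(lab))
  k <- length(pops)
  if (k < 2L) abort("need at least 2 populations to build a tree.")
  indiv <- copying_matrix(counts, reference_labeling)

  # cluster state: profile (K-dim), member count, display label (the
  # lexicographically smallest leaf inside, for deterministic ties),
  # node id into the children/height tables
  prof <- t(vapply(pops, function(p) colMeans(indiv[lab == p, , drop = FALSE]),
                   numeric(ncol(indiv))))
  size <- as.numeric(table(lab)[pops])
  clab <- pops
  node <- seq_len(k)
  children <- vector("list", 2L * k - 1L)
  heights <- numeric(2L * k - 1L)
  node_label <- c(pops, rep(NA_character_, k - 1L))

  merges <- vector("list", k - 1L)
  tie_seen <- FALSE
  for (step in seq_len(k - 1L)) {
    n_cur <- length(clab)
    d <- pairwise_tvd(prof)
    best <- Inf; bi <- bj <- NA_integer_
    ord <- order(clab)      # scan label-sorted so ties pick smallest pair
    for (a in seq_len(n_cur - 1L)) {
      for (b in (a + 1L):n_cur) {
        i <- ord[a]; j <- ord[b]
        if (d[i, j] < best - 1e-15) {
          best <- d[i, j]; bi <- i; bj <- j
        } else if (abs(d[i, j] - best) <= 1e-15) {
          tie_seen <- TRUE
        }
      }
    }
    pair <- sort(c(clab[bi], clab[bj]))
    merges[[step]] <- tibble::tibble(step = step, left = pair[1],
                                     right = pair[2], tvd = best)
    new_id <- k + step
    children[[new_id]] <- c(node[bi], node[bj])
    heights[new_id] <- best
    # merged profile: size-weighted mean = mean over all member individuals
    w <- size[c(bi, bj)]
    prof[bi, ] <- (w[1] * prof[bi, ] + w[2] * prof[bj, ]) / sum(w)
    size[bi] <- sum(w)
    clab[bi] <- pair[1]
    node[bi] <- new_id
    prof <- prof[-bj, , drop = FALSE]
    size <- size[-bj]; clab <- clab[-bj]; node <- node[-bj]
  }
  if (tie_seen) {
    inform("tied minimal TVD encountered; broken by lexicographic label order.")
  }
  structure(list(
    merges = dplyr::bind_rows(merges),
    leaves = pops,
    children = children,
    heights = heights,
    node_label = node_label,
    root = 2L * k - 1L
  ), class = "tvd_tree")
}

#' @export
print.tvd_tree <- function(x, ...) {
  cat(sprintf("<tvd_tree: %d populations, %d merges (root TVD %.4f)>\n",
              length(x$leaves), nrow(x$merges), max(x$merges$tvd)))
  print(x$merges)
  invisible(x)
}

#' @describeIn build_tvd_tree The merge table as a tibble.
#' @param x A `tvd_tree` object.
#' @param ... Unused.
#' @method tidy tvd_tree
#' @export
tidy.tvd_tree <- function(x, ...) x$merges

#' Export a TVD-tree as a Newick string
#'
#' Node heights are the merge TVD values (cumulative-height convention);
#' a branch length is the parent's height minus the child's, clipped at
#' zero (with a warning) when a later merge had a smaller TVD. Leaves
#' sit at height zero.
#'
#' @param tree A [build_tvd_tree()] object.
#' @param scale_branches If `TRUE` (default) branch lengths encode TVD;
#'   if `FALSE` a topology-only Newick string is written.
#' @return A single Newick string, terminated by `;`.
#' @export
to_newick <- function(tree, scale_branches = TRUE) {
  clipped <- FALSE
  render <- function(id, parent_h) {
    h <- tree$heights[id]
    bl <- parent_h - h
    if (bl < 0) {
      clipped <<- TRUE
      bl <- 0
    }
    kids <- tree$children[[id]]
    core <- if (is.null(kids)) {
      tree$node_label[id]
    } else {
      paste0("(", render(kids[1], h), ",", render(kids[2], h), ")")
    }
    if (scale_branches) paste0(core, ":", format(bl, digits = 10)) else core
  }
  h_root <- tree$heights[tree$root]
  kids <- tree$children[[tree$root]]
  out <- paste0("(", render(kids[1], h_root), ",", render(kids[2], h_root), ");")
  if (clipped) {
    warn("non-monotone merge heights: negative branch length(s) clipped to 0.")
  }
  out
}

#' @describeIn build_tvd_tree Dendrogram of the merge history drawn from
#'   the Newick export (requires the ape package).
#' @param object A `tvd_tree` object.
#' @method autoplot tvd_tree
#' @export
autoplot.tvd_tree <- function(object, ...) {
  df <- object$merges
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$tvd)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(
      label = paste(.data$left, .data$right, sep = " + ")),
      hjust = -0.1, size = 3) +
    ggplot2::labs(x = "merge step", y = "TVD at merge") +
    ggplot2::theme_minimal()
}
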