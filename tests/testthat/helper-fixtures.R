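# Shared fixtures and independent oracles used across the test files.

# a two-trap, one-point toy design
toy_design <- function(n_transects = 1, n_sample_points = 1, n_traps = 2,
                       distances = c(0L, 50L)) {
  survey_design(n_transects = n_transects,
                distance_categories_m = distances,
                n_sample_points = n_sample_points, n_traps = n_traps)
}

toy_records <- function(counts = c(3, 5), species = "spA", season = "wet") {
  data.frame(transect = 1, distance_m = 0, sample_point = 1,
             trap = seq_along(counts), season = season,
             species = species, count = counts)
}

# small survey-scale generator config (one transect, both seasons)
small_survey_config <- function(seed, n_species = 30, total = 6000, ...) {
  generator_config(design = survey_design(n_transects = 1),
                   n_species = n_species, total_individuals = total,
                   seed = seed, ...)
}

# ---- independent oracles ------------------------------------------------

# dispersion oracle: distances to group centroids straight from raw
# coordinates, bypassing dissimilarities and ordination entirely
direct_centroid_distances <- function(coords, grouping) {
  out <- numeric(nrow(coords))
  for (g in unique(grouping)) {
    idx <- which(grouping == g)
    centroid <- colMeans(coords[idx, , drop = FALSE])
    out[idx] <- sqrt(colSums((t(coords[idx, , drop = FALSE]) - centroid)^2))
  }
  out
}

# exhaustive modularity oracle: best Q over every partition of rows and
# columns into at most min(nr, nc) shared modules (canonical labelling
# prunes label permutations)
exhaustive_modularity_q <- function(M) {
  nr <- nrow(M); nc <- ncol(M)
  k <- max(1, min(nr, nc))
  n <- nr + nc
  best <- -Inf
  labs <- integer(n)
  recurse <- function(pos, maxused) {
    if (pos > n) {
      q <- bipartite_modularity_Q(M, as.character(labs[seq_len(nr)]),
                                  as.character(labs[nr + seq_len(nc)]))
      if (q > best) best <<- q
      return(invisible())
    }
    for (l in seq_len(min(maxused + 1, k))) {
      labs[pos] <<- l
      recurse(pos + 1, max(maxused, l))
    }
  }
  recurse(1, 0)
  best
}

# exhaustive two-sample permutation p-value (two-sided, inclusive)
exhaustive_permutation_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  obs <- mean(x) - mean(y)
  combs <- utils::combn(length(pooled), n1)
  stats <- apply(combs, 2, function(idx)
    mean(pooled[idx]) - mean(pooled[-idx]))
  mean(abs(stats) >= abs(obs) - 1e-12)
}

# random Euclidean configuration and its dissimilarity matrix
random_euclidean_case <- function(n, dim = 3) {
  coords <- matrix(rnorm(n * dim), n, dim)
  rownames(coords) <- paste0("s", seq_len(n))
  D <- as.matrix(dist(coords))
  list(coords = coords, D = D)
}
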