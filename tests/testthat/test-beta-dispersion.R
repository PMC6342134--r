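test_that("modified Gower weights an order of magnitude like a composition change", {
  # one species, tenfold abundance change: distance exactly 1
  D <- modified_gower(rbind(a = c(spA = 1), b = c(spA = 10)))
  expect_equal(unname(D["a", "b"]), 1)
  # one compositional change over two non-double-zero species: 0.5
  D <- modified_gower(rbind(a = c(spA = 1, spB = 0), b = c(spA = 1, spB = 1)))
  expect_equal(unname(D["a", "b"]), 0.5)
  # identical samples
  D <- modified_gower(rbind(a = c(2, 3), b = c(2, 3)))
  expect_equal(unname(D["a", "b"]), 0)
  # two entirely empty samples are an undefined pair
  expect_error(modified_gower(rbind(a = c(0, 0), b = c(0, 0), c = c(1, 0))),
               "undefined pair.*'a' and 'b'")
})

test_that("modified Gower shifts by one unit when data are scaled by the base", {
  set.seed(31)
  x <- matrix(rpois(30, 4) + 1, 5, 6)  # all present: clean shift property
  D1 <- modified_gower(x, log_base = 10)
  D2 <- modified_gower(10 * x, log_base = 10)
  # every per-species transform shifts by exactly 1, differences unchanged
  expect_equal(unclass(D2), unclass(D1), tolerance = 1e-12)
})

test_that("modified Gower agrees with vegan's altGower on log-transformed data", {
  skip_if_not_installed("vegan")
  set.seed(12)
  x <- matrix(rpois(48, 2), 6, 8)
  x[rowSums(x) == 0, 1] <- 1
  ours <- modified_gower(x, log_base = 10)
  ref <- as.matrix(vegan::vegdist(vegan::decostand(x, "log", logbase = 10),
                                  method = "altGower"))
  expect_equal(unclass(ours), ref, ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("PCoA embeds any dissimilarity with the signed-distance identity", {
  # Euclidean-embeddable: collinear points, one positive eigenvalue,
  # distances reproduced exactly
  coords <- matrix(c(0, 1, 3), ncol = 1)
  D <- as.matrix(dist(coords))
  rownames(D) <- colnames(D) <- paste0("s", 1:3)
  emb <- pcoa(D)
  expect_equal(sum(emb$eigenvalues > 1e-8), 1)
  expect_equal(ncol(emb$neg), 0)
  expect_equal(as.matrix(dist(emb$pos)), D, ignore_attr = TRUE)

  # centering rank: at most n - 1 nonzero eigenvalues
  set.seed(8)
  case <- random_euclidean_case(5)
  emb <- pcoa(case$D)
  expect_lte(sum(abs(emb$eigenvalues) > 1e-8 * max(abs(emb$eigenvalues))), 4)

  # a non-Euclidean dissimilarity: negative eigenvalues appear, yet
  # d^2 = d+^2 - d-^2 still reconstructs the input
  Dn <- matrix(c(0, 1, 1, 1,
                 1, 0, 1, 1,
                 1, 1, 0, 2.4,
                 1, 1, 2.4, 0), 4, 4)
  emb <- pcoa(Dn)
  expect_gt(ncol(emb$neg), 0)
  dpos2 <- as.matrix(dist(emb$pos))^2
  dneg2 <- if (ncol(emb$neg) > 0) as.matrix(dist(emb$neg))^2 else 0
  expect_equal(dpos2 - dneg2, Dn^2, ignore_attr = TRUE, tolerance = 1e-8)

  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("dispersion from the embedding equals direct coordinate geometry", {
  # group of two samples at distance d: each sits d/2 from the centroid
  coords <- matrix(c(0, 0, 4, 0), 2, 2, byrow = TRUE,
                   dimnames = list(c("a", "b"), NULL))
  D <- as.matrix(dist(coords))
  res <- dispersion(pcoa(D), c(a = "g", b = "g"))
  expect_equal(res$distance, c(2, 2))

  # oracle equivalence over random Euclidean configurations, group sizes 1-6
  set.seed(99)
  for (rep in 1:40) {
    n <- sample(3:6, 1)
    case <- random_euclidean_case(n)
    grouping <- sample(letters[1:sample(1:3, 1)], n, replace = TRUE)
    got <- dispersion(pcoa(case$D), setNames(grouping, rownames(case$coords)))
    expect_equal(got$distance, direct_centroid_distances(case$coords, grouping),
                 tolerance = 1e-8)
  }

  # singletons and identical samples
  case <- random_euclidean_case(4)
  res <- dispersion(pcoa(case$D), setNames(letters[1:4], rownames(case$coords)))
  expect_equal(res$distance, rep(0, 4))
  expect_error(dispersion(pcoa(case$D), c(s1 = "a")), "missing from grouping")
})

test_that("dispersion agrees with vegan::betadisper on a non-Euclidean matrix", {
  skip_if_not_installed("vegan")
  set.seed(21)
  x <- matrix(rpois(60, 3), 10, 6, dimnames = list(paste0("t", 1:10), NULL))
  x[rowSums(x) == 0, 1] <- 1
  D <- modified_gower(x)
  grp <- rep(c("a", "b"), each = 5)
  ours <- dispersion(pcoa(D), setNames(grp, rownames(D)))
  ref <- vegan::betadisper(as.dist(D), grp, type = "centroid")
  expect_equal(ours$distance, unname(ref$distances), tolerance = 1e-6)
})

test_that("multiscale dispersion reflects where variation is planted", {
  # zero within-sample-point variation: identical traps in a point
  d <- survey_design(n_transects = 2, distance_categories_m = c(0L, 100L),
                     n_sample_points = 2, n_traps = 2)
  grid <- expand.grid(trap = 1:2, sample_point = 1:2, distance_m = c(0L, 100L),
                      transect = 1:2)
  set.seed(42)
  point_counts <- matrix(rpois(8 * 3, 5) + 1, 8, 3)  # one row per sample point
  pkey <- with(grid, interaction(transect, distance_m, sample_point))
  recs <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[rep(i, 3), ]
    rownames(g) <- NULL
    data.frame(g, season = "wet", species = paste0("sp", 1:3),
               count = point_counts[as.integer(pkey)[i], ])
  }))
  tab <- trap_table(recs, d)
  disp <- multiscale_dispersion(tab, "wet")
  sp <- disp[disp$scale == "sample_point", "distance"]
  tr <- disp[disp$scale == "transect", "distance"]
  expect_equal(sp, rep(0, length(sp)))
  expect_gt(mean(tr), 0)

  # exchangeable traps: mean squared distance scales as (1 - 1/n) with
  # group size n, so scale means follow the group-size correction
  cfg <- generator_config(design = survey_design(n_transects = 2),
                          n_species = 15, total_individuals = 6000,
                          distance_trend = c(wet = 0, dry = 0),
                          season_effect = 1, seed = 17)
  tab <- generate_survey(cfg)
  disp <- multiscale_dispersion(tab, "wet")
  msq <- tapply(disp$distance^2, disp$scale, mean)
  # nesting monotonicity: sample point (n~3) <= distance-by-transect
  # (n~15) <= transect (n~105)
  expect_lt(msq[["sample_point"]], msq[["distance_by_transect"]])
  expect_lt(msq[["distance_by_transect"]], msq[["transect"]])
  # after the (1 - 1/n) group-size correction the implied per-trap
  # variances agree across scales
  gsize <- stats::ave(disp$distance, disp$scale, disp$group, FUN = length)
  corr <- tapply(disp$distance^2 / (1 - 1 / pmax(gsize, 2)), disp$scale, mean)
  expect_lt(max(corr) / min(corr), 1.25)
})

test_that("planted among-category divergence raises the category-scale dispersion", {
  # distance trend shifts composition along the gradient: traps within a
  # category stay similar while categories diverge
  cfg <- generator_config(design = survey_design(n_transects = 2),
                          n_species = 15, total_individuals = 8000,
                          distance_trend = c(wet = -0.4, dry = 0),
                          season_effect = 1, structure = "modular",
                          strength = 0.8, seed = 23)
  disp <- multiscale_dispersion(generate_survey(cfg), "wet")
  m <- tapply(disp$distance, disp$scale, mean)
  expect_gt(m[["distance_category"]], m[["sample_point"]])
})
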