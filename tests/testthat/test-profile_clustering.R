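test_that("scale_profile_matrix centers, scales, and warns on constants", {
  m <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_warning(s <- scale_profile_matrix(m), "constant")
  expect_equal(unname(s[, "a"]), c(-1, 0, 1))
  expect_equal(unname(s[, "b"]), c(0, 0, 0))

  set.seed(2)
  r <- matrix(rnorm(60), 10, 6)
  sr <- scale_profile_matrix(r)
  expect_equal(unname(colMeans(sr)), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(apply(sr, 2, sd)), rep(1, 6), tolerance = 1e-12)
})

test_that("profile_distance implements 1 - r and euclidean with guards", {
  m <- rbind(x = c(1, 2, 3, 4), y = c(1, 2, 3, 4), z = c(4, 3, 2, 1))
  d <- profile_distance(m, "pearson")
  expect_equal(d["x", "y"], 0)
  expect_equal(d["x", "z"], 2)  # perfectly anti-correlated
  expect_true(isSymmetric(d))
  expect_equal(unname(diag(d)), rep(0, 3))

  # hand-computed r on a 3 x 4 toy
  toy <- rbind(p = c(1, 3, 2, 5), q = c(2, 2, 4, 4), r = c(5, 1, 2, 2))
  dtoy <- profile_distance(toy, "pearson")
  expect_equal(dtoy["p", "q"], 1 - cor(toy["p", ], toy["q", ]))

  de <- profile_distance(m, "euclidean")
  expect_equal(de["x", "z"], sqrt(sum((m["x", ] - m["z", ])^2)))

  m_na <- m; m_na[1, 1:2] <- NA
  expect_error(profile_distance(m_na, "spearman"), "fewer than 3")
})

test_that("hcluster reproduces textbook topologies and the naive oracle", {
  d <- matrix(5, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  diag(d) <- 0
  d["A", "B"] <- d["B", "A"] <- 1
  for (link in c("single", "complete", "average", "median")) {
    hc <- hcluster(d, link)
    expect_equal(dendro_clades(hc)[[1]], c("A", "B"), info = link)
  }

  # chaining configuration where single and complete linkage disagree:
  # equidistant points on a line (ties broken lexicographically)
  x <- c(p1 = 0, p2 = 1, p3 = 2, p4 = 3)
  dl <- as.matrix(dist(x))
  cl_single <- dendro_clades(hcluster(dl, "single"))
  cl_complete <- dendro_clades(hcluster(dl, "complete"))
  expect_false(identical(cl_single[[3]], cl_complete[[3]]) &&
                 identical(cl_single[[2]], cl_complete[[2]]))

  # average-linkage heights match the brute-force O(n^3) oracle
  set.seed(8)
  for (trial in 1:5) {
    pts <- matrix(rnorm(12), 6, 2)
    dm <- as.matrix(dist(pts))
    dimnames(dm) <- list(letters[1:6], letters[1:6])
    hc <- hcluster(dm, "average")
    oracle <- oracle_average_linkage(dm)
    expect_equal(hc$height, oracle$heights, tolerance = 1e-12)
    got_clades <- lapply(dendro_clades(hc), function(l) sort(match(l, letters)))
    expect_equal(got_clades, oracle$merges)
  }

  # all four linkages agree with stats::hclust on random matrices
  for (trial in 1:5) {
    dm <- as.matrix(dist(matrix(rnorm(14), 7, 2)))
    dimnames(dm) <- list(LETTERS[1:7], LETTERS[1:7])
    for (link in c("single", "complete", "average")) {
      hc <- hcluster(dm, link)
      ref <- stats::hclust(as.dist(dm), method = link)
      expect_equal(hc$height, ref$height, tolerance = 1e-12,
                   info = paste(link, trial))
    }
    # median linkage on squared distances, heights back on original scale
    hc_med <- hcluster(dm, "median")
    ref_med <- stats::hclust(as.dist(dm^2), method = "median")
    expect_equal(hc_med$height, sqrt(pmax(ref_med$height, 0)),
                 tolerance = 1e-12, info = paste("median", trial))
  }
})

test_that("multiscale bootstrap supports planted blocks and clamps extremes", {
  mm <- planted_block_matrix(n_per_block = 5, n_metrics = 12, noise = 0.25,
                             seed = 3)
  sc <- scale_profile_matrix(mm)
  b <- multiscale_bootstrap(sc, "pearson", "average", n_per_scale = 100,
                            seed = 1)
  sizes <- vapply(b$clades, length, 1L)
  blocks <- which(sizes == 5)
  expect_length(blocks, 2)
  expect_true(all(b$au[blocks] >= 0.95))
  expect_true(all(b$bp >= 0 & b$bp <= 1))
  expect_true(all(b$au >= 0 & b$au <= 1))
  # root clade present in every replicate -> clamped AU = 1 with flag
  root <- which(sizes == nrow(sc))
  expect_equal(b$au[root], 1)
  expect_equal(b$flags[root], "always")
  # bookkeeping: replicates per combination
  expect_equal(b$n_replicates, 10 * 100)
})

test_that("subtree co-occurrence matches the hand-counted 4-leaf example", {
  labs <- c("A", "B", "C", "D")
  t1 <- tree_from_dist(list(list("A", "B", 1), list("C", "D", 1)), labs)
  t2 <- tree_from_dist(list(list("A", "C", 1), list("B", "D", 1)), labs)
  t3 <- tree_from_dist(list(list("A", "B", 1), list("A", "C", 2)), labs)
  s <- subtree_cooccurrence(list(t1, t2, t3))
  # hand-counted pair events (T3 caterpillar contributes AB, AC, BC, AD,
  # BD, CD via the parent clades of C and D): AB=2, CD=2, AC=2, BD=2,
  # BC=1, AD=1; every leaf total is 5
  expect_equal(s["A", "B"], 2 * 2 / (5 + 5))
  expect_equal(s["C", "D"], 2 * 2 / (5 + 5))
  expect_equal(s["A", "C"], 2 * 2 / (5 + 5))
  expect_equal(s["B", "D"], 2 * 2 / (5 + 5))
  expect_equal(s["B", "C"], 2 * 1 / (5 + 5))
  expect_equal(s["A", "D"], 2 * 1 / (5 + 5))
  expect_true(isSymmetric(unclass(s)))
  expect_equal(unname(diag(s)), rep(1, 4))
  # invariant to replicate order
  s2 <- subtree_cooccurrence(list(t3, t1, t2))
  expect_equal(unclass(s2), unclass(s))
})

test_that("always-sister pairs score 1 and never-co-clustered pairs score 0", {
  labs <- c("A", "B", "C", "D")
  # cherry (A,B) always merges with the (C,D) cherry, never a lone leaf
  trees <- replicate(5, tree_from_dist(
    list(list("A", "B", 1), list("C", "D", 1)), labs), simplify = FALSE)
  s <- subtree_cooccurrence(trees)
  expect_equal(s["A", "B"], 1)
  expect_equal(s["C", "D"], 1)
  expect_equal(s["A", "C"], 0)
  expect_equal(s["B", "D"], 0)
})

test_that("pca_profiles returns orthonormal loadings and sane fractions", {
  set.seed(6)
  base <- rnorm(8)
  rank1 <- outer(c(1, 2, 3, 4, 5), base)
  dimnames(rank1) <- list(paste0("f", 1:5), paste0("m", 1:8))
  p <- pca_profiles(rank1)
  expect_equal(p$variance_explained[1], 1, tolerance = 1e-9)
  expect_equal(sum(p$variance_explained), 1, tolerance = 1e-9)
  g <- t(p$loadings) %*% p$loadings
  expect_equal(unname(g), diag(ncol(p$loadings)), tolerance = 1e-9)

  # isotropic 2-metric noise: PC1 fraction near 1/2
  fr <- vapply(1:60, function(i) {
    m <- matrix(rnorm(40), 20, 2)
    pca_profiles(m)$variance_explained[1]
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.55), 0.1)  # slightly above 0.5 by ordering
})

test_that("clustering_design enumerates the 16-combination bootstrap plan", {
  cd <- clustering_design()
  expect_equal(cd$n_combinations, 16)
  expect_equal(cd$n_boot_total, 160000)
  expect_setequal(unique(cd$combinations$distance),
                  c("pearson", "spearman", "kendall", "euclidean"))
  expect_setequal(unique(cd$combinations$linkage),
                  c("single", "complete", "average", "median"))
})

test_that("cluster_family_profiles accumulates replicates across combinations", {
  mm <- planted_block_matrix(n_per_block = 3, n_metrics = 8, seed = 5)
  sc <- scale_profile_matrix(mm)
  res <- cluster_family_profiles(sc, distances = c("pearson", "euclidean"),
                                 linkages = c("average", "complete"),
                                 scales = c(0.8, 1, 1.2), n_per_scale = 20,
                                 seed = 2)
  expect_equal(res$n_replicates_total, 4 * 3 * 20)
  expect_equal(sum(res$combinations[[1]]$pair_counts) > 0, TRUE)
  s <- res$similarity
  expect_true(all(s >= 0 & s <= 1))
  expect_true(isSymmetric(unclass(s)))
})
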