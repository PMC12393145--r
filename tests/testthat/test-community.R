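# Dissimilarities, ordination and permutation tests.

test_that("relative abundance normalises rows and rejects empty samples", {
  x <- rbind(s1 = c(2, 2), s2 = c(1, 3), s3 = c(0, 5))
  p <- relative_abundance(x)
  expect_equal(p["s1", ], c(0.5, 0.5))
  expect_equal(p["s2", ], c(0.25, 0.75))
  expect_equal(p["s3", ], c(0, 1))
  expect_equal(unname(rowSums(p)), rep(1, 3), tolerance = 1e-9)
  expect_error(relative_abundance(rbind(s1 = c(1, 1), bad = c(0, 0))),
               "bad")
})

test_that("Bray-Curtis matches hand computation and its limits", {
  x <- rbind(a = c(0.5, 0.5), b = c(1, 0), c = c(0.5, 0.5))
  D <- bray_curtis(x)
  expect_equal(unname(D["a", "b"]), 0.5)
  expect_equal(unname(D["a", "c"]), 0)
  disj <- rbind(a = c(1, 2, 0, 0), b = c(0, 0, 3, 1))
  expect_equal(unname(bray_curtis(disj)["a", "b"]), 1)
  expect_true(isSymmetric(D) && all(diag(D) == 0))
})

test_that("Bray-Curtis agrees with vegan and ignores taxon column order", {
  x <- rand_exchangeable_counts(7, seed = 11)
  D <- bray_curtis(x)
  expect_equal(max(abs(D - as.matrix(vegan::vegdist(x, "bray")))), 0,
               tolerance = 1e-12)
  perm <- sample(ncol(x))
  expect_equal(bray_curtis(x[, perm]), D, tolerance = 1e-12)
})

test_that("PCoA reproduces classical scaling geometry", {
  # equilateral triangle, side 1: two equal positive eigenvalues, third ~ 0
  D3 <- matrix(1, 3, 3) - diag(3)
  e <- pcoa(D3)
  ev <- sort(e$eig, decreasing = TRUE)
  expect_equal(ev[1], ev[2], tolerance = 1e-10)
  expect_equal(ev[3], 0, tolerance = 1e-10)
  # Euclidean input: embedding reconstructs distances exactly
  D <- rand_euclid_dist(9, seed = 2)
  p <- pcoa(D)
  expect_lt(max(abs(as.matrix(dist(p$points)) - D)), 1e-8)
  expect_equal(p$eig[p$eig > 1e-8],
               cmdscale(D, k = 2, eig = TRUE)$eig[p$eig > 1e-8],
               tolerance = 1e-8)
  # duplicated samples land on the same coordinates
  Dd <- as.matrix(dist(c(0, 0, 3)))
  pd <- pcoa(Dd)
  expect_equal(unname(pd$points[1, ]), unname(pd$points[2, ]),
               tolerance = 1e-10)
})

test_that("PCoA reports negative eigenvalues of semimetric inputs", {
  # 4 points, all pairs at distance 1 except one pair at 1.9: satisfies
  # the triangle inequality but admits no Euclidean embedding
  D <- matrix(1, 4, 4) - diag(4)
  D[1, 2] <- D[2, 1] <- 1.9
  e <- pcoa(D)
  expect_true(any(e$negative))
  expect_lt(min(e$eig), 0)
  expect_lt(ncol(e$points), 4)
})

test_that("PERMANOVA matches vegan's pseudo-F and R2", {
  x <- rand_exchangeable_counts(10, seed = 21)
  D <- bray_curtis(relative_abundance(x))
  g <- rep(c("u", "v"), each = 5)
  mine <- permanova(D, g, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(as.dist(D) ~ g, permutations = 19)
  expect_equal(mine$statistic, ref$F[1], tolerance = 1e-10)
  expect_equal(mine$variance_explained, ref$R2[1], tolerance = 1e-10)
})

test_that("PERMANOVA separates duplicated groups completely", {
  x <- rbind(a1 = c(10, 0, 0), a2 = c(10, 0, 0), a3 = c(10, 0, 0),
             b1 = c(0, 5, 5), b2 = c(0, 5, 5), b3 = c(0, 5, 5))
  D <- bray_curtis(x)
  res <- permanova(D, rep(c("a", "b"), each = 3), exact = TRUE)
  expect_equal(res$variance_explained, 1, tolerance = 1e-10)
  expect_equal(res$p_value, 2 / 20)  # identity and the group swap tie
})

test_that("permutation tests are label-exchange invariant and seeded", {
  x <- rand_exchangeable_counts(8, seed = 31)
  D <- bray_curtis(relative_abundance(x))
  g <- rep(c("u", "v"), each = 4)
  r1 <- permanova(D, g, n_perm = 199, seed = 7)
  ord <- c(3, 1, 8, 2, 5, 4, 7, 6)
  r2 <- permanova(D[ord, ord], g[ord], n_perm = 199, seed = 7)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
  expect_identical(r1$p_value, permanova(D, g, n_perm = 199, seed = 7)$p_value)
  expect_gt(r1$p_value, 0)
  expect_gte(r1$p_value, 1 / 200)
  # group-size validation
  expect_error(permanova(D, c("u", rep("v", 7)), n_perm = 9),
               "fewer than 2")
  expect_error(permanova(D, g, n_perm = 0), ">= 1")
})

test_that("PERMDISP sees equal dispersions in mirror-image groups", {
  set.seed(12)
  a <- matrix(rnorm(10), 5)
  b <- sweep(a, 2, c(50, 50), "+")   # same internal geometry, far away
  D <- as.matrix(dist(rbind(a, b)))
  rownames(D) <- colnames(D) <- paste0("s", 1:10)
  res <- permdisp(D, rep(c("a", "b"), each = 5), n_perm = 199, seed = 3)
  expect_lt(res$statistic, 1e-10)
  expect_equal(res$p_value, 1, tolerance = 1e-9)
})

test_that("PERMDISP distances match vegan::betadisper on Euclidean data", {
  set.seed(13)
  pts <- matrix(rnorm(24), 12)
  D <- as.matrix(dist(pts))
  rownames(D) <- colnames(D) <- paste0("s", 1:12)
  g <- rep(c("a", "b"), each = 6)
  res <- permdisp(D, g, n_perm = 99, seed = 1)
  ref <- vegan::betadisper(as.dist(D), g, type = "centroid")
  expect_equal(unname(res$distances), unname(ref$distances),
               tolerance = 1e-8)
  expect_equal(res$statistic, anova(ref)$`F value`[1], tolerance = 1e-8)
})

test_that("PERMDISP's observed F is maximal when one group has zero spread", {
  x <- rbind(a1 = c(1, 9), a2 = c(1, 9), a3 = c(1, 9),
             b1 = c(8, 1), b2 = c(2, 8), b3 = c(9, 9))
  D <- as.matrix(dist(x))
  g <- rep(c("a", "b"), each = 3)
  res <- permdisp(D, g, exact = TRUE)
  # independent enumeration over all 20 assignments of the same distances
  z <- res$distances
  f_of <- function(codes) {
    m <- tapply(z, codes, mean)
    ssb <- sum(tabulate(codes) * (m - mean(z))^2)
    ssw <- sum((z - m[codes])^2)
    (ssb / 1) / (ssw / 4)
  }
  combs <- combn(6, 3)
  fs <- apply(combs, 2, function(idx) {
    codes <- rep(2L, 6); codes[idx] <- 1L
    f_of(codes)
  })
  expect_equal(res$statistic, max(fs), tolerance = 1e-10)
  expect_equal(res$p_value, mean(fs >= res$statistic - 1e-12))
  expect_true(all(z >= 0))
  expect_equal(sum(z[g == "a"]), 0, tolerance = 1e-10)
})

test_that("rarefaction hits the target depth deterministically", {
  x <- rand_exchangeable_counts(4, depth = 300, seed = 41)
  r <- rarefy_counts(x, 100, seed = 2)
  expect_true(all(rowSums(r) == 100))
  expect_identical(r, rarefy_counts(x, 100, seed = 2))
  expect_error(rarefy_counts(x, 1000, seed = 2), "below")
})
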