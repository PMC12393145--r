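# Mantel tests and the radius scan.

test_that("geographic distances are plain Euclidean metres", {
  loc <- data.frame(sample_id = c("a", "b", "c", "d"),
                    x = c(0, 3, 0, 1), y = c(0, 4, 0, 0))
  D <- geographic_distance_matrix(loc)
  expect_equal(unname(D["a", "b"]), 5)
  expect_equal(unname(D["a", "c"]), 0)
  expect_equal(unname(D["a", "d"]), 1)
  expect_error(
    geographic_distance_matrix(data.frame(sample_id = c("a", "a"),
                                          x = 1:2, y = 1:2)),
    "duplicated")
})

test_that("identical matrices give Mantel r = 1 and degenerate input errors", {
  D <- rand_euclid_dist(6, seed = 3)
  m <- mantel(D, D, n_perm = 99, seed = 1)
  expect_equal(m$r, 1, tolerance = 1e-12)
  expect_gte(m$p_value, 1 / 100)
  Z <- matrix(1, 6, 6) - diag(6)  # constant off-diagonal: zero variance
  expect_error(mantel(D, Z, n_perm = 9), "zero variance")
  expect_error(mantel(D, rand_euclid_dist(5, seed = 1), n_perm = 9),
               "differ in size")
})

test_that("Mantel r agrees with vegan on random matrices", {
  Da <- rand_euclid_dist(9, seed = 7)
  Db <- rand_euclid_dist(9, seed = 8)
  Dc <- rand_euclid_dist(9, seed = 9)
  expect_equal(mantel(Da, Db, n_perm = 9, seed = 1)$r,
               unname(vegan::mantel(as.dist(Da), as.dist(Db),
                                    permutations = 0)$statistic),
               tolerance = 1e-10)
  expect_equal(partial_mantel(Da, Db, Dc, n_perm = 9, seed = 1)$r,
               unname(vegan::mantel.partial(as.dist(Da), as.dist(Db),
                                            as.dist(Dc),
                                            permutations = 0)$statistic),
               tolerance = 1e-10)
})

test_that("the Mantel null p-value is approximately uniform", {
  Da <- rand_euclid_dist(10, seed = 100)
  rejections <- vapply(1:200, function(s) {
    Db <- rand_euclid_dist(10, seed = 200 + s)  # independent of Da
    mantel(Da, Db, n_perm = 199, seed = s)$p_value <= 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.01)
  expect_lte(mean(rejections), 0.10)
})

test_that("controlling for a constant matrix reduces to the simple Mantel", {
  Da <- rand_euclid_dist(8, seed = 17)
  Db <- rand_euclid_dist(8, seed = 18)
  Dc <- matrix(2, 8, 8) - 2 * diag(8)
  dimnames(Dc) <- dimnames(Da)
  expect_equal(partial_mantel(Da, Db, Dc, n_perm = 9, seed = 1)$r,
               mantel(Da, Db, n_perm = 9, seed = 1)$r, tolerance = 1e-12)
})

test_that("controlling a matrix for itself leaves no correlation", {
  Da <- rand_euclid_dist(8, seed = 19)
  Db <- rand_euclid_dist(8, seed = 20)
  expect_equal(partial_mantel(Da, Db, Da, n_perm = 9, seed = 1)$r, 0,
               tolerance = 1e-10)
  expect_error(partial_mantel(Da, Db, 2 * Db, n_perm = 9), "collinear")
})

test_that("a single-radius scan reduces to one partial Mantel call", {
  land <- generate_landscape(landscape_config(seed = 23L))
  prof <- random_source_profiles(
    c("bare", "forb", "shrub", names(land$map$avg_grass)), seed = 2)
  tab <- simulate_trap_communities(land$map, land$locations, prof,
                                   trap_sim_config(seed = 3))
  D <- bray_curtis(relative_abundance(tab))
  scan <- radius_scan(land$map, land$locations, D, radii = 1.5,
                      n_perm = 99, seed = 11)
  plant_D <- bray_curtis(plant_composition_matrix(land$map, land$locations,
                                                  1.5))
  geo_D <- geographic_distance_matrix(land$locations)
  ref <- partial_mantel(D, plant_D, geo_D, n_perm = 99,
                        seed = dispersalkit:::substream(11, "radius", 1))
  expect_equal(scan$results$r, ref$r, tolerance = 1e-12)
  expect_identical(scan$results$p_value, ref$p_value)
  expect_equal(scan$best_radius_m, 1.5)
})

test_that("scans are deterministic under a fixed seed", {
  land <- generate_landscape(landscape_config(seed = 29L))
  prof <- random_source_profiles(
    c("bare", "forb", "shrub", names(land$map$avg_grass)), seed = 2)
  tab <- simulate_trap_communities(land$map, land$locations, prof,
                                   trap_sim_config(seed = 3))
  D <- bray_curtis(relative_abundance(tab))
  radii <- c(0.5, 1, 2)
  s1 <- radius_scan(land$map, land$locations, D, radii = radii,
                    n_perm = 49, seed = 4)
  s2 <- radius_scan(land$map, land$locations, D, radii = radii,
                    n_perm = 49, seed = 4)
  expect_identical(s1$results, s2$results)
  expect_true(s1$best_radius_m %in% radii)
  expect_true(all(diff(s1$results$radius_m) > 0))
})

test_that("radii with identical plant composition are flagged, not fatal", {
  map <- one_patch_map("shrub")   # one category everywhere
  loc <- data.frame(sample_id = paste0("t", 1:6),
                    x = seq(5, 35, length.out = 6), y = 15,
                    stringsAsFactors = FALSE)
  D <- rand_euclid_dist(6, seed = 31)
  dimnames(D) <- list(loc$sample_id, loc$sample_id)
  scan <- radius_scan(map, loc, D, radii = c(0.5, 1), n_perm = 19, seed = 1)
  expect_true(all(scan$results$degenerate))
  expect_true(is.na(scan$best_radius_m))
})
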