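# Shared fixture builders (everything is generated in code).

# a map consisting of a single huge category polygon covering the domain
one_patch_map <- function(category = "shrub", domain = c(0, 0, 40, 30)) {
  plant_map(
    list(list(poly = dispersalkit:::rect_poly(domain[1], domain[2],
                                              domain[3], domain[4]),
              category = category)),
    domain = domain, avg_grass = c(grass = 1))
}

# Euclidean distance matrix of random planar points (always embeddable)
rand_euclid_dist <- function(n, seed) {
  set.seed(seed)
  pts <- matrix(rnorm(2 * n), n)
  D <- as.matrix(dist(pts))
  dimnames(D) <- list(paste0("s", 1:n), paste0("s", 1:n))
  D
}

# random count table, samples exchangeable (single underlying profile)
rand_exchangeable_counts <- function(n, depth = 500, n_taxa = 40,
                                     seed = 1) {
  set.seed(seed)
  prob <- rgamma(n_taxa, 1)
  prob <- prob / sum(prob)
  x <- t(rmultinom(n, depth, prob))
  rownames(x) <- paste0("s", seq_len(n))
  x
}

# closed-slide decay series built directly from the model
closed_series <- function(days, n0, delta, ecosystem = "shrubland") {
  data.frame(
    slide_id = sprintf("c%03d", seq_along(days)),
    slide_type = "closed", ecosystem = ecosystem, transect = 1L,
    offset_m = -7, day = days,
    cells_per_cm2 = n0 * exp(-delta * days),
    stringsAsFactors = FALSE)
}

open_series <- function(days, I, delta) {
  mu <- if (delta > 0) (I / delta) * (1 - exp(-delta * days)) else I * days
  data.frame(
    slide_id = sprintf("o%03d", seq_along(days)),
    slide_type = "open", ecosystem = "grassland", transect = 1L,
    offset_m = 7, day = days, cells_per_cm2 = mu,
    stringsAsFactors = FALSE)
}
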