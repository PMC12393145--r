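# Mantel correlations between distance matrices and the radius-scanned
# partial Mantel analysis that localises the spatial scale at which
# surrounding vegetation predicts the composition of trapped microbes.

lower_vec <- function(D) D[lower.tri(D)]

check_aligned <- function(..., min_n = 4L) {
  mats <- list(...)
  n <- nrow(mats[[1L]])
  for (m in mats) {
    if (nrow(m) != n)
      stop("distance matrices differ in size", call. = FALSE)
  }
  nms <- lapply(mats, rownames)
  nms <- nms[!vapply(nms, is.null, TRUE)]
  if (length(nms) > 1L && !all(vapply(nms[-1L], identical, TRUE, nms[[1L]])))
    stop("distance matrices are not aligned on the same sample order",
         call. = FALSE)
  if (n < min_n)
    stop(sprintf("need at least %d samples", min_n), call. = FALSE)
  n
}

# residuals of y on x (with intercept); if x has no variance, y is only
# centred, so "controlling" for a constant matrix is a no-op
resid_on <- function(y, x) {
  if (var(x) < 1e-14) return(y - mean(y))
  b <- cov(x, y) / var(x)
  y - mean(y) - b * (x - mean(x))
}

#' Euclidean geographic distance matrix
#'
#' @param locations data.frame with columns sample_id, x, y (planar
#'   coordinates, metres).
#' @return square symmetric matrix of pairwise Euclidean distances with
#'   sample ids as dimnames.
#' @export
geographic_distance_matrix <- function(locations) {
  req <- c("sample_id", "x", "y")
  if (!all(req %in% names(locations)))
    stop("`locations` needs columns sample_id, x, y", call. = FALSE)
  if (anyDuplicated(locations$sample_id))
    stop("duplicated sample id: ",
         locations$sample_id[duplicated(locations$sample_id)][1L],
         call. = FALSE)
  if (nrow(locations) < 2L)
    stop("need >= 2 locations", call. = FALSE)
  D <- as.matrix(dist(cbind(locations$x, locations$y)))
  dimnames(D) <- list(locations$sample_id, locations$sample_id)
  D
}

#' Simple Mantel test
#'
#' Pearson correlation of the strictly-lower-triangle entries of two
#' aligned distance matrices, with a one-sided (positive association)
#' permutation p-value obtained by jointly permuting the rows and columns
#' of the first matrix (add-one rule).  `exact = TRUE` enumerates all
#' relabelings (n <= 8).
#'
#' @param Da,Db aligned distance matrices (>= 4 samples).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param exact enumerate all n! relabelings.
#' @return object of class `mantel_result` with r, p_value,
#'   n_permutations, partial = FALSE.
#' @export
mantel <- function(Da, Db, n_perm = 999L, seed = NULL, exact = FALSE) {
  Da <- validate_dist_matrix(Da, "Da")
  Db <- validate_dist_matrix(Db, "Db")
  n <- check_aligned(Da, Db, min_n = 4L)
  va <- lower_vec(Da)
  vb <- lower_vec(Db)
  if (var(va) < 1e-14 || var(vb) < 1e-14)
    stop("undefined correlation: a distance matrix has zero variance",
         call. = FALSE)
  r_obs <- cor(va, vb)
  if (exact) {
    perms <- all_perms(n)
    stats <- apply(perms, 1L, function(p)
      cor(lower_vec(Da[p, p]), vb))
    p_val <- mean(stats >= r_obs - 1e-12)
    n_used <- nrow(perms)
  } else {
    n_perm <- check_count(n_perm, "n_perm")
    stats <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
      p <- sample(n)
      cor(lower_vec(Da[p, p]), vb)
    }, numeric(1L)))
    p_val <- (1 + sum(stats >= r_obs - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(list(r = r_obs, p_value = p_val, n_permutations = n_used,
                 partial = FALSE, radius_m = NA_real_, seed = seed,
                 exact = exact),
            class = "mantel_result")
}

#' Partial Mantel test
#'
#' Correlation between two distance matrices after removing, from each, the
#' linear dependence on a third (residual method): `r` is the Pearson
#' correlation of the OLS residuals of the lower-triangle vectors of `Da`
#' and `Db` on that of `Dc`.  The permutation null relabels the focal
#' matrix `Da` (rows and columns jointly) and recomputes its residuals;
#' the p-value is one-sided for positive association with the add-one
#' rule.  A constant `Dc` controls for nothing, so the statistic reduces
#' to the simple Mantel r.
#'
#' @param Da focal distance matrix (permuted under the null).
#' @param Db comparison distance matrix.
#' @param Dc conditioning distance matrix (e.g. geographic distance).
#' @inheritParams mantel
#' @return object of class `mantel_result` with partial = TRUE.
#' @export
partial_mantel <- function(Da, Db, Dc, n_perm = 999L, seed = NULL) {
  Da <- validate_dist_matrix(Da, "Da")
  Db <- validate_dist_matrix(Db, "Db")
  Dc <- validate_dist_matrix(Dc, "Dc")
  n <- check_aligned(Da, Db, Dc, min_n = 5L)
  n_perm <- check_count(n_perm, "n_perm")
  va <- lower_vec(Da)
  vb <- lower_vec(Db)
  vc <- lower_vec(Dc)
  if (var(va) < 1e-14 || var(vb) < 1e-14)
    stop("undefined correlation: a distance matrix has zero variance",
         call. = FALSE)
  eb <- resid_on(vb, vc)
  if (var(eb) < 1e-14)
    stop("degenerate partial correlation: `Db` is perfectly collinear ",
         "with the conditioning matrix", call. = FALSE)
  # a focal matrix identical (up to affine scale) to the conditioning one
  # has nothing left to correlate: its partial r is 0 by convention
  pcor <- function(v) {
    e <- resid_on(v, vc)
    if (var(e) < 1e-14) 0 else cor(e, eb)
  }
  r_obs <- pcor(va)
  stats <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    p <- sample(n)
    pcor(lower_vec(Da[p, p]))
  }, numeric(1L)))
  p_val <- (1 + sum(stats >= r_obs - 1e-12)) / (1 + n_perm)
  structure(list(r = r_obs, p_value = p_val, n_permutations = n_perm,
                 partial = TRUE, radius_m = NA_real_, seed = seed,
                 exact = FALSE),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("%s Mantel test: r = %.4f, P = %.4g (%d permutations)%s\n",
              if (x$partial) "Partial" else "Simple", x$r, x$p_value,
              x$n_permutations,
              if (is.finite(x$radius_m))
                sprintf(" [radius %.3g m]", x$radius_m) else ""))
  invisible(x)
}

#' Default radius grid for the scale scan
#'
#' Eleven log-spaced radii spanning 0.1 to 4 m.
#'
#' @param n number of radii.
#' @param from,to range in metres.
#' @return strictly increasing numeric vector.
#' @export
default_radii <- function(n = 11L, from = 0.1, to = 4) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Radius-scanned partial Mantel analysis
#'
#' For each candidate radius, computes the plant composition around every
#' sample ([plant_composition_at_radius()]), the Bray-Curtis distance
#' matrix of those compositions, and the partial Mantel correlation of the
#' microbial distance matrix with the plant distance matrix controlling
#' for geographic distance.  The radius with the largest partial r
#' localises the spatial scale at which surrounding vegetation best
#' predicts the composition of arriving microbes.  Radii at which all
#' samples share an identical plant composition are flagged degenerate and
#' excluded from the argmax.  Per-radius permutations use independent
#' substreams derived from `seed`.
#'
#' @param map a [plant_map()].
#' @param samples data.frame with sample_id, x, y, aligned with
#'   `microbial_D`'s dimnames.
#' @param microbial_D microbial community dissimilarity matrix.
#' @param radii strictly increasing radii (m); default [default_radii()].
#' @param avg_grass grass composition for unmapped area.
#' @param n_perm permutations per radius.
#' @param seed integer seed for the scan.
#' @param holm also report Holm-adjusted p-values across radii.
#' @return object of class `radius_scan`: `results` data.frame (radius_m,
#'   r, p_value, p_holm, n_permutations, degenerate), `best_radius_m`,
#'   `best_r`.
#' @export
radius_scan <- function(map, samples, microbial_D, radii = default_radii(),
                        avg_grass = map$avg_grass, n_perm = 999L,
                        seed = NULL, holm = TRUE) {
  stopifnot(inherits(map, "plant_map"))
  if (!is.numeric(radii) || length(radii) == 0L || any(radii <= 0) ||
      is.unsorted(radii, strictly = TRUE))
    stop("`radii` must be strictly increasing and positive", call. = FALSE)
  microbial_D <- validate_dist_matrix(microbial_D, "microbial_D")
  if (!is.null(rownames(microbial_D)) &&
      !identical(rownames(microbial_D), samples$sample_id))
    stop("`microbial_D` is not aligned with `samples`", call. = FALSE)
  geo_D <- geographic_distance_matrix(samples)
  res <- data.frame(radius_m = radii, r = NA_real_, p_value = NA_real_,
                    n_permutations = NA_integer_, degenerate = FALSE)
  for (i in seq_along(radii)) {
    comp <- plant_composition_matrix(map, samples, radii[i],
                                     avg_grass = avg_grass)
    plant_D <- bray_curtis(comp)
    if (var(lower_vec(plant_D)) < 1e-14) {
      res$degenerate[i] <- TRUE
      next
    }
    m <- partial_mantel(microbial_D, plant_D, geo_D, n_perm = n_perm,
                        seed = if (is.null(seed)) NULL else
                          substream(seed, "radius", i))
    res$r[i] <- m$r
    res$p_value[i] <- m$p_value
    res$n_permutations[i] <- m$n_permutations
  }
  if (holm) {
    ok <- !res$degenerate
    res$p_holm <- NA_real_
    res$p_holm[ok] <- stats::p.adjust(res$p_value[ok], method = "holm")
  }
  usable <- which(!res$degenerate)
  best <- if (length(usable)) usable[which.max(res$r[usable])] else NA_integer_
  structure(list(results = res,
                 best_radius_m = if (is.na(best)) NA_real_ else radii[best],
                 best_r = if (is.na(best)) NA_real_ else res$r[best],
                 radii = radii, n_permutations = n_perm, seed = seed),
            class = "radius_scan")
}

#' @export
print.radius_scan <- function(x, ...) {
  cat(sprintf("Radius scan: %d radii from %.3g to %.3g m\n",
              length(x$radii), min(x$radii), max(x$radii)))
  print(transform(x$results, r = round(r, 4), p_value = round(p_value, 4)),
        row.names = FALSE)
  cat(sprintf("strongest partial Mantel correlation: r = %.4f at %.3g m\n",
              x$best_r, x$best_radius_m))
  invisible(x)
}

#' Plot a radius scan
#'
#' Partial Mantel r against radius (log axis); radii significant at the 5%
#' level are drawn filled.
#'
#' @param x a `radius_scan`.
#' @param alpha significance level for the filled symbols.
#' @param ... passed to [plot()].
#' @export
plot.radius_scan <- function(x, alpha = 0.05, ...) {
  r <- x$results
  plot(r$radius_m, r$r, log = "x", xlab = "radius (m)",
       ylab = "partial Mantel r", type = "b",
       pch = ifelse(!is.na(r$p_value) & r$p_value <= alpha, 16, 1), ...)
  abline(v = x$best_radius_m, lty = 3)
  invisible(x)
}
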