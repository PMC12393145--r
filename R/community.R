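# Compositional dissimilarity and permutation tests, implemented directly
# from the distance matrix: Bray-Curtis, principal coordinates, PERMANOVA
# (Anderson's pseudo-F) and PERMDISP (homogeneity of dispersions).

validate_dist_matrix <- function(D, name = "D") {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D))
    stop(sprintf("`%s` must be square", name), call. = FALSE)
  if (any(!is.finite(D)) || any(D < 0))
    stop(sprintf("`%s` must be finite and non-negative", name), call. = FALSE)
  if (max(abs(D - t(D))) > 1e-8)
    stop(sprintf("`%s` must be symmetric", name), call. = FALSE)
  if (any(abs(diag(D)) > 1e-8))
    stop(sprintf("`%s` must have a zero diagonal", name), call. = FALSE)
  D
}

#' Convert a count table to relative abundance
#'
#' @param table samples x taxa matrix (or data.frame) of non-negative
#'   counts.
#' @return matrix of proportions; rows sum to 1.
#' @export
relative_abundance <- function(table) {
  x <- as.matrix(table)
  if (any(x < 0)) stop("counts must be non-negative", call. = FALSE)
  tot <- rowSums(x)
  if (any(tot <= 0)) {
    bad <- rownames(x)[which(tot <= 0)[1L]] %||% which(tot <= 0)[1L]
    stop("empty sample: ", bad, call. = FALSE)
  }
  x / tot
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{BC(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}, computed
#' between all sample pairs of a counts or proportions table.
#'
#' @param table samples x taxa matrix; rows are samples.
#' @return square symmetric matrix with zero diagonal; entries in \[0, 1\].
#' @export
bray_curtis <- function(table) {
  x <- as.matrix(table)
  if (any(x < 0)) stop("abundances must be non-negative", call. = FALSE)
  tot <- rowSums(x)
  if (any(tot <= 0)) {
    bad <- rownames(x)[which(tot <= 0)[1L]] %||% which(tot <= 0)[1L]
    stop("Bray-Curtis undefined: sample ", bad, " is all zero", call. = FALSE)
  }
  num <- as.matrix(dist(x, method = "manhattan"))
  D <- num / outer(tot, tot, "+")
  diag(D) <- 0
  dimnames(D) <- list(rownames(x), rownames(x))
  D
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of a dissimilarity matrix: the matrix
#' \eqn{-\frac12 d_{ij}^2} is double-centred and eigendecomposed; axes are
#' returned for positive eigenvalues.  Negative eigenvalues (possible for
#' semimetric dissimilarities such as Bray-Curtis) are reported, not
#' dropped silently.
#'
#' @param D distance matrix (square symmetric, zero diagonal).
#' @return object of class `pcoa`: `points` (n x k coordinates for positive
#'   eigenvalues), `eig` (all eigenvalues), `negative` (logical flags).
#' @export
pcoa <- function(D) {
  D <- validate_dist_matrix(D)
  n <- nrow(D)
  A <- -0.5 * D^2
  B <- A - matrix(rowMeans(A), n, n) - matrix(colMeans(A), n, n, byrow = TRUE) +
    mean(A)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9 + 1e-12
  pos <- e$values > tol
  pts <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  rownames(pts) <- rownames(D)
  structure(list(points = pts, eig = e$values, negative = e$values < -tol),
            class = "pcoa")
}

#' @export
print.pcoa <- function(x, ...) {
  cat(sprintf("PCoA: %d samples, %d positive axes", nrow(x$points),
              ncol(x$points)))
  if (any(x$negative))
    cat(sprintf(", %d negative eigenvalues (min %.3g)", sum(x$negative),
                min(x$eig)))
  cat("\n")
  invisible(x)
}

# --- permutation machinery ---------------------------------------------

# all permutations of 1..n (n <= 8), one per row
all_perms <- function(n) {
  if (n > 8L) stop("exhaustive enumeration limited to n <= 8", call. = FALSE)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, matrix(c(seq_len(n)[-k])[sub], nrow(sub), n - 1L))
  }))
}

# all distinct arrangements of a label vector, one per row
multiset_perms <- function(v) {
  v <- as.integer(v)
  counts <- table(v)
  total <- exp(lgamma(length(v) + 1) - sum(lgamma(counts + 1)))
  if (total > 1e5)
    stop("too many distinct label arrangements for exhaustive enumeration",
         call. = FALSE)
  rec <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1L, 1L))
    out <- list()
    for (x in unique(v)) {
      i <- match(x, v)
      sub <- rec(v[-i])
      out[[length(out) + 1L]] <- cbind(x, sub, deparse.level = 0)
    }
    do.call(rbind, out)
  }
  rec(v)
}

permanova_f <- function(d2, codes, sizes, sst, a, n) {
  ssw <- 0
  for (l in seq_along(sizes)) {
    idx <- which(codes == l)
    ssw <- ssw + sum(d2[idx, idx]) / (2 * sizes[l])
  }
  ssb <- sst - ssw
  c(f = (ssb / (a - 1)) / (ssw / (n - a)), r2 = ssb / sst)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-way PERMANOVA computed directly from the dissimilarity matrix:
#' \eqn{SS_{total} = \frac1N \sum_{i<j} d_{ij}^2},
#' \eqn{SS_{within} = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d_{ij}^2}, and
#' the pseudo-F compares the between- and within-group mean squares.
#' Significance comes from permuting group labels; the p-value uses the
#' add-one rule \eqn{(1 + \#\{F^* \ge F\})/(1 + n_{perm})}, so it can never
#' be exactly zero.  With `exact = TRUE` all distinct label arrangements
#' are enumerated instead and the p-value is the exact tail proportion.
#'
#' @param D dissimilarity matrix.
#' @param groups group labels, one per sample; >= 2 groups, each with >= 2
#'   samples.
#' @param n_perm number of random permutations (ignored when `exact`).
#' @param seed integer seed for the permutation stream.
#' @param exact enumerate all distinct label arrangements.
#' @return object of class `perm_test` with statistic (pseudo-F), p_value,
#'   variance_explained (partial R2 of the grouping), df, n_permutations,
#'   seed.
#' @export
permanova <- function(D, groups, n_perm = 999L, seed = NULL, exact = FALSE) {
  D <- validate_dist_matrix(D)
  g <- factor(groups)
  n <- nrow(D)
  if (length(g) != n)
    stop("`groups` must have one label per sample", call. = FALSE)
  sizes <- table(g)
  if (nlevels(g) < 2L)
    stop("need >= 2 groups", call. = FALSE)
  if (any(sizes < 2L))
    stop("group ", sQuote(names(sizes)[sizes < 2L][1L]),
         " has fewer than 2 samples", call. = FALSE)
  if (!exact) n_perm <- check_count(n_perm, "n_perm")
  a <- nlevels(g)
  d2 <- D^2
  sst <- sum(d2) / (2 * n)
  codes <- as.integer(g)
  obs <- permanova_f(d2, codes, as.numeric(sizes), sst, a, n)
  if (exact) {
    arr <- multiset_perms(codes)
    stats <- apply(arr, 1L, function(cc)
      permanova_f(d2, cc, as.numeric(sizes), sst, a, n)[1L])
    p <- mean(stats >= obs[1L] - 1e-12)
    n_used <- nrow(arr)
  } else {
    stats <- with_seed(seed, vapply(seq_len(n_perm), function(b)
      permanova_f(d2, sample(codes), as.numeric(sizes), sst, a, n)[1L],
      numeric(1L)))
    p <- (1 + sum(stats >= obs[1L] - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(list(method = "PERMANOVA", statistic = unname(obs[1L]),
                 df = c(a - 1L, n - a), p_value = p,
                 variance_explained = unname(obs[2L]),
                 n_permutations = n_used, seed = seed, exact = exact),
            class = "perm_test")
}

dispersion_f <- function(z, codes, a, n) {
  gm <- tapply(z, codes, mean)
  sizes <- tabulate(codes, a)
  ssb <- sum(sizes * (gm - mean(z))^2)
  ssw <- sum((z - gm[codes])^2)
  c(f = (ssb / (a - 1)) / (ssw / (n - a)), r2 = ssb / (ssb + ssw))
}

#' Permutation test for homogeneity of multivariate dispersions (PERMDISP)
#'
#' Embeds the samples by principal coordinates (positive-eigenvalue axes
#' only), computes each sample's Euclidean distance to its own group
#' centroid, and F-tests the group effect on those distances; significance
#' by permuting group labels over the fixed centroid distances (add-one
#' rule).
#'
#' @inheritParams permanova
#' @return object of class `perm_test` (statistic = F on centroid
#'   distances; variance_explained = R2 of group on those distances).
#' @export
permdisp <- function(D, groups, n_perm = 999L, seed = NULL, exact = FALSE) {
  D <- validate_dist_matrix(D)
  g <- factor(groups)
  n <- nrow(D)
  if (length(g) != n)
    stop("`groups` must have one label per sample", call. = FALSE)
  sizes <- table(g)
  if (nlevels(g) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(sizes < 2L))
    stop("group ", sQuote(names(sizes)[sizes < 2L][1L]),
         " has fewer than 2 samples", call. = FALSE)
  if (!exact) n_perm <- check_count(n_perm, "n_perm")
  pts <- pcoa(D)$points
  codes <- as.integer(g)
  a <- nlevels(g)
  cent <- apply(pts, 2L, function(col) tapply(col, codes, mean))
  cent <- matrix(cent, nrow = a)
  z <- sqrt(rowSums((pts - cent[codes, , drop = FALSE])^2))
  obs <- dispersion_f(z, codes, a, n)
  if (exact) {
    arr <- multiset_perms(codes)
    stats <- apply(arr, 1L, function(cc) dispersion_f(z, cc, a, n)[1L])
    p <- mean(stats >= obs[1L] - 1e-12)
    n_used <- nrow(arr)
  } else {
    stats <- with_seed(seed, vapply(seq_len(n_perm), function(b)
      dispersion_f(z, sample(codes), a, n)[1L], numeric(1L)))
    p <- (1 + sum(stats >= obs[1L] - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(list(method = "PERMDISP", statistic = unname(obs[1L]),
                 df = c(a - 1L, n - a), p_value = p,
                 variance_explained = unname(obs[2L]),
                 n_permutations = n_used, seed = seed, exact = exact,
                 distances = z, group = g),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("%s: pseudo-F(%d, %d) = %.3f, P = %.4g (%s %d permutations)\n",
              x$method, x$df[1L], x$df[2L], x$statistic, x$p_value,
              if (isTRUE(x$exact)) "exhaustive," else "", x$n_permutations))
  if (!is.null(x$variance_explained))
    cat(sprintf("  variance explained: %.1f%%\n",
                100 * x$variance_explained))
  invisible(x)
}

#' Seeded rarefaction of a count table
#'
#' Subsamples each sample without replacement to a common depth.
#'
#' @param table samples x taxa integer matrix.
#' @param depth target depth; samples below it are an error.
#' @param seed integer seed.
#' @return rarefied integer matrix with row sums equal to `depth`.
#' @export
rarefy_counts <- function(table, depth, seed = 1L) {
  x <- as.matrix(table)
  depth <- check_count(depth, "depth")
  if (any(rowSums(x) < depth))
    stop("sample(s) below rarefaction depth", call. = FALSE)
  out <- with_seed(seed, {
    t(apply(x, 1L, function(row) {
      pool <- rep.int(seq_along(row), row)
      keep <- sample(pool, depth)
      tabulate(keep, length(row))
    }))
  })
  dimnames(out) <- dimnames(x)
  out
}
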