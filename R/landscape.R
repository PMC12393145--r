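# Labelled plant polygon maps: construction, synthetic generation, and
# plant composition within circular buffers around sampling points.

#' Labelled plant polygon map
#'
#' Container for a mapped landscape: labelled patch polygons (shrubs, forbs,
#' bare soil, ...) inside a rectangular domain, with grass treated as the
#' implicit background of unmapped area.  Patches carry a draw order; where
#' patches overlap, the earlier-drawn patch owns the shared area, so the
#' effective regions never overlap.
#'
#' @param patches list of patches, each a list with elements `poly`
#'   (an n x 2 vertex matrix, metres) and `category` (non-empty string).
#' @param domain numeric length-4 `c(xmin, ymin, xmax, ymax)` in metres.
#' @param boundary_x_m x-coordinate of the linear ecosystem boundary, or
#'   `NULL` when the map has no two-ecosystem structure.
#' @param avg_grass named numeric vector of average grass composition used
#'   for unmapped area; normalised to sum to 1.
#' @return an object of class `plant_map`.
#' @export
plant_map <- function(patches, domain, boundary_x_m = NULL,
                      avg_grass = c(grass = 1)) {
  if (length(domain) != 4L || domain[1L] >= domain[3L] ||
      domain[2L] >= domain[4L])
    stop("`domain` must be c(xmin, ymin, xmax, ymax) with positive extent",
         call. = FALSE)
  if (!is.numeric(avg_grass) || is.null(names(avg_grass)) ||
      any(avg_grass < 0) || sum(avg_grass) <= 0)
    stop("`avg_grass` must be a named non-negative vector with positive sum",
         call. = FALSE)
  patches <- lapply(patches, function(p) {
    if (is.null(p$poly) || !is.matrix(p$poly) || ncol(p$poly) != 2L ||
        nrow(p$poly) < 3L)
      stop("each patch needs a `poly` vertex matrix with >= 3 rows",
           call. = FALSE)
    if (!is.character(p$category) || !nzchar(p$category))
      stop("each patch needs a non-empty `category` string", call. = FALSE)
    p$poly <- orient_ccw(p$poly)
    p$bbox <- poly_bbox(p$poly)
    p
  })
  structure(
    list(patches = patches, domain = as.numeric(domain),
         boundary_x_m = boundary_x_m,
         avg_grass = avg_grass / sum(avg_grass)),
    class = "plant_map")
}

#' @export
print.plant_map <- function(x, ...) {
  cats <- vapply(x$patches, `[[`, "", "category")
  cat(sprintf("plant_map: %d patches over a %.1f x %.1f m domain\n",
              length(cats), x$domain[3L] - x$domain[1L],
              x$domain[4L] - x$domain[2L]))
  if (length(cats)) print(table(category = cats))
  cat("grass background:",
      paste(sprintf("%s=%.2f", names(x$avg_grass), x$avg_grass),
            collapse = ", "), "\n")
  invisible(x)
}

#' Configuration of a synthetic two-ecosystem landscape
#'
#' Parameters of the simulated field design: a rectangular domain split by a
#' vertical boundary into a shrubland half (left) and a grassland half
#' (right), crossed by parallel transects with traps placed at fixed signed
#' offsets from the boundary.  Patch centers follow independent Poisson
#' processes; patch radii are lognormal with coefficient of variation 0.3
#' around `patch_radius_mean_m`.  Shrub patches are placed only in the
#' shrubland half; forb and bare-soil patches occur in both halves.
#'
#' @param domain_width_m,domain_height_m domain extent in metres.
#' @param boundary_x_m x-position of the ecosystem boundary (strictly inside
#'   the domain).
#' @param n_transects number of parallel transects.
#' @param trap_offsets_m signed trap distances from the boundary (m);
#'   negative = shrubland, positive = grassland; all nonzero.
#' @param shrub_density_per_m2,forb_density_per_m2,bare_density_per_m2
#'   patch-center intensities (per m2), all >= 0.
#' @param patch_radius_mean_m mean patch radius (m), > 0.
#' @param avg_grass_composition named vector of grass-category cover used
#'   for unmapped area.
#' @param seed integer seed making the landscape reproducible.
#' @return an object of class `landscape_config` (a validated list).
#' @export
landscape_config <- function(domain_width_m = 40, domain_height_m = 30,
                             boundary_x_m = 20, n_transects = 3,
                             trap_offsets_m = c(-15, -7, -3, -1, 1, 3, 7, 15),
                             shrub_density_per_m2 = 0.06,
                             forb_density_per_m2 = 0.05,
                             bare_density_per_m2 = 0.05,
                             patch_radius_mean_m = 0.9,
                             avg_grass_composition =
                               c(grass_avena = 0.55, grass_bromus = 0.30,
                                 grass_festuca = 0.15),
                             seed = 1L) {
  check_number(domain_width_m, "domain_width_m", 0, strict = TRUE)
  check_number(domain_height_m, "domain_height_m", 0, strict = TRUE)
  check_number(boundary_x_m, "boundary_x_m")
  if (boundary_x_m <= 0 || boundary_x_m >= domain_width_m)
    stop("`boundary_x_m` must lie strictly inside the domain", call. = FALSE)
  n_transects <- check_count(n_transects, "n_transects")
  if (!is.numeric(trap_offsets_m) || length(trap_offsets_m) == 0L ||
      any(trap_offsets_m == 0))
    stop("`trap_offsets_m` must be nonzero signed distances", call. = FALSE)
  for (nm in c("shrub_density_per_m2", "forb_density_per_m2",
               "bare_density_per_m2"))
    check_number(get(nm), nm, 0)
  check_number(patch_radius_mean_m, "patch_radius_mean_m", 0, strict = TRUE)
  x <- boundary_x_m + trap_offsets_m
  if (any(x <= 0 | x >= domain_width_m))
    stop("configuration error: domain too small for the requested trap ",
         "offsets", call. = FALSE)
  structure(
    list(domain_width_m = domain_width_m, domain_height_m = domain_height_m,
         boundary_x_m = boundary_x_m, n_transects = n_transects,
         trap_offsets_m = sort(trap_offsets_m),
         shrub_density_per_m2 = shrub_density_per_m2,
         forb_density_per_m2 = forb_density_per_m2,
         bare_density_per_m2 = bare_density_per_m2,
         patch_radius_mean_m = patch_radius_mean_m,
         avg_grass_composition = avg_grass_composition,
         seed = as.integer(seed)),
    class = "landscape_config")
}

#' Generate a synthetic two-ecosystem landscape
#'
#' Draws patch polygons (discs clipped to their ecosystem half) from Poisson
#' point processes and places trap locations along transects at the
#' configured offsets from the ecosystem boundary.  Deterministic given the
#' config seed.
#'
#' @param config a [landscape_config()].
#' @return list with `map` (a [plant_map()]) and `locations` (data.frame
#'   with columns sample_id, x, y, ecosystem, transect, offset_m).
#' @export
generate_landscape <- function(config) {
  if (!inherits(config, "landscape_config"))
    config <- do.call(landscape_config, config)
  W <- config$domain_width_m
  H <- config$domain_height_m
  bx <- config$boundary_x_m
  halves <- list(shrubland = c(0, bx), grassland = c(bx, W))
  plan <- list(
    list(category = "shrub", density = config$shrub_density_per_m2,
         halves = "shrubland"),
    list(category = "forb", density = config$forb_density_per_m2,
         halves = c("shrubland", "grassland")),
    list(category = "bare", density = config$bare_density_per_m2,
         halves = c("shrubland", "grassland")))
  sdlog <- sqrt(log1p(0.3^2))
  meanlog <- log(config$patch_radius_mean_m) - sdlog^2 / 2
  patches <- with_seed(config$seed, {
    out <- list()
    for (p in plan) {
      if (p$density <= 0) next
      for (hname in p$halves) {
        hx <- halves[[hname]]
        area <- (hx[2L] - hx[1L]) * H
        n <- rpois(1L, p$density * area)
        if (n == 0L) next
        cx <- runif(n, hx[1L], hx[2L])
        cy <- runif(n, 0, H)
        r <- rlnorm(n, meanlog, sdlog)
        half_rect <- rect_poly(hx[1L], 0, hx[2L], H)
        for (i in seq_len(n)) {
          poly <- clip_poly(circle_poly(c(cx[i], cy[i]), r[i], 64L), half_rect)
          if (nrow(poly) < 3L) next
          out[[length(out) + 1L]] <- list(
            poly = poly, category = p$category,
            center = c(cx[i], cy[i]), radius = r[i], ecosystem = hname)
        }
      }
    }
    out
  })
  map <- plant_map(patches, c(0, 0, W, H), boundary_x_m = bx,
                   avg_grass = config$avg_grass_composition)
  ty <- H * (seq_len(config$n_transects) - 0.5) / config$n_transects
  grid <- expand.grid(offset_m = config$trap_offsets_m,
                      transect = seq_len(config$n_transects))
  locations <- data.frame(
    sample_id = sprintf("T%d_%s%02.0f", grid$transect,
                        ifelse(grid$offset_m < 0, "S", "G"),
                        abs(grid$offset_m)),
    x = bx + grid$offset_m,
    y = ty[grid$transect],
    ecosystem = ifelse(grid$offset_m < 0, "shrubland", "grassland"),
    transect = grid$transect,
    offset_m = grid$offset_m,
    stringsAsFactors = FALSE)
  list(map = map, locations = locations)
}

#' Plant composition within a circle around a point
#'
#' Intersects a circular buffer with every labelled patch (exact convex
#' polygon clipping; overlapping patches resolved by draw order, earliest
#' wins) and reports per-category area fractions of the circle-domain
#' intersection.  Unmapped residual area is distributed across the grass
#' categories in proportion to `avg_grass`.
#'
#' @param map a [plant_map()].
#' @param point numeric length-2 buffer center (m); must lie so that the
#'   circle intersects the domain.
#' @param radius_m buffer radius (m), > 0.
#' @param avg_grass grass composition for unmapped area; defaults to the
#'   map's.
#' @param circle_vertices polygonal resolution of the buffer circle.
#' @return a named numeric vector of class `plant_composition` over all map
#'   categories plus the grass categories; entries are >= 0 and sum to 1.
#' @export
plant_composition_at_radius <- function(map, point, radius_m,
                                        avg_grass = map$avg_grass,
                                        circle_vertices = 256L) {
  stopifnot(inherits(map, "plant_map"))
  check_number(radius_m, "radius_m", 0, strict = TRUE)
  if (!is.numeric(point) || length(point) != 2L || any(!is.finite(point)))
    stop("`point` must be numeric length 2", call. = FALSE)
  dom <- map$domain
  circ <- clip_poly(circle_poly(point, radius_m, circle_vertices),
                    rect_poly(dom[1L], dom[2L], dom[3L], dom[4L]))
  denom <- if (nrow(circ) >= 3L) poly_area(circ) else 0
  if (denom <= 1e-12)
    stop("circle lies entirely outside the map domain", call. = FALSE)
  cats <- sort(unique(vapply(map$patches, `[[`, "", "category")))
  mapped <- setNames(numeric(length(cats)), cats)
  cbox <- poly_bbox(circ)
  cand <- which(vapply(map$patches, function(p) bbox_overlap(p$bbox, cbox),
                       TRUE))
  for (k in cand) {
    pk <- map$patches[[k]]
    base <- clip_poly(circ, pk$poly)
    if (nrow(base) < 3L) next
    bb <- poly_bbox(base)
    earlier <- cand[cand < k]
    holes <- lapply(
      earlier[vapply(earlier,
                     function(j) bbox_overlap(map$patches[[j]]$bbox, bb),
                     TRUE)],
      function(j) map$patches[[j]]$poly)
    mapped[pk$category] <- mapped[pk$category] + region_area(base, holes)
  }
  mapped <- pmax(mapped, 0)   # guard against float-cancellation dust
  residual <- max(denom - sum(mapped), 0)
  grass <- avg_grass / sum(avg_grass)
  comp <- c(mapped, residual * grass) / denom
  comp <- comp / sum(comp)
  structure(comp, class = "plant_composition")
}

#' @export
print.plant_composition <- function(x, ...) {
  v <- unclass(x)
  cat("plant composition (area fractions):\n")
  print(round(v[v > 0 | seq_along(v) <= 6], 4))
  invisible(x)
}

#' Plant composition matrix for a set of sample locations
#'
#' Convenience wrapper applying [plant_composition_at_radius()] to each row
#' of a location table.
#'
#' @param map a [plant_map()].
#' @param locations data.frame with columns sample_id, x, y.
#' @param radius_m buffer radius (m).
#' @inheritParams plant_composition_at_radius
#' @return samples x categories matrix of area fractions, rows summing to 1.
#' @export
plant_composition_matrix <- function(map, locations, radius_m,
                                     avg_grass = map$avg_grass,
                                     circle_vertices = 256L) {
  comps <- lapply(seq_len(nrow(locations)), function(i)
    unclass(plant_composition_at_radius(
      map, c(locations$x[i], locations$y[i]), radius_m,
      avg_grass = avg_grass, circle_vertices = circle_vertices)))
  out <- do.call(rbind, comps)
  rownames(out) <- locations$sample_id
  out
}
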