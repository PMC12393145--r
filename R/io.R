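# Readers and writers (TSV, GeoJSON, JSON) and the pipeline driver.
# One tabular dialect: UTF-8 TSV with "." decimals; one geometry dialect:
# GeoJSON.  Readers validate and reject rather than coerce.

#' Read a taxon count table
#'
#' TSV with a header; first column holds sample ids, remaining columns
#' integer taxon counts.
#'
#' @param path file path.
#' @return integer matrix samples x taxa.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("format error: expected a sample-id column plus taxon columns ",
         "(is the header missing?)", call. = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate sample id: ", ids[duplicated(ids)][1L], call. = FALSE)
  counts <- df[, -1L, drop = FALSE]
  for (j in seq_along(counts)) {
    v <- counts[[j]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v != round(v)))
      stop(sprintf("non-integer count in column '%s' (row %d)",
                   names(counts)[j],
                   which(!is.numeric(v) | v != round(v))[1L]), call. = FALSE)
    if (any(v < 0))
      stop(sprintf("negative count in column '%s' (row %d)",
                   names(counts)[j], which(v < 0)[1L]), call. = FALSE)
  }
  m <- as.matrix(counts)
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' Write a taxon count table
#'
#' @param table samples x taxa matrix with sample ids as rownames.
#' @param path output file.
#' @export
write_count_table <- function(table, path) {
  df <- data.frame(sample_id = rownames(table), as.data.frame(table),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cell-count series
#'
#' TSV with columns slide_id, slide_type, ecosystem, transect, offset_m,
#' day, cells_per_cm2; validated on read.
#'
#' @param path file path.
#' @return a validated data.frame.
#' @export
read_cell_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    stop("empty input: ", path, " has no records", call. = FALSE)
  validate_cell_counts(df, context = path)
  df
}

#' @rdname read_cell_counts
#' @param series cell-count data.frame to write.
#' @export
write_cell_counts <- function(series, path) {
  validate_cell_counts(series)
  cols <- c("slide_id", "slide_type", "ecosystem", "transect", "offset_m",
            "day", "cells_per_cm2")
  write.table(series[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read / write a square distance matrix
#'
#' TSV with sample ids in both the header row and the first column.
#'
#' @param path file path.
#' @return square symmetric matrix.
#' @export
read_distance_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- ids
  if (!identical(colnames(m), ids))
    stop("distance matrix header does not match its sample-id column",
         call. = FALSE)
  validate_dist_matrix(m)
}

#' @rdname read_distance_matrix
#' @param D matrix to write.
#' @export
write_distance_matrix <- function(D, path) {
  df <- data.frame(sample_id = rownames(D), as.data.frame(D),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a plant polygon map as GeoJSON
#'
#' Patches become Polygon features with properties `category` and `order`
#' (draw order; earlier patches own overlapping area).  Domain, ecosystem
#' boundary and the grass background travel in the collection's
#' `properties` member.
#'
#' @param map a [plant_map()].
#' @param path file path.
#' @export
write_landscape_geojson <- function(map, path) {
  features <- lapply(seq_along(map$patches), function(k) {
    p <- map$patches[[k]]
    ring <- rbind(p$poly, p$poly[1L, , drop = FALSE])
    list(type = "Feature",
         properties = list(category = p$category, order = k),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(
                           lapply(seq_len(nrow(ring)),
                                  function(i) as.numeric(ring[i, ]))))))
  })
  gj <- list(type = "FeatureCollection",
             properties = list(domain = map$domain,
                               boundary_x_m = map$boundary_x_m,
                               avg_grass = as.list(map$avg_grass)),
             features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_landscape_geojson
#' @export
read_landscape_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection"))
    stop("not a GeoJSON FeatureCollection: ", path, call. = FALSE)
  patches <- lapply(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1L]]
    poly <- do.call(rbind, lapply(ring, function(v)
      c(as.numeric(v[[1L]]), as.numeric(v[[2L]]))))
    poly <- poly[-nrow(poly), , drop = FALSE]  # drop closing vertex
    list(poly = poly, category = f$properties$category)
  })
  ord <- order(vapply(gj$features, function(f)
    as.numeric(f$properties$order %||% NA_real_), numeric(1L)),
    na.last = TRUE)
  grass <- unlist(gj$properties$avg_grass)
  plant_map(patches[ord], as.numeric(unlist(gj$properties$domain)),
            boundary_x_m = gj$properties$boundary_x_m,
            avg_grass = grass)
}

#' Pipeline configuration
#'
#' Bundles the seeds and parameters of a full synthetic run.  A single
#' top-level seed deterministically derives per-stage substreams.
#'
#' @param outdir output directory (created if absent).
#' @param seed non-negative integer master seed.
#' @param n_perm permutations for all permutation tests.
#' @param radii radius grid for the scale scan.
#' @param landscape a [landscape_config()].
#' @param trap a [trap_sim_config()].
#' @param kinetics a [kinetics_sim_config()].
#' @param counts_path,table_path,map_path,meta_path optional paths to
#'   existing inputs; when all are supplied, the simulate stage is skipped.
#' @return object of class `run_config`.
#' @export
run_config <- function(outdir, seed = 1L, n_perm = 999L,
                       radii = default_radii(),
                       landscape = landscape_config(),
                       trap = trap_sim_config(),
                       kinetics = kinetics_sim_config(),
                       counts_path = NULL, table_path = NULL,
                       map_path = NULL, meta_path = NULL) {
  seed <- check_count(seed, "seed", lower = 0L)
  n_perm <- check_count(n_perm, "n_perm")
  ext <- list(counts_path = counts_path, table_path = table_path,
              map_path = map_path, meta_path = meta_path)
  given <- !vapply(ext, is.null, TRUE)
  if (any(given) && !all(given))
    stop("pre-flight error: supply all of counts_path, table_path, ",
         "map_path, meta_path, or none", call. = FALSE)
  if (all(given)) {
    missing <- unlist(ext)[!file.exists(unlist(ext))]
    if (length(missing))
      stop("pre-flight error: missing input file(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(c(list(outdir = outdir, seed = seed, n_perm = n_perm,
                   radii = radii, landscape = landscape, trap = trap,
                   kinetics = kinetics, simulate = !all(given)), ext),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> fit-kinetics -> permanova/permdisp ->
#' scale-scan, writing every artifact as TSV/GeoJSON/JSON under
#' `config$outdir` plus a manifest JSON recording the package version,
#' seeds, parameters, record counts and timing of every stage.  Any stage
#' failure aborts with a stage-named error.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$outdir, ...)
  manifest <- list(package = "dispersalkit",
                   version = as.character(utils::packageVersion("dispersalkit")),
                   seed = config$seed, n_perm = config$n_perm,
                   stages = list())
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    info <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[name]] <<- c(list(name = name,
                                       seconds = round(proc.time()[["elapsed"]] - t0, 3)),
                                  info)
    invisible(NULL)
  }

  paths <- list()
  stage("simulate", function() {
    if (!config$simulate) {
      paths <<- list(map = config$map_path, meta = config$meta_path,
                     table = config$table_path, counts = config$counts_path)
      return(list(skipped = TRUE))
    }
    ls_cfg <- config$landscape
    ls_cfg$seed <- substream(config$seed, "landscape")
    land <- generate_landscape(ls_cfg)
    prof <- random_source_profiles(
      c(sort(unique(vapply(land$map$patches, `[[`, "", "category"))),
        names(land$map$avg_grass)),
      seed = substream(config$seed, "profiles"))
    trap_cfg <- config$trap
    trap_cfg$seed <- substream(config$seed, "traps")
    table <- simulate_trap_communities(land$map, land$locations, prof,
                                       trap_cfg)
    kin_cfg <- config$kinetics
    kin_cfg$seed <- substream(config$seed, "kinetics")
    open <- simulate_cell_counts(kin_cfg, "open")
    closed_cfg <- kin_cfg
    closed_cfg$sample_days <- c(3, 7, 14, 28, 56)
    closed_cfg$slides_per_timepoint <- 7L
    closed <- simulate_cell_counts(closed_cfg, "closed")
    counts <- rbind(open, closed)
    paths <<- list(map = out("landscape.geojson"), meta = out("samples.tsv"),
                   table = out("taxon_counts.tsv"),
                   counts = out("cell_counts.tsv"))
    write_landscape_geojson(land$map, paths$map)
    write.table(land$locations, paths$meta, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_count_table(table, paths$table)
    write_cell_counts(counts, paths$counts)
    jsonlite::write_json(
      list(landscape = unclass(ls_cfg), trap = unclass(trap_cfg),
           kinetics = unclass(kin_cfg)),
      out("ground_truth.json"), auto_unbox = TRUE, digits = NA)
    list(n_patches = length(land$map$patches),
         n_samples = nrow(land$locations), n_slides = nrow(counts))
  })

  series <- read_cell_counts(paths$counts)
  table <- read_count_table(paths$table)
  meta <- read.delim(paths$meta, stringsAsFactors = FALSE)
  map <- read_landscape_geojson(paths$map)

  fit <- NULL
  stage("fit-kinetics", function() {
    fit <<- fit_immigration_death(series)
    hom <- test_slope_homogeneity(series[series$slide_type == "closed", ])
    jsonlite::write_json(
      list(delta_per_day = fit$immigration$delta_used,
           percent_dying_per_day = summary(fit)$percent_dying_per_day,
           immigration_I = fit$immigration$immigration_I,
           immigration_I_se = fit$immigration$immigration_I_se,
           slope_homogeneity = list(f = hom$f_statistic, p = hom$p_value),
           se_method = paste("SE of mean ln I, delta-method transformed;",
                             "delta fixed at the pooled closed-slide",
                             "estimate")),
      out("kinetics_fit.json"), auto_unbox = TRUE, digits = NA)
    per_group <- do.call(rbind, lapply(
      unique(series$ecosystem), function(eco) {
        f <- fit_death_rate(series, ecosystem = eco)
        data.frame(ecosystem = eco, slope_per_day = f$slope_per_day,
                   delta_per_day = f$delta_per_day,
                   percent_dying_per_day = f$percent_dying_per_day,
                   r_squared = f$r_squared, n = f$n_points)
      }))
    write.table(per_group, out("death_rates_by_group.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(n_records = nrow(series))
  })

  D <- NULL
  stage("permanova", function() {
    D <<- bray_curtis(relative_abundance(table))
    groups <- meta$ecosystem[match(rownames(D), meta$sample_id)]
    pa <- permanova(D, groups, n_perm = config$n_perm,
                    seed = substream(config$seed, "permanova"))
    pd <- permdisp(D, groups, n_perm = config$n_perm,
                   seed = substream(config$seed, "permdisp"))
    write_distance_matrix(D, out("bray_curtis.tsv"))
    jsonlite::write_json(
      list(permanova = list(pseudo_f = pa$statistic, p_value = pa$p_value,
                            variance_explained = pa$variance_explained),
           permdisp = list(f = pd$statistic, p_value = pd$p_value),
           note = paste("relative abundance, Bray-Curtis; PERMDISP uses",
                        "PCoA centroids on positive-eigenvalue axes")),
      out("community_tests.json"), auto_unbox = TRUE, digits = NA)
    list(n_samples = nrow(D), permanova_p = pa$p_value)
  })

  stage("scale-scan", function() {
    scan <- radius_scan(map, meta, D, radii = config$radii,
                        n_perm = config$n_perm,
                        seed = substream(config$seed, "scan"))
    write.table(scan$results, out("radius_scan.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(best_radius_m = scan$best_radius_m, best_r = scan$best_r,
           radii = scan$radii),
      out("radius_scan.json"), auto_unbox = TRUE, digits = NA)
    list(best_radius_m = scan$best_radius_m)
  })

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
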