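# Synthetic trap communities and cell-count series with known ground truth.

#' Per-category taxon source profiles
#'
#' Each plant category acts as a microbial source with its own taxon
#' relative-abundance profile; an ambient (air) background profile
#' contributes a fixed mixture weight everywhere.
#'
#' @param profiles categories x taxa matrix of relative abundances; each row
#'   must be non-negative and sum to 1 (within 1e-9; rows are renormalised).
#' @param background_profile relative-abundance vector over the same taxa.
#' @param background_weight ambient mixture fraction in \[0, 1\].
#' @return object of class `source_profiles`.
#' @export
source_profiles <- function(profiles, background_profile,
                            background_weight = 0.15) {
  profiles <- as.matrix(profiles)
  if (is.null(rownames(profiles)))
    stop("`profiles` needs category rownames", call. = FALSE)
  if (any(profiles < 0) || any(background_profile < 0))
    stop("profiles must be non-negative", call. = FALSE)
  rs <- rowSums(profiles)
  if (any(abs(rs - 1) > 1e-9) || abs(sum(background_profile) - 1) > 1e-9)
    stop("each profile must sum to 1 (within 1e-9)", call. = FALSE)
  check_number(background_weight, "background_weight", 0)
  if (background_weight > 1)
    stop("`background_weight` must be in [0, 1]", call. = FALSE)
  if (length(background_profile) != ncol(profiles))
    stop("`background_profile` length must match the taxon dimension",
         call. = FALSE)
  if (is.null(colnames(profiles)))
    colnames(profiles) <- sprintf("t%03d", seq_len(ncol(profiles)))
  structure(list(categories = rownames(profiles),
                 profiles = profiles / rs,
                 background_profile = background_profile /
                   sum(background_profile),
                 background_weight = background_weight),
            class = "source_profiles")
}

#' Random source profiles for simulation studies
#'
#' Draws one sparse Dirichlet taxon profile per category (concentration
#' `concentration` per taxon, giving well-separated sources) and a more even
#' Dirichlet background.
#'
#' @param categories character vector of plant categories.
#' @param n_taxa number of taxa.
#' @param background_weight ambient mixture fraction.
#' @param concentration per-taxon Dirichlet concentration of the category
#'   profiles (small = sparse, distinct sources).
#' @param seed integer seed.
#' @return a [source_profiles()] object.
#' @export
random_source_profiles <- function(categories, n_taxa = 120L,
                                   background_weight = 0.15,
                                   concentration = 0.4, seed = 1L) {
  n_taxa <- check_count(n_taxa, "n_taxa")
  with_seed(seed, {
    prof <- t(vapply(categories, function(cat) {
      g <- rgamma(n_taxa, shape = concentration)
      g / sum(g)
    }, numeric(n_taxa)))
    bg <- rgamma(n_taxa, shape = 5)
    source_profiles(prof, bg / sum(bg), background_weight)
  })
}

#' Trap community simulation settings
#'
#' @param influence_radius_m the true radius (m) at which surrounding plant
#'   composition determines a trap's expected microbial composition.
#' @param reads_per_sample sequencing-depth analogue (counts per sample).
#' @param overdispersion Dirichlet concentration scalar; finite values add
#'   extra-multinomial noise (smaller = noisier), `Inf` = pure multinomial.
#' @param seed integer seed.
#' @export
trap_sim_config <- function(influence_radius_m = 1, reads_per_sample = 5000L,
                            overdispersion = 300, seed = 1L) {
  check_number(influence_radius_m, "influence_radius_m", 0, strict = TRUE)
  reads_per_sample <- check_count(reads_per_sample, "reads_per_sample")
  if (!identical(overdispersion, Inf))
    check_number(overdispersion, "overdispersion", 0, strict = TRUE)
  structure(list(influence_radius_m = influence_radius_m,
                 reads_per_sample = reads_per_sample,
                 overdispersion = overdispersion, seed = as.integer(seed)),
            class = "trap_sim_config")
}

#' Simulate trap microbial communities from a landscape
#'
#' Each trap's expected taxon profile is the cover-weighted mixture of the
#' category source profiles within the true influence radius, blended with
#' the ambient background:
#' \deqn{p = (1-w)\sum_c f_c(\rho^*)\,\pi_c + w\,\pi_0.}
#' Counts are drawn multinomially at the configured read depth, optionally
#' through a Dirichlet layer for overdispersion.  Deterministic given the
#' config seed.
#'
#' @param map a [plant_map()].
#' @param locations data.frame with sample_id, x, y.
#' @param profiles a [source_profiles()]; its categories must cover every
#'   category appearing in compositions (map categories plus grass).
#' @param cfg a [trap_sim_config()].
#' @return integer matrix samples x taxa of class `matrix`; rows sum to
#'   `reads_per_sample`.
#' @export
simulate_trap_communities <- function(map, locations, profiles, cfg) {
  stopifnot(inherits(profiles, "source_profiles"),
            inherits(cfg, "trap_sim_config"))
  comp <- plant_composition_matrix(map, locations, cfg$influence_radius_m)
  missing <- setdiff(colnames(comp), profiles$categories)
  if (length(missing))
    stop("categories missing from source profiles: ",
         paste(missing, collapse = ", "), call. = FALSE)
  P <- profiles$profiles[colnames(comp), , drop = FALSE]
  w <- profiles$background_weight
  expected <- (1 - w) * (comp %*% P) +
    matrix(w * profiles$background_profile, nrow(comp), ncol(P), byrow = TRUE)
  expected <- expected / rowSums(expected)
  counts <- with_seed(cfg$seed, {
    t(vapply(seq_len(nrow(expected)), function(i) {
      p <- expected[i, ]
      if (is.finite(cfg$overdispersion)) {
        g <- rgamma(length(p), shape = cfg$overdispersion * p)
        p <- if (sum(g) > 0) g / sum(g) else expected[i, ]
      }
      as.integer(rmultinom(1L, cfg$reads_per_sample, p))
    }, integer(ncol(expected))))
  })
  dimnames(counts) <- list(locations$sample_id, colnames(P))
  counts
}

#' Expected trap taxon profiles (no sampling noise)
#'
#' The deterministic mixture underlying [simulate_trap_communities()];
#' useful for ground-truth checks.
#'
#' @inheritParams simulate_trap_communities
#' @return samples x taxa matrix of expected relative abundances.
#' @export
expected_trap_profiles <- function(map, locations, profiles, cfg) {
  comp <- plant_composition_matrix(map, locations, cfg$influence_radius_m)
  P <- profiles$profiles[colnames(comp), , drop = FALSE]
  w <- profiles$background_weight
  expected <- (1 - w) * (comp %*% P) +
    matrix(w * profiles$background_profile, nrow(comp), ncol(P), byrow = TRUE)
  expected / rowSums(expected)
}

#' Cell-count kinetics simulation settings
#'
#' Ground-truth parameters of the immigration-death process on trap slides.
#' Defaults mirror a two-month deployment with 24 open traps collected at
#' four time points (96 accumulation slides).
#'
#' @param immigration_rate_I immigration rate (cells cm^-2 day^-1), >= 0.
#' @param death_rate_delta death rate (day^-1), >= 0.
#' @param initial_density_N0 inoculum density on closed slides
#'   (cells cm^-2), > 0.
#' @param sample_days strictly increasing positive collection days.
#' @param slides_per_timepoint slides collected per day.
#' @param noise_cv lognormal coefficient of variation of measured counts
#'   (unit-median multiplicative noise); 0 = noiseless.
#' @param seed integer seed.
#' @export
kinetics_sim_config <- function(immigration_rate_I = 1060,
                                death_rate_delta = 0.02799,
                                initial_density_N0 = 1e5,
                                sample_days = c(7, 14, 28, 56),
                                slides_per_timepoint = 24L,
                                noise_cv = 0.5, seed = 1L) {
  check_number(immigration_rate_I, "immigration_rate_I", 0)
  check_number(death_rate_delta, "death_rate_delta", 0)
  check_number(initial_density_N0, "initial_density_N0", 0, strict = TRUE)
  if (!is.numeric(sample_days) || any(sample_days <= 0) ||
      any(diff(sample_days) <= 0))
    stop("`sample_days` must be strictly positive and increasing",
         call. = FALSE)
  slides_per_timepoint <- check_count(slides_per_timepoint,
                                      "slides_per_timepoint")
  check_number(noise_cv, "noise_cv", 0)
  structure(list(immigration_rate_I = immigration_rate_I,
                 death_rate_delta = death_rate_delta,
                 initial_density_N0 = initial_density_N0,
                 sample_days = sample_days,
                 slides_per_timepoint = slides_per_timepoint,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "kinetics_sim_config")
}

#' Simulate trap cell-count series
#'
#' Closed (death-rate) slides decay from the inoculum,
#' \eqn{N(t) = N_0 e^{-\delta t}}; open (accumulation) slides start sterile
#' and approach the immigration-death balance,
#' \eqn{N(t) = (I/\delta)(1 - e^{-\delta t})} (limit \eqn{I t} when
#' \eqn{\delta = 0}).  Measured counts are the mean multiplied by
#' unit-median lognormal noise with the configured CV.  Each slide is
#' destructively sampled once.  Deterministic given the config seed (open
#' and closed draws use distinct substreams of the same seed).
#'
#' @param cfg a [kinetics_sim_config()].
#' @param slide_type `"open"` or `"closed"`.
#' @return data.frame with columns slide_id, slide_type, ecosystem,
#'   transect, offset_m, day, cells_per_cm2.
#' @export
simulate_cell_counts <- function(cfg, slide_type = c("open", "closed")) {
  stopifnot(inherits(cfg, "kinetics_sim_config"))
  slide_type <- match.arg(slide_type)
  I <- cfg$immigration_rate_I
  delta <- cfg$death_rate_delta
  if (slide_type == "closed" && cfg$initial_density_N0 <= 0)
    stop("degenerate series: closed slides need a positive inoculum N0",
         call. = FALSE)
  if (slide_type == "open" && I <= 0)
    stop("degenerate series: open slides need a positive immigration rate",
         call. = FALSE)
  mean_at <- function(t) {
    if (slide_type == "closed") cfg$initial_density_N0 * exp(-delta * t)
    else if (delta > 0) (I / delta) * (1 - exp(-delta * t))
    else I * t
  }
  # slide positions: open slides span all transect offsets, closed slides
  # sit 7 m into each ecosystem on each transect (as deployed in the field
  # design this emulates)
  pos <- if (slide_type == "open")
    expand.grid(offset_m = c(-15, -7, -3, -1, 1, 3, 7, 15), transect = 1:3)
  else expand.grid(offset_m = c(-7, 7), transect = 1:3)
  nper <- cfg$slides_per_timepoint
  days <- rep(cfg$sample_days, each = nper)
  idx <- (seq_along(days) - 1L) %% nrow(pos) + 1L
  mu <- mean_at(days)
  noise <- with_seed(substream(cfg$seed, slide_type), {
    if (cfg$noise_cv > 0) {
      sdlog <- sqrt(log1p(cfg$noise_cv^2))
      exp(rnorm(length(days), 0, sdlog))
    } else rep(1, length(days))
  })
  data.frame(
    slide_id = sprintf("%s_d%03d_s%02d", slide_type, as.integer(days),
                       sequence(rep(nper, length(cfg$sample_days)))),
    slide_type = slide_type,
    ecosystem = ifelse(pos$offset_m[idx] < 0, "shrubland", "grassland"),
    transect = pos$transect[idx],
    offset_m = pos$offset_m[idx],
    day = days,
    cells_per_cm2 = mu * noise,
    stringsAsFactors = FALSE)
}
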