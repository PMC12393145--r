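# Immigration-death kinetics: death rate from closed-slide decay,
# immigration rate from open-slide accumulation, and the slope-homogeneity
# (ANCOVA) test between ecosystems.

validate_cell_counts <- function(series, context = "cell count series") {
  req <- c("slide_id", "slide_type", "ecosystem", "transect", "offset_m",
           "day", "cells_per_cm2")
  miss <- setdiff(req, names(series))
  if (length(miss))
    stop(sprintf("%s is missing columns: %s", context,
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (nrow(series) == 0L)
    stop(sprintf("%s is empty", context), call. = FALSE)
  bad_type <- setdiff(unique(series$slide_type), c("open", "closed"))
  if (length(bad_type))
    stop(sprintf("unknown slide_type %s; allowed values are 'open', 'closed'",
                 paste(sQuote(bad_type), collapse = ", ")), call. = FALSE)
  if (any(!is.finite(series$day)) || any(series$day < 0))
    stop("`day` must be finite and >= 0", call. = FALSE)
  bad <- which(!is.finite(series$cells_per_cm2) | series$cells_per_cm2 <= 0)
  if (length(bad))
    stop(sprintf("non-positive cell count in record %d (slide %s, day %g)",
                 bad[1L], series$slide_id[bad[1L]], series$day[bad[1L]]),
         call. = FALSE)
  tt <- tapply(series$slide_type, series$slide_id,
               function(x) length(unique(x)))
  if (any(tt > 1L))
    stop("slide_type is inconsistent for slide ", names(tt)[tt > 1L][1L],
         call. = FALSE)
  invisible(series)
}

#' Convert between a daily death rate and percent dying per day
#'
#' A continuous per-capita death rate \eqn{\delta} (day^-1) corresponds to a
#' daily loss of \eqn{(1 - e^{-\delta}) \times 100} percent of the
#' community, and conversely \eqn{\delta = -\log(1 - d/100)}.
#'
#' @param delta death rate (day^-1), >= 0.
#' @param percent percent of the community dying per day, in \[0, 100).
#' @return the converted value.
#' @export
delta_to_percent <- function(delta) {
  check_number(delta, "delta", 0)
  (1 - exp(-delta)) * 100
}

#' @rdname delta_to_percent
#' @export
percent_to_delta <- function(percent) {
  check_number(percent, "percent", 0)
  if (percent >= 100)
    stop("`percent` must be < 100", call. = FALSE)
  -log(1 - percent / 100)
}

#' Fit the community death rate from closed-slide decay
#'
#' Ordinary least squares of ln(cells/cm2) on day over the closed
#' (death-rate) slides.  The death rate is \eqn{\delta = -}slope and the
#' daily community loss is \eqn{(1 - e^{-\delta}) \times 100} percent.
#'
#' @param series cell-count data.frame (see [simulate_cell_counts()] /
#'   [read_cell_counts()] for the column contract).
#' @param ecosystem optional ecosystem label restricting the fit.
#' @return object of class `death_rate_fit` with elements slope_per_day,
#'   slope_se, delta_per_day, percent_dying_per_day, intercept,
#'   intercept_se, r_squared, n_points, and the underlying `lm` fit.
#' @export
fit_death_rate <- function(series, ecosystem = NULL) {
  validate_cell_counts(series)
  d <- series[series$slide_type == "closed", , drop = FALSE]
  if (!is.null(ecosystem)) d <- d[d$ecosystem %in% ecosystem, , drop = FALSE]
  if (nrow(d) == 0L)
    stop("no closed-slide records to fit", call. = FALSE)
  if (length(unique(d$day)) < 3L)
    stop("insufficient data: need >= 3 distinct days among closed slides",
         call. = FALSE)
  fit <- lm(log(cells_per_cm2) ~ day, data = d)
  sm <- summary(fit)
  slope <- unname(coef(fit)[2L])
  delta <- -slope
  structure(list(
    slope_per_day = slope,
    slope_se = sm$coefficients[2L, 2L],
    delta_per_day = delta,
    delta_se = sm$coefficients[2L, 2L],
    percent_dying_per_day = if (delta >= 0) delta_to_percent(delta) else
      -(exp(-slope) - 1) * 100,
    intercept = unname(coef(fit)[1L]),
    intercept_se = sm$coefficients[1L, 2L],
    r_squared = sm$r.squared,
    n_points = nrow(d),
    ecosystem = ecosystem %||% "all",
    lm = fit), class = "death_rate_fit")
}

#' @export
print.death_rate_fit <- function(x, ...) {
  cat("Death-rate fit (ln cells/cm2 ~ day,", x$ecosystem, "closed slides)\n")
  cat(sprintf("  slope  = %.5f +/- %.5f per day (n = %d, R2 = %.3f)\n",
              x$slope_per_day, x$slope_se, x$n_points, x$r_squared))
  cat(sprintf("  delta  = %.5f per day\n", x$delta_per_day))
  cat(sprintf("  loss   = %.2f%% of the community per day\n",
              x$percent_dying_per_day))
  invisible(x)
}

#' @export
coef.death_rate_fit <- function(object, ...) {
  c(intercept = object$intercept, slope_per_day = object$slope_per_day,
    delta_per_day = object$delta_per_day)
}

#' Test homogeneity of decay slopes across groups (ANCOVA)
#'
#' Fits ln(cells) ~ day + group + day:group by least squares and F-tests
#' the interaction term against the additive model, i.e. whether the decay
#' (or accumulation) slope differs among groups such as ecosystems.
#'
#' @param series cell-count data.frame; should contain a single slide type.
#' @param group_field metadata column defining the groups (default
#'   `"ecosystem"`).
#' @return object of class `slope_homogeneity` with f_statistic, df_num,
#'   df_den, p_value and per-group slopes.
#' @export
test_slope_homogeneity <- function(series, group_field = "ecosystem") {
  validate_cell_counts(series)
  if (!group_field %in% names(series))
    stop("unknown group field ", sQuote(group_field), call. = FALSE)
  g <- factor(series[[group_field]])
  if (nlevels(g) < 2L)
    stop("need >= 2 groups for a slope-homogeneity test", call. = FALSE)
  days_per_group <- tapply(series$day, g, function(x) length(unique(x)))
  if (any(days_per_group < 3L))
    stop("singular design: group ",
         sQuote(names(days_per_group)[days_per_group < 3L][1L]),
         " observed at fewer than 3 distinct days", call. = FALSE)
  d <- data.frame(lc = log(series$cells_per_cm2), day = series$day, g = g)
  full <- lm(lc ~ day * g, data = d)
  additive <- lm(lc ~ day + g, data = d)
  an <- anova(additive, full)
  slopes <- vapply(levels(g), function(lv)
    unname(coef(lm(lc ~ day, data = d[d$g == lv, ]))[2L]), numeric(1L))
  structure(list(
    f_statistic = an$F[2L],
    df_num = an$Df[2L],
    df_den = an$Res.Df[2L],
    p_value = an$`Pr(>F)`[2L],
    group_slopes = slopes,
    ss_interaction = an$`Sum of Sq`[2L],
    group_field = group_field), class = "slope_homogeneity")
}

#' @export
print.slope_homogeneity <- function(x, ...) {
  cat(sprintf("Slope homogeneity (day x %s interaction)\n", x$group_field))
  cat(sprintf("  F(%d, %d) = %.3f, P = %.3g\n", x$df_num, x$df_den,
              x$f_statistic, x$p_value))
  cat("  group slopes:",
      paste(sprintf("%s = %.4f", names(x$group_slopes), x$group_slopes),
            collapse = ", "), "\n")
  invisible(x)
}

#' Fit the immigration rate from open-slide accumulation
#'
#' Under the immigration-death model \eqn{dN/dt = I - \delta N} with
#' \eqn{N(0) = 0}, the open-slide mean is
#' \eqn{N(t) = (I/\delta)(1 - e^{-\delta t})} (\eqn{I t} when
#' \eqn{\delta = 0}).  With \eqn{\delta} fixed externally (from the closed
#' slides) the model is linear in \eqn{I} on the ln scale:
#' \eqn{\ln N(t) = \ln I + \ln[(1 - e^{-\delta t})/\delta]}, so
#' \eqn{\ln\hat I} is the mean offset and its standard error is the usual
#' standard error of that mean; the SE of \eqn{\hat I} follows by the delta
#' method.  Day-0 records are excluded (model value 0).
#'
#' @param series cell-count data.frame; only open-slide records are used.
#' @param delta fixed death rate (day^-1), >= 0.
#' @return object of class `immigration_fit` with immigration_I,
#'   immigration_I_se, delta_used, residual_sd (ln scale), n_points.
#' @export
fit_immigration_rate <- function(series, delta) {
  validate_cell_counts(series)
  check_number(delta, "delta", 0)
  d <- series[series$slide_type == "open" & series$day > 0, , drop = FALSE]
  if (nrow(d) == 0L)
    stop("no open-slide records with day > 0", call. = FALSE)
  g <- if (delta > 0) (1 - exp(-delta * d$day)) / delta else d$day
  ln_i <- log(d$cells_per_cm2) - log(g)
  n <- length(ln_i)
  mean_ln_i <- mean(ln_i)
  res_sd <- if (n > 1L) sd(ln_i) else 0
  se_ln_i <- res_sd / sqrt(n)
  I <- exp(mean_ln_i)
  structure(list(
    immigration_I = I,
    immigration_I_se = I * se_ln_i,
    delta_used = delta,
    residual_sd = res_sd,
    n_points = n), class = "immigration_fit")
}

#' @export
print.immigration_fit <- function(x, ...) {
  cat("Immigration-rate fit (immigration-death model, delta fixed)\n")
  cat(sprintf("  I     = %.1f +/- %.1f cells/cm2/day (n = %d)\n",
              x$immigration_I, x$immigration_I_se, x$n_points))
  cat(sprintf("  delta = %.5f per day; plateau I/delta = %.0f cells/cm2\n",
              x$delta_used,
              if (x$delta_used > 0) x$immigration_I / x$delta_used else Inf))
  invisible(x)
}

#' @export
coef.immigration_fit <- function(object, ...) {
  c(immigration_I = object$immigration_I, delta = object$delta_used)
}

#' Immigration as a fraction of a source community
#'
#' Expresses the immigration rate as a percentage of the standing cell
#' density of a candidate source (e.g. leaf litter), rounded to two
#' decimals.
#'
#' @param I immigration rate (cells cm^-2 day^-1), >= 0.
#' @param source_density source cell density (cells cm^-2), > 0.
#' @return percentage, rounded to two decimals.
#' @export
immigration_fraction_of_source <- function(I, source_density) {
  check_number(I, "I", 0)
  check_number(source_density, "source_density", 0, strict = TRUE)
  round(100 * I / source_density, 2)
}

#' Fit the full immigration-death model to a trap series
#'
#' The umbrella fit: estimates the death rate from the closed slides
#' ([fit_death_rate()]) and, holding that rate fixed, the immigration rate
#' from the open slides ([fit_immigration_rate()]).
#'
#' @param series cell-count data.frame containing both slide types.
#' @param delta optional fixed death rate; when `NULL` it is estimated from
#'   the closed slides.
#' @return object of class `immigration_death_fit` with components `death`
#'   (a `death_rate_fit`, or `NULL` when `delta` was supplied),
#'   `immigration` (an `immigration_fit`), and the input series.
#' @seealso [predict.immigration_death_fit()], [simulate.immigration_death_fit()]
#' @export
fit_immigration_death <- function(series, delta = NULL) {
  validate_cell_counts(series)
  death <- NULL
  if (is.null(delta)) {
    death <- fit_death_rate(series)
    delta <- death$delta_per_day
  }
  immigration <- fit_immigration_rate(series, delta)
  structure(list(death = death, immigration = immigration,
                 series = series), class = "immigration_death_fit")
}

#' @export
print.immigration_death_fit <- function(x, ...) {
  cat("Immigration-death model fit\n")
  if (!is.null(x$death)) {
    cat(sprintf("  death:       delta = %.5f /day (%.2f%% of cells per day)\n",
                x$death$delta_per_day, x$death$percent_dying_per_day))
  } else {
    cat(sprintf("  death:       delta = %.5f /day (supplied)\n",
                x$immigration$delta_used))
  }
  cat(sprintf("  immigration: I = %.1f +/- %.1f cells/cm2/day\n",
              x$immigration$immigration_I, x$immigration$immigration_I_se))
  invisible(x)
}

#' @export
summary.immigration_death_fit <- function(object, ...) {
  im <- object$immigration
  out <- list(
    delta_per_day = im$delta_used,
    percent_dying_per_day = delta_to_percent(max(im$delta_used, 0)),
    immigration_I = im$immigration_I,
    immigration_I_se = im$immigration_I_se,
    plateau = if (im$delta_used > 0) im$immigration_I / im$delta_used else Inf,
    n_open = im$n_points,
    n_closed = if (!is.null(object$death)) object$death$n_points else NA_integer_,
    death_r_squared = if (!is.null(object$death)) object$death$r_squared else NA_real_)
  class(out) <- "summary.immigration_death_fit"
  out
}

#' @export
print.summary.immigration_death_fit <- function(x, ...) {
  cat("Immigration-death model summary\n")
  cat(sprintf("  delta      %.5f /day  (%.2f%%/day; closed n = %s, R2 = %s)\n",
              x$delta_per_day, x$percent_dying_per_day,
              format(x$n_closed), format(round(x$death_r_squared, 3))))
  cat(sprintf("  I          %.1f +/- %.1f cells/cm2/day (open n = %d)\n",
              x$immigration_I, x$immigration_I_se, x$n_open))
  cat(sprintf("  plateau    %.0f cells/cm2 (I/delta)\n", x$plateau))
  invisible(x)
}

#' @export
coef.immigration_death_fit <- function(object, ...) {
  c(immigration_I = object$immigration$immigration_I,
    delta_per_day = object$immigration$delta_used)
}

#' Predicted mean cell densities from a fitted immigration-death model
#'
#' @param object an `immigration_death_fit`.
#' @param newdata data.frame with columns `day` and `slide_type`; defaults
#'   to the fitted series.
#' @param ... unused.
#' @return numeric vector of predicted mean cells/cm2.
#' @export
predict.immigration_death_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$series
  delta <- object$immigration$delta_used
  I <- object$immigration$immigration_I
  n0 <- if (!is.null(object$death)) exp(object$death$intercept) else NA_real_
  vapply(seq_len(nrow(newdata)), function(i) {
    t <- newdata$day[i]
    if (newdata$slide_type[i] == "open") {
      if (delta > 0) (I / delta) * (1 - exp(-delta * t)) else I * t
    } else {
      n0 * exp(-delta * t)
    }
  }, numeric(1L))
}

#' @export
residuals.immigration_death_fit <- function(object, ...) {
  mu <- predict(object)
  log(object$series$cells_per_cm2) - log(mu)
}

#' Simulate new series from a fitted immigration-death model
#'
#' @param object an `immigration_death_fit`.
#' @param nsim number of replicate series.
#' @param seed integer seed.
#' @param slide_type which dynamics to simulate.
#' @param noise_cv lognormal CV of the simulated counts; defaults to the CV
#'   implied by the ln-scale residual spread of the fit.
#' @param ... unused.
#' @return a list of `nsim` cell-count data.frames.
#' @export
simulate.immigration_death_fit <- function(object, nsim = 1, seed = 1L,
                                           slide_type = "open",
                                           noise_cv = NULL, ...) {
  im <- object$immigration
  if (is.null(noise_cv))
    noise_cv <- sqrt(expm1(im$residual_sd^2))
  days <- sort(unique(object$series$day[object$series$day > 0]))
  if (length(days) < 2L) days <- c(7, 14, 28, 56)
  lapply(seq_len(nsim), function(k) {
    cfg <- kinetics_sim_config(
      immigration_rate_I = im$immigration_I,
      death_rate_delta = im$delta_used,
      initial_density_N0 = if (!is.null(object$death))
        exp(object$death$intercept) else 1e5,
      sample_days = days,
      slides_per_timepoint = max(1L, ceiling(im$n_points / length(days))),
      noise_cv = noise_cv,
      seed = substream(seed, "simulate", k))
    simulate_cell_counts(cfg, slide_type)
  })
}

#' Plot a fitted immigration-death model
#'
#' ln cell density against day for both slide types with the fitted decay
#' line and accumulation curve.
#'
#' @param x an `immigration_death_fit`.
#' @param ... passed to [plot()].
#' @export
plot.immigration_death_fit <- function(x, ...) {
  s <- x$series
  col <- ifelse(s$slide_type == "open", "#1b7837", "#762a83")
  plot(s$day, log(s$cells_per_cm2), col = col, pch = 16,
       xlab = "day", ylab = "ln cells per cm2", ...)
  tt <- seq(min(s$day), max(s$day), length.out = 200)
  open_mu <- predict(x, data.frame(day = tt, slide_type = "open"))
  lines(tt[open_mu > 0], log(open_mu[open_mu > 0]), col = "#1b7837")
  if (!is.null(x$death)) {
    closed_mu <- predict(x, data.frame(day = tt, slide_type = "closed"))
    lines(tt, log(closed_mu), col = "#762a83")
  }
  legend("bottomright", c("open (accumulation)", "closed (death)"),
         col = c("#1b7837", "#762a83"), pch = 16, bty = "n")
  invisible(x)
}
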