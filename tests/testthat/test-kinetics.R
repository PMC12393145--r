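# Immigration-death model fits.

test_that("an exact exponential decay is recovered perfectly", {
  s <- closed_series(0:10, 1000, 0.1)
  f <- suppressWarnings(fit_death_rate(s))
  expect_equal(f$slope_per_day, -0.1, tolerance = 1e-10)
  expect_equal(f$delta_per_day, 0.1, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  expect_equal(f$intercept, log(1000), tolerance = 1e-10)
})

test_that("a constant series has slope and daily loss zero", {
  s <- closed_series(c(1, 5, 9, 20), 500, 0)
  f <- suppressWarnings(fit_death_rate(s))
  expect_equal(f$slope_per_day, 0, tolerance = 1e-12)
  expect_equal(f$percent_dying_per_day, 0, tolerance = 1e-10)
})

test_that("death-rate preconditions are enforced", {
  s <- closed_series(c(1, 2), 100, 0.1)
  expect_error(fit_death_rate(s), "3 distinct days")
  bad <- closed_series(1:4, 100, 0.1)
  bad$cells_per_cm2[2] <- 0
  expect_error(fit_death_rate(bad), "record 2")
  s2 <- closed_series(1:4, 100, 0.1)
  s2$slide_type <- "opne"
  expect_error(fit_death_rate(s2), "open.*closed|allowed")
})

test_that("percent dying per day and delta are mutually consistent", {
  for (d in c(0.001, 0.02799, 0.3, 2)) {
    expect_equal(percent_to_delta(delta_to_percent(d)), d,
                 tolerance = 1e-12)
  }
  expect_lt(delta_to_percent(5), 100)
})

test_that("duplicated groups give an interaction F of zero", {
  set.seed(8)
  a <- closed_series(rep(1:5, 2), 1000, 0.1, ecosystem = "a")
  a$cells_per_cm2 <- a$cells_per_cm2 * exp(rnorm(10, 0, 0.1))
  b <- a
  b$ecosystem <- "b"
  b$slide_id <- paste0("b", b$slide_id)
  h <- test_slope_homogeneity(rbind(a, b))
  expect_equal(h$f_statistic, 0, tolerance = 1e-9)
  expect_equal(h$p_value, 1, tolerance = 1e-9)
})

test_that("interaction SS equals SSE(additive) - SSE(full)", {
  set.seed(9)
  a <- closed_series(rep(1:6, 2), 1000, 0.1, ecosystem = "a")
  b <- closed_series(rep(1:6, 2), 800, 0.25, ecosystem = "b")
  s <- rbind(a, b)
  s$cells_per_cm2 <- s$cells_per_cm2 * exp(rnorm(nrow(s), 0, 0.2))
  h <- test_slope_homogeneity(s)
  d <- data.frame(lc = log(s$cells_per_cm2), day = s$day,
                  g = factor(s$ecosystem))
  sse_add <- deviance(lm(lc ~ day + g, d))
  sse_full <- deviance(lm(lc ~ day * g, d))
  expect_equal(h$ss_interaction, sse_add - sse_full, tolerance = 1e-10)
  expect_equal(unname(h$group_slopes["a"]),
               unname(coef(lm(lc ~ day, d[d$g == "a", ]))[2]))
})

test_that("clearly different slopes are detected with high power", {
  pvals <- vapply(1:200, function(s) {
    set.seed(1000 + s)
    a <- closed_series(rep(1:5, 4), 1000, 0.1, ecosystem = "a")
    b <- closed_series(rep(1:5, 4), 1000, 0.5, ecosystem = "b")
    x <- rbind(a, b)
    x$cells_per_cm2 <- x$cells_per_cm2 * exp(rnorm(40, 0, 0.01))
    test_slope_homogeneity(x)$p_value
  }, numeric(1))
  expect_gte(mean(pvals < 0.01), 0.95)
})

test_that("immigration closed form recovers noiseless truth and the linear limit", {
  s <- open_series(c(7, 14, 28, 56), 1060, 0.02799)
  f <- fit_immigration_rate(s, 0.02799)
  expect_equal(f$immigration_I, 1060, tolerance = 1e-6)
  expect_equal(f$immigration_I_se, 0, tolerance = 1e-8)
  lin <- open_series(1:5, 50, 0)
  expect_equal(fit_immigration_rate(lin, 0)$immigration_I, 50,
               tolerance = 1e-10)
  expect_error(fit_immigration_rate(s, -0.1), ">= 0")
})

test_that("day-0 open records are excluded from the ln-scale fit", {
  s <- open_series(c(7, 14, 28), 200, 0.05)
  s0 <- rbind(s, data.frame(slide_id = "o000", slide_type = "open",
                            ecosystem = "grassland", transect = 1L,
                            offset_m = 7, day = 0, cells_per_cm2 = 1))
  f <- fit_immigration_rate(s0, 0.05)
  expect_equal(f$n_points, 3L)
  expect_equal(f$immigration_I, 200, tolerance = 1e-8)
})

test_that("the closed-form estimate matches a grid-search minimizer", {
  for (k in 1:10) {
    set.seed(400 + k)
    I <- runif(1, 100, 2000)
    delta <- runif(1, 0.005, 0.1)
    s <- open_series(sort(sample(1:60, 6)), I, delta)
    s$cells_per_cm2 <- s$cells_per_cm2 * exp(rnorm(6, 0, 0.3))
    f <- fit_immigration_rate(s, delta)
    grid <- seq(f$immigration_I * 0.5, f$immigration_I * 1.5,
                length.out = 4001)
    g <- (1 - exp(-delta * s$day)) / delta
    sse <- vapply(grid, function(ii)
      sum((log(s$cells_per_cm2) - log(ii * g))^2), numeric(1))
    expect_lt(abs(grid[which.min(sse)] - f$immigration_I),
              diff(grid[1:2]) + 1e-9)
  }
})

test_that("predicted open-slide trajectory is increasing and bounded by I/delta", {
  s <- rbind(open_series(c(7, 14, 28, 56), 1060, 0.02799),
             closed_series(c(3, 7, 14, 28), 1e5, 0.02799))
  fit <- suppressWarnings(fit_immigration_death(s))
  tt <- data.frame(day = seq(1, 300, by = 1), slide_type = "open")
  mu <- predict(fit, tt)
  expect_true(all(diff(mu) > 0))
  expect_true(all(mu < fit$immigration$immigration_I /
                    fit$immigration$delta_used))
  expect_equal(coef(fit)[["immigration_I"]], 1060, tolerance = 1e-6)
  expect_equal(summary(fit)$percent_dying_per_day,
               delta_to_percent(0.02799))
  expect_length(residuals(fit), nrow(s))
  sim <- simulate(fit, nsim = 2, seed = 5)
  expect_length(sim, 2)
  expect_s3_class(sim[[1]], "data.frame")
})

test_that("immigration as a fraction of a source behaves at the limits", {
  expect_equal(immigration_fraction_of_source(0, 2.8e6), 0)
  expect_equal(immigration_fraction_of_source(1000, 1000), 100)
  expect_error(immigration_fraction_of_source(10, 0), "> 0")
})
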