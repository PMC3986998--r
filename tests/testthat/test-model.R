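test_that("sum scores follow the published worked-example arithmetic", {
  items <- c(dishes_sausage = 2, butter_in_cooking = 0, fruit_per_day = 1,
             cheese_slices = 6, coldcut_frankfurter_slices = 0, male = 1)
  mult <- published_fat_model()$multipliers
  expect_equal(build_sum_score(items, mult), -9)

  expect_equal(build_sum_score(c(a = 5, b = 2), c(a = 0, b = 0)), 0)
  expect_equal(build_sum_score(c(a = 7), c(a = -3)), -21)

  expect_error(build_sum_score(c(a = 1), c(a = 1, b = 2)),
               "b", class = "fiq_coding_error")
  # undetermined multiplier with a nonzero answer cannot be scored
  expect_error(build_sum_score(c(a = 1, b = 1), c(a = 1, b = NA)),
               "undetermined", class = "fiq_coding_error")
  expect_equal(build_sum_score(c(a = 1, b = 0), c(a = 1, b = NA)), 1)
})

test_that("fit_linear matches closed-form OLS on a hand dataset", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2.0, 2.9, 4.2, 4.9, 6.1)
  fit <- fit_linear(x, y)
  # normal equations by hand
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  sse <- sum((y - intercept - slope * x)^2)
  expect_equal(fit$slope, slope)
  expect_equal(fit$intercept, intercept)
  expect_equal(fit$r_squared, 1 - sse / sum((y - mean(y))^2))
  expect_equal(fit$mse, sse / 3)

  perfect <- suppressWarnings(fit_linear(x, 3 + 2 * x))
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$mse, 0, tolerance = 1e-25)

  expect_error(fit_linear(rep(2, 5), y), class = "fiq_degenerate_error")
  expect_error(fit_linear(x, c(0, 1, 2, 3, 4), log_flag = TRUE),
               class = "fiq_domain_error")
})

test_that("R^2 is near zero when targets are independent of the score", {
  set.seed(501)
  x <- rnorm(2000)
  fit <- fit_linear(x, rnorm(2000))
  expect_lt(fit$r_squared, 0.01)
})

test_that("bias correction factor is exp(mse/2)", {
  expect_identical(bias_correction_factor(0), 1)
  expect_equal(bias_correction_factor(2), exp(1))
  expect_equal(bias_correction_factor(0.5), exp(0.25))
  expect_error(bias_correction_factor(-0.1), class = "fiq_domain_error")
})

test_that("multiplier search terminates at init under scale non-identifiability", {
  # single free item: every nonzero multiplier gives the same R^2
  d <- generate_known_model_data(50, c(a = 1), noise_sd = 0, seed = 21)
  s <- optimize_multipliers(d["a"], d$target)
  expect_equal(unname(s$multipliers), 1L)
  expect_equal(s$r_squared, 1)
})

test_that("search finds exact weights on noise-free two-item data", {
  d <- generate_known_model_data(100, c(a = 2, b = 1), noise_sd = 0, seed = 7)
  s <- optimize_multipliers(d[, c("a", "b")], d$target)
  expect_equal(s$r_squared, 1, tolerance = 1e-12)
  expect_true(ratios_recovered(as.numeric(s$multipliers), c(2, 1), band = 0))

  # oracle: exhaustive search over a small integer grid cannot beat it
  X <- as.matrix(d[, c("a", "b")])
  grid_r2 <- function(m) {
    sc <- drop(X %*% m)
    if (var(sc) == 0) 0 else cor(sc, d$target)^2
  }
  best <- max(apply(expand.grid(a = -3:3, b = -3:3), 1, grid_r2))
  expect_lte(best, s$r_squared + 1e-4)
})

test_that("accepted R^2 trace is nondecreasing and result locally optimal", {
  d <- generate_known_model_data(300, c(a = 3, b = 1, c = -2),
                                 intercept = 4, slope = 2, noise_sd = 3,
                                 seed = 31)
  s <- optimize_multipliers(d[, c("a", "b", "c")], d$target)
  expect_true(all(diff(s$r2_trace) >= 0))
  expect_true(is_local_optimum(d[, c("a", "b", "c")], d$target, s$multipliers))
  # deterministic replay
  s2 <- optimize_multipliers(d[, c("a", "b", "c")], d$target)
  expect_identical(s$multipliers, s2$multipliers)
  expect_identical(s$r2_trace, s2$r2_trace)
})

test_that("degenerate inits and runaway searches fail loudly", {
  d <- generate_known_model_data(100, c(a = 3, b = 1), noise_sd = 1, seed = 41)
  expect_error(
    optimize_multipliers(d[, c("a", "b")], d$target, init = c(a = 0.5, b = 1)),
    class = "fiq_config_error"
  )
  expect_error(
    optimize_multipliers(d[, c("a", "b")], d$target, max_passes = 0L),
    class = "fiq_convergence_error"
  )
})

test_that("fitted scoring models are complete, deterministic and predictive", {
  d <- generate_known_model_data(400, c(a = 3, b = 1, c = -2),
                                 intercept = 12, slope = 1.5, noise_sd = 3,
                                 seed = 51)
  m1 <- fit_scoring_model(d, target = "target", items = c("a", "b", "c"),
                          nutrient = "fibre", units = "g")
  m2 <- fit_scoring_model(d, target = "target", items = c("a", "b", "c"),
                          nutrient = "fibre", units = "g")
  expect_identical(m1$multipliers, m2$multipliers)
  expect_equal(m1$intercept, m2$intercept)
  expect_gt(m1$r_squared, 0.8)
  expect_equal(m1$bias_factor, 1)     # linear model: no correction

  g <- glance(m1)
  expect_equal(g$nutrient, "fibre")
  td <- tidy(m1)
  expect_setequal(td$term[td$role == "multiplier"], c("a", "b", "c"))

  expect_error(
    fit_scoring_model(dplyr::mutate(d, target = target - min(target)),
                      target = "target", items = c("a", "b", "c"),
                      log_flag = TRUE),
    class = "fiq_domain_error"
  )
})

test_that("predictions are invariant to joint multiplier/slope rescaling", {
  d <- generate_known_model_data(200, c(a = 2, b = 1), intercept = 5,
                                 slope = 2, noise_sd = 1, seed = 61)
  m <- fit_scoring_model(d, target = "target", items = c("a", "b"))
  scaled <- m
  scaled$multipliers <- m$multipliers * 3L
  scaled$slope <- m$slope / 3
  p1 <- residual_diagnostics(m, d, "target")$predicted
  p2 <- residual_diagnostics(scaled, d, "target")$predicted
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("residual diagnostics are centred for linear fits, zero for perfect", {
  d <- generate_known_model_data(150, c(a = 2, b = -1), intercept = 3,
                                 slope = 2, noise_sd = 0, seed = 71)
  # start the search at the true weights: R^2 = 1 there, so it stays put
  # and the fitted line reproduces the targets exactly
  m <- suppressWarnings(
    fit_scoring_model(d, target = "target", items = c("a", "b"),
                      init = c(a = 2, b = -1))
  )
  diag0 <- residual_diagnostics(m, d, "target")
  expect_equal(diag0$residual, rep(0, nrow(d)), tolerance = 1e-9)

  d2 <- generate_known_model_data(150, c(a = 2, b = -1), intercept = 3,
                                  slope = 2, noise_sd = 4, seed = 72)
  m2 <- fit_scoring_model(d2, target = "target", items = c("a", "b"))
  expect_equal(mean(residual_diagnostics(m2, d2, "target")$residual), 0,
               tolerance = 1e-9)
  expect_s3_class(autoplot(m2, d2, "target"), "ggplot")
})

test_that("models round-trip through their file format bit-for-bit", {
  d <- generate_known_model_data(120, c(a = 2, b = 1), intercept = 8,
                                 slope = 0.5, noise_sd = 0.3, seed = 81)
  d$target <- abs(d$target) + 1
  m <- fit_scoring_model(d, target = "target", items = c("a", "b"),
                         log_flag = TRUE, nutrient = "vitamin_c", units = "mg")
  expect_gte(m$bias_factor, 1)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scoring_model(m, path)
  back <- read_scoring_model(path)
  expect_identical(back$multipliers, m$multipliers)
  expect_identical(
    residual_diagnostics(back, d, "target")$predicted,
    residual_diagnostics(m, d, "target")$predicted
  )
  # the published model's undetermined coefficient survives serialization
  pathp <- withr::local_tempfile(fileext = ".yaml")
  write_scoring_model(published_fat_model(), pathp)
  pub <- read_scoring_model(pathp)
  expect_true(is.na(pub$multipliers[["butter_in_cooking"]]))
  expect_error(read_scoring_model(system.file("extdata", "codebook.yaml",
                                              package = "fiq16")),
               class = "fiq_schema_error")
})
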