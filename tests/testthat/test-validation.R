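test_that("spearman_rs handles identity, reversal and ties like hand ranking", {
  x <- c(3, 1, 4, 1, 5, 9)
  expect_equal(spearman_rs(x, x)$r_s, 1)
  expect_equal(spearman_rs(x, -x)$r_s, -1)
  expect_equal(spearman_rs(x, x)$p_value, 0)

  y <- c(2, 7, 1, 8, 2, 8)        # ties in both vectors
  expect_equal(spearman_rs(x, y)$r_s, spearman_brute(x, y), tolerance = 1e-14)
  expect_equal(spearman_rs(x, y)$r_s,
               cor(x, y, method = "spearman"), tolerance = 1e-14)

  # two-sided t approximation
  res <- spearman_rs(x, y)
  tstat <- res$r_s * sqrt((6 - 2) / (1 - res$r_s^2))
  expect_equal(res$p_value, 2 * pt(-abs(tstat), 4))

  expect_error(spearman_rs(rep(1, 5), 1:5), class = "fiq_degenerate_error")
  expect_error(spearman_rs(1:2, 1:2), class = "fiq_domain_error")
})

test_that("spearman_rs is invariant under strictly monotone transforms", {
  set.seed(401)
  for (i in 1:20) {
    x <- rnorm(25); y <- rnorm(25)
    base <- spearman_rs(x, y)$r_s
    expect_equal(spearman_rs(exp(x), y)$r_s, base, tolerance = 1e-12)
    expect_equal(spearman_rs(x, y^3)$r_s, base, tolerance = 1e-12)
  }
})

test_that("tertile assignment splits evenly, larger groups low, stable ties", {
  expect_equal(assign_tertiles(1:9), rep(1:3, each = 3))
  expect_equal(as.integer(table(assign_tertiles(rnorm(77)))), c(26L, 26L, 25L))
  expect_equal(as.integer(table(assign_tertiles(rnorm(76)))), c(26L, 25L, 25L))

  # label order follows value order
  v <- c(10, 1, 5, 7, 2, 9)
  expect_equal(assign_tertiles(v), c(3L, 1L, 2L, 2L, 1L, 3L))

  # tied boundary values resolved by stable input order
  expect_equal(assign_tertiles(c(1, 1, 1, 1, 2, 3)), c(1L, 1L, 2L, 2L, 3L, 3L))
  expect_warning(lab <- assign_tertiles(rep(4, 6)), "stable input order")
  expect_equal(lab, c(1L, 1L, 2L, 2L, 3L, 3L))
})

test_that("cross-classification counts exact and opposite shares", {
  a <- c(1, 1, 2, 2, 3, 3)
  cc <- cross_classification(a, a)
  expect_equal(cc$exact_pct, 100)
  expect_equal(cc$opposite_pct, 0)

  flipped <- 4 - a
  cc <- cross_classification(a, flipped)
  expect_equal(cc$exact_pct, 100 * sum(a == 2) / 6)
  expect_equal(cc$opposite_pct, 100 * sum(a != 2) / 6)

  expect_error(cross_classification(c(1, 4), c(1, 2)), class = "fiq_coding_error")
})

test_that("weighted kappa matches its defining sums", {
  expect_equal(weighted_kappa(diag(c(5, 5, 5))), 1)

  # chance-only table: outer product of its marginals
  marg <- c(0.5, 0.3, 0.2)
  chance <- outer(marg, marg) * 100
  expect_equal(weighted_kappa(chance), 0, tolerance = 1e-12)
  expect_equal(weighted_kappa(chance, "quadratic"), 0, tolerance = 1e-12)

  tab <- matrix(c(5, 2, 0, 2, 5, 2, 0, 2, 5), 3, 3, byrow = TRUE)
  expect_equal(weighted_kappa(tab), kappa_brute(tab), tolerance = 1e-14)
  expect_equal(weighted_kappa(tab, "quadratic"),
               kappa_brute(tab, "quadratic"), tolerance = 1e-14)

  expect_error(weighted_kappa(matrix(0, 3, 3)), class = "fiq_domain_error")
})

test_that("agreement statistics equal brute force on random instances", {
  set.seed(402)
  for (i in 1:300) {
    n <- sample(6:30, 1)
    a <- sample(1:3, n, replace = TRUE)
    b <- sample(1:3, n, replace = TRUE)
    cc <- cross_classification(a, b)
    bf <- cross_brute(a, b)
    expect_equal(unname(cc$table), unname(bf$table))
    expect_equal(cc$exact_pct, bf$exact_pct, tolerance = 1e-12)
    expect_equal(cc$opposite_pct, bf$opposite_pct, tolerance = 1e-12)
    expect_equal(weighted_kappa(cc$table), kappa_brute(cc$table), tolerance = 1e-12)

    x <- round(rnorm(n), 1)       # rounding forces occasional ties
    y <- round(rnorm(n), 1)
    expect_equal(spearman_rs(x, y)$r_s, spearman_brute(x, y), tolerance = 1e-12)
  }
})

test_that("kappa is 1 iff off-diagonal counts vanish; bounded in [-1, 1]", {
  set.seed(403)
  for (i in 1:100) {
    tab <- matrix(sample(0:8, 9, replace = TRUE), 3, 3)
    if (sum(tab) == 0) next
    k <- weighted_kappa(tab)
    expect_gte(k, -1); expect_lte(k, 1)
    off_diag_zero <- sum(tab) - sum(diag(tab)) == 0
    expect_equal(k == 1, off_diag_zero)
  }
})

test_that("agreement percentages are invariant under joint 1<->3 relabeling", {
  set.seed(404)
  a <- sample(1:3, 40, replace = TRUE)
  b <- sample(1:3, 40, replace = TRUE)
  cc <- cross_classification(a, b)
  rc <- cross_classification(4 - a, 4 - b)
  expect_equal(rc$exact_pct, cc$exact_pct)
  expect_equal(rc$opposite_pct, cc$opposite_pct)
  expect_equal(weighted_kappa(rc$table), weighted_kappa(cc$table), tolerance = 1e-12)
})

test_that("a perfectly agreeing cohort validates at r_s = 1 and exact 100%", {
  set.seed(405)
  n <- 30
  est <- tibble::tibble(
    participant_id = sprintf("p%02d", 1:n),
    fibre_g = runif(n, 5, 40), vitamin_c_mg = runif(n, 20, 150)
  )
  ref <- est
  report <- fiq_validate(estimates = est, references = ref)
  expect_equal(report$nutrient_results$r_s, c(1, 1))
  expect_equal(report$nutrient_results$exact_pct, c(100, 100))
  expect_equal(report$nutrient_results$opposite_pct, c(0, 0))
  expect_equal(report$nutrient_results$weighted_kappa, c(1, 1))
})

test_that("independent instruments give near-chance agreement", {
  set.seed(406)
  n <- 3000
  est <- tibble::tibble(participant_id = as.character(1:n), fibre_g = runif(n))
  ref <- tibble::tibble(participant_id = as.character(1:n), fibre_g = runif(n))
  report <- fiq_validate(estimates = est, references = ref)
  expect_lt(abs(report$nutrient_results$r_s), 0.06)
  expect_equal(report$nutrient_results$exact_pct, 100 / 3, tolerance = 0.1)
  expect_equal(report$nutrient_results$opposite_pct, 200 / 9, tolerance = 0.15)
})

test_that("unmatched participants are reported by id", {
  est <- tibble::tibble(participant_id = c("a", "b", "c"), fibre_g = 1:3)
  ref <- tibble::tibble(participant_id = c("a", "b", "x"), fibre_g = 1:3)
  expect_error(fiq_validate(estimates = est, references = ref), "c, x",
               class = "fiq_match_error")
})

test_that("the full report covers all 26 food groups on synthetic cohorts", {
  cohort <- generate_cohort(cohort_spec(n = 30, seed = 14))
  report <- fiq_validate(
    estimates = estimate_nutrients(cohort$responses),
    references = cohort$records,
    frequencies = fiq_food_group_frequencies(cohort$responses)
  )
  expect_setequal(report$food_group_results$id, food_groups())
  expect_equal(nrow(report$nutrient_results), 12)
  expect_s3_class(tidy(report), "tbl_df")
  expect_s3_class(autoplot(report), "ggplot")
  # every cross table sums to n
  for (tab in report$cross_tables) expect_equal(sum(tab), report$n)
})
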