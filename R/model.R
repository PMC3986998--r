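#' Encode questionnaire answers as numeric scoring items
#'
#' Produces the per-participant numeric item values that integer-multiplier
#' sum scores are built from, in the questionnaire's native units: dish
#' counts per week, slices/decilitres/glasses per day, frequency-category
#' midpoints per day, convenience totals (`cheese_slices`, `milk_dl`,
#' `coldcut_slices`, `bread_slices`, `cereal_dl`), and 0/1 indicators for
#' sex (`male`) and the fat-choice items (`butter_in_cooking`,
#' `oil_in_cooking`, `spread_butter`, `spread_margarine`, `dressing_oil`,
#' `cream_user`).  The published fat score uses exactly these units: 2
#' sausage dishes per week contribute 2 points under a multiplier of 1.
#'
#' @inheritParams validate_responses
#' @return A tibble, one row per participant, `participant_id` first.
#' @export
encode_scoring_items <- function(responses, codebook = fiq_codebook()) {
  r <- validate_responses(responses, codebook)
  freq <- function(col, item) frequency_to_daily(r[[col]], item, codebook)
  tibble(
    participant_id = r$participant_id,
    male = as.numeric(r$sex == "male"),
    meals_per_day = freq("meals_per_day", "meals_per_day"),
    fastfood_per_day = freq("freq_fastfood", "fast_food"),
    fruit_per_day = freq("freq_fruit", "fruits_berries"),
    vegetable_per_day = freq("freq_vegetable", "vegetables"),
    sugar_rich_per_day = freq("freq_sugar_rich", "sugar_rich_foods"),
    sweets_per_day = freq("freq_sweets", "sweets"),
    dishes_fish = r$dishes_fish, dishes_sausage = r$dishes_sausage,
    dishes_chicken = r$dishes_chicken, dishes_meat = r$dishes_meat,
    dishes_vegetable = r$dishes_vegetable,
    milk_fat_free_dl = r$milk_fat_free_dl, milk_low_fat_dl = r$milk_low_fat_dl,
    milk_whole_dl = r$milk_whole_dl,
    milk_dl = r$milk_fat_free_dl + r$milk_low_fat_dl + r$milk_whole_dl,
    cheese_low_fat_slices = r$cheese_low_fat_slices,
    cheese_regular_slices = r$cheese_regular_slices,
    cheese_slices = r$cheese_low_fat_slices + r$cheese_regular_slices,
    coldcut_low_fat_slices = r$coldcut_low_fat_slices,
    coldcut_regular_slices = r$coldcut_regular_slices,
    coldcut_frankfurter_slices = r$coldcut_frankfurter_slices,
    coldcut_slices = r$coldcut_low_fat_slices + r$coldcut_regular_slices +
      r$coldcut_frankfurter_slices,
    bread_rye_crisp_slices = r$bread_rye_crisp_slices,
    bread_multigrain_slices = r$bread_multigrain_slices,
    bread_white_slices = r$bread_white_slices,
    bread_slices = r$bread_rye_crisp_slices + r$bread_multigrain_slices +
      r$bread_white_slices,
    cereal_porridge_dl = r$cereal_porridge_dl,
    cereal_flakes_dl = r$cereal_flakes_dl,
    cereal_dl = r$cereal_porridge_dl + r$cereal_flakes_dl,
    bev_coffee_cups = r$bev_coffee_cups, bev_tea_cups = r$bev_tea_cups,
    bev_soft_drink_glasses = r$bev_soft_drink_glasses,
    bev_sweetened_juice_glasses = r$bev_sweetened_juice_glasses,
    bev_fruit_juice_glasses = r$bev_fruit_juice_glasses,
    bev_beer_bottles = r$bev_beer_bottles, bev_wine_glasses = r$bev_wine_glasses,
    bev_spirits_servings = r$bev_spirits_servings,
    butter_in_cooking = as.numeric(r$cooking_fat_type == "butter_or_butter_spread"),
    oil_in_cooking = as.numeric(r$cooking_fat_type == "vegetable_oil_or_margarine"),
    cream_user = as.numeric(r$cream_in_cooking != "never"),
    spread_butter = as.numeric(r$spread_on_bread_type == "butter_or_butter_spread"),
    spread_margarine = as.numeric(r$spread_on_bread_type == "vegetable_margarine"),
    dressing_oil = as.numeric(r$dressing_type == "oil_based")
  )
}

#' Integer-weighted sum score
#'
#' `SC = sum(multiplier_i * value_i)` over the model's items.  A multiplier
#' stored as `NA` marks a coefficient that is not numerically known (see
#' [published_fat_model()]); it contributes nothing when the item value is
#' zero and is an error otherwise.
#'
#' @param item_values A named numeric vector, or a data frame of item
#'   columns (one score per row).
#' @param multipliers Named integer vector; names must be item names
#'   present in `item_values`.
#' @return Numeric sum score(s).
#' @export
#' @examples
#' build_sum_score(
#'   c(dishes_sausage = 2, butter_in_cooking = 0, fruit_per_day = 1,
#'     cheese_slices = 6, coldcut_frankfurter_slices = 0, male = 1),
#'   c(dishes_sausage = 1, butter_in_cooking = NA, fruit_per_day = -12,
#'     cheese_slices = 1, coldcut_frankfurter_slices = 3, male = -5)
#' )  # -9
build_sum_score <- function(item_values, multipliers) {
  if (is.data.frame(item_values)) {
    vals <- as.matrix(item_values[, names(multipliers), drop = FALSE])
  } else {
    missing_items <- setdiff(names(multipliers), names(item_values))
    if (length(missing_items) > 0) {
      .fiq_stop(paste0("missing item value for: ", paste(missing_items, collapse = ", ")),
                "fiq_coding_error")
    }
    vals <- matrix(item_values[names(multipliers)], nrow = 1,
                   dimnames = list(NULL, names(multipliers)))
  }
  if (anyNA(vals)) .fiq_stop("missing item values", "fiq_coding_error")
  m <- as.numeric(multipliers)
  undetermined <- is.na(m)
  if (any(undetermined)) {
    active <- vals[, undetermined, drop = FALSE] != 0
    if (any(active)) {
      .fiq_stop(paste0("item(s) with an undetermined multiplier have nonzero values: ",
                       paste(names(multipliers)[undetermined], collapse = ", ")),
                "fiq_coding_error")
    }
    m[undetermined] <- 0
  }
  drop(vals %*% m)
}

#' Simple linear regression of a target on a sum score
#'
#' Ordinary least squares of the (optionally natural-log-transformed)
#' target on the score.  Returns the coefficients, the coefficient of
#' determination and the mean squared error, taken as the regression
#' error-variance estimate `SSE / (n - 2)` — the quantity entering the
#' `exp(MSE/2)` back-transformation correction.
#'
#' @param scores Numeric predictor (the sum score).
#' @param targets Numeric response (reference nutrient intake).
#' @param log_flag If `TRUE`, regress `log(targets)`; all targets must be
#'   positive.
#' @return A list: `intercept`, `slope`, `r_squared`, `mse`, `n`,
#'   `log_flag`, `fitted`, `residuals` (on the regression scale).
#' @export
fit_linear <- function(scores, targets, log_flag = FALSE) {
  n <- length(scores)
  if (n != length(targets)) .fiq_stop("scores and targets must have equal length", "fiq_domain_error")
  if (n < 3) .fiq_stop("need at least 3 observations", "fiq_domain_error")
  if (var(scores) == 0) .fiq_stop("degenerate fit: constant scores", "fiq_degenerate_error")
  if (log_flag && any(targets <= 0)) {
    .fiq_stop("log transform requires strictly positive targets", "fiq_domain_error")
  }
  y <- if (log_flag) log(targets) else targets
  fit <- lm(y ~ scores)
  sm <- summary(fit)
  list(
    intercept = unname(stats::coef(fit)[1]), slope = unname(stats::coef(fit)[2]),
    r_squared = sm$r.squared,
    mse = sum(stats::residuals(fit)^2) / (n - 2),
    n = n, log_flag = log_flag,
    fitted = unname(stats::fitted(fit)), residuals = unname(stats::residuals(fit))
  )
}

#' Back-transformation bias correction factor
#'
#' Multiplicative correction `exp(MSE / 2)` applied when predictions from a
#' natural-log-scale regression are exponentiated back to the original
#' scale; `MSE` is the regression mean squared error.
#'
#' @param mse Nonnegative mean squared error.
#' @return `exp(mse / 2)`.
#' @export
#' @examples
#' bias_correction_factor(0)    # 1
#' bias_correction_factor(0.5)  # exp(0.25)
bias_correction_factor <- function(mse) {
  if (any(!is.finite(mse)) || any(mse < 0)) {
    .fiq_stop("mse must be finite and >= 0", "fiq_domain_error")
  }
  exp(mse / 2)
}

# R^2 of target ~ sum score for a multiplier configuration; 0 when the
# score is constant (no informative fit exists there)
.score_r2 <- function(X, y, m) {
  sc <- drop(X %*% m)
  if (var(sc) == 0) return(0)
  suppressWarnings(cor(sc, y))^2
}

#' Coordinate-wise integer multiplier search
#'
#' The scoring-model weight search: starting from an initial integer
#' configuration, items are visited in a fixed order; for each item the
#' multiplier is stepped by +1 (tried first) or -1, and kept stepping in
#' the improving direction while the R-squared of the simple regression of
#' the target on the resulting sum score strictly increases.  Passes over
#' the item order repeat until a full pass changes no multiplier.  The
#' returned configuration is a +/-1 local optimum; the sequence of accepted
#' R-squared values is nondecreasing by construction.
#'
#' "Strictly increases" is judged against the tolerance `tol` (default
#' `1e-4`, i.e. at the fourth decimal of R-squared, the precision at which
#' fit statistics are conventionally reported); ties keep the current
#' multiplier.  The tolerance is substantive, not merely numerical: an
#' integer sum score identifies only the direction of the weight vector,
#' so ever-larger integer configurations can refine that direction with
#' ever-smaller R-squared gains, and counting arbitrarily small gains as
#' improvement inflates the multipliers without bound.  Safety caps
#' (|multiplier| <= `max_multiplier`, at most `max_passes` passes) turn a
#' runaway search into an explicit non-convergence error.
#'
#' @param items A data frame of numeric item columns (a `participant_id`
#'   column, if present, is ignored).
#' @param targets Numeric reference intakes, one per row of `items`.
#' @param item_order Character vector naming the free items, in visiting
#'   order; defaults to all item columns.
#' @param init Named integer vector of starting multipliers (default all 1).
#' @param log_flag Regress on the natural-log scale.
#' @param tol Minimum R-squared gain counted as an improvement.
#' @param max_multiplier,max_passes Safety caps.
#' @return A list of class `fiq_multiplier_search`: `multipliers` (named
#'   integers), `r_squared`, `r2_trace` (accepted values, nondecreasing),
#'   `passes`, `tol`, `converged`.
#' @export
optimize_multipliers <- function(items, targets, item_order = NULL, init = NULL,
                                 log_flag = FALSE, tol = 1e-4,
                                 max_multiplier = 100L, max_passes = 500L) {
  items <- as_tibble(items)
  items$participant_id <- NULL
  if (is.null(item_order)) item_order <- names(items)
  unknown <- setdiff(item_order, names(items))
  if (length(unknown) > 0) {
    .fiq_stop(paste0("item_order names absent from items: ",
                     paste(unknown, collapse = ", ")), "fiq_config_error")
  }
  X <- as.matrix(items[, item_order, drop = FALSE])
  if (anyNA(X)) .fiq_stop("items contain missing values", "fiq_domain_error")
  y <- if (log_flag) {
    if (any(targets <= 0)) .fiq_stop("log transform requires positive targets", "fiq_domain_error")
    log(targets)
  } else targets

  m <- rep(1, length(item_order))
  names(m) <- item_order
  if (!is.null(init)) {
    if (any(init != round(init))) .fiq_stop("init multipliers must be integers", "fiq_config_error")
    m[names(init)] <- init
  }

  eps <- tol
  r2 <- .score_r2(X, y, m)
  trace <- r2
  passes <- 0L
  repeat {
    passes <- passes + 1L
    if (passes > max_passes) {
      .fiq_stop(sprintf("multiplier search did not converge within %d passes", max_passes),
                "fiq_convergence_error")
    }
    changed <- FALSE
    for (j in seq_along(m)) {
      for (dir in c(1, -1)) {       # +1 tried before -1
        stepped <- FALSE
        repeat {
          cand <- m
          cand[j] <- cand[j] + dir
          if (abs(cand[j]) > max_multiplier) {
            .fiq_stop(sprintf("multiplier for '%s' exceeded |%d|: search not converging",
                              item_order[j], max_multiplier), "fiq_convergence_error")
          }
          r2_new <- .score_r2(X, y, cand)
          if (r2_new > r2 + eps) {
            m <- cand; r2 <- r2_new; trace <- c(trace, r2)
            changed <- TRUE; stepped <- TRUE
          } else break
        }
        if (stepped) break          # direction found and exhausted; next item
      }
    }
    if (!changed) break
  }
  structure(list(multipliers = setNames(as.integer(round(m)), item_order),
                 r_squared = r2, r2_trace = trace, passes = passes,
                 tol = tol, converged = TRUE),
            class = "fiq_multiplier_search")
}

#' Check +/-1 local optimality of a multiplier configuration
#'
#' Exhaustively perturbs every free multiplier by +1 and -1 and verifies
#' that no perturbation increases the score R-squared beyond the search
#' tolerance (`tol`, identical in meaning to [optimize_multipliers()]'s).
#'
#' @inheritParams optimize_multipliers
#' @param multipliers Named integer configuration to check.
#' @return `TRUE` if locally optimal, else `FALSE`.
#' @export
is_local_optimum <- function(items, targets, multipliers, log_flag = FALSE,
                             tol = 1e-4) {
  items <- as_tibble(items)
  items$participant_id <- NULL
  X <- as.matrix(items[, names(multipliers), drop = FALSE])
  y <- if (log_flag) log(targets) else targets
  r2 <- .score_r2(X, y, as.numeric(multipliers))
  for (j in seq_along(multipliers)) {
    for (dir in c(1, -1)) {
      cand <- as.numeric(multipliers)
      cand[j] <- cand[j] + dir
      if (.score_r2(X, y, cand) > r2 + tol) return(FALSE)
    }
  }
  TRUE
}

#' Fit a complete scoring model for one nutrient
#'
#' Composes the multiplier search, the simple linear regression of the
#' reference intake on the final sum score, and (for log-scale models) the
#' `exp(MSE/2)` bias correction into a self-contained scoring model.
#'
#' @inheritParams optimize_multipliers
#' @param data A data frame containing the item columns and the target.
#' @param target Name of the reference-intake column.
#' @param items Character vector of free item columns (the sum-variable
#'   items chosen for this nutrient).
#' @param nutrient Identifier stored on the model.
#' @param units Unit label of the predictions (e.g. `"E%"`, `"g"`).
#' @return An object of class `fiq_model`; see [published_fat_model()] for
#'   the fields.
#' @export
#' @examples
#' d <- generate_known_model_data(200, c(a = 3, b = 1, c = -2),
#'                                intercept = 10, slope = 2,
#'                                noise_sd = 1, seed = 42)
#' m <- fit_scoring_model(d, target = "target", items = c("a", "b", "c"))
#' glance(m)
fit_scoring_model <- function(data, target, items, item_order = items,
                              init = NULL, log_flag = FALSE, nutrient = target,
                              units = "", tol = 1e-4, max_multiplier = 100L,
                              max_passes = 500L) {
  data <- as_tibble(data)
  targets <- data[[target]]
  if (is.null(targets)) .fiq_stop(sprintf("no column '%s' in data", target), "fiq_schema_error")
  if (anyNA(targets)) .fiq_stop("missing targets", "fiq_domain_error")
  search <- optimize_multipliers(data[, items, drop = FALSE], targets,
                                 item_order = item_order, init = init,
                                 log_flag = log_flag, tol = tol,
                                 max_multiplier = max_multiplier,
                                 max_passes = max_passes)
  sc <- build_sum_score(data[, items, drop = FALSE], search$multipliers)
  fit <- fit_linear(sc, targets, log_flag = log_flag)
  new_fiq_model(
    nutrient = nutrient, units = units,
    multipliers = search$multipliers,
    intercept = fit$intercept, slope = fit$slope, log_flag = log_flag,
    mse = fit$mse, r_squared = fit$r_squared, n = fit$n,
    r2_trace = search$r2_trace, passes = search$passes
  )
}

# low-level constructor shared by the fitter, the published fixture and the
# model reader
new_fiq_model <- function(nutrient, units, multipliers, intercept, slope,
                          log_flag, mse = NA_real_, r_squared = NA_real_,
                          n = NA_integer_, r2_trace = NULL, passes = NA_integer_,
                          source = "fitted") {
  if (any(!is.na(multipliers) & multipliers != round(multipliers))) {
    .fiq_stop("multipliers must be integers", "fiq_config_error")
  }
  bias <- if (log_flag && is.finite(mse)) bias_correction_factor(mse) else 1
  structure(
    list(nutrient = nutrient, units = units,
         multipliers = setNames(as.integer(round(multipliers)), names(multipliers)),
         intercept = intercept, slope = slope, log_flag = log_flag,
         bias_factor = bias, mse = mse, r_squared = r_squared, n = n,
         r2_trace = r2_trace, passes = passes, source = source),
    class = "fiq_model"
  )
}

#' @export
print.fiq_model <- function(x, ...) {
  cat(sprintf("<fiq_model> %s [%s]%s\n", x$nutrient, x$units,
              if (x$log_flag) " (log scale)" else ""))
  mm <- x$multipliers[is.na(x$multipliers) | x$multipliers != 0]
  cat("  SC =", paste(sprintf("%s x %s", ifelse(is.na(mm), "?", mm), names(mm)),
                      collapse = " + "), "\n")
  cat(sprintf("  prediction = %s%.4g + %.4g x SC%s\n",
              if (x$log_flag) sprintf("%.6g x exp(", x$bias_factor) else "",
              x$intercept, x$slope, if (x$log_flag) ")" else ""))
  if (is.finite(x$r_squared)) {
    cat(sprintf("  R^2 = %.3f, MSE = %.4g, n = %s\n", x$r_squared, x$mse, x$n))
  }
  invisible(x)
}

#' Tidy and summarise fitted scoring models
#'
#' `tidy()` returns one row per model item (the integer multipliers, with
#' the intercept and slope of the regression as attributes-free extra
#' rows); `glance()` returns the one-row fit summary.  `tidy()` on a
#' validation report stacks the food-group and nutrient agreement tables.
#'
#' @param x An `fiq_model` (or `fiq_validation`) object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.fiq_model <- function(x, ...) {
  dplyr::bind_rows(
    tibble(term = names(x$multipliers), role = "multiplier",
           estimate = as.numeric(x$multipliers)),
    tibble(term = c("(intercept)", "(slope)"), role = "coefficient",
           estimate = c(x$intercept, x$slope))
  )
}

#' @rdname tidy.fiq_model
#' @export
glance.fiq_model <- function(x, ...) {
  tibble(nutrient = x$nutrient, units = x$units, r_squared = x$r_squared,
         mse = x$mse, log_flag = x$log_flag, bias_factor = x$bias_factor,
         n = x$n, passes = x$passes)
}

#' Residual diagnostics on the prediction scale
#'
#' Predictions and residuals on the original (back-transformed) intake
#' scale, for plotting residuals against predicted intakes.  For a fitted
#' linear (non-log) model the raw residual mean is zero by OLS
#' orthogonality.  Unlike patient scoring, diagnostics do not clamp
#' negative predictions: a fitted line dipping below zero is exactly what
#' the plot should reveal.
#'
#' @param model An `fiq_model`.
#' @param data Data frame with the model's item columns and the target.
#' @param target Name of the reference-intake column.
#' @return A tibble: `participant_id` (if present), `predicted`,
#'   `observed`, `residual`.
#' @export
residual_diagnostics <- function(model, data, target) {
  data <- as_tibble(data)
  sc <- build_sum_score(data[, names(model$multipliers), drop = FALSE],
                        model$multipliers)
  pred <- predict_from_score(model, sc, clamp = FALSE)
  out <- tibble(predicted = pred, observed = data[[target]],
                residual = data[[target]] - pred)
  if ("participant_id" %in% names(data)) {
    out <- mutate(out, participant_id = data$participant_id, .before = 1)
  }
  out
}

#' @rdname residual_diagnostics
#' @param object An `fiq_model`.
#' @param ... Passed `data` and `target` (as for `residual_diagnostics`).
#' @export
autoplot.fiq_model <- function(object, ...) {
  diag <- residual_diagnostics(object, ...)
  ggplot2::ggplot(diag, ggplot2::aes(x = .data$predicted, y = .data$residual)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = sprintf("predicted %s (%s)", object$nutrient, object$units),
      y = "residual (observed - predicted)"
    )
}

#' Suggest a log transform from residual normality
#'
#' Heuristic for the per-nutrient log flag: fits the model both ways and
#' recommends the scale whose regression residuals look more Gaussian
#' (larger Shapiro-Wilk W).  Skipped (returns `FALSE`) when targets are
#' not strictly positive.
#'
#' @inheritParams fit_scoring_model
#' @return `TRUE` if the log scale is recommended.
#' @export
suggest_log_flag <- function(data, target, items) {
  targets <- as_tibble(data)[[target]]
  if (any(targets <= 0)) return(FALSE)
  sc <- build_sum_score(as_tibble(data)[, items, drop = FALSE],
                        setNames(rep(1L, length(items)), items))
  if (var(sc) == 0) return(FALSE)
  w_raw <- stats::shapiro.test(fit_linear(sc, targets, FALSE)$residuals)$statistic
  w_log <- stats::shapiro.test(fit_linear(sc, targets, TRUE)$residuals)$statistic
  unname(w_log > w_raw)
}

#' Read and write scoring models
#'
#' Serializes an `fiq_model` to YAML: multipliers, intercept, slope, log
#' flag, bias factor, R-squared and MSE — everything needed to reproduce
#' predictions bit-for-bit.
#'
#' @param model An `fiq_model`.
#' @param path File path.
#' @return `read_scoring_model()` returns an `fiq_model`.
#' @export
write_scoring_model <- function(model, path) {
  x <- list(
    schema = "fiq16/scoring-model/1",
    nutrient = model$nutrient, units = model$units,
    multipliers = as.list(model$multipliers),
    intercept = model$intercept, slope = model$slope,
    log_flag = model$log_flag, mse = model$mse,
    r_squared = model$r_squared, n = model$n, source = model$source
  )
  yaml::write_yaml(x, path, precision = 17)
  invisible(path)
}

#' @rdname write_scoring_model
#' @export
read_scoring_model <- function(path) {
  x <- yaml::read_yaml(path)
  if (!identical(x$schema, "fiq16/scoring-model/1")) {
    .fiq_stop(sprintf("'%s' is not a scoring-model file", path), "fiq_schema_error")
  }
  mult <- vapply(x$multipliers, function(v) if (is.null(v)) NA_real_ else as.numeric(v),
                 numeric(1))
  new_fiq_model(
    nutrient = x$nutrient, units = x$units %||% "", multipliers = mult,
    intercept = x$intercept, slope = x$slope, log_flag = isTRUE(x$log_flag),
    mse = x$mse %||% NA_real_, r_squared = x$r_squared %||% NA_real_,
    n = x$n %||% NA_integer_, source = x$source %||% "file"
  )
}
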