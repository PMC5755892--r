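#' Percent difference between paired volumes
#'
#' `100 * |automated - reference| / reference`, the unsigned percent
#' deviation of the automated measurement from the reference standard.
#'
#' @param automated_cm3,reference_cm3 numeric vectors of paired volumes.
#' @return Numeric vector of percent differences.
#' @export
percent_difference <- function(automated_cm3, reference_cm3) {
  if (any(!is.finite(reference_cm3)) || any(reference_cm3 <= 0))
    stop("reference volumes must be positive", call. = FALSE)
  100 * abs(automated_cm3 - reference_cm3) / reference_cm3
}

#' Validate a table of paired automated/reference volumes
#'
#' @param df data frame with columns `exam_id`, `side`, `quantity`
#'   (`"total"` or `"air_free"`), `automated_cm3`, `reference_cm3`.
#' @return The validated tibble with class `paired_volumes`.
#' @export
paired_volumes <- function(df) {
  need <- c("exam_id", "side", "quantity", "automated_cm3",
            "reference_cm3")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(df$automated_cm3 <= 0) || any(df$reference_cm3 <= 0))
    stop("all volumes must be positive", call. = FALSE)
  if (!all(df$quantity %in% c("total", "air_free")))
    stop("quantity must be \"total\" or \"air_free\"", call. = FALSE)
  key <- paste(df$exam_id, df$side, df$quantity)
  if (anyDuplicated(key))
    stop("duplicate (exam_id, side, quantity) rows", call. = FALSE)
  out <- tibble::as_tibble(df[need])
  class(out) <- c("paired_volumes", class(out))
  out
}

#' Read paired volumes from CSV
#'
#' Expects the header `exam_id,side,quantity,automated_cm3,reference_cm3`.
#'
#' @param file_path CSV path.
#' @return A [paired_volumes()] tibble.
#' @export
read_paired_volumes <- function(file_path) {
  df <- readr::read_csv(file_path, show_col_types = FALSE,
                        col_types = readr::cols(
                          exam_id = readr::col_character(),
                          side = readr::col_character(),
                          quantity = readr::col_character(),
                          automated_cm3 = readr::col_double(),
                          reference_cm3 = readr::col_double()))
  paired_volumes(df)
}

quantity_subset <- function(pairs, quantity) {
  sub <- pairs[pairs$quantity == quantity, , drop = FALSE]
  if (nrow(sub) < 3L)
    stop("need at least 3 pairs for quantity \"", quantity, "\"",
         call. = FALSE)
  sub
}

#' Ordinary least squares of automated on reference volumes
#'
#' Fits `automated = intercept + slope * reference`; the reference
#' (manual) volume is the x axis throughout the package.
#'
#' @param pairs a [paired_volumes()] tibble.
#' @param quantity `"total"` or `"air_free"`.
#' @return Object of class `agreement_fit`: list with `slope`,
#'   `intercept`, `r_squared`, `n`, `quantity` and the underlying `lm`
#'   fit.
#' @export
fit_regression <- function(pairs, quantity = "total") {
  sub <- quantity_subset(pairs, quantity)
  if (stats::sd(sub$reference_cm3) == 0)
    stop("reference volumes are constant; regression is degenerate",
         call. = FALSE)
  fit <- stats::lm(automated_cm3 ~ reference_cm3, data = sub)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = stats::cor(sub$automated_cm3,
                                        sub$reference_cm3)^2,
                 n = nrow(sub), quantity = quantity, model = fit),
            class = "agreement_fit")
}

#' @export
print.agreement_fit <- function(x, ...) {
  cat(sprintf("<agreement_fit> %s: y = %.3f x %+.3f, R^2 = %.3f (n = %d)\n",
              x$quantity, x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.agreement_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @export
glance.agreement_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, n = x$n, quantity = x$quantity)
}

#' Bland-Altman agreement analysis
#'
#' Differences are automated minus reference; the bias is their mean and
#' the limits of agreement are `bias +/- multiplier * SD` with the sample
#' (n-1) standard deviation.
#'
#' @param pairs a [paired_volumes()] tibble.
#' @param quantity `"total"` or `"air_free"`.
#' @param loa_multiplier limits-of-agreement multiplier; 1.96 for the 95%
#'   interval (default), 2.0 for the two-SD convention.
#' @return Object of class `bland_altman`: list with `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `loa_multiplier`, `n`, `quantity`,
#'   `differences`, `means`.
#' @export
bland_altman <- function(pairs, quantity = "total", loa_multiplier = 1.96) {
  sub <- quantity_subset(pairs, quantity)
  d <- sub$automated_cm3 - sub$reference_cm3
  bias <- mean(d)
  sdd <- stats::sd(d)
  structure(list(bias = bias, sd_diff = sdd,
                 loa_low = bias - loa_multiplier * sdd,
                 loa_high = bias + loa_multiplier * sdd,
                 loa_multiplier = loa_multiplier,
                 n = nrow(sub), quantity = quantity,
                 differences = d,
                 means = (sub$automated_cm3 + sub$reference_cm3) / 2),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(paste0("<bland_altman> %s: bias %.2f cm^3, LoA [%.2f, %.2f]",
                     " (x %.2f SD, n = %d)\n"),
              x$quantity, x$bias, x$loa_low, x$loa_high,
              x$loa_multiplier, x$n))
  invisible(x)
}

#' @export
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(bias = x$bias, sd_diff = x$sd_diff, loa_low = x$loa_low,
                 loa_high = x$loa_high, loa_multiplier = x$loa_multiplier,
                 n = x$n, quantity = x$quantity)
}

#' Full method-agreement summary
#'
#' Per quantity present in the input: number of pairs, mean and SD of the
#' percent difference, the regression of automated on reference, the
#' Bland-Altman bias and limits, and the cohort mean and SD of the
#' automated volumes.
#'
#' @param pairs a [paired_volumes()] tibble.
#' @param loa_multiplier passed to [bland_altman()].
#' @return A tibble of class `agreement_report`, one row per quantity.
#' @export
summarize_cohort <- function(pairs, loa_multiplier = 1.96) {
  pairs <- paired_volumes(pairs)
  rows <- lapply(unique(pairs$quantity), function(q) {
    sub <- quantity_subset(pairs, q)
    pct <- percent_difference(sub$automated_cm3, sub$reference_cm3)
    fit <- fit_regression(pairs, q)
    ba <- bland_altman(pairs, q, loa_multiplier)
    tibble::tibble(
      quantity = q, n_pairs = nrow(sub),
      mean_percent_difference = mean(pct),
      sd_percent_difference = stats::sd(pct),
      slope = fit$slope, intercept = fit$intercept,
      r_squared = fit$r_squared,
      bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
      loa_multiplier = loa_multiplier,
      mean_automated = mean(sub$automated_cm3),
      sd_automated = stats::sd(sub$automated_cm3))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("agreement_report", class(out))
  out
}

#' @export
glance.agreement_report <- function(x, ...) tibble::as_tibble(x)

#' Synthetic stand-in for the published per-patient volume table
#'
#' The published validation compared automated and manual volumes for 60
#' sinuses; the raw per-patient table is not redistributable here. This
#' function deterministically constructs a synthetic 60-sinus table whose
#' exact sample statistics (OLS slope/intercept/R-squared of automated on
#' reference, Bland-Altman bias and limits, cohort mean and SD of the
#' automated totals) round to the published summary values, so the
#' agreement machinery can be exercised end-to-end. It is synthetic data:
#' individual rows are not real patients.
#'
#' @return A [paired_volumes()] tibble with 120 rows (60 sinuses, two
#'   quantities).
#' @export
synthetic_s1_pairs <- function() {
  n <- 60L
  z <- stats::qnorm(stats::ppoints(n))
  z <- (z - mean(z)) / stats::sd(z)
  e0 <- z^2 - mean(z^2)           # exactly orthogonal to 1 and z
  build <- function(alpha, bias, mean_y, sd_d, var_y) {
    x_bar <- mean_y - bias
    beta <- (mean_y - alpha) / x_bar
    var_d <- sd_d^2
    sxx <- (var_y - var_d) / (beta^2 - (beta - 1)^2)
    see <- var_d - (beta - 1)^2 * sxx
    x <- x_bar + sqrt(sxx) * z
    e <- e0 * sqrt(see * (n - 1) / sum(e0^2))
    y <- alpha + beta * x + e
    list(x = x, y = y)
  }
  tot <- build(alpha = -0.22, bias = -0.766, mean_y = 14.7,
               sd_d = 0.9512, var_y = 4.4499^2)
  # air-free: var_y derived from the target R^2 instead of a target SD
  alpha_a <- 0.088; bias_a <- -0.676; xbar_a <- 14.525; sd_da <- 0.849
  beta_a <- 1 + (bias_a - alpha_a) / xbar_a
  r2_a <- 0.978
  denom <- beta_a^2 - (beta_a - 1)^2
  var_ya <- beta_a^2 * sd_da^2 / (beta_a^2 - r2_a * denom)
  air <- build(alpha = alpha_a, bias = bias_a, mean_y = xbar_a + bias_a,
               sd_d = sd_da, var_y = var_ya)
  ids <- rep(sprintf("P%02d", 1:30), each = 2L)
  sides <- rep(c("right", "left"), times = 30L)
  paired_volumes(tibble::tibble(
    exam_id = c(ids, ids),
    side = c(sides, sides),
    quantity = rep(c("total", "air_free"), each = n),
    automated_cm3 = c(tot$y, air$y),
    reference_cm3 = c(tot$x, air$x)))
}
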