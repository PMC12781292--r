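#' Internal validation helpers
#'
#' @noRd
assert_int_range <- function(x, lo, hi, what) {
  if (anyNA(x)) abort(paste0("missing values in ", what))
  bad <- which(x < lo | x > hi | x != round(x))
  if (length(bad) > 0) {
    abort(sprintf(
      "%s out of range [%d, %d] at position(s) %s (value(s) %s)",
      what, lo, hi,
      paste(head(bad, 5), collapse = ", "),
      paste(head(x[bad], 5), collapse = ", ")
    ))
  }
  invisible(x)
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# Deterministic child seed, kept within 32-bit integer range.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 7919 * k) %% 2147483647L)
}

#' Wald confidence interval from an estimate and standard error
#'
#' Normal-quantile (z) interval, the convention used throughout the
#' dose-response contrasts: `estimate +/- z * se` with `z = qnorm(1 - (1 -
#' level) / 2)` (1.96 for a 95% interval).
#'
#' @param estimate Point estimate.
#' @param se Standard error.
#' @param level Coverage level, default 0.95.
#' @return A tibble with columns `estimate`, `se`, `conf.low`, `conf.high`.
#' @examples
#' wald_ci(56.43, 6.56)
#' @export
wald_ci <- function(estimate, se, level = 0.95) {
  if (any(se < 0)) abort("se must be nonnegative")
  z <- qnorm(1 - (1 - level) / 2)
  tibble(
    estimate = estimate, se = se,
    conf.low = estimate - z * se, conf.high = estimate + z * se
  )
}

#' Survey response rate as a printed percentage
#'
#' @param completed Number of completed questionnaires.
#' @param approached Number of people approached.
#' @param digits Decimal places of the percentage (default 1, as reports print).
#' @return Percentage on the 0-100 scale.
#' @examples
#' response_rate(645, 887)
#' @export
response_rate <- function(completed, approached, digits = 1) {
  if (approached <= 0 || completed < 0 || completed > approached) {
    abort("need 0 <= completed <= approached with approached > 0")
  }
  round(100 * completed / approached, digits)
}

#' Descriptive summaries for a cohort table
#'
#' Reporting utilities mirroring a typical participant-characteristics table:
#' categorical variables as counts and percentages, continuous variables as
#' median, IQR, range and a Shapiro-Wilk normality test.
#'
#' @param data A data frame.
#' @param vars Column names to summarise; defaults to all columns.
#' @return A tibble; one row per category (categorical) or per variable
#'   (continuous).
#' @export
describe_cohort <- function(data, vars = names(data)) {
  stopifnot(is.data.frame(data))
  rows <- purrr::map(vars, function(v) {
    x <- data[[v]]
    if (is.null(x)) abort(paste0("unknown column: ", v))
    if (is.numeric(x)) {
      sw <- if (length(x) >= 3 && length(x) <= 5000 && sd(x) > 0) {
        shapiro.test(x)
      } else {
        list(statistic = NA_real_, p.value = NA_real_)
      }
      tibble(
        variable = v, category = NA_character_,
        n = length(x), percent = NA_real_,
        median = median(x), iqr = IQR(x),
        min = min(x), max = max(x),
        shapiro_w = unname(sw$statistic), shapiro_p = sw$p.value
      )
    } else {
      tab <- table(x)
      tibble(
        variable = v, category = names(tab),
        n = as.integer(tab), percent = round(100 * as.integer(tab) / length(x), 1),
        median = NA_real_, iqr = NA_real_, min = NA_real_, max = NA_real_,
        shapiro_w = NA_real_, shapiro_p = NA_real_
      )
    }
  })
  dplyr::bind_rows(rows)
}
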