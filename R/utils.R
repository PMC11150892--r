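# Internal helpers shared across modules.

WEEK_SECONDS <- 7 * 86400

#' Difference between two datetimes in weeks
#'
#' @param later,earlier `POSIXct` vectors.
#' @return Numeric weeks (days / 7), fractional.
#' @keywords internal
weeks_between <- function(later, earlier) {
  as.numeric(difftime(later, earlier, units = "days")) / 7
}

#' Convert weeks to seconds
#' @keywords internal
weeks_to_secs <- function(w) w * WEEK_SECONDS

# Quantiles are computed with linear interpolation (type 7) throughout the
# package so that medians and IQRs are reproducible bit-for-bit.
q_lin <- function(x, p) unname(stats::quantile(x, p, type = 7, names = FALSE))

med_iqr <- function(x) {
  if (length(x) == 0) {
    return(c(median = NA_real_, q1 = NA_real_, q3 = NA_real_))
  }
  c(median = q_lin(x, 0.5), q1 = q_lin(x, 0.25), q3 = q_lin(x, 0.75))
}

mean_sd_med_iqr <- function(x) {
  if (length(x) == 0) {
    return(tibble::tibble(
      n = 0L, mean = NA_real_, sd = NA_real_,
      median = NA_real_, q1 = NA_real_, q3 = NA_real_
    ))
  }
  tibble::tibble(
    n = length(x),
    mean = mean(x),
    sd = stats::sd(x),
    median = q_lin(x, 0.5),
    q1 = q_lin(x, 0.25),
    q3 = q_lin(x, 0.75)
  )
}

#' Percentage of a count ratio
#'
#' All cohort rates in the package are reported as `100 * numerator /
#' denominator`, rounded half-even to `dp` decimal places.
#'
#' @param numerator,denominator Non-negative counts; `denominator > 0`.
#' @param dp Decimal places for the percentage (default 2).
#' @return A list with `numerator`, `denominator` and `pct`.
#' @examples
#' ratio_pct(43183, 45401)  # 95.11
#' @export
ratio_pct <- function(numerator, denominator, dp = 2) {
  if (denominator == 0) {
    stop("ratio_pct(): denominator is zero", call. = FALSE)
  }
  list(
    numerator = numerator,
    denominator = denominator,
    pct = round(100 * numerator / denominator, dp)
  )
}

route_string <- function(activities) paste(activities, collapse = " -> ")

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
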