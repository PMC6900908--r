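#' Reference summary tables from the original two-session study
#'
#' Published per-condition summary statistics (mean, SD, paired t and Cohen's
#' d at n = 15) for the band-power changes and BRUMS-32 score changes of the
#' screening session (three combined-stimulus ratios) and the comparison
#' session (SHAM, binaural beat, natural sound, combined stimulus). Shipped
#' as plain CSV under `inst/extdata/` and used as inputs to the internal
#' consistency check.
#'
#' @return Named list of tibbles: `session1_bands`, `session1_brums`,
#'   `session2_bands`, `session2_brums`.
#' @export
reference_tables <- function() {
  rd <- function(name) {
    tibble::as_tibble(utils::read.csv(
      system.file("extdata", name, package = "thetabeat", mustWork = TRUE),
      stringsAsFactors = FALSE))
  }
  list(session1_bands = rd("reference_session1_bands.csv"),
       session1_brums = rd("reference_session1_brums.csv"),
       session2_bands = rd("reference_session2_bands.csv"),
       session2_brums = rd("reference_session2_brums.csv"))
}

#' Check printed t statistics against their rounded mean and SD
#'
#' For each row of a reference table, the paired t implied by the printed
#' two-decimal mean and SD at sample size `n` is only known up to the rounding
#' of those two cells. This computes the interval of |t| compatible with
#' `mean` in `[|m| - 0.005, |m| + 0.005]` and `sd` in `[s - 0.005, s + 0.005]`
#' and flags rows whose printed t (allowing its own half-unit-in-last-place
#' rounding) falls outside -- i.e. rows that are internally inconsistent as
#' printed.
#'
#' @param table Tibble with `mean`, `sd`, `t` columns (see
#'   [reference_tables()]).
#' @param n Sample size behind the summary statistics (default 15).
#' @param t_digits Decimal places the t column is printed to (default 3).
#' @return The input with added columns `t_lo`, `t_hi` (bounds on |t|) and
#'   `consistent` (logical).
#' @export
check_printed_consistency <- function(table, n = 15, t_digits = 3) {
  stopifnot(all(c("mean", "sd", "t") %in% names(table)))
  rt <- sqrt(n)
  am <- abs(table$mean)
  t_lo <- pmax(am - 0.005, 0) * rt / (table$sd + 0.005)
  t_hi <- (am + 0.005) * rt / pmax(table$sd - 0.005, 1e-12)
  tol <- 0.5 * 10^(-t_digits)
  out <- table
  out$t_lo <- t_lo
  out$t_hi <- t_hi
  out$consistent <- abs(table$t) >= t_lo - tol & abs(table$t) <= t_hi + tol
  out
}
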