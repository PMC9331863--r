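# Dosing regimens: ordered intravenous infusion events.

#' Create a dosing regimen of intravenous infusions
#'
#' A regimen is an ordered set of infusion events, each with a dose amount
#' (mg), a start time (hours since the first dose) and an infusion duration
#' (hours). Dalbavancin is administered as short (0.5 h) infusions at weekly
#' intervals; the helper [weekly_regimen()] builds the common schedules.
#'
#' @param amount numeric vector of dose amounts (mg), all `>= 0`.
#' @param start_time numeric vector of start times (h since first dose),
#'   strictly increasing, all `>= 0`.
#' @param infusion_duration infusion durations (h), all `> 0`; recycled.
#' @return An object of class `"regimen"`: a data frame with columns
#'   `amount`, `start_time`, `infusion_duration`.
#' @examples
#' # 1500 mg on day 1 plus 1500 mg on day 8
#' regimen(c(1500, 1500), c(0, 168))
#' @export
regimen <- function(amount, start_time = 0, infusion_duration = 0.5) {
  n <- length(amount)
  if (n < 1L) stop("a regimen needs at least one dose event")
  start_time <- rep_len(start_time, n)
  infusion_duration <- rep_len(infusion_duration, n)
  if (any(!is.finite(amount)) || any(amount < 0))
    stop("dose amounts must be finite and >= 0")
  if (any(!is.finite(start_time)) || any(start_time < 0))
    stop("start times must be finite and >= 0")
  if (n > 1L && any(diff(start_time) <= 0))
    stop("dose start times must be strictly increasing")
  if (any(infusion_duration <= 0))
    stop("infusion durations must be > 0")
  structure(
    data.frame(amount = amount, start_time = start_time,
               infusion_duration = infusion_duration),
    class = c("regimen", "data.frame"))
}

#' Weekly dosing schedules
#'
#' Convenience constructor for the schedules used clinically: equal or
#' front-loaded doses one week (168 h) apart.
#'
#' @param amounts dose amounts (mg), one per weekly administration.
#' @param infusion_duration infusion duration in hours (default 0.5).
#' @return A [regimen()].
#' @examples
#' weekly_regimen(c(1000, 500))   # approved: 1000 mg d1 + 500 mg d8
#' weekly_regimen(1500)           # single 1500 mg dose
#' @export
weekly_regimen <- function(amounts, infusion_duration = 0.5) {
  regimen(amounts, 168 * (seq_along(amounts) - 1), infusion_duration)
}

#' Named preset dosing regimens
#'
#' Presets cover the label regimens for preserved renal function and renal
#' impairment plus the doubled one-week-apart regimens explored for long-term
#' treatment. Two renal-impairment split presets are provided because usage
#' differs between sources: `"impaired_split"` (500 mg d1 + 375 mg d8) and
#' `"impaired_split_label"` (750 mg d1 + 375 mg d8).
#'
#' @param name one of `"single_1500"`, `"split_1000_500"`, `"double_1500"`,
#'   `"single_1000"`, `"impaired_split"`, `"impaired_split_label"`,
#'   `"double_1000"`.
#' @return A [regimen()].
#' @export
preset_regimen <- function(name) {
  switch(match.arg(name, c("single_1500", "split_1000_500", "double_1500",
                           "single_1000", "impaired_split",
                           "impaired_split_label", "double_1000")),
    single_1500          = weekly_regimen(1500),
    split_1000_500       = weekly_regimen(c(1000, 500)),
    double_1500          = weekly_regimen(c(1500, 1500)),
    single_1000          = weekly_regimen(1000),
    impaired_split       = weekly_regimen(c(500, 375)),
    impaired_split_label = weekly_regimen(c(750, 375)),
    double_1000          = weekly_regimen(c(1000, 1000)))
}

#' @export
print.regimen <- function(x, ...) {
  cat(sprintf("Dosing regimen: %d infusion(s), total dose %g mg\n",
              nrow(x), sum(x$amount)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

total_dose <- function(reg) sum(reg$amount)
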