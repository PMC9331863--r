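# Synthetic-cohort generator: study-like sparse TDM datasets with known
# ground truth, for validating estimation and diagnostics when the clinical
# data themselves are not available.

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the published study population: 69 subjects; covariates
#' drawn from truncated distributions calibrated to the reported median/IQR
#' and min-max ranges (CLcr median 93, IQR 72-104, range 3-141 mL/min/1.73 m2;
#' weight median 75 kg; age median 62 y; albumin median 3.7 g/dL); 2-14 weekly
#' doses of 1000 or 1500 mg (median 2, most patients two doses); a median of
#' 3 sparse samples per subject drawn after the second dose, trough-weighted
#' with an occasional post-infusion peak, for roughly 290 concentrations in
#' total.
#'
#' @param n_subjects number of subjects (default 69).
#' @param clcr_meanlog,clcr_sdlog log-normal parameters of the CLcr
#'   distribution (defaults calibrated to median 93, IQR 72-104).
#' @param clcr_range hard truncation range for CLcr.
#' @param weight_median,weight_sd,weight_range truncated-normal weight (kg).
#' @param age_median,age_sd,age_range truncated-normal age (years).
#' @param albumin_median,albumin_sd,albumin_range truncated-normal albumin
#'   (g/dL).
#' @param height_median,height_sd,height_range truncated-normal height (cm).
#' @param prob_male probability a subject is male.
#' @param dose_count_probs probabilities for 2..14 doses per subject.
#' @param dose_amounts possible per-dose amounts (mg).
#' @param dose_amount_probs sampling probabilities for `dose_amounts`.
#' @param samples_mu,samples_size negative-binomial parameters for the number
#'   of samples per subject (1 + NB, capped at `samples_max`).
#' @param samples_max maximum samples per subject.
#' @param samples_range optional integer vector; when given, the number of
#'   samples per subject is drawn uniformly from it instead of the
#'   negative-binomial rule (e.g. `3:5` for a moderately rich design).
#' @param peak_fraction fraction of samples taken shortly after infusion end
#'   rather than at trough-like times.
#' @param trough_window days after a dose within which trough-like samples are
#'   drawn uniformly.
#' @param lloq lower limit of quantification (mg/L); observations below are
#'   flagged BLQ.
#' @return An object of class `"cohort_config"` (a list).
#' @export
cohort_config <- function(n_subjects = 69,
                          clcr_meanlog = log(93), clcr_sdlog = 0.2726,
                          clcr_range = c(3, 141),
                          weight_median = 75, weight_sd = 19.3,
                          weight_range = c(42, 143),
                          age_median = 62, age_sd = 16.3,
                          age_range = c(19, 90),
                          albumin_median = 3.7, albumin_sd = 0.52,
                          albumin_range = c(2.5, 4.6),
                          height_median = 170, height_sd = 8.9,
                          height_range = c(150, 200),
                          prob_male = 44 / 69,
                          dose_count_probs = c(0.464, 0.246, 0.10, 0.06,
                                               0.04, 0.03, 0.02, 0.012,
                                               0.008, 0.006, 0.005, 0.005,
                                               0.004),
                          dose_amounts = c(1000, 1500),
                          dose_amount_probs = c(0.2, 0.8),
                          samples_mu = 3.2, samples_size = 2,
                          samples_max = 19, samples_range = NULL,
                          peak_fraction = 0.1,
                          trough_window = c(5, 9),
                          lloq = 0.5) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (length(dose_count_probs) != 13L)
    stop("dose_count_probs must give probabilities for 2..14 doses")
  cfg <- as.list(environment())
  cfg$dose_count_probs <- dose_count_probs / sum(dose_count_probs)
  cfg$dose_amount_probs <- dose_amount_probs / sum(dose_amount_probs)
  structure(cfg, class = "cohort_config")
}

rtrunc <- function(n, rfun, lo, hi, ...) {
  x <- rfun(n, ...)
  while (any(bad <- x < lo | x > hi)) x[bad] <- rfun(sum(bad), ...)
  x
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws covariates, individual parameters (via the population model's IIV),
#' a weekly dosing regimen and sparse observation times per subject, then
#' evaluates true concentrations and applies the residual error model.
#' Observations below the LLOQ are flagged BLQ. True individual parameters
#' are retained per subject for recovery tests. Seed the R RNG with
#' `set.seed()` for reproducibility.
#'
#' @param cfg a [cohort_config()].
#' @param m a [population_model()] (default: the published final model).
#' @return An object of class `"pk_cohort"`: a list of subject records, each
#'   with elements `id`, `covariates`, `regimen`, `obs` (data frame with
#'   `time`, `conc`, `blq`) and `truth` (the generating [pk_params()]).
#' @examples
#' set.seed(42)
#' coh <- generate_cohort(cohort_config(n_subjects = 5))
#' summarize_cohort(coh)
#' @export
generate_cohort <- function(cfg = cohort_config(), m = dalbavancin_model()) {
  stopifnot(inherits(cfg, "cohort_config"))
  subjects <- vector("list", cfg$n_subjects)
  for (i in seq_len(cfg$n_subjects)) {
    cov <- list(
      CLcr = rtrunc(1, stats::rlnorm, cfg$clcr_range[1], cfg$clcr_range[2],
                    meanlog = cfg$clcr_meanlog, sdlog = cfg$clcr_sdlog),
      age = rtrunc(1, rnorm, cfg$age_range[1], cfg$age_range[2],
                   mean = cfg$age_median, sd = cfg$age_sd),
      weight = rtrunc(1, rnorm, cfg$weight_range[1], cfg$weight_range[2],
                      mean = cfg$weight_median, sd = cfg$weight_sd),
      height = rtrunc(1, rnorm, cfg$height_range[1], cfg$height_range[2],
                      mean = cfg$height_median, sd = cfg$height_sd),
      sex = if (runif(1) < cfg$prob_male) "M" else "F",
      albumin = rtrunc(1, rnorm, cfg$albumin_range[1], cfg$albumin_range[2],
                       mean = cfg$albumin_median, sd = cfg$albumin_sd))
    cov$serum_creatinine <- NA_real_
    n_dose <- sample(2:14, 1, prob = cfg$dose_count_probs)
    amt <- sample(cfg$dose_amounts, 1, prob = cfg$dose_amount_probs)
    reg <- weekly_regimen(rep(amt, n_dose))
    truth <- sample_individual(m, cov$CLcr)
    n_samp <- if (!is.null(cfg$samples_range))
      sample(cfg$samples_range, 1)
    else min(1 + stats::rnbinom(1, size = cfg$samples_size,
                                mu = cfg$samples_mu), cfg$samples_max)
    # samples taken after the second dose: pick a dose >= 2, then either a
    # trough-like time (uniform days after it) or an early post-infusion peak
    dose_idx <- if (n_dose == 2L) rep(2L, n_samp)
      else sample(2:n_dose, n_samp, replace = TRUE)
    is_peak <- runif(n_samp) < cfg$peak_fraction
    offs <- ifelse(is_peak,
                   runif(n_samp, 0.5 + 0.1, 2),
                   runif(n_samp, cfg$trough_window[1] * 24,
                         cfg$trough_window[2] * 24))
    t_obs <- sort(reg$start_time[dose_idx] + offs)
    true_c <- concentration(truth, reg, t_obs)
    obs_c <- apply_residual_error(true_c, b = m$prop_error_b,
                                  a = m$add_error_a)
    subjects[[i]] <- list(
      id = i, covariates = cov, regimen = reg,
      obs = data.frame(time = t_obs, conc = as.numeric(obs_c),
                       blq = as.numeric(obs_c) < cfg$lloq),
      truth = truth)
  }
  structure(subjects, class = "pk_cohort", lloq = cfg$lloq)
}

#' @export
print.pk_cohort <- function(x, ...) {
  s <- summarize_cohort(x)
  cat(sprintf("Synthetic PK cohort: %d subjects, %d concentrations (%d BLQ)\n",
              s$n_subjects, s$n_observations, s$n_blq))
  invisible(x)
}

#' Summarize a cohort in the style of a demographics table
#'
#' Medians and interquartile ranges of the covariates, dose counts and
#' samples per subject, plus observation totals.
#'
#' @param cohort a `"pk_cohort"` (or list of subject records).
#' @return A list with scalar counts and a data frame `covariates` of
#'   median/IQR summaries.
#' @export
summarize_cohort <- function(cohort) {
  if (length(cohort) == 0L) stop("empty cohort")
  g <- function(f) vapply(cohort, f, numeric(1))
  med_iqr <- function(x) c(median = median(x), q1 = unname(quantile(x, .25)),
                           q3 = unname(quantile(x, .75)))
  covs <- rbind(
    CLcr = med_iqr(g(function(s) s$covariates$CLcr)),
    age = med_iqr(g(function(s) s$covariates$age)),
    weight = med_iqr(g(function(s) s$covariates$weight)),
    albumin = med_iqr(g(function(s) s$covariates$albumin)),
    n_doses = med_iqr(g(function(s) nrow(s$regimen))),
    n_samples = med_iqr(g(function(s) nrow(s$obs))))
  n_obs <- sum(g(function(s) nrow(s$obs)))
  list(n_subjects = length(cohort),
       n_observations = as.integer(n_obs),
       n_blq = as.integer(sum(g(function(s) sum(s$obs$blq)))),
       n_male = sum(g(function(s) s$covariates$sex == "M")),
       covariates = as.data.frame(covs))
}
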