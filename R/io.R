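# Dataset I/O in the pharmacometrics exchange dialect (NONMEM-style rows:
# one row per dose or observation event), plus covariate utilities.

DATASET_COLUMNS <- c("ID", "TIME", "EVID", "AMT", "DUR", "DV", "BLQ",
                     "CLCR", "AGE", "WT", "HT", "SEX", "ALB", "SCR")
REQUIRED_COLUMNS <- c("ID", "TIME", "EVID", "AMT", "DUR", "DV", "CLCR")

#' Read a NONMEM-style analysis dataset
#'
#' One row per event; `EVID = 1` rows are infusion dose events (`AMT` mg over
#' `DUR` h), `EVID = 0` rows are observations (`DV` mg/L). `TIME` is hours
#' since the subject's first dose. Covariates (`CLCR`, and optionally `AGE`,
#' `WT`, `HT`, `SEX`, `ALB`, `SCR`) are carried on every row. Observations
#' with `DV` below the LLOQ are flagged BLQ on read.
#'
#' @param path CSV file path.
#' @param lloq lower limit of quantification (mg/L, default 0.5).
#' @return A validated data frame of class `"pk_dataset"`.
#' @export
read_dataset <- function(path, lloq = 0.5) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(d))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  for (col in c("TIME", "EVID", "AMT", "DUR", "DV", "CLCR")) {
    v <- d[[col]]
    bad <- which(!is.na(v) & !is.finite(suppressWarnings(as.numeric(v))))
    if (length(bad))
      stop(sprintf("non-numeric %s at row(s) %s", col,
                   paste(head(bad, 5), collapse = ", ")))
    d[[col]] <- as.numeric(v)
  }
  if (any(bad <- d$TIME < 0, na.rm = TRUE))
    stop("negative TIME at row(s) ", paste(head(which(bad), 5),
                                           collapse = ", "))
  for (id in unique(d$ID)) {
    tt <- d$TIME[d$ID == id]
    if (is.unsorted(tt))
      stop("times not non-decreasing within subject ", id)
  }
  dose <- d$EVID == 1
  if (any(bad <- dose & (is.na(d$AMT) | d$AMT <= 0)))
    stop("dose rows must have AMT > 0 (row(s) ",
         paste(head(which(bad), 5), collapse = ", "), ")")
  obs <- d$EVID == 0
  if (any(bad <- obs & (is.na(d$DV) | d$DV < 0)))
    stop("observation rows must have DV >= 0 (row(s) ",
         paste(head(which(bad), 5), collapse = ", "), ")")
  d$BLQ <- ifelse(obs, as.integer(d$DV < lloq), 0L)
  structure(d, class = c("pk_dataset", "data.frame"), lloq = lloq)
}

#' Write a cohort (or dataset) to NONMEM-style CSV
#'
#' @param x a `"pk_cohort"` or `"pk_dataset"`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(x, path) {
  d <- if (inherits(x, "pk_cohort")) as_pk_dataset(x) else x
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert between cohort and tabular dataset representations
#'
#' `as_pk_dataset()` flattens a subject-record cohort into the NONMEM-style
#' event table; `as_pk_cohort()` rebuilds subject records (regimen,
#' observations, covariates) from such a table. A `"pk_cohort"` passes
#' through unchanged.
#'
#' @param x a `"pk_cohort"` or `"pk_dataset"`/data frame.
#' @return The converted object.
#' @export
as_pk_dataset <- function(x) {
  stopifnot(inherits(x, "pk_cohort"))
  rows <- lapply(x, function(s) {
    cv <- s$covariates
    base <- data.frame(
      ID = s$id, CLCR = cv$CLcr,
      AGE = cv$age %||% NA_real_, WT = cv$weight %||% NA_real_,
      HT = cv$height %||% NA_real_, SEX = cv$sex %||% NA_character_,
      ALB = cv$albumin %||% NA_real_,
      SCR = cv$serum_creatinine %||% NA_real_)
    dose <- data.frame(TIME = s$regimen$start_time, EVID = 1L,
                       AMT = s$regimen$amount,
                       DUR = s$regimen$infusion_duration,
                       DV = NA_real_, BLQ = 0L)
    ob <- data.frame(TIME = s$obs$time, EVID = 0L, AMT = NA_real_,
                     DUR = NA_real_, DV = s$obs$conc,
                     BLQ = as.integer(s$obs$blq))
    ev <- rbind(dose, ob)
    ev <- ev[order(ev$TIME, -ev$EVID), ]
    cbind(base[rep(1, nrow(ev)), , drop = FALSE], ev)
  })
  d <- do.call(rbind, rows)
  rownames(d) <- NULL
  d <- d[, DATASET_COLUMNS]
  structure(d, class = c("pk_dataset", "data.frame"))
}

#' @rdname as_pk_dataset
#' @export
as_pk_cohort <- function(x) {
  if (inherits(x, "pk_cohort")) return(x)
  stopifnot(is.data.frame(x))
  subs <- lapply(split(x, x$ID), function(d) {
    dose <- d[d$EVID == 1, ]
    ob <- d[d$EVID == 0, ]
    first <- d[1, ]
    list(id = first$ID,
         covariates = list(
           CLcr = first$CLCR, age = first$AGE %||% NA_real_,
           weight = first$WT %||% NA_real_, height = first$HT %||% NA_real_,
           sex = first$SEX %||% NA_character_,
           albumin = first$ALB %||% NA_real_,
           serum_creatinine = first$SCR %||% NA_real_),
         regimen = regimen(dose$AMT, dose$TIME, dose$DUR),
         obs = data.frame(time = ob$TIME, conc = ob$DV,
                          blq = as.logical(ob$BLQ %||%
                                             rep(0L, nrow(ob)))),
         truth = NULL)
  })
  names(subs) <- NULL
  structure(subs, class = "pk_cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Estimated glomerular filtration rate (CKD-EPI 2009)
#'
#' The 2009 CKD-EPI creatinine equation:
#' `eGFR = 141 * min(Scr/k, 1)^a * max(Scr/k, 1)^-1.209 * 0.993^age * 1.018[female]`
#' with `k = 0.7` (female) or `0.9` (male) and `a = -0.329` (female) or
#' `-0.411` (male). The result, in mL/min/1.73 m2, is used as the CLcr
#' covariate.
#'
#' @param serum_creatinine serum creatinine (mg/dL), `> 0`; vectorized.
#' @param age age (years), `> 0`.
#' @param sex `"M"`/`"male"` or `"F"`/`"female"` (vectorized).
#' @return eGFR in mL/min/1.73 m2.
#' @examples
#' ckd_epi(0.7, 50, "F")  # ~ 101
#' ckd_epi(0.9, 60, "M")  # ~ 93
#' @export
ckd_epi <- function(serum_creatinine, age, sex) {
  if (any(serum_creatinine <= 0)) stop("serum creatinine must be positive")
  if (any(age <= 0)) stop("age must be positive")
  female <- toupper(substr(sex, 1, 1)) == "F"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  r <- serum_creatinine / kappa
  141 * pmin(r, 1)^alpha * pmax(r, 1)^-1.209 * 0.993^age *
    ifelse(female, 1.018, 1)
}
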