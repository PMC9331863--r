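# Deterministic concentration-time solutions for linear mammillary models
# with multi-dose IV infusion input. The 2-compartment closed form is the
# fast path; a matrix-exponential solver over the full rate matrix provides
# the general n-compartment path and serves as an internal cross-check.

#' Individual pharmacokinetic parameters
#'
#' Disposition parameters of a linear mammillary model with central-compartment
#' elimination: clearance `CL` (L/h), central volume `V1` (L) and, for models
#' with peripheral compartments, inter-compartmental clearances and peripheral
#' volumes (`Q`/`V2`, and `Q3`/`V3` for a third compartment).
#'
#' @param CL clearance (L/h), `> 0`.
#' @param V1 central volume of distribution (L), `> 0`.
#' @param Q inter-compartmental clearance (L/h), `>= 0`; `Q = 0` collapses the
#'   model to one compartment.
#' @param V2 peripheral volume (L), `> 0` when `Q > 0`.
#' @param Q3,V3 optional third-compartment parameters.
#' @return An object of class `"pk_params"` (named numeric vector).
#' @examples
#' pk_params(CL = 0.043, V1 = 6.14, Q = 0.026, V2 = 9.52)
#' @export
pk_params <- function(CL, V1, Q = 0, V2 = NA, Q3 = NULL, V3 = NULL) {
  p <- c(CL = CL, V1 = V1)
  if (!is.null(Q3)) {
    p <- c(p, Q = Q, V2 = V2, Q3 = Q3, V3 = V3)
  } else if (Q > 0 || !is.na(V2)) {
    p <- c(p, Q = Q, V2 = V2)
  }
  validate_pk_params(p)
  structure(p, class = "pk_params")
}

validate_pk_params <- function(p) {
  if (any(!is.finite(p))) stop("PK parameters must be finite")
  if (p[["CL"]] <= 0 || p[["V1"]] <= 0)
    stop("CL and V1 must be strictly positive")
  if (length(p) >= 4) {
    if (p[["Q"]] < 0) stop("Q must be >= 0")
    if (p[["Q"]] > 0 && p[["V2"]] <= 0) stop("V2 must be > 0 when Q > 0")
  }
  if (length(p) >= 6) {
    if (p[["Q3"]] < 0) stop("Q3 must be >= 0")
    if (p[["Q3"]] > 0 && p[["V3"]] <= 0) stop("V3 must be > 0 when Q3 > 0")
  }
  invisible(p)
}

n_compartments <- function(p) length(p) %/% 2L

#' Micro rate constants of a two-compartment model
#'
#' Converts clearance/volume parameters to first-order rate constants:
#' `k10 = CL/V1`, `k12 = Q/V1`, `k21 = Q/V2` (all 1/h).
#'
#' @param p a [pk_params()] object (or compatible named vector).
#' @return Named numeric vector `c(k10, k12, k21)`; for a one-compartment
#'   model `k12 = k21 = 0`.
#' @export
micro_constants <- function(p) {
  validate_pk_params(p)
  k10 <- p[["CL"]] / p[["V1"]]
  if (length(p) < 4 || p[["Q"]] == 0)
    return(c(k10 = k10, k12 = 0, k21 = 0))
  c(k10 = k10, k12 = p[["Q"]] / p[["V1"]], k21 = p[["Q"]] / p[["V2"]])
}

# strip Q = 0 tails so the C++ layer sees the effective model order
effective_params <- function(p) {
  p <- unclass(p)
  if (length(p) >= 6 && p[["Q3"]] == 0) p <- p[1:4]
  if (length(p) >= 4 && p[["Q"]] == 0) p <- p[1:2]
  p
}

#' Concentration in the central compartment
#'
#' Total (bound + unbound) plasma concentration at the requested times under a
#' multi-dose IV infusion regimen, by superposition of the closed-form
#' constant-rate-infusion solution (during- and post-infusion branches) over
#' dose events. Times before the first dose return 0.
#'
#' @param p a [pk_params()] object.
#' @param reg a [regimen()].
#' @param times numeric vector of times (h since first dose), non-decreasing.
#' @return Numeric vector of concentrations (mg/L), same length as `times`.
#' @examples
#' p <- pk_params(CL = 0.043, V1 = 6.14, Q = 0.026, V2 = 9.52)
#' concentration(p, weekly_regimen(c(1500, 1500)), c(336, 672, 1008))
#' @export
concentration <- function(p, reg, times) {
  validate_pk_params(p)
  if (length(times) < 1L) stop("empty time grid")
  if (any(!is.finite(times)) || any(times < 0))
    stop("times must be finite and >= 0")
  if (is.unsorted(times)) stop("time grid must be non-decreasing")
  pe <- effective_params(p)
  cpp_conc(as.numeric(pe), n_compartments(pe), reg$amount, reg$start_time,
           reg$infusion_duration, as.numeric(times))
}

#' @rdname concentration
#' @export
concentration_profile <- concentration

#' Concentration via the matrix-exponential path
#'
#' General solver for any linear mammillary model: propagates compartment
#' amounts across the piecewise-constant infusion schedule with the matrix
#' exponential of the full rate matrix. Slower than [concentration()] but
#' dimension-agnostic; the two paths validate each other.
#'
#' @inheritParams concentration
#' @return Numeric vector of concentrations (mg/L).
#' @export
concentration_matexp <- function(p, reg, times) {
  validate_pk_params(p)
  if (length(times) < 1L) stop("empty time grid")
  if (is.unsorted(times)) stop("time grid must be non-decreasing")
  pe <- effective_params(p)
  ncmt <- n_compartments(pe)
  A <- rate_matrix(pe)
  # breakpoints: infusion starts/ends, piecewise-constant input rate
  brk <- sort(unique(c(0, reg$start_time,
                       reg$start_time + reg$infusion_duration)))
  out <- numeric(length(times))
  x <- numeric(ncmt)
  t_cur <- 0
  ti <- 1L
  segs <- c(brk, Inf)
  for (si in seq_len(length(segs) - 1L)) {
    t0 <- segs[si]; t1 <- segs[si + 1L]
    rate <- sum(reg$amount[reg$start_time <= t0 &
                             t0 < reg$start_time + reg$infusion_duration] /
                  reg$infusion_duration[reg$start_time <= t0 &
                             t0 < reg$start_time + reg$infusion_duration])
    b <- c(rate, numeric(ncmt - 1L))
    step <- function(x, h) {
      E <- as.matrix(Matrix::expm(A * h))
      drop(E %*% x + if (rate > 0) solve(A, (E - diag(ncmt)) %*% b)
           else numeric(ncmt))
    }
    while (ti <= length(times) && times[ti] <= t1) {
      out[ti] <- step(x, times[ti] - t0)[1L] / p[["V1"]]
      ti <- ti + 1L
    }
    if (ti > length(times)) break
    if (is.finite(t1)) x <- step(x, t1 - t0)
  }
  out
}

rate_matrix <- function(p) {
  k <- micro_constants(p)
  ncmt <- n_compartments(p)
  if (ncmt == 1L) return(matrix(-k[["k10"]], 1, 1))
  if (ncmt == 2L)
    return(matrix(c(-(k[["k10"]] + k[["k12"]]), k[["k12"]],
                    k[["k21"]], -k[["k21"]]), 2, 2))
  k13 <- p[["Q3"]] / p[["V1"]]; k31 <- p[["Q3"]] / p[["V3"]]
  matrix(c(-(k[["k10"]] + k[["k12"]] + k13), k[["k12"]], k13,
           k[["k21"]], -k[["k21"]], 0,
           k31, 0, -k31), 3, 3)
}

#' Terminal half-life
#'
#' Half-life of the slowest disposition phase, `ln(2)/lambda_z` where
#' `lambda_z` is the smallest eigenvalue magnitude of the disposition matrix.
#' For a one-compartment model this is `ln(2) * V1 / CL`.
#'
#' @param p a [pk_params()] object.
#' @return Terminal half-life in hours.
#' @examples
#' terminal_half_life(pk_params(CL = 0.043, V1 = 6.14, Q = 0.026, V2 = 9.52))
#' @export
terminal_half_life <- function(p) {
  validate_pk_params(p)
  pe <- effective_params(p)
  lam <- cpp_disposition_rates(as.numeric(pe), n_compartments(pe))
  log(2) / min(lam)
}

#' Total area under the concentration-time curve
#'
#' For linear kinetics the AUC from zero to infinity equals total administered
#' dose divided by clearance, independent of the schedule.
#'
#' @param p a [pk_params()] object.
#' @param reg a [regimen()].
#' @return AUC to infinity (mg*h/L).
#' @export
auc_to_infinity <- function(p, reg) {
  validate_pk_params(p)
  total_dose(reg) / p[["CL"]]
}
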