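# Independent numerical oracle: integrate the compartment-amount ODE system
# segment-by-segment with deSolve (piecewise-constant infusion input) and
# return central concentrations. Kept free of the package's closed-form and
# matrix-exponential code paths.
ode_conc <- function(p, reg, times) {
  k10 <- p[["CL"]] / p[["V1"]]
  ncmt <- length(p) %/% 2
  if (ncmt >= 2 && p[["Q"]] > 0) {
    k12 <- p[["Q"]] / p[["V1"]]; k21 <- p[["Q"]] / p[["V2"]]
  } else { k12 <- k21 <- 0; ncmt <- max(ncmt, 1) }
  k13 <- if (ncmt >= 3 && p[["Q3"]] > 0) p[["Q3"]] / p[["V1"]] else 0
  k31 <- if (k13 > 0) p[["Q3"]] / p[["V3"]] else 0
  nstate <- if (k13 > 0) 3 else if (k12 > 0) 2 else 1
  derivs <- function(t, A, parms) {
    r <- parms$rate
    d1 <- r - (k10 + k12 + k13) * A[1] +
      (if (nstate >= 2) k21 * A[2] else 0) +
      (if (nstate >= 3) k31 * A[3] else 0)
    d <- c(d1,
           if (nstate >= 2) k12 * A[1] - k21 * A[2],
           if (nstate >= 3) k13 * A[1] - k31 * A[3])
    list(d)
  }
  brk <- sort(unique(c(0, reg$start_time,
                       reg$start_time + reg$infusion_duration, times)))
  A <- numeric(nstate)
  out <- numeric(length(times))
  for (i in seq_len(length(brk) - 1)) {
    t0 <- brk[i]; t1 <- brk[i + 1]
    active <- reg$start_time <= t0 & t0 < reg$start_time +
      reg$infusion_duration
    rate <- sum(reg$amount[active] / reg$infusion_duration[active])
    sol <- deSolve::lsoda(A, c(t0, t1), derivs, parms = list(rate = rate),
                          rtol = 1e-11, atol = 1e-13)
    A <- as.numeric(sol[nrow(sol), -1])
    hit <- which(abs(times - t1) < 1e-12)
    out[hit] <- A[1] / p[["V1"]]
  }
  out[times == 0] <- 0
  out
}

# random plausible two-compartment parameter draws for property tests
random_pk_params <- function() {
  pk_params(CL = exp(runif(1, log(0.01), log(0.2))),
            V1 = exp(runif(1, log(3), log(20))),
            Q = exp(runif(1, log(0.005), log(0.1))),
            V2 = exp(runif(1, log(3), log(30))))
}

# hand-built cohort with a fixed design (no generator involvement):
# n subjects, common regimen and sampling times, parameters drawn from m
make_design_cohort <- function(n, m, reg, times, clcr = NULL,
                               residual = TRUE) {
  subjects <- lapply(seq_len(n), function(i) {
    cl <- if (is.null(clcr)) runif(1, 40, 130) else clcr[i]
    p <- sample_individual(m, cl)
    tc <- concentration(p, reg, times)
    oc <- if (residual)
      as.numeric(apply_residual_error(tc, b = m$prop_error_b,
                                      a = m$add_error_a))
    else tc
    list(id = i, covariates = list(CLcr = cl), regimen = reg,
         obs = data.frame(time = times, conc = oc, blq = FALSE),
         truth = p)
  })
  structure(subjects, class = "pk_cohort")
}

table2_typical <- function(clcr = 93) {
  m <- dalbavancin_model()
  pk_params(CL = typical_clearance(m, clcr), V1 = m$theta[["V1"]],
            Q = m$theta[["Q"]], V2 = m$theta[["V2"]])
}
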