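# Nonlinear mixed-effects estimation: marginal likelihood (Laplace
# approximation, with an importance-sampling cross-check), population fitting,
# model-selection utilities, covariate screening and MAP individual
# (empirical-Bayes) estimation.

param_names <- function(ncmt) {
  switch(ncmt, c("CL", "V1"), c("CL", "V1", "Q", "V2"),
         c("CL", "V1", "Q", "V2", "Q3", "V3"))
}

# internal: convert a cohort to the flat per-subject lists the C++ layer
# expects, dropping BLQ observations (M1) and subjects with no usable data
prepare_subjects <- function(cohort, drop_blq = TRUE) {
  subs <- lapply(cohort, function(s) {
    keep <- if (drop_blq) !s$obs$blq else rep(TRUE, nrow(s$obs))
    list(id = s$id, clcr = s$covariates$CLcr,
         amt = s$regimen$amount, start = s$regimen$start_time,
         dur = s$regimen$infusion_duration,
         time = s$obs$time[keep], conc = s$obs$conc[keep])
  })
  usable <- vapply(subs, function(s) length(s$time) > 0L, logical(1))
  if (!all(usable))
    warning(sprintf("%d subject(s) with no usable observations excluded",
                    sum(!usable)))
  if (!any(usable)) stop("no subjects with usable observations")
  subs[usable]
}

# typical-value matrix (n_subj x npar) under the exponential CLcr model
typical_matrix <- function(theta, beta, clcr, ncmt) {
  pn <- param_names(ncmt)
  typ <- matrix(rep(theta[pn], each = length(clcr)), nrow = length(clcr),
                dimnames = list(NULL, pn))
  typ[, "CL"] <- theta[["CL"]] * exp(beta * clcr)
  typ
}

#' Marginal -2 log-likelihood of a population model
#'
#' Integrates the subject-level random effects out of the likelihood, either
#' by the Laplace approximation at the posterior mode of each subject's
#' random effects (default; deterministic) or by importance sampling with a
#' Gaussian proposal centred at that mode.
#'
#' @param m a [population_model()].
#' @param cohort a `"pk_cohort"` (see [generate_cohort()]) or NONMEM-style
#'   data frame (see [read_dataset()]). BLQ observations are dropped.
#' @param method `"laplace"` or `"importance"`.
#' @param n_is number of importance-sampling draws per subject.
#' @return The -2 log-likelihood (scalar), with attribute `"per_subject"`.
#' @export
marginal_loglik <- function(m, cohort, method = c("laplace", "importance"),
                            n_is = 1000) {
  method <- match.arg(method)
  cohort <- as_pk_cohort(cohort)
  subs <- prepare_subjects(cohort)
  theta <- m$theta
  typ <- typical_matrix(c(theta), m$beta_CLcr_CL,
                        vapply(subs, `[[`, numeric(1), "clcr"), 2L)
  omega <- as.numeric(m$omega)
  if (method == "laplace") {
    r <- cpp_m2ll(typ, omega, m$add_error_a, m$prop_error_b, subs, 2L,
                  matrix(0, length(subs), 4L))
    out <- r$m2ll
    attr(out, "per_subject") <- r$per_subject
    attr(out, "eta") <- r$eta
    return(out)
  }
  per <- vapply(seq_along(subs), function(i)
    is_m2ll_subject(typ[i, ], omega, m$add_error_a, m$prop_error_b,
                    subs[[i]], n_is), numeric(1))
  out <- sum(per)
  attr(out, "per_subject") <- per
  out
}

# subject-level -log p(y | individual params), combined error model
subject_nll <- function(ind, sub, a, b, ncmt = 2L) {
  if (any(!is.finite(ind)) || any(ind[1:2] <= 0)) return(1e10)
  f <- cpp_conc(as.numeric(ind), ncmt, sub$amt, sub$start, sub$dur, sub$time)
  sdv <- sqrt(a^2 + (b * f)^2)
  if (any(sdv <= 0) || any(!is.finite(sdv))) return(1e10)
  -sum(dnorm(sub$conc, f, sdv, log = TRUE))
}

# importance sampling with proposal N(eta_hat, H^-1) from the Laplace step
is_m2ll_subject <- function(typ, omega, a, b, sub, n_is) {
  free <- which(omega > 0)
  d <- length(free)
  h <- function(ef) {
    eta <- numeric(length(omega)); eta[free] <- ef
    subject_nll(typ * exp(eta), sub, a, b) +
      sum(0.5 * log(2 * pi) + log(omega[free]) +
            0.5 * ef^2 / omega[free]^2)
  }
  if (d == 0) return(2 * h(numeric(0)))
  opt <- optim(numeric(d), h, method = "BFGS")
  H <- optimHess(opt$par, h)
  Sig <- tryCatch(solve(H), error = function(e) diag(d) * 0.25)
  L <- tryCatch(chol(Sig), error = function(e) diag(sqrt(pmax(diag(Sig),
                                                              1e-4))))
  Z <- matrix(rnorm(n_is * d), n_is, d)
  E <- Z %*% L + matrix(opt$par, n_is, d, byrow = TRUE)
  log_q <- -0.5 * d * log(2 * pi) - 0.5 * determinant(Sig)$modulus -
    0.5 * rowSums((Z %*% L) %*% H * (Z %*% L))
  log_p <- -apply(E, 1, h)
  w <- log_p - log_q
  mx <- max(w)
  -2 * (mx + log(mean(exp(w - mx))))
}

#' Bayesian information criterion from an objective function value
#'
#' `BIC = OFV + k * log(n)` where OFV is -2 log-likelihood, `k` the number of
#' estimated parameters and `n` the number of observations.
#'
#' @param ofv objective function value (-2 log-likelihood).
#' @param n_params number of estimated parameters.
#' @param n_obs number of observations (`>= 1`).
#' @return The BIC (scalar).
#' @export
bic <- function(ofv, n_params, n_obs) {
  if (n_obs < 1) stop("n_obs must be >= 1")
  ofv + n_params * log(n_obs)
}

#' Likelihood-ratio test for nested models
#'
#' Chi-square upper-tail probability of the OFV drop between a reduced and a
#' full (nested) model.
#'
#' @param ofv_reduced,ofv_full objective function values (-2 log-likelihood);
#'   `ofv_reduced >= ofv_full` for a proper comparison (warned otherwise).
#' @param df degrees of freedom (number of additional parameters), `>= 1`.
#' @return The p-value.
#' @export
lrt <- function(ofv_reduced, ofv_full, df = 1) {
  if (df < 1) stop("df must be >= 1")
  if (ofv_reduced < ofv_full)
    warning("reduced model has lower OFV than full model")
  pchisq(max(ofv_reduced - ofv_full, 0), df = df, lower.tail = FALSE)
}

default_init <- function(ncmt, covariate) {
  th <- switch(ncmt,
               c(CL = 0.041, V1 = 15),
               c(CL = 0.041, V1 = 6.15, Q = 0.026, V2 = 10.51),
               c(CL = 0.041, V1 = 6.15, Q = 0.02, V2 = 8, Q3 = 0.01, V3 = 3))
  list(theta = th,
       beta = if (covariate) 0.002 else NULL,
       omega = setNames(rep(0.3, length(th)),
                        paste0("omega_", names(th))),
       b = 0.3)
}

#' Fit a population pharmacokinetic model by maximum likelihood
#'
#' Maximizes the Laplace-approximate marginal likelihood over the typical
#' values, the optional CLcr-on-clearance exponential covariate coefficient,
#' the diagonal log-normal IIV magnitudes and the residual error, for a 1-,
#' 2- or 3-compartment disposition model with IV infusion input.
#'
#' Parameters are estimated on the log scale (the covariate coefficient on
#' the natural scale); relative standard errors are obtained from the
#' observed information matrix at the optimum. IIV magnitudes are bounded
#' below at 0.001; an estimate at the bound is reported as such.
#'
#' @param cohort a `"pk_cohort"` or NONMEM-style data frame; BLQ
#'   observations are excluded (M1 method).
#' @param n_compartments 1, 2 or 3.
#' @param covariate `"CLcr"` to estimate the exponential CLcr effect on
#'   clearance, or `NULL` for no covariate.
#' @param error_model `"proportional"` (default), `"additive"` or
#'   `"combined"`.
#' @param init optional named list with elements `theta` (named vector),
#'   `beta`, `omega` (named vector), `b`, `a` overriding the defaults.
#' @param fix character vector of parameter names (e.g. `"omega_Q"`, `"b"`)
#'   held fixed at their initial values.
#' @param control list passed to [stats::optim()] (method `"L-BFGS-B"`).
#' @return An object of class `"popfit"` with methods `print`, `summary`,
#'   `coef`, `logLik`, `predict`, `residuals`, `plot` and `simulate`.
#' @examples
#' \donttest{
#' set.seed(7)
#' coh <- generate_cohort(cohort_config(n_subjects = 25))
#' fit <- fit_population(coh, covariate = "CLcr")
#' summary(fit)
#' }
#' @export
fit_population <- function(cohort, n_compartments = 2, covariate = "CLcr",
                           error_model = c("proportional", "additive",
                                           "combined"),
                           init = NULL, fix = character(),
                           control = list(maxit = 300, factr = 1e8)) {
  error_model <- match.arg(error_model)
  ncmt <- as.integer(n_compartments)
  if (!ncmt %in% 1:3) stop("n_compartments must be 1, 2 or 3")
  has_cov <- !is.null(covariate)
  cohort <- as_pk_cohort(cohort)
  subs <- prepare_subjects(cohort)
  clcr <- vapply(subs, `[[`, numeric(1), "clcr")
  n_obs <- sum(vapply(subs, function(s) length(s$time), integer(1)))
  if (n_obs < 2) stop("need at least two observations")

  ini <- default_init(ncmt, has_cov)
  if (!is.null(init)) {
    if (!is.null(init$theta)) ini$theta[names(init$theta)] <- init$theta
    if (!is.null(init$beta)) ini$beta <- init$beta
    if (!is.null(init$omega)) ini$omega[names(init$omega)] <- init$omega
    if (!is.null(init$b)) ini$b <- init$b
    if (!is.null(init$a)) ini$a <- init$a
  }
  pn <- param_names(ncmt)
  use_b <- error_model %in% c("proportional", "combined")
  use_a <- error_model %in% c("additive", "combined")
  if (use_a && is.null(ini$a)) ini$a <- 1

  # assemble the transformed parameter vector: log(theta), beta,
  # log(omega), log(error sds)
  full <- c(setNames(log(ini$theta), paste0("theta_", pn)),
            if (has_cov) c(beta_CLcr_CL = ini$beta),
            log(ini$omega),
            if (use_b) c(b = log(ini$b)),
            if (use_a) c(a = log(ini$a)))
  is_log <- setNames(!grepl("^beta", names(full)), names(full))
  bad_fix <- setdiff(fix, names(full))
  if (length(bad_fix)) stop("unknown parameters in fix: ",
                            paste(bad_fix, collapse = ", "))
  est_idx <- setdiff(names(full), fix)
  lower <- setNames(rep(-Inf, length(full)), names(full))
  lower[grep("^omega", names(full))] <- log(1e-3)
  lower[names(full) == "b"] <- log(0.005)
  lower[names(full) == "a"] <- log(1e-3)

  eta0 <- matrix(0, length(subs), length(pn))
  # the covariate is centred at the cohort median during estimation (the
  # uncentred intercept is an extrapolation to CLcr = 0 and sits on a flat
  # ridge with beta); the reported theta_CL is back-transformed afterwards
  clcr_ref <- if (has_cov && !any(c("theta_CL", "beta_CLcr_CL") %in% fix))
    median(clcr) else 0
  if (clcr_ref > 0)
    full[["theta_CL"]] <- full[["theta_CL"]] + ini$beta * clcr_ref
  unpack <- function(par_est) {
    full[est_idx] <- par_est
    theta <- exp(full[paste0("theta_", pn)]); names(theta) <- pn
    list(theta = theta,
         beta = if (has_cov) unname(full[["beta_CLcr_CL"]]) else 0,
         omega = exp(full[paste0("omega_", pn)]),
         b = if (use_b) exp(full[["b"]]) else 0,
         a = if (use_a) exp(full[["a"]]) else 0)
  }
  # inner random-effect modes are re-found from zero on every call so the
  # objective is a deterministic function of the parameters (finite-difference
  # gradients would otherwise see warm-start state)
  objective <- function(par_est) {
    p <- unpack(par_est)
    typ <- typical_matrix(p$theta, p$beta, clcr - clcr_ref, ncmt)
    r <- cpp_m2ll(typ, as.numeric(p$omega), p$a, p$b, subs, ncmt, eta0)
    if (!is.finite(r$m2ll)) 1e10 else r$m2ll
  }
  # the covariate coefficient lives on a much smaller natural scale than the
  # log-transformed parameters; scale it so finite-difference steps are sane
  if (is.null(control$parscale)) {
    ps <- rep(1, length(est_idx))
    ps[est_idx == "beta_CLcr_CL"] <- 0.01
    control$parscale <- ps
  }
  opt <- optim(full[est_idx], objective, method = "L-BFGS-B",
               lower = lower[est_idx], control = control)
  opt$par <- setNames(opt$par, est_idx)
  p <- unpack(opt$par)
  typ <- typical_matrix(p$theta, p$beta, clcr - clcr_ref, ncmt)
  final <- cpp_m2ll(typ, as.numeric(p$omega), p$a, p$b, subs, ncmt, eta0)
  if (clcr_ref > 0)
    p$theta[["CL"]] <- p$theta[["CL"]] * exp(-p$beta * clcr_ref)

  # observed-information standard errors on the estimation scale
  se <- setNames(rep(NA_real_, length(opt$par)), est_idx)
  H <- tryCatch(optimHess(opt$par, objective,
                          control = list(parscale = control$parscale)),
                error = function(e) NULL)
  vcov_est <- NULL
  if (!is.null(H)) {
    vcov_est <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(vcov_est)) {
      dimnames(vcov_est) <- list(est_idx, est_idx)
      dg <- diag(vcov_est)
      se[dg > 0] <- sqrt(dg[dg > 0])
    }
  }
  natural <- ifelse(is_log[est_idx], exp(opt$par), opt$par)
  # undo the covariate centring for the reported clearance intercept:
  # log(theta_CL) = log(theta_CL_at_ref) - beta * clcr_ref
  if (clcr_ref > 0 && all(c("theta_CL", "beta_CLcr_CL") %in% est_idx)) {
    natural[["theta_CL"]] <-
      exp(opt$par[["theta_CL"]] - p$beta * clcr_ref)
    if (!is.null(vcov_est)) {
      v <- vcov_est["theta_CL", "theta_CL"] +
        clcr_ref^2 * vcov_est["beta_CLcr_CL", "beta_CLcr_CL"] -
        2 * clcr_ref * vcov_est["theta_CL", "beta_CLcr_CL"]
      se[["theta_CL"]] <- if (v > 0) sqrt(v) else NA_real_
    }
  }
  # on the log scale SE approximates the CV of the estimate, so RSE% is
  # 100*SE; for the covariate coefficient use 100*SE/|estimate|
  rse <- ifelse(is_log[est_idx], 100 * se, 100 * se / abs(natural))
  estimates <- data.frame(parameter = est_idx, estimate = unname(natural),
                          rse_percent = unname(rse))
  fixed <- setNames(ifelse(is_log[fix], exp(full[fix]), full[fix]), fix)

  n_params <- length(est_idx)
  eta <- final$eta
  colnames(eta) <- pn
  model <- if (ncmt == 2L)
    population_model(theta_CL = p$theta[["CL"]], theta_V1 = p$theta[["V1"]],
                     theta_Q = p$theta[["Q"]], theta_V2 = p$theta[["V2"]],
                     beta_CLcr_CL = p$beta,
                     omega_CL = p$omega[[1]], omega_V1 = p$omega[[2]],
                     omega_Q = p$omega[[3]], omega_V2 = p$omega[[4]],
                     prop_error_b = min(p$b, 0.999), add_error_a = p$a)
  out <- list(theta = p$theta, beta_CLcr_CL = if (has_cov) p$beta else NULL,
              omega = p$omega, b = p$b, a = p$a,
              model = model, estimates = estimates, fixed = fixed,
              ofv = final$m2ll, bic = bic(final$m2ll, n_params, n_obs),
              n_params = n_params, n_obs = n_obs, n_subjects = length(subs),
              n_compartments = ncmt, error_model = error_model,
              covariate = if (has_cov) "CLcr" else NULL,
              eta = eta, subjects = subs,
              omega_at_bound = names(p$omega)[p$omega <= 1.05e-3],
              converged = opt$convergence == 0,
              message = opt$message, call = match.call())
  class(out) <- "popfit"
  if (!out$converged)
    warning("optimizer did not report convergence: ", opt$message)
  out
}

#' @export
print.popfit <- function(x, ...) {
  cat(sprintf("Population PK fit: %d-compartment, %s error%s\n",
              x$n_compartments, x$error_model,
              if (!is.null(x$covariate))
                paste0(", CLcr on CL (exponential)") else ""))
  cat(sprintf("  %d subjects, %d observations\n", x$n_subjects, x$n_obs))
  cat(sprintf("  OFV %.2f, BIC %.2f (%d parameters)%s\n", x$ofv, x$bic,
              x$n_params,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(x$estimates, row.names = FALSE, digits = 4)
  if (length(x$omega_at_bound))
    cat("  IIV at lower bound:", paste(x$omega_at_bound, collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
summary.popfit <- function(object, ...) {
  est <- object$estimates
  est$iiv_cv_percent <- ifelse(grepl("^omega", est$parameter),
                               100 * est$estimate, NA_real_)
  structure(list(estimates = est, ofv = object$ofv, bic = object$bic,
                 n_obs = object$n_obs, n_subjects = object$n_subjects,
                 converged = object$converged),
            class = "summary.popfit")
}

#' @export
print.summary.popfit <- function(x, ...) {
  cat(sprintf("Parameter estimates (%d subjects, %d observations)\n",
              x$n_subjects, x$n_obs))
  print(x$estimates, row.names = FALSE, digits = 4)
  cat(sprintf("OFV %.2f  BIC %.2f  converged: %s\n", x$ofv, x$bic,
              x$converged))
  invisible(x)
}

#' @export
coef.popfit <- function(object, ...) {
  setNames(object$estimates$estimate, object$estimates$parameter)
}

#' @export
logLik.popfit <- function(object, ...) {
  structure(-object$ofv / 2, df = object$n_params, nobs = object$n_obs,
            class = "logLik")
}

#' Predictions from a population fit
#'
#' Population predictions use each subject's covariate-adjusted typical
#' values (random effects at zero); individual predictions use the
#' empirical-Bayes random-effect modes from the fit.
#'
#' @param object a `"popfit"`.
#' @param type `"individual"` (default) or `"population"`.
#' @param ... unused.
#' @return Data frame with `id`, `time`, `observed`, `predicted`.
#' @export
predict.popfit <- function(object, type = c("individual", "population"),
                           ...) {
  type <- match.arg(type)
  pn <- param_names(object$n_compartments)
  beta <- if (is.null(object$beta_CLcr_CL)) 0 else object$beta_CLcr_CL
  rows <- lapply(seq_along(object$subjects), function(i) {
    s <- object$subjects[[i]]
    typ <- c(typical_matrix(object$theta, beta, s$clcr,
                            object$n_compartments))
    ind <- if (type == "individual") typ * exp(object$eta[i, ]) else typ
    f <- cpp_conc(ind, object$n_compartments, s$amt, s$start, s$dur, s$time)
    data.frame(id = s$id, time = s$time, observed = s$conc, predicted = f)
  })
  do.call(rbind, rows)
}

#' @export
residuals.popfit <- function(object, type = c("individual", "population"),
                             ...) {
  pr <- predict(object, type = match.arg(type))
  sdv <- sqrt(object$a^2 + (object$b * pr$predicted)^2)
  (pr$observed - pr$predicted) / sdv
}

#' @export
plot.popfit <- function(x, ...) {
  pr <- predict(x, type = "individual")
  g <- gof_regression(pr$observed, pr$predicted)
  plot(pr$predicted, pr$observed,
       xlab = "Individual-predicted concentration (mg/L)",
       ylab = "Observed concentration (mg/L)", ...)
  abline(0, 1, lty = 2)
  abline(g$intercept, g$slope)
  legend("topleft", bty = "n",
         legend = sprintf("R² = %.2f, slope = %.2f", g$r_squared,
                          g$slope))
  invisible(x)
}

#' Simulate replicate datasets from a fitted model
#'
#' Draws new random effects and residual errors at the original design
#' (same subjects, regimens, covariates and sampling times).
#'
#' @param object a `"popfit"` (2-compartment fits only).
#' @param nsim number of replicate datasets.
#' @param seed optional seed passed to [set.seed()].
#' @param ... unused.
#' @return A list of `nsim` `"pk_cohort"` objects.
#' @export
simulate.popfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(object$model))
    stop("simulate() requires a 2-compartment fit")
  design <- popfit_design(object)
  replicate(nsim, simulate_design(object$model, design), simplify = FALSE)
}

popfit_design <- function(object) {
  lapply(object$subjects, function(s)
    list(id = s$id, clcr = s$clcr,
         regimen = regimen(s$amt, s$start, s$dur), times = s$time))
}

# one simulated replicate of a design under model m (IIV + residual error)
simulate_design <- function(m, design) {
  subjects <- lapply(design, function(d) {
    p <- sample_individual(m, d$clcr)
    tc <- concentration(p, d$regimen, d$times)
    oc <- apply_residual_error(tc, b = m$prop_error_b, a = m$add_error_a)
    list(id = d$id, covariates = list(CLcr = d$clcr), regimen = d$regimen,
         obs = data.frame(time = d$times, conc = as.numeric(oc),
                          blq = FALSE),
         truth = p)
  })
  structure(subjects, class = "pk_cohort")
}

#' Screen covariates against empirical-Bayes random effects
#'
#' Pearson correlation (point-biserial for binary covariates) of each
#' random-effect vector from a fit against each covariate; pairs with
#' p < `alpha` are proposed for formal likelihood-ratio inclusion.
#'
#' @param fit a `"popfit"`.
#' @param covariates data frame of per-subject covariates (one row per
#'   subject in the fit, in fit order).
#' @param alpha significance level for flagging (default 0.05).
#' @return An object of class `"covariate_screen"`: data frame with columns
#'   `parameter`, `covariate`, `r`, `p_value`, `selected`.
#' @export
screen_covariates <- function(fit, covariates, alpha = 0.05) {
  if (fit$n_subjects < 3) stop("need at least 3 subjects")
  if (nrow(covariates) != fit$n_subjects)
    stop("covariates must have one row per fitted subject")
  usable <- vapply(colnames(covariates), function(cv) {
    x <- covariates[[cv]]
    if (is.character(x) || is.factor(x)) x <- as.numeric(factor(x))
    if (length(unique(x[is.finite(x)])) < 2) {
      warning("covariate ", cv, " is constant; skipped")
      return(FALSE)
    }
    TRUE
  }, logical(1))
  rows <- list()
  for (p in colnames(fit$eta)) {
    eta <- fit$eta[, p]
    if (sd(eta) == 0) next  # no IIV estimated for this parameter
    for (cv in colnames(covariates)[usable]) {
      x <- covariates[[cv]]
      if (is.character(x) || is.factor(x)) x <- as.numeric(factor(x))
      ok <- is.finite(x)
      ct <- cor.test(eta[ok], x[ok])
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = p, covariate = cv, r = unname(ct$estimate),
        p_value = ct$p.value)
    }
  }
  out <- do.call(rbind, rows)
  out$selected <- out$p_value < alpha
  class(out) <- c("covariate_screen", "data.frame")
  out
}

#' MAP (empirical-Bayes) individual parameter estimation
#'
#' Maximizes the posterior of a subject's random effects given their
#' observations, combining the population prior with the residual-error
#' likelihood. With no usable observations the typical values are returned
#' with all random effects at zero.
#'
#' @param m a [population_model()].
#' @param subject a subject record (list with `covariates`, `regimen`,
#'   `obs`), e.g. one element of a `"pk_cohort"`.
#' @return A [pk_params()] with attribute `"eta"`.
#' @export
map_estimate <- function(m, subject) {
  keep <- !subject$obs$blq
  typ <- typical_params(m, subject$covariates$CLcr)
  if (!any(keep)) {
    p <- pk_params(typ[["CL"]], typ[["V1"]], typ[["Q"]], typ[["V2"]])
    attr(p, "eta") <- setNames(numeric(4), names(m$omega))
    return(p)
  }
  sub <- list(amt = subject$regimen$amount,
              start = subject$regimen$start_time,
              dur = subject$regimen$infusion_duration,
              time = subject$obs$time[keep], conc = subject$obs$conc[keep])
  r <- cpp_m2ll(matrix(typ, 1), as.numeric(m$omega), m$add_error_a,
                m$prop_error_b, list(sub), 2L, matrix(0, 1, 4))
  eta <- drop(r$eta)
  ind <- typ * exp(eta)
  p <- pk_params(ind[["CL"]], ind[["V1"]], ind[["Q"]], ind[["V2"]])
  attr(p, "eta") <- setNames(eta, names(m$omega))
  p
}
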