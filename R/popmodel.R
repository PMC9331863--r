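# Population layer: typical values, the creatinine-clearance covariate model
# on clearance, log-normal inter-individual variability and the residual
# error model.

#' Construct a population pharmacokinetic model
#'
#' Describes the population distribution of two-compartment disposition
#' parameters: typical values, a creatinine-clearance (CLcr) covariate effect
#' on clearance, diagonal log-normal inter-individual variability (IIV) and a
#' proportional (optionally combined) residual error.
#'
#' The covariate model on clearance is, by default, the uncentred exponential
#' form `CL = theta_CL * exp(beta * CLcr)`; a centred power form
#' `CL = theta_CL * (CLcr/ref)^beta` is available via `covariate_form`.
#' IIV magnitudes `omega_*` are log-scale standard deviations (reported in
#' the field as approximately 100*omega %CV).
#'
#' @param theta_CL typical clearance at covariate baseline (L/h).
#' @param theta_V1 typical central volume (L).
#' @param theta_Q typical inter-compartmental clearance (L/h).
#' @param theta_V2 typical peripheral volume (L).
#' @param beta_CLcr_CL covariate coefficient of CLcr on CL (per mL/min/1.73m2);
#'   0 disables the covariate effect.
#' @param omega_CL,omega_V1,omega_Q,omega_V2 IIV standard deviations
#'   (log scale, dimensionless), all `>= 0`.
#' @param prop_error_b proportional residual error SD (fraction, `0 <= b < 1`).
#' @param add_error_a additive residual error SD (mg/L, default 0: purely
#'   proportional error).
#' @param covariate_form `"exponential"` (default) or `"power"`.
#' @param covariate_reference centering value for the power form
#'   (mL/min/1.73m2); ignored by the exponential form.
#' @return An object of class `"population_model"`.
#' @seealso [dalbavancin_model()] for the published parameter sets.
#' @export
population_model <- function(theta_CL, theta_V1, theta_Q, theta_V2,
                             beta_CLcr_CL = 0,
                             omega_CL = 0, omega_V1 = 0, omega_Q = 0,
                             omega_V2 = 0,
                             prop_error_b = 0, add_error_a = 0,
                             covariate_form = c("exponential", "power"),
                             covariate_reference = NA_real_) {
  covariate_form <- match.arg(covariate_form)
  theta <- c(CL = theta_CL, V1 = theta_V1, Q = theta_Q, V2 = theta_V2)
  omega <- c(CL = omega_CL, V1 = omega_V1, Q = omega_Q, V2 = omega_V2)
  if (any(theta[c("CL", "V1", "V2")] <= 0) || theta[["Q"]] < 0)
    stop("typical values must be positive (Q may be 0)")
  if (any(omega < 0)) stop("IIV magnitudes must be >= 0")
  if (prop_error_b < 0 || prop_error_b >= 1)
    stop("proportional error b must satisfy 0 <= b < 1")
  if (add_error_a < 0) stop("additive error a must be >= 0")
  if (covariate_form == "power" && beta_CLcr_CL != 0 &&
      !is.finite(covariate_reference))
    stop("the power covariate form needs a finite covariate_reference")
  structure(list(theta = theta, beta_CLcr_CL = beta_CLcr_CL, omega = omega,
                 prop_error_b = prop_error_b, add_error_a = add_error_a,
                 covariate_form = covariate_form,
                 covariate_reference = covariate_reference),
            class = "population_model")
}

#' Published dalbavancin population models
#'
#' The final model carries the CLcr covariate on clearance
#' (`CL = 0.029 * exp(0.0043 * CLcr)` L/h, so about 0.043 L/h at the cohort
#' median CLcr of 93 mL/min/1.73 m2); the base model has no covariate.
#' IIV percentages are interpreted as log-scale SD * 100.
#'
#' @param preset `"final"` (default) or `"base"`.
#' @return A [population_model()].
#' @examples
#' m <- dalbavancin_model()
#' typical_clearance(m, clcr = 93)
#' @export
dalbavancin_model <- function(preset = c("final", "base")) {
  switch(match.arg(preset),
    final = population_model(
      theta_CL = 0.029, theta_V1 = 6.14, theta_Q = 0.026, theta_V2 = 9.52,
      beta_CLcr_CL = 0.0043,
      omega_CL = 0.2644, omega_V1 = 0.1610, omega_Q = 0.5090,
      omega_V2 = 0.3715, prop_error_b = 0.3392),
    base = population_model(
      theta_CL = 0.041, theta_V1 = 6.15, theta_Q = 0.026, theta_V2 = 10.51,
      beta_CLcr_CL = 0,
      omega_CL = 0.3176, omega_V1 = 0.1610, omega_Q = 0.4506,
      omega_V2 = 0.3719, prop_error_b = 0.3392))
}

#' @export
print.population_model <- function(x, ...) {
  cat("Population PK model (2-compartment, IV infusion)\n")
  cat(sprintf("  Typical values: CL %.4g L/h, V1 %.4g L, Q %.4g L/h, V2 %.4g L\n",
              x$theta[["CL"]], x$theta[["V1"]], x$theta[["Q"]],
              x$theta[["V2"]]))
  if (x$beta_CLcr_CL != 0)
    cat(sprintf("  CLcr on CL (%s form): beta = %.4g\n",
                x$covariate_form, x$beta_CLcr_CL))
  cat(sprintf("  IIV (log-SD): CL %.3g, V1 %.3g, Q %.3g, V2 %.3g\n",
              x$omega[["CL"]], x$omega[["V1"]], x$omega[["Q"]],
              x$omega[["V2"]]))
  cat(sprintf("  Residual error: proportional b = %.4g%s\n", x$prop_error_b,
              if (x$add_error_a > 0)
                sprintf(", additive a = %.4g mg/L", x$add_error_a) else ""))
  invisible(x)
}

#' Typical (covariate-adjusted) clearance
#'
#' @param m a [population_model()].
#' @param clcr creatinine clearance (mL/min/1.73 m2), `> 0`; vectorized.
#' @return Typical clearance (L/h) at each `clcr`.
#' @examples
#' typical_clearance(dalbavancin_model(), 93)  # ~ 0.043 L/h
#' @export
typical_clearance <- function(m, clcr) {
  if (any(clcr <= 0)) stop("clcr must be strictly positive")
  th <- m$theta[["CL"]]
  if (m$beta_CLcr_CL == 0) return(rep(th, length(clcr)))
  switch(m$covariate_form,
         exponential = th * exp(m$beta_CLcr_CL * clcr),
         power = th * (clcr / m$covariate_reference)^m$beta_CLcr_CL)
}

# typical parameter vector (CL covariate-adjusted) for one subject
typical_params <- function(m, clcr) {
  c(CL = typical_clearance(m, clcr), V1 = m$theta[["V1"]],
    Q = m$theta[["Q"]], V2 = m$theta[["V2"]])
}

#' Sample individual parameters from the population
#'
#' Each disposition parameter is the covariate-adjusted typical value times
#' `exp(eta)` with independent `eta ~ N(0, omega^2)` (diagonal random-effect
#' covariance, exponential random effects).
#'
#' @param m a [population_model()].
#' @param clcr the subject's creatinine clearance (mL/min/1.73 m2).
#' @return A [pk_params()] object with attribute `"eta"` holding the sampled
#'   random effects.
#' @export
sample_individual <- function(m, clcr) {
  eta <- rnorm(4) * m$omega
  typ <- typical_params(m, clcr)
  ind <- typ * exp(eta)
  p <- pk_params(CL = ind[["CL"]], V1 = ind[["V1"]], Q = ind[["Q"]],
                 V2 = ind[["V2"]])
  attr(p, "eta") <- setNames(eta, names(m$omega))
  p
}

#' Apply the residual error model to true concentrations
#'
#' Observed concentration = `f * (1 + b*eps)` (plus an additive component when
#' `add_error_a > 0`), `eps ~ N(0,1)`. Negative draws are floored at zero and
#' flagged via the `"floored"` attribute.
#'
#' @param true_conc vector of model-predicted (true) concentrations (mg/L).
#' @param b proportional residual SD (fraction); defaults from `m` if given.
#' @param a additive residual SD (mg/L).
#' @return Vector of observed concentrations with attribute `"floored"`.
#' @export
apply_residual_error <- function(true_conc, b, a = 0) {
  if (any(true_conc < 0)) stop("true concentrations must be >= 0")
  sdv <- sqrt(a^2 + (b * true_conc)^2)
  obs <- true_conc + rnorm(length(true_conc)) * sdv
  fl <- obs < 0
  obs[fl] <- 0
  attr(obs, "floored") <- fl
  obs
}

#' Read or write a population model as a YAML configuration
#'
#' Field names mirror the [population_model()] arguments so a saved model can
#' be inspected or edited by hand and read back losslessly.
#'
#' @param m a [population_model()].
#' @param path file path.
#' @return `read_model()` returns a [population_model()];
#'   `write_model()` returns `path` invisibly.
#' @export
write_model <- function(m, path) {
  yaml::write_yaml(list(
    theta_CL = unname(m$theta[["CL"]]), theta_V1 = unname(m$theta[["V1"]]),
    theta_Q = unname(m$theta[["Q"]]), theta_V2 = unname(m$theta[["V2"]]),
    beta_CLcr_CL = m$beta_CLcr_CL,
    omega_CL = unname(m$omega[["CL"]]), omega_V1 = unname(m$omega[["V1"]]),
    omega_Q = unname(m$omega[["Q"]]), omega_V2 = unname(m$omega[["V2"]]),
    prop_error_b = m$prop_error_b, add_error_a = m$add_error_a,
    covariate_form = m$covariate_form,
    covariate_reference = m$covariate_reference), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$covariate_reference <- if (is.null(cfg$covariate_reference))
    NA_real_ else as.numeric(cfg$covariate_reference)
  do.call(population_model, cfg)
}
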