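m_final <- dalbavancin_model()

test_that("with no random effects the marginal likelihood is the Gaussian deviance", {
  m0 <- population_model(theta_CL = 0.043, theta_V1 = 6.14, theta_Q = 0.026,
                         theta_V2 = 9.52, prop_error_b = 0.3)
  set.seed(21)
  reg <- weekly_regimen(c(1500, 1000))
  coh <- make_design_cohort(4, m0, reg, times = c(200, 340, 500))
  got <- marginal_loglik(m0, coh)
  # direct closed form: proportional-error Gaussian deviance at typical values
  p <- pk_params(0.043, 6.14, 0.026, 9.52)
  dev <- 0
  for (s in coh) {
    f <- concentration(p, s$regimen, s$obs$time)
    dev <- dev - 2 * sum(dnorm(s$obs$conc, f, 0.3 * f, log = TRUE))
  }
  expect_equal(as.numeric(got), dev, tolerance = 1e-8)

  # duplicating a subject doubles that subject's contribution
  coh2 <- structure(c(coh, coh[1]), class = "pk_cohort")
  got2 <- marginal_loglik(m0, coh2)
  expect_equal(as.numeric(got2) - as.numeric(got),
               attr(got, "per_subject")[1], tolerance = 1e-8)
})

test_that("Laplace and importance-sampling likelihoods agree", {
  set.seed(31)
  reg <- weekly_regimen(c(1500, 1500))
  coh <- make_design_cohort(10, m_final, reg,
                            times = c(170, 300, 336, 500, 672))
  lap <- as.numeric(marginal_loglik(m_final, coh, method = "laplace"))
  set.seed(32)
  is_ <- as.numeric(marginal_loglik(m_final, coh, method = "importance",
                                    n_is = 3000))
  expect_lt(abs(lap - is_) / abs(is_), 0.01)
})

test_that("BIC and LRT arithmetic", {
  expect_equal(bic(100, 0, 289), 100)
  expect_equal(bic(100, 5, 289), 100 + 5 * log(289))
  # BIC differences are invariant to a constant OFV shift
  expect_equal(bic(150, 5, 100) - bic(150, 3, 100),
               bic(950, 5, 100) - bic(950, 3, 100))
  expect_error(bic(100, 2, 0), "n_obs")

  expect_equal(lrt(103.84, 100, df = 1), pchisq(3.84, 1, lower.tail = FALSE))
  expect_equal(round(lrt(103.84, 100, df = 1), 2), 0.05)
  expect_equal(lrt(100, 100, df = 1), 1)
  expect_lt(lrt(110.83, 100, df = 1), 0.0011)
  expect_gt(lrt(110.83, 100, df = 1), 0.0009)
  expect_error(lrt(100, 90, df = 0), "df")
  expect_warning(lrt(90, 100, df = 1), "lower OFV")
})

test_that("noise-free fixed-effects data recover the generating thetas", {
  truth <- population_model(theta_CL = 0.035, theta_V1 = 7, theta_Q = 0.03,
                            theta_V2 = 11)
  reg <- weekly_regimen(c(1500, 1500))
  times <- c(1, 24, 96, 170, 240, 336, 504, 840)
  coh <- make_design_cohort(4, truth, reg, times, clcr = c(50, 80, 100, 120),
                            residual = FALSE)
  fit <- fit_population(coh, covariate = NULL,
                        init = list(omega = c(omega_CL = 0, omega_V1 = 0,
                                              omega_Q = 0, omega_V2 = 0),
                                    b = 0.01),
                        fix = c("omega_CL", "omega_V1", "omega_Q",
                                "omega_V2", "b"),
                        control = list(maxit = 500, factr = 1e2,
                                       ndeps = rep(1e-5, 4)))
  expect_true(fit$converged)
  expect_equal(unname(fit$theta),
               c(0.035, 7, 0.03, 11), tolerance = 1e-3)
})

test_that("population fitting recovers generating parameters from a synthetic cohort", {
  # moderately rich design (3-5 samples per subject); the sparse-data IIVs on
  # Q and V2 are held at their generating values, mirroring practice when a
  # design cannot inform them
  set.seed(41)
  coh <- generate_cohort(cohort_config(samples_range = 3:5), m_final)
  fit <- fit_population(coh, covariate = "CLcr",
                        init = list(omega = c(omega_Q = 0.5090,
                                              omega_V2 = 0.3715)),
                        fix = c("omega_Q", "omega_V2"))
  expect_lt(abs(fit$theta[["CL"]] - 0.029) / 0.029, 0.40)
  expect_gt(fit$beta_CLcr_CL, 0)
  expect_lt(abs(fit$omega[["omega_CL"]] - 0.2644) / 0.2644, 0.50)
  expect_lt(abs(fit$b - 0.3392) / 0.3392, 0.15)
  expect_equal(fit$n_subjects, 69)
  # fit report exposes RSEs and the methods work
  expect_true(all(c("estimate", "rse_percent") %in% names(fit$estimates)))
  expect_s3_class(summary(fit), "summary.popfit")
  expect_length(coef(fit), fit$n_params)
  expect_equal(as.numeric(logLik(fit)), -fit$ofv / 2)
  pr <- predict(fit)
  expect_equal(nrow(pr), fit$n_obs)
  expect_true(all(pr$predicted > 0))
})

test_that("empty and degenerate datasets are rejected", {
  expect_error(fit_population(structure(list(), class = "pk_cohort")))
  m0 <- dalbavancin_model()
  reg <- weekly_regimen(1500)
  one <- make_design_cohort(1, m0, reg, times = 200)
  expect_error(fit_population(one), "at least two")
})

sparse_iiv_fix <- list(init = list(omega = c(omega_Q = 0.5090,
                                             omega_V2 = 0.3715)),
                       fix = c("omega_Q", "omega_V2"))

test_that("adding a nested parameter never increases the OFV", {
  set.seed(51)
  coh <- generate_cohort(cohort_config(n_subjects = 30,
                                       samples_range = 3:5), m_final)
  fit0 <- fit_population(coh, covariate = NULL,
                         init = sparse_iiv_fix$init,
                         fix = sparse_iiv_fix$fix)
  ini1 <- sparse_iiv_fix$init
  ini1$theta <- fit0$theta
  ini1$beta <- 0
  fit1 <- fit_population(coh, covariate = "CLcr", init = ini1,
                         fix = sparse_iiv_fix$fix)
  expect_lte(fit1$ofv, fit0$ofv + 0.1)
  expect_gte(lrt(fit0$ofv, fit1$ofv, df = 1), 0)
})

test_that("covariate screening flags a planted clearance covariate", {
  # power for the CLcr-on-CL effect is modest at the study's size because
  # empirical-Bayes shrinkage attenuates the correlation; a larger cohort
  # makes the check sharp
  set.seed(62)
  coh <- generate_cohort(cohort_config(n_subjects = 120,
                                       samples_range = 3:5), m_final)
  # fit WITHOUT the covariate; CLcr must then correlate with eta_CL
  fit <- fit_population(coh, covariate = NULL,
                        init = sparse_iiv_fix$init, fix = sparse_iiv_fix$fix)
  covs <- data.frame(
    CLcr = sapply(coh, function(s) s$covariates$CLcr)[
      sapply(fit$subjects, `[[`, "id")],
    noise = rnorm(fit$n_subjects))
  sc <- screen_covariates(fit, covs)
  row <- sc[sc$parameter == "CL" & sc$covariate == "CLcr", ]
  expect_lt(row$p_value, 0.05)
  expect_gt(row$r, 0)
  expect_true(row$selected)

  # a covariate identical to the random effect correlates perfectly
  covs2 <- data.frame(mirror = fit$eta[, "CL"])
  sc2 <- screen_covariates(fit, covs2)
  expect_gt(sc2$r[sc2$parameter == "CL"], 0.999)

  expect_warning(screen_covariates(fit, data.frame(flat = rep(1,
    fit$n_subjects))), "constant")

  # permuted covariates are rarely flagged on the same fit
  hits <- 0
  for (r in 1:40) {
    covs3 <- data.frame(perm = sample(rnorm(fit$n_subjects)))
    sc3 <- screen_covariates(fit, covs3)
    hits <- hits + any(abs(sc3$r[sc3$parameter == "CL"]) > 0.3)
  }
  expect_lt(hits / 40, 0.2)
})

test_that("MAP estimation is self-consistent and shrinks with the prior", {
  reg <- weekly_regimen(c(1500, 1500))
  truth <- pk_params(0.05, 7, 0.03, 8)
  times <- c(1, 48, 170, 336, 504, 840)
  subj <- list(id = 1, covariates = list(CLcr = 93), regimen = reg,
               obs = data.frame(time = times,
                                conc = concentration(truth, reg, times),
                                blq = FALSE))
  wide <- population_model(theta_CL = 0.043, theta_V1 = 6.14,
                           theta_Q = 0.026, theta_V2 = 9.52,
                           omega_CL = 2, omega_V1 = 2, omega_Q = 2,
                           omega_V2 = 2, prop_error_b = 0.05)
  est <- map_estimate(wide, subj)
  expect_equal(unclass(est)[1:4], unclass(truth)[1:4], tolerance = 0.01,
               ignore_attr = TRUE)

  # no observations returns typical values with zero etas
  none <- subj
  none$obs <- data.frame(time = numeric(0), conc = numeric(0),
                         blq = logical(0))
  est0 <- map_estimate(m_final, none)
  expect_equal(unname(attr(est0, "eta")), rep(0, 4))
  expect_equal(est0[["CL"]], typical_clearance(m_final, 93))

  # one observation lying exactly on the typical prediction keeps eta at 0
  typ <- pk_params(typical_clearance(m_final, 93), 6.14, 0.026, 9.52)
  one <- subj
  one$obs <- data.frame(time = 336, conc = concentration(typ, reg, 336),
                        blq = FALSE)
  est1 <- map_estimate(m_final, one)
  # the mode tilts slightly away from zero because the proportional-error
  # sd depends on the prediction; the shift is O(b^2), far below the IIV
  expect_lt(abs(attr(est1, "eta")[["CL"]]), 0.06)

  # shrinkage: smaller omegas pull the MAP estimate toward typical values
  omegas <- c(1, 0.5, 0.2, 0.05)
  dist <- sapply(omegas, function(w) {
    mw <- population_model(theta_CL = 0.043, theta_V1 = 6.14,
                           theta_Q = 0.026, theta_V2 = 9.52,
                           omega_CL = w, omega_V1 = w, omega_Q = w,
                           omega_V2 = w, prop_error_b = 0.2)
    sum(abs(attr(map_estimate(mw, subj), "eta")))
  })
  expect_true(all(diff(dist) < 1e-6))
})
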