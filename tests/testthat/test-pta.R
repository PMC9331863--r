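m_final <- dalbavancin_model()

test_that("PD target arithmetic is mutually consistent", {
  pd <- pd_target()
  expect_equal(threshold_for_target(pd), 111.1 * 0.125 / (24 * 0.07))
  expect_equal(round(threshold_for_target(pd), 2), 8.27)
  # doubling the MIC doubles the required concentration
  pd2 <- pd_target(mic = 0.25)
  expect_equal(threshold_for_target(pd2), 2 * threshold_for_target(pd))
  expect_equal(threshold_for_target(pd_target(unbound_fraction = 1,
                                              fauc_mic_target = 24,
                                              mic = 1)), 1)

  expect_equal(fauc_mic(8.04, pd), 24 * 0.07 * 8.04 / 0.125)
  expect_equal(round(fauc_mic(8.04, pd), 1), 108.1)
  expect_equal(fauc_mic(0, pd), 0)
  expect_equal(fauc_mic(16.08, pd), 2 * fauc_mic(8.04, pd))  # linearity
  # the round-trip: threshold back through fauc_mic hits the target ratio
  expect_equal(fauc_mic(threshold_for_target(pd), pd), 111.1)
  expect_error(pd_target(unbound_fraction = 0), "unbound")
})

test_that("renal classes validate their bounds", {
  expect_error(renal_class("bad", 60, 30), "clcr_low")
  rcs <- default_renal_classes()
  expect_named(rcs, c("<30", "30-59", "60-89", "90-120"))
  expect_equal(rcs[["30-59"]]$clcr_low, 30)
  expect_equal(rcs[["30-59"]]$clcr_high, 60)
})

test_that("class simulation is reproducible, degenerate-safe and linear in dose", {
  rc <- renal_class("fixed", 92.999, 93.001)
  m0 <- population_model(theta_CL = 0.029, theta_V1 = 6.14, theta_Q = 0.026,
                         theta_V2 = 9.52, beta_CLcr_CL = 0.0043)
  reg <- weekly_regimen(1500)
  set.seed(7)
  M <- simulate_class(m0, reg, rc, n = 100)
  # no IIV and a near-degenerate class: all subjects essentially identical
  expect_lt(max(apply(M, 2, function(x) diff(range(x)) / mean(x))), 1e-4)

  set.seed(8)
  M1 <- simulate_class(m_final, reg, default_renal_classes()[["60-89"]],
                       n = 200)
  set.seed(8)
  M2 <- simulate_class(m_final, reg, default_renal_classes()[["60-89"]],
                       n = 200)
  expect_identical(M1, M2)

  set.seed(8)
  Mdouble <- simulate_class(m_final, weekly_regimen(3000),
                            default_renal_classes()[["60-89"]], n = 200)
  expect_equal(Mdouble, 2 * M1, tolerance = 1e-12)

  expect_error(simulate_class(m_final, reg, rc, n = 50), "100")
})

test_that("PTA curve counts attainment fractions", {
  M <- matrix(c(rep(10, 9), 5, rep(1, 10)), nrow = 10,
              dimnames = list(NULL, c("week2", "week3")))
  attr(M, "weeks") <- 2:3
  expect_equal(unname(pta_curve(M, 8.04)), c(0.9, 0))
  expect_equal(unname(pta_curve(M, 1e9)), c(0, 0))
  expect_equal(unname(pta_curve(M, 0.5)), c(1, 1))
  expect_error(pta_curve(matrix(numeric(0), 0, 2), 8), "non-empty")
  expect_error(pta_curve(M, -1), "positive")
})

test_that("optimal duration is the last week of a continuous optimal run", {
  wk <- 2:12
  expect_equal(optimal_duration(rep(0.95, 11), weeks = wk), 12)
  expect_equal(optimal_duration(c(0.95, 0.85, rep(0.5, 9)), weeks = wk), 2)
  expect_equal(optimal_duration(c(0.89, rep(0.95, 10)), weeks = wk), 0)
  # a later recovery above the level does not extend the continuous run
  expect_equal(optimal_duration(c(0.95, 0.95, 0.85, 0.95, rep(0.2, 7)),
                                weeks = wk), 3)
})

test_that("percentile bands match a direct sort-based computation", {
  set.seed(9)
  vals <- rlnorm(100, log(15), 0.5)
  M <- matrix(vals, ncol = 1, dimnames = list(NULL, "week6"))
  attr(M, "weeks") <- 6L
  b <- percentile_band(M, 6)
  q <- quantile(vals, c(0.05, 0.95), names = FALSE)
  expect_equal(b$low, q[1])
  expect_equal(b$high, q[2])
  expect_equal(b$fold_difference, q[2] / q[1])

  expect_equal(percentile_band(matrix(rep(3, 50), ncol = 1,
    dimnames = list(NULL, "week2")), 2)$fold_difference, 1)
  M50 <- M
  b50 <- percentile_band(M50, 6, percentiles = c(50, 50))
  expect_equal(b50$fold_difference, 1)
  Mz <- matrix(rep(0, 100), ncol = 1, dimnames = list(NULL, "week2"))
  expect_warning(bz <- percentile_band(Mz, 2), "zero")
  expect_true(is.na(bz$fold_difference))
})

test_that("TDM timing sits one week before the end of optimal coverage", {
  expect_equal(tdm_timing(6)$day, 35)
  expect_equal(tdm_timing(5)$day, 28)
  expect_equal(tdm_timing(4)$day, 21)
  expect_equal(tdm_timing(2)$day, 7)
  expect_false(tdm_timing(2)$immediate)
  expect_warning(out <- tdm_timing(1), "immediate")
  expect_true(out$immediate)
})

test_that("scenario runs compose their building blocks", {
  set.seed(10)
  res <- run_scenarios(m_final,
                       scenarios = data.frame(class = "60-89",
                                              regimen = "double_1500"),
                       n = 300)
  set.seed(10)
  M <- simulate_class(m_final, preset_regimen("double_1500"),
                      default_renal_classes()[["60-89"]], n = 300)
  pta <- pta_curve(M, 8.04)
  expect_equal(res$detail[[1]]$pta, pta)
  expect_equal(res$table$optimal_weeks, optimal_duration(pta))

  # default scenario table: 3 regimens for <30 plus 3 x 3 for the rest
  sc <- default_scenarios()
  expect_equal(nrow(sc), 12)
  expect_equal(sum(sc$class == "<30"), 3)
})

test_that("PTA declines after the last dose and grows with total dose", {
  set.seed(12)
  res <- run_scenarios(m_final,
                       scenarios = data.frame(
                         class = c("30-59", "30-59"),
                         regimen = c("single_1500", "double_1500")),
                       n = 1000)
  pta_single <- res$detail[[1]]$pta
  pta_double <- res$detail[[2]]$pta
  # evaluation grid starts after each regimen's final dose: non-increasing
  expect_true(all(diff(pta_single) <= 0))
  expect_true(all(diff(pta_double) <= 0))
  expect_gte(res$table$optimal_weeks[2], res$table$optimal_weeks[1])
  expect_true(all(pta_double >= pta_single - 0.03))
})
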