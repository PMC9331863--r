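test_that("micro constants follow from clearances and volumes", {
  p <- pk_params(CL = 0.043, V1 = 6.14, Q = 0.026, V2 = 9.52)
  k <- micro_constants(p)
  expect_equal(unname(k["k10"]), 0.043 / 6.14)
  expect_equal(unname(k["k12"]), 0.026 / 6.14)
  expect_equal(unname(k["k21"]), 0.026 / 9.52)
  expect_equal(unname(k["k10"]) * 6.14, 0.043)  # k10*V1 = CL exactly
  expect_true(all(k > 0))

  # Q = 0 collapses to one compartment
  k0 <- micro_constants(pk_params(CL = 0.04, V1 = 6, Q = 0, V2 = 9))
  expect_equal(unname(k0[c("k12", "k21")]), c(0, 0))
  # CL numerically equal to V1 gives unit elimination rate
  expect_equal(unname(micro_constants(pk_params(CL = 5, V1 = 5))["k10"]), 1)
})

test_that("invalid parameters are rejected", {
  expect_error(pk_params(CL = -1, V1 = 6), "positive")
  expect_error(pk_params(CL = 0.04, V1 = 0), "positive")
  expect_error(pk_params(CL = 0.04, V1 = 6, Q = 0.02, V2 = -3), "V2")
})

test_that("concentration handles trivial regimens and superposition", {
  p <- table2_typical()
  reg0 <- regimen(0, 0)
  tg <- c(0, 10, 200, 1000)
  expect_equal(concentration(p, reg0, tg), rep(0, 4))

  # two identical doses: value at 300 h equals single-dose at 300 h + 132 h
  reg2 <- regimen(c(1500, 1500), c(0, 168))
  reg1 <- regimen(1500, 0)
  expect_equal(concentration(p, reg2, 300),
               concentration(p, reg1, 300) + concentration(p, reg1, 132))

  # superposition over a longer regimen, to machine precision
  amts <- c(1500, 1000, 1000, 500)
  starts <- c(0, 168, 336, 504)
  regn <- regimen(amts, starts)
  grid <- seq(0, 1500, by = 37)
  single <- sapply(seq_along(amts), function(i)
    concentration(p, regimen(amts[i], 0), pmax(grid - starts[i], 0)) *
      (grid >= starts[i]))
  expect_equal(concentration(p, regn, grid), rowSums(single),
               tolerance = 1e-12)

  # time before the first dose gives zero, not an error
  reg_late <- regimen(1500, 24)
  expect_equal(concentration(p, reg_late, c(0, 12)), c(0, 0))
})

test_that("closed form matches the ODE oracle across random parameter draws", {
  skip_if_not_installed("deSolve")
  set.seed(101)
  reg <- regimen(c(1500, 1000), c(0, 168))
  times <- sort(c(0.25, 0.5, 1, 6, 24, runif(20, 0, 2016)))
  for (i in 1:100) {
    p <- random_pk_params()
    cf <- concentration(p, reg, times)
    oc <- ode_conc(p, reg, times)
    expect_lt(max(abs(cf - oc) / pmax(oc, 1e-9)), 1e-6)
  }
})

test_that("typical-profile closed form matches the matrix-exponential path", {
  p <- table2_typical()
  reg <- regimen(1500, 0)
  grid <- seq(1, 2016, by = 1)
  cf <- concentration(p, reg, grid)
  me <- concentration_matexp(p, reg, grid)
  expect_lt(max(abs(cf - me) / pmax(me, 1e-12)), 1e-6)

  # and for a three-compartment model
  p3 <- pk_params(CL = 0.04, V1 = 6, Q = 0.03, V2 = 9, Q3 = 0.012, V3 = 4)
  grid3 <- seq(1, 2016, by = 24)
  expect_lt(max(abs(concentration(p3, reg, grid3) -
                      concentration_matexp(p3, reg, grid3)) /
                  pmax(concentration_matexp(p3, reg, grid3), 1e-12)), 1e-6)
})

test_that("concentration_profile is the vectorized scalar call", {
  p <- table2_typical()
  reg <- weekly_regimen(c(1500, 1500))
  expect_error(concentration(p, reg, numeric(0)), "empty")
  grid <- seq(0, 2016, length.out = 1000)
  scalar <- vapply(grid, function(t) concentration(p, reg, t), numeric(1))
  expect_equal(concentration_profile(p, reg, grid), scalar)
})

test_that("terminal half-life comes from the slow disposition eigenvalue", {
  p <- table2_typical(clcr = 93)
  k <- micro_constants(p)
  A <- matrix(c(-(k["k10"] + k["k12"]), k["k12"], k["k21"], -k["k21"]), 2, 2)
  beta_oracle <- min(abs(eigen(A)$values))
  expect_equal(terminal_half_life(p), log(2) / beta_oracle,
               tolerance = 1e-10)
  expect_gt(terminal_half_life(p), 180)  # the drug's defining property

  # one-compartment degenerate case
  expect_equal(terminal_half_life(pk_params(CL = 0.693147, V1 = 1, Q = 0,
                                            V2 = 5)), 1, tolerance = 1e-6)

  # doubling both volumes doubles the half-life at fixed CL and Q
  p2 <- pk_params(CL = p[["CL"]], V1 = 2 * p[["V1"]], Q = p[["Q"]],
                  V2 = 2 * p[["V2"]])
  expect_equal(terminal_half_life(p2), 2 * terminal_half_life(p),
               tolerance = 1e-9)
})

test_that("AUC to infinity is dose over clearance and conserves mass", {
  p <- pk_params(CL = 0.043, V1 = 6.14, Q = 0.026, V2 = 9.52)
  expect_equal(auc_to_infinity(p, regimen(1500, 0)), 1500 / 0.043)
  expect_equal(auc_to_infinity(p, regimen(0, 0)), 0)
  reg2 <- regimen(c(800, 800), c(0, 168))
  expect_equal(auc_to_infinity(p, reg2), 2 * 800 / 0.043)

  # mass balance: integral of CL*C(t) recovers the administered dose
  # (fine grid over the infusions, coarser over the long tail)
  grid <- sort(unique(c(seq(0, 4, by = 0.02), seq(168, 172, by = 0.02),
                        seq(4, 30000, by = 2))))
  cc <- concentration(p, reg2, grid)
  auc_num <- sum((cc[-1] + cc[-length(cc)]) / 2 * diff(grid))
  expect_equal(auc_num * p[["CL"]], 1600, tolerance = 1e-3)
})

test_that("concentration declines monotonically late after the last dose", {
  set.seed(77)
  reg <- weekly_regimen(c(1500, 1500))
  for (i in 1:20) {
    p <- random_pk_params()
    k <- micro_constants(p)
    # distribution half-life from the fast eigenvalue
    s <- k["k10"] + k["k12"] + k["k21"]
    fast <- (s + sqrt(s^2 - 4 * k["k10"] * k["k21"])) / 2
    t_start <- 168 + 0.5 + 5 * log(2) / fast
    grid <- seq(t_start, t_start + 5000, length.out = 400)
    cc <- concentration(p, reg, grid)
    expect_true(all(diff(cc) < 0))
  }
})
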