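test_that("right-hand sides match hand-evaluated derivatives", {
  p <- model_params(alpha = 0.04, K = 5.2246)
  d <- rhs_full(c(T = 1, I = 0, V = 0, C = 0), p)
  expect_equal(d[["T"]], 0.04 * (1 - 1 / 5.2246), tolerance = 1e-12)
  expect_equal(d[c("I", "V", "C")], c(I = 0, V = 0, C = 0))

  # extinction state is a fixed point of all three models
  p2 <- model_params(alpha = 0.1, K = 2, beta_TV = 1, beta_CV = 1,
                     theta_TC = 1, theta_IC = 1, gamma = 0.5, b = 10,
                     omega = 0.1, delta = 0.2, mu = -0.3)
  expect_equal(unname(rhs_full(c(T = 0, I = 0, V = 0, C = 0), p2)),
               rep(0, 4))
  expect_equal(unname(rhs_cart(c(T = 0, C = 0), p2)), rep(0, 2))
  expect_equal(unname(rhs_ov(c(T = 0, I = 0, V = 0), p2)), rep(0, 3))

  p3 <- model_params(alpha = 0.04, K = 5.2246, gamma = 0.1, b = 25,
                     omega = 0.05, delta = 0.3, mu = 0.5, theta_IC = 2,
                     beta_CV = 1)
  d3 <- rhs_full(c(T = 0, I = 0.1, V = 0.05, C = 0.2), p3)
  expect_equal(d3[["I"]], -0.05, tolerance = 1e-12)
  expect_equal(d3[["V"]], 0.2475, tolerance = 1e-12)
  expect_equal(d3[["C"]], -0.06, tolerance = 1e-12)

  p4 <- model_params(alpha = 0.04, K = 5.2246, theta_TC = 0.01,
                     delta = 0.02, mu = 0.03)
  d4 <- rhs_cart(c(T = 1, C = 1), p4)
  expect_equal(d4[["T"]], 0.04 * (1 - 1 / 5.2246) - 0.01, tolerance = 1e-12)
  expect_equal(d4[["C"]], 0.01, tolerance = 1e-12)

  p5 <- model_params(alpha = 0.04, K = 5.2246, beta_TV = 0.5, gamma = 0.1,
                     b = 25, omega = 0.05)
  d5 <- rhs_ov(c(T = 1, I = 0.1, V = 0.05), p5)
  expect_equal(d5[["I"]], 0.015, tolerance = 1e-12)
  expect_equal(d5[["V"]], 0.2475, tolerance = 1e-12)
})

test_that("carrying capacity is a fixed point and reductions are logistic", {
  p <- model_params(alpha = 0.07, K = 3.4)
  expect_equal(rhs_cart(c(T = 3.4, C = 0), p)[["T"]], 0)
  # theta_TC = 0, C arbitrary: pure logistic derivative
  p2 <- set_params(p, delta = 0.1)
  expect_equal(rhs_cart(c(T = 1.2, C = 0.7), p2)[["T"]],
               0.07 * 1.2 * (1 - 1.2 / 3.4))
  # OV module with no virus or infected cells: logistic in T
  expect_equal(rhs_ov(c(T = 1.2, I = 0, V = 0), p)[["T"]],
               0.07 * 1.2 * (1 - 1.2 / 3.4))
})

test_that("infection flux is conserved between T and I compartments", {
  set.seed(42)
  for (i in 1:25) {
    p <- model_params(alpha = runif(1, 0.01, 0.2), K = runif(1, 1, 10),
                      beta_TV = runif(1, 0, 2), gamma = runif(1, 0.01, 0.5),
                      b = runif(1, 0.1, 100), omega = runif(1, 0, 0.5))
    st <- c(T = runif(1, 0, 5), I = runif(1, 0, 2), V = runif(1, 0, 3))
    d <- rhs_ov(st, p)
    flux <- p[["beta_TV"]] * st[["T"]] * st[["V"]]
    logistic_part <- p[["alpha"]] * st[["T"]] *
      (1 - (st[["T"]] + st[["I"]]) / p[["K"]])
    expect_equal(d[["T"]] - logistic_part, -flux, tolerance = 1e-12)
    expect_equal(d[["I"]] + p[["gamma"]] * st[["I"]], flux,
                 tolerance = 1e-12)
  }
})

test_that("state validation rejects malformed input", {
  p <- model_params()
  expect_error(rhs_full(c(T = 1, I = 0, V = 0), p), "missing")
  expect_error(rhs_full(c(T = NaN, I = 0, V = 0, C = 0), p), "finite")
  expect_error(rhs_full(c(T = -1, I = 0, V = 0, C = 0), p), ">= 0")
  expect_error(rhs_cart(c(T = 1, C = 0, I = 0.5, V = 0), p), "I = 0")
  expect_error(model_params(alpha = -0.1), ">= 0")
  expect_error(model_params(K = 0), "K must be > 0")
  expect_silent(validate_params(model_params(mu = -0.5)))
})

test_that("simulated untreated growth matches the logistic closed form", {
  p <- model_params(alpha = 0.08, K = 5.2246)
  tr <- simulate_model("cart", p, dose_condition(t0_tumor = 0.95),
                       t_end = 96)
  cf <- logistic_growth(tr$time_h, 0.95, 0.08, 5.2246)
  expect_lt(max(abs(tr$T_ci - cf) / cf), 1e-6)
  # OV module with no virus dose: same logistic, I and V identically zero
  tr2 <- simulate_model("ov", set_params(p, beta_TV = 1, gamma = 0.05,
                                         b = 25, omega = 0.05),
                        dose_condition(v0 = 0), t_end = 96)
  expect_lt(max(abs(tr2$T_ci - cf) / cf), 1e-6)
  expect_equal(max(tr2$I_ci), 0)
  expect_equal(max(tr2$V_moi), 0)
})

test_that("doses enter as impulses at their administration times", {
  p <- default_truth_params()
  cond <- dose_condition(et_ratio = 1 / 25, v0 = 0.002,
                         t_admin_cart = 10, t_admin_ov = 4)
  tr <- simulate_model("full", p, cond, t_end = 24)
  expect_equal(tr$V_moi[tr$time_h < 4], rep(0, sum(tr$time_h < 4)))
  expect_equal(tr$C_ci[tr$time_h < 10], rep(0, sum(tr$time_h < 10)))
  expect_equal(tr$V_moi[tr$time_h == 4], 0.002, tolerance = 1e-9)
  expect_equal(tr$C_ci[tr$time_h == 10], cart_dose_ci(cond),
               tolerance = 1e-6)
  expect_error(simulate_model("full", p, cond, t_end = 8), "t_end")
})

test_that("treatment suppresses the tumor relative to untreated growth", {
  p <- default_truth_params()
  cond <- dose_condition(et_ratio = 1 / 25, v0 = 0.002)
  treated <- simulate_model("full", p, cond, t_end = 72)
  untreated <- simulate_model("cart", set_params(p, theta_TC = 0,
                                                 beta_TV = 0),
                              dose_condition(t0_tumor = cond$t0_tumor),
                              t_end = 72)
  expect_lt(auc_ci(treated, c(0, 72)), auc_ci(untreated, c(0, 72)))
})

test_that("trajectories stay non-negative across random parameter draws", {
  set.seed(7)
  for (i in 1:20) {
    p <- model_params(alpha = runif(1, 0.01, 0.15), K = runif(1, 2, 8),
                      beta_TV = runif(1, 0, 0.5), beta_CV = runif(1, 0, 0.1),
                      theta_TC = runif(1, 0, 1), theta_IC = runif(1, 0, 2),
                      gamma = runif(1, 0.01, 0.3), b = runif(1, 0.1, 200),
                      omega = runif(1, 0.01, 0.3), delta = runif(1, 0, 0.3),
                      mu = runif(1, -0.3, 0.3))
    cond <- dose_condition(et_ratio = 1 / sample(c(10, 25, 50), 1),
                           v0 = runif(1, 1e-4, 0.05))
    tr <- simulate_model("full", p, cond, t_end = 72, dt_out = 1)
    expect_true(all(tr$T_ci >= 0 & tr$I_ci >= 0 &
                      tr$V_moi >= 0 & tr$C_ci >= 0))
  }
})

test_that("trajectory CSV writer round-trips through read.csv", {
  p <- default_truth_params()
  tr <- simulate_model("full", p, dose_condition(et_ratio = 1/50,
                                                 v0 = 0.002), t_end = 48)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  back <- read.csv(f)
  expect_equal(names(back), c("time_h", "T_ci", "I_ci", "V_moi", "C_ci"))
  expect_equal(back$T_ci, tr$T_ci, tolerance = 1e-12)
})
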