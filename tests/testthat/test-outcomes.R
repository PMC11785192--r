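test_that("AUC reproduces closed-form integrals and is additive", {
  flat <- data.frame(time_h = seq(0, 72, 0.25), ci = 1)
  expect_equal(auc_ci(flat, c(0, 72)), 72, tolerance = 1e-12)
  ramp <- data.frame(time_h = seq(0, 72, 0.25),
                     ci = seq(0, 72, 0.25) / 72)
  expect_equal(auc_ci(ramp, c(0, 72)), 36, tolerance = 1e-12)
  # additivity over adjacent windows, with off-grid edges
  p <- default_truth_params()
  tr <- simulate_model("full", p, dose_condition(et_ratio = 1/25,
                                                 v0 = 0.002), t_end = 72)
  expect_equal(auc_ci(tr, c(0, 30.1)) + auc_ci(tr, c(30.1, 72)),
               auc_ci(tr, c(0, 72)), tolerance = 1e-10)
  expect_error(auc_ci(tr, c(50, 50)), "t_end > t_start")
  expect_error(auc_ci(tr, c(0, 100)), "range")
})

test_that("AUC refinement error of a smooth trajectory is tiny", {
  p <- default_truth_params()
  cond <- dose_condition(et_ratio = 1 / 25, v0 = 0.002)
  coarse <- simulate_model("full", p, cond, t_end = 72, dt_out = 0.5)
  fine <- simulate_model("full", p, cond, t_end = 72, dt_out = 0.25)
  a1 <- auc_ci(coarse, c(0, 72))
  a2 <- auc_ci(fine, c(0, 72))
  expect_lt(abs(a1 - a2) / a2, 1e-4)  # < 0.01%
})

test_that("final burden interpolates T + I and sits at K when untreated", {
  p <- default_truth_params()
  un <- simulate_model("cart", set_params(p, theta_TC = 0),
                       dose_condition(), t_end = 200)
  expect_equal(final_burden(un, 200), p[["K"]], tolerance = 1e-3)
  # strong killing drives the burden below untreated at 72 h
  strong <- simulate_model("full", set_params(p, theta_TC = 5,
                                              theta_IC = 5),
                           dose_condition(et_ratio = 1 / 10, v0 = 0.002),
                           t_end = 72)
  expect_lt(final_burden(strong, 72), final_burden(un, 72))
  expect_gte(final_burden(strong, 72), 0)
  expect_error(final_burden(strong, 100), "range")
})

test_that("zero-dose outcome equals the untreated outcome", {
  p <- default_truth_params()
  out <- predict_outcome(dose_condition(), p)
  un <- simulate_model("cart", set_params(p, theta_TC = 0),
                       dose_condition(), t_end = 72)
  expect_equal(out$auc, auc_ci(un, c(0, 72)), tolerance = 1e-6)
  expect_equal(out$final_burden, final_burden(un, 72), tolerance = 1e-6)
})

test_that("predicted AUC decreases with virus dose below saturation", {
  p <- default_truth_params()
  doses <- c(1e-4, 1e-3, 1e-2)
  aucs <- vapply(doses, function(v) {
    predict_outcome(dose_condition(et_ratio = 1 / 50, v0 = v), p)$auc
  }, numeric(1))
  expect_true(all(diff(aucs) < 0))
})

test_that("parameter interpolation is exact at sources and clamps at 0", {
  p1 <- set_params(default_truth_params(), beta_TV = 2, theta_TC = 0.3,
                   theta_IC = 1)
  p2 <- set_params(default_truth_params(), beta_TV = 4, theta_TC = 0.5,
                   theta_IC = 3)
  fits <- list("0.0008" = p1, "0.002" = p2)
  # target at a source dose returns the source estimates
  at_src <- interpolate_params_vs_dose(fits, 0.0008)
  expect_equal(at_src[["beta_TV"]], 2, tolerance = 1e-12)
  expect_equal(at_src[["theta_TC"]], 0.3, tolerance = 1e-12)
  # linear midpoint
  mid <- interpolate_params_vs_dose(fits, 0.0014)
  expect_equal(mid[["beta_TV"]], 3, tolerance = 1e-12)
  # delta and mu carried over unchanged
  expect_equal(mid[["delta"]], p1[["delta"]])
  expect_equal(mid[["mu"]], p1[["mu"]])
  # extrapolation far below the sources: clamped at 0 with a warning
  expect_warning(lo <- interpolate_params_vs_dose(fits, 1.2e-5),
                 "clamped")
  expect_gte(lo[["beta_TV"]], 0)
  expect_error(interpolate_params_vs_dose(fits, -1), ">= 0")
  expect_error(interpolate_params_vs_dose(fits["0.0008"], 1e-3),
               "2 source doses")
})

test_that("three-source interpolation reproduces a quadratic exactly", {
  doses <- c(0.0008, 0.002, 0.03)
  f <- function(v) 1 + 5 * v + 40 * v^2
  fits <- setNames(lapply(doses, function(v) {
    set_params(default_truth_params(), beta_TV = f(v))
  }), doses)
  got <- interpolate_params_vs_dose(fits, 0.01)
  expect_equal(got[["beta_TV"]], f(0.01), tolerance = 1e-10)
})

test_that("delay scan matrices behave on inert axes and are deterministic", {
  p <- default_truth_params()
  # no CAR T dose: AUC constant along the CAR T-delay axis
  sc_ov <- delay_scan(p, dose_condition(v0 = 0.002), grid_step = 20)
  for (i in seq_along(sc_ov$ov_delays)) {
    expect_lt(diff(range(sc_ov$auc[i, ])), 1e-9)
  }
  # no doses at all: constant everywhere, equal to the untreated outcome
  sc0 <- delay_scan(p, dose_condition(), grid_step = 20)
  un <- predict_outcome(dose_condition(), p)
  expect_lt(diff(range(sc0$auc)), 1e-9)
  expect_equal(sc0$auc[1, 1], un$auc, tolerance = 1e-9)
  # determinism
  cond <- dose_condition(et_ratio = 1 / 25, v0 = 0.002)
  a <- delay_scan(p, cond, grid_step = 20)
  b <- delay_scan(p, cond, grid_step = 20)
  expect_identical(a$auc, b$auc)
  expect_identical(a$burden, b$burden)
  expect_error(delay_scan(p, cond, grid_step = 7), "divide")
})

test_that("reported argmin attains the matrix minimum with earliest ties", {
  p <- default_truth_params()
  cond <- dose_condition(et_ratio = 1 / 25, v0 = 0.002)
  sc <- delay_scan(p, cond, grid_step = 10)
  i <- match(sc$argmin_auc[["ov_delay"]], sc$ov_delays)
  j <- match(sc$argmin_auc[["cart_delay"]], sc$cart_delays)
  expect_equal(sc$auc[i, j], min(sc$auc))
  i2 <- match(sc$argmin_burden[["ov_delay"]], sc$ov_delays)
  j2 <- match(sc$argmin_burden[["cart_delay"]], sc$cart_delays)
  expect_equal(sc$burden[i2, j2], min(sc$burden))
  # tie-breaking on a constant matrix: earliest schedule
  sc0 <- delay_scan(p, dose_condition(), grid_step = 20)
  expect_equal(unname(sc0$argmin_auc), c(0, 0))
})

test_that("band mask flags exactly the cells within mean +/- sd", {
  p <- default_truth_params()
  cond <- dose_condition(et_ratio = 1 / 25, v0 = 0.002)
  ref <- delay_scan(p, cond, grid_step = 20)
  band <- c(mean(ref$auc), sd(ref$auc))
  sc <- delay_scan(p, cond, grid_step = 20, experimental_band = band)
  expect_identical(sc$band_mask, abs(sc$auc - band[1]) <= band[2])
  expect_true(any(sc$band_mask))
  long <- delay_scan_long(sc)
  expect_equal(nrow(long), length(sc$auc))
  expect_equal(long$auc[long$ov_delay_h == 20 & long$cart_delay_h == 40],
               sc$auc["20", "40"])
})

test_that("monotherapy delay curves are flat at zero dose", {
  p <- default_truth_params()
  flat <- delay_scan_mono("cart", p, doses = 0, delays = c(0, 20, 40))
  expect_lt(diff(range(flat$auc)), 1e-9)
})

test_that("mono-combo comparison reports planted differences and AUCs", {
  base <- default_truth_params()
  combo_p <- set_params(base, beta_TV = 2 * base[["beta_TV"]],
                        theta_TC = 1.5 * base[["theta_TC"]])
  mono_ov <- list("OV0.002" = list(
    params = base, condition = dose_condition(v0 = 0.002),
    beta_TV_mean = base[["beta_TV"]], beta_TV_sd = 0))
  mono_cart <- list("ET1-25" = list(
    params = base, condition = dose_condition(et_ratio = 1 / 25),
    theta_TC_mean = base[["theta_TC"]], theta_TC_sd = 0))
  combo <- list("ET1-25_OV0.002" = list(
    params = combo_p,
    condition = dose_condition(et_ratio = 1 / 25, v0 = 0.002),
    beta_TV_mean = combo_p[["beta_TV"]], beta_TV_sd = 0,
    theta_TC_mean = combo_p[["theta_TC"]], theta_TC_sd = 0))
  tab <- compare_mono_combo(mono_ov, mono_cart, combo)
  expect_equal(nrow(tab), 1)
  expect_gt(tab$beta_TV_combo, tab$beta_TV_mono)
  expect_gt(tab$theta_TC_combo, tab$theta_TC_mono)
  expect_lt(tab$auc_combo, min(tab$auc_mono_ov, tab$auc_mono_cart))
  # identical parameter sets in both arms: zero differences
  combo_same <- combo
  combo_same[[1]]$params <- base
  combo_same[[1]]$beta_TV_mean <- base[["beta_TV"]]
  combo_same[[1]]$theta_TC_mean <- base[["theta_TC"]]
  tab0 <- compare_mono_combo(mono_ov, mono_cart, combo_same)
  expect_equal(tab0$beta_TV_combo - tab0$beta_TV_mono, 0)
  expect_equal(tab0$theta_TC_combo - tab0$theta_TC_mono, 0)
  # mismatched dose sets are refused
  expect_error(compare_mono_combo(mono_ov, mono_cart,
                                  list("ET1-10_OV0.03" = combo[[1]])),
               "matching")
})
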