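test_that("SSE objective matches its definition on simple cases", {
  p <- default_truth_params()
  panel <- generate_untreated(p, noise_spec(0, 1))
  s <- panel_series(panel, "untreated", 1)
  tr <- simulate_model("cart", set_params(p, theta_TC = 0),
                       dose_condition(), t_end = 72)
  # prediction identical to observation: zero error (up to interpolation)
  expect_lt(sse_ci(s, tr, "T"), 1e-12)
  # constant offset d on n unmasked points contributes n d^2
  s2 <- s
  d <- 0.17
  s2$ci <- s2$ci + d
  n <- sum(!s2$attachment)
  expect_equal(sse_ci(s2, tr, "T"), n * d^2, tolerance = 1e-6)
  # masking additional points removes exactly their terms
  s3 <- s2
  extra <- which(!s3$attachment)[1:8]
  s3$attachment[extra] <- TRUE
  expect_equal(sse_ci(s2, tr, "T") - sse_ci(s3, tr, "T"), 8 * d^2,
               tolerance = 1e-6)
  # no overlap between observations and prediction window
  s_all_masked <- s
  s_all_masked$attachment <- TRUE
  expect_error(sse_ci(s_all_masked, tr, "T"), "overlap")
})

test_that("SSE against a 4x coarser output grid agrees within 0.5%", {
  p <- default_truth_params()
  panel <- generate_treatment_panel(
    p, list(dose_condition(et_ratio = 1 / 25, v0 = 0.002)),
    noise_spec(0.05, 1, seed = 6))
  s <- panel_series(panel, "ET1-25_OV0.002", 1)
  cond <- attr(s, "condition")
  cnd <- dose_condition(et_ratio = cond$et_ratio, v0 = cond$v0,
                        t0_tumor = s$ci[!s$attachment][1])
  dense <- simulate_model("full", p, cnd, t_end = 72, dt_out = 0.25)
  coarse <- simulate_model("full", p, cnd, t_end = 72, dt_out = 1)
  a <- sse_ci(s, dense)
  b <- sse_ci(s, coarse)
  expect_lt(abs(a - b) / a, 0.005)
})

test_that("logistic fit recovers noiseless growth to 0.1%", {
  p <- default_truth_params()
  panel <- generate_untreated(p, noise_spec(0, 1))
  fit <- fit_carrying_capacity(panel, test_pso(swarm = 20, iters = 60))
  est <- setNames(fit$aggregate$mean, fit$aggregate$parameter)
  expect_lt(rel_err(est[["alpha"]], p[["alpha"]]), 0.001)
  expect_lt(rel_err(est[["K"]], p[["K"]]), 0.001)
  expect_lt(rel_err(est[["T0"]], 0.95), 0.001)
  expect_true(all(fit$per_replicate$sse >= 0))
})

test_that("logistic fit under noise recovers within 5% with 3 replicates", {
  p <- default_truth_params()
  panel <- generate_untreated(p, noise_spec(0.05, 3, seed = 2))
  fit <- fit_carrying_capacity(panel, test_pso(swarm = 20, iters = 60))
  est <- setNames(fit$aggregate$mean, fit$aggregate$parameter)
  expect_lt(rel_err(est[["alpha"]], p[["alpha"]]), 0.05)
  expect_lt(rel_err(est[["K"]], p[["K"]]), 0.05)
  # replicate spread is reported
  expect_equal(nrow(fit$per_replicate), 3)
  expect_true(all(is.finite(fit$aggregate$sd)))
})

test_that("a series already at plateau reports alpha spread, not failure", {
  p <- set_params(default_truth_params(), alpha = 0.5)  # at K well before 24 h
  panel <- generate_untreated(p, noise_spec(0.02, 3, seed = 3),
                              t0_tumor = 5.2)
  fit <- suppressWarnings(
    fit_carrying_capacity(panel, test_pso(swarm = 15, iters = 40)))
  est <- setNames(fit$aggregate$mean, fit$aggregate$parameter)
  # K is still identified by the plateau level
  expect_lt(rel_err(est[["K"]], p[["K"]]), 0.05)
  expect_equal(nrow(fit$per_replicate), 3)
})

test_that("declining series triggers the non-growth warning", {
  p <- default_truth_params()
  panel <- generate_untreated(p, noise_spec(0, 1))
  declining <- panel
  declining$ci <- rev(declining$ci)
  attributes(declining) <- attributes(panel)
  declining$ci <- rev(panel$ci)
  expect_warning(fit_carrying_capacity(declining,
                                       test_pso(swarm = 10, iters = 10)),
                 "does not grow")
})

test_that("CAR T module fit recovers noiseless truth within 1%", {
  p <- default_truth_params()
  panel <- generate_treatment_panel(p, list(dose_condition(et_ratio = 1/25)),
                                    noise_spec(0, 1))
  fit <- fit_cart_module(panel, alpha = p[["alpha"]], K = p[["K"]],
                         config = test_pso(seed = 1, iters = 60))
  est <- setNames(fit$aggregate$mean, fit$aggregate$parameter)
  expect_lt(rel_err(est[["theta_TC"]], p[["theta_TC"]]), 0.01)
  expect_lt(rel_err(est[["delta"]], p[["delta"]]), 0.01)
  expect_lt(rel_err(est[["mu"]], p[["mu"]]), 0.01)
  # estimates respect their declared bounds
  b <- default_fit_bounds()
  for (nm in fit$free_names) {
    expect_gte(est[[nm]], b[[nm]][1])
    expect_lte(est[[nm]], b[[nm]][2])
  }
})

test_that("a null CAR T effect fits to a negligible kill rate", {
  p <- set_params(default_truth_params(), theta_TC = 0)
  panel <- generate_treatment_panel(p, list(dose_condition(et_ratio = 1/10)),
                                    noise_spec(0, 1))
  fit <- fit_cart_module(panel, alpha = p[["alpha"]], K = p[["K"]],
                         config = test_pso(seed = 4, iters = 60))
  est <- setNames(fit$aggregate$mean, fit$aggregate$parameter)
  # kill rate indistinguishable from zero at the data scale
  expect_lt(est[["theta_TC"]] * 0.095 * 72, 0.05)
  expect_lt(min(fit$per_replicate$sse), 1e-4)
})

test_that("full-model fit recovers truth and the kill-rate ordering", {
  p <- default_truth_params()  # theta_IC > theta_TC in truth
  panel <- generate_treatment_panel(
    p, list(dose_condition(et_ratio = 1 / 25, v0 = 0.002)),
    noise_spec(0, 1))
  fixed <- set_params(model_params(alpha = p[["alpha"]], K = p[["K"]]),
                      gamma = p[["gamma"]], b = p[["b"]],
                      omega = p[["omega"]], delta = p[["delta"]],
                      mu = p[["mu"]])
  fit <- fit_full_model(panel, fixed,
                        config = test_pso(seed = 2, swarm = 28, iters = 80))
  est <- setNames(fit$aggregate$mean, fit$aggregate$parameter)
  for (nm in c("theta_IC", "beta_CV", "beta_TV", "theta_TC")) {
    expect_lt(rel_err(est[[nm]], p[[nm]]), 0.05)
  }
  expect_gt(est[["theta_IC"]], est[["theta_TC"]])
})

test_that("OV fit separates burst-size-sensitive from insensitive rates", {
  p <- default_truth_params()
  panel <- generate_treatment_panel(p, list(dose_condition(v0 = 0.002)),
                                    noise_spec(0, 1))
  fit <- suppressWarnings(
    fit_ov_module(panel, K = p[["K"]], omega = p[["omega"]],
                  b_grid = c(2.5, 25, 250),
                  config = test_pso(seed = 3, iters = 60)))
  # alpha is insensitive to b; the recovered values sit near truth
  expect_lt(fit$alpha_cv, 0.1)
  expect_lt(rel_err(fit$alpha_hat, p[["alpha"]]), 0.02)
  expect_lt(rel_err(fit$gamma_hat, p[["gamma"]]), 0.02)
  # at the generating burst size all three rates are recovered
  at_truth <- fit$stage1[fit$stage1$b == 25, ]
  expect_lt(rel_err(at_truth$beta_TV, p[["beta_TV"]]), 0.02)
  # stage-2 infection rate decreases with the assumed burst size
  bt <- fit$beta_tv[order(fit$beta_tv$b), ]
  expect_true(all(diff(bt$beta_TV) < 0))
})

test_that("fits are deterministic given the configuration seed", {
  p <- default_truth_params()
  panel <- generate_untreated(p, noise_spec(0.05, 2, seed = 8))
  cfg <- test_pso(swarm = 12, iters = 25)
  a <- fit_carrying_capacity(panel, cfg)
  b <- fit_carrying_capacity(panel, cfg)
  expect_identical(a$per_replicate, b$per_replicate)
})
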