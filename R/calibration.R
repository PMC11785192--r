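#' Default calibration bounds
#'
#' Box bounds used by the staged fits, bracketing the scales implied by the
#' parameter units and typical cell-index magnitudes. `mu` may be negative
#' (net CAR T exhaustion). All positive rates are searched on a log10
#' scale because their plausible ranges span several decades; their lower
#' bounds are therefore small positive floors, indistinguishable from zero
#' at the scale of the data, rather than exact zeros.
#'
#' @return Named list of `c(lower, upper)` pairs.
#' @export
default_fit_bounds <- function() {
  list(alpha = c(1e-4, 1), K = c(0.1, 20), T0 = c(0.01, 5),
       beta_TV = c(1e-6, 1e3), beta_CV = c(1e-8, 1e3),
       theta_TC = c(1e-6, 10), theta_IC = c(1e-6, 10),
       gamma = c(1e-4, 1), delta = c(1e-6, 1), mu = c(-1, 1))
}

# Free parameters searched on the log10 scale (all but the sign-changing
# CAR T expansion/exhaustion rate).
log_scaled <- function(free_names) free_names != "mu"

encode_free <- function(x, islog) {
  out <- x
  out[islog] <- log10(x[islog])
  out
}

decode_free <- function(x, islog) {
  out <- x
  out[islog] <- 10^x[islog]
  out
}

# Swarm optimum followed by restarted Nelder-Mead descent from the best
# few mutually distant particle positions: the SSE surface has narrow
# curved valleys (where a swarm alone converges slowly) and occasional
# secondary basins (where a single local descent can strand). The box is
# enforced by an infinite objective outside the bounds.
pso_polish_minimize <- function(obj, lower, upper, config,
                                polish_restarts = 3, n_starts = 3,
                                n_swarms = 1) {
  best <- NULL
  for (sw in seq_len(n_swarms) - 1L) {
    cfg <- config
    cfg$seed <- config$seed + 500009L * sw
    run <- pso_polish_single(obj, lower, upper, cfg, polish_restarts,
                             n_starts)
    if (is.null(best) || run$value < best$value) best <- run
  }
  best
}

pso_polish_single <- function(obj, lower, upper, config,
                              polish_restarts = 3, n_starts = 3) {
  boxed <- function(x) {
    if (any(x < lower) || any(x > upper)) return(Inf)
    obj(x)
  }
  res <- pso_minimize(boxed, lower, upper, config)
  x <- res$par
  v <- res$value
  if (polish_restarts > 0 && is.finite(v)) {
    span <- upper - lower
    starts <- list(res$par)
    for (i in order(res$pbest_val)) {
      if (length(starts) >= n_starts) break
      cand <- res$pbest[i, ]
      if (!is.finite(res$pbest_val[i])) next
      far <- all(vapply(starts, function(s) {
        max(abs(s - cand) / span) > 0.02
      }, logical(1)))
      if (far) starts[[length(starts) + 1L]] <- cand
    }
    for (x0 in starts) {
      xk <- x0
      vk <- boxed(xk)
      for (k in seq_len(polish_restarts)) {
        pol <- tryCatch(
          if (length(xk) == 1L) {
            optim(xk, boxed, method = "Brent", lower = lower,
                  upper = upper)
          } else {
            optim(xk, boxed, method = "Nelder-Mead",
                  control = list(maxit = 1500, reltol = 1e-14))
          },
          error = function(e) NULL)
        if (!is.null(pol) && pol$value <= vk) {
          xk <- pol$par
          vk <- pol$value
        }
      }
      if (vk < v) {
        x <- xk
        v <- vk
      }
    }
  }
  list(par = x, value = v, history = res$history)
}

#' Sum-of-squares error between a series and a model trajectory
#'
#' The calibration objective: squared differences between the observed
#' cell index and the model's tumor signal, summed over the unmasked
#' (post-attachment) observation times. The prediction is interpolated
#' linearly to the observation times; the tumor signal is `T + I` for the
#' OV and full models and `T` for the CAR T module.
#'
#' @param observed One replicate's series: data frame `time_h`, `ci`,
#'   `attachment`, with a `t_treat` attribute giving the treatment
#'   reference time on the `time_h` axis (default 24 h).
#' @param traj A `trajectory` with time 0 at the treatment reference.
#' @param observable `"total"` (`T + I`) or `"T"`.
#' @return Non-negative scalar.
#' @export
sse_ci <- function(observed, traj, observable = c("total", "T")) {
  observable <- match.arg(observable)
  t_treat <- attr(observed, "t_treat")
  if (is.null(t_treat)) t_treat <- 24
  obs <- observed[!observed$attachment, ]
  t_rel <- obs$time_h - t_treat
  keep <- t_rel >= min(traj$time_h) - 1e-9 & t_rel <= max(traj$time_h) + 1e-9
  if (!any(keep)) stop("no overlap between observations and trajectory")
  sig <- if (observable == "total") tumor_signal(traj) else traj$T_ci
  pred <- approx(traj$time_h, sig, xout = pmin(pmax(t_rel[keep],
                                                    min(traj$time_h)),
                                               max(traj$time_h)))$y
  sum((obs$ci[keep] - pred)^2)
}

new_fit_result <- function(per_replicate, free_names) {
  agg <- do.call(rbind, lapply(split(per_replicate,
                                     per_replicate$condition_id),
                               function(d) {
    data.frame(condition_id = d$condition_id[1], parameter = free_names,
               mean = vapply(free_names, function(p) mean(d[[p]]),
                             numeric(1)),
               sd = vapply(free_names, function(p) sd(d[[p]]), numeric(1)))
  }))
  rownames(agg) <- NULL
  structure(list(per_replicate = per_replicate, aggregate = agg,
                 free_names = free_names),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> free parameters:",
      paste(x$free_names, collapse = ", "), "\n")
  print(x$aggregate)
  invisible(x)
}

#' Aggregate estimate of one parameter
#'
#' @param fit A `fit_result`.
#' @param parameter Parameter name.
#' @param condition_id Optional condition; defaults to the mean across all.
#' @return Scalar mean estimate.
#' @export
fit_estimate <- function(fit, parameter, condition_id = NULL) {
  agg <- fit$aggregate
  if (!is.null(condition_id)) agg <- agg[agg$condition_id == condition_id, ]
  mean(agg$mean[agg$parameter == parameter])
}

panel_condition_ids <- function(panel) names(attr(panel, "conditions"))

# Model-based SSE objective over the panel's unmasked window for one
# replicate. x holds the free parameters in free_names order; the initial
# tumor burden is the first unmasked observation (not fitted).
make_objective <- function(model, series, cond, fixed_params, free_names,
                           observable, dt_fit = 0.5) {
  obs <- series[!series$attachment, ]
  t_treat <- attr(series, "t_treat")
  t_end <- max(obs$time_h) - t_treat
  t0_obs <- obs$ci[1]
  function(x) {
    p <- fixed_params
    p[free_names] <- x
    p <- tryCatch(set_params(p), error = function(e) NULL)
    if (is.null(p)) return(Inf)
    cnd <- dose_condition(et_ratio = cond$et_ratio, v0 = cond$v0,
                          t_admin_cart = cond$t_admin_cart,
                          t_admin_ov = cond$t_admin_ov,
                          t0_tumor = t0_obs)
    tr <- simulate_model(model, p, cnd, t_end = t_end, dt_out = dt_fit)
    sse_ci(series, tr, observable)
  }
}

run_replicate_fits <- function(panel, model, fixed_params, free_names,
                               observable, bounds, config,
                               condition_ids = NULL, n_swarms = 1L) {
  ids <- condition_ids %||% panel_condition_ids(panel)
  islog <- log_scaled(free_names)
  lower <- encode_free(vapply(free_names, function(p) bounds[[p]][1],
                              numeric(1)), islog)
  upper <- encode_free(vapply(free_names, function(p) bounds[[p]][2],
                              numeric(1)), islog)
  rows <- list()
  for (id in ids) {
    cond <- attr(panel, "conditions")[[id]]$condition
    reps <- sort(unique(panel$replicate[panel$condition_id == id]))
    for (r in reps) {
      series <- panel_series(panel, id, r)
      obj_raw <- make_objective(model, series, cond, fixed_params,
                                free_names, observable)
      obj <- function(x) obj_raw(decode_free(x, islog))
      cfg <- config
      cfg$seed <- config$seed + 101L * match(id, ids) + r
      res <- pso_polish_minimize(obj, lower, upper, cfg,
                                 n_swarms = n_swarms)
      row <- data.frame(condition_id = id, replicate = r, sse = res$value,
                        seed = cfg$seed)
      row[free_names] <- as.list(decode_free(res$par, islog))
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit logistic growth to untreated series
#'
#' Stage 1 of the calibration: estimates the tumor growth rate `alpha`, the
#' carrying capacity `K` and the burden at the window start `T0` by
#' particle-swarm least squares against the logistic closed form, per
#' replicate, over the unmasked fit window. The replicate mean and standard
#' deviation are reported.
#'
#' @param panel A `ci_panel` containing an untreated condition.
#' @param config A [pso_config()].
#' @param bounds Bounds list as in [default_fit_bounds()].
#' @return A `fit_result` with free parameters `alpha`, `K`, `T0`.
#' @export
fit_carrying_capacity <- function(panel, config = pso_config(),
                                  bounds = default_fit_bounds()) {
  ids <- panel_condition_ids(panel)
  id <- if ("untreated" %in% ids) "untreated" else ids[1]
  free <- c("alpha", "K", "T0")
  islog <- log_scaled(free)
  lower <- encode_free(vapply(free, function(p) bounds[[p]][1],
                              numeric(1)), islog)
  upper <- encode_free(vapply(free, function(p) bounds[[p]][2],
                              numeric(1)), islog)
  reps <- sort(unique(panel$replicate[panel$condition_id == id]))
  rows <- list()
  for (r in reps) {
    series <- panel_series(panel, id, r)
    obs <- series[!series$attachment, ]
    if (tail(obs$ci, 1) < obs$ci[1]) {
      warning("series does not grow (terminal < initial); fitting anyway")
    }
    t_rel <- obs$time_h - min(obs$time_h)
    obj <- function(x) {
      th <- decode_free(x, islog)
      sum((obs$ci - logistic_growth(t_rel, th[3], th[1], th[2]))^2)
    }
    cfg <- config
    cfg$seed <- config$seed + r
    res <- pso_polish_minimize(obj, lower, upper, cfg)
    th <- decode_free(res$par, islog)
    rows[[length(rows) + 1L]] <- data.frame(
      condition_id = id, replicate = r, sse = res$value, seed = cfg$seed,
      alpha = th[1], K = th[2], T0 = th[3])
  }
  new_fit_result(do.call(rbind, rows), free)
}

#' Fit the CAR T module to monotherapy series
#'
#' Estimates the CAR T kill rate `theta_TC`, death rate `delta` and
#' expansion/exhaustion rate `mu` (which may be negative) by particle-swarm
#' least squares of the CAR T module against each replicate, with `alpha`
#' and `K` fixed from the untreated fit. The initial tumor burden is the
#' first unmasked observation; the CAR T inoculum follows the condition's
#' E:T ratio.
#'
#' @param panel A `ci_panel` of CAR T monotherapy conditions.
#' @param alpha,K Fixed growth parameters from [fit_carrying_capacity()].
#' @param config A [pso_config()].
#' @param bounds Bounds list.
#' @return A `fit_result` with free parameters `theta_TC`, `delta`, `mu`,
#'   aggregated per E:T condition.
#' @export
fit_cart_module <- function(panel, alpha, K, config = pso_config(),
                            bounds = default_fit_bounds()) {
  fixed <- model_params(alpha = alpha, K = K)
  free <- c("theta_TC", "delta", "mu")
  per <- run_replicate_fits(panel, "cart", fixed, free, "T", bounds, config)
  new_fit_result(per, free)
}

#' Two-stage OV-module fit across burst sizes
#'
#' Stage 1 fits `(alpha, beta_TV, gamma)` at every burst size on the grid;
#' because the burst size is not identifiable from impedance data alone, it
#' is scanned rather than fitted. The across-grid coefficient of variation
#' of `alpha` and `gamma` is computed to verify they are insensitive to
#' `b` (a warning is issued when they are not); both are then fixed to
#' their across-grid medians and stage 2 refits
#' `beta_TV` alone at each grid point, yielding the `beta_TV(b)` table
#' whose log-log slope is close to -1.
#'
#' @param panel A `ci_panel` of OV monotherapy conditions.
#' @param K Fixed carrying capacity.
#' @param omega Fixed virus clearance rate (1/h).
#' @param b_grid Burst-size grid (MOI/CI); default 11 log-spaced points
#'   spanning 0.025 to 2500.
#' @param config A [pso_config()].
#' @param bounds Bounds list.
#' @return An object of class `ov_fit`: list with `stage1` (per condition,
#'   replicate and `b`), `alpha_hat`, `gamma_hat`, `alpha_cv`, `gamma_cv`,
#'   `beta_tv` (stage-2 table) and `beta_tv_mean` (per-condition average
#'   over the grid and replicates).
#' @export
fit_ov_module <- function(panel, K, omega = 0.05,
                          b_grid = default_burst_grid(),
                          config = pso_config(),
                          bounds = default_fit_bounds()) {
  ids <- panel_condition_ids(panel)
  stage1 <- list()
  for (b in b_grid) {
    fixed <- model_params(K = K, omega = omega, b = b)
    per <- run_replicate_fits(panel, "ov", fixed,
                              c("alpha", "beta_TV", "gamma"),
                              "total", bounds, config, ids)
    per$b <- b
    stage1[[length(stage1) + 1L]] <- per
  }
  stage1 <- do.call(rbind, stage1)
  # medians: at the far ends of the 5-decade grid the misspecified model
  # can push gamma to a bound, which would contaminate a mean
  alpha_hat <- median(stage1$alpha)
  gamma_hat <- median(stage1$gamma)
  alpha_cv <- sd(stage1$alpha) / mean(stage1$alpha)
  gamma_cv <- sd(stage1$gamma) / mean(stage1$gamma)
  if (length(b_grid) > 1 && (alpha_cv > 0.1 || gamma_cv > 0.1)) {
    warning(sprintf(
      "stage-1 estimates vary across the burst-size grid (CV alpha %.0f%%, gamma %.0f%%); the fixed-average premise holds only approximately",
      100 * alpha_cv, 100 * gamma_cv))
  }

  beta_tv <- list()
  for (b in b_grid) {
    fixed <- model_params(alpha = alpha_hat, K = K, omega = omega, b = b,
                          gamma = gamma_hat)
    per <- run_replicate_fits(panel, "ov", fixed, "beta_TV", "total",
                              bounds, config, ids)
    per$b <- b
    beta_tv[[length(beta_tv) + 1L]] <- per
  }
  beta_tv <- do.call(rbind, beta_tv)
  beta_tv_mean <- do.call(rbind, lapply(split(beta_tv, beta_tv$condition_id),
                                        function(d) {
    data.frame(condition_id = d$condition_id[1],
               beta_TV_mean = mean(d$beta_TV), beta_TV_sd = sd(d$beta_TV))
  }))
  rownames(beta_tv_mean) <- NULL
  structure(list(stage1 = stage1, alpha_hat = alpha_hat,
                 gamma_hat = gamma_hat, alpha_cv = alpha_cv,
                 gamma_cv = gamma_cv, b_grid = b_grid, beta_tv = beta_tv,
                 beta_tv_mean = beta_tv_mean),
            class = "ov_fit")
}

#' Default burst-size grid
#'
#' Eleven log-spaced points spanning the literature burst-size range of
#' 0.025 to 2500 MOI/CI (about two points per decade).
#'
#' @return Numeric vector.
#' @export
default_burst_grid <- function() {
  exp(seq(log(0.025), log(2500), length.out = 11))
}

#' @export
print.ov_fit <- function(x, ...) {
  cat(sprintf(
    "<ov_fit> %d burst sizes; alpha = %.4g (CV %.1f%%), gamma = %.4g (CV %.1f%%)\n",
    length(x$b_grid), x$alpha_hat, 100 * x$alpha_cv, x$gamma_hat,
    100 * x$gamma_cv))
  print(x$beta_tv_mean)
  invisible(x)
}

#' Fit the full model to combination-therapy series
#'
#' Estimates the combination-specific parameters `theta_IC`, `beta_CV`,
#' `beta_TV` and `theta_TC` (optionally also `alpha`) per replicate and
#' condition, with the remaining parameters fixed from the earlier stages:
#' `K` from the untreated fit, `gamma` from the OV fit, `delta` and `mu`
#' from the CAR T fit at the matching E:T ratio, and `b`, `omega` held at
#' their reference values.
#'
#' @param panel A `ci_panel` of combination conditions.
#' @param fixed A [model_params()] carrying the fixed values (`alpha`, `K`,
#'   `gamma`, `b`, `omega`, `delta`, `mu`).
#' @param config A [pso_config()].
#' @param bounds Bounds list.
#' @param fit_alpha If `TRUE`, `alpha` is refit alongside the four
#'   combination parameters.
#' @param profile_theta_IC If `TRUE` (default), augment the swarm search
#'   with a deterministic profile over `theta_IC`: the combination SSE
#'   surface has two nearby basins — a deep one at the generating
#'   parameters and a shallow one trading the infected-cell kill rate
#'   against CAR T infection — and a swarm alone can collapse into the
#'   shallow one. `theta_IC` is scanned over a log-spaced decade grid
#'   spanning its bounds with the other parameters re-fit at each point,
#'   and the best profile point seeds a final all-parameter descent; the
#'   better of the two routes is kept.
#' @return A `fit_result`.
#' @export
fit_full_model <- function(panel, fixed, config = pso_config(),
                           bounds = default_fit_bounds(),
                           fit_alpha = FALSE, profile_theta_IC = TRUE) {
  free <- c("theta_IC", "beta_CV", "beta_TV", "theta_TC")
  if (fit_alpha) free <- c(free, "alpha")
  if (!profile_theta_IC) {
    per <- run_replicate_fits(panel, "full", fixed, free, "total", bounds,
                              config)
    return(new_fit_result(per, free))
  }
  ids <- panel_condition_ids(panel)
  islog <- log_scaled(free)
  lower <- encode_free(vapply(free, function(p) bounds[[p]][1],
                              numeric(1)), islog)
  upper <- encode_free(vapply(free, function(p) bounds[[p]][2],
                              numeric(1)), islog)
  tic_grid <- 10^seq(log10(bounds$theta_IC[1]), log10(bounds$theta_IC[2]),
                     by = 1)
  rows <- list()
  for (id in ids) {
    cond <- attr(panel, "conditions")[[id]]$condition
    reps <- sort(unique(panel$replicate[panel$condition_id == id]))
    for (r in reps) {
      series <- panel_series(panel, id, r)
      obj_raw <- make_objective("full", series, cond, fixed, free, "total")
      obj <- function(x) obj_raw(decode_free(x, islog))
      cfg <- config
      cfg$seed <- config$seed + 101L * match(id, ids) + r
      best <- pso_polish_minimize(obj, lower, upper, cfg)

      # deterministic theta_IC profile, warm-started from the swarm
      # solution: the swarm reliably locates the infection-active region
      # but can pick the wrong theta_IC basin; re-descending the other
      # parameters at each grid value of theta_IC and polishing the best
      # profile points resolves the basin choice
      boxed <- function(x) {
        if (any(x < lower) || any(x > upper)) return(Inf)
        obj(x)
      }
      sub_idx <- which(free != "theta_IC")
      tic_idx <- which(free == "theta_IC")
      profiles <- list()
      for (tic in tic_grid) {
        sub_box <- function(xs) {
          x <- numeric(length(free))
          x[sub_idx] <- xs
          x[tic_idx] <- log10(tic)
          boxed(x)
        }
        pol <- tryCatch(optim(best$par[sub_idx], sub_box,
                              method = "Nelder-Mead",
                              control = list(maxit = 800,
                                             reltol = 1e-12)),
                        error = function(e) NULL)
        if (is.null(pol)) next
        x_full <- numeric(length(free))
        x_full[sub_idx] <- pol$par
        x_full[tic_idx] <- log10(tic)
        profiles[[length(profiles) + 1L]] <- list(par = x_full,
                                                  value = pol$value)
      }
      ord <- order(vapply(profiles, function(z) z$value, numeric(1)))
      for (i in ord[seq_len(min(2L, length(ord)))]) {
        xk <- profiles[[i]]$par
        vk <- profiles[[i]]$value
        for (k in 1:2) {
          pol <- tryCatch(optim(xk, boxed, method = "Nelder-Mead",
                                control = list(maxit = 1500,
                                               reltol = 1e-14)),
                          error = function(e) NULL)
          if (!is.null(pol) && pol$value <= vk) {
            xk <- pol$par
            vk <- pol$value
          }
        }
        if (vk < best$value) best <- list(par = xk, value = vk)
      }

      row <- data.frame(condition_id = id, replicate = r,
                        sse = best$value, seed = cfg$seed)
      row[free] <- as.list(decode_free(best$par, islog))
      rows[[length(rows) + 1L]] <- row
    }
  }
  new_fit_result(do.call(rbind, rows), free)
}
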