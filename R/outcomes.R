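#' Tumor area under the curve
#'
#' Trapezoidal integral of the tumor signal over a time window: for a model
#' trajectory the signal is `T + I` (matching the impedance observable),
#' for a data series it is the measured cell index. Window edges falling
#' between grid points are included by linear interpolation.
#'
#' @param x A `trajectory` from [simulate_model()], or a data frame with
#'   columns `time_h` and `ci`.
#' @param window `c(t_start, t_end)` in hours, within the available range.
#' @return AUC in CI·h.
#' @examples
#' p <- model_params(alpha = 0.08, K = 5.2246)
#' tr <- simulate_model("cart", p, dose_condition(), t_end = 72)
#' auc_ci(tr, c(0, 72))
#' @export
auc_ci <- function(x, window) {
  if (length(window) != 2 || window[2] <= window[1]) {
    stop("window must be c(t_start, t_end) with t_end > t_start")
  }
  if (inherits(x, "trajectory")) {
    t <- x$time_h; v <- tumor_signal(x)
  } else {
    t <- x$time_h; v <- x$ci
  }
  if (window[1] < min(t) - 1e-9 || window[2] > max(t) + 1e-9) {
    stop("window outside the available time range")
  }
  inside <- t > window[1] & t < window[2]
  tt <- c(window[1], t[inside], window[2])
  vv <- c(approx(t, v, xout = window[1])$y, v[inside],
          approx(t, v, xout = window[2])$y)
  sum(diff(tt) * (head(vv, -1) + tail(vv, -1)) / 2)
}

#' Tumor burden at the final time point
#'
#' `T + I` at `t_final`, linearly interpolated on the trajectory grid.
#'
#' @param traj A `trajectory`.
#' @param t_final Evaluation time (h), within the trajectory range.
#' @return Burden in CI.
#' @export
final_burden <- function(traj, t_final = 72) {
  if (t_final < min(traj$time_h) || t_final > max(traj$time_h)) {
    stop("t_final outside the trajectory range")
  }
  approx(traj$time_h, tumor_signal(traj), xout = t_final)$y
}

#' Simulated outcome of one dosing condition
#'
#' Simulates the full model for a condition and summarizes the outcome by
#' the tumor AUC over the window and the final burden `T + I` at
#' `t_final`. Time 0 is the treatment reference; delayed administrations
#' compete on the same horizon.
#'
#' @param condition A [dose_condition()].
#' @param params A [model_params()] (fitted or interpolated).
#' @param window AUC window (h).
#' @param t_final Final evaluation time (h).
#' @return An `outcome_summary`: list with `auc`, `final_burden`,
#'   `condition`.
#' @export
predict_outcome <- function(condition, params, window = c(0, 72),
                            t_final = 72) {
  t_end <- max(window[2], t_final)
  tr <- simulate_model("full", params, condition, t_end = t_end,
                       dt_out = 0.25)
  structure(list(auc = auc_ci(tr, window),
                 final_burden = final_burden(tr, t_final),
                 condition = condition),
            class = "outcome_summary")
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat(sprintf("<outcome_summary> AUC %.3f CI.h, final burden %.4f CI\n",
              x$auc, x$final_burden))
  invisible(x)
}

#' Monotherapy versus combination parameter comparison
#'
#' Tabulates the infection rate `beta_TV` (OV monotherapy vs combination)
#' and the CAR T kill rate `theta_TC` (CAR T monotherapy vs combination)
#' side by side for matching dose levels, together with the simulated AUC
#' of each scenario under its own parameter set.
#'
#' @param mono_ov Named list mapping an OV dose label (e.g. `"OV0.002"`) to
#'   list(params =, condition =, beta_TV_mean =, beta_TV_sd =).
#' @param mono_cart Named list mapping an E:T label (e.g. `"ET1-25"`) to
#'   list(params =, condition =, theta_TC_mean =, theta_TC_sd =).
#' @param combo Named list mapping a combination label (must be
#'   `"<et>_<ov>"` for labels present in the monotherapy lists) to
#'   list(params =, condition =, beta_TV_mean =, beta_TV_sd =,
#'   theta_TC_mean =, theta_TC_sd =).
#' @param window AUC window (h).
#' @return Data frame with one row per combination label: monotherapy and
#'   combination means and sds for `beta_TV` and `theta_TC`, and the AUC of
#'   the two monotherapies and the combination.
#' @export
compare_mono_combo <- function(mono_ov, mono_cart, combo,
                               window = c(0, 72)) {
  rows <- list()
  for (id in names(combo)) {
    parts <- strsplit(id, "_", fixed = TRUE)[[1]]
    et_id <- parts[1]; ov_id <- parts[2]
    if (!et_id %in% names(mono_cart) || !ov_id %in% names(mono_ov)) {
      stop("no matching monotherapy doses for combination ", id)
    }
    co <- combo[[id]]; mc <- mono_cart[[et_id]]; mv <- mono_ov[[ov_id]]
    rows[[length(rows) + 1L]] <- data.frame(
      condition_id = id,
      beta_TV_mono = mv$beta_TV_mean, beta_TV_mono_sd = mv$beta_TV_sd,
      beta_TV_combo = co$beta_TV_mean, beta_TV_combo_sd = co$beta_TV_sd,
      theta_TC_mono = mc$theta_TC_mean, theta_TC_mono_sd = mc$theta_TC_sd,
      theta_TC_combo = co$theta_TC_mean, theta_TC_combo_sd = co$theta_TC_sd,
      auc_mono_ov = predict_outcome(mv$condition, mv$params, window)$auc,
      auc_mono_cart = predict_outcome(mc$condition, mc$params, window)$auc,
      auc_combo = predict_outcome(co$condition, co$params, window)$auc)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Interpolate fitted parameters to a new virus dose
#'
#' Predicts the parameter set for an untested virus dose from fits at known
#' doses: each dose-dependent parameter is carried through the unique
#' polynomial in the dose through the source points (linear for two
#' sources), extrapolating where requested and clamping negative values at
#' 0 with a warning. The CAR T intrinsic rates `delta` and `mu` and the
#' fixed constants `b`, `omega`, `K` are carried over unchanged: virus dose
#' does not affect them.
#'
#' @param fits_at_doses Named list mapping a source dose (names coercible
#'   to numeric, MOI) to a [model_params()] fitted at that dose (for one
#'   E:T ratio).
#' @param target_v0 Target dose (MOI, >= 0).
#' @param interp_names Parameters treated as dose-dependent.
#' @return A `model_params` for the target dose.
#' @export
interpolate_params_vs_dose <- function(fits_at_doses, target_v0,
                                       interp_names = c("alpha", "beta_TV",
                                                        "beta_CV",
                                                        "theta_TC",
                                                        "theta_IC",
                                                        "gamma")) {
  if (target_v0 < 0) stop("target dose must be >= 0")
  doses <- as.numeric(names(fits_at_doses))
  if (length(doses) < 2) stop("need at least 2 source doses")
  if (anyNA(doses)) stop("names of fits_at_doses must be the source doses")
  base <- fits_at_doses[[which.min(abs(doses - target_v0))]]
  out <- base
  clamped <- character(0)
  for (nm in interp_names) {
    yvals <- vapply(fits_at_doses, function(p) p[[nm]], numeric(1))
    val <- lagrange_eval(doses, yvals, target_v0)
    if (val < 0) {
      clamped <- c(clamped, nm)
      val <- 0
    }
    out[nm] <- val
  }
  if (length(clamped)) {
    warning("negative interpolated value clamped to 0 for: ",
            paste(clamped, collapse = ", "))
  }
  set_params(out)
}

# Unique interpolating polynomial through (x, y), evaluated at x0.
lagrange_eval <- function(x, y, x0) {
  n <- length(x)
  sum(vapply(seq_len(n), function(i) {
    others <- setdiff(seq_len(n), i)
    y[i] * prod((x0 - x[others]) / (x[i] - x[others]))
  }, numeric(1)))
}

#' Therapy-delay scan for combination treatment
#'
#' Simulates the full model over a grid of (OV delay, CAR T delay) pairs in
#' `[0, delay_max]` hours and records the tumor AUC and final burden for
#' each schedule. Time 0 is the no-delay administration reference: the AUC
#' window and final time are fixed there, so delayed schedules compete on
#' the same horizon. Ties for the minimum are broken in favour of the
#' smallest OV delay, then the smallest CAR T delay (earliest feasible
#' schedule). Failed integrations are recorded per cell, not fatal.
#'
#' @param params A [model_params()].
#' @param condition A [dose_condition()] giving the doses; its
#'   administration times are overridden by the scanned delays.
#' @param grid_step Grid step (h); must divide `delay_max`.
#' @param delay_max Largest delay (h).
#' @param window AUC window (h).
#' @param t_final Final burden evaluation time (h).
#' @param experimental_band Optional `c(mean, sd)` of the experimental AUC;
#'   cells with `|AUC - mean| <= sd` are flagged in `band_mask`.
#' @return A `delay_scan` object: list with `ov_delays`, `cart_delays`,
#'   `auc` and `burden` matrices (rows = OV delays, columns = CAR T
#'   delays), `argmin_auc`, `argmin_burden` (named vectors of delays),
#'   `band_mask` (or `NULL`), `failed` matrix.
#' @export
delay_scan <- function(params, condition, grid_step = 1, delay_max = 40,
                       window = c(0, 72), t_final = 72,
                       experimental_band = NULL) {
  if (grid_step <= 0 || (delay_max / grid_step) %% 1 != 0) {
    stop("grid_step must divide delay_max")
  }
  ov_delays <- seq(0, delay_max, by = grid_step)
  cart_delays <- seq(0, delay_max, by = grid_step)
  n1 <- length(ov_delays); n2 <- length(cart_delays)
  auc_m <- matrix(NA_real_, n1, n2, dimnames = list(ov_delays, cart_delays))
  bur_m <- auc_m
  failed <- matrix(FALSE, n1, n2)
  t_end <- max(window[2], t_final)
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      cnd <- dose_condition(et_ratio = condition$et_ratio,
                            v0 = condition$v0,
                            t_admin_cart = cart_delays[j],
                            t_admin_ov = ov_delays[i],
                            t0_tumor = condition$t0_tumor)
      res <- tryCatch({
        tr <- simulate_model("full", params, cnd, t_end = t_end,
                             dt_out = 0.25)
        c(auc_ci(tr, window), final_burden(tr, t_final))
      }, error = function(e) NULL)
      if (is.null(res)) {
        failed[i, j] <- TRUE
      } else {
        auc_m[i, j] <- res[1]
        bur_m[i, j] <- res[2]
      }
    }
  }
  band_mask <- NULL
  if (!is.null(experimental_band)) {
    band_mask <- abs(auc_m - experimental_band[1]) <= experimental_band[2]
  }
  structure(list(ov_delays = ov_delays, cart_delays = cart_delays,
                 auc = auc_m, burden = bur_m,
                 argmin_auc = scan_argmin(auc_m, ov_delays, cart_delays),
                 argmin_burden = scan_argmin(bur_m, ov_delays, cart_delays),
                 band_mask = band_mask, failed = failed,
                 condition = condition),
            class = "delay_scan")
}

# First index pair attaining the minimum, scanning OV delays (rows) first.
scan_argmin <- function(m, ov_delays, cart_delays) {
  best <- min(m, na.rm = TRUE)
  hits <- which(m - best <= 0 & !is.na(m), arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  c(ov_delay = ov_delays[hits[1, 1]], cart_delay = cart_delays[hits[1, 2]])
}

#' @export
print.delay_scan <- function(x, ...) {
  cat(sprintf(
    "<delay_scan> %dx%d grid; best AUC %.3f at OV+%gh / CAR T+%gh\n",
    length(x$ov_delays), length(x$cart_delays), min(x$auc, na.rm = TRUE),
    x$argmin_auc["ov_delay"], x$argmin_auc["cart_delay"]))
  invisible(x)
}

#' Delay-scan results as a long data frame
#'
#' @param scan A `delay_scan`.
#' @return Data frame `ov_delay_h`, `cart_delay_h`, `auc`, `final_burden`,
#'   `in_band`.
#' @export
delay_scan_long <- function(scan) {
  grid <- expand.grid(ov_delay_h = scan$ov_delays,
                      cart_delay_h = scan$cart_delays)
  grid$auc <- as.vector(scan$auc)
  grid$final_burden <- as.vector(scan$burden)
  grid$in_band <- if (is.null(scan$band_mask)) NA else
    as.vector(scan$band_mask)
  grid
}

#' Monotherapy delay curves
#'
#' Outcome versus a single administration delay for each dose level of one
#' monotherapy, on the same fixed horizon as [delay_scan()].
#'
#' @param model `"cart"` or `"ov"`.
#' @param params A [model_params()].
#' @param doses E:T fractions (for `"cart"`) or virus doses in MOI (for
#'   `"ov"`).
#' @param delays Delay grid (h).
#' @param window,t_final As in [delay_scan()].
#' @param t0_tumor Tumor burden at the reference time (CI).
#' @return Data frame `dose`, `delay_h`, `auc`, `final_burden`.
#' @export
delay_scan_mono <- function(model = c("cart", "ov"), params, doses,
                            delays = seq(0, 40, by = 1),
                            window = c(0, 72), t_final = 72,
                            t0_tumor = 0.95) {
  model <- match.arg(model)
  t_end <- max(window[2], t_final)
  rows <- list()
  for (d in doses) {
    for (dl in delays) {
      cnd <- if (model == "cart") {
        dose_condition(et_ratio = d, t_admin_cart = dl,
                       t0_tumor = t0_tumor)
      } else {
        dose_condition(v0 = d, t_admin_ov = dl, t0_tumor = t0_tumor)
      }
      tr <- simulate_model(model, params, cnd, t_end = t_end,
                           dt_out = 0.25)
      rows[[length(rows) + 1L]] <- data.frame(
        dose = d, delay_h = dl, auc = auc_ci(tr, window),
        final_burden = approx(tr$time_h, tumor_signal(tr),
                              xout = t_final)$y)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
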