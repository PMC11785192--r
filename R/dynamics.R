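#' Model right-hand sides
#'
#' Time derivatives of the model compartments at one state. `rhs_full` is the
#' four-compartment model coupling tumor cells (T, CI), infected tumor cells
#' (I, CI), free virus (V, MOI) and CAR T-cells (C, CI):
#' \deqn{\dot T = \alpha T (1 - (T+I)/K) - \beta_{TV} T V - \theta_{TC} T C}
#' \deqn{\dot I = \beta_{TV} T V - \gamma I - \theta_{IC} I C}
#' \deqn{\dot V = \gamma b I - \omega V}
#' \deqn{\dot C = -\delta C + \mu C (T+I) - \beta_{CV} C V}
#' `rhs_cart` is the predator-prey CAR T monotherapy reduction (I = V = 0)
#' and `rhs_ov` the SIR-type virus monotherapy reduction (C = 0).
#'
#' @param state Named numeric vector with elements `T`, `I`, `V`, `C`
#'   (unused compartments may be omitted for the sub-modules; they must be
#'   zero if present).
#' @param params A [model_params()] object.
#' @return Named numeric vector of derivatives (per hour) for the model's
#'   compartments.
#' @examples
#' p <- model_params(alpha = 0.04, K = 5.2246)
#' rhs_full(c(T = 1, I = 0, V = 0, C = 0), p)
#' @export
rhs_full <- function(state, params) {
  st <- check_state(state, c("T", "I", "V", "C"))
  validate_params(params)
  T <- st[["T"]]; I <- st[["I"]]; V <- st[["V"]]; C <- st[["C"]]
  p <- as.list(params)
  c(T = p$alpha * T * (1 - (T + I) / p$K) - p$beta_TV * T * V -
        p$theta_TC * T * C,
    I = p$beta_TV * T * V - p$gamma * I - p$theta_IC * I * C,
    V = p$gamma * p$b * I - p$omega * V,
    C = -p$delta * C + p$mu * C * (T + I) - p$beta_CV * C * V)
}

#' @rdname rhs_full
#' @export
rhs_cart <- function(state, params) {
  st <- check_state(state, c("T", "C"))
  if (any(c(st["I"], st["V"]) != 0, na.rm = TRUE)) {
    stop("the CAR T module requires I = 0 and V = 0")
  }
  validate_params(params)
  T <- st[["T"]]; C <- st[["C"]]
  p <- as.list(params)
  c(T = p$alpha * T * (1 - T / p$K) - p$theta_TC * T * C,
    C = -p$delta * C + p$mu * C * T)
}

#' @rdname rhs_full
#' @export
rhs_ov <- function(state, params) {
  st <- check_state(state, c("T", "I", "V"))
  if (isTRUE(st["C"] != 0)) stop("the OV module requires C = 0")
  validate_params(params)
  T <- st[["T"]]; I <- st[["I"]]; V <- st[["V"]]
  p <- as.list(params)
  c(T = p$alpha * T * (1 - (T + I) / p$K) - p$beta_TV * T * V,
    I = p$beta_TV * T * V - p$gamma * I,
    V = p$gamma * p$b * I - p$omega * V)
}

check_state <- function(state, need) {
  if (is.null(names(state))) stop("state must be a named vector")
  missing <- setdiff(need, names(state))
  if (length(missing)) {
    stop("state is missing component(s): ", paste(missing, collapse = ", "))
  }
  if (any(!is.finite(state))) stop("state components must be finite")
  if (any(state < -1e-9)) {
    stop("state components must be >= 0 (got ",
         min(state), ")")
  }
  pmax(state, 0)
}

#' Logistic growth closed form
#'
#' Untreated tumor growth solution `T0 K / (T0 + (K - T0) exp(-alpha t))`.
#'
#' @param t Time (h), vector.
#' @param T0 Initial burden (CI).
#' @param alpha Growth rate (1/h).
#' @param K Carrying capacity (CI).
#' @return Burden at `t` (CI).
#' @export
logistic_growth <- function(t, T0, alpha, K) {
  T0 * K / (T0 + (K - T0) * exp(-alpha * t))
}

model_compartments <- function(model) {
  switch(model,
         full = c("T", "I", "V", "C"),
         cart = c("T", "C"),
         ov   = c("T", "I", "V"),
         stop("unknown model id: ", model))
}

model_symbols <- function(model) {
  switch(model,
         full = list(func = "cartov_deriv_full"),
         cart = list(func = "cartov_deriv_cart"),
         ov   = list(func = "cartov_deriv_ov"))
}

#' Simulate a treatment scenario
#'
#' Integrates one of the three models from the treatment reference time
#' `t = 0`, with tumor burden `condition$t0_tumor` and no infected cells.
#' Doses enter as instantaneous jumps: the virus compartment jumps by
#' `condition$v0` MOI at `t_admin_ov` and the CAR T compartment by
#' [cart_dose_ci()] at `t_admin_cart`; the integration is segmented at the
#' administration times. A stiff-capable solver (lsoda, compiled
#' right-hand sides) is used because large burst sizes make the virus
#' dynamics stiff.
#'
#' @param model One of `"full"`, `"cart"`, `"ov"`.
#' @param params A [model_params()].
#' @param condition A [dose_condition()]. For `"cart"` the virus dose is
#'   ignored and must be 0; for `"ov"` the CAR T dose must be 0.
#' @param t_end End of the simulation (h), must exceed both administration
#'   times.
#' @param dt_out Output grid spacing (h).
#' @param rtol,atol Solver tolerances.
#' @return An object of class `trajectory`: a data frame with columns
#'   `time_h`, `T_ci`, `I_ci`, `V_moi`, `C_ci`, with the parameters and
#'   condition stored as attributes.
#' @examples
#' p <- model_params(alpha = 0.08, K = 5.2246, theta_TC = 0.4,
#'                   delta = 0.01, mu = 0.02)
#' tr <- simulate_model("cart", p, dose_condition(et_ratio = 1/25), t_end = 72)
#' head(tr)
#' @export
simulate_model <- function(model = c("full", "cart", "ov"), params, condition,
                           t_end, dt_out = 0.25, rtol = 1e-8, atol = 1e-10) {
  model <- match.arg(model)
  validate_params(params)
  stopifnot(inherits(condition, "dose_condition"))
  if (dt_out <= 0) stop("dt_out must be > 0")
  if (model == "cart" && condition$v0 > 0) {
    stop("the CAR T module cannot receive a virus dose")
  }
  if (model == "ov" && condition$et_ratio > 0) {
    stop("the OV module cannot receive a CAR T dose")
  }
  admin <- c(
    if (model != "cart" && condition$v0 > 0) condition$t_admin_ov,
    if (model != "ov" && condition$et_ratio > 0) condition$t_admin_cart)
  if (length(admin) && t_end <= max(admin)) {
    stop("t_end must exceed the latest administration time")
  }

  comp <- model_compartments(model)
  y <- setNames(numeric(length(comp)), comp)
  y["T"] <- condition$t0_tumor

  times_out <- seq(0, t_end, by = dt_out)
  if (abs(times_out[length(times_out)] - t_end) > 1e-12) {
    times_out <- c(times_out, t_end)
  }
  breaks <- sort(unique(c(0, admin, t_end)))
  breaks <- breaks[breaks <= t_end]

  rows <- vector("list", length(breaks) - 1L + 1L)
  out_all <- NULL
  for (k in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[k]; t1 <- breaks[k + 1L]
    # apply impulse doses scheduled at the segment start
    if (model != "cart" && condition$v0 > 0 &&
        isTRUE(all.equal(t0, condition$t_admin_ov))) {
      y["V"] <- y["V"] + condition$v0
    }
    if (model != "ov" && condition$et_ratio > 0 &&
        isTRUE(all.equal(t0, condition$t_admin_cart))) {
      y["C"] <- y["C"] + cart_dose_ci(condition)
    }
    seg_times <- unique(c(t0, times_out[times_out > t0 & times_out < t1], t1))
    out <- integrate_segment(model, y, seg_times, params, rtol, atol)
    y <- clip_state(out[nrow(out), -1L], t1)
    # report post-jump states at administration times (right-continuous)
    keep <- if (k < length(breaks) - 1L) -nrow(out) else seq_len(nrow(out))
    out_all <- rbind(out_all, out[keep, , drop = FALSE])
  }

  df <- data.frame(time_h = out_all[, 1L])
  df$T_ci  <- clip_col(out_all[, "T"], df$time_h)
  df$I_ci  <- if ("I" %in% comp) clip_col(out_all[, "I"], df$time_h) else 0
  df$V_moi <- if ("V" %in% comp) clip_col(out_all[, "V"], df$time_h) else 0
  df$C_ci  <- if ("C" %in% comp) clip_col(out_all[, "C"], df$time_h) else 0
  df <- df[df$time_h %in% times_out | seq_len(nrow(df)) == nrow(df), ]
  rownames(df) <- NULL
  structure(df, params = params, condition = condition, model = model,
            class = c("trajectory", "data.frame"))
}

integrate_segment <- function(model, y, seg_times, params, rtol, atol) {
  sym <- model_symbols(model)
  out <- try(deSolve::lsoda(
    y = y, times = seg_times, func = sym$func, parms = unclass(params),
    dllname = "cartov", initfunc = "cartov_init11",
    rtol = rtol, atol = atol, maxsteps = 20000), silent = TRUE)
  if (inherits(out, "try-error") || nrow(out) < length(seg_times)) {
    t_fail <- if (inherits(out, "try-error")) seg_times[1L] else
      out[nrow(out), 1L]
    stop(sprintf("integration failed near t = %.3f h", t_fail))
  }
  out
}

# Clip small negative solver excursions to zero; larger negatives indicate a
# genuine failure and raise.
clip_state <- function(y, t_now) {
  if (any(y < -1e-9)) {
    stop(sprintf("negative state (%.3g) at t = %.3f h", min(y), t_now))
  }
  pmax(y, 0)
}

clip_col <- function(v, times) {
  if (any(v < -1e-9)) {
    stop(sprintf("negative state (%.3g) at t = %.3f h",
                 min(v), times[which.min(v)]))
  }
  pmax(v, 0)
}

#' Tumor signal of a trajectory
#'
#' The observable tumor burden `T + I` (CI), matching what the impedance
#' readout measures: infected and non-infected adherent tumor cells are
#' indistinguishable.
#'
#' @param traj A `trajectory`.
#' @return Numeric vector aligned with `traj$time_h`.
#' @export
tumor_signal <- function(traj) {
  traj$T_ci + traj$I_ci
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> model '%s', %d points over [0, %g] h\n",
              attr(x, "model"), nrow(x), max(x$time_h)))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Write a trajectory as CSV
#'
#' Columns: `time_h, T_ci, I_ci, V_moi, C_ci`.
#'
#' @param traj A `trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  write.csv(as.data.frame(traj)[, c("time_h", "T_ci", "I_ci",
                                    "V_moi", "C_ci")],
            path, row.names = FALSE)
  invisible(path)
}
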