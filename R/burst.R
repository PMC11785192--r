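#' Unit conversion constants
#'
#' Conversion factors between virological units (PFU, cells) and the
#' instrument units (MOI, CI): `1 MOI = pfu_per_moi PFU` and
#' `1 CI = cells_per_ci cells`.
#'
#' @param pfu_per_moi Plaque-forming units per MOI unit (default 2e4).
#' @param cells_per_ci Cells per cell-index unit (default 5e3; the mapping
#'   is instrument- and cell-line-specific and therefore configurable).
#' @return An object of class `unit_conversion`.
#' @export
unit_conversion <- function(pfu_per_moi = 2e4, cells_per_ci = 5e3) {
  if (pfu_per_moi <= 0 || cells_per_ci <= 0) {
    stop("conversion factors must be > 0")
  }
  structure(list(pfu_per_moi = pfu_per_moi, cells_per_ci = cells_per_ci),
            class = "unit_conversion")
}

#' Convert burst size between PFU/cell and MOI/CI
#'
#' A burst size of `b` PFU per cell equals
#' `b / pfu_per_moi * cells_per_ci` MOI per CI. With the default factors the
#' literature range of 0.1 to 1e4 PFU/cell maps to 0.025 to 2500 MOI/CI.
#'
#' @param b_pfu_per_cell Burst size in PFU/cell (> 0).
#' @param conv A [unit_conversion()].
#' @return Burst size in MOI/CI.
#' @examples
#' burst_pfu_to_moi_ci(1e4)   # 2500
#' burst_pfu_to_moi_ci(0.1)   # 0.025
#' @export
burst_pfu_to_moi_ci <- function(b_pfu_per_cell, conv = unit_conversion()) {
  if (any(b_pfu_per_cell <= 0)) stop("burst size must be > 0")
  b_pfu_per_cell / conv$pfu_per_moi * conv$cells_per_ci
}

#' @rdname burst_pfu_to_moi_ci
#' @param b_moi_per_ci Burst size in MOI/CI (> 0).
#' @export
burst_moi_ci_to_pfu <- function(b_moi_per_ci, conv = unit_conversion()) {
  if (any(b_moi_per_ci <= 0)) stop("burst size must be > 0")
  b_moi_per_ci * conv$pfu_per_moi / conv$cells_per_ci
}

#' Tumor infection rate from initial rates
#'
#' Evaluating the OV module at the moment of infection links the infection
#' rate to the initial state and its derivatives:
#' `beta_TV = (b I'(0) + V'(0) + omega V(0)) / (b T(0) V(0))`.
#' With `I'(0) = 0`, taking logarithms gives the log-log relation
#' `log beta_TV = -log b + log((V'(0) + omega V(0)) / (T(0) V(0)))`:
#' the fitted infection rate is inversely proportional to the assumed burst
#' size.
#'
#' @param b Burst size (MOI/CI, > 0).
#' @param omega Virus clearance rate (1/h).
#' @param T0 Tumor burden at infection (CI, > 0).
#' @param V0 Virus dose (MOI, > 0).
#' @param V0_rate Initial virus rate of change `V'(0)` (MOI/h).
#' @param I0_rate Initial infected-cell rate of change `I'(0)` (CI/h).
#' @return The implied `beta_TV` (1/(MOI h)).
#' @examples
#' beta_from_initial_rates(b = 25, omega = 0.05, T0 = 1, V0 = 0.03)
#' @export
beta_from_initial_rates <- function(b, omega, T0, V0, V0_rate = 0,
                                    I0_rate = 0) {
  if (b <= 0 || T0 <= 0 || V0 <= 0) stop("b, T0 and V0 must be > 0")
  denom <- b * T0 * V0
  if (denom == 0) stop("zero denominator")
  (b * I0_rate + V0_rate + omega * V0) / denom
}

#' Log-log regression of infection rate on burst size
#'
#' Ordinary least squares of `log(beta_TV)` on `log(b)` for a burst-size
#' sweep. An exact inverse relationship `beta_TV = c / b` yields slope -1
#' with zero residuals.
#'
#' @param b_grid Burst sizes (positive, ascending).
#' @param beta_tv Fitted infection rates, aligned with `b_grid`.
#' @return List with `slope`, `intercept`, `max_residual`.
#' @export
loglog_relation_check <- function(b_grid, beta_tv) {
  if (length(b_grid) < 3) stop("need at least 3 grid points")
  if (length(beta_tv) != length(b_grid)) stop("length mismatch")
  if (any(b_grid <= 0) || any(beta_tv <= 0)) {
    stop("b_grid and beta_tv must be positive")
  }
  if (is.unsorted(b_grid, strictly = TRUE)) {
    stop("b_grid must be strictly ascending")
  }
  fit <- lm(log(beta_tv) ~ log(b_grid))
  list(slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       max_residual = max(abs(fit$residuals)))
}

#' Infected fraction along a trajectory
#'
#' `I(t) / (T(t) + I(t))`, with the state linearly interpolated between
#' output grid points.
#'
#' @param traj A `trajectory` from [simulate_model()].
#' @param t Evaluation time (h), within the trajectory range.
#' @return Fraction in `[0, 1]`.
#' @export
infected_fraction_at <- function(traj, t) {
  if (t < min(traj$time_h) || t > max(traj$time_h)) {
    stop("t outside the trajectory range")
  }
  T_t <- approx(traj$time_h, traj$T_ci, xout = t)$y
  I_t <- approx(traj$time_h, traj$I_ci, xout = t)$y
  tot <- T_t + I_t
  if (tot <= 0) stop("undefined fraction: T + I = 0 at t = ", t)
  min(max(I_t / tot, 0), 1)
}

#' Infected-fraction surface over burst size and clearance rate
#'
#' Simulates the OV module for every `(b, omega)` pair and evaluates the
#' infected fraction at each evaluation time. Optionally marks the cells
#' whose fraction lies within an experimental mean +/- sd band.
#'
#' @param params Base [model_params()]; `b` and `omega` are overridden per
#'   grid cell.
#' @param b_grid Burst sizes (MOI/CI, positive).
#' @param omega_grid Clearance rates (1/h, positive).
#' @param v0 Virus dose (MOI).
#' @param eval_times Evaluation times (h).
#' @param band Optional named list per evaluation time (e.g.
#'   `list("24" = c(mean, sd))`) marking cells within mean +/- sd.
#' @param t0_tumor Tumor burden at infection (CI).
#' @return Long-format data frame `b`, `omega`, `time_h`, `fraction`,
#'   `in_band` (NA without a band), `failed` (logical; integration failures
#'   are recorded, not fatal).
#' @export
infected_fraction_surface <- function(params, b_grid, omega_grid, v0,
                                      eval_times = c(24, 48), band = NULL,
                                      t0_tumor = 0.95) {
  if (any(b_grid < 0) || any(omega_grid < 0)) stop("grids must be >= 0")
  cond <- dose_condition(v0 = v0, t0_tumor = t0_tumor)
  rows <- list()
  for (b in b_grid) {
    for (om in omega_grid) {
      p <- set_params(params, b = b, omega = om)
      tr <- tryCatch(
        simulate_model("ov", p, cond, t_end = max(eval_times),
                       dt_out = 0.25),
        error = function(e) NULL)
      for (tt in eval_times) {
        frac <- if (is.null(tr)) NA_real_ else infected_fraction_at(tr, tt)
        in_band <- NA
        key <- as.character(tt)
        if (!is.null(band) && !is.null(band[[key]]) && !is.na(frac)) {
          in_band <- abs(frac - band[[key]][1]) <= band[[key]][2]
        }
        rows[[length(rows) + 1L]] <- data.frame(
          b = b, omega = om, time_h = tt, fraction = frac,
          in_band = in_band, failed = is.null(tr))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Interpolate assay fractions to new doses
#'
#' Shape-preserving (monotone Fritsch-Carlson) cubic interpolation of the
#' infected fraction against log10 dose, applied to each replicate's dose
#' series separately; the per-dose mean and standard deviation across the
#' replicate interpolants are returned. Doses span several decades, hence
#' the logarithmic abscissa. No extrapolation is performed.
#'
#' @param assay An `infected_fraction_assay` (columns `dose_moi`, `time_h`,
#'   `replicate`, `infected_fraction`).
#' @param target_doses Doses (MOI) within the measured range.
#' @return Data frame `dose_moi`, `time_h`, `mean`, `sd`.
#' @export
interp_fraction_vs_dose <- function(assay, target_doses) {
  doses <- sort(unique(assay$dose_moi))
  if (length(doses) < 4) stop("need at least 4 measured doses")
  if (any(target_doses < min(doses)) || any(target_doses > max(doses))) {
    stop("extrapolation outside the measured dose range is not supported")
  }
  rows <- list()
  for (tt in sort(unique(assay$time_h))) {
    reps <- sort(unique(assay$replicate[assay$time_h == tt]))
    per_rep <- vapply(reps, function(r) {
      sub <- assay[assay$time_h == tt & assay$replicate == r, ]
      sub <- sub[order(sub$dose_moi), ]
      f <- splinefun(log10(sub$dose_moi), sub$infected_fraction,
                     method = "monoH.FC")
      pmin(pmax(f(log10(target_doses)), 0), 1)
    }, numeric(length(target_doses)))
    per_rep <- matrix(per_rep, nrow = length(target_doses))
    rows[[length(rows) + 1L]] <- data.frame(
      dose_moi = target_doses, time_h = tt,
      mean = rowMeans(per_rep),
      sd = apply(per_rep, 1L, sd))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
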