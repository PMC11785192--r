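#' Reference generating parameter set
#'
#' The parameter values used by the synthetic-data generator as ground
#' truth. The fixed constants follow the reference calibration of the
#' impedance assay (`K = 5.2246` CI, `b = 25` MOI/CI,
#' `omega = 0.05` 1/h); the remaining rates are chosen so that the
#' simulated panel reproduces the qualitative behaviour of the in vitro
#' study at its sub-optimal doses: untreated wells plateau near `K` by
#' 96 h, each monotherapy suppresses the tumor partially and
#' dose-dependently, and every combination outperforms both of its
#' matched monotherapies.
#'
#' @return A [model_params()] object.
#' @export
default_truth_params <- function() {
  model_params(alpha = 0.08, K = 5.2246, beta_TV = 0.02, beta_CV = 0.003,
               theta_TC = 0.4, theta_IC = 1, gamma = 0.05, b = 25,
               omega = 0.05, delta = 0.01, mu = 0.02)
}

#' Noise and replicate specification
#'
#' @param sigma_rel Relative scale of the multiplicative measurement noise
#'   (dimensionless, >= 0). The impedance readout is positive with roughly
#'   proportional scatter, so noise is modelled log-normal.
#' @param n_replicates Number of replicate wells per condition (>= 1).
#' @param seed Integer seed making generation deterministic.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sigma_rel = 0.05, n_replicates = 3, seed = 1L) {
  if (sigma_rel < 0) stop("sigma_rel must be >= 0")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  structure(list(sigma_rel = sigma_rel,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Multiplicative log-normal measurement noise
#'
#' Multiplies a clean signal by `exp(rnorm(0, sigma) - sigma^2/2)` factors;
#' the `-sigma^2/2` shift makes the factors mean-one, so the noise is
#' unbiased. Uses (and advances) the current RNG state.
#'
#' @param x Clean signal values (>= 0).
#' @param sigma_rel Relative noise scale.
#' @return Noisy values, clipped at 0.
#' @export
apply_ci_noise <- function(x, sigma_rel) {
  if (sigma_rel == 0) return(x)
  pmax(x * exp(rnorm(length(x), mean = -sigma_rel^2 / 2, sd = sigma_rel)), 0)
}

condition_id <- function(condition) {
  parts <- character(0)
  if (condition$et_ratio > 0) {
    parts <- c(parts, sprintf("ET1-%g", round(1 / condition$et_ratio)))
  }
  if (condition$v0 > 0) parts <- c(parts, sprintf("OV%g", condition$v0))
  if (!length(parts)) parts <- "untreated"
  id <- paste(parts, collapse = "_")
  if (condition$t_admin_cart > 0 || condition$t_admin_ov > 0) {
    id <- sprintf("%s_dC%g_dV%g", id, condition$t_admin_cart,
                  condition$t_admin_ov)
  }
  id
}

# Clean (noiseless) observed CI trace for one condition on the full
# post-seeding grid. The first `attach_end` hours model cell attachment as a
# linear ramp from 0 to the treatment-trigger burden t0_tumor; this window
# is excluded from all fitting. Treatment impulses are applied at
# `attach_end + t_admin_*`, i.e. the trigger time is the first time the
# clean CI reaches t0_tumor (within the 0.9-1 trigger band of the assay
# protocol).
clean_ci_trace <- function(params, condition, t_max = 96, dt = 0.25,
                           attach_end = 24) {
  times <- seq(0, t_max, by = dt)
  ramp <- condition$t0_tumor * pmin(times / attach_end, 1)
  grow_t <- times[times >= attach_end] - attach_end
  model <- if (condition$et_ratio > 0 && condition$v0 > 0) "full"
  else if (condition$et_ratio > 0) "cart"
  else if (condition$v0 > 0) "ov"
  else "none"
  if (model == "none") {
    sig <- logistic_growth(grow_t, condition$t0_tumor, params[["alpha"]],
                           params[["K"]])
  } else {
    tr <- simulate_model(model, params, condition,
                         t_end = max(grow_t), dt_out = dt)
    sig <- tumor_signal(tr)
  }
  ci <- c(ramp[times < attach_end], sig)
  data.frame(time_h = times, ci = ci, attachment = times < attach_end)
}

#' Generate untreated impedance growth curves
#'
#' Emulates xCELLigence cell-index traces of untreated wells: a linear
#' 24 h attachment ramp (masked from fitting), logistic growth from the
#' trigger burden to the carrying capacity, 15-minute sampling to 96 h, and
#' multiplicative log-normal measurement noise per replicate.
#'
#' @param params A [model_params()]; `alpha` and `K` drive the growth.
#' @param noise A [noise_spec()].
#' @param t0_tumor Burden (CI) at the end of the attachment ramp.
#' @return A `ci_panel`: data frame with columns `time_h`, `ci`,
#'   `replicate`, `condition_id`, `attachment`, with per-condition metadata
#'   in the `conditions` attribute.
#' @examples
#' panel <- generate_untreated(model_params(alpha = 0.08, K = 5.2246),
#'                             noise_spec(sigma_rel = 0, n_replicates = 1))
#' @export
generate_untreated <- function(params, noise = noise_spec(),
                               t0_tumor = 0.95) {
  generate_treatment_panel(params,
                           list(dose_condition(t0_tumor = t0_tumor)), noise)
}

#' Generate a panel of treated impedance time series
#'
#' For each dosing condition, simulates the matching model (CAR T module,
#' OV module, or full model) from the treatment trigger, observes the tumor
#' signal `T + I` (the impedance readout cannot distinguish infected from
#' non-infected adherent cells), prepends the masked attachment ramp, and
#' applies multiplicative log-normal noise per replicate. Replicate noise
#' streams are seeded deterministically from `noise$seed`, the condition
#' index and the replicate index.
#'
#' @param params A [model_params()] (the generating truth).
#' @param conditions List of [dose_condition()] objects.
#' @param noise A [noise_spec()].
#' @param t_max,dt,attach_end Grid extent (h), spacing (h) and attachment
#'   window length (h).
#' @return A `ci_panel` (see [generate_untreated()]).
#' @export
generate_treatment_panel <- function(params, conditions,
                                     noise = noise_spec(),
                                     t_max = 96, dt = 0.25,
                                     attach_end = 24) {
  stopifnot(is.list(conditions), length(conditions) >= 1)
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)

  meta <- list()
  rows <- list()
  for (i in seq_along(conditions)) {
    cond <- conditions[[i]]
    stopifnot(inherits(cond, "dose_condition"))
    id <- condition_id(cond)
    clean <- clean_ci_trace(params, cond, t_max = t_max, dt = dt,
                            attach_end = attach_end)
    meta[[id]] <- list(condition = cond, attach_end = attach_end,
                       t_treat = attach_end)
    for (r in seq_len(noise$n_replicates)) {
      set.seed(noise$seed + 7919L * (i - 1L) + r)
      rows[[length(rows) + 1L]] <- data.frame(
        time_h = clean$time_h,
        ci = apply_ci_noise(clean$ci, noise$sigma_rel),
        replicate = r,
        condition_id = id,
        attachment = clean$attachment)
    }
  }
  panel <- do.call(rbind, rows)
  rownames(panel) <- NULL
  structure(panel, conditions = meta, params = params,
            class = c("ci_panel", "data.frame"))
}

#' @export
print.ci_panel <- function(x, ...) {
  meta <- attr(x, "conditions")
  cat(sprintf("<ci_panel> %d condition(s) x %d replicate(s), %d rows\n",
              length(meta), length(unique(x$replicate)), nrow(x)))
  cat("conditions:", paste(names(meta), collapse = ", "), "\n")
  invisible(x)
}

#' Subset one replicate series from a panel
#'
#' @param panel A `ci_panel`.
#' @param id Condition id (see panel printout).
#' @param replicate Replicate number.
#' @return Data frame `time_h`, `ci`, `attachment` with the condition
#'   metadata attached.
#' @export
panel_series <- function(panel, id, replicate) {
  meta <- attr(panel, "conditions")[[id]]
  if (is.null(meta)) stop("unknown condition id: ", id)
  out <- panel[panel$condition_id == id & panel$replicate == replicate,
               c("time_h", "ci", "attachment")]
  if (!nrow(out)) stop("no rows for replicate ", replicate)
  rownames(out) <- NULL
  structure(out, condition = meta$condition, attach_end = meta$attach_end,
            t_treat = meta$t_treat)
}

#' Generate an infected-cell-fraction assay table
#'
#' Simulates the OV module for each virus dose and reports the infected
#' fraction `I/(T+I)` at the evaluation times, in duplicate (or
#' `noise$n_replicates`) with additive truncated-Gaussian noise of standard
#' deviation `noise$sigma_rel` on the fraction scale.
#'
#' @param params A [model_params()] with the OV-module rates set.
#' @param doses Virus doses (MOI).
#' @param noise A [noise_spec()]; `n_replicates` defaults to duplicate
#'   wells.
#' @param eval_times Assay read times (h after infection).
#' @param t0_tumor Tumor burden (CI) at infection.
#' @return An `infected_fraction_assay`: data frame with columns
#'   `dose_moi`, `time_h`, `replicate`, `infected_fraction`.
#' @export
generate_infected_fraction_assay <- function(params,
                                             doses = c(0.0005, 0.001, 0.01,
                                                       0.1, 1),
                                             noise = noise_spec(
                                               n_replicates = 2),
                                             eval_times = c(24, 48),
                                             t0_tumor = 0.95) {
  if (any(doses < 0)) stop("doses must be >= 0")
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(noise$seed)

  rows <- list()
  for (d in doses) {
    if (d == 0) {
      frac <- rep(0, length(eval_times))
    } else {
      tr <- simulate_model("ov", params,
                           dose_condition(v0 = d, t0_tumor = t0_tumor),
                           t_end = max(eval_times), dt_out = 0.25)
      frac <- vapply(eval_times, function(tt) infected_fraction_at(tr, tt),
                     numeric(1))
    }
    for (r in seq_len(noise$n_replicates)) {
      eps <- if (noise$sigma_rel > 0) {
        rnorm(length(eval_times), 0, noise$sigma_rel)
      } else 0
      rows[[length(rows) + 1L]] <- data.frame(
        dose_moi = d, time_h = eval_times, replicate = r,
        infected_fraction = pmin(pmax(frac + eps, 0), 1))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, params = params, seed = noise$seed,
            class = c("infected_fraction_assay", "data.frame"))
}
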