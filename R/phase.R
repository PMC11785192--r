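#' Non-dimensionalize the CAR T module
#'
#' Scaling `Y1 = T/K`, `Y2 = (theta_TC/alpha) C`, `tau = alpha t` reduces the
#' predator-prey CAR T module to
#' `Y1' = Y1(1 - Y1) - Y1 Y2`, `Y2' = -A Y2 + B Y1 Y2` with
#' `A = delta/alpha` (scaled CAR T death rate) and `B = mu K / alpha`
#' (scaled CAR T expansion rate).
#'
#' @param params A [model_params()] with `alpha > 0`.
#' @return An object of class `scaled_cart_params`: list with `A` and `B`.
#' @examples
#' nondim_cart(model_params(alpha = 0.05, K = 5.2, delta = 0.029,
#'                          mu = 0.00025))
#' @export
nondim_cart <- function(params) {
  validate_params(params)
  if (params[["alpha"]] <= 0) stop("scaling undefined: alpha must be > 0")
  scaled_cart_params(A = params[["delta"]] / params[["alpha"]],
                     B = params[["mu"]] * params[["K"]] / params[["alpha"]])
}

#' @param A Scaled CAR T death rate (dimensionless, >= 0).
#' @param B Scaled CAR T expansion rate (dimensionless; sign follows `mu`).
#' @rdname nondim_cart
#' @export
scaled_cart_params <- function(A, B) {
  if (!is.finite(A) || !is.finite(B)) stop("A and B must be finite")
  if (A < 0) stop("A must be >= 0")
  structure(list(A = A, B = B), class = "scaled_cart_params")
}

#' Non-dimensionalize the OV module
#'
#' Scaling `y1 = T/K`, `y2 = I/K`, `y3 = (beta_TV/alpha) V`, `tau = alpha t`
#' reduces the SIR-type virus module to `y1' = y1(1 - y1 - y2) - y1 y3`,
#' `y2' = y1 y3 - D y2`, `y3' = E y2 - F y3` with `D = gamma/alpha` (scaled
#' lysis rate), `E = gamma b beta_TV K / alpha^2` (scaled viral production
#' strength) and `F = omega/alpha` (scaled clearance rate).
#'
#' @param params A [model_params()] with `alpha > 0`.
#' @return An object of class `scaled_ov_params`: list with `D`, `E`, `F`.
#' @export
nondim_ov <- function(params) {
  validate_params(params)
  a <- params[["alpha"]]
  if (a <= 0) stop("scaling undefined: alpha must be > 0")
  scaled_ov_params(
    D = params[["gamma"]] / a,
    E = params[["gamma"]] * params[["b"]] * params[["beta_TV"]] *
      params[["K"]] / a^2,
    F = params[["omega"]] / a)
}

#' @param D Scaled lysis rate (>= 0).
#' @param E Scaled viral production strength (>= 0).
#' @param F Scaled clearance rate (>= 0).
#' @rdname nondim_ov
#' @export
scaled_ov_params <- function(D, E, F) {
  vals <- c(D = D, E = E, F = F)
  if (any(!is.finite(vals))) stop("D, E, F must be finite")
  if (any(vals < 0)) stop("D, E, F must be >= 0")
  structure(list(D = D, E = E, F = F), class = "scaled_ov_params")
}

stability_label <- function(eig, tol = 1e-9) {
  re <- Re(eig)
  if (max(re) < -tol) "stable"
  else if (max(re) > tol) "unstable"
  else "center"
}

#' Equilibria of the scaled CAR T module
#'
#' The extinction point (0, 0) and the tumor-only point (1, 0) always exist;
#' a coexistence point `(A/B, 1 - A/B)` exists in the non-negative quadrant
#' iff `0 < A/B <= 1` (i.e. `B >= A > 0`). Stability is labelled from the
#' eigenvalues of the Jacobian. For `A = 0`, `B > 0` the `Y1 = 0` axis is a
#' degenerate line of equilibria, flagged via the `degenerate_line`
#' attribute.
#'
#' @param scaled A [scaled_cart_params()].
#' @return Data frame with columns `Y1`, `Y2`, `stability`; attribute
#'   `degenerate_line` is `TRUE` in the degenerate case.
#' @examples
#' equilibria_cart(scaled_cart_params(A = 0.58, B = 0.026))  # 2 equilibria
#' equilibria_cart(scaled_cart_params(A = 0.58, B = 1.31))   # 3 equilibria
#' @export
equilibria_cart <- function(scaled) {
  stopifnot(inherits(scaled, "scaled_cart_params"))
  A <- scaled$A; B <- scaled$B
  pts <- list(c(0, 0), c(1, 0))
  if (B != 0) {
    y1 <- A / B
    if (y1 > 0 && y1 < 1) pts <- c(pts, list(c(y1, 1 - y1)))
    # A/B == 1 coincides with (1, 0); A = 0 handled as degenerate line
  }
  jac <- function(y) {
    matrix(c(1 - 2 * y[1] - y[2], -y[1],
             B * y[2], -A + B * y[1]),
           nrow = 2, byrow = TRUE)
  }
  out <- do.call(rbind, lapply(pts, function(y) {
    data.frame(Y1 = y[1], Y2 = y[2],
               stability = stability_label(eigen(jac(y),
                                                 only.values = TRUE)$values))
  }))
  attr(out, "degenerate_line") <- (A == 0 && B > 0)
  out
}

#' Equilibria of the scaled OV module
#'
#' The extinction point (0, 0, 0) and the tumor-only point (1, 0, 0) always
#' exist. An endemic (persistent-infection) equilibrium with
#' `y1* = D F / E` exists iff `E > D F`; its remaining coordinates follow
#' from the nullclines: `y2* = F (1 - y1*) / (E + F)`, `y3* = (E/F) y2*`.
#' Stability is labelled from the Jacobian eigenvalues.
#'
#' @param scaled A [scaled_ov_params()].
#' @return Data frame with columns `y1`, `y2`, `y3`, `stability`.
#' @examples
#' equilibria_ov(scaled_ov_params(D = 0.58, E = 1, F = 0.48))  # 3 equilibria
#' @export
equilibria_ov <- function(scaled) {
  stopifnot(inherits(scaled, "scaled_ov_params"))
  D <- scaled$D; E <- scaled$E; F <- scaled$F
  pts <- list(c(0, 0, 0), c(1, 0, 0))
  if (E > 0 && E > D * F) {
    y1 <- D * F / E
    y2 <- F * (1 - y1) / (E + F)
    y3 <- E * y2 / F
    pts <- c(pts, list(c(y1, y2, y3)))
  }
  out <- do.call(rbind, lapply(pts, function(y) {
    data.frame(y1 = y[1], y2 = y[2], y3 = y[3],
               stability = stability_label(
                 eigen(jac_ov_scaled(y, D, E, F),
                       only.values = TRUE)$values))
  }))
  out
}

jac_ov_scaled <- function(y, D, E, F) {
  matrix(c(1 - 2 * y[1] - y[2] - y[3], -y[1], -y[1],
           y[3], -D, y[1],
           0, E, -F),
         nrow = 3, byrow = TRUE)
}

#' Endemic-existence threshold of the scaled OV module
#'
#' The endemic equilibrium exists iff `E` exceeds `D * F`; in the original
#' parameters this is the basic-reproduction-style condition
#' `b beta_TV K / omega > 1`.
#'
#' @param scaled A [scaled_ov_params()].
#' @return The threshold `D * F`.
#' @export
endemic_threshold_ov <- function(scaled) {
  scaled$D * scaled$F
}

#' Hopf threshold of the endemic OV equilibrium
#'
#' Locates, by bisection in `E`, the value at which the endemic equilibrium
#' loses stability (largest real part of its Jacobian eigenvalues crosses
#' zero). Past this threshold the infection dynamics settle on a limit cycle
#' rather than the endemic point.
#'
#' @param D,F Scaled lysis and clearance rates.
#' @param E_range Search bracket for `E`; must bracket a sign change of the
#'   leading eigenvalue real part.
#' @param tol Bisection tolerance on `E`.
#' @return The critical `E` value.
#' @export
hopf_threshold_ov <- function(D, F, E_range = NULL, tol = 1e-6) {
  lead <- function(E) {
    eq <- equilibria_ov(scaled_ov_params(D, E, F))
    en <- eq[nrow(eq), ]
    max(Re(eigen(jac_ov_scaled(c(en$y1, en$y2, en$y3), D, E, F),
                 only.values = TRUE)$values))
  }
  if (is.null(E_range)) {
    lo <- D * F * 1.001
    hi <- D * F * 2
    while (lead(hi) < 0 && hi < D * F * 1e6) hi <- hi * 2
    E_range <- c(lo, hi)
  }
  f_lo <- lead(E_range[1]); f_hi <- lead(E_range[2])
  if (f_lo * f_hi > 0) stop("E_range does not bracket the Hopf threshold")
  while (diff(E_range) > tol) {
    mid <- mean(E_range)
    if (lead(mid) * f_lo <= 0) E_range[2] <- mid else {
      E_range[1] <- mid; f_lo <- lead(E_range[1])
    }
  }
  mean(E_range)
}

#' Simulate the scaled OV module
#'
#' @param scaled A [scaled_ov_params()].
#' @param y0 Initial state `(y1, y2, y3)`.
#' @param tau_end Horizon in scaled time.
#' @param dtau_out Output spacing.
#' @return Data frame `tau`, `y1`, `y2`, `y3`.
#' @export
simulate_scaled_ov <- function(scaled, y0, tau_end, dtau_out = 0.1) {
  stopifnot(inherits(scaled, "scaled_ov_params"))
  times <- seq(0, tau_end, by = dtau_out)
  out <- deSolve::lsoda(
    y = c(y1 = y0[1], y2 = y0[2], y3 = y0[3]), times = times,
    func = "cartov_deriv_ov_scaled",
    parms = c(scaled$D, scaled$E, scaled$F),
    dllname = "cartov", initfunc = "cartov_init3",
    rtol = 1e-8, atol = 1e-10, maxsteps = 20000)
  as.data.frame(out)[, c("time", "y1", "y2", "y3")] |>
    setNames(c("tau", "y1", "y2", "y3"))
}

#' Limit-cycle detection in the scaled OV module
#'
#' Simulates from a 5% perturbation of the endemic equilibrium (or from an
#' interior point if no endemic equilibrium exists), discards the first half
#' of the horizon as transient, and classifies the dynamics as
#' `"oscillates"` when the post-transient peak-to-peak amplitude of `y1`
#' exceeds `amp_tol`, else `"converges"`.
#'
#' @param scaled A [scaled_ov_params()].
#' @param horizon Scaled-time horizon (first half discarded as transient).
#' @param amp_tol Peak-to-peak amplitude threshold on `y1`.
#' @return List with `classification` (`"oscillates"` or `"converges"`) and
#'   `amplitude` (post-transient peak-to-peak range of `y1`).
#' @examples
#' detect_limit_cycle(scaled_ov_params(D = 0.58, E = 3.5, F = 0.48))
#' @export
detect_limit_cycle <- function(scaled, horizon = 3000, amp_tol = 1e-3) {
  eq <- equilibria_ov(scaled)
  if (nrow(eq) >= 3) {
    en <- as.numeric(eq[3, c("y1", "y2", "y3")])
    y0 <- en * 1.05
  } else {
    y0 <- c(0.5, 0.1, 0.1)
  }
  tr <- simulate_scaled_ov(scaled, y0, tau_end = horizon, dtau_out = 0.25)
  post <- tr[tr$tau >= horizon / 2, ]
  amp <- diff(range(post$y1))
  list(classification = if (amp > amp_tol) "oscillates" else "converges",
       amplitude = amp)
}
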