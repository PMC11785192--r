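#' Model parameter set
#'
#' Construct and validate the named parameter set of the tumor / CAR T /
#' oncolytic virus model. All rates are per hour; cell burdens are in
#' cell-index (CI) units and virus in multiplicity-of-infection (MOI) units,
#' following the impedance-assay convention.
#'
#' @param alpha Tumor proliferation rate (1/h).
#' @param K Tumor carrying capacity (CI). Must be positive.
#' @param beta_TV Tumor infection rate by the virus (1/(MOI h)).
#' @param beta_CV CAR T-cell infection rate by the virus (1/(MOI h)).
#' @param theta_TC CAR T kill rate of non-infected tumor cells (1/(CI h)).
#' @param theta_IC CAR T kill rate of infected tumor cells (1/(CI h)).
#' @param gamma Infected-cell lysis rate (1/h).
#' @param b Virus burst size (MOI/CI): free virus released per CI of lysed
#'   infected cells.
#' @param omega Virus clearance rate (1/h).
#' @param delta CAR T-cell death rate (1/h).
#' @param mu CAR T expansion/exhaustion rate (1/(CI h)). May be negative:
#'   it is the net of stimulation and exhaustion on tumor contact.
#'
#' @return An object of class `model_params`: a named numeric vector of the
#'   11 parameters in a fixed order.
#' @examples
#' p <- model_params(alpha = 0.08, K = 5.2246, beta_TV = 0.1, gamma = 0.05,
#'                   b = 25, omega = 0.05, theta_TC = 0.4, delta = 0.01,
#'                   mu = 0.02)
#' p["K"]
#' @export
model_params <- function(alpha = 0.08, K = 5.2246,
                         beta_TV = 0, beta_CV = 0,
                         theta_TC = 0, theta_IC = 0,
                         gamma = 0, b = 0, omega = 0,
                         delta = 0, mu = 0) {
  p <- c(alpha = alpha, K = K, beta_TV = beta_TV, beta_CV = beta_CV,
         theta_TC = theta_TC, theta_IC = theta_IC, gamma = gamma,
         b = b, omega = omega, delta = delta, mu = mu)
  validate_params(p)
  class(p) <- c("model_params", "numeric")
  p
}

param_names <- function() {
  c("alpha", "K", "beta_TV", "beta_CV", "theta_TC", "theta_IC",
    "gamma", "b", "omega", "delta", "mu")
}

validate_params <- function(p) {
  nm <- param_names()
  if (!all(nm %in% names(p))) {
    stop("model_params must contain: ", paste(setdiff(nm, names(p)),
                                              collapse = ", "))
  }
  if (any(!is.finite(p[nm]))) {
    stop("all model parameters must be finite")
  }
  nonneg <- setdiff(nm, "mu")
  if (any(p[nonneg] < 0)) {
    bad <- nonneg[p[nonneg] < 0]
    stop("parameter(s) must be >= 0: ", paste(bad, collapse = ", "))
  }
  if (p[["K"]] <= 0) stop("K must be > 0")
  invisible(p)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named values replaced, re-validated.
#'
#' @param params A [model_params()] object.
#' @param ... Named scalar replacements, e.g. `b = 250`.
#' @return A `model_params` object.
#' @export
set_params <- function(params, ...) {
  repl <- c(...)
  if (length(repl)) {
    unknown <- setdiff(names(repl), param_names())
    if (length(unknown)) stop("unknown parameter(s): ",
                              paste(unknown, collapse = ", "))
    params[names(repl)] <- repl
  }
  validate_params(params)
  class(params) <- c("model_params", "numeric")
  params
}

#' Dosing condition for one well
#'
#' Describes how a well is treated: the effector-to-target (E:T) ratio of the
#' CAR T dose, the initial virus dose, when each agent is administered
#' (hours after the treatment reference time), and the tumor burden at the
#' treatment reference.
#'
#' @param et_ratio CAR T effector-to-target ratio as a fraction, e.g. `1/25`
#'   for the 1:25 condition; 0 means no CAR T-cells.
#' @param v0 Initial virus dose (MOI); 0 means no virus.
#' @param t_admin_cart CAR T administration time (h, >= 0).
#' @param t_admin_ov Virus administration time (h, >= 0).
#' @param t0_tumor Tumor burden (CI) at the treatment reference time; the
#'   impedance protocol treats when the cell index reaches about 0.9-1.
#' @return An object of class `dose_condition` (named list).
#' @examples
#' dose_condition(et_ratio = 1/25, v0 = 0.002)
#' @export
dose_condition <- function(et_ratio = 0, v0 = 0, t_admin_cart = 0,
                           t_admin_ov = 0, t0_tumor = 0.95) {
  if (et_ratio < 0) stop("et_ratio must be >= 0")
  if (v0 < 0) stop("v0 must be >= 0")
  if (t_admin_cart < 0 || t_admin_ov < 0) {
    stop("administration times must be >= 0")
  }
  if (t0_tumor <= 0) stop("t0_tumor must be > 0")
  structure(list(et_ratio = et_ratio, v0 = v0,
                 t_admin_cart = t_admin_cart, t_admin_ov = t_admin_ov,
                 t0_tumor = t0_tumor),
            class = "dose_condition")
}

#' CAR T dose in cell-index units
#'
#' The CAR T inoculum for a condition, converted to the model's CI scale:
#' `et_ratio * t0_tumor`. The E:T ratio counts effector cells per tumor cell,
#' and both populations share the same cells-per-CI factor, so the factor
#' cancels.
#'
#' @param condition A [dose_condition()].
#' @return CAR T dose in CI units.
#' @export
cart_dose_ci <- function(condition) {
  condition$et_ratio * condition$t0_tumor
}

#' @export
print.dose_condition <- function(x, ...) {
  et <- if (x$et_ratio > 0) sprintf("1:%g", 1 / x$et_ratio) else "none"
  cat(sprintf(
    "<dose_condition> E:T %s (t=%g h), V0 %g MOI (t=%g h), T0 %g CI\n",
    et, x$t_admin_cart, x$v0, x$t_admin_ov, x$t0_tumor))
  invisible(x)
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  print(unclass(x))
  invisible(x)
}

#' Read / write a parameter set as JSON
#'
#' Parameter sets are serialized as a flat JSON map keyed by the parameter
#' symbol names (alpha, K, beta_TV, ...), units as in the model definition.
#'
#' @param params A [model_params()] object.
#' @param path File path.
#' @return `write_params_json` returns `path` invisibly; `read_params_json`
#'   returns a `model_params` object.
#' @export
write_params_json <- function(params, path) {
  jsonlite::write_json(as.list(unclass(params)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(model_params, as.list(x[param_names()]))
}
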