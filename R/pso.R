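#' Particle swarm optimizer configuration
#'
#' Hyperparameters of the global-best particle swarm used for calibration.
#' Defaults are standard global-best settings: inertia 0.7 with cognitive
#' and social weights 1.5.
#'
#' @param swarm_size Number of particles (>= 2).
#' @param max_iters Maximum iterations.
#' @param inertia Inertia weight.
#' @param c_cognitive Cognitive (personal-best) acceleration weight.
#' @param c_social Social (global-best) acceleration weight.
#' @param seed Integer seed; every PSO run is reproducible from it.
#' @param tol_rel Relative-improvement threshold for early stopping.
#' @param patience Iterations without relative improvement `> tol_rel`
#'   before stopping.
#' @return An object of class `pso_config`.
#' @export
pso_config <- function(swarm_size = 50, max_iters = 300, inertia = 0.7,
                       c_cognitive = 1.5, c_social = 1.5, seed = 1L,
                       tol_rel = 1e-8, patience = 30) {
  if (swarm_size < 2) stop("swarm_size must be >= 2")
  if (any(c(inertia, c_cognitive, c_social) < 0)) {
    stop("PSO weights must be >= 0")
  }
  structure(list(swarm_size = as.integer(swarm_size),
                 max_iters = as.integer(max_iters), inertia = inertia,
                 c_cognitive = c_cognitive, c_social = c_social,
                 seed = as.integer(seed), tol_rel = tol_rel,
                 patience = as.integer(patience)),
            class = "pso_config")
}

#' Global-best particle swarm minimization
#'
#' Minimizes `fn` over a box by a standard global-best particle swarm with
#' inertia, cognitive and social velocity updates and reflective boundary
#' handling. Particles whose objective evaluates non-finite are assigned
#' `+Inf` rather than aborting the run. The run terminates at `max_iters`
#' or once the relative improvement of the best value stays below
#' `tol_rel` for `patience` consecutive iterations. The global RNG state is
#' saved and restored, so a run is a pure function of its inputs and seed.
#'
#' @param fn Objective: takes a numeric vector, returns a scalar.
#' @param lower,upper Finite bound vectors of equal length.
#' @param config A [pso_config()].
#' @return List with `par` (best position), `value` (best objective),
#'   `history` (best value per iteration, non-increasing), and the final
#'   per-particle bests `pbest` / `pbest_val` (useful as starts for local
#'   refinement).
#' @examples
#' res <- pso_minimize(function(x) sum(x^2), rep(-5, 3), rep(5, 3),
#'                     pso_config(seed = 7))
#' res$value
#' @export
pso_minimize <- function(fn, lower, upper, config = pso_config()) {
  stopifnot(length(lower) == length(upper))
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    stop("bounds must be finite")
  }
  if (any(lower >= upper)) stop("each lower bound must be < its upper bound")
  d <- length(lower)
  n <- config$swarm_size
  span <- upper - lower

  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  eval_fn <- function(x) {
    v <- tryCatch(fn(x), error = function(e) Inf)
    if (!is.finite(v)) Inf else v
  }

  pos <- matrix(runif(n * d, rep(lower, each = n), rep(upper, each = n)),
                nrow = n)
  vel <- matrix(runif(n * d, rep(-span, each = n), rep(span, each = n)),
                nrow = n) * 0.1
  val <- apply(pos, 1L, eval_fn)
  pbest <- pos
  pbest_val <- val
  g <- which.min(val)
  gbest <- pos[g, ]
  gbest_val <- val[g]

  history <- numeric(0)
  stall <- 0L
  for (iter in seq_len(config$max_iters)) {
    r1 <- matrix(runif(n * d), nrow = n)
    r2 <- matrix(runif(n * d), nrow = n)
    vel <- config$inertia * vel +
      config$c_cognitive * r1 * (pbest - pos) +
      config$c_social * r2 * sweep(pos, 2L, gbest, function(p, g) g - p)
    pos <- pos + vel
    # reflective boundaries
    for (j in seq_len(d)) {
      below <- pos[, j] < lower[j]
      above <- pos[, j] > upper[j]
      pos[below, j] <- pmin(2 * lower[j] - pos[below, j], upper[j])
      pos[above, j] <- pmax(2 * upper[j] - pos[above, j], lower[j])
      vel[below | above, j] <- -vel[below | above, j]
    }
    val <- apply(pos, 1L, eval_fn)
    improved <- val < pbest_val
    pbest[improved, ] <- pos[improved, , drop = FALSE]
    pbest_val[improved] <- val[improved]
    g <- which.min(pbest_val)
    prev_best <- gbest_val
    if (pbest_val[g] < gbest_val) {
      gbest_val <- pbest_val[g]
      gbest <- pbest[g, ]
    }
    history <- c(history, gbest_val)
    rel_impr <- if (is.finite(prev_best) && prev_best != 0) {
      (prev_best - gbest_val) / abs(prev_best)
    } else if (prev_best == 0) 0 else Inf
    stall <- if (rel_impr > config$tol_rel) 0L else stall + 1L
    if (stall >= config$patience) break
  }
  list(par = gbest, value = gbest_val, history = history,
       pbest = pbest, pbest_val = pbest_val)
}
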