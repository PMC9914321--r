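#' Particle swarm optimizer settings
#'
#' Canonical inertia-weight PSO. Each particle carries a position x and
#' velocity v over the tuned parameters; per iteration
#'
#'   v' = w*v + c1*r1*(xBest - x) + c2*r2*(gBest - x)
#'   x' = x + v'
#'
#' with r1, r2 uniform in \[0, 1\] drawn per component, xBest the
#' particle's personal best and gBest the swarm best. Velocities are capped
#' componentwise at `v_max_frac` of the bound span; positions are clipped
#' into bounds with the velocity component zeroed at the violated wall.
#'
#' @param swarm_size Number of particles (default 30).
#' @param iterations Number of update iterations after the initial
#'   evaluation (default 10).
#' @param w Inertia weight (default 0.7).
#' @param c1,c2 Cognitive and social acceleration constants (default 1.5).
#' @param v_max_frac Velocity cap as a fraction of each bound span
#'   (default 0.2).
#' @param seed Integer seed; every run is fully reproducible given the seed.
#' @param elitist_init Seed one particle at a caller-supplied starting
#'   position (see `init` in [pso_maximize()]); guarantees the optimized
#'   fitness is at least the starting point's fitness.
#' @return An object of class `pso_config`.
#' @export
pso_config <- function(swarm_size = 30L, iterations = 10L,
                       w = 0.7, c1 = 1.5, c2 = 1.5,
                       v_max_frac = 0.2, seed = 1L, elitist_init = TRUE) {
  swarm_size <- as.integer(swarm_size); iterations <- as.integer(iterations)
  stopifnot(swarm_size >= 2L, iterations >= 1L, c1 > 0, c2 > 0,
            v_max_frac > 0)
  structure(list(swarm_size = swarm_size, iterations = iterations,
                 w = w, c1 = c1, c2 = c2, v_max_frac = v_max_frac,
                 seed = as.integer(seed), elitist_init = isTRUE(elitist_init)),
            class = "pso_config")
}

#' PSO velocity update
#'
#' One velocity step for a single particle, exposed for inspection and
#' testing; [pso_maximize()] applies the same rule swarm-wide.
#'
#' @param velocity,position,pbest,gbest Numeric vectors of equal length.
#' @param cfg A [pso_config].
#' @param v_max Componentwise velocity cap.
#' @param r1,r2 Uniform draws in \[0, 1\] (vectors recycled to the
#'   parameter dimension); supplied by the optimizer from its seeded
#'   stream, or fixed here for deterministic checks.
#' @return The updated, capped velocity vector.
#' @export
pso_update_velocity <- function(velocity, position, pbest, gbest, cfg,
                                v_max, r1 = stats::runif(length(position)),
                                r2 = stats::runif(length(position))) {
  d <- length(position)
  if (length(velocity) != d || length(pbest) != d || length(gbest) != d) {
    stop("velocity, position, pbest and gbest must share a dimension",
         call. = FALSE)
  }
  v <- cfg$w * velocity + cfg$c1 * r1 * (pbest - position) +
    cfg$c2 * r2 * (gbest - position)
  clamp(v, -v_max, v_max)
}

#' PSO position update
#'
#' Unit-time-step move `x' = x + v`, clipped into bounds with absorbing
#' walls: a component clipped at a bound has its velocity zeroed.
#'
#' @param position,velocity Numeric vectors of equal length.
#' @param lower,upper Bound vectors.
#' @return List with the new `position` and (possibly zeroed) `velocity`.
#' @export
pso_update_position <- function(position, velocity, lower, upper) {
  x <- position + velocity
  hit <- x < lower | x > upper
  x <- clamp(x, lower, upper)
  velocity[hit] <- 0
  list(position = x, velocity = velocity)
}

#' Maximize an objective with particle swarm optimization
#'
#' Positions are initialized uniformly within bounds (optionally with one
#' elitist particle at `init`), velocities at zero; the initial evaluation
#' counts as iteration 0 and is followed by `cfg$iterations` update sweeps.
#' gBest is updated greedily, so its fitness trace is non-decreasing by
#' construction.
#'
#' @param objective Function taking a parameter vector, returning a scalar
#'   to maximize.
#' @param lower,upper Numeric bound vectors (one entry per tuned
#'   parameter); names are carried onto the result.
#' @param cfg A [pso_config].
#' @param init Optional starting position for the elitist particle
#'   (ignored unless `cfg$elitist_init`); clipped into bounds.
#' @return An object of class `pso_result`: `best_position`,
#'   `best_fitness`, `gbest_trace` (length `iterations + 1`, including the
#'   initial evaluation), `seed`.
#' @examples
#' res <- pso_maximize(function(x) -(x - 0.3)^2, 0, 1,
#'                     pso_config(iterations = 50, seed = 7))
#' res$best_position
#' @export
pso_maximize <- function(objective, lower, upper, cfg = pso_config(),
                         init = NULL) {
  stopifnot(inherits(cfg, "pso_config"))
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  d <- length(lower)
  if (length(upper) != d || any(lower >= upper)) {
    stop("bounds must satisfy lower < upper per parameter", call. = FALSE)
  }
  v_max <- cfg$v_max_frac * (upper - lower)
  n <- cfg$swarm_size

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(cfg$seed)

  # rows = particles
  pos <- matrix(runif(n * d, rep(lower, each = n), rep(upper, each = n)),
                n, d)
  if (cfg$elitist_init && !is.null(init)) {
    pos[1L, ] <- clamp(as.numeric(init), lower, upper)
  }
  vel <- matrix(0, n, d)

  fit <- apply(pos, 1L, objective)
  pbest <- pos; pbest_fit <- fit
  g <- which.max(pbest_fit)
  gbest <- pbest[g, ]; gbest_fit <- pbest_fit[g]
  trace <- numeric(cfg$iterations + 1L)
  trace[1L] <- gbest_fit

  for (it in seq_len(cfg$iterations)) {
    for (i in seq_len(n)) {
      vel[i, ] <- pso_update_velocity(vel[i, ], pos[i, ], pbest[i, ], gbest,
                                      cfg, v_max)
      upd <- pso_update_position(pos[i, ], vel[i, ], lower, upper)
      pos[i, ] <- upd$position; vel[i, ] <- upd$velocity
    }
    fit <- apply(pos, 1L, objective)
    better <- fit > pbest_fit
    pbest[better, ] <- pos[better, , drop = FALSE]
    pbest_fit[better] <- fit[better]
    g <- which.max(pbest_fit)
    if (pbest_fit[g] > gbest_fit) {
      gbest <- pbest[g, ]; gbest_fit <- pbest_fit[g]
    }
    trace[it + 1L] <- gbest_fit
  }

  best <- stats::setNames(gbest, names(lower))
  structure(list(best_position = best, best_fitness = gbest_fit,
                 gbest_trace = trace, seed = cfg$seed),
            class = "pso_result")
}

#' @export
print.pso_result <- function(x, ...) {
  cat(sprintf("<pso_result fitness=%.4f after %d iterations, seed=%d>\n",
              x$best_fitness, length(x$gbest_trace) - 1L, x$seed))
  if (!is.null(x$best_params)) print(x$best_params)
  invisible(x)
}

#' EME fitness of an S-curve candidate
#'
#' Substitutes a candidate parameter vector (named subset of
#' `alpha`/`beta`/`gamma`/`delta`) into `base`, enhances the normalized
#' image with the configured S-curve (local, tiled, blended by default),
#' de-normalizes to the raw scale and returns the [eme()] of the result.
#' This is the objective the swarm maximizes.
#'
#' @param img Normalized [gray_image].
#' @param candidate Named numeric vector of tuned parameter values.
#' @param base An [scurve_params] supplying the untuned constants.
#' @param tiles,blend,local S-curve application mode (defaults: local,
#'   8 x 8 grid, blended).
#' @return EME of the enhanced image (dB).
#' @export
scurve_fitness <- function(img, candidate, base = scurve_params(),
                           tiles = 8L, blend = TRUE, local = TRUE) {
  p <- substitute_params(base, candidate)
  enh <- if (local) scurve_local(img, p, tiles = tiles, blend = blend)
         else scurve_global(img, p)
  eme(denormalize(enh))
}

substitute_params <- function(base, candidate) {
  stopifnot(inherits(base, "scurve_params"))
  nm <- names(candidate)
  if (is.null(nm) || !all(nm %in% c("alpha", "beta", "gamma", "delta"))) {
    stop("candidate must be named with a subset of alpha/beta/gamma/delta",
         call. = FALSE)
  }
  vals <- unclass(base)
  vals[nm] <- as.numeric(candidate)
  scurve_params(vals$alpha, vals$beta, vals$gamma, vals$delta)
}

#' Tune S-curve parameters by PSO against EME
#'
#' Runs [pso_maximize()] over the selected S-curve parameters (by default
#' the two asymptote constants alpha and beta, searched in \[0.5, 1\] and
#' \[0, 0.5\]) with [scurve_fitness()] as the objective. With elitist
#' initialization (default) one particle starts at `base`'s values of the
#' tuned parameters, so the optimized EME can never fall below the
#' fixed-parameter EME.
#'
#' @inheritParams scurve_fitness
#' @param cfg A [pso_config] (defaults: swarm 30, 10 iterations).
#' @param bounds Named list of `c(low, high)` per tuned parameter.
#' @return A `pso_result` whose `best_params` is the full [scurve_params]
#'   with the tuned values substituted in.
#' @export
optimize_scurve <- function(img, base = scurve_params(), cfg = pso_config(),
                            bounds = list(alpha = c(0.5, 1), beta = c(0, 0.5)),
                            tiles = 8L, blend = TRUE, local = TRUE) {
  stopifnot(is_gray_image(img))
  if (img$range != "normalized") {
    stop("optimize_scurve() needs a normalized image", call. = FALSE)
  }
  nm <- names(bounds)
  lower <- stats::setNames(vapply(bounds, `[`, numeric(1), 1L), nm)
  upper <- stats::setNames(vapply(bounds, `[`, numeric(1), 2L), nm)
  init <- stats::setNames(unlist(unclass(base)[nm]), nm)
  res <- pso_maximize(
    function(x) scurve_fitness(img, stats::setNames(x, nm), base,
                               tiles = tiles, blend = blend, local = local),
    lower, upper, cfg, init = init
  )
  names(res$best_position) <- nm
  res$best_params <- substitute_params(base, res$best_position)
  res
}
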