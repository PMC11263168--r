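#' Tunicate Swarm Algorithm configuration
#'
#' Holds the control parameters of the swarm search. The defaults are the
#' published settings for threshold optimisation: 30 agents, 100 iterations,
#' `c1 = 0.7`, `c2 = 0.3`, `c3 = 0.5`, and social-force speed subordinates
#' `o_min = 1`, `o_max = 4`.
#'
#' Although the algorithm's source literature draws `c1`, `c2`, `c3` fresh
#' from U(0, 1) at every use, the published application fixes them; set
#' `randomize_c = TRUE` to recover the fully stochastic original, which
#' explores more aggressively and reaches higher precision on smooth
#' objectives.
#'
#' @param population_size number of search agents (>= 2).
#' @param max_iterations fixed iteration budget (no early stopping).
#' @param c1,c2,c3 control constants in \[0, 1\].
#' @param o_min,o_max speed subordinates of the social force (`o_min < o_max`).
#' @param randomize_c redraw `c1`, `c2`, `c3` uniformly per agent per step.
#' @param seed integer seed for the whole optimisation run, or `NULL` to use
#'   the current RNG state.
#' @return object of class `"tsa_config"`.
#' @export
tsa_config <- function(population_size = 30L, max_iterations = 100L,
                       c1 = 0.7, c2 = 0.3, c3 = 0.5,
                       o_min = 1, o_max = 4,
                       randomize_c = FALSE, seed = NULL) {
  stopifnot(population_size >= 2, max_iterations >= 1,
            c1 >= 0, c1 <= 1, c2 >= 0, c2 <= 1, c3 >= 0, c3 <= 1)
  if (o_min >= o_max) stop("`o_min` must be less than `o_max`", call. = FALSE)
  structure(list(population_size = as.integer(population_size),
                 max_iterations = as.integer(max_iterations),
                 c1 = c1, c2 = c2, c3 = c3,
                 o_min = o_min, o_max = o_max,
                 randomize_c = isTRUE(randomize_c),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "tsa_config")
}

.clamp <- function(x, bounds) {
  if (is.null(bounds)) x else pmin(pmax(x, bounds[1]), bounds[2])
}

.check_finite_fitness <- function(f, x) {
  if (!is.finite(f))
    stop("objective returned a non-finite value at position ", format(x),
         call. = FALSE)
  f
}

#' Jet-propulsion move of one search agent
#'
#' Proposes a new position relative to the best agent found so far. With
#' water-flow advection `F = c1 * f0`, gravity balance `G = c2 + c3 - F`,
#' social force `U = o_min + c1 * (o_max - o_min)` and `A = G / U`, the move
#' is `best + A * OD` when `r_rand >= 0.5` and `best - A * OD` otherwise,
#' where `OD = |best - r_rand * position|` is the distance to the food
#' source. `f0` and `r_rand` are drawn uniformly on \[0, 1\] from the current
#' RNG stream when not supplied.
#'
#' @param position current (scalar) agent position.
#' @param best_position best position found so far.
#' @param config a [tsa_config()].
#' @param bounds optional `c(lower, upper)`; the result is clamped into it.
#' @param r_rand,f0 optional pinned random draws (for testing).
#' @return proposed scalar position.
#' @export
jet_propulsion_step <- function(position, best_position, config = tsa_config(),
                                bounds = NULL, r_rand = NULL, f0 = NULL) {
  c1 <- config$c1; c2 <- config$c2; c3 <- config$c3
  if (config$randomize_c) {
    c1 <- stats::runif(1); c2 <- stats::runif(1); c3 <- stats::runif(1)
  }
  if (is.null(f0)) f0 <- stats::runif(1)
  if (is.null(r_rand)) r_rand <- stats::runif(1)
  FF <- c1 * f0
  G <- c2 + c3 - FF
  U <- config$o_min + c1 * (config$o_max - config$o_min)
  A <- G / U
  OD <- abs(best_position - r_rand * position)
  out <- if (r_rand >= 0.5) best_position + A * OD else best_position - A * OD
  .clamp(out, bounds)
}

#' Swarm move of one search agent
#'
#' Averages the jet-propulsion candidate with a neighbouring agent's
#' position: `(previous + candidate) / (2 + c1)`. With `randomize_c = TRUE`
#' a fresh `c1 ~ U(0, 1)` is drawn for the divisor.
#'
#' @param previous_position position of the neighbouring (already updated)
#'   agent.
#' @param candidate_position jet-propulsion proposal for this agent.
#' @param config a [tsa_config()].
#' @param bounds optional `c(lower, upper)` clamp.
#' @return updated scalar position.
#' @examples
#' swarm_step(0, 27, tsa_config(c1 = 0.7)) # 27 / 2.7 = 10
#' @export
swarm_step <- function(previous_position, candidate_position,
                       config = tsa_config(), bounds = NULL) {
  c1 <- if (config$randomize_c) stats::runif(1) else config$c1
  .clamp((previous_position + candidate_position) / (2 + c1), bounds)
}

#' Initialise a swarm population
#'
#' Draws `population_size` positions i.i.d. uniform on the bounds, evaluates
#' the objective and records the initial best. Seeds the RNG from
#' `config$seed` when set.
#'
#' @param objective scalar function to minimise.
#' @param bounds numeric `c(lower, upper)`, `lower < upper`.
#' @param config a [tsa_config()].
#' @return object of class `"tsa_population"`: list with `positions`,
#'   `fitnesses`, `best_position`, `best_fitness`.
#' @export
tsa_init_population <- function(objective, bounds, config = tsa_config()) {
  if (length(bounds) != 2L || !(bounds[1] < bounds[2]))
    stop("`bounds` must be c(lower, upper) with lower < upper", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  pos <- stats::runif(config$population_size, bounds[1], bounds[2])
  fit <- vapply(pos, function(p) .check_finite_fitness(objective(p), p), 0)
  i <- which.min(fit)
  structure(list(positions = pos, fitnesses = fit,
                 best_position = pos[i], best_fitness = fit[i]),
            class = "tsa_population")
}

#' Minimise a 1-D objective with the Tunicate Swarm Algorithm
#'
#' Runs the swarm for a fixed iteration budget. Each iteration sweeps the
#' agents in order: a [jet_propulsion_step()] proposes a move relative to
#' the best-so-far position; every agent after the first is then averaged
#' with its predecessor's fresh position by [swarm_step()], modelling the
#' swarming of neighbouring tunicates. Each new position is evaluated
#' immediately and the best-so-far is updated on the spot, so later agents
#' in the same sweep already exploit earlier improvements.
#'
#' @param objective scalar function to minimise; must be finite on the
#'   bounds.
#' @param bounds numeric `c(lower, upper)` box constraint (out-of-bounds
#'   moves are clamped to the boundary).
#' @param config a [tsa_config()].
#' @return object of class `"tsa_result"`: list with `best_position`,
#'   `best_fitness`, `fitness_trace` (best-so-far after each iteration,
#'   non-increasing) and `iterations_run`.
#' @examples
#' res <- tsa_optimize(function(x) (x - 42)^2, c(0, 255),
#'                     tsa_config(seed = 1))
#' res$best_position
#' @export
tsa_optimize <- function(objective, bounds, config = tsa_config()) {
  pop <- tsa_init_population(objective, bounds, config)
  pos <- pop$positions
  fit <- pop$fitnesses
  best <- pop$best_position
  bf <- pop$best_fitness
  n <- config$population_size
  trace <- numeric(config$max_iterations)
  for (iter in seq_len(config$max_iterations)) {
    prev_new <- NULL
    for (i in seq_len(n)) {
      cand <- jet_propulsion_step(pos[i], best, config, bounds)
      newp <- if (i == 1L) cand else swarm_step(prev_new, cand, config, bounds)
      f <- .check_finite_fitness(objective(newp), newp)
      pos[i] <- newp
      fit[i] <- f
      prev_new <- newp
      if (f < bf) {
        bf <- f
        best <- newp
      }
    }
    trace[iter] <- bf
  }
  structure(list(best_position = best, best_fitness = bf,
                 fitness_trace = trace,
                 iterations_run = config$max_iterations),
            class = "tsa_result")
}

#' @export
print.tsa_result <- function(x, ...) {
  cat("Tunicate Swarm Algorithm result\n")
  cat(sprintf("  best position: %.6g\n", x$best_position))
  cat(sprintf("  best fitness:  %.6g\n", x$best_fitness))
  cat(sprintf("  iterations:    %d\n", x$iterations_run))
  invisible(x)
}

#' @export
print.tsa_config <- function(x, ...) {
  cat(sprintf(
    "TSA config: %d agents, %d iterations, c = (%.3g, %.3g, %.3g)%s\n",
    x$population_size, x$max_iterations, x$c1, x$c2, x$c3,
    if (x$randomize_c) " [randomised per step]" else ""))
  invisible(x)
}
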