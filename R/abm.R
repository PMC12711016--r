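# run body with a local, restored RNG state so simulator seeding never
# perturbs the caller's random stream
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Initialize an agent-based world
#'
#' Deterministic construction of the world for a given configuration: agent
#' sub-lattice placement, golden-angle headings, lowest-index infection
#' seeds, and the fixed cell information landscape. For enhanced
#' configurations the group tags are drawn from the seeded RNG, so identical
#' `(config, seed)` pairs give bit-identical worlds.
#'
#' @param config A [world_config()] or [enhanced_config()].
#' @param seed Seed for the group draw (enhanced only); defaults to
#'   `config$seed`. The tag stream is decoupled from the tick dynamics.
#' @return An `abm_world`: a list with per-agent vectors (`x`, `y`,
#'   `heading`, `status`, `energy`, `group`, `post_timer`, `armed`), the cell
#'   fields `q_true`, `q_false` (length `M^2`, row-major), and `tick`, with
#'   the configuration attached as an attribute.
#' @examples
#' w <- init_world(world_config("SI", M = 11, N = 10))
#' world_counts(w)
#' @export
init_world <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "world_config"))
  w <- abm_init_cpp(cfg_to_cpp(config))
  w <- structure(w, config = config, class = "abm_world")
  if (isTRUE(config$enhanced))
    w <- assign_groups(w, config$group_fraction, seed = group_seed(seed))
  w
}

# initialization randomness (group tags) comes from a stream separate from
# the tick dynamics, so enhanced runs with inert information channels are
# count-identical to simple runs under the same seed
group_seed <- function(seed) (as.integer(seed) + 499979L) %% 2147483647L

#' @export
print.abm_world <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("<abm_world> ", cfg$model, ", ", x$M, "x", x$M, " cells, ", x$N,
      " agents, tick ", x$tick, "\n  counts: ", sep = "")
  print(world_counts(x))
  invisible(x)
}

#' Per-status agent counts of a world
#' @param world An `abm_world`.
#' @return Named integer vector `c(S, E, I, R)`.
#' @export
world_counts <- function(world) {
  counts <- tabulate(world$status + 1L, nbins = 4L)
  stats::setNames(counts, c("S", "E", "I", "R"))
}

#' Euclidean distance on a toroidal grid
#'
#' Minimal-image distance between points on an `M x M` torus (agents leaving
#' one border reappear on the opposite side). Symmetric and bounded by
#' `M * sqrt(2) / 2`.
#'
#' @param a,b Points: length-2 vectors or two-column matrices of `(x, y)`.
#' @param M Grid side.
#' @return Numeric distance(s).
#' @examples
#' toroidal_distance(c(0, 0), c(9, 0), M = 10)  # wraps to 1
#' @export
toroidal_distance <- function(a, b, M) {
  a <- matrix(as.numeric(a), ncol = 2)
  b <- matrix(as.numeric(b), ncol = 2)
  d <- a - b[rep_len(seq_len(nrow(b)), nrow(a)), , drop = FALSE]
  d <- d - M * round(d / M)
  sqrt(rowSums(d^2))
}

#' Movement target of one agent
#'
#' Returns the cell with the highest information quantity among cells within
#' radius `r` of the agent and within half the view angle of its heading.
#' Ties are broken by the nearest cell, then by the smallest row-major cell
#' index. `NULL` when no cell is visible.
#'
#' @param agent List with fields `x`, `y` (0-based cell coordinates) and
#'   `heading` (degrees, counter-clockwise from the +x axis).
#' @param world An `abm_world`, or an `M x M` matrix of cell information
#'   quantities indexed `q[y + 1, x + 1]`.
#' @param r Decision radius in cells.
#' @param theta View angle in degrees.
#' @return List with the target's `x`, `y`, or `NULL` if none visible.
#' @export
select_move_target <- function(agent, world, r, theta) {
  q <- if (inherits(world, "abm_world")) {
    matrix(world$q_true + world$q_false, nrow = world$M, byrow = TRUE)
  } else as.matrix(world)
  res <- select_target_cpp(agent$x, agent$y, agent$heading, q, r, theta)
  if (length(res) == 0) NULL else res
}

#' Run one scheduler phase on a world
#'
#' Unit-level access to the engine's phases, in the per-tick order
#' `movement`, `consume`, `post` (enhanced only), `spreading`, `stigmergy`
#' (enhanced only), `state` (incubation, recovery, immunity loss with at
#' most one transition per agent), `cells`. Randomness is taken from the
#' session RNG; seed it with `set.seed()` for reproducible phases.
#'
#' @param world An `abm_world`.
#' @param phase Phase name (see Details).
#' @return The updated `abm_world`.
#' @export
abm_phase <- function(world, phase) {
  cfg <- attr(world, "config")
  out <- abm_phase_cpp(world, cfg_to_cpp(cfg), phase)
  structure(out, config = cfg, class = "abm_world")
}

#' Simulate an agent-based model run
#'
#' Executes the phase scheduler for `T` ticks: movement, (enhanced:
#' consumption and posting), contact spreading, (enhanced: environmental
#' infection), state updates and cell replenishment, with agents visited in
#' a fresh seeded random permutation each phase. Vital dynamics are
#' disabled, so the per-status counts sum to `N` at every tick.
#'
#' @param config A [world_config()] or [enhanced_config()].
#' @param T Number of ticks (non-negative integer).
#' @param record_events Keep an infection event log (`tick`, `agent`,
#'   `channel`, `source`, groups) for channel audits?
#' @param seed Seed for this run; defaults to `config$seed`.
#' @return A `trajectory` of integer counts with attributes `world` (final
#'   state) and, if requested, `events` (data frame; `channel` is
#'   `"contact"` or `"environment"`).
#' @examples
#' tr <- run_abm(world_config("SI", M = 11, N = 20, beta = 0.5), T = 50)
#' tail(tr)
#' @export
run_abm <- function(config, T, record_events = FALSE, seed = config$seed) {
  stopifnot(inherits(config, "world_config"))
  if (length(T) != 1 || !is.finite(T) || T < 0 || T != round(T))
    stop("T must be a non-negative integer tick count", call. = FALSE)
  cpp_cfg <- cfg_to_cpp(config)
  w <- init_world(config, seed = seed)
  res <- with_local_seed(seed,
    abm_run_cpp(w, cpp_cfg, as.integer(T), isTRUE(record_events)))
  counts <- res$counts
  spec <- config$spec
  traj <- as_trajectory(tick = 0:T,
                        S = counts[, 1], E = counts[, 2],
                        I = counts[, 3], R = counts[, 4],
                        spec = spec, params = config,
                        kind = if (isTRUE(config$enhanced)) "abm-enhanced"
                               else "abm-simple")
  attr(traj, "world") <- structure(res$world, config = config,
                                   class = "abm_world")
  if (isTRUE(record_events)) {
    ev <- res$events
    attr(traj, "events") <- data.frame(
      tick = ev$tick, agent = ev$agent,
      channel = c("contact", "environment")[ev$channel],
      source = ev$source, src_group = ev$src_group,
      tgt_group = ev$tgt_group)
  }
  traj
}

#' Mean and standard deviation over repeated seeded runs
#'
#' Repeats an agent-based experiment under identical initial conditions with
#' different seeds and averages the outcomes, the standard practice before
#' comparing against an equation-based trajectory.
#'
#' @param config A [world_config()] or [enhanced_config()].
#' @param T Ticks per run.
#' @param runs Number of runs (`>= 1`).
#' @param seeds Optional explicit seed vector of length `runs`; defaults to
#'   `config$seed + 0:(runs - 1)`.
#' @return A list of class `run_ensemble` with elements `mean` (a
#'   `trajectory` of kind `"abm-mean"`), `sd` (data frame of per-tick
#'   standard deviations), `runs`, and `seeds`.
#' @export
average_runs <- function(config, T, runs = 10, seeds = NULL) {
  if (length(runs) != 1 || runs < 1 || runs != round(runs))
    stop("runs must be a positive integer", call. = FALSE)
  if (is.null(seeds)) seeds <- config$seed + 0:(runs - 1)
  if (length(seeds) != runs) stop("need one seed per run", call. = FALSE)
  acc <- array(0, dim = c(T + 1, 4, runs))
  for (i in seq_len(runs)) {
    tr <- run_abm(config, T, seed = seeds[i])
    m <- as.matrix(as.data.frame(tr)[, c("S", "E", "I", "R")])
    m[is.na(m)] <- 0
    acc[, , i] <- m
  }
  mu <- apply(acc, c(1, 2), mean)
  sdv <- if (runs > 1) apply(acc, c(1, 2), stats::sd) else mu * 0
  spec <- config$spec
  mean_traj <- as_trajectory(tick = 0:T, S = mu[, 1], E = mu[, 2],
                             I = mu[, 3], R = mu[, 4], spec = spec,
                             params = config, kind = "abm-mean")
  structure(list(mean = mean_traj,
                 sd = data.frame(tick = 0:T, S = sdv[, 1], E = sdv[, 2],
                                 I = sdv[, 3], R = sdv[, 4]),
                 runs = runs, seeds = seeds),
            class = "run_ensemble")
}

#' @export
print.run_ensemble <- function(x, ...) {
  cat("<run_ensemble> ", x$runs, " runs, ", nrow(x$mean) - 1, " ticks, model ",
      attr(x$mean, "model"), "\n", sep = "")
  invisible(x)
}
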