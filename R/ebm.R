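#' One forward-Euler step of a discrete SEIRS-class model
#'
#' Advances the compartment state by one tick. The full SEIRS flux template
#' is
#' \deqn{S' = -\beta S I / N + \xi R,\quad E' = \beta S I / N - \sigma E,}
#' \deqn{I' = \sigma E - \gamma I,\quad R' = \gamma I - \xi R,}
#' with inactive transitions contributing zero flux (for models without an E
#' compartment the infection flux feeds I directly, and for SIS the recovery
#' flux returns to S). Each compartment's outflux is clamped to the
#' compartment content, so conservation \eqn{S+E+I+R=N} holds for any rate
#' combination in `[0, 1]`.
#'
#' @param state An [ebm_state()].
#' @param params An [ebm_params()].
#' @param spec A [make_model_spec()] result.
#' @return The state one tick later (class `ebm_state`).
#' @examples
#' s <- ebm_state(S = 990, I = 10)
#' ebm_step(s, ebm_params(beta = 0.2, sigma = 0.1, gamma = 0.05, xi = 0.01),
#'          make_model_spec("SEIRS"))
#' @export
ebm_step <- function(state, params, spec) {
  stopifnot(inherits(state, "ebm_state"), inherits(params, "ebm_params"),
            inherits(spec, "model_spec"))
  S <- state$S; E <- state$E; I <- state$I; R <- state$R
  N <- params$N
  inf <- min(params$beta * S * I / N, S)
  inc <- if (spec$has_E) min(params$sigma * E, E) else 0
  rec <- if (spec$rec_mode != "none") min(params$gamma * I, I) else 0
  loss <- if (spec$has_xi) min(params$xi * R, R) else 0
  if (spec$has_E) {
    S <- S - inf + loss
    E <- E + inf - inc
    I <- I + inc - rec
  } else {
    S <- S - inf + loss + if (spec$rec_mode == "to_S") rec else 0
    E <- 0
    I <- I + inf - rec
  }
  R <- R + (if (spec$rec_mode == "to_R") rec else 0) - loss
  if (identical(spec$states, c("S", "I"))) I <- N - S  # exact mirror closure
  ebm_state(S = S, E = E, I = I, R = R, t = state$t + 1L)
}

#' Simulate a discrete-time equation-based model
#'
#' Iterates [ebm_step()] for `T` ticks (the loop itself runs in compiled
#' code) and returns the trajectory, including the initial state at tick 0.
#'
#' @param params An [ebm_params()].
#' @param init An [ebm_state()] giving the tick-0 compartments.
#' @param spec A [make_model_spec()] result.
#' @param T Number of ticks (non-negative integer).
#' @return A `trajectory` object (see [as_trajectory()]): a data frame with
#'   columns `tick`, `S`, `E`, `I`, `R`, inactive compartments `NA`.
#' @examples
#' tr <- simulate_ebm(ebm_params(beta = 0.3, N = 150),
#'                    ebm_state(S = 142, I = 8), make_model_spec("SI"), T = 50)
#' head(tr)
#' @export
simulate_ebm <- function(params, init, spec, T) {
  stopifnot(inherits(params, "ebm_params"), inherits(init, "ebm_state"),
            inherits(spec, "model_spec"))
  if (length(T) != 1 || !is.finite(T) || T < 0 || T != round(T))
    stop("T must be a non-negative integer tick count", call. = FALSE)
  m <- ebm_run_cpp(c(init$S, init$E, init$I, init$R),
                   params$beta, params$sigma, params$gamma, params$xi,
                   as.integer(spec$has_E),
                   switch(spec$rec_mode, none = 0L, to_S = 1L, to_R = 2L),
                   as.integer(spec$has_xi), params$N, as.integer(T))
  as_trajectory(tick = 0:T, S = m[, 1], E = m[, 2], I = m[, 3], R = m[, 4],
                spec = spec, params = params, kind = "ebm")
}

#' Trajectory container
#'
#' A trajectory is a per-tick record of the compartment counts of one model
#' run (real-valued for the equation-based models, integer agent counts for
#' the agent-based models). Compartments that are not part of the model are
#' stored as `NA` and written as empty CSV fields by [write_trajectory()].
#'
#' @param tick Integer tick index starting at 0.
#' @param S,E,I,R Compartment series (recycled `NA` allowed for inactive).
#' @param spec The [make_model_spec()] the run used.
#' @param params Parameter record to attach (list).
#' @param kind One of `"ebm"`, `"abm-simple"`, `"abm-enhanced"`, `"abm-mean"`.
#' @return A data frame of class `trajectory` with attributes `model`,
#'   `params` and `kind`.
#' @export
as_trajectory <- function(tick, S, E = NA_real_, I = NA_real_, R = NA_real_,
                          spec, params = list(), kind = "ebm") {
  df <- data.frame(tick = as.integer(tick), S = S, E = E, I = I, R = R)
  for (v in setdiff(c("S", "E", "I", "R"), spec$states)) df[[v]] <- NA_real_
  structure(df, model = spec$name, params = params, kind = kind,
            class = c("trajectory", "data.frame"))
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> model ", attr(x, "model"), " (", attr(x, "kind"), "), ",
      nrow(x), " ticks\n", sep = "")
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("... (", nrow(x) - 6, " more rows)\n", sep = "")
  invisible(x)
}

#' Active-compartment matrix of a trajectory
#'
#' @param traj A `trajectory`.
#' @return Numeric matrix with one column per active compartment.
#' @export
trajectory_states <- function(traj) {
  spec <- make_model_spec(attr(traj, "model"))
  as.matrix(as.data.frame(traj)[, spec$states, drop = FALSE])
}
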