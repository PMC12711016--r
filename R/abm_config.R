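#' Configuration for the simple agent-based world
#'
#' Builds the full parameter record for one agent-based run: grid size,
#' population, perception/contact geometry, energy accounting, information
#' landscape and the compartmental rates of the submodel being emulated.
#' Reference experiments use `M = 33, N = 150` (small variant) and
#' `M = 99, N = 1350` (large variant); both have the same agent density.
#'
#' Initialization is deterministic: agents are placed on an evenly spaced
#' sub-lattice with headings `(i * 137.5) %% 360` degrees, the `I0` infected
#' (and, under Case II, `E0` exposed) seeds are the lowest-index agents, and
#' the cell information landscape is a fixed sinusoidal pattern. Case I and
#' Case II differ only in the initial exposed count (`E0 = 0` vs
#' `E0 = ceiling(0.05 N)` for models with an E compartment).
#'
#' @param model Model name passed to [make_model_spec()].
#' @param M Grid side in cells (toroidal `M x M` world).
#' @param N Number of agents.
#' @param beta,sigma,gamma,xi Per-tick transition probabilities.
#' @param case `"I"` (no initial exposed) or `"II"` (initial exposed seeded).
#' @param I0,E0 Initial infected/exposed counts; defaults `ceiling(0.05 N)`
#'   and, for Case II models with E, `ceiling(0.05 N)`.
#' @param r Perception radius (cells) used for agent-agent sensing.
#' @param theta View angle in degrees (cone centred on the heading).
#' @param d_c Contact radius for point-to-point spreading (cells).
#' @param d_e Decision radius for movement-target selection; defaults to `r`.
#' @param e_c Energy cost per movement.
#' @param e0 Initial agent energy.
#' @param growth Per-tick information replenishment on cells.
#' @param q_max Maximum information quantity per cell.
#' @param seed Integer RNG seed (reproducibility contract: identical
#'   `(config, seed)` gives a bit-identical trajectory).
#' @param contact_scale Multiplier mapping `beta` to the per-contact success
#'   probability. Default `pi * d_c^2 * N / M^2` (capped at 1), i.e. `beta`
#'   scaled by expected contact-neighbourhood occupancy so that at the
#'   reference densities expected new infections per tick approximate the
#'   mean-field flux `beta * S * I / N`.
#' @return A list of class `world_config`.
#' @examples
#' world_config("SI", beta = 0.3)
#' @export
world_config <- function(model = "SI", M = 33, N = 150,
                         beta = 0.2, sigma = 0, gamma = 0, xi = 0,
                         case = c("II", "I"), I0 = NULL, E0 = NULL,
                         r = 5, theta = 120, d_c = 1.5, d_e = r, e_c = 1,
                         e0 = 100, growth = 0.1, q_max = 10, seed = 1L,
                         contact_scale = NULL) {
  case <- match.arg(case)
  spec <- make_model_spec(model)
  rates <- ebm_params(beta, sigma, gamma, xi, N)  # validates ranges
  if (M < 1 || M != round(M)) stop("M must be a positive integer", call. = FALSE)
  if (N < 1 || N != round(N)) stop("N must be a positive integer", call. = FALSE)
  if (is.null(I0)) I0 <- ceiling(0.05 * N)
  if (is.null(E0)) E0 <- if (case == "II" && spec$has_E) ceiling(0.05 * N) else 0
  if (!spec$has_E) E0 <- 0
  if (I0 + E0 > N)
    stop("I0 + E0 exceeds the population size N", call. = FALSE)
  if (is.null(contact_scale)) contact_scale <- min(1, pi * d_c^2 * N / M^2)
  structure(list(model = model, spec = spec, M = as.integer(M),
                 N = as.integer(N),
                 beta = beta, sigma = sigma, gamma = gamma, xi = xi,
                 case = case, I0 = as.integer(I0), E0 = as.integer(E0),
                 r = r, theta = theta, d_c = d_c, d_e = d_e, e_c = e_c,
                 e0 = e0, growth = growth, q_max = q_max,
                 seed = as.integer(seed), contact_scale = contact_scale,
                 enhanced = FALSE),
            class = "world_config")
}

#' Configuration for the enhanced agent-based model
#'
#' Extends [world_config()] with the information-environment layer: cells
#' carry true and false content, agents consume and (after a delay) post
#' information of their own type, susceptible agents can be infected by
#' false content on their cell (stigmergy), and agent-to-agent belief in
#' false information is gated by group membership (homophily). The infection
#' rate `beta` is split equally between the two channels: contact
#' transmission uses `beta / 2` and the environmental per-tick probability is
#' `(beta / 2) * min(q_false / q_max, 1)` on the agent's cell.
#'
#' @inheritParams world_config
#' @param group_fraction Expected share of agents in group G1 (seeded draw).
#' @param homophily Gate agent-to-agent infection on equal groups?
#' @param I_R Per-tick regrowth of true information on cells (external
#'   sources); false information only grows through infected posts.
#' @param L_M_S,L_M_I Movement energy losses for non-infected/infected agents.
#' @param L_P_S,L_P_I Posting energy losses for non-infected/infected agents.
#' @param D_P_S,D_P_I Consume-to-post delays in ticks (positive integers).
#' @param post_quantum Information quantity deposited per post.
#' @param consume_bite Maximum quantity consumed from a cell per tick.
#' @param ... Further arguments passed to [world_config()] (geometry,
#'   energy, seed, `contact_scale`).
#' @return A list of class `c("enhanced_config", "world_config")`.
#' @examples
#' enhanced_config("SI", beta = 0.3, group_fraction = 0.8)
#' @export
enhanced_config <- function(model = "SI", M = 99, N = 1350,
                            beta = 0.2, sigma = 0, gamma = 0, xi = 0,
                            case = c("II", "I"), I0 = NULL, E0 = NULL,
                            group_fraction = 0.8, homophily = TRUE,
                            I_R = 0.1, L_M_S = 1, L_M_I = 1,
                            L_P_S = 1, L_P_I = 1, D_P_S = 5L, D_P_I = 5L,
                            post_quantum = 1, consume_bite = 1, ...) {
  cfg <- world_config(model = model, M = M, N = N, beta = beta, sigma = sigma,
                      gamma = gamma, xi = xi, case = case, I0 = I0, E0 = E0,
                      ...)
  if (group_fraction < 0 || group_fraction > 1)
    stop("group_fraction must lie in [0, 1]", call. = FALSE)
  if (D_P_S < 1 || D_P_I < 1 || D_P_S != round(D_P_S) || D_P_I != round(D_P_I))
    stop("posting delays D_P must be positive integers", call. = FALSE)
  cfg$enhanced <- TRUE
  cfg$group_fraction <- group_fraction
  cfg$homophily <- isTRUE(homophily)
  cfg$I_R <- I_R
  cfg$L_M_S <- L_M_S; cfg$L_M_I <- L_M_I
  cfg$L_P_S <- L_P_S; cfg$L_P_I <- L_P_I
  cfg$D_P_S <- as.integer(D_P_S); cfg$D_P_I <- as.integer(D_P_I)
  cfg$post_quantum <- post_quantum
  cfg$consume_bite <- consume_bite
  class(cfg) <- c("enhanced_config", "world_config")
  cfg
}

#' @export
print.world_config <- function(x, ...) {
  cat("<", if (isTRUE(x$enhanced)) "enhanced_config" else "world_config",
      "> model ", x$model, ", world ", x$M, "x", x$M, ", ", x$N, " agents\n",
      "  rates: beta=", x$beta, " sigma=", x$sigma, " gamma=", x$gamma,
      " xi=", x$xi, "\n  case ", x$case, " (I0=", x$I0, ", E0=", x$E0,
      "), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# flat list consumed by the compiled engine
cfg_to_cpp <- function(cfg) {
  list(M = cfg$M, N = cfg$N,
       beta = cfg$beta, sigma = cfg$sigma, gamma = cfg$gamma, xi = cfg$xi,
       has_E = as.integer(cfg$spec$has_E),
       rec_mode = switch(cfg$spec$rec_mode, none = 0L, to_S = 1L, to_R = 2L),
       has_xi = as.integer(cfg$spec$has_xi),
       r = cfg$r, theta = cfg$theta, d_c = cfg$d_c, d_e = cfg$d_e,
       e_c = cfg$e_c, growth = cfg$growth, q_max = cfg$q_max,
       contact_scale = cfg$contact_scale,
       enhanced = as.integer(isTRUE(cfg$enhanced)),
       homophily = as.integer(isTRUE(cfg$homophily)),
       group_fraction = cfg$group_fraction %||% 0,
       I_R = cfg$I_R %||% 0,
       L_M_S = cfg$L_M_S %||% cfg$e_c, L_M_I = cfg$L_M_I %||% cfg$e_c,
       L_P_S = cfg$L_P_S %||% 0, L_P_I = cfg$L_P_I %||% 0,
       D_P_S = cfg$D_P_S %||% 1L, D_P_I = cfg$D_P_I %||% 1L,
       post_quantum = cfg$post_quantum %||% 0,
       consume_bite = cfg$consume_bite %||% 0,
       e0 = cfg$e0, I0 = cfg$I0, E0 = cfg$E0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# matching equation-based setup for intermodel comparison
ebm_from_config <- function(cfg) {
  list(params = ebm_params(cfg$beta, cfg$sigma, cfg$gamma, cfg$xi, cfg$N),
       init = ebm_state(S = cfg$N - cfg$I0 - cfg$E0, E = cfg$E0, I = cfg$I0,
                        R = 0),
       spec = cfg$spec)
}
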