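# Per-agent semantics of the enhanced information environment. These
# operate on plain agent/cell records and define the rules the compiled
# scheduler applies population-wide; tests cross-check the two.

#' Assign homophily groups to the agents of a world
#'
#' Each agent is tagged as group 1 with the given expected proportion via an
#' independent seeded draw; tags are fixed for the run.
#'
#' @param world An `abm_world`.
#' @param fraction Expected share of agents in group G1, in `[0, 1]`.
#' @param seed Integer seed for the draw.
#' @return The world with its `group` vector set (1 = G1, 2 = G2).
#' @export
assign_groups <- function(world, fraction, seed) {
  if (fraction < 0 || fraction > 1)
    stop("fraction must lie in [0, 1]", call. = FALSE)
  g <- with_local_seed(seed,
                       ifelse(stats::runif(world$N) < fraction, 1L, 2L))
  world$group <- g
  world
}

#' Homophily gate for agent-to-agent belief
#'
#' Agents only believe false information arriving from agents of their own
#' social group, so agent-to-agent S->I and S->E transitions are conditional
#' on equal groups. Environmental (stigmergic) infection is not gated: the
#' rule concerns agents, not cells.
#'
#' @param source,target Agent records with a `group` field (1 or 2).
#' @return `TRUE` (allow) if the groups are equal, `FALSE` (block) otherwise.
#' @examples
#' homophily_gate(list(group = 1), list(group = 1))  # allow
#' homophily_gate(list(group = 1), list(group = 2))  # block
#' @export
homophily_gate <- function(source, target) {
  sg <- source$group; tg <- target$group
  if (is.null(sg) || is.null(tg) || length(sg) != 1 || length(tg) != 1 ||
      is.na(sg) || is.na(tg) || !sg %in% c(1, 2) || !tg %in% c(1, 2))
    stop("both agents must carry a group tag (1 or 2)", call. = FALSE)
  sg == tg
}

#' Post information onto a cell
#'
#' An agent whose posting timer has expired (and which has consumed since
#' its last post) deposits a fixed quantum of information of its own type:
#' infected agents deposit false-type content, all others true-type. The
#' cell total is capped at `q_max`, the agent pays the status-specific
#' posting cost and its timer restarts at the status-specific delay.
#'
#' @param agent Record with `status` (`"S"`, `"E"`, `"I"`, `"R"`), `energy`,
#'   `post_timer`, and `armed` (has consumed since last post).
#' @param cell Record with `q_true`, `q_false`.
#' @param config An [enhanced_config()].
#' @return List with updated `agent` and `cell`, plus `posted` flag.
#' @export
post_information <- function(agent, cell, config) {
  agent$armed <- isTRUE(agent$armed)
  if (!agent$armed || agent$post_timer > 0)
    return(list(agent = agent, cell = cell, posted = FALSE))
  cap <- config$q_max - (cell$q_true + cell$q_false)
  amt <- min(config$post_quantum, max(cap, 0))
  infected <- identical(agent$status, "I")
  if (infected) cell$q_false <- cell$q_false + amt
  else cell$q_true <- cell$q_true + amt
  agent$energy <- agent$energy - if (infected) config$L_P_I else config$L_P_S
  agent$post_timer <- if (infected) config$D_P_I else config$D_P_S
  agent$armed <- FALSE
  list(agent = agent, cell = cell, posted = TRUE)
}

#' Consume information from the agent's cell
#'
#' The agent takes up to `consume_bite` from the cell (proportionally from
#' the true and false content) and gains that amount of energy, so the sum
#' of agent energy and cell content is conserved by the exchange. The first
#' consumption after a post arms the next post and starts the
#' status-specific delay countdown.
#'
#' @inheritParams post_information
#' @return List with updated `agent` and `cell`, plus `consumed` amount.
#' @export
consume_information <- function(agent, cell, config) {
  tot <- cell$q_true + cell$q_false
  b <- min(tot, config$consume_bite)
  if (b <= 0) return(list(agent = agent, cell = cell, consumed = 0))
  fshare <- cell$q_false / tot
  cell$q_false <- max(cell$q_false - b * fshare, 0)
  cell$q_true <- max(cell$q_true - b * (1 - fshare), 0)
  agent$energy <- agent$energy + b
  if (!isTRUE(agent$armed)) {
    agent$armed <- TRUE
    agent$post_timer <- if (identical(agent$status, "I")) config$D_P_I
                        else config$D_P_S
  }
  list(agent = agent, cell = cell, consumed = b)
}

#' Environment-mediated (stigmergic) infection
#'
#' A susceptible agent standing on a cell with false-type content transitions
#' with per-tick probability `(beta / 2) * min(q_false / q_max, 1)` — half of
#' the infection rate is allocated to the environmental channel, scaled by
#' the local false-information saturation. The transition goes to E for
#' models with incubation, to I otherwise. Homophily does not gate this
#' channel.
#'
#' @param agent Record with `status = "S"`.
#' @param cell Record with `q_false`.
#' @param beta Infection rate.
#' @param config An [enhanced_config()] (for `q_max` and the model spec).
#' @return The agent, possibly transitioned; uses the session RNG.
#' @export
stigmergy_infection <- function(agent, cell, beta, config) {
  if (!identical(agent$status, "S")) return(agent)
  p <- stigmergy_probability(cell$q_false, beta, config$q_max)
  if (p > 0 && stats::runif(1) < p)
    agent$status <- if (config$spec$has_E) "E" else "I"
  agent
}

#' Per-tick probability of environmental infection
#' @param q_false False-information quantity on the cell.
#' @param beta Infection rate.
#' @param q_max Cell capacity.
#' @return `(beta / 2) * min(q_false / q_max, 1)`.
#' @export
stigmergy_probability <- function(q_false, beta, q_max) {
  if (q_false <= 0 || beta <= 0) return(0)
  0.5 * beta * min(q_false / q_max, 1)
}

#' Run an enhanced agent-based model
#'
#' Convenience wrapper: [run_abm()] on an [enhanced_config()].
#'
#' @param config An [enhanced_config()].
#' @param T Ticks.
#' @param ... Passed to [run_abm()].
#' @return A `trajectory` of kind `"abm-enhanced"`.
#' @export
run_enhanced <- function(config, T, ...) {
  if (!inherits(config, "enhanced_config"))
    stop("run_enhanced() needs an enhanced_config", call. = FALSE)
  run_abm(config, T, ...)
}
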