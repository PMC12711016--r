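#' Structure of a SEIRS-class submodel
#'
#' The six compartmental models in the family (`SI`, `SIS`, `SIR`, `SIRS`,
#' `SEIR`, `SEIRS`) are all reductions of the full SEIRS template: they share
#' the same four possible transitions (infection S->E/I, incubation E->I,
#' recovery I->R or I->S, immunity loss R->S) and differ only in which
#' transitions are active. `make_model_spec()` returns that structure, which
#' every simulator and the sweep harness consult so that reduced models are
#' obtained by zeroing fluxes rather than by separate code paths.
#'
#' @param name Model name, one of `"SI"`, `"SIS"`, `"SIR"`, `"SIRS"`,
#'   `"SEIR"`, `"SEIRS"`.
#' @return An object of class `model_spec`: a list with elements `name`,
#'   `states` (active compartments), `transitions` (active transitions),
#'   and the engine flags `has_E`, `rec_mode` (`"none"`, `"to_S"`, `"to_R"`)
#'   and `has_xi`.
#' @examples
#' make_model_spec("SI")
#' make_model_spec("SEIRS")$transitions
#' @export
make_model_spec <- function(name) {
  name <- toupper(as.character(name)[1])
  defs <- list(
    SI    = list(states = c("S", "I"),
                 transitions = "infection", rec_mode = "none"),
    SIS   = list(states = c("S", "I"),
                 transitions = c("infection", "recovery"), rec_mode = "to_S"),
    SIR   = list(states = c("S", "I", "R"),
                 transitions = c("infection", "recovery"), rec_mode = "to_R"),
    SIRS  = list(states = c("S", "I", "R"),
                 transitions = c("infection", "recovery", "immunity_loss"),
                 rec_mode = "to_R"),
    SEIR  = list(states = c("S", "E", "I", "R"),
                 transitions = c("infection", "incubation", "recovery"),
                 rec_mode = "to_R"),
    SEIRS = list(states = c("S", "E", "I", "R"),
                 transitions = c("infection", "incubation", "recovery",
                                 "immunity_loss"),
                 rec_mode = "to_R")
  )
  if (!name %in% names(defs))
    stop("unknown model '", name, "'; expected one of ",
         paste(names(defs), collapse = ", "), call. = FALSE)
  d <- defs[[name]]
  structure(list(name = name, states = d$states, transitions = d$transitions,
                 has_E = "incubation" %in% d$transitions,
                 rec_mode = d$rec_mode,
                 has_xi = "immunity_loss" %in% d$transitions),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", x$name, "\n", sep = "")
  cat("  states:      ", paste(x$states, collapse = ", "), "\n", sep = "")
  cat("  transitions: ", paste(x$transitions, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Per-tick rates for the equation-based models
#'
#' Rates are interpreted as per-tick fractions of the source compartment
#' moving along a transition (the discrete-time analogue of the continuous
#' rates); each must lie in `[0, 1]`. Rates attached to transitions that are
#' absent from the model spec are ignored by the simulators.
#'
#' @param beta Infection rate per tick.
#' @param sigma Incubation rate per tick.
#' @param gamma Recovery rate per tick.
#' @param xi Immunity-loss rate per tick.
#' @param N Total population size (positive).
#' @return A validated list of class `ebm_params`.
#' @examples
#' ebm_params(beta = 0.2, gamma = 0.05, N = 1000)
#' @export
ebm_params <- function(beta = 0, sigma = 0, gamma = 0, xi = 0, N = 1000) {
  rates <- c(beta = beta, sigma = sigma, gamma = gamma, xi = xi)
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 1))
    stop("rates beta, sigma, gamma, xi must lie in [0, 1]", call. = FALSE)
  if (!is.finite(N) || N <= 0)
    stop("N must be a positive population size", call. = FALSE)
  structure(list(beta = beta, sigma = sigma, gamma = gamma, xi = xi, N = N),
            class = "ebm_params")
}

#' Compartment state of an equation-based model
#'
#' @param S,E,I,R Real-valued compartment counts (each `>= 0`).
#' @param t Tick index (non-negative integer).
#' @return A list of class `ebm_state`.
#' @export
ebm_state <- function(S, E = 0, I = 0, R = 0, t = 0) {
  v <- c(S = S, E = E, I = I, R = R)
  if (any(!is.finite(v)) || any(v < 0))
    stop("compartments must be finite and non-negative", call. = FALSE)
  if (t < 0 || t != round(t)) stop("t must be a non-negative integer", call. = FALSE)
  structure(list(S = S, E = E, I = I, R = R, t = as.integer(t)),
            class = "ebm_state")
}
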