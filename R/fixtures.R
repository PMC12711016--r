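#' Generate a synthetic vaccine-acceptance series
#'
#' Emulates a longitudinal two-mirrored-percentage acceptance survey: a
#' smooth sigmoidal decline in acceptance that crosses the 50% line once
#' near a configurable inversion week (the qualitative shape of a population
#' whose accepting/non-accepting proportions invert mid-series), with
#' optional seeded Gaussian noise. The mirror constraint
#' `S_RW + I_RW = 100` holds exactly at every point.
#'
#' @param n_points Number of biweekly samples (default 19, spanning 36
#'   weeks at 2-week sampling).
#' @param start_acceptance Percent accepting at week 0.
#' @param inversion_week Week at which `S_RW` crosses 50%.
#' @param noise_sd Standard deviation of the additive noise (percent).
#' @param seed Integer seed for the noise draw.
#' @param shape_scale Width (weeks) of the sigmoidal transition.
#' @return An [acceptance_series()].
#' @examples
#' generate_acceptance_series(noise_sd = 0)
#' @export
generate_acceptance_series <- function(n_points = 19, start_acceptance = 65,
                                       inversion_week = 20, noise_sd = 1,
                                       seed = 1, shape_scale = 8) {
  week <- seq(0, by = 2, length.out = n_points)
  A <- (start_acceptance - 50) / tanh(inversion_week / shape_scale)
  s <- 50 + A * tanh((inversion_week - week) / shape_scale)
  if (noise_sd > 0)
    s <- s + with_local_seed(seed, stats::rnorm(n_points, 0, noise_sd))
  s <- pmin(pmax(s, 0), 100)
  acceptance_series(week = week, S_RW = s)
}

#' Reference world presets
#'
#' Frozen configurations for the three reference experiment instances: the
#' small simple variant (33 x 33 cells, 150 agents), the large simple
#' variant (99 x 99 cells, 1350 agents), and the enhanced model
#' (99 x 99, 1350 agents, social groups split 80/20).
#'
#' @param preset One of `"small-simple"`, `"large-simple"`, `"enhanced"`.
#' @param ... Overrides passed to [world_config()]/[enhanced_config()]
#'   (e.g. `model`, rates, `case`, `seed`).
#' @return A `world_config` or `enhanced_config`.
#' @examples
#' toy_world("small-simple", model = "SI", beta = 0.3)
#' @export
toy_world <- function(preset = c("small-simple", "large-simple", "enhanced"),
                      ...) {
  preset <- match.arg(preset)
  switch(preset,
    "small-simple" = world_config(M = 33, N = 150, ...),
    "large-simple" = world_config(M = 99, N = 1350, ...),
    "enhanced" = enhanced_config(M = 99, N = 1350, group_fraction = 0.8, ...))
}
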