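# which of the four rates a model actually uses (sweep axes)
active_axes <- function(spec) {
  ax <- "beta"
  if (spec$has_E) ax <- c(ax, "sigma")
  if (spec$rec_mode != "none") ax <- c(ax, "gamma")
  if (spec$has_xi) ax <- c(ax, "xi")
  ax
}

# one grid point: averaged ABM runs vs matched EBM, metric pairs
sweep_point <- function(model, variant, world, agents, rates, runs_per_cell,
                        T, seed, tau, overrides) {
  maker <- if (variant == "enhanced") enhanced_config else world_config
  args <- c(list(model = model, M = world, N = agents,
                 beta = rates[["beta"]], sigma = rates[["sigma"]],
                 gamma = rates[["gamma"]], xi = rates[["xi"]],
                 seed = seed),
            overrides)
  cfg <- do.call(maker, args)
  ens <- average_runs(cfg, T, runs = runs_per_cell,
                      seeds = seed + 0:(runs_per_cell - 1))
  eb <- ebm_from_config(cfg)
  etr <- simulate_ebm(eb$params, eb$init, eb$spec, T)
  compare_trajectories(ens$mean, etr, tau = tau)
}

#' Full-grid intermodel-equivalence sweep
#'
#' Runs the agent-based model (averaged over `runs_per_cell` seeded runs)
#' and the matched equation-based model at every combination of the model's
#' active rates over a regular grid, computes the `(rho, NRMSE)` metric
#' pairs per compartment, and summarizes mean and standard deviation per
#' variable across the grid. The default grid is `{0.1, 0.2, ..., 1.0}` per
#' axis, giving 10 combinations for SI up to 10^4 for SEIRS.
#'
#' @param model Model name (see [make_model_spec()]).
#' @param variant `"simple"` or `"enhanced"` agent-based variant.
#' @param world Grid side `M` (33 small variant, 99 large variant).
#' @param agents Agent count `N` (150 small, 1350 large).
#' @param grid_step Step of the rate grid over `[0.1, 1]`; must divide 0.9.
#' @param runs_per_cell Agent-based runs averaged per grid point.
#' @param T Ticks per run.
#' @param seed Base seed; grid points use disjoint derived seed blocks.
#' @param tau Zero-variance match threshold.
#' @param axes Optional subset of axes to vary (others held at `fixed`).
#' @param fixed Named list of rate values for axes not varied.
#' @param grid Optional explicit data frame of rate combinations (columns
#'   among `beta`, `sigma`, `gamma`, `xi`) overriding the regular grid.
#' @param overrides Named list of extra [world_config()]/[enhanced_config()]
#'   arguments (e.g. `case`, geometry).
#' @param progress Print one line per grid point?
#' @return A `sweep_result`: list with `metrics` (long data frame:
#'   rates, `variable`, `rho_raw`, `rho`, `nrmse`, `adjusted`), `summary`
#'   (per-variable mean/SD), `grid`, and the run settings.
#' @examples
#' \donttest{
#' sw <- run_sweep("SI", grid_step = 0.3, runs_per_cell = 2, T = 200)
#' sw$summary
#' }
#' @export
run_sweep <- function(model, variant = c("simple", "enhanced"),
                      world = 33, agents = 150, grid_step = 0.1,
                      runs_per_cell = 10, T = 2000, seed = 1, tau = 0.05,
                      axes = NULL, fixed = list(), grid = NULL,
                      overrides = list(), progress = FALSE) {
  variant <- match.arg(variant)
  spec <- make_model_spec(model)
  all_axes <- active_axes(spec)
  if (is.null(grid)) {
    if (grid_step <= 0 || grid_step > 0.9)
      stop("grid_step must lie in (0, 0.9]", call. = FALSE)
    vals <- seq(0.1, 1 + 1e-9, by = grid_step)  # anchored at 0.1
    vary <- if (is.null(axes)) all_axes else intersect(all_axes, axes)
    grid <- do.call(expand.grid,
                    stats::setNames(rep(list(vals), length(vary)), vary))
  }
  for (ax in setdiff(c("beta", "sigma", "gamma", "xi"), names(grid)))
    grid[[ax]] <- if (!is.null(fixed[[ax]])) fixed[[ax]]
                  else if (ax %in% all_axes) 0.1 else 0
  metrics <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    rates <- as.list(grid[i, c("beta", "sigma", "gamma", "xi")])
    mp <- sweep_point(model, variant, world, agents, rates, runs_per_cell,
                      T, seed = seed + (i - 1) * runs_per_cell, tau = tau,
                      overrides = overrides)
    metrics[[i]] <- cbind(model = model,
                          grid[i, c("beta", "sigma", "gamma", "xi")],
                          as.data.frame(mp), row.names = NULL)
    if (progress)
      message(sprintf("[%d/%d] %s", i, nrow(grid),
                      paste(names(rates), unlist(rates), sep = "=",
                            collapse = " ")))
  }
  metrics <- do.call(rbind, metrics)
  summary <- do.call(rbind, lapply(split(metrics, metrics$variable), function(d)
    data.frame(variable = d$variable[1],
               mean_nrmse = mean(d$nrmse), sd_nrmse = stats::sd(d$nrmse),
               mean_rho = mean(d$rho), sd_rho = stats::sd(d$rho),
               n = nrow(d))))
  rownames(summary) <- NULL
  summary <- summary[match(spec$states, summary$variable), , drop = FALSE]
  structure(list(model = model, variant = variant, world = world,
                 agents = agents, metrics = metrics, summary = summary,
                 grid = grid, runs_per_cell = runs_per_cell, T = T,
                 seed = seed, tau = tau),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> ", x$model, " (", x$variant, " ABM, ", x$world, "x",
      x$world, ", ", x$agents, " agents), ", nrow(x$grid),
      " grid points x ", x$runs_per_cell, " runs, ", x$T, " ticks\n",
      sep = "")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Two-axis equivalence heatmap matrices
#'
#' Varies two rates on a regular grid (others fixed) and returns per-variable
#' matrices of the adjusted correlation and NRMSE, the raw material for
#' equivalence heatmaps.
#'
#' @inheritParams run_sweep
#' @param axes Character vector of the two rates to vary.
#' @param step Grid step (default 0.05, anchored at 0.1).
#' @return List with `axes`, axis `values`, and per-variable matrices
#'   `rho[[v]]`, `nrmse[[v]]` (rows: first axis, columns: second axis).
#' @export
sweep_heatmap <- function(model, axes = c("beta", "gamma"),
                          variant = c("simple", "enhanced"), world = 33,
                          agents = 150, step = 0.05, runs_per_cell = 10,
                          T = 2000, seed = 1, tau = 0.05, fixed = list(),
                          overrides = list(), progress = FALSE) {
  variant <- match.arg(variant)
  stopifnot(length(axes) == 2)
  vals <- seq(0.1, 1, by = step)
  grid <- do.call(expand.grid, stats::setNames(list(vals, vals), axes))
  sw <- run_sweep(model, variant = variant, world = world, agents = agents,
                  runs_per_cell = runs_per_cell, T = T, seed = seed,
                  tau = tau, fixed = fixed, grid = grid,
                  overrides = overrides, progress = progress)
  vars <- unique(sw$metrics$variable)
  shape <- function(col) {
    lapply(stats::setNames(vars, vars), function(v) {
      d <- sw$metrics[sw$metrics$variable == v, ]
      matrix(d[[col]], nrow = length(vals), ncol = length(vals),
             dimnames = list(vals, vals))
    })
  }
  list(model = model, axes = axes, values = vals,
       rho = shape("rho"), nrmse = shape("nrmse"), sweep = sw)
}
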