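#' Longitudinal acceptance series
#'
#' Two mirrored percentage series over a biweekly sampling grid: the share
#' of the population accepting (`S_RW`, the susceptible analogue) and not
#' accepting (`I_RW`, the infected analogue), summing to 100 at every point.
#'
#' @param week Week indices (typically `seq(0, 36, by = 2)`, 19 points).
#' @param S_RW Percent accepting.
#' @param I_RW Percent not accepting; defaults to `100 - S_RW`.
#' @return Data frame of class `acceptance_series`.
#' @export
acceptance_series <- function(week, S_RW, I_RW = 100 - S_RW) {
  if (length(week) != length(S_RW) || length(S_RW) != length(I_RW))
    stop("week, S_RW, I_RW must have equal length", call. = FALSE)
  if (any(abs(S_RW + I_RW - 100) > 1e-6))
    stop("S_RW and I_RW must be mirrored percentages summing to 100",
         call. = FALSE)
  if (any(S_RW < 0 | S_RW > 100))
    stop("S_RW must lie in [0, 100]", call. = FALSE)
  structure(data.frame(week = week, S_RW = S_RW, I_RW = I_RW),
            class = c("acceptance_series", "data.frame"))
}

#' Bin a series by window averaging
#'
#' Reduces a model output series to `n_bins` points by averaging over
#' `n_bins` contiguous, near-equal windows (used to bring tick-resolution
#' simulations down to the sampling grid of a real-world series).
#'
#' @param raw Numeric series, length `>= n_bins`.
#' @param n_bins Number of output points.
#' @return Numeric vector of length `n_bins`.
#' @examples
#' bin_series(c(1, 2, 3, 4), 2)  # c(1.5, 3.5)
#' @export
bin_series <- function(raw, n_bins) {
  L <- length(raw)
  if (n_bins < 1 || n_bins != round(n_bins))
    stop("n_bins must be a positive integer", call. = FALSE)
  if (L < n_bins)
    stop("series shorter than the number of bins", call. = FALSE)
  bounds <- floor(seq_len(n_bins) * L / n_bins)
  starts <- c(0, bounds[-n_bins]) + 1
  vapply(seq_len(n_bins),
         function(i) mean(raw[starts[i]:bounds[i]]), numeric(1))
}

# parameter bounds of the two search spaces. Rates are searched on a log
# scale (they span decades; the floor only affects sampling, the full
# interval including 0 remains valid input), integer dims are rounded.
dim_spec <- function(lo, hi, int = FALSE, log = FALSE)
  list(lo = lo, hi = hi, int = int, log = log)

fit_bounds <- function(model_kind) {
  rate <- dim_spec(0, 1, log = TRUE)
  if (model_kind == "ebm")
    list(beta = rate, gamma = rate, T_F = dim_spec(1, 336, int = TRUE))
  else
    list(beta = rate, gamma = rate, P_M = dim_spec(1, 15),
         T_F = dim_spec(1, 336, int = TRUE), I_R = rate,
         L_M_S = dim_spec(1, 100, int = TRUE),
         L_M_I = dim_spec(1, 100, int = TRUE),
         L_P_S = dim_spec(1, 100, int = TRUE),
         L_P_I = dim_spec(1, 100, int = TRUE),
         D_P_S = dim_spec(1, 25, int = TRUE),
         D_P_I = dim_spec(1, 25, int = TRUE))
}

LOG_FLOOR <- 1e-5
to_search <- function(v, b) if (b$log) log(max(v, LOG_FLOOR)) else v
from_search <- function(u, b) {
  v <- if (b$log) exp(u) else u
  v <- min(max(v, b$lo), b$hi)
  if (b$int) round(v) else v
}
search_range <- function(b)
  if (b$log) log(c(max(b$lo, LOG_FLOOR), b$hi)) else c(b$lo, b$hi)

#' Calibration problem for the SIS acceptance fit
#'
#' Defines the multi-objective search (maximize Pearson rho, minimize NRMSE
#' of the model susceptible series against the acceptance series) over the
#' parameter space of the chosen model family. The equation-based space is
#' `{beta, gamma, T_F}`; the agent-based space adds the population
#' multiplier, information regrowth, energy losses and posting delays.
#'
#' @param target An [acceptance_series()].
#' @param model_kind `"ebm"` (discrete SIS) or `"abm"` (enhanced SIS ABM).
#' @param budget Number of trials the sampler may evaluate.
#' @param seed Integer seed making the whole search reproducible.
#' @param n_abm_runs Agent-based runs averaged per candidate evaluation.
#' @param world Grid side used for agent-based candidates.
#' @param tau Zero-variance adjustment threshold for rho.
#' @return A list of class `fit_problem`.
#' @export
fit_problem <- function(target, model_kind = c("ebm", "abm"), budget = 300,
                        seed = 1, n_abm_runs = 3, world = 33, tau = 0.05) {
  model_kind <- match.arg(model_kind)
  stopifnot(inherits(target, "acceptance_series"))
  if (budget < 1) stop("budget must be >= 1", call. = FALSE)
  structure(list(target = target, model_kind = model_kind,
                 budget = as.integer(budget), seed = as.integer(seed),
                 n_abm_runs = n_abm_runs, world = world, tau = tau,
                 bounds = fit_bounds(model_kind),
                 weeks_span = max(target$week)),
            class = "fit_problem")
}

check_bounds <- function(params, bounds) {
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    v <- params[[nm]]
    if (is.null(v) || !is.finite(v) || v < b$lo || v > b$hi)
      stop("parameter '", nm, "' missing or outside [", b$lo, ", ", b$hi,
           "]", call. = FALSE)
    if (b$int && v != round(v))
      stop("parameter '", nm, "' must be an integer", call. = FALSE)
  }
  invisible(TRUE)
}

#' Evaluate one candidate parameter set
#'
#' Simulates the SIS model of the problem's family for `T_F` ticks per
#' real-world week over the target horizon, with the susceptible/infected
#' split initialized to approximate the first datapoint and the population
#' normalized to percentages. The tick-resolution susceptible series is
#' binned to the target length and scored against `S_RW`.
#'
#' @param params Named list within the problem's bounds.
#' @param problem A [fit_problem()].
#' @return List with `rho` (zero-variance adjusted), `rho_raw`, `nrmse`,
#'   and the binned percent series `series`.
#' @export
evaluate_candidate <- function(params, problem) {
  stopifnot(inherits(problem, "fit_problem"))
  check_bounds(params, problem$bounds)
  target <- problem$target
  T <- as.integer(round(params$T_F) * problem$weeks_span)
  run_model <- if (problem$model_kind == "ebm") {
    function(s0) {
      tr <- simulate_ebm(ebm_params(beta = params$beta, gamma = params$gamma,
                                    N = 100),
                         ebm_state(S = s0, I = 100 - s0),
                         make_model_spec("SIS"), T)
      as.data.frame(tr)$S
    }
  } else {
    function(s0) {
      N <- max(1L, as.integer(round(100 * params$P_M)))
      I0 <- max(1L, min(N - 1L, as.integer(round(N * (100 - s0) / 100))))
      cfg <- enhanced_config("SIS", M = problem$world, N = N,
                             beta = params$beta, gamma = params$gamma,
                             I_R = params$I_R,
                             L_M_S = params$L_M_S, L_M_I = params$L_M_I,
                             L_P_S = params$L_P_S, L_P_I = params$L_P_I,
                             D_P_S = round(params$D_P_S),
                             D_P_I = round(params$D_P_I),
                             I0 = I0, case = "I",
                             seed = problem$seed)
      ens <- average_runs(cfg, T, runs = problem$n_abm_runs,
                          seeds = problem$seed + 0:(problem$n_abm_runs - 1))
      as.data.frame(ens$mean)$S / N * 100
    }
  }
  # initialize so the model's own first bin approximates the first
  # datapoint: one fixed-point correction on S(0) (a decaying series'
  # first window mean always sits below its starting value)
  s_rw0 <- target$S_RW[1]
  b1 <- bin_series(run_model(s_rw0), nrow(target))[1]
  s0 <- min(max(s_rw0 + (s_rw0 - b1), 0), 100)
  binned <- bin_series(run_model(s0), nrow(target))
  e <- nrmse(binned, target$S_RW)
  r_raw <- pearson_rho(binned, target$S_RW)
  adj <- adjust_rho(r_raw, e, problem$tau)
  list(rho = adj$rho, rho_raw = r_raw, nrmse = e, series = binned)
}

# scalarization used inside the sampler (reporting uses the Pareto front)
fit_score <- function(rho, nrmse) nrmse + 0.25 * (1 - rho)

# draw one candidate: TPE-style density-ratio sampling over the evaluated
# trials (good/bad split at the lower score quartile). All kernel work
# happens in the search scale (log scale for rate dimensions).
sample_candidate <- function(bounds, trials, n_cand = 24) {
  nms <- names(bounds)
  if (nrow(trials) < 8) {  # not enough history: uniform draw in search scale
    out <- lapply(nms, function(nm) {
      b <- bounds[[nm]]
      r <- search_range(b)
      from_search(stats::runif(1, r[1], r[2]), b)
    })
    return(stats::setNames(out, nms))
  }
  q <- stats::quantile(trials$score, 0.25, names = FALSE)
  good <- trials[trials$score <= q, , drop = FALSE]
  bad <- trials[trials$score > q, , drop = FALSE]
  if (nrow(good) < 2) {
    ord <- order(trials$score)
    good <- trials[ord[1:2], , drop = FALSE]
  }
  if (nrow(bad) < 2) bad <- trials
  kde_bw <- function(x, b) {
    r <- search_range(b)
    max(1.06 * stats::sd(x) * length(x)^(-0.2), 0.01 * (r[2] - r[1]), 1e-8)
  }
  log_dens <- function(x, pts, bw) log(mean(stats::dnorm(x, pts, bw)) + 1e-300)
  gs <- lapply(nms, function(nm)
    vapply(good[[nm]], to_search, numeric(1), b = bounds[[nm]]))
  bs <- lapply(nms, function(nm)
    vapply(bad[[nm]], to_search, numeric(1), b = bounds[[nm]]))
  names(gs) <- names(bs) <- nms
  # joint perturbations around anchor trials, so correlated good regions
  # (e.g. a rate ratio) are preserved in the proposals
  cand <- matrix(0, n_cand, length(nms), dimnames = list(NULL, nms))
  anchors <- sample.int(nrow(good), n_cand, replace = TRUE)
  for (j in seq_along(nms)) {
    b <- bounds[[nms[j]]]
    bw <- kde_bw(gs[[j]], b)
    r <- search_range(b)
    cand[, j] <- pmin(pmax(stats::rnorm(n_cand, gs[[j]][anchors], bw), r[1]),
                      r[2])
  }
  ratio <- numeric(n_cand)
  for (j in seq_along(nms)) {
    b <- bounds[[nms[j]]]
    bwg <- kde_bw(gs[[j]], b); bwb <- kde_bw(bs[[j]], b)
    for (k in seq_len(n_cand))
      ratio[k] <- ratio[k] + log_dens(cand[k, j], gs[[j]], bwg) -
                             log_dens(cand[k, j], bs[[j]], bwb)
  }
  best <- which.max(ratio)
  out <- lapply(seq_along(nms), function(j)
    from_search(cand[best, j], bounds[[nms[j]]]))
  stats::setNames(out, nms)
}

#' Fit a model family to an acceptance series
#'
#' Multi-objective calibration: maximize the Pearson correlation and
#' minimize the NRMSE of the model susceptible series against the target.
#' Candidates are proposed by a seeded Tree-structured-Parzen-Estimator-style
#' sampler (Latin-hypercube warmup, then sampling from a kernel-density
#' model of the best quartile weighted by the good/bad density ratio). The
#' reported best is chosen lexicographically (NRMSE ascending, then rho
#' descending) among the Pareto-front trials.
#'
#' @param problem A [fit_problem()].
#' @return A `fit_result`: list with `best_params`, `best_rho`,
#'   `best_nrmse`, `best_series`, `trials` (full trace), and `pareto`
#'   (indices of non-dominated trials).
#' @export
fit_model <- function(problem) {
  stopifnot(inherits(problem, "fit_problem"))
  bounds <- problem$bounds
  nms <- names(bounds)
  budget <- problem$budget
  with_local_seed(problem$seed, {
    # evaluation budget: LHS warmup, TPE-style sampling, then a
    # derivative-free polish of the continuous dimensions
    n_polish <- if (budget >= 50) min(120, floor(budget / 3)) else 0
    n_tpe <- budget - n_polish
    n0 <- min(n_tpe, max(8, min(30, ceiling(budget / 5))))
    warm <- lhs::randomLHS(n0, length(nms))
    trials <- NULL
    results <- vector("list", budget)
    for (t in seq_len(n_tpe)) {
      params <- if (t <= n0) {
        stats::setNames(lapply(seq_along(nms), function(j) {
          b <- bounds[[nms[j]]]
          r <- search_range(b)
          from_search(r[1] + warm[t, j] * (r[2] - r[1]), b)
        }), nms)
      } else sample_candidate(bounds, trials)
      ev <- evaluate_candidate(params, problem)
      row <- as.data.frame(params)
      row$rho <- ev$rho; row$nrmse <- ev$nrmse
      row$score <- fit_score(ev$rho, ev$nrmse)
      row$trial <- t
      trials <- if (is.null(trials)) row else rbind(trials, row)
      results[[t]] <- ev
    }
    if (n_polish > 0) {
      cont <- nms[!vapply(bounds, `[[`, logical(1), "int")]
      # multi-start: the best trial overall plus the best at other integer
      # settings (the tick factor trades off against the rates, so distinct
      # settings index different basins)
      ord <- order(trials$score)
      anchors <- list(as.list(trials[ord[1], nms]))
      int_key <- function(row) paste(unlist(row[setdiff(nms, cont)]),
                                     collapse = "/")
      seen <- int_key(anchors[[1]])
      for (i in ord[-1]) {
        if (length(anchors) >= 3) break
        key <- int_key(as.list(trials[i, nms]))
        if (!key %in% seen) {
          anchors <- c(anchors, list(as.list(trials[i, nms])))
          seen <- c(seen, key)
        }
      }
      used <- 0
      if (length(cont) > 0) {
        for (anchor in anchors) {
          if (n_polish - used < 10 || min(trials$score) <= 0.02) break
          par0 <- vapply(cont, function(nm)
            to_search(anchor[[nm]], bounds[[nm]]), numeric(1))
          fn <- function(u) {
            params <- anchor
            for (j in seq_along(cont))
              params[[cont[j]]] <- from_search(u[j], bounds[[cont[j]]])
            ev <- evaluate_candidate(params, problem)
            used <<- used + 1
            row <- as.data.frame(params)
            row$rho <- ev$rho; row$nrmse <- ev$nrmse
            row$score <- fit_score(ev$rho, ev$nrmse)
            row$trial <- n_tpe + used
            trials <<- rbind(trials, row)
            results[[n_tpe + used]] <<- ev
            row$score
          }
          # short simplex runs with restarts: a fresh simplex at the last
          # endpoint escapes premature simplex collapse
          prev <- Inf
          repeat {
            left <- n_polish - used
            if (left < 10) break
            o <- try(stats::optim(par0, fn, method = "Nelder-Mead",
                                  control = list(maxit = min(35,
                                    floor(left / 1.5)))),
                     silent = TRUE)
            if (inherits(o, "try-error")) break
            par0 <- o$par
            if (o$value <= 0.02 || prev - o$value < 1e-4) break
            prev <- o$value
          }
        }
      }
    }
    rownames(trials) <- NULL
    dominated <- vapply(seq_len(nrow(trials)), function(i)
      any(trials$rho >= trials$rho[i] & trials$nrmse <= trials$nrmse[i] &
          (trials$rho > trials$rho[i] | trials$nrmse < trials$nrmse[i])),
      logical(1))
    pareto <- which(!dominated)
    pareto <- pareto[order(trials$nrmse[pareto], -trials$rho[pareto])]
    best <- pareto[1]
    structure(list(best_params = as.list(trials[best, nms]),
                   best_rho = trials$rho[best],
                   best_nrmse = trials$nrmse[best],
                   best_series = results[[best]]$series,
                   trials = trials, pareto = pareto, problem = problem),
              class = "fit_result")
  })
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> ", x$problem$model_kind, " fit, ",
      nrow(x$trials), " trials\n  best: rho = ", signif(x$best_rho, 4),
      ", NRMSE = ", signif(x$best_nrmse, 4), "\n  params: ",
      paste(names(x$best_params), signif(unlist(x$best_params), 4),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}
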