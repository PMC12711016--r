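#' Pearson correlation between two outcome series
#'
#' Sample correlation `cov(ya, ye) / (sd(ya) sd(ye))` between homonymous
#' outcome variables of two models over the same sampling grid. The
#' correlation is undefined when either series has zero variance (a constant
#' compartment); this is signalled with `NA` so that the zero-variance
#' adjustment rule ([adjust_rho()]) can be applied.
#'
#' @param ya,ye Numeric series of equal length `>= 2`.
#' @return Correlation in `[-1, 1]`, or `NA_real_` when undefined.
#' @examples
#' pearson_rho(1:10, (1:10) * 2)   # 1
#' pearson_rho(1:10, rep(5, 10))   # NA: zero variance
#' @export
pearson_rho <- function(ya, ye) {
  if (length(ya) != length(ye))
    stop("series must have equal length", call. = FALSE)
  if (length(ya) < 2) stop("need at least two samples", call. = FALSE)
  sa <- stats::sd(ya); se <- stats::sd(ye)
  if (sa == 0 || se == 0) return(NA_real_)
  r <- stats::cov(ya, ye) / (sa * se)
  max(-1, min(1, r))
}

#' Normalized root-mean-square error between two series
#'
#' Root-mean-square error divided by the pooled range of both series
#' (`max` and `min` taken over `ya` and `ye` together), giving a
#' dimensionless score in `[0, 1]`: 0 is a perfect match, 1 the worst
#' possible. Two identical constant series have zero pooled range and return
#' 0 by convention.
#'
#' @param ya,ye Numeric series of equal length.
#' @return NRMSE in `[0, 1]`.
#' @examples
#' nrmse(c(0, 1), c(1, 0))  # 1
#' @export
nrmse <- function(ya, ye) {
  if (length(ya) != length(ye))
    stop("series must have equal length", call. = FALSE)
  rng <- max(ya, ye) - min(ya, ye)
  if (rng == 0) return(0)
  sqrt(mean((ya - ye)^2)) / rng
}

#' Zero-variance adjustment of an undefined correlation
#'
#' When a compartment is constant in one of the two models the Pearson
#' correlation cannot be calculated; to avoid skewing grid summaries the
#' pair is scored as a match (1) or not-a-match (0) based on its NRMSE.
#'
#' @param rho Correlation or `NA` sentinel from [pearson_rho()].
#' @param nrmse NRMSE of the same pair.
#' @param tau Match threshold on NRMSE (default 0.05).
#' @return List with `rho` (the possibly adjusted value) and `adjusted` flag.
#' @examples
#' adjust_rho(NA_real_, 0.01)  # rho = 1
#' adjust_rho(0.6, 0.4)        # passthrough
#' @export
adjust_rho <- function(rho, nrmse, tau = 0.05) {
  if (!is.na(rho)) return(list(rho = rho, adjusted = FALSE))
  list(rho = if (nrmse <= tau) 1 else 0, adjusted = TRUE)
}

#' Equivalence metrics for homonymous variable pairs
#'
#' Computes one `(rho, NRMSE)` pair per active compartment of two
#' trajectories from the same model class (e.g. the SI agent-based
#' susceptible series against the SI equation-based susceptible series),
#' applying the zero-variance adjustment.
#'
#' @param abm,ebm `trajectory` objects of the same model class and length.
#' @param tau Zero-variance match threshold passed to [adjust_rho()].
#' @return Data frame of class `metric_pairs`: `variable`, `rho_raw`
#'   (`NA` when undefined), `rho` (adjusted), `nrmse`, `adjusted`.
#' @export
compare_trajectories <- function(abm, ebm, tau = 0.05) {
  ma <- attr(abm, "model"); me <- attr(ebm, "model")
  if (!identical(ma, me))
    stop("model class mismatch: '", ma, "' vs '", me, "'", call. = FALSE)
  if (nrow(abm) != nrow(ebm))
    stop("trajectories must have the same length", call. = FALSE)
  spec <- make_model_spec(ma)
  rows <- lapply(spec$states, function(v) {
    ya <- as.data.frame(abm)[[v]]; ye <- as.data.frame(ebm)[[v]]
    r <- pearson_rho(ya, ye)
    e <- nrmse(ya, ye)
    adj <- adjust_rho(r, e, tau)
    data.frame(variable = v, rho_raw = r, rho = adj$rho, nrmse = e,
               adjusted = adj$adjusted)
  })
  structure(do.call(rbind, rows), class = c("metric_pairs", "data.frame"))
}
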