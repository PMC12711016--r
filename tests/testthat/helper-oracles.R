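# Independent reference implementations used as oracles. These deliberately
# avoid the package's code paths (and stats::cor/cov shortcuts) so that
# agreement is informative.

# two-pass Pearson correlation
naive_pearson <- function(ya, ye) {
  n <- length(ya)
  ma <- sum(ya) / n; me <- sum(ye) / n
  cv <- sum((ya - ma) * (ye - me)) / (n - 1)
  sa <- sqrt(sum((ya - ma)^2) / (n - 1))
  se <- sqrt(sum((ye - me)^2) / (n - 1))
  if (sa == 0 || se == 0) return(NA_real_)
  cv / (sa * se)
}

naive_nrmse <- function(ya, ye) {
  rng <- max(c(ya, ye)) - min(c(ya, ye))
  if (rng == 0) return(0)
  sqrt(sum((ya - ye)^2) / length(ya)) / rng
}

# straight transcription of the four-compartment flux template, one tick
euler_oracle <- function(S, E, I, R, beta, sigma, gamma, xi, N,
                         has_E, rec_mode, has_xi) {
  inf <- beta * S * I / N
  inc <- if (has_E) sigma * E else 0
  rec <- if (rec_mode != "none") gamma * I else 0
  loss <- if (has_xi) xi * R else 0
  if (has_E) {
    c(S = S - inf + loss, E = E + inf - inc,
      I = I + inc - rec + if (rec_mode == "none") 0 else 0,
      R = R + (if (rec_mode == "to_R") rec else 0) - loss)
  } else {
    c(S = S - inf + loss + (if (rec_mode == "to_S") rec else 0), E = 0,
      I = I + inf - rec,
      R = R + (if (rec_mode == "to_R") rec else 0) - loss)
  }
}

# exhaustive cone scan replicating the documented target tie-break
brute_target <- function(x, y, heading, q, r, theta) {
  M <- nrow(q)
  best <- NULL
  for (dy in -ceiling(r):ceiling(r)) for (dx in -ceiling(r):ceiling(r)) {
    if (dx == 0 && dy == 0) next
    d <- sqrt(dx^2 + dy^2)
    if (d > r + 1e-9) next
    ang <- atan2(dy, dx) * 180 / pi
    diff <- abs(((ang - heading + 540) %% 360) - 180)
    if (diff > theta / 2 + 1e-9) next
    gx <- (x + dx) %% M; gy <- (y + dy) %% M
    idx <- gy * M + gx
    qv <- q[gy + 1, gx + 1]
    cand <- list(x = gx, y = gy, q = qv, d = d, idx = idx)
    if (is.null(best) || qv > best$q ||
        (qv == best$q && d < best$d - 1e-9) ||
        (qv == best$q && abs(d - best$d) <= 1e-9 && idx < best$idx))
      best <- cand
  }
  best
}

# brute-force window averaging
brute_bins <- function(x, n) {
  L <- length(x)
  ends <- floor(seq_len(n) * L / n)
  starts <- c(0, ends[-n]) + 1
  sapply(seq_len(n), function(i) mean(x[starts[i]:ends[i]]))
}

all_models <- c("SI", "SIS", "SIR", "SIRS", "SEIR", "SEIRS")

tiny_world <- function(model = "SI", M = 11, N = 12, beta = 0.5, ...) {
  world_config(model, M = M, N = N, beta = beta, ...)
}
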