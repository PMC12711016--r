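test_that("model specs encode the transition structure of the family", {
  si <- make_model_spec("SI")
  expect_setequal(si$states, c("S", "I"))
  expect_identical(si$transitions, "infection")

  seirs <- make_model_spec("SEIRS")
  expect_setequal(seirs$states, c("S", "E", "I", "R"))
  expect_setequal(seirs$transitions,
                  c("infection", "incubation", "recovery", "immunity_loss"))

  # E is a state exactly when incubation is a transition
  for (m in all_models) {
    spec <- make_model_spec(m)
    expect_identical("E" %in% spec$states,
                     "incubation" %in% spec$transitions, info = m)
  }
  # SIS recovers back to S, SIR onwards to R
  expect_identical(make_model_spec("SIS")$rec_mode, "to_S")
  expect_identical(make_model_spec("SIR")$rec_mode, "to_R")

  expect_error(make_model_spec("SEIRX"), "unknown model")
})

test_that("parameter and state validation rejects out-of-range input", {
  expect_error(ebm_params(beta = 1.2), "rates")
  expect_error(ebm_params(beta = 0.5, N = 0), "N must")
  expect_error(ebm_state(S = -1), "non-negative")
  expect_error(simulate_ebm(ebm_params(N = 10), ebm_state(S = 10),
                            make_model_spec("SI"), T = -1), "non-negative")
})

test_that("one Euler step reproduces the hand-computed SEIRS example", {
  s <- ebm_step(ebm_state(S = 990, E = 0, I = 10, R = 0),
                ebm_params(beta = 0.2, sigma = 0.1, gamma = 0.05, xi = 0.01,
                           N = 1000),
                make_model_spec("SEIRS"))
  expect_equal(c(s$S, s$E, s$I, s$R), c(988.02, 1.98, 9.50, 0.50),
               tolerance = 1e-12)
})

test_that("inactive or zero-rate transitions leave the state unchanged", {
  for (m in all_models) {
    spec <- make_model_spec(m)
    s <- ebm_step(ebm_state(S = 100), ebm_params(0.5, 0.5, 0.5, 0.5, 100),
                  spec)
    expect_equal(c(s$S, s$E, s$I, s$R), c(100, 0, 0, 0), info = m)
  }
  s <- ebm_step(ebm_state(S = 90, I = 10),
                ebm_params(beta = 0, N = 100), make_model_spec("SI"))
  expect_equal(c(s$S, s$I), c(90, 10))
})

test_that("ebm_step agrees with an independent flux transcription", {
  set.seed(42)
  for (k in 1:100) {
    m <- sample(all_models, 1)
    spec <- make_model_spec(m)
    N <- 1000
    v <- as.vector(stats::rmultinom(1, N, rep(0.25, 4)))
    if (!spec$has_E) { v[1] <- v[1] + v[2]; v[2] <- 0 }
    if (!"R" %in% spec$states) { v[1] <- v[1] + v[4]; v[4] <- 0 }
    r <- runif(4)
    got <- ebm_step(ebm_state(v[1], v[2], v[3], v[4]),
                    ebm_params(r[1], r[2], r[3], r[4], N), spec)
    want <- euler_oracle(v[1], v[2], v[3], v[4], r[1], r[2], r[3], r[4], N,
                         spec$has_E, spec$rec_mode, spec$has_xi)
    expect_equal(c(got$S, got$E, got$I, got$R), unname(want),
                 tolerance = 1e-12, info = paste(m, k))
  }
})

test_that("trajectories conserve the population for every model", {
  set.seed(7)
  for (m in all_models) {
    spec <- make_model_spec(m)
    r <- runif(4, 0.1, 1)
    N <- 500
    tr <- simulate_ebm(ebm_params(r[1], r[2], r[3], r[4], N),
                       ebm_state(S = 450, I = 50), spec, T = 300)
    tot <- rowSums(trajectory_states(tr))
    expect_lt(max(abs(tot - N)), 1e-9 * N)
    expect_true(all(trajectory_states(tr) >= -1e-12))
  }
})

test_that("simulate_ebm matches iterated single steps", {
  spec <- make_model_spec("SEIRS")
  p <- ebm_params(0.7, 0.3, 0.6, 0.2, 200)
  tr <- simulate_ebm(p, ebm_state(S = 150, E = 20, I = 20, R = 10), spec, 50)
  s <- ebm_state(S = 150, E = 20, I = 20, R = 10)
  for (t in 1:50) s <- ebm_step(s, p, spec)
  expect_equal(unlist(as.data.frame(tr)[51, c("S", "E", "I", "R")]),
               c(S = s$S, E = s$E, I = s$I, R = s$R), tolerance = 1e-12)
})

test_that("degenerate and monotone cases behave as closed-form analysis says", {
  spec <- make_model_spec("SI")
  p <- ebm_params(beta = 1, N = 100)
  tr0 <- simulate_ebm(p, ebm_state(S = 90, I = 10), spec, 0)
  expect_identical(nrow(tr0), 1L)
  expect_equal(as.data.frame(tr0)$S, 90)

  tr <- simulate_ebm(p, ebm_state(S = 90, I = 10), spec, 200)
  expect_true(all(diff(as.data.frame(tr)$I) >= -1e-12))

  # SIS endemic level: I converges to N (1 - gamma/beta)
  p2 <- ebm_params(beta = 0.6, gamma = 0.2, N = 1000)
  tr2 <- simulate_ebm(p2, ebm_state(S = 990, I = 10),
                      make_model_spec("SIS"), 3000)
  expect_equal(utils::tail(as.data.frame(tr2)$I, 1),
               1000 * (1 - 0.2 / 0.6), tolerance = 1e-6)
})

test_that("reduced models nest inside the SEIRS template", {
  pS <- ebm_params(0.4, 0.3, 0.2, 0, 300)
  init <- ebm_state(S = 250, E = 20, I = 20, R = 10)
  a <- simulate_ebm(pS, init, make_model_spec("SEIRS"), 400)
  b <- simulate_ebm(pS, init, make_model_spec("SEIR"), 400)
  expect_equal(trajectory_states(a), trajectory_states(b),
               tolerance = 1e-14)

  # sigma = 1 drains E each tick: E stays below the max infection flux
  pE <- ebm_params(beta = 0.8, sigma = 1, gamma = 0.1, xi = 0, N = 400)
  trE <- simulate_ebm(pE, ebm_state(S = 380, I = 20),
                      make_model_spec("SEIRS"), 300)
  expect_true(all(as.data.frame(trE)$E <= 0.8 * 400 / 4 + 1e-9))
})
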