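test_that("group assignment is seeded, proportional and reproducible", {
  cfg <- enhanced_config("SI", M = 33, N = 1350, beta = 0.2, seed = 1)
  w <- init_world(cfg)
  g1 <- assign_groups(w, 1, seed = 5)
  expect_true(all(g1$group == 1L))
  g <- assign_groups(w, 0.8, seed = 5)
  expect_equal(sum(g$group == 1L), 1080, tolerance = 40 / 1080)
  g2 <- assign_groups(w, 0.8, seed = 5)
  expect_identical(g$group, g2$group)
  expect_false(identical(g$group, assign_groups(w, 0.8, seed = 6)$group))
})

test_that("the homophily gate only allows same-group belief", {
  expect_true(homophily_gate(list(group = 1), list(group = 1)))
  expect_true(homophily_gate(list(group = 2), list(group = 2)))
  expect_false(homophily_gate(list(group = 1), list(group = 2)))
  expect_error(homophily_gate(list(group = NA), list(group = 1)), "group tag")
  expect_error(homophily_gate(list(), list(group = 1)), "group tag")
})

test_that("posting deposits the poster's information type after the delay", {
  cfg <- enhanced_config("SI", beta = 0.2, L_P_S = 0, L_P_I = 3,
                         D_P_S = 4, D_P_I = 2)
  cell <- list(q_true = 1, q_false = 0)
  inf <- list(status = "I", energy = 10, post_timer = 0, armed = TRUE)
  out <- post_information(inf, cell, cfg)
  expect_true(out$posted)
  expect_equal(out$cell$q_false, 1)       # infected posts false content
  expect_equal(out$agent$energy, 7)       # pays L_P_I
  expect_equal(out$agent$post_timer, 2)   # D_P_I restarts

  sus <- list(status = "S", energy = 10, post_timer = 0, armed = TRUE)
  out2 <- post_information(sus, cell, cfg)
  expect_equal(out2$cell$q_true, 2)
  expect_equal(out2$agent$energy, 10)     # L_P_S = 0

  # timer not expired: nothing happens
  late <- list(status = "I", energy = 10, post_timer = 3, armed = TRUE)
  out3 <- post_information(late, cell, cfg)
  expect_false(out3$posted)
  expect_identical(out3$cell, cell)
  expect_equal(out3$agent$energy, 10)
})

test_that("consumption conserves energy-plus-content and arms posting", {
  cfg <- enhanced_config("SI", beta = 0.2, consume_bite = 1, D_P_S = 6)
  agent <- list(status = "S", energy = 2, post_timer = 0, armed = FALSE)
  cell <- list(q_true = 0.6, q_false = 0.9)
  before <- agent$energy + cell$q_true + cell$q_false
  out <- consume_information(agent, cell, cfg)
  after <- out$agent$energy + out$cell$q_true + out$cell$q_false
  expect_equal(after, before)                       # 1:1 bookkeeping
  expect_equal(out$consumed, 1)
  expect_equal(out$cell$q_false / out$cell$q_true, 0.9 / 0.6,
               tolerance = 1e-12)                   # proportional depletion
  # the consume-then-post delay contract
  expect_true(out$agent$armed)
  expect_equal(out$agent$post_timer, 6)
  blocked <- post_information(out$agent, out$cell, cfg)
  expect_false(blocked$posted)

  # empty cell: no gain, no change
  out0 <- consume_information(agent, list(q_true = 0, q_false = 0), cfg)
  expect_equal(out0$consumed, 0)
  expect_equal(out0$agent$energy, 2)
})

test_that("environmental infection scales with local false information", {
  expect_equal(stigmergy_probability(0, 1, 10), 0)     # all-true cell
  expect_equal(stigmergy_probability(5, 0, 10), 0)     # beta = 0
  expect_equal(stigmergy_probability(10, 1, 10), 0.5)  # saturated, beta = 1
  expect_equal(stigmergy_probability(2.5, 0.8, 10), 0.5 * 0.8 * 0.25)

  cfg <- enhanced_config("SEIRS", beta = 1, sigma = .5, gamma = .5, xi = .5)
  set.seed(1)
  ag <- stigmergy_infection(list(status = "S"), list(q_false = 1e9), 1, cfg)
  expect_identical(ag$status, "E")  # incubating models transition to E
})

test_that("with inert channels the enhanced model reduces to the simple one", {
  s <- run_abm(world_config("SI", M = 33, N = 150, beta = 0.2, seed = 9), 300)
  e <- run_abm(enhanced_config("SI", M = 33, N = 150, beta = 0.4,
                               consume_bite = 0, post_quantum = 0,
                               I_R = 0.1, group_fraction = 1, seed = 9), 300)
  expect_identical(s$S, e$S)  # same seed, halved contact beta
})

test_that("disabling both infection channels freezes all susceptibles", {
  cfg <- enhanced_config("SI", M = 21, N = 60, beta = 0, seed = 3)
  tr <- run_abm(cfg, 200)
  expect_true(all(tr$S == tr$S[1]))
})

test_that("cell truth bookkeeping stays non-negative and capped", {
  cfg <- enhanced_config("SI", M = 21, N = 60, beta = 0.8, q_max = 10,
                         seed = 13)
  tr <- run_abm(cfg, 300)
  w <- attr(tr, "world")
  expect_true(all(w$q_true >= 0))
  expect_true(all(w$q_false >= 0))
  expect_true(all(w$q_true + w$q_false <= 10 + 1e-9))
})

test_that("homophily seals groups against cross-group contact infection", {
  # no environmental channel (nothing is ever posted), gate on
  cfg <- enhanced_config("SI", M = 33, N = 300, beta = 1, post_quantum = 0,
                         group_fraction = 0.5, homophily = TRUE, seed = 17)
  tr <- run_abm(cfg, 400, record_events = TRUE)
  ev <- attr(tr, "events")
  contact <- ev[ev$channel == "contact", ]
  expect_gt(nrow(contact), 0)
  expect_true(all(contact$src_group == contact$tgt_group))
  expect_identical(nrow(ev[ev$channel == "environment", ]), 0L)

  # gate off: cross-group infections do occur
  cfg2 <- enhanced_config("SI", M = 33, N = 300, beta = 1, post_quantum = 0,
                          group_fraction = 0.5, homophily = FALSE, seed = 17)
  ev2 <- attr(run_abm(cfg2, 400, record_events = TRUE), "events")
  expect_gt(sum(ev2$src_group != ev2$tgt_group & ev2$channel == "contact"), 0)
})

test_that("homophily with unequal groups changes the infection dynamics", {
  base <- list(model = "SI", M = 33, N = 150, beta = 0.5, seed = 23)
  gated <- do.call(enhanced_config, c(base, list(group_fraction = 0.8,
                                                 homophily = TRUE)))
  open <- do.call(enhanced_config, c(base, list(group_fraction = 0.8,
                                                homophily = FALSE)))
  mg <- average_runs(gated, 300, runs = 8)
  mo <- average_runs(open, 300, runs = 8)
  ig <- as.data.frame(mg$mean)$I; io <- as.data.frame(mo$mean)$I
  expect_gt(max(abs(ig - io)), 0)
  # blocking cross-group belief slows the outbreak
  expect_gt(which(ig >= 75)[1], which(io >= 75)[1])
})
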