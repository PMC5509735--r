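# LIF integration, fire generation, feedback bookkeeping, and the
# epoch-quantized engine.

test_that("integration sums gated conductances in LRS units", {
  cfg <- network_config()
  net <- new_network(cfg, "lrs")
  net <- integrate_epoch(net, 1, c(1, 1, rep(0, 14)))
  expect_equal(net$v_int, 2.0)          # 2 full-LRS spikes = threshold
  expect_true(check_fire(net, 1))

  # no active PREs: potential unchanged
  v0 <- net$v_int
  net <- integrate_epoch(net, 1, rep(0, 16))
  expect_equal(net$v_int, v0)

  # mixed states: direct conductance-sum oracle
  R <- matrix(1e6, 1, 16)
  R[1, 1:3] <- 1e4
  net2 <- new_network(cfg, R)
  mask <- c(rep(1, 4), rep(0, 12))
  net2 <- integrate_epoch(net2, 1, mask)
  oracle <- sum(mask / R[1, ]) / (1 / 1e4)
  expect_equal(net2$v_int, oracle)
  expect_equal(net2$v_int, 3.01)

  expect_error(integrate_epoch(net, 5, mask), "out of range")
  expect_error(integrate_epoch(net, 1, rep(1, 9)), "16 PREs")
})

test_that("potential is non-decreasing in every active conductance", {
  cfg <- network_config()
  set.seed(51)
  for (i in 1:10) {
    R <- matrix(10^runif(16, 4, 6), 1, 16)
    mask <- as.numeric(runif(16) < 0.5)
    base <- integrate_epoch(new_network(cfg, R), 1, mask)$v_int
    j <- sample(which(mask > 0), 1)
    R2 <- R
    R2[1, j] <- R2[1, j] / 2           # double one active conductance
    expect_gte(integrate_epoch(new_network(cfg, R2), 1, mask)$v_int, base)
  }
})

test_that("fire threshold uses the fire-at-threshold convention", {
  net <- new_network(network_config())
  net$v_int <- 2.0
  expect_true(check_fire(net))
  net$v_int <- 1.99
  expect_false(check_fire(net))
  net$v_int <- 0
  expect_false(check_fire(net))
})

test_that("fire events potentiate open gates, discharge, and inhibit peers", {
  cfg <- network_config(n_pre = 9, n_post = 2)
  net <- new_network(cfg, "hrs")
  net$v_int <- c(2.5, 1.0)
  a <- c(1, 1, 1, rep(0, 6))
  out <- fire_event(net, 1, a)
  expect_equal(out$R[1, 1:3], rep(1e4, 3))   # open gates set to LRS
  expect_equal(out$R[1, 4:9], rep(1e6, 6))   # closed gates untouched
  expect_equal(out$R[2, ], rep(1e6, 9))      # other POST untouched
  expect_equal(out$v_int[1], 0)              # discharge
  expect_equal(out$v_int[2], 0.6)            # 40% winner-take-all inhibition
  expect_true(out$pending[1])

  expect_error(fire_event(new_network(cfg), 1, a), "threshold")
  expect_error(fire_event(net, 3, a), "out of range")
})

test_that("lateral inhibition is multiplicative and never goes negative", {
  cfg <- network_config(n_pre = 9, n_post = 2)
  set.seed(61)
  for (i in 1:20) {
    net <- new_network(cfg, "hrs")
    net$v_int <- c(2 + runif(1, 0, 3), runif(1, 0, 4))
    out <- fire_event(net, 1, rep(0, 9))
    expect_gte(out$v_int[2], 0)
    expect_equal(out$v_int[2], net$v_int[2] * 0.6)
  }
})

test_that("recognition mode fires without any synaptic side effect", {
  cfg <- network_config(stdp_enabled = FALSE)
  net <- new_network(cfg, "hrs")
  net$v_int <- 3
  out <- fire_event(net, 1, rep(1, 16))
  expect_identical(out$R, net$R)
  expect_false(out$pending[1])
  expect_equal(out$v_int[1], 0)
})

test_that("a noise frame right after a fire depresses its synapses", {
  cfg <- network_config()
  pat <- builtin_pattern("diag4")
  net <- new_network(cfg, ideal_weights(pat))
  out1 <- step_epoch(net, pat)             # pattern epoch: fire
  expect_true(out1$events$fired[1])
  expect_true(out1$net$pending[1])
  noise <- rep(0, 16)
  noise[2] <- 1                            # one background PRE active
  out2 <- step_epoch(out1$net, noise)      # pending negative pulse lands
  expect_false(out2$events$fired[1])
  expect_equal(out2$net$R[1, 2], 1e6)      # that synapse reset to HRS
  expect_false(out2$net$pending[1])
  expect_equal(out2$events$n_reset, 0L)    # it was HRS already: no switch
})

test_that("a new fire replaces the pending negative pulse, protecting the pattern", {
  cfg <- network_config()
  pat <- builtin_pattern("diag4")
  net <- new_network(cfg, ideal_weights(pat))
  out1 <- step_epoch(net, pat)
  out2 <- step_epoch(out1$net, pat)        # pattern again: fires again
  expect_true(out2$events$fired[1])
  mask <- as_pre_vector(pat) > 0
  expect_equal(out2$net$R[1, mask], rep(1e4, 4))  # pattern stays LRS
  expect_true(out2$net$pending[1])
})

test_that("epoch stepping matches the fresh-network arithmetic", {
  cfg <- network_config()
  pat <- builtin_pattern("diag4")
  # all-HRS array: 4 active HRS synapses contribute 0.04 units, no fire
  out <- step_epoch(new_network(cfg, "hrs"), pat)
  expect_false(out$events$fired[1])
  expect_equal(out$net$v_int[1], 0.04)
  expect_equal(out$events$v_peak[1], 0.04)
  # learned array: 4 LRS units cross the threshold
  out2 <- step_epoch(new_network(cfg, ideal_weights(pat)), pat)
  expect_true(out2$events$fired[1])
  # empty stimulus: nothing changes (no leak by default)
  net3 <- new_network(cfg, "hrs")
  out3 <- step_epoch(net3, rep(0, 16))
  expect_equal(out3$net$v_int, net3$v_int)
  expect_identical(out3$net$R, net3$R)
  expect_error(step_epoch(net3, rep(1, 9)), "16 PREs")
})

test_that("every switching event lands on a binary level (sigma = 0)", {
  set.seed(71)
  cfg <- network_config(n_pre = 9, n_post = 1)
  net <- new_network(cfg, "random")
  for (e in 1:100) {
    stim <- make_noise(3, 3, 0.3)
    net <- step_epoch(net, stim)$net
    expect_true(all(net$R %in% c(1e4, 1e6)))
  }
})

test_that("with STDP disabled the weight vector is schedule-invariant", {
  set.seed(81)
  cfg <- network_config(n_pre = 9, stdp_enabled = FALSE)
  net <- new_network(cfg, "random")
  R0 <- net$R
  for (e in 1:50) net <- step_epoch(net, make_noise(3, 3, 0.5))$net
  expect_identical(net$R, R0)
})

test_that("optional potential decay leaks between epochs", {
  cfg <- network_config(decay = 0.5)
  net <- new_network(cfg, "hrs")
  net$v_int <- 1.0
  out <- step_epoch(net, rep(0, 16))
  expect_equal(out$net$v_int[1], 0.5)
})

test_that("graded stimulation orders learned conductances by gray level", {
  cfg <- network_config(n_pre = 4, n_post = 1)
  net <- new_network(cfg, "lrs")   # fire-capable immediately
  stim <- c(1.0, 0.5, 1.0, 0)      # 2.5 LRS units: crosses the threshold
  out <- step_epoch(net, stim)
  expect_true(out$events$fired[1])
  g <- 1 / out$net$R[1, ]
  expect_gt(g[1], g[2])            # light pixel -> higher conductance
  expect_equal(out$net$R[1, 1], 1e4)
  expect_equal(out$net$R[1, 2], 2e4)
  expect_equal(out$net$R[1, 4], 1e4)  # closed gate untouched
})
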