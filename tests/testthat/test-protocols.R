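# Experiment protocols: stochastic schedules, training, recognition,
# tracking, and their statistical properties.

test_that("schedules materialize the requested phases and probabilities", {
  p1 <- builtin_pattern("diag4")
  p2 <- builtin_pattern("antidiag4")
  p3 <- builtin_pattern("corners4")
  sch <- build_schedule(list(training_phase(p1, 300), training_phase(p2, 300),
                             training_phase(p3, 400)), seed = 5)
  expect_length(sch$kind, 1000)
  expect_equal(tabulate(sch$phase), c(300L, 300L, 400L))
  expect_length(sch$images, 1000)

  all_pat <- build_schedule(list(training_phase(p1, 50)), p_pattern = 1,
                            seed = 5)
  expect_true(all(all_pat$kind == "pattern"))
  expect_identical(all_pat$images[[17]], p1)

  expect_error(build_schedule(list()), "non-empty")
  expect_error(training_phase(p1, 0), "positive")
  expect_error(build_schedule(list(training_phase(p1, 10)), p_pattern = 2),
               "p_pattern")
})

test_that("noise epochs carry binomial pixel statistics", {
  p1 <- builtin_pattern("diag4")
  sch <- build_schedule(list(training_phase(p1, 10000)), p_pattern = 0,
                        noise_density = 0.03, seed = 9)
  mean_active <- mean(vapply(sch$images, sum, numeric(1)))
  se <- sqrt(16 * 0.03 * 0.97 / 10000)
  expect_lt(abs(mean_active - 16 * 0.03), 3 * se)
})

test_that("schedules and runs are reproducible bit-exactly under a seed", {
  p1 <- builtin_pattern("diag4")
  s1 <- build_schedule(list(training_phase(p1, 100)), seed = 77)
  s2 <- build_schedule(list(training_phase(p1, 100)), seed = 77)
  expect_identical(s1$kind, s2$kind)
  expect_identical(s1$images, s2$images)
  cfg <- network_config()
  l1 <- run_training(cfg, "hrs", s1, seed = 3)
  l2 <- run_training(cfg, "hrs", s2, seed = 3)
  expect_identical(l1$events, l2$events)
  expect_identical(l1$net$R, l2$net$R)
})

test_that("without stimuli or noise the weights never change", {
  p1 <- builtin_pattern("diag4")
  sch <- build_schedule(list(training_phase(p1, 100)), p_pattern = 0,
                        noise_density = 0, seed = 2)
  cfg <- network_config()
  log <- run_training(cfg, "hrs", sch)
  expect_identical(log$net$R, log$snapshots[["0"]])
  expect_equal(sum(log$events$n_set) + sum(log$events$n_reset), 0L)
})

test_that("the diagonal pattern is learned from scratch under defaults", {
  p1 <- builtin_pattern("diag4")
  cfg <- network_config()
  set.seed(123)
  log <- run_training(cfg, "hrs", static_schedule(p1, 300))
  fa <- first_adherence_epoch(log, p1)
  expect_false(is.na(fa))
  expect_lt(fa, 300)
  # at first adherence: 4 pattern synapses LRS, 12 background HRS
  r <- log$weights[fa + 1L, 1L, ]
  mask <- as_pre_vector(p1) > 0
  expect_equal(r[mask], rep(1e4, 4))
  expect_equal(r[!mask], rep(1e6, 12))
})

test_that("learning success is independent of the initial weight state", {
  # an all-LRS or random preparation must depress every background synapse
  # through stray noise hits, which takes longer than learning from HRS,
  # so the comparison horizon is 1000 epochs (all preparations reach the
  # stochastic steady state well within it)
  p1 <- builtin_pattern("diag4")
  cfg <- network_config()
  success <- sapply(c("hrs", "lrs", "random"), function(ini) {
    mean(sapply(1:20, function(s) {
      set.seed(4000 + s)   # same schedules across initializations
      log <- run_training(cfg, ini, static_schedule(p1, 1000))
      !is.na(first_adherence_epoch(log, p1))
    }))
  })
  expect_true(all(success >= 0.7))
  # rates are statistically indistinguishable across preparations
  counts <- rbind(success * 20, (1 - success) * 20)
  if (any(success < 1)) {
    p <- stats::fisher.test(counts)$p.value
    expect_gt(p, 0.01)
  } else {
    expect_true(all(success == 1))
  }
})

test_that("a new pattern overwrites the old one across a phase change", {
  p1 <- builtin_pattern("diag4")
  p2 <- builtin_pattern("antidiag4")
  cfg <- network_config()
  ok <- sapply(1:10, function(s) {
    set.seed(5000 + s)
    sch <- build_schedule(list(training_phase(p1, 300),
                               training_phase(p2, 600)))
    log <- run_training(cfg, "hrs", sch, record_weights = FALSE)
    r <- log$net$R[1, ]
    old_only <- (as_pre_vector(p1) > 0) & !(as_pre_vector(p2) > 0)
    new_only <- (as_pre_vector(p2) > 0) & !(as_pre_vector(p1) > 0)
    all(r[old_only] == 1e6) && all(r[new_only] == 1e4)
  })
  expect_gte(mean(ok), 0.5)
})

test_that("test-pattern enumeration is exhaustive and ordered", {
  tp <- enumerate_test_patterns(16, 4)
  expect_equal(nrow(tp), choose(16, 4))
  expect_true(all(rowSums(tp) == 4))
  expect_equal(nrow(unique(tp)), nrow(tp))
  # lexicographic by active-index tuple
  expect_equal(which(tp[1, ]), 1:4)
  expect_equal(which(tp[2, ]), c(1:3, 5))
  expect_equal(which(tp[nrow(tp), ]), 13:16)

  expect_equal(nrow(enumerate_test_patterns(16, 0)), 1)
  expect_equal(sum(enumerate_test_patterns(16, 0)), 0)

  # independent double-loop oracle for the small case
  pairs <- list()
  for (i in 1:8) for (j in (i + 1):9) pairs[[length(pairs) + 1L]] <- c(i, j)
  tp92 <- enumerate_test_patterns(9, 2)
  expect_equal(nrow(tp92), length(pairs))
  for (k in seq_along(pairs))
    expect_equal(which(tp92[k, ]), pairs[[k]])

  expect_error(enumerate_test_patterns(9, 10), "exceed")
})

test_that("recognition on ideal weights collapses to five exact levels", {
  p1 <- builtin_pattern("diag4")
  cfg <- network_config()
  rec <- run_recognition(ideal_weights(p1), p1, threshold = 3.5,
                         config = cfg)
  expect_equal(nrow(rec), 1820)
  # engine path equals the direct conductance-sum oracle
  tp <- enumerate_test_patterns(16, 4)
  v_direct <- as.numeric(tp %*% (1 / ideal_weights(p1)[1, ])) * 1e4
  expect_equal(rec$v_int, v_direct)
  # one level per overlap count: v = k + (4 - k) * 0.01
  expect_equal(sort(unique(rec$v_int)),
               sapply(0:4, function(k) k + (4 - k) * 0.01))
  for (k in 0:4)
    expect_true(all(rec$v_int[rec$overlap == k] == k + (4 - k) * 0.01))
  # sub-distribution sizes follow the hypergeometric counts
  expect_equal(as.integer(table(rec$overlap)),
               sapply(0:4, function(k) choose(4, k) * choose(12, 4 - k)))
  # strictly increasing in overlap
  agg <- tapply(rec$v_int, rec$overlap, unique)
  expect_true(all(diff(unlist(agg)) > 0))
})

test_that("recognition thresholds separate the training pattern", {
  p1 <- builtin_pattern("diag4")
  cfg <- network_config()
  rec <- run_recognition(ideal_weights(p1), p1, threshold = 3.5, config = cfg)
  expect_equal(sum(rec$fired), 1L)
  expect_equal(rec$overlap[rec$fired], 4L)        # only the training pattern
  # a tiny threshold fires every (non-empty) test pattern
  rec0 <- run_recognition(ideal_weights(p1), p1, threshold = 1e-9,
                          config = cfg)
  expect_true(all(rec0$fired))
  expect_error(run_recognition(ideal_weights(p1), p1, threshold = 0,
                               config = cfg), "positive")
  s <- summary(rec)
  expect_equal(s$n_distinct_levels, 5L)
  expect_equal(s$n_fired, 1L)
  expect_equal(nrow(s$by_overlap), 5L)
})

test_that("tracking validates its geometry", {
  cfg2 <- network_config(n_pre = 9, n_post = 2)
  expect_error(run_tracking(network_config(n_pre = 9, n_post = 1),
                            list(builtin_pattern("top_bar3"),
                                 builtin_pattern("bottom_bar3"))),
               "2-POST")
  expect_error(run_tracking(cfg2, list(builtin_pattern("top_bar3"),
                                       builtin_pattern("top_bar3"))),
               "disjoint")
  # zero shift steps: a single static phase, no change counts
  trk <- run_tracking(cfg2, list(builtin_pattern("top_bar3"),
                                 builtin_pattern("bottom_bar3")),
                      n_shift_steps = 0, epochs_per_phase = 100, seed = 1)
  expect_length(trk$phase_end_R, 1L)
  expect_equal(ncol(trk$changed), 0L)
})

test_that("two POSTs never specialize to the same image", {
  cfg2 <- network_config(n_pre = 9, n_post = 2)
  pats <- list(builtin_pattern("top_bar3"), builtin_pattern("bottom_bar3"))
  for (s in 1:20) {
    trk <- run_tracking(cfg2, pats, n_shift_steps = 1,
                        epochs_per_phase = 500, seed = 6000 + s)
    for (k in seq_along(trk$phase_end_R)) {
      a <- trk$adherence[, , k]
      for (im in 1:2)
        expect_false(all(a[, im]),
                     label = sprintf("seed %d phase %d image %d", s, k, im))
    }
  }
})

test_that("training logs summarize into per-phase verdicts", {
  p1 <- builtin_pattern("diag4")
  cfg <- network_config()
  set.seed(321)
  log <- run_training(cfg, "hrs", static_schedule(p1, 200))
  s <- summary(log)
  expect_s3_class(s, "summary.experiment_log")
  expect_equal(nrow(s$phases), 1L)
  expect_equal(s$phases$epochs, 200L)
  expect_true(s$phases$fires > 0)
  expect_identical(summary(log)$phases, summarize(log)$phases)
})
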