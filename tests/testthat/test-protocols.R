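test_that("schedules validate phase kinds and ordering", {
  s <- phase_schedule(unsupervised = 5, train_T1 = 10, test_T1 = 2)
  expect_s3_class(s, "phase_schedule")
  expect_error(phase_schedule(train_T1 = 5, unsupervised = 5),
               "must precede")
  expect_error(phase_schedule(nonsense = 3), "unknown phase kind")
})

test_that("performance is the rewarded fraction of consumed particles", {
  expect_equal(performance(7, 3)$value, 0.7)
  expect_equal(performance(0, 5)$value, 0)
  p <- performance(0, 0)
  expect_false(p$defined)
  expect_true(is.na(p$value))
})

test_that("presets assemble the documented phase sequences", {
  cfg <- snn_config()
  s1 <- schedule_preset("sequential", "desk", cfg)
  expect_equal(s1$kind[1], "unsupervised")
  expect_equal(sum(s1$kind == "train_T1"), 1)
  expect_equal(sum(s1$kind == "train_T2"), 1)
  s2 <- schedule_preset("interleaved_sleep_T2", "reduced", cfg)
  expect_true("interleaved_S_T2" %in% s2$kind)
  expect_equal(s2$aeons[s2$kind == "train_T1"],
               cfg$schedule$reduced$train)
})

test_that("a small schedule runs end-to-end with labelled records", {
  cfg <- test_cfg()
  sched <- phase_schedule(unsupervised = 1, train_T1 = 2, test_T1 = 1)
  run <- run_schedule(sched, seed = 3, n_trials = 2, cfg = cfg,
                      keep_net = TRUE, snapshot_every = 100)
  expect_length(run$trials, 2)
  tt <- run$trials[[1]]$tests
  expect_equal(tt$phase, "test_T1#1")
  info <- run$trials[[1]]$snapshot_info
  expect_true(all(grepl("^(unsupervised|train_T1)", info$phase)))
  expect_equal(ncol(run$trials[[1]]$snapshots), 6272)
  # trial independence: same master seed reproduces bit-identically
  run2 <- run_schedule(sched, seed = 3, n_trials = 1, cfg = cfg,
                       keep_net = TRUE, snapshot_every = 100)
  expect_identical(run$trials[[1]]$net$W_ho, run2$trials[[1]]$net$W_ho)
})

test_that("interleaved protocols alternate task and sleep blocks strictly", {
  cfg <- test_cfg()
  sched <- phase_schedule(unsupervised = 1, train_T1 = 2,
                          interleaved_S_T1 = 4, test_T1 = 1)
  run <- run_schedule(sched, seed = 8, n_trials = 1, cfg = cfg,
                      snapshot_every = 100)
  info <- run$trials[[1]]$snapshot_info
  sub <- info$sub[info$phase == "interleaved_S_T1#1"]
  expect_equal(sub, c("task1", "sleep2", "task3", "sleep4"))
  # sleep diagnostics recorded with targets from the training phase
  sd <- run$trials[[1]]$sleep_diag[["interleaved_S_T1#1"]]
  expect_equal(sd$target, run$trials[[1]]$hid_rates[["train_T1#1"]])
})

test_that("hidden-layer dropout: full removal silences the network", {
  res <- quick_awake(20, seed = 13)
  d <- dropout_test(res$net, fractions = c(0, 1), task = 1, aeons = 2,
                    seed = 2)
  expect_equal(d$fraction, c(0, 1))
  expect_true(all(d$rewarded + d$punished >= 0))
  # with every hidden neuron removed the network cannot see: behaviour
  # degenerates to exploration-driven wandering
  net2 <- res$net
  net2$hidden_active <- rep(0L, net2$n_hid)
  env <- task_environment(1, test_cfg(), seed = 5)
  r <- run_epochs(net2, env, agent_state(c(10, 10)),
                  somnus:::default_phase("test", 1), 100)
  expect_equal(sum(r$hid_spikes), 0)
})
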