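test_that("default architecture has 842 neurons and 6272 H->O synapses", {
  net <- build_network(1)
  expect_equal(net$n_in + net$n_hid + 9, 842)
  expect_equal(length(net$W_ho), 6272)
  expect_equal(dim(net$W_ho), c(784, 8))
  # every hidden neuron has exactly 9 distinct afferents
  expect_true(all(apply(net$src, 1, function(s) length(unique(s)) == 9)))
  expect_true(all(net$W_ih >= 0))
  # neurons start at the silent fixed point
  r <- resting_state(map_params())
  expect_equal(unique(net$V), r$V)
  expect_equal(unique(net$I), r$I)
  # uniform initial output weights, balanced inhibition
  expect_equal(unique(as.vector(net$W_ho)), 0.125)
  expect_equal(unique(net$WI), -0.125)
})

test_that("same seed rebuilds identical wiring and weights", {
  a <- build_network(42)
  b <- build_network(42)
  expect_identical(a$src, b$src)
  expect_identical(a$W_ih, b$W_ih)
  c <- build_network(43)
  expect_false(identical(a$src, c$src))
})

test_that("stimulated input neurons spike; empty field keeps previous direction", {
  cfg <- test_cfg()
  net <- build_network(2, cfg)
  vf0 <- matrix(0L, 7, 7)
  set.seed(1)
  r0 <- run_epoch(net, vf0, last_dir = 3L)
  expect_equal(r0$input_spikes, 0)
  expect_equal(r0$direction, 3)              # zero spikes -> previous move
  vf1 <- vf0; vf1[1, 1] <- 1L; vf1[1, 2] <- 1L
  set.seed(2)
  r1 <- run_epoch(net, vf1)
  expect_gte(r1$input_spikes, 2)             # each stimulated neuron fires
})

test_that("engine runs are bit-reproducible under a fixed seed", {
  go <- function() {
    set.seed(77)
    net <- build_network(77, test_cfg())
    env <- task_environment(1, test_cfg(), seed = 78)
    agent <- agent_state(c(25, 25))
    ph <- somnus:::default_phase("train", 1, plastic_ho = TRUE)
    run_epochs(net, env, agent, ph, 30)
  }
  a <- go(); b <- go()
  expect_identical(a$net$W_ho, b$net$W_ho)
  expect_identical(a$consumption, b$consumption)
  expect_identical(a$dirs, b$dirs)
  expect_identical(a$env$cells, b$env$cells)
})

test_that("exploration override frequency matches the exploration probability", {
  set.seed(9)
  agent <- agent_state(explore = 1)
  d <- replicate(3000, decide_move(2L, agent))
  expect_true(all(d %in% 0:7))
  freq <- table(factor(d, 0:7)) / 3000
  expect_true(all(abs(freq - 1 / 8) < 4 * sqrt(1 / 8 * 7 / 8 / 3000)))
  agent2 <- agent_state(explore = 0.01)
  o <- replicate(1e4, decide_move(2L, agent2) != 2L)
  p_other <- 0.01 * 7 / 8                    # override may redraw the same move
  expect_lt(abs(mean(o) - p_other), 3 * sqrt(p_other * (1 - p_other) / 1e4))
})

test_that("a fully random policy in a symmetric environment is at chance", {
  r <- random_forage(4000, task = 1, seed = 123)
  n <- r$rewarded + r$punished
  expect_gt(n, 100)
  expect_lt(abs(r$discriminability - 0.5), 3 * sqrt(0.25 / n))
})

test_that("the nonfunctional centre output neuron receives no decision weight", {
  res <- quick_awake(10, seed = 5)
  expect_true(all(res$dirs %in% -1:7))       # 8 directions only
  # centre neuron has no incoming synapses: W_ho has 8 columns
  expect_equal(ncol(res$net$W_ho), 8)
})
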