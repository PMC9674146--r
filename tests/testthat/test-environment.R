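test_that("particle placement honours density, equal orientations and adjacency", {
  env <- init_environment(50, 50, 0.10, seed = 7)
  expect_equal(sum(env$cells > 0), 250)          # 10% of 2500 cells
  expect_equal(length(env$ori), 125)             # two pixels per particle
  counts <- table(env$ori)
  expect_true(max(counts) - min(counts) <= 1)    # ~31 per orientation
  # every particle occupies exactly 2 cells consistent with its orientation
  for (id in seq_along(env$ori)) {
    cells <- which(env$cells == id)
    expect_length(cells, 2)
  }
  # adjacency: the 8-neighbourhood of each pixel holds no other particle
  occ <- which(env$cells > 0, arr.ind = TRUE)
  for (k in seq_len(nrow(occ))) {
    id <- env$cells[occ[k, 1], occ[k, 2]]
    for (dr in -1:1) for (dc in -1:1) {
      v <- somnus:::cell_at(env, occ[k, 1] + dr, occ[k, 2] + dc)
      expect_true(v == 0 || v == id)
    }
  }
})

test_that("degenerate and restricted environments", {
  expect_equal(length(init_environment(50, 50, 0, seed = 1)$ori), 0)
  env2 <- init_environment(50, 50, 0.10,
                           c("horizontal", "neg_diagonal"), seed = 2)
  expect_setequal(unique(env2$ori), c(0L, 3L))
  counts <- table(env2$ori)
  expect_true(max(counts) - min(counts) <= 1)
  expect_error(init_environment(50, 50, 0.5), "density")
  expect_error(init_environment(50, 50, 0.1, character(0)), "orientation")
})

test_that("visual field maps particle pixels to egocentric coordinates", {
  env <- somnus:::empty_environment(snn_config())
  expect_equal(sum(get_visual_field(env, c(25, 25))), 0)
  # plant one horizontal particle with anchor 2 up, 2 left of the agent
  env$ori <- 0L; env$pr <- 23L; env$pc <- 23L
  env$cells[23, 23] <- 1L; env$cells[23, 24] <- 1L
  vf <- get_visual_field(env, c(25, 25))
  expect_equal(sum(vf), 2)
  expect_equal(vf[2, 2], 1L)   # (23,23) -> offset (-2,-2) -> vf[2,2]
  expect_equal(vf[2, 3], 1L)
  # brute-force window scan agrees on a dense random grid
  env2 <- init_environment(50, 50, 0.10, seed = 9)
  for (pos in list(c(1, 1), c(25, 40), c(50, 50))) {
    vf2 <- get_visual_field(env2, pos)
    for (a in 1:7) for (b in 1:7) {
      r <- somnus:::wrap1(pos[1] + a - 4, 50)
      c <- somnus:::wrap1(pos[2] + b - 4, 50)
      expect_equal(vf2[a, b], as.integer(env2$cells[r, c] != 0))
    }
  }
})

test_that("moves consume whole particles, respawn them and classify rewards", {
  set.seed(3)
  env <- init_environment(20, 20, 0.1, c("horizontal", "neg_diagonal"),
                          seed = 3)
  n_h <- sum(env$ori == 0); n_d <- sum(env$ori == 3)
  # step onto a horizontal pixel during Task 1
  hid <- which(env$ori == 0)[1]
  agent <- agent_state(c(env$pr[hid], somnus:::wrap1(env$pc[hid] - 1, 20)))
  st <- move_agent(env, agent, 4, task = 1)  # move right onto the anchor
  expect_equal(st$event$kind, "rewarded")
  expect_equal(st$event$s_rp, 1)
  expect_equal(sum(st$env$ori == 0), n_h)    # count conserved per orientation
  expect_equal(sum(st$env$ori == 3), n_d)
  expect_equal(sum(st$env$cells > 0), 2 * (n_h + n_d))
  expect_equal(st$agent$explore, 0.01)       # reset on acquisition
  # punished and empty events
  did <- which(st$env$ori == 3)[1]
  ag2 <- agent_state(c(st$env$pr[did], somnus:::wrap1(st$env$pc[did] - 1, 20)))
  st2 <- move_agent(st$env, ag2, 4, task = 1)
  expect_equal(st2$event$kind, "punished")
  expect_equal(st2$event$s_rp, -0.001)
  empty_env <- somnus:::empty_environment(snn_config())
  st3 <- move_agent(empty_env, agent_state(c(5, 5)), 1, task = 1)
  expect_equal(st3$event$kind, "empty")
  expect_equal(st3$event$s_rp, -1e-4)
})

test_that("exploration probability grows 1% per empty move and caps at 1", {
  env <- somnus:::empty_environment(snn_config())
  agent <- agent_state(c(10, 10))
  for (i in 1:20) {
    st <- move_agent(env, agent, (i %% 8), task = 1)
    env <- st$env; agent <- st$agent
  }
  expect_equal(agent$explore, 0.21)   # 0.01 base + 20 increments
  for (i in 1:200) agent <- move_agent(env, agent, 1, task = 1)$agent
  expect_equal(agent$explore, 1)
})

test_that("adjacency and counts survive many consume/respawn cycles", {
  set.seed(11)
  env <- init_environment(15, 15, 0.1, seed = 11)
  agent <- agent_state(c(8, 8))
  counts0 <- table(factor(env$ori, 0:3))
  for (i in 1:300) {
    st <- move_agent(env, agent, sample(0:7, 1), task = 1)
    env <- st$env; agent <- st$agent
  }
  expect_equal(table(factor(env$ori, 0:3)), counts0)
  occ <- which(env$cells > 0, arr.ind = TRUE)
  for (k in seq_len(nrow(occ))) {
    id <- env$cells[occ[k, 1], occ[k, 2]]
    for (dr in -1:1) for (dc in -1:1) {
      v <- somnus:::cell_at(env, occ[k, 1] + dr, occ[k, 2] + dc)
      expect_true(v == 0 || v == id)
    }
  }
})
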