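test_that("trace values match the closed form K exp(-|dt|/Tc)", {
  sp <- stdp_params()
  expect_equal(stdp_trace(0, 0), 0.04, tolerance = 1e-12)
  expect_equal(stdp_trace(0, 40), 0.04 * exp(-1), tolerance = 1e-12)
  expect_equal(stdp_trace(10, 0), -0.04 * exp(-0.25), tolerance = 1e-12)
  # sign and magnitude across a grid of lags
  for (dt in c(1, 5, 20, 60)) {
    expect_equal(stdp_trace(0, dt), 0.04 * exp(-dt / 40), tolerance = 1e-12)
    expect_equal(stdp_trace(dt, 0), -0.04 * exp(-dt / 40), tolerance = 1e-12)
    expect_lte(abs(stdp_trace(0, dt)), sp$k_max)
  }
})

test_that("unsupervised application is multiplicative with a zero clip", {
  expect_equal(apply_unsupervised_stdp(0.5, 0), 0.5)
  expect_equal(apply_unsupervised_stdp(0.5, 0.04), 0.52)
  expect_equal(apply_unsupervised_stdp(0, -0.04), 0)    # stays clipped
  w <- 0.1
  for (i in 1:50) {
    w2 <- apply_unsupervised_stdp(w, 0.04)
    expect_gt(w2, w)                                    # monotone growth
    w <- w2
  }
  expect_equal(apply_unsupervised_stdp(1, -0.02, mode = "additive"), 0.98)
})

test_that("rewarded update reproduces the single-trace closed form", {
  w <- matrix(0.125, 4, 2)
  w_i0 <- rowSums(w)
  traces <- data.frame(h = 2L, o = 1L, tr = 0.04, te = 5)
  # one trace, one epoch old, c = 1, W_i = W_i0, Avg_tr = Sum_tr
  sum_tr <- 0.04 / (6 - 5 + 1)
  for (s_rp in c(1, 0.5, -0.001)) {
    r <- apply_rewarded_update(w, traces, s_rp, t_now = 6, avg_tr = sum_tr,
                               w_i0 = w_i0)
    expect_equal(r$w_ho[2, 1], 0.125 * (1 + s_rp * 0.02), tolerance = 1e-12)
    expect_equal(r$w_ho[1, 1], 0.125)       # untouched synapse
    expect_equal(r$sum_tr, sum_tr)
  }
  # S_rp = 0 leaves weights exactly unchanged
  r0 <- apply_rewarded_update(w, traces, 0, 6, sum_tr, w_i0)
  expect_identical(r0$w_ho, w)
  # no live traces: weights unchanged, Avg_tr decays toward zero
  old <- data.frame(h = 1L, o = 1L, tr = 0.04, te = 0)
  r1 <- apply_rewarded_update(w, old, 1, t_now = 10, avg_tr = 0.5, w_i0 = w_i0)
  expect_identical(r1$w_ho, w)
  expect_equal(r1$avg_tr, 0.99 * 0.5)
})

test_that("traces never act beyond their 6-epoch lifetime", {
  w <- matrix(1, 2, 2)
  tr <- data.frame(h = 1L, o = 1L, tr = 0.04, te = 0)
  just_alive <- apply_rewarded_update(w, tr, 1, t_now = 6, avg_tr = 0.02,
                                      w_i0 = rowSums(w))
  expect_gt(just_alive$w_ho[1, 1], 1)
  expired <- apply_rewarded_update(w, tr, 1, t_now = 6.5, avg_tr = 0.02,
                                   w_i0 = rowSums(w))
  expect_identical(expired$w_ho, w)
})

test_that("homeostatic target moves by (1 +/- D_tar) and scaling restores sums", {
  w <- matrix(runif(16, 0.05, 0.2), 4, 4)
  w_j0 <- rep(0.5, 4)
  # rate below target for 10 epochs: exact compound growth
  tgt <- w_j0
  for (i in 1:10)
    tgt <- homeostatic_scale(w, tgt, rate_j = rep(0, 4))$w_j0
  expect_equal(tgt, rep(0.5 * 1.001^10, 4), tolerance = 1e-12)
  # at-target rate leaves W_j0 unchanged, column sums match exactly
  r <- homeostatic_scale(w, w_j0, rate_j = rep(1, 4))
  expect_equal(r$w_j0, w_j0)
  expect_equal(colSums(r$w_ho), w_j0, tolerance = 1e-12)
  # arbitrary perturbation then scaling restores the invariant
  w2 <- w; w2[2, 3] <- w2[2, 3] * 7
  r2 <- homeostatic_scale(w2, w_j0, rate_j = rep(2, 4))
  expect_equal(colSums(r2$w_ho), r2$w_j0, tolerance = 1e-12)
})

test_that("heterosynaptic rescaling preserves proportions and flags zero columns", {
  w <- matrix(c(1, 1, 2, 4), 2, 2)
  r <- heterosynaptic_rescale(w, w_j0 = colSums(w))
  expect_equal(r$w_ho, w)                       # already normalized
  w2 <- w; w2[1, 1] <- 2                        # double one weight
  r2 <- heterosynaptic_rescale(w2, w_j0 = colSums(w))
  expect_equal(colSums(r2$w_ho), colSums(w))
  expect_equal(r2$w_ho[1, 1] / r2$w_ho[2, 1], 2)  # relative ratio kept
  wz <- matrix(0, 2, 2)
  rz <- heterosynaptic_rescale(wz, w_j0 = c(1, 1))
  expect_equal(rz$skipped, c(1L, 2L))
})

test_that("inhibitory weights equal the negative mean of outgoing excitation", {
  w <- matrix(0.3, 5, 8)
  expect_equal(inhibitory_balance(w), rep(-0.3, 5))
  w2 <- matrix(runif(40), 5, 8)
  expect_equal(inhibitory_balance(w2), -rowMeans(w2))
  expect_true(all(inhibitory_balance(w2) <= 0))
})

test_that("freezing marks floor(fraction * N) top weights with index tie-breaks", {
  w <- matrix(runif(6272), 784, 8)
  expect_equal(sum(freeze_top_fraction(w, 0)), 0)
  expect_equal(sum(freeze_top_fraction(w, 1)), 6272)
  m <- freeze_top_fraction(w, 0.1)
  expect_equal(sum(m), 627)                     # floor(0.1 * 6272)
  expect_gte(min(w[m]), max(w[!m]))
  # ties broken by synapse index
  wt <- matrix(1, 4, 2)
  mt <- freeze_top_fraction(wt, 0.5)
  expect_equal(which(mt), 1:4)
})
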