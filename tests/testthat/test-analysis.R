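# hand-buildable miniature network for analysis metrics
toy_net <- function(vfs = 7, n_hid = 2, src, w_ih, w_ho) {
  list(vfs = vfs, n_in = vfs^2, n_hid = n_hid,
       src = src, W_ih = w_ih, W_ho = w_ho)
}

test_that("hidden receptive fields place afferent weights at source coordinates", {
  src <- rbind(c(1L, 2L, 9L), c(25L, 26L, 27L))
  w <- rbind(c(0.5, 0.25, 1), c(1, 2, 3))
  net <- toy_net(src = src, w_ih = w, w_ho = matrix(1, 2, 8))
  rf <- receptive_field_hidden(net, 1)
  expect_equal(rf[1, 1], 0.5)     # input 1 -> cell (1,1)
  expect_equal(rf[1, 2], 0.25)    # input 2 -> cell (1,2)
  expect_equal(rf[2, 2], 1)       # input 9 -> cell (2,2)
  expect_equal(sum(rf), 1.75)
})

test_that("output receptive fields are weighted averages of hidden fields", {
  src <- rbind(c(1L, 2L, 3L), c(4L, 5L, 6L))
  w_ih <- rbind(c(1, 1, 1), c(2, 2, 2))
  w_ho <- matrix(1, 2, 8)          # uniform: unweighted mean
  net <- toy_net(src = src, w_ih = w_ih, w_ho = w_ho)
  rf1 <- receptive_field_hidden(net, 1)
  rf2 <- receptive_field_hidden(net, 2)
  expect_equal(receptive_field_output(net, 3), (rf1 + rf2) / 2)
  # single contributing hidden neuron: output RF equals that hidden RF
  w_ho2 <- w_ho; w_ho2[2, 3] <- 0
  expect_equal(receptive_field_output(toy_net(src = src, w_ih = w_ih,
                                              w_ho = w_ho2), 3), rf1)
  # hand-verified weighted average with weights 3 and 1
  w_ho3 <- w_ho; w_ho3[1, 5] <- 3
  expect_equal(receptive_field_output(toy_net(src = src, w_ih = w_ih,
                                              w_ho = w_ho3), 5),
               (3 * rf1 + rf2) / 4)
  w_ho0 <- matrix(0, 2, 8)
  expect_error(receptive_field_output(toy_net(src = src, w_ih = w_ih,
                                              w_ho = w_ho0), 1), "zero total")
})

# independent brute-force PRM: explicit sums with receptive fields built
# from scratch, no reuse of the package's helpers
prm_oracle <- function(net, ori_code) {
  vfs <- net$vfs
  off <- switch(ori_code + 1, c(0, 1), c(1, 0), c(-1, 1), c(1, 1))
  total <- 0
  for (o in 1:8) {
    j9 <- if (o <= 4) o - 1 else o
    dr <- j9 %/% 3 - 1; dc <- j9 %% 3 - 1
    band <- function(d) if (d < 0) 1:3 else if (d == 0)
      ((vfs + 1) / 2 - 1):((vfs + 1) / 2 + 1) else (vfs - 2):vfs
    acc <- matrix(0, vfs, vfs)
    for (h in seq_len(net$n_hid)) {
      wh <- matrix(0, vfs, vfs)
      for (a in seq_len(ncol(net$src))) {
        i <- net$src[h, a]
        wh[(i - 1) %/% vfs + 1, (i - 1) %% vfs + 1] <-
          wh[(i - 1) %/% vfs + 1, (i - 1) %% vfs + 1] + net$W_ih[h, a]
      }
      s <- matrix(0, vfs, vfs)
      for (r in 1:vfs) for (c in 1:vfs) {
        r2 <- r + off[1]; c2 <- c + off[2]
        if (r2 < 1 || r2 > vfs || c2 < 1 || c2 > vfs) next
        p <- matrix(0, vfs, vfs); p[r, c] <- 1; p[r2, c2] <- 1
        s <- s + (wh * p) * sum(wh * p)^2
      }
      acc <- acc + net$W_ho[h, o] * s
    }
    total <- total + sum(acc[band(dr), band(dc)])
  }
  total
}

test_that("PRM agrees with the brute-force oracle and behaves on edge cases", {
  fx <- tiny_fixture(seed = 2)
  net7 <- build_network(3, test_cfg())
  net7$W_ho <- matrix(runif(6272, 0, 0.3), 784, 8)
  for (oc in 0:3)
    expect_equal(prm(net7, ORIENTATIONS[oc + 1]), prm_oracle(net7, oc),
                 tolerance = 1e-9)
  # all-zero input weights give zero responsiveness
  net0 <- net7; net0$W_ih[] <- 0
  for (o in ORIENTATIONS) expect_equal(prm(net0, o), 0)
})

test_that("a planted horizontal detector prefers horizontal particles", {
  # one hidden neuron seeing exactly a horizontal pair in the upper-left,
  # wired only to the up-left output neuron
  net <- toy_net(n_hid = 1, src = matrix(c(1L, 2L), 1, 2),
                 w_ih = matrix(c(1, 1), 1, 2),
                 w_ho = matrix(c(1, rep(0, 7)), 1, 8))
  expect_gt(prm(net, "horizontal"), 0)
  expect_gt(prm(net, "horizontal"), prm(net, "vertical"))
  expect_gt(prm(net, "horizontal"), prm(net, "neg_diagonal"))
})

test_that("PRM is invariant under hidden permutation and equivariant under rotation", {
  net <- build_network(5, test_cfg())
  net$W_ho <- matrix(runif(6272, 0, 0.2), 784, 8)
  p <- sample(net$n_hid)
  net_p <- net
  net_p$src <- net$src[p, ]; net_p$W_ih <- net$W_ih[p, ]
  net_p$W_ho <- net$W_ho[p, ]
  for (o in c("horizontal", "pos_diagonal"))
    expect_equal(prm(net_p, o), prm(net, o), tolerance = 1e-9)
  # rotate the visual field and motor map by 90 degrees: horizontal and
  # vertical responsiveness swap
  rot_cell <- function(i, vfs = 7) {
    r <- (i - 1) %/% vfs + 1; c <- (i - 1) %% vfs + 1
    (c - 1) * vfs + (vfs - r + 1)          # (r,c) -> (c, vfs+1-r)
  }
  rot_out <- c(3L, 5L, 8L, 2L, 7L, 1L, 4L, 6L)  # decision idx after rotation
  net_r <- net
  net_r$src <- matrix(vapply(as.integer(net$src), rot_cell, numeric(1)),
                      nrow(net$src), ncol(net$src))
  net_r$W_ho <- net$W_ho[, order(rot_out)]
  expect_equal(prm(net_r, "vertical"), prm(net, "horizontal"),
               tolerance = 1e-9)
})

test_that("task-relevant synapse extraction uses the ceil rule with index ties", {
  u <- rep(1, 6272)
  ids <- task_relevant_synapses(u)
  expect_length(ids, 628)                  # ceiling(0.1 * 6272)
  expect_equal(ids, 1:628)                 # ties resolved by index
  v <- c(rep(0, 100), 5, rep(0, 49))
  expect_true(101 %in% task_relevant_synapses(v))
  w <- runif(500)
  ids2 <- task_relevant_synapses(w, quantile = 0.8)
  expect_length(ids2, 100)
  expect_gte(min(w[ids2]), max(w[-ids2]))
})

test_that("manifold distance: membership, simple geometry, triangle bound", {
  s <- rbind(rep(0, 4), c(1, 1, 0, 0))
  expect_equal(manifold_distance(c(1, 1, 0, 0), s), 0)
  expect_equal(manifold_distance(c(1, 0, 0, 0), rbind(rep(0, 4))), 1)
  expect_error(manifold_distance(1:3, s), "dimension")
  expect_error(manifold_distance(1:4, s[0, , drop = FALSE]), "empty")
  set.seed(2)
  for (i in 1:20) {
    S <- matrix(rnorm(40), 10, 4)
    a <- rnorm(4); b <- rnorm(4)
    expect_lte(manifold_distance(a, S),
               sqrt(sum((a - b)^2)) + manifold_distance(b, S) + 1e-12)
  }
})

test_that("2-D weight histograms conserve mass and sit on the diagonal for identity", {
  set.seed(8)
  w <- runif(6272, 0, 0.4)
  h <- weight_histogram_2d(w, w, n_bins = 40)
  expect_equal(sum(h$counts_raw), 6272)
  expect_equal(sum(diag(h$counts_raw)), 6272)   # all mass on the diagonal
  expect_true(all(h$counts <= 50))
  expect_equal(h$marginal_a, h$marginal_b)
  # small perturbation stays within one bin of the diagonal
  bw <- diff(h$breaks[1:2])
  h2 <- weight_histogram_2d(w, pmin(pmax(w + runif(6272, -bw / 3, bw / 3), 0),
                                    max(w)), n_bins = 40)
  nz <- which(h2$counts_raw > 0, arr.ind = TRUE)
  expect_true(all(abs(nz[, 1] - nz[, 2]) <= 1))
  expect_equal(sum(h2$counts_raw), 6272)
})

test_that("SVM classifier separates planted weight-state clusters with the sign convention", {
  set.seed(4)
  d <- 30
  t1 <- matrix(rnorm(20 * d, mean = 0), 20, d)
  t2 <- matrix(rnorm(20 * d, mean = 1.5), 20, d)
  q <- rbind(t1[1, ], rnorm(d, 0), rnorm(d, 1.5))
  dv <- svm_weight_classifier(t1, t2, q)
  expect_lt(dv[1], 0)                      # duplicate training point: T1 side
  expect_lt(dv[2], 0)
  expect_gt(dv[3], 0)
  expect_error(svm_weight_classifier(t1[0, , drop = FALSE], t2, q), "classes")
})

test_that("embeddings expose planted clusters and flag degenerate input", {
  same <- matrix(1, 5, 10)
  e0 <- embed_trajectory(same, "pca", 2)
  expect_true(e0$degenerate)
  set.seed(6)
  x <- rbind(matrix(rnorm(150, 0, 0.2), 15, 10),
             matrix(rnorm(150, 3, 0.2), 15, 10))
  for (m in c("pca", "kpca")) {
    e <- embed_trajectory(x, m, 2)
    expect_false(e$degenerate)
    g1 <- e$coords[1:15, 1]; g2 <- e$coords[16:30, 1]
    expect_true(max(min(g1) - max(g2), min(g2) - max(g1)) > 0)  # separated
  }
  # deterministic given inputs
  e2 <- embed_trajectory(x, "pca", 2)
  expect_identical(embed_trajectory(x, "pca", 2)$coords, e2$coords)
})
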