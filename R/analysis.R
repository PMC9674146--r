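#' Receptive field of a hidden neuron
#'
#' Places each of the neuron's afferent weights at its source's visual-field
#' coordinate (zeros elsewhere).
#'
#' @param net an `snn` (uses `W_ih` and `src`).
#' @param hidden_id hidden neuron index (1-based).
#' @return `vfs` x `vfs` real matrix.
#' @export
receptive_field_hidden <- function(net, hidden_id) {
  rf <- matrix(0, net$vfs, net$vfs)
  for (a in seq_len(ncol(net$src))) {
    i <- net$src[hidden_id, a]           # row-major input index
    r <- (i - 1) %/% net$vfs + 1; c <- (i - 1) %% net$vfs + 1
    rf[r, c] <- rf[r, c] + net$W_ih[hidden_id, a]
  }
  rf
}

#' Receptive field of an output (decision) neuron
#'
#' Weighted average of the hidden receptive fields, weights given by the
#' hidden-to-output synaptic strengths onto this neuron.
#'
#' @param net an `snn`.
#' @param output_id decision neuron index (1-8).
#' @export
receptive_field_output <- function(net, output_id) {
  w <- net$W_ho[, output_id]
  tot <- sum(w)
  if (tot <= 0) stop("zero total weight onto output neuron ", output_id)
  rf <- matrix(0, net$vfs, net$vfs)
  for (h in which(w > 0)) rf <- rf + w[h] * receptive_field_hidden(net, h)
  rf / tot
}

#' All placements of a two-pixel particle inside the visual field
#'
#' @param orientation one of [ORIENTATIONS] (or its 0-3 code).
#' @param vfs field side length.
#' @return list of `vfs` x `vfs` binary mask matrices, one per in-bounds
#'   placement.
#' @export
particle_masks <- function(orientation, vfs = 7) {
  oc <- if (is.character(orientation)) match(orientation, ORIENTATIONS) - 1L
        else as.integer(orientation)
  off <- ori_offset(oc)
  masks <- list()
  for (r in 1:vfs) for (c in 1:vfs) {
    r2 <- r + off[1]; c2 <- c + off[2]
    if (r2 >= 1 && r2 <= vfs && c2 >= 1 && c2 <= vfs) {
      m <- matrix(0, vfs, vfs); m[r, c] <- 1; m[r2, c2] <- 1
      masks[[length(masks) + 1]] <- m
    }
  }
  masks
}

direction_band <- function(d, vfs) {
  h <- (vfs + 1) / 2
  if (d < 0) 1:3 else if (d == 0) (h - 1):(h + 1) else (vfs - 2):vfs
}

#' Direction mask of a decision neuron
#'
#' A 3x3 block of ones placed at the part of the visual field toward which
#' the neuron moves the agent: corner blocks for diagonal directions,
#' edge-middle blocks for cardinal ones.
#'
#' @param output_id decision neuron index 1-8 (row-major over the 3x3 motor
#'   grid without its centre).
#' @param vfs field side length.
#' @export
direction_mask <- function(output_id, vfs = 7) {
  j9 <- if (output_id <= 4) output_id - 1 else output_id  # skip centre
  dr <- j9 %/% 3 - 1; dc <- j9 %% 3 - 1
  m <- matrix(0, vfs, vfs)
  m[direction_band(dr, vfs), direction_band(dc, vfs)] <- 1
  m
}

#' Particle responsiveness metric (PRM)
#'
#' Scalar measure of how strongly a given particle orientation, at any
#' visual-field position, drives the output layer toward the matching
#' movement direction:
#' `PRM = sum_O grand(DirectionMask(O) * sum_H W_HO * sum_P (W_H * P) grand(W_H * P)^2)`
#' where `*` is elementwise, `grand` the sum of all entries, `W_H` the
#' hidden neuron's receptive field and `P` ranges over all placements of
#' the particle.
#'
#' @param net an `snn`.
#' @param particle_type one of [ORIENTATIONS].
#' @return scalar.
#' @export
prm <- function(net, particle_type) {
  masks <- particle_masks(particle_type, net$vfs)
  n_hid <- net$n_hid
  inner <- vector("list", n_hid)
  for (h in seq_len(n_hid)) {
    wh <- receptive_field_hidden(net, h)
    s <- matrix(0, net$vfs, net$vfs)
    for (p in masks) {
      wp <- wh * p
      s <- s + wp * sum(wp)^2
    }
    inner[[h]] <- s
  }
  total <- 0
  for (o in 1:8) {
    acc <- matrix(0, net$vfs, net$vfs)
    for (h in seq_len(n_hid)) acc <- acc + net$W_ho[h, o] * inner[[h]]
    total <- total + sum(direction_mask(o, net$vfs) * acc)
  }
  total
}

#' Task-relevant synapse identification
#'
#' Ids (column-major over the hidden-by-output weight matrix) of the
#' weights in the top `1 - quantile` of the snapshot's distribution:
#' exactly `ceiling((1 - quantile) * N)` synapses, ties at the threshold
#' broken by index.
#'
#' @param snapshot flattened weight vector (or matrix).
#' @param quantile cut point, default 0.9 (top 10%).
#' @return integer vector of synapse ids.
#' @export
task_relevant_synapses <- function(snapshot, quantile = 0.9) {
  v <- as.vector(snapshot)
  n_take <- ceiling((1 - quantile) * length(v))
  ord <- order(-v, seq_along(v), method = "radix")
  sort(ord[seq_len(n_take)])
}

#' SVM classification of weight configurations
#'
#' Trains a radial-basis-function support vector machine to separate
#' weight snapshots recorded after training one task from those after the
#' other, then reports the signed distance to the decision boundary for
#' held-out query snapshots.  Sign convention: the Task-1 side is
#' negative.
#'
#' @param train_t1,train_t2 snapshot matrices (rows = snapshots).
#' @param query matrix of held-out snapshots.
#' @param cost,gamma SVM hyperparameters; `gamma = NULL` (default) sets the
#'   RBF width by the median heuristic, `1 / median(squared pairwise
#'   training distance)`, which adapts to the weight scale of the runs.
#' @return numeric vector of decision values, one per query row.
#' @export
svm_weight_classifier <- function(train_t1, train_t2, query,
                                  cost = 1, gamma = NULL) {
  train_t1 <- rbind(train_t1); train_t2 <- rbind(train_t2)
  if (nrow(train_t1) == 0 || nrow(train_t2) == 0)
    stop("both classes need training snapshots")
  x <- rbind(train_t1, train_t2)
  y <- factor(c(rep("T1", nrow(train_t1)), rep("T2", nrow(train_t2))))
  if (is.null(gamma)) {
    d2 <- as.vector(dist(x))^2
    gamma <- if (any(d2 > 0)) 1 / median(d2[d2 > 0]) else 1 / ncol(x)
  }
  args <- list(x = x, y = y, kernel = "radial", cost = cost, scale = FALSE,
               gamma = gamma)
  fit <- do.call(e1071::svm, args)
  dv_train <- attr(predict(fit, x, decision.values = TRUE), "decision.values")
  flip <- if (mean(dv_train[seq_len(nrow(train_t1))]) > 0) -1 else 1
  dv <- attr(predict(fit, rbind(query), decision.values = TRUE),
             "decision.values")
  flip * as.vector(dv)
}

#' Low-dimensional embedding of weight trajectories
#'
#' @param snapshots matrix of flattened weight vectors (rows ordered in
#'   time or pooled across protocols).
#' @param method `"pca"` (prcomp) or `"kpca"` (RBF kernel PCA with a
#'   median-heuristic bandwidth).
#' @param dims number of output dimensions.
#' @return list with `coords` (n x dims), `method`, and `degenerate`
#'   (TRUE when the snapshots carry no variance).
#' @export
embed_trajectory <- function(snapshots, method = c("pca", "kpca"), dims = 2) {
  method <- match.arg(method)
  snapshots <- rbind(snapshots)
  if (nrow(snapshots) < dims + 1) stop("need at least dims + 1 snapshots")
  if (all(apply(snapshots, 2, sd) == 0))
    return(list(coords = matrix(0, nrow(snapshots), dims), method = method,
                degenerate = TRUE))
  if (method == "pca") {
    p <- prcomp(snapshots, center = TRUE, scale. = FALSE)
    k <- min(dims, ncol(p$x))
    coords <- p$x[, seq_len(k), drop = FALSE]
  } else {
    d2 <- as.vector(dist(snapshots))^2
    sig <- 1 / median(d2[d2 > 0])
    kp <- kernlab::kpca(snapshots, kernel = "rbfdot",
                        kpar = list(sigma = sig),
                        features = min(dims, nrow(snapshots) - 1))
    coords <- kernlab::rotated(kp)
  }
  if (ncol(coords) < dims)
    coords <- cbind(coords, matrix(0, nrow(coords), dims - ncol(coords)))
  list(coords = coords[, seq_len(dims), drop = FALSE], method = method,
       degenerate = FALSE)
}

#' Distance from a point to a solution-manifold point set
#'
#' Minimum Euclidean distance in full weight space between `point` and the
#' members of the sampled manifold.
#'
#' @param point numeric vector.
#' @param manifold matrix with one sampled weight state per row.
#' @return scalar distance.
#' @export
manifold_distance <- function(point, manifold) {
  manifold <- rbind(manifold)
  if (nrow(manifold) == 0) stop("empty manifold point set")
  if (length(point) != ncol(manifold)) stop("dimension mismatch")
  sqrt(min(colSums((t(manifold) - point)^2)))
}

#' Manifold point sets from a run record
#'
#' Collects the snapshots from the last fifth of the designated phases of
#' each trial.  Membership follows the convention that single-task training
#' and both interleaved protocols sample a task's manifold, while the
#' manifold intersection is sampled only by interleaved protocols.
#'
#' @param run a `somnus_run`.
#' @param phases character vector of phase-label prefixes (e.g.
#'   `"train_T1"`, `"interleaved_S_T1"`).
#' @return matrix of snapshot rows.
#' @export
manifold_points <- function(run, phases) {
  out <- NULL
  for (tr in run$trials) {
    info <- tr$snapshot_info
    if (is.null(info)) next
    for (ph in unique(info$phase)) {
      if (!any(startsWith(ph, phases))) next
      idx <- which(info$phase == ph)
      keep <- idx[info$aeon[idx] >= quantile(info$aeon[idx], 0.8)]
      out <- rbind(out, tr$snapshots[keep, , drop = FALSE])
    }
  }
  out
}

#' Two-dimensional synaptic weight histogram
#'
#' Bins each synapse by its strength at two time slices; counts are capped
#' (display convention: 50) and the marginal 1-D histograms are returned
#' alongside.  Mass (before capping) is conserved at the synapse count.
#'
#' @param snapshot_a,snapshot_b equal-length weight vectors (x and y axes).
#' @param n_bins number of bins per axis.
#' @param count_cap per-bin display cap.
#' @return list `counts` (capped matrix), `counts_raw`, `breaks`,
#'   `marginal_a`, `marginal_b`.
#' @export
weight_histogram_2d <- function(snapshot_a, snapshot_b, n_bins = 50,
                                count_cap = 50) {
  stopifnot(length(snapshot_a) == length(snapshot_b))
  lim <- range(c(snapshot_a, snapshot_b, 0))
  breaks <- seq(lim[1], lim[2] + 1e-12, length.out = n_bins + 1)
  ia <- pmin(findInterval(snapshot_a, breaks, rightmost.closed = TRUE), n_bins)
  ib <- pmin(findInterval(snapshot_b, breaks, rightmost.closed = TRUE), n_bins)
  counts <- matrix(0L, n_bins, n_bins)
  for (k in seq_along(ia)) counts[ia[k], ib[k]] <- counts[ia[k], ib[k]] + 1L
  list(counts = pmin(counts, count_cap), counts_raw = counts, breaks = breaks,
       marginal_a = rowSums(counts), marginal_b = colSums(counts))
}
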