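#' STDP parameters
#'
#' @param tc_ms trace time constant (40 ms).
#' @param k_max trace maximum magnitude `K` (0.04; sign is +K for
#'   pre-before-post and -K for post-before-pre).
#' @param pair_window pairing window in steps (120; each new spike is
#'   compared to all opposite-side spikes within the window).
#' @param trace_lifetime stored-trace lifetime in epochs (6).
#' @param c_epochs smoothing constant `c` (1 epoch) in the trace weighting.
#' @param delta_avg running-average rate for `Avg_tr`.
#' @param avg_floor lower floor on `Avg_tr` to avoid division blow-up.
#' @export
stdp_params <- function(tc_ms = 40, k_max = 0.04, pair_window = 120,
                        trace_lifetime = 6, c_epochs = 1,
                        delta_avg = 0.01, avg_floor = 1e-6) {
  stopifnot(tc_ms > 0, delta_avg > 0, delta_avg < 1)
  list(tc_ms = tc_ms, k_max = k_max, pair_window = pair_window,
       trace_lifetime = trace_lifetime, c_epochs = c_epochs,
       delta_avg = delta_avg, avg_floor = avg_floor)
}

#' STDP trace value for a spike pair
#'
#' `+K exp(-|dt|/Tc)` for a causal (pre-before-post) pairing and
#' `-K exp(-|dt|/Tc)` for an anti-causal one.
#'
#' @param t_pre,t_post spike times in ms.
#' @param params an [stdp_params()].
#' @return signed trace value.
#' @examples
#' stdp_trace(0, 0)    # simultaneous pair: +K = 0.04
#' stdp_trace(0, 40)   # causal, one time constant: 0.04 * exp(-1)
#' stdp_trace(10, 0)   # anti-causal: -0.04 * exp(-0.25)
#' @export
stdp_trace <- function(t_pre, t_post, params = stdp_params()) {
  s <- if (t_post >= t_pre) 1 else -1
  s * params$k_max * exp(-abs(t_post - t_pre) / params$tc_ms)
}

#' Immediate (unsupervised) STDP application
#'
#' Input-to-hidden traces act as soon as they are created; the default is
#' the multiplicative form `W <- W (1 + tr)`, mirroring the rewarded rule;
#' an additive mode is available.  Weights are clipped at zero.
#'
#' @param w weight (scalar or vector/matrix).
#' @param trace signed trace value(s).
#' @param mode `"multiplicative"` or `"additive"`.
#' @export
apply_unsupervised_stdp <- function(w, trace, mode = c("multiplicative", "additive")) {
  mode <- match.arg(mode)
  w2 <- if (mode == "multiplicative") w * (1 + trace) else w + trace
  pmax(w2, 0)
}

#' Rewarded (reinforcement) STDP update
#'
#' On each reward or punishment event the stored hidden-to-output traces
#' are converted into weight changes:
#' `Sum_tr = sum_k tr_k / (t - t_k + c)` over all live traces,
#' `Delta_k = S_rp (tr_k / (t - t_k + c)) (Sum_tr / Avg_tr)`, and each
#' synapse is multiplied by `prod_k (1 + (W_i0 / W_i) Delta_k)` over its
#' own traces, where `W_i` is the hidden neuron's current total output
#' strength and `W_i0` its initial target.  `Avg_tr` then relaxes toward
#' `Sum_tr` at rate `delta_avg`.  Frozen synapses are untouched and
#' per-factor multipliers are clamped at zero.
#'
#' @param w_ho hidden-by-output excitatory weight matrix.
#' @param traces data frame with columns `h`, `o` (1-based synapse indices),
#'   `tr` (trace value) and `te` (creation epoch).
#' @param s_rp reward scalar.
#' @param t_now current epoch.
#' @param avg_tr running average of `Sum_tr`.
#' @param w_i0 per-hidden-neuron target output sums.
#' @param params an [stdp_params()].
#' @param frozen optional logical matrix like `w_ho`.
#' @return list `w_ho`, `avg_tr`, `sum_tr`.
#' @export
apply_rewarded_update <- function(w_ho, traces, s_rp, t_now, avg_tr, w_i0,
                                  params = stdp_params(), frozen = NULL) {
  live <- traces[t_now - traces$te <= params$trace_lifetime, , drop = FALSE]
  wgt <- if (nrow(live)) live$tr / (t_now - live$te + params$c_epochs) else numeric(0)
  sum_tr <- sum(wgt)
  if (nrow(live) && s_rp != 0) {
    ratio <- sum_tr / max(avg_tr, params$avg_floor)
    w_i <- rowSums(w_ho)
    for (k in seq_len(nrow(live))) {
      h <- live$h[k]; o <- live$o[k]
      if (!is.null(frozen) && frozen[h, o]) next
      dk <- s_rp * wgt[k] * ratio
      fac <- 1 + (if (w_i[h] > 0) w_i0[h] / w_i[h] else 1) * dk
      w_ho[h, o] <- w_ho[h, o] * max(fac, 0)
    }
  }
  avg_tr <- (1 - params$delta_avg) * avg_tr + params$delta_avg * sum_tr
  list(w_ho = w_ho, avg_tr = avg_tr, sum_tr = sum_tr)
}

#' Homeostatic synaptic scaling
#'
#' Applied once per epoch per output neuron: the target input sum `W_j0`
#' steps up by a factor `1 + d_tar` when the neuron fired below its target
#' rate, down by `1 - d_tar` when above, and is unchanged at the target;
#' incoming excitatory weights are then rescaled so the column sum equals
#' `W_j0` exactly (frozen entries keep their value; the remainder is
#' distributed over unfrozen entries).
#'
#' @param w_ho weight matrix (hidden x output).
#' @param w_j0 target input sums per output neuron.
#' @param rate_j measured spike counts per epoch per output neuron.
#' @param target_rate homeostatic set point (spikes/epoch).
#' @param d_tar per-epoch adjustment step.
#' @param frozen optional logical matrix.
#' @return list `w_ho`, `w_j0`, `skipped` (columns with zero unfrozen mass).
#' @export
homeostatic_scale <- function(w_ho, w_j0, rate_j, target_rate = 1,
                              d_tar = 0.001, frozen = NULL) {
  w_j0 <- w_j0 * ifelse(rate_j < target_rate, 1 + d_tar,
                        ifelse(rate_j > target_rate, 1 - d_tar, 1))
  res <- heterosynaptic_rescale(w_ho, w_j0, frozen)
  list(w_ho = res$w_ho, w_j0 = w_j0, skipped = res$skipped)
}

#' Heterosynaptic rescaling
#'
#' After every plasticity event each output neuron's incoming excitatory
#' weights are renormalized so their sum equals the homeostatic target,
#' preserving relative proportions among unfrozen synapses.
#'
#' @inheritParams homeostatic_scale
#' @return list `w_ho`, `skipped` (flagged zero columns).
#' @export
heterosynaptic_rescale <- function(w_ho, w_j0, frozen = NULL) {
  skipped <- integer(0)
  for (j in seq_len(ncol(w_ho))) {
    fz <- if (is.null(frozen)) rep(FALSE, nrow(w_ho)) else frozen[, j]
    us <- sum(w_ho[!fz, j]); fs <- sum(w_ho[fz, j])
    tgt <- w_j0[j] - fs
    if (us > 0 && tgt > 0) {
      w_ho[!fz, j] <- w_ho[!fz, j] * tgt / us
    } else {
      skipped <- c(skipped, j)
    }
  }
  list(w_ho = w_ho, skipped = skipped)
}

#' Inhibitory balance rule
#'
#' Every hidden neuron's outgoing inhibitory weight is set to the negative
#' mean of its outgoing excitatory weights.
#'
#' @param w_ho excitatory weight matrix (hidden x output).
#' @return vector of inhibitory weights (one per hidden neuron, `<= 0`).
#' @export
inhibitory_balance <- function(w_ho) -rowMeans(w_ho)

#' Freeze the strongest fraction of weights
#'
#' Marks the top `floor(fraction * N)` hidden-to-output weights by value;
#' ties at the threshold break by synapse index (column-major).  Frozen
#' synapses are exempt from all subsequent updates.
#'
#' @param w_ho weight matrix.
#' @param fraction fraction in `[0, 1]`.
#' @return logical matrix mask, same shape as `w_ho`.
#' @export
freeze_top_fraction <- function(w_ho, fraction) {
  stopifnot(fraction >= 0, fraction <= 1)
  n <- floor(fraction * length(w_ho))
  mask <- matrix(FALSE, nrow(w_ho), ncol(w_ho))
  if (n > 0) {
    ord <- order(as.vector(w_ho), seq_along(w_ho), decreasing = c(TRUE, FALSE),
                 method = "radix")
    mask[ord[seq_len(n)]] <- TRUE
  }
  mask
}
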