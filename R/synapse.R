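#' Synapse parameters
#'
#' Event-driven conductance: on a presynaptic spike the conductance is
#' incremented by the normalized weight scaled by a stochastic release
#' factor uniform on `[1-R, 1+R]`; otherwise it relaxes geometrically with
#' ratio `gamma`.  The synaptic current is `-g (V_post - V_rev)`, so the
#' reversal potential determines excitatory vs inhibitory action.
#'
#' @param gamma relaxation ratio in `[0, 1)`.
#' @param release_var release variability `R` in `[0, 1)`, standard 0.12.
#' @param v_rev_exc,v_rev_inh reversal potentials in map units.
#' @export
synapse_params <- function(gamma = 0.6, release_var = 0.12,
                           v_rev_exc = 0, v_rev_inh = -1.1) {
  stopifnot(gamma >= 0, gamma < 1, release_var >= 0, release_var < 1)
  list(gamma = gamma, release_var = release_var,
       v_rev_exc = v_rev_exc, v_rev_inh = v_rev_inh)
}

#' Advance one synapse one step
#'
#' @param g current conductance.
#' @param params a [synapse_params()].
#' @param pre_spiked did the presynaptic neuron spike this step?
#' @param w plastic weight of the synapse.
#' @param w_target postsynaptic normalization: the target input sum of the
#'   receiving neuron (default mode), its instantaneous input sum, or a
#'   target rate, per `norm`.
#' @param x uniform(0,1) draw from the caller's seeded stream (release
#'   variability); ignored when no spike arrives.
#' @param v_post postsynaptic fast variable (for the current).
#' @param type `"exc"` or `"inh"`.
#' @param norm normalization mode, informational; the caller supplies the
#'   matching `w_target`.
#' @return list `g` (updated conductance) and `i_syn` (current delivered
#'   this step, computed from the updated conductance).
#' @export
step_synapse <- function(g, params, pre_spiked, w, w_target, x = NULL,
                         v_post = -1, type = c("exc", "inh"),
                         norm = c("target_sum", "instant_sum", "rate")) {
  type <- match.arg(type)
  norm <- match.arg(norm)
  if (w_target <= 0) stop("degenerate normalization: w_target <= 0")
  g <- params$gamma * g
  if (isTRUE(pre_spiked)) {
    if (is.null(x)) x <- runif(1)
    rel <- 1 - params$release_var + 2 * x * params$release_var
    g <- g + rel * w / w_target
  }
  v_rev <- if (type == "exc") params$v_rev_exc else params$v_rev_inh
  list(g = g, i_syn = -g * (v_post - v_rev))
}
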