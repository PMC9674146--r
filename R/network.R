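#' Build the three-layer spiking network
#'
#' Default dimensions: a 7x7 input layer (49 neurons), a 28x28 hidden layer
#' (784), and a 3x3 output layer whose centre neuron is nonfunctional,
#' leaving 8 decision neurons — 842 neurons in total and 784 x 8 = 6272
#' hidden-to-output excitatory synapses.  Each hidden neuron receives
#' excitatory synapses from 9 distinct input neurons chosen uniformly at
#' random, with strengths drawn from a normal distribution truncated at
#' zero; every hidden neuron sends one excitatory and one inhibitory
#' synapse to every decision neuron, all excitatory strengths initially
#' uniform and the inhibitory strength the negative mean of the excitatory
#' ones.  All neurons start at the silent fixed point.
#'
#' @param seed integer seed (wiring and initial weights).
#' @param cfg a [snn_config()].
#' @return an `snn` object (list of state vectors/matrices; see fields
#'   `W_ih`, `src`, `W_ho`, `WI`, `Wj0`, `Wi0`, `frozen`, `hidden_active`).
#' @examples
#' net <- build_network(seed = 1)
#' net                     # 842 neurons, 6272 hidden-to-output synapses
#' dim(net$W_ho)
#' @export
build_network <- function(seed = 1, cfg = snn_config()) {
  set.seed(child_seed(seed, "wiring"))
  vfs <- cfg$network$vfs
  n_in <- vfs^2
  n_hid <- cfg$network$hidden_side^2
  n_aff <- cfg$network$n_afferents
  rest <- resting_state(map_params(cfg$neuron$alpha, cfg$neuron$mu,
                                   cfg$neuron$sigma, cfg$neuron$beta_e,
                                   cfg$neuron$sigma_e, cfg$neuron$dt))
  n_neu <- n_in + n_hid + 9
  src <- t(vapply(seq_len(n_hid), function(h) sample.int(n_in, n_aff),
                  integer(n_aff)))
  w_ih <- matrix(pmax(rnorm(n_hid * n_aff, cfg$network$w_ih_mean,
                            cfg$network$w_ih_cv * cfg$network$w_ih_mean), 0),
                 n_hid, n_aff)
  w0 <- cfg$network$w_ho_init
  net <- list(
    vfs = as.integer(vfs), n_in = as.integer(n_in), n_hid = as.integer(n_hid),
    V = rep(rest$V, n_neu), I = rep(rest$I, n_neu), Vprev = rep(rest$V, n_neu),
    Gexc = numeric(n_neu), Ginh = numeric(n_neu),
    W_ih = w_ih, src = src, row0 = rowSums(w_ih),
    W_ho = matrix(w0, n_hid, 8), WI = rep(-w0, n_hid),
    Wj0 = rep(n_hid * w0, 8), Wj0_ref = rep(n_hid * w0, 8),
    Wi0 = rep(8 * w0, n_hid),
    frozen = matrix(0L, n_hid, 8),
    hidden_active = rep(1L, n_hid),
    avg_tr = -1, epoch_now = 0,   # negative = uninitialized; adopts the
                                  # first realized trace-sum scale

    sleep_lambda = rep(cfg$sleep$lambda_init, n_hid),
    sleep_rate_ema = numeric(n_hid),
    traces = list(h = integer(0), o = integer(0),
                  tr = numeric(0), te = numeric(0)),
    cfg = cfg)
  class(net) <- "snn"
  net
}

#' @export
print.snn <- function(x, ...) {
  cat("somnus spiking network:", x$n_in, "input /", x$n_hid, "hidden /",
      "9 output neurons (", x$n_in + x$n_hid + 9, "total ),",
      length(x$W_ho), "H->O excitatory synapses\n")
  cat("  epoch", x$epoch_now, "| frozen:", sum(x$frozen),
      "| dropped hidden:", sum(x$hidden_active == 0), "\n")
  invisible(x)
}

default_phase <- function(type = "train", task = 0, plastic_ih = FALSE,
                          plastic_ho = FALSE, homeostatic = TRUE,
                          motor = TRUE, input_on = TRUE, s_rp_sleep = 0.5,
                          snapshot_every = 0L, target_rates = numeric(0),
                          fixed_vf = NULL) {
  list(type = type, task = as.integer(task), plastic_ih = plastic_ih,
       plastic_ho = plastic_ho, homeostatic = homeostatic, motor = motor,
       input_on = input_on, s_rp_sleep = s_rp_sleep,
       snapshot_every = as.integer(snapshot_every),
       target_rates = target_rates, fixed_vf = fixed_vf)
}

#' Run one or more epochs of a phase through the compiled engine
#'
#' @param net an `snn`.
#' @param env a `particle_grid`.
#' @param agent an [agent_state()].
#' @param phase a phase description (see [run_schedule()] for the phase
#'   kinds); internal callers construct it directly.
#' @param n_epochs number of 600-step epochs.
#' @return engine result list: updated `net`, `env`, `agent` plus per-epoch
#'   `consumption` codes (0 none, 1 rewarded, 2 punished, 3 other),
#'   chosen `dirs`, per-neuron spike totals, snapshots and diagnostics.
#' @export
run_epochs <- function(net, env, agent, phase, n_epochs) {
  res <- engine_run(net, env, agent, phase, as.integer(n_epochs),
                    engine_cfg(net$cfg))
  res$net$cfg <- net$cfg
  class(res$net) <- "snn"
  class(res$env) <- "particle_grid"
  res$env$width <- env$width; res$env$height <- env$height
  res
}

#' Run a single epoch against a supplied visual field
#'
#' Stimulates the input neurons marked in `visual_field` with a brief
#' suprathreshold pulse, iterates the 600-step dynamics, and decodes the
#' movement direction as the decision neuron with most spikes in the first
#' 300 steps (ties uniform at random; zero spikes keeps the previous
#' direction).  The agent does not move.
#'
#' @param net an `snn`.
#' @param visual_field binary matrix of side `net$vfs`.
#' @param plasticity_mode `"none"`, `"unsupervised"` (I->H) or
#'   `"rewarded"` (H->O trace collection).
#' @param last_dir previous direction code for the zero-spike fallback.
#' @return list: `direction`, per-layer spike counts, updated `net`.
#' @export
run_epoch <- function(net, visual_field, plasticity_mode = "none",
                      last_dir = -1L) {
  stopifnot(nrow(visual_field) == net$vfs)
  env <- empty_environment(net$cfg)
  agent <- agent_state(c(1, 1), last_dir = last_dir)
  phase <- default_phase(type = "train", task = 0,
                         plastic_ih = plasticity_mode == "unsupervised",
                         plastic_ho = plasticity_mode == "rewarded",
                         homeostatic = FALSE, motor = FALSE,
                         fixed_vf = matrix(as.integer(visual_field),
                                           net$vfs, net$vfs))
  res <- run_epochs(net, env, agent, phase, 1)
  list(direction = res$dirs[1],
       input_spikes = res$in_spike_total,
       hidden_spikes = res$hid_spikes,
       output_spikes = res$out_spikes,
       net = res$net)
}

empty_environment <- function(cfg = snn_config()) {
  env <- list(cells = matrix(0L, cfg$env$height, cfg$env$width),
              ori = integer(0), pr = integer(0), pc = integer(0),
              width = as.integer(cfg$env$width),
              height = as.integer(cfg$env$height), density = 0)
  class(env) <- "particle_grid"
  env
}

#' Resolve the final movement from network choice and exploration
#'
#' With probability `agent$explore` a uniformly random direction overrides
#' the network's choice.
#'
#' @param network_choice direction code 0-7 (or -1 when undecided).
#' @param agent an [agent_state()].
#' @return direction code.
#' @export
decide_move <- function(network_choice, agent) {
  if (runif(1) < agent$explore) sample(0:7, 1) else network_choice
}

task_orientations <- function(task) {
  if (task == 1) c("horizontal", "neg_diagonal")
  else if (task == 2) c("vertical", "pos_diagonal")
  else ORIENTATIONS
}

#' Build the environment matching a phase kind
#'
#' Unsupervised phases present all four particle orientations; task
#' training/testing phases present only the task's rewarded and punished
#' orientations, in equal numbers.
#' @param task 0 (all orientations), 1 or 2.
#' @param cfg a [snn_config()].
#' @param seed optional seed.
#' @export
task_environment <- function(task, cfg = snn_config(), seed = NULL) {
  init_environment(cfg$env$width, cfg$env$height, cfg$env$density,
                   task_orientations(task), seed = seed)
}
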