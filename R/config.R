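#' Default simulation configuration
#'
#' Returns the full nested parameter list used by every simulation entry
#' point.  Values printed in the source model description are fixed here
#' (map parameters alpha = 3.65, mu = 5e-4, sigma = 0.06, beta_e = 0.133,
#' sigma_e = 1, step 0.5 ms; release variability R = 0.12; STDP time
#' constant Tc = 40 ms, trace maximum K = 0.04, 120-step pairing window,
#' 6-epoch trace lifetime, c = 1 epoch; rewards +1 / -0.001 / -0.0001,
#' sleep reward 0.5; 600-step epochs with a 300-step decision window;
#' 50x50 world at 10% cell density; 7x7 visual field; 28x28 hidden layer
#' with 9 afferents each; exploration probability 1% plus 1% per
#' non-acquiring move).  Quantities the model description leaves free
#' (conductance relaxation gamma, reversal potentials in map units,
#' projection gains, input pulse, homeostatic step and target rate,
#' running-average rate delta) are package defaults documented in the
#' methods vignette.
#'
#' @param ... named overrides of the form `group$name`, e.g.
#'   `synapse = list(gamma = 0.5)`; unknown names are an error.
#' @return A nested named list with classes `somnus_config`.
#' @export
snn_config <- function(...) {
  cfg <- list(
    neuron = list(alpha = 3.65, mu = 5e-4, sigma = 0.06,
                  beta_e = 0.133, sigma_e = 1, dt = 0.5),
    synapse = list(gamma = 0.6, release_var = 0.12,
                   v_rev_exc = 0, v_rev_inh = -1.1,
                   gain_ih = 0.8, gain_ho = 450, gain_inh = 450,
                   gain_noise = 12,
                   norm_mode = "target_sum"),
    stdp = list(tc_ms = 40, k_max = 0.04, pair_window = 120,
                trace_lifetime = 6, c_epochs = 1,
                delta_avg = 0.01, avg_floor = 1e-6,
                unsupervised_mode = "multiplicative"),
    homeostasis = list(d_tar = 0.001, target_rate = 1,
                       in_sleep = TRUE),
    network = list(vfs = 7, hidden_side = 28, n_afferents = 9,
                   w_ho_init = 0.125, w_ih_mean = 1, w_ih_cv = 0.25,
                   w_floor_frac = 0.005, w_ih_cap_frac = 0.25),
    policy = list(explore_base = 0.01, explore_step = 0.01,
                  pulse_amp = 8, pulse_steps = 2,
                  epoch_steps = 600, decision_steps = 300),
    env = list(width = 50, height = 50, density = 0.10),
    rewards = list(rewarded = 1, punished = -0.001, empty = -1e-4,
                   sleep = 0.5),
    sleep = list(interval_aeons = 1, mode = "per_neuron_rates",
                 ctrl_gain = 0.08, ctrl_ema = 0.15,
                 lambda_init = 3),
    schedule = list(preset = "desk",
                    full = list(unsupervised = 2000, train = 10000, test = 500,
                                interleaved = 10000),
                    reduced = list(unsupervised = 100, train = 500, test = 25,
                                   interleaved = 500),
                    desk = list(unsupervised = 5, train = 120, test = 15,
                                interleaved = 120)),
    snapshot_every = 200
  )
  class(cfg) <- "somnus_config"
  override_config(cfg, list(...))
}

override_config <- function(cfg, over) {
  for (g in names(over)) {
    if (!g %in% names(cfg)) stop("unknown config group: ", g)
    if (!is.list(over[[g]])) { cfg[[g]] <- over[[g]]; next }
    for (nm in names(over[[g]])) {
      if (!nm %in% names(cfg[[g]]))
        stop("unknown config field: ", g, "$", nm)
      cfg[[g]][[nm]] <- over[[g]][[nm]]
    }
  }
  cfg
}

#' Load and validate a configuration file
#'
#' Reads a YAML file whose top-level keys mirror [snn_config()] groups and
#' merges it over the defaults.  Unknown groups or fields are rejected with
#' a message naming the offending key; an empty file yields the defaults.
#'
#' @param path YAML file path.
#' @return A `somnus_config` list.
#' @export
load_config <- function(path) {
  over <- yaml::read_yaml(path)
  if (is.null(over)) over <- list()
  do.call(snn_config, over)
}

# flatten the cfg groups the C++ engine needs
engine_cfg <- function(cfg) {
  list(alpha = cfg$neuron$alpha, mu = cfg$neuron$mu, sigma = cfg$neuron$sigma,
       beta_e = cfg$neuron$beta_e, sigma_e = cfg$neuron$sigma_e,
       dt = cfg$neuron$dt,
       gamma = cfg$synapse$gamma, release_var = cfg$synapse$release_var,
       vrp_exc = cfg$synapse$v_rev_exc, vrp_inh = cfg$synapse$v_rev_inh,
       gain_ih = cfg$synapse$gain_ih, gain_ho = cfg$synapse$gain_ho,
       gain_inh = cfg$synapse$gain_inh, gain_noise = cfg$synapse$gain_noise,
       pulse_amp = cfg$policy$pulse_amp, pulse_steps = cfg$policy$pulse_steps,
       epoch_steps = cfg$policy$epoch_steps,
       decision_steps = cfg$policy$decision_steps,
       tc_ms = cfg$stdp$tc_ms, k_max = cfg$stdp$k_max,
       pair_window = cfg$stdp$pair_window,
       trace_lifetime = cfg$stdp$trace_lifetime,
       c_epochs = cfg$stdp$c_epochs, delta_avg = cfg$stdp$delta_avg,
       avg_floor = cfg$stdp$avg_floor,
       d_tar = cfg$homeostasis$d_tar,
       target_rate = cfg$homeostasis$target_rate,
       explore_base = cfg$policy$explore_base,
       explore_step = cfg$policy$explore_step,
       ctrl_gain = cfg$sleep$ctrl_gain, ctrl_ema = cfg$sleep$ctrl_ema,
       w_floor = cfg$network$w_floor_frac * cfg$network$w_ho_init,
       wih_cap_frac = cfg$network$w_ih_cap_frac)
}

#' Derive a named child seed from a master seed
#'
#' One master seed spawns reproducible child streams (wiring, environment,
#' exploration, sleep noise ...) so that modules can be re-run in
#' isolation.  Children stay below 2^31.
#'
#' @param seed master integer seed.
#' @param stream stream name or integer offset.
#' @return integer seed.
#' @export
child_seed <- function(seed, stream) {
  off <- if (is.character(stream)) {
    sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  } else as.integer(stream)
  as.integer((as.double(seed) * 48271 + off * 16807) %% 2147483647)
}
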