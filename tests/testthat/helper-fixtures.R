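# Shared miniature objects. Everything is generated in code at test time.

# full-architecture config with the cheap policy settings used throughout
test_cfg <- function(...) {
  snn_config(policy = list(pulse_amp = 8, pulse_steps = 2), ...)
}

# a miniature network: 3x3 field, 4 hidden neurons, 3 afferents each
tiny_fixture <- function(seed = 1, ...) {
  make_fixture(seed = seed, env_side = 9, density = 0.1, vfs = 3,
               hidden_side = 2, n_afferents = 3, ...)
}

# run one awake phase on a fresh full-size network; returns engine result
quick_awake <- function(n_epochs, seed = 4, task = 1, type = "train",
                        plastic_ho = (type == "train"), cfg = test_cfg()) {
  set.seed(seed)
  net <- build_network(seed, cfg)
  env <- task_environment(task, cfg, seed = seed + 100)
  agent <- agent_state(c(25, 25))
  ph <- somnus:::default_phase(type, task, plastic_ho = plastic_ho,
                               homeostatic = plastic_ho)
  run_epochs(net, env, agent, ph, n_epochs)
}
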