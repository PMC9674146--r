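#' Sleep-phase configuration
#'
#' During simulated REM-like sleep the input layer is silenced, the output
#' layer is decoupled from movement, and each hidden neuron is driven by an
#' independent Poisson spike train whose intensity is servo-adjusted so the
#' realized firing rate tracks a target.  Plasticity runs as rewarded STDP
#' with a constant reward of 0.5 per movement cycle, which makes it
#' functionally unsupervised.
#'
#' @param mode `"per_neuron_rates"` (targets per hidden neuron from awake
#'   training) or `"uniform_rate"` (all neurons share the population mean).
#' @param target_rates numeric vector of spikes/epoch per hidden neuron.
#' @param interval_aeons length of one sleep interval in aeons (100-cycle
#'   blocks).
#' @param s_rp constant sleep reward (0.5).
#' @export
sleep_config <- function(mode = c("per_neuron_rates", "uniform_rate"),
                         target_rates = NULL, interval_aeons = 1,
                         s_rp = 0.5) {
  mode <- match.arg(mode)
  stopifnot(interval_aeons >= 1, is.null(target_rates) || all(target_rates >= 0))
  list(mode = mode, target_rates = target_rates,
       interval_aeons = interval_aeons, s_rp = s_rp)
}

#' Target sleep rates from recorded awake activity
#'
#' Per-neuron mean hidden-layer firing rates are averaged across the named
#' training phases (average of per-phase means), matching the constraint
#' that spiking statistics be conserved across awake and sleep.
#'
#' @param hid_rates named list of per-neuron rate vectors, one per phase
#'   (as collected by [run_schedule()]).
#' @param phases character vector of phase labels to average.
#' @param mode as in [sleep_config()]; `"uniform_rate"` replaces every
#'   target by the hidden-population mean.
#' @return numeric vector of target rates (spikes/epoch).
#' @export
record_target_rates <- function(hid_rates, phases = names(hid_rates),
                                mode = "per_neuron_rates") {
  if (length(phases) == 0) stop("no phases supplied")
  miss <- setdiff(phases, names(hid_rates))
  if (length(miss)) stop("phase not recorded: ", paste(miss, collapse = ", "))
  m <- vapply(phases, function(p) hid_rates[[p]], hid_rates[[phases[1]]])
  tgt <- rowMeans(as.matrix(m))
  if (mode == "uniform_rate") tgt <- rep(mean(tgt), length(tgt))
  tgt
}

# seed the Poisson-intensity servo from the targets on first use so the
# first interval does not start with a rate transient
prepare_sleep <- function(net, target_rates) {
  if (all(net$sleep_rate_ema == 0)) {
    net$sleep_lambda <- pmax(target_rates * 1.2, 0.05)
    net$sleep_rate_ema <- target_rates
  }
  net
}

sleep_phase <- function(net, target_rates, s_rp = 0.5, snapshot_every = 0L) {
  default_phase(type = "sleep", task = 0, plastic_ih = FALSE,
                plastic_ho = TRUE,
                homeostatic = net$cfg$homeostasis$in_sleep,
                motor = FALSE, input_on = FALSE, s_rp_sleep = s_rp,
                snapshot_every = snapshot_every,
                target_rates = target_rates)
}

#' Run a sleep interval
#'
#' @param net an `snn`.
#' @param sleep a [sleep_config()] with `target_rates` set.
#' @param env,agent current environment and agent (both untouched by sleep;
#'   passed through for state continuity).
#' @param snapshot_every snapshot interval in epochs (0 = none).
#' @return engine result (see [run_epochs()]); the input layer emits no
#'   spikes and the agent does not move.
#' @export
run_sleep_interval <- function(net, sleep, env = NULL, agent = NULL,
                               snapshot_every = 0L) {
  if (is.null(sleep$target_rates)) stop("sleep target_rates not set")
  tgt <- sleep$target_rates
  if (sleep$mode == "uniform_rate") tgt <- rep(mean(tgt), length(tgt))
  if (is.null(env)) env <- empty_environment(net$cfg)
  if (is.null(agent)) agent <- agent_state()
  net <- prepare_sleep(net, tgt)
  run_epochs(net, env, agent,
             sleep_phase(net, tgt, sleep$s_rp, snapshot_every),
             sleep$interval_aeons * 100)
}
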