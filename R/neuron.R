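#' Map-neuron parameters
#'
#' Two-variable Rulkov-type difference-equation neuron.  `alpha` shapes the
#' fast nonlinearity, `mu` sets the slow-variable timescale (`mu << 1`),
#' `sigma` the resting drive, and `beta_e`/`sigma_e` couple external current
#' into the fast and slow equations.  One step is `dt` = 0.5 ms.
#' @param alpha,mu,sigma,beta_e,sigma_e,dt see description.
#' @export
map_params <- function(alpha = 3.65, mu = 5e-4, sigma = 0.06,
                       beta_e = 0.133, sigma_e = 1, dt = 0.5) {
  stopifnot(alpha > 1, mu > 0, mu < 0.1)
  list(alpha = alpha, mu = mu, sigma = sigma,
       beta_e = beta_e, sigma_e = sigma_e, dt = dt)
}

#' Neuron state constructor
#' @param V,I,V_prev fast variable, slow variable, previous-step fast variable.
#' @export
neuron_state <- function(V = -1, I = -1, V_prev = V) {
  list(V = V, I = I, V_prev = V_prev, spiked = FALSE)
}

#' Silent fixed point of the map
#'
#' The slow variable equilibrates where `V = sigma - 1`; substituting into
#' the subthreshold branch `V = alpha/(1 - V) - 1 + I` gives the resting
#' `I`.  Stable because `|f'(V)| = alpha/(1-V)^2 < 1` there.
#' @param params a [map_params()].
#' @return a [neuron_state()] at rest.
#' @export
resting_state <- function(params = map_params()) {
  V <- params$sigma - 1
  I <- V + 1 - params$alpha / (1 - V)
  neuron_state(V = V, I = I, V_prev = V)
}

#' Advance a map neuron one step
#'
#' Fast variable update uses the three-branch piecewise map: subthreshold
#' (`V <= 0`) follows `alpha/(1-V) - 1 + I*`; the spike peak (`0 < V <
#' alpha + I*` with `V_prev <= 0`) jumps to the plateau `alpha + I*` and is
#' the step on which the spike is registered; otherwise the neuron resets
#' to -1.  Here `I* = I + beta_e * I_ext`.  The slow variable integrates
#' `I <- I - mu (V + 1) + mu sigma + mu sigma_e I_ext`.
#'
#' @param state a [neuron_state()]; must be finite.
#' @param params a [map_params()].
#' @param I_ext external current for this step.
#' @return updated state with `spiked` flag.
#' @export
step_neuron <- function(state, params, I_ext = 0) {
  if (!all(is.finite(c(state$V, state$I)))) stop("non-finite neuron state")
  Istar <- state$I + params$beta_e * I_ext
  v <- state$V
  spiked <- FALSE
  if (v <= 0) {
    nv <- params$alpha / (1 - v) - 1 + Istar
  } else if (v < params$alpha + Istar && state$V_prev <= 0) {
    nv <- params$alpha + Istar
    spiked <- TRUE
  } else {
    nv <- -1
  }
  ni <- state$I - params$mu * (v + 1) + params$mu * params$sigma +
    params$mu * params$sigma_e * I_ext
  list(V = nv, I = ni, V_prev = v, spiked = spiked)
}

#' Iterate a map neuron over an input sequence (pure R)
#'
#' Reference implementation used to cross-check the compiled engine.
#' @param params a [map_params()].
#' @param I_ext numeric vector of external currents, one per step.
#' @param state initial state, default resting.
#' @return list of `V`, `I`, `spiked` vectors and the final state.
#' @export
simulate_neuron <- function(params, I_ext, state = resting_state(params)) {
  n <- length(I_ext)
  V <- numeric(n); I <- numeric(n); spk <- logical(n)
  for (s in seq_len(n)) {
    state <- step_neuron(state, params, I_ext[s])
    V[s] <- state$V; I[s] <- state$I; spk[s] <- state$spiked
  }
  list(V = V, I = I, spiked = spk, state = state)
}
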