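# somnus

Spiking-network reinforcement learning with sleep replay: a desk-scale
simulator for studying catastrophic forgetting and its rescue by
interleaved sleep in a biologically grounded network.

## The problem

Networks trained with local plasticity rules overwrite old tasks when
trained on new ones.  Animals do not — and a long-standing hypothesis
credits sleep: offline reactivation of the neurons engaged during
learning lets old memory traces strengthen without access to the old
training data.  `somnus` implements a complete, self-contained testbed
for this idea, for computational neuroscientists who want to manipulate
the mechanism (plasticity rules, replay statistics, freezing, dropout)
rather than re-derive the simulator.

## The model

A virtual agent forages on a toroidal 50x50 grid scattered with
two-pixel particles in four orientations (10% cell density, equal
representation, no two particles adjacent).  Task 1 rewards horizontal
particles and punishes negative diagonals; Task 2 is the complementary
vertical/positive-diagonal task.  Performance is discriminability —
rewarded / (rewarded + punished) among consumed particles — with 0.5 at
chance.

The agent is a three-layer feed-forward spiking network of 842
map-based (Rulkov-type) neurons:

* **Input layer** (7x7): one neuron per visual-field cell, pulsed when
  its cell holds a particle pixel.
* **Hidden layer** (28x28): each neuron receives excitatory synapses
  from 9 random input neurons; these synapses follow standard STDP
  during an initial unsupervised phase and are then frozen.
* **Output layer** (3x3, nonfunctional centre): 8 decision neurons in
  all-to-all excitatory + inhibitory balance with the hidden layer
  (6272 plastic excitatory synapses).  The neuron spiking most in the
  first half of each 600-step epoch sets the move.

Each neuron obeys the two-variable map
`V' = f_alpha(V, I + beta_e I_ext)`, `I' = I - mu(V+1) + mu sigma +
mu sigma_e I_ext` (`alpha = 3.65`, `mu = 5e-4`, 0.5 ms steps), which
produces spikes without ODE integration.  Hidden-to-output synapses
learn by **rewarded STDP**: spike pairings store decaying traces
`+-K e^(-|dt|/Tc)` (`K = 0.04`, `Tc = 40 ms`) for 6 epochs, and every
reward event `S_rp` converts the live traces into multiplicative weight
updates scaled by `S_rp`, trace age, and a running-average
normalization, followed by heterosynaptic renormalization of each
output's input sum to its homeostatic target.

**Sleep** silences the input layer, decouples the motor output, drives
each hidden neuron with Poisson noise matched to its awake firing rate,
and runs the same plasticity with constant `S_rp = 0.5`.  Interleaving
100-cycle sleep blocks with new-task training lets replay re-strengthen
the old task's strong synapses while the new task is learned —
preventing catastrophic forgetting without old-task data.

## Worked example

```r
library(somnus)
cfg   <- snn_config()                          # all model constants
sched <- schedule_preset("single_T1", "desk", cfg)   # unsup + Task 1 + tests
run   <- run_schedule(sched, seed = 7, n_trials = 3, cfg = cfg)
test_summary(run)
```

which prints (desk preset — 5 aeons unsupervised, 120 aeons of Task 1
training, 15-aeon test phases, 3 network initializations):

```
      phase task      mean         sd
1 test_T1#1    1 0.5390770 0.02958560
2 test_T2#1    2 0.4613981 0.05936348
```

Read: after Task 1 training the agent consumes rewarded (horizontal)
particles more often than punished (negative-diagonal) ones — mean
test discriminability 0.539 against the 0.5 chance level — while the
untrained complementary Task 2 sits at chance (0.461, within binomial
error of 0.5 at ~60 consumptions per trial).  Desk-scale magnitudes are
deliberately modest: single trials range from chance to ~0.65, and the
asymptotic values (~0.7) require training runs three orders of
magnitude longer (the `full` preset).  The sequential
(`"sequential"`) and sleep-interleaved (`"interleaved_sleep_T2"`)
schedules expose catastrophic forgetting and sleep-replay protocols the
same way; `run_sleep_interval()` gives direct access to the sleep
phase.  The methods vignette documents what each scale can and cannot
resolve.

Analysis tools operate on the phase-labelled weight snapshots every run
records: `receptive_field_output()`, `prm()` (particle responsiveness),
`task_relevant_synapses()`, `svm_weight_classifier()`,
`embed_trajectory()` (PCA/kPCA), `manifold_distance()` and
`weight_histogram_2d()`.  A thin command-line wrapper lives at
`inst/cli/somnus.R` (`run`, `sleep`, `analyze`).

See the methods vignette (`vignettes/sleep-replay-methods.Rmd`) for the
full model description, parameter tables and design rationale.

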