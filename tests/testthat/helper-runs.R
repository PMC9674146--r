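# Desk-scale protocol runs shared by the acceptance tests.  Computed once
# per session on first use; every consumer reads the same cached object.

.run_cache <- new.env(parent = emptyenv())

acceptance_runs <- function() {
  if (!is.null(.run_cache$runs)) return(.run_cache$runs)
  cfg <- snn_config(policy = list(pulse_amp = 8, pulse_steps = 2))
  seqr <- run_schedule(schedule_preset("sequential", "desk", cfg),
                       seed = 101, n_trials = 3, cfg = cfg, keep_net = TRUE)
  slpr <- run_schedule(schedule_preset("interleaved_sleep_T2", "desk", cfg),
                       seed = 101, n_trials = 3, cfg = cfg, keep_net = TRUE)
  .run_cache$runs <- list(sequential = seqr, sleep = slpr, cfg = cfg)
  .run_cache$runs
}

# pooled discriminability over trials for one test phase label
pooled_test <- function(run, label) {
  tt <- do.call(rbind, lapply(run$trials, `[[`, "tests"))
  tt <- tt[tt$phase == label, ]
  list(value = sum(tt$rewarded) / sum(tt$rewarded + tt$punished),
       n = sum(tt$rewarded + tt$punished))
}

# late-phase (last fifth) snapshots across trials for phases matching pat
late_snapshots <- function(run, pat) {
  out <- NULL
  for (tr in run$trials) {
    info <- tr$snapshot_info
    idx <- which(grepl(pat, info$phase))
    if (!length(idx)) next
    idx <- idx[info$aeon[idx] >= stats::quantile(info$aeon[idx], 0.8)]
    out <- rbind(out, tr$snapshots[idx, , drop = FALSE])
  }
  out
}
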