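PHASE_KINDS <- c("unsupervised", "train_T1", "train_T2", "test_T1", "test_T2",
                 "interleaved_T1T2", "interleaved_S_T1", "interleaved_S_T2",
                 "interleaved_US_T1", "interleaved_US_T2", "sleep_only",
                 "freeze")

#' Build a phase schedule
#'
#' A schedule is an ordered list of phases, each a phase kind plus a
#' duration in aeons (1 aeon = 100 epochs / movement cycles).  The
#' unsupervised phase must precede any task phase, and input-to-hidden
#' plasticity is enabled only there (afterwards those synapses are frozen).
#' A `freeze` entry takes a `fraction` instead of a duration and freezes
#' that fraction of the strongest hidden-to-output weights.
#'
#' @param ... phases as `kind = aeons` pairs, e.g.
#'   `phase_schedule(unsupervised = 20, train_T1 = 60, test_T1 = 10)`;
#'   use `freeze = 0.05` for freezing.
#' @return a `phase_schedule` object (data frame `kind`, `aeons`).
#' @export
phase_schedule <- function(...) {
  args <- list(...)
  kinds <- names(args)
  bad <- setdiff(kinds, PHASE_KINDS)
  if (length(bad)) stop("unknown phase kind: ", paste(bad, collapse = ", "))
  sched <- data.frame(kind = kinds, aeons = as.numeric(unlist(args)))
  task_seen <- FALSE
  for (k in sched$kind) {
    if (k != "unsupervised" && k != "freeze") task_seen <- TRUE
    if (k == "unsupervised" && task_seen)
      stop("unsupervised phase must precede any task phase")
  }
  class(sched) <- c("phase_schedule", "data.frame")
  sched
}

#' Standard schedules at a given scale preset
#'
#' @param name one of `"single_T1"`, `"single_T2"`, `"sequential"`
#'   (T1 then T2), `"sequential_sleep"` (T1, T2, then sleep-interleaved T1),
#'   `"interleaved"` (T1 then Interleaved_T1,T2),
#'   `"interleaved_sleep_T2"` (T1 then Interleaved_S,T2).
#' @param preset `"desk"`, `"reduced"` or `"full"`; durations come from the
#'   configuration's schedule table.
#' @param cfg a [snn_config()].
#' @export
schedule_preset <- function(name = c("single_T1", "single_T2", "sequential",
                                     "sequential_sleep", "interleaved",
                                     "interleaved_sleep_T2"),
                            preset = NULL, cfg = snn_config()) {
  name <- match.arg(name)
  preset <- preset %||% cfg$schedule$preset
  d <- cfg$schedule[[preset]]
  if (is.null(d)) stop("unknown preset: ", preset)
  switch(name,
    single_T1 = phase_schedule(unsupervised = d$unsupervised,
                               train_T1 = d$train,
                               test_T1 = d$test, test_T2 = d$test),
    single_T2 = phase_schedule(unsupervised = d$unsupervised,
                               train_T2 = d$train,
                               test_T1 = d$test, test_T2 = d$test),
    sequential = phase_schedule(unsupervised = d$unsupervised,
                                train_T1 = d$train,
                                test_T1 = d$test, test_T2 = d$test,
                                train_T2 = d$train,
                                test_T1 = d$test, test_T2 = d$test),
    sequential_sleep = phase_schedule(unsupervised = d$unsupervised,
                                      train_T1 = d$train,
                                      test_T1 = d$test, test_T2 = d$test,
                                      train_T2 = d$train,
                                      test_T1 = d$test, test_T2 = d$test,
                                      interleaved_S_T1 = d$interleaved,
                                      test_T1 = d$test, test_T2 = d$test),
    interleaved = phase_schedule(unsupervised = d$unsupervised,
                                 train_T1 = d$train,
                                 test_T1 = d$test, test_T2 = d$test,
                                 interleaved_T1T2 = d$interleaved,
                                 test_T1 = d$test, test_T2 = d$test),
    interleaved_sleep_T2 = phase_schedule(unsupervised = d$unsupervised,
                                          train_T1 = d$train,
                                          test_T1 = d$test, test_T2 = d$test,
                                          interleaved_S_T2 = d$interleaved,
                                          test_T1 = d$test, test_T2 = d$test))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

phase_for_kind <- function(kind, task, snapshot_every) {
  switch(kind,
    unsupervised = default_phase("unsupervised", 0, plastic_ih = TRUE,
                                 plastic_ho = FALSE, homeostatic = FALSE,
                                 snapshot_every = snapshot_every),
    train = default_phase("train", task, plastic_ih = FALSE,
                          plastic_ho = TRUE, homeostatic = TRUE,
                          snapshot_every = snapshot_every),
    test = default_phase("test", task, plastic_ih = FALSE,
                         plastic_ho = FALSE, homeostatic = FALSE,
                         snapshot_every = 0L))
}

consumption_performance <- function(cons, aeon0, trial, label) {
  n <- length(cons)
  if (n == 0) return(NULL)
  aeon <- aeon0 + (seq_len(n) - 1) %/% 100
  rew <- tapply(cons == 1, aeon, sum)
  pun <- tapply(cons == 2, aeon, sum)
  tot <- rew + pun
  data.frame(trial = trial, phase = label,
             aeon = as.numeric(names(rew)),
             rewarded = as.vector(rew), punished = as.vector(pun),
             value = ifelse(tot > 0, rew / tot, NA_real_))
}

#' Run a full experiment schedule
#'
#' Executes the phases of a [phase_schedule()] in order for one or more
#' independently initialized trials.  Training phases use rewarded STDP on
#' the hidden-to-output synapses with homeostatic scaling; input-to-hidden
#' STDP runs only in the unsupervised phase; test phases disable all
#' plasticity.  Task environments contain only the task's two particle
#' orientations and are retained across interleaved blocks.
#' Sleep-interleaved phases alternate 100-cycle task and sleep blocks; the
#' sleep targets are the per-neuron hidden rates averaged over all
#' preceding training phases (the `US` variants use the population-mean
#' uniform rate).
#'
#' @param schedule a [phase_schedule()].
#' @param seed master seed; trial `t` uses a derived child seed.
#' @param n_trials number of network initializations.
#' @param cfg a [snn_config()].
#' @param keep_net keep each trial's final network state in the record.
#' @param snapshot_every weight-snapshot interval in epochs.
#' @param sleep_rates optional explicit sleep target-rate vector (used by
#'   protocols that sleep before any training has been recorded).
#' @return a `somnus_run` object: per-trial performance series
#'   (`$performance`), test-phase summaries (`$tests`), phase-labelled
#'   weight snapshots (`$snapshots`, `$snapshot_info`), per-phase hidden
#'   rates, sleep diagnostics, and optionally final networks.
#' @export
run_schedule <- function(schedule, seed = 1, n_trials = 1, cfg = snn_config(),
                         keep_net = FALSE, snapshot_every = NULL,
                         sleep_rates = NULL) {
  stopifnot(inherits(schedule, "phase_schedule"), n_trials >= 1)
  snapshot_every <- as.integer(snapshot_every %||% cfg$snapshot_every)
  trials <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    set.seed(child_seed(seed, paste0("trial", tr)))
    net <- build_network(child_seed(seed, tr), cfg)
    agent <- agent_state(c(sample.int(cfg$env$height, 1),
                           sample.int(cfg$env$width, 1)))
    envs <- list()   # retained task environments, keyed by task code
    get_env <- function(task) {
      key <- as.character(task)
      if (is.null(envs[[key]]))
        envs[[key]] <<- task_environment(task, cfg)
      envs[[key]]
    }
    perf <- list(); tests <- list(); hid_rates <- list()
    snaps <- list(); snap_info <- list(); sleep_diag <- list()
    label_count <- list()
    for (pi in seq_len(nrow(schedule))) {
      kind <- schedule$kind[pi]; aeons <- schedule$aeons[pi]
      label_count[[kind]] <- (label_count[[kind]] %||% 0) + 1
      label <- paste0(kind, "#", label_count[[kind]])
      if (kind == "freeze") {
        net$frozen <- matrix(as.integer(freeze_top_fraction(net$W_ho, aeons)),
                             net$n_hid, 8)
        next
      }
      run_block <- function(block_phase, task, n_epochs, sub) {
        env <- if (block_phase$type == "sleep") empty_environment(cfg)
               else get_env(task)
        res <- run_epochs(net, env, agent, block_phase, n_epochs)
        net <<- res$net; agent <<- res$agent
        if (block_phase$type != "sleep") envs[[as.character(task)]] <<- res$env
        p <- consumption_performance(res$consumption,
                                     res$net$epoch_now %/% 100 -
                                       length(res$consumption) %/% 100,
                                     tr, label)
        if (!is.null(p)) perf[[length(perf) + 1]] <<- p
        if (nrow(res$snapshots) > 0) {
          snaps[[length(snaps) + 1]] <<- res$snapshots
          snap_info[[length(snap_info) + 1]] <<-
            data.frame(trial = tr, phase = label, sub = sub,
                       aeon = res$snap_epochs / 100)
        }
        res
      }
      if (kind == "unsupervised") {
        res <- run_block(phase_for_kind("unsupervised", 0, snapshot_every),
                         0, aeons * 100, "unsupervised")
      } else if (kind %in% c("train_T1", "train_T2")) {
        task <- if (kind == "train_T1") 1 else 2
        res <- run_block(phase_for_kind("train", task, snapshot_every),
                         task, aeons * 100, "train")
        hid_rates[[label]] <- res$hid_spikes / (aeons * 100)
      } else if (kind %in% c("test_T1", "test_T2")) {
        task <- if (kind == "test_T1") 1 else 2
        res <- run_block(phase_for_kind("test", task, 0L),
                         task, aeons * 100, "test")
        cons <- res$consumption
        nr <- sum(cons == 1); np <- sum(cons == 2)
        tests[[length(tests) + 1]] <-
          data.frame(trial = tr, phase = label, task = task,
                     rewarded = nr, punished = np,
                     value = if (nr + np > 0) nr / (nr + np) else NA_real_)
      } else if (kind == "interleaved_T1T2") {
        for (b in seq_len(aeons)) {
          task <- if (b %% 2 == 1) 1 else 2
          run_block(phase_for_kind("train", task, snapshot_every),
                    task, 100, paste0("block", b))
        }
      } else if (kind %in% c("interleaved_S_T1", "interleaved_S_T2",
                             "interleaved_US_T1", "interleaved_US_T2",
                             "sleep_only")) {
        task <- if (grepl("T1$", kind)) 1 else if (grepl("T2$", kind)) 2 else 0
        uniform <- grepl("US", kind)
        tgt <- sleep_rates
        if (is.null(tgt)) {
          train_phases <- names(hid_rates)
          if (length(train_phases) == 0)
            stop(kind, " needs recorded training rates or explicit sleep_rates")
          tgt <- record_target_rates(hid_rates, train_phases,
                                     mode = if (uniform) "uniform_rate"
                                            else "per_neuron_rates")
        } else if (uniform) tgt <- rep(mean(tgt), length(tgt))
        if (kind == "sleep_only") {
          net <- prepare_sleep(net, tgt)
          res <- run_block(sleep_phase(net, tgt, cfg$rewards$sleep,
                                       snapshot_every), 0, aeons * 100, "sleep")
          sleep_diag[[label]] <- list(target = tgt,
                                      realized = res$hid_spikes / (aeons * 100))
        } else {
          realized <- numeric(net$n_hid); sleep_epochs <- 0
          for (b in seq_len(aeons)) {
            if (b %% 2 == 1) {
              run_block(phase_for_kind("train", task, snapshot_every),
                        task, 100, paste0("task", b))
            } else {
              net <- prepare_sleep(net, tgt)
              res <- run_block(sleep_phase(net, tgt, cfg$rewards$sleep,
                                           snapshot_every),
                               0, 100, paste0("sleep", b))
              realized <- realized + res$hid_spikes; sleep_epochs <- sleep_epochs + 100
            }
          }
          if (sleep_epochs > 0)
            sleep_diag[[label]] <- list(target = tgt,
                                        realized = realized / sleep_epochs)
        }
      }
    }
    trials[[tr]] <- list(
      performance = do.call(rbind, perf),
      tests = do.call(rbind, tests),
      snapshots = if (length(snaps)) do.call(rbind, snaps) else
        matrix(0, 0, net$n_hid * 8),
      snapshot_info = if (length(snap_info)) do.call(rbind, snap_info) else NULL,
      hid_rates = hid_rates,
      sleep_diag = sleep_diag,
      net = if (keep_net) net else NULL)
  }
  out <- list(trials = trials, schedule = schedule, seed = seed, cfg = cfg)
  class(out) <- "somnus_run"
  out
}

#' @export
print.somnus_run <- function(x, ...) {
  cat("somnus run:", length(x$trials), "trial(s), schedule:\n")
  print(as.data.frame(x$schedule))
  tt <- test_summary(x)
  if (!is.null(tt) && nrow(tt)) {
    cat("test-phase discriminability (mean over trials):\n")
    print(tt)
  }
  invisible(x)
}

#' Summarize test-phase performance across trials
#'
#' @param run a `somnus_run`.
#' @return data frame with one row per test phase: mean and sd of
#'   discriminability over trials.
#' @export
test_summary <- function(run) {
  tt <- do.call(rbind, lapply(run$trials, `[[`, "tests"))
  if (is.null(tt)) return(NULL)
  agg <- aggregate(value ~ phase + task, tt, function(v) c(mean(v), sd(v)))
  data.frame(phase = agg$phase, task = agg$task,
             mean = agg$value[, 1], sd = agg$value[, 2])
}

#' Discriminability over a consumption window
#'
#' Fraction of consumed particles that were rewarded; 0.5 is chance.
#' @param rewarded,punished counts over the window.
#' @return list `value` (NA with `defined = FALSE` when nothing was
#'   consumed) and `defined`.
#' @export
performance <- function(rewarded, punished) {
  tot <- rewarded + punished
  list(value = if (tot > 0) rewarded / tot else NA_real_, defined = tot > 0)
}

#' Hidden-layer dropout robustness test
#'
#' Cumulatively removes random hidden neurons from a trained network and
#' measures test-phase discriminability at each removal fraction, with all
#' plasticity disabled.
#'
#' @param net a trained `snn`.
#' @param fractions increasing removal fractions in `[0, 1]`.
#' @param task task to test.
#' @param aeons test duration per fraction.
#' @param seed seed for the removal order and test environment.
#' @return data frame `fraction`, `rewarded`, `punished`, `value`.
#' @export
dropout_test <- function(net, fractions = seq(0, 1, 0.1), task = 1,
                         aeons = 5, seed = 1) {
  stopifnot(all(diff(fractions) >= 0))
  cfg <- net$cfg
  set.seed(child_seed(seed, "dropout"))
  order_removed <- sample.int(net$n_hid)
  env <- task_environment(task, cfg)
  agent <- agent_state(c(sample.int(cfg$env$height, 1),
                         sample.int(cfg$env$width, 1)))
  out <- NULL
  for (f in fractions) {
    n_rm <- floor(f * net$n_hid)
    net$hidden_active <- rep(1L, net$n_hid)
    if (n_rm > 0) net$hidden_active[order_removed[seq_len(n_rm)]] <- 0L
    res <- run_epochs(net, env, agent, phase_for_kind("test", task, 0L),
                      aeons * 100)
    net <- res$net; env <- res$env; agent <- res$agent
    nr <- sum(res$consumption == 1); np <- sum(res$consumption == 2)
    out <- rbind(out, data.frame(fraction = f, rewarded = nr, punished = np,
                                 value = if (nr + np > 0) nr / (nr + np)
                                         else NA_real_))
  }
  out
}
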