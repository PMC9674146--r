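fmt_full <- function(x) sprintf("%.17g", x)

#' Write a run record to a plain-text run container
#'
#' The container is a directory of text files: `meta.json` (format version,
#' seed, schedule and configuration echo — enough to re-run the experiment
#' bit-identically), `performance.csv`, `tests.csv`, `snapshot_info.csv`
#' and `snapshots.csv` (one row per phase-labelled weight snapshot, full
#' double precision).
#'
#' @param run a `somnus_run`.
#' @param path directory to create.
#' @export
write_run <- function(run, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(format = "somnus-run-1", seed = run$seed,
               schedule = as.data.frame(run$schedule),
               n_trials = length(run$trials),
               cfg = run$cfg[setdiff(names(run$cfg), "schedule")],
               schedule_cfg = run$cfg$schedule)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  perf <- do.call(rbind, lapply(run$trials, `[[`, "performance"))
  tests <- do.call(rbind, lapply(run$trials, `[[`, "tests"))
  info <- do.call(rbind, lapply(run$trials, `[[`, "snapshot_info"))
  snaps <- do.call(rbind, lapply(run$trials, `[[`, "snapshots"))
  write.csv(perf, file.path(path, "performance.csv"), row.names = FALSE)
  write.csv(tests, file.path(path, "tests.csv"), row.names = FALSE)
  write.csv(info, file.path(path, "snapshot_info.csv"), row.names = FALSE)
  if (!is.null(snaps) && nrow(snaps) > 0) {
    con <- file(file.path(path, "snapshots.csv"), "w")
    on.exit(close(con))
    for (i in seq_len(nrow(snaps)))
      writeLines(paste(fmt_full(snaps[i, ]), collapse = ","), con)
  } else file.create(file.path(path, "snapshots.csv"))
  invisible(path)
}

#' Read a run container written by [write_run()]
#'
#' @param path container directory.
#' @return list with `meta`, `performance`, `tests`, `snapshot_info`,
#'   `snapshots` (numeric matrix).  A container with an unknown format
#'   version is rejected.
#' @export
read_run <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$format, "somnus-run-1"))
    stop("unsupported run-container format: ", meta$format)
  rd <- function(f) {
    p <- file.path(path, f)
    if (file.exists(p) && file.size(p) > 0) read.csv(p) else NULL
  }
  lines <- readLines(file.path(path, "snapshots.csv"))
  snaps <- if (length(lines))
    do.call(rbind, lapply(strsplit(lines, ","), as.numeric)) else
    matrix(0, 0, 0)
  list(meta = meta, performance = rd("performance.csv"),
       tests = rd("tests.csv"), snapshot_info = rd("snapshot_info.csv"),
       snapshots = snaps)
}

#' Miniature fixture network and environment
#'
#' Deterministic down-scaled objects for tests and examples: a small world,
#' a network with a 3x3 visual field, a 2x2 hidden layer and the standard
#' 8-decision output layer.  Optionally plants a single-afferent receptive
#' field so analysis metrics can be verified by hand.
#'
#' @param seed integer seed.
#' @param env_side world side length.
#' @param density particle density.
#' @param vfs visual-field side (odd).
#' @param hidden_side hidden grid side.
#' @param n_afferents afferents per hidden neuron.
#' @param planted_rf optional list(`hidden`, `inputs`, `weight`) forcing
#'   hidden neuron `hidden` to draw afferents `inputs` with equal weights.
#' @return list `net`, `env`, `agent`, `cfg`.
#' @export
make_fixture <- function(seed = 1, env_side = 9, density = 0.1, vfs = 3,
                         hidden_side = 2, n_afferents = 3,
                         planted_rf = NULL) {
  cfg <- snn_config(network = list(vfs = vfs, hidden_side = hidden_side,
                                   n_afferents = n_afferents),
                    env = list(width = env_side, height = env_side,
                               density = density))
  net <- build_network(seed, cfg)
  if (!is.null(planted_rf)) {
    h <- planted_rf$hidden
    ins <- planted_rf$inputs
    pad <- setdiff(seq_len(net$n_in), ins)
    net$src[h, ] <- c(ins, pad[seq_len(ncol(net$src) - length(ins))])
    net$W_ih[h, ] <- c(rep(planted_rf$weight, length(ins)),
                       rep(0, ncol(net$src) - length(ins)))
    net$row0[h] <- sum(net$W_ih[h, ])
  }
  set.seed(child_seed(seed, "fixture-env"))
  env <- init_environment(env_side, env_side, density)
  agent <- agent_state(c((env_side + 1) %/% 2, (env_side + 1) %/% 2))
  list(net = net, env = env, agent = agent, cfg = cfg)
}
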