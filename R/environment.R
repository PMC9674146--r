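#' Particle orientations
#' @export
ORIENTATIONS <- c("horizontal", "vertical", "pos_diagonal", "neg_diagonal")

# pixel offset of a particle's second cell relative to its anchor
ori_offset <- function(ori_code) {
  switch(ori_code + 1L,
         c(0L, 1L),    # horizontal
         c(1L, 0L),    # vertical
         c(-1L, 1L),   # positive diagonal
         c(1L, 1L))    # negative diagonal
}

wrap1 <- function(x, n) ((x - 1L) %% n) + 1L

#' Build a foraging environment
#'
#' Places two-pixel food particles on a toroidal grid at a given occupied-cell
#' density.  The four orientations are represented equally (up to one
#' particle when counts do not divide evenly) and no two distinct particles
#' ever occupy adjacent cells (8-neighbourhood).
#'
#' @param width,height grid dimensions in cells.
#' @param density fraction of cells occupied by particle pixels, in (0, 0.3].
#'   `density = 0` gives an empty grid.
#' @param orientations subset of [ORIENTATIONS] to place.
#' @param seed optional integer seed.
#' @return A `particle_grid` object: list with `cells` (height x width integer
#'   matrix, 0 = empty, otherwise particle id), `ori` (orientation code per
#'   particle, 0-3), `pr`/`pc` (anchor coordinates), `width`, `height`,
#'   `density`.
#' @examples
#' env <- init_environment(50, 50, 0.10, seed = 1)
#' sum(env$cells > 0)        # 250 occupied cells = 125 two-pixel particles
#' table(env$ori)            # orientations equally represented
#' @export
init_environment <- function(width = 50, height = 50, density = 0.10,
                             orientations = ORIENTATIONS, seed = NULL) {
  if (density < 0 || density > 0.3) stop("density must lie in [0, 0.3]")
  if (length(orientations) == 0) stop("need at least one orientation")
  orientations <- match.arg(orientations, ORIENTATIONS, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  n_part <- floor(density * width * height / 2)
  codes <- match(orientations, ORIENTATIONS) - 1L
  ori <- rep(codes, length.out = n_part)
  if (n_part > 0) ori <- sample(ori)
  env <- list(cells = matrix(0L, height, width), ori = integer(0),
              pr = integer(0), pc = integer(0),
              width = as.integer(width), height = as.integer(height),
              density = density)
  class(env) <- "particle_grid"
  for (id in seq_len(n_part)) {
    env$ori <- c(env$ori, ori[id])
    env$pr <- c(env$pr, NA_integer_); env$pc <- c(env$pc, NA_integer_)
    env <- respawn_particle(env, id, max_tries = 200000)
  }
  env
}

cell_at <- function(env, r, c) env$cells[wrap1(r, env$height), wrap1(c, env$width)]

neigh_clear <- function(env, r, c, skip_id) {
  for (dr in -1:1) for (dc in -1:1) {
    v <- cell_at(env, r + dr, c + dc)
    if (v != 0 && v != skip_id) return(FALSE)
  }
  TRUE
}

placement_ok <- function(env, r, c, ori_code, skip_id) {
  off <- ori_offset(ori_code)
  cell_at(env, r, c) == 0 && cell_at(env, r + off[1], c + off[2]) == 0 &&
    neigh_clear(env, r, c, skip_id) &&
    neigh_clear(env, r + off[1], c + off[2], skip_id)
}

#' Place (or replace) a particle at a random admissible location
#'
#' @param env a `particle_grid`.
#' @param id particle id to (re)place; its cells must already be vacated.
#' @param max_tries bounded retry budget before signalling an over-dense grid.
#' @return the updated environment.
#' @export
respawn_particle <- function(env, id, max_tries = 200000) {
  oc <- env$ori[id]
  off <- ori_offset(oc)
  for (i in seq_len(max_tries)) {
    r <- sample.int(env$height, 1); c <- sample.int(env$width, 1)
    if (placement_ok(env, r, c, oc, id)) {
      env$pr[id] <- r; env$pc[id] <- c
      env$cells[r, c] <- id
      env$cells[wrap1(r + off[1], env$height), wrap1(c + off[2], env$width)] <- id
      return(env)
    }
  }
  stop("could not place particle under the adjacency constraint; ",
       "requested density too high")
}

remove_particle <- function(env, id) {
  off <- ori_offset(env$ori[id])
  env$cells[env$pr[id], env$pc[id]] <- 0L
  env$cells[wrap1(env$pr[id] + off[1], env$height),
            wrap1(env$pc[id] + off[2], env$width)] <- 0L
  env
}

#' Egocentric visual field
#'
#' Binary occupancy of the `vfs` x `vfs` window centred on the agent; the
#' grid is toroidal so the window always reads defined cells.
#'
#' @param env a `particle_grid`.
#' @param pos agent position `c(row, col)`.
#' @param vfs window side length (odd), default 7.
#' @return integer matrix of 0/1.
#' @export
get_visual_field <- function(env, pos, vfs = 7) {
  half <- (vfs - 1) / 2
  vf <- matrix(0L, vfs, vfs)
  for (a in 1:vfs) for (b in 1:vfs)
    if (cell_at(env, pos[1] + a - 1 - half, pos[2] + b - 1 - half) != 0)
      vf[a, b] <- 1L
  vf
}

#' Agent state constructor
#'
#' @param pos starting position `c(row, col)`.
#' @param last_dir direction code 0-7 (row-major over the 8 neighbours) or -1.
#' @param explore exploration probability, floor 0.01.
#' @export
agent_state <- function(pos = c(25, 25), last_dir = -1L, explore = 0.01) {
  list(r = as.integer(pos[1]), c = as.integer(pos[2]),
       last_dir = as.integer(last_dir), explore = explore)
}

DIR_OFFSETS <- rbind(c(-1,-1), c(-1,0), c(-1,1), c(0,-1),
                     c(0,1), c(1,-1), c(1,0), c(1,1))

#' Move the agent one cell and classify the outcome
#'
#' Stepping onto either pixel of a particle consumes the whole particle,
#' which immediately respawns (same orientation) at a random admissible
#' location, conserving counts per orientation.  The returned reward event
#' carries the task-dependent reward scalar: +1 for the task's rewarded
#' orientation, -0.001 for its punished orientation, -0.0001 for an empty
#' cell.  Acquisitions reset the exploration probability to its floor;
#' non-acquiring moves increase it by 1%.
#'
#' @param env a `particle_grid`.
#' @param agent an [agent_state()].
#' @param direction 0-7 direction code, or "stay".
#' @param task 1 (horizontal rewarded / neg-diagonal punished),
#'   2 (vertical rewarded / pos-diagonal punished) or NULL (no task:
#'   acquisitions are classified `other`).
#' @param cfg a [snn_config()] (exploration constants).
#' @return list `env`, `agent`, `event` where `event` has `kind`
#'   (`"rewarded"`, `"punished"`, `"empty"`, `"other"`) and `s_rp`.
#' @export
move_agent <- function(env, agent, direction, task = NULL, cfg = snn_config()) {
  if (!identical(direction, "stay")) {
    d <- DIR_OFFSETS[direction + 1L, ]
    agent$r <- wrap1(agent$r + d[1], env$height)
    agent$c <- wrap1(agent$c + d[2], env$width)
    agent$last_dir <- as.integer(direction)
  }
  id <- env$cells[agent$r, agent$c]
  if (id > 0) {
    oc <- env$ori[id]
    env <- remove_particle(env, id)
    env <- respawn_particle(env, id)
    kind <- "other"
    if (!is.null(task)) {
      if (oc == c(0L, 1L)[task]) kind <- "rewarded"
      if (oc == c(3L, 2L)[task]) kind <- "punished"
    }
    agent$explore <- cfg$policy$explore_base
  } else {
    kind <- "empty"
    agent$explore <- min(1, agent$explore + cfg$policy$explore_step)
  }
  s_rp <- switch(kind, rewarded = cfg$rewards$rewarded,
                 punished = cfg$rewards$punished,
                 empty = cfg$rewards$empty, other = 0)
  list(env = env, agent = agent, event = list(kind = kind, s_rp = s_rp))
}

#' Random-policy foraging baseline
#'
#' Moves uniformly at random for `n_moves` epochs' worth of moves in a
#' task environment and tallies consumed particles.  With both task
#' orientations at equal density the expected discriminability is the 0.5
#' chance level.
#'
#' @param n_moves number of moves.
#' @param task task id (controls the rewarded/punished labelling).
#' @param seed integer seed.
#' @param cfg configuration (environment dimensions and density).
#' @return list with counts `rewarded`, `punished`, `empty` and
#'   `discriminability`.
#' @export
random_forage <- function(n_moves, task = 1, seed = 1, cfg = snn_config()) {
  set.seed(seed)
  oris <- if (task == 1) c("horizontal", "neg_diagonal")
          else c("vertical", "pos_diagonal")
  env <- init_environment(cfg$env$width, cfg$env$height, cfg$env$density, oris)
  agent <- agent_state(c(sample.int(cfg$env$height, 1), sample.int(cfg$env$width, 1)))
  counts <- c(rewarded = 0, punished = 0, empty = 0, other = 0)
  dirs <- sample.int(8, n_moves, replace = TRUE) - 1L
  for (i in seq_len(n_moves)) {
    st <- move_agent(env, agent, dirs[i], task = task, cfg = cfg)
    env <- st$env; agent <- st$agent
    counts[st$event$kind] <- counts[st$event$kind] + 1
  }
  list(rewarded = counts[["rewarded"]], punished = counts[["punished"]],
       empty = counts[["empty"]],
       discriminability = counts[["rewarded"]] /
         (counts[["rewarded"]] + counts[["punished"]]))
}

#' Export an environment snapshot as a data frame
#'
#' One row per particle pixel with the particle id and orientation label;
#' suitable for CSV export.
#' @param env a `particle_grid`.
#' @export
environment_table <- function(env) {
  rows <- which(env$cells != 0, arr.ind = TRUE)
  id <- env$cells[rows]
  data.frame(row = rows[, 1], col = rows[, 2], particle = id,
             orientation = ORIENTATIONS[env$ori[id] + 1])
}
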