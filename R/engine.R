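# ---------------------------------------------------------------------------
# Deterministic, seedable simulator of the monkey-adapted Pac-Man task.
#
# One engine step = one tile traversal = 0.417 s of game clock; actions are
# per-tile joystick decisions.  Ghost randomness (scared-mode moves) flows
# through a small internal generator stored in the game state, so that a
# recorded episode can be replayed exactly from its initial state and action
# sequence without touching R's global RNG.
# ---------------------------------------------------------------------------

#' Reward table of the task
#'
#' Juice-drop values of the game elements and the completion-bonus schedule.
#' Pellets are worth 2 drops, energizers 4, ghosts 8; the five fruit kinds
#' yield 3, 5, 8, 12, and 17 drops.  Clearing the maze pays a bonus that
#' decreases with the number of rounds (attempts) used: 20 drops within
#' rounds 1-3, 10 within rounds 4-5, and 5 beyond round 5.  The scared mode
#' triggered by an energizer lasts 14 s, with a 2 s warning flash at the end.
#'
#' @param pellet,energizer,ghost Drops for the respective consumption.
#' @param fruit Named vector of drops per fruit kind.
#' @param completion_bonus Drops for clearing the maze, as a length-3 vector
#'   for round brackets 1-3, 4-5, and >5.
#' @param scared_duration Scared-mode duration in seconds.
#' @param flash_duration Warning-flash portion at the end of the scared mode,
#'   in seconds.
#' @param death_timeout_seconds Time-out penalty after a death (bookkeeping
#'   only; it does not advance the step counter).
#' @return An object of class `reward_table`.
#' @export
reward_table <- function(pellet = 2, energizer = 4, ghost = 8,
                         fruit = c(cherry = 3, strawberry = 5, orange = 8,
                                   apple = 12, melon = 17),
                         completion_bonus = c(20, 10, 5),
                         scared_duration = 14,
                         flash_duration = 2,
                         death_timeout_seconds = 5) {
  stopifnot(pellet >= 0, energizer >= 0, ghost >= 0, all(fruit >= 0),
            length(completion_bonus) == 3L, !is.unsorted(rev(completion_bonus)))
  structure(list(pellet = pellet, energizer = energizer, ghost = ghost,
                 fruit = fruit, completion_bonus = completion_bonus,
                 scared_duration = scared_duration,
                 flash_duration = flash_duration,
                 death_timeout_seconds = death_timeout_seconds),
            class = "reward_table")
}

# bonus drops for finishing in round r
.completion_bonus <- function(rt, round_index) {
  if (round_index <= 3) rt$completion_bonus[1L]
  else if (round_index <= 5) rt$completion_bonus[2L]
  else rt$completion_bonus[3L]
}

#' Engine configuration
#'
#' Run-level knobs of the simulator that are not juice values.
#'
#' @param n_pellets Number of pellets placed at game start (the task uses 88
#'   or 73 depending on configuration).
#' @param n_energizers Number of energizers placed at game start (3 or 4).
#' @param scared_rule How scared ghosts move: `"random"` (uniform among
#'   non-reversing legal moves, at half speed) or `"homeward"` (half-speed
#'   greedy retreat toward the ghost home).
#' @param ghost_contact `"standard"` applies the usual contact rules;
#'   `"none"` disables deaths and ghost meals.
#' @param ghost_policy `"chase"` is the standard behavior (Blinky pursues,
#'   Clyde pursues beyond eight tiles); `"wander"` replaces the normal-mode
#'   chase with a full-speed random non-reversing walk.  The combination
#'   `ghost_contact = "none", ghost_policy = "wander"` is the
#'   parameter-recovery condition: deaths cannot cut the ground-truth weight
#'   schedule, and no ghost trails Pac-Man (a pursuer one tile behind makes
#'   the evade utilities collinear with any forward movement, destroying
#'   weight identifiability).
#' @param place_fruit Whether a fruit is placed at game start.
#' @param step_seconds Game-clock duration of one engine step (one tile).
#' @return An object of class `game_config`.
#' @export
game_config <- function(n_pellets = 88L, n_energizers = 4L,
                        scared_rule = c("random", "homeward"),
                        ghost_contact = c("standard", "none"),
                        ghost_policy = c("chase", "wander"),
                        place_fruit = TRUE,
                        step_seconds = 0.417) {
  structure(list(n_pellets = as.integer(n_pellets),
                 n_energizers = as.integer(n_energizers),
                 scared_rule = match.arg(scared_rule),
                 ghost_contact = match.arg(ghost_contact),
                 ghost_policy = match.arg(ghost_policy),
                 place_fruit = isTRUE(place_fruit),
                 step_seconds = step_seconds),
            class = "game_config")
}

# --- internal minimal generator (Park-Miller) for in-state ghost randomness --
.rng_next <- function(x) (16807 * x) %% 2147483647
.rng_unif <- function(x) x / 2147483647

.new_ghost <- function(name, pos, facing) {
  list(name = name, pos = pos, facing = facing,
       mode = "normal", scared_timer = 0)
}

#' Start a new game
#'
#' Places pellets and energizers uniformly at random over the walkable tiles
#' of three randomly chosen maze quadrants (one quadrant stays empty), drops
#' one random fruit, and puts Pac-Man and the ghosts at their start tiles.
#'
#' @param maze A `maze_graph` with named start tiles.
#' @param rt A [reward_table()].
#' @param config A [game_config()].
#' @param seed Optional integer seed (`set.seed` is called when non-`NULL`);
#'   with `NULL` the current RNG stream is used.
#' @return An object of class `game_state`.
#' @export
new_game <- function(maze, rt = reward_table(), config = game_config(),
                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.na(maze$start_pacman) || is.na(maze$start_blinky) || is.na(maze$start_clyde)) {
    stop("maze lacks named start tiles (P, B, C)")
  }
  ids <- which(maze$walkable)
  excl <- c(maze$home, maze$tunnel_tiles, maze$start_pacman)
  cand <- setdiff(ids, excl)
  pos <- tile_pos(maze, cand)
  quadrant <- 1L + (pos$col >= maze$ncol %/% 2L) + 2L * (pos$row >= maze$nrow %/% 2L)
  empty_q <- sample.int(4L, 1L)
  pool <- cand[quadrant != empty_q]
  n_items <- config$n_pellets + config$n_energizers
  if (length(pool) < n_items) {
    stop("not enough walkable tiles in three quadrants for ", n_items, " items")
  }
  placed <- sample(pool, n_items)
  pellets <- sort(placed[seq_len(config$n_pellets)])
  energizers <- sort(placed[config$n_pellets + seq_len(config$n_energizers)])

  fruit <- NULL
  if (config$place_fruit) {
    slots <- if (length(maze$fruit_slots) > 0L) maze$fruit_slots else setdiff(cand, placed)
    fruit <- list(pos = slots[sample.int(length(slots), 1L)],
                  kind = names(rt$fruit)[sample.int(length(rt$fruit), 1L)])
  }

  first_dir <- function(p) .priority_order(available_directions(maze, p))[1L]
  structure(list(
    pacman = maze$start_pacman,
    pacman_facing = first_dir(maze$start_pacman),
    ghosts = list(
      blinky = .new_ghost("blinky", maze$start_blinky, first_dir(maze$start_blinky)),
      clyde = .new_ghost("clyde", maze$start_clyde, first_dir(maze$start_clyde))
    ),
    pellets = pellets,
    energizers = energizers,
    fruit = fruit,
    time_step = 0L,
    round_index = 1L,
    clock_seconds = 0,
    initial_pellets = length(pellets),
    cleared = FALSE,
    rng = (floor(stats::runif(1) * 2147483645) + 1)
  ), class = "game_state")
}

#' @export
print.game_state <- function(x, ...) {
  cat(sprintf("<game_state> t=%d round=%d pellets=%d energizers=%d pacman=%d (%s)\n",
              x$time_step, x$round_index, length(x$pellets), length(x$energizers),
              x$pacman, x$pacman_facing))
  invisible(x)
}

# candidate ghost moves: available, no immediate reversal unless forced
.ghost_candidates <- function(maze, pos, facing) {
  dirs <- available_directions(maze, pos)
  keep <- setdiff(dirs, opposite_direction(facing))
  if (length(keep) == 0L) dirs else keep
}

# greedy non-reversing step minimizing shortest-path distance to `target`;
# ties broken by the fixed priority up > left > down > right
.greedy_step <- function(maze, pos, facing, target) {
  cand <- .ghost_candidates(maze, pos, facing)
  dt <- .dist_to(maze, target)
  vals <- -dt[maze$neighbors[pos, cand]]
  names(vals) <- cand
  if (!any(is.finite(vals))) return(.priority_order(cand)[1L])  # unreachable target
  .argmax_direction(vals)
}

#' Ghost chase policies
#'
#' `blinky_policy()` always chases Pac-Man: among legal non-reversing moves
#' it takes the one minimizing the shortest-path distance of the next tile to
#' Pac-Man.  `clyde_policy()` does the same while Clyde is more than eight
#' tiles from Pac-Man; at eight tiles or closer it retreats toward the
#' lower-left corner of the maze.  Ties are broken by the fixed priority
#' up > left > down > right.
#'
#' @param maze A `maze_graph`.
#' @param state A `game_state` (the ghost must be in normal mode).
#' @return A direction name.
#' @export
blinky_policy <- function(maze, state) {
  g <- state$ghosts$blinky
  .greedy_step(maze, g$pos, g$facing, state$pacman)
}

#' @rdname blinky_policy
#' @export
clyde_policy <- function(maze, state) {
  g <- state$ghosts$clyde
  target <- if (maze_distance(maze, g$pos, state$pacman) > 8) {
    state$pacman
  } else {
    maze$corner_lower_left
  }
  .greedy_step(maze, g$pos, g$facing, target)
}

# direction for a scared ghost under the configured rule; returns the
# direction plus the advanced rng state
.scared_move <- function(maze, ghost, rng, rule) {
  cand <- .ghost_candidates(maze, ghost$pos, ghost$facing)
  if (rule == "homeward") {
    home_target <- maze$home[1L]
    return(list(dir = .greedy_step(maze, ghost$pos, ghost$facing, home_target), rng = rng))
  }
  rng <- .rng_next(rng)
  k <- 1L + floor(.rng_unif(rng) * length(cand))
  list(dir = cand[[min(k, length(cand))]], rng = rng)
}

.reward_event <- function(kind, drops, time_step, pos = NA_integer_) {
  data.frame(kind = kind, drops = drops, time_step = time_step, pos = pos,
             stringsAsFactors = FALSE)
}

#' Advance the game by one step
#'
#' Executes one joystick decision: Pac-Man advances one tile in direction `a`
#' if available (otherwise continues along its facing if possible, else
#' stalls), consumes any item on the entered tile, the ghosts move under
#' their mode policies, contacts are resolved (a normal ghost kills and
#' resets the round; a scared ghost is eaten), timers advance, and the
#' completion bonus is paid when the last pellet and energizer are gone.
#' Pass-through contact (Pac-Man and a ghost swapping tiles) counts.
#' Scared ghosts and ghosts inside a tunnel advance only on alternate steps.
#'
#' @param maze A `maze_graph`.
#' @param state A `game_state`.
#' @param a The chosen direction.
#' @param rt A [reward_table()].
#' @param config A [game_config()].
#' @return A list with elements `state` (the successor `game_state`) and
#'   `events` (a data frame of reward events: `kind`, `drops`, `time_step`).
#' @export
step_game <- function(maze, state, a, rt = reward_table(), config = game_config()) {
  if (!a %in% DIRECTIONS) stop("action must be one of ", paste(DIRECTIONS, collapse = ", "))
  s <- state
  t <- s$time_step
  events <- .reward_event(character(0), numeric(0), integer(0), integer(0))
  emit <- function(kind, drops, pos = NA_integer_) {
    events <<- rbind(events, .reward_event(kind, drops, t, pos))
  }

  # --- Pac-Man moves -------------------------------------------------------
  pac_old <- s$pacman
  avail <- available_directions(maze, pac_old)
  move_dir <- if (a %in% avail) a else if (s$pacman_facing %in% avail) s$pacman_facing else NA
  if (!is.na(move_dir)) {
    s$pacman <- maze$neighbors[[pac_old, move_dir]]
    s$pacman_facing <- move_dir
  }

  # --- consumption ---------------------------------------------------------
  if (s$pacman %in% s$pellets) {
    s$pellets <- setdiff(s$pellets, s$pacman)
    emit("pellet", rt$pellet, s$pacman)
  }
  just_scared <- character(0)
  if (s$pacman %in% s$energizers) {
    s$energizers <- setdiff(s$energizers, s$pacman)
    emit("energizer", rt$energizer, s$pacman)
    for (gn in names(s$ghosts)) {
      if (s$ghosts[[gn]]$mode != "dead") {
        s$ghosts[[gn]]$mode <- "scared"
        s$ghosts[[gn]]$scared_timer <- rt$scared_duration
        just_scared <- c(just_scared, gn)
      }
    }
  }
  if (!is.null(s$fruit) && s$pacman == s$fruit$pos) {
    emit("fruit", rt$fruit[[s$fruit$kind]], s$pacman)
    s["fruit"] <- list(NULL)            # keep the slot, drop the fruit
  }

  died <- FALSE
  contact_rules <- config$ghost_contact == "standard"

  resolve_contact <- function(gn) {
    g <- s$ghosts[[gn]]
    if (g$mode %in% c("scared", "flash")) {
      emit("ghost", rt$ghost, g$pos)
      s$ghosts[[gn]]$mode <<- "dead"
      s$ghosts[[gn]]$scared_timer <<- 0
    } else if (g$mode == "normal") {
      died <<- TRUE
    }
  }

  # contact from Pac-Man's own move, before the ghosts respond
  if (contact_rules) {
    for (gn in names(s$ghosts)) {
      if (s$ghosts[[gn]]$pos == s$pacman) resolve_contact(gn)
    }
  }

  # --- maze cleared?  ghosts are skipped once the game is over -------------
  if (!died && !s$cleared && length(s$pellets) == 0L && length(s$energizers) == 0L) {
    emit("completion_bonus", .completion_bonus(rt, s$round_index))
    s$cleared <- TRUE
  }

  # --- ghosts move ---------------------------------------------------------
  if (!died && !s$cleared) {
    for (gn in names(s$ghosts)) {
      g <- s$ghosts[[gn]]
      slowed <- g$mode %in% c("scared", "flash") || g$pos %in% maze$tunnel_tiles
      advances <- !slowed || (t %% 2L == 0L)
      if (!advances) next
      if (g$mode == "dead") {
        home_target <- if (gn == "blinky") maze$start_blinky else maze$start_clyde
        if (g$pos == home_target) {           # reached the pen: respawn
          s$ghosts[[gn]]$mode <- "normal"
          g <- s$ghosts[[gn]]
          dir <- .greedy_step(maze, g$pos, g$facing, s$pacman)
        } else {
          dir <- .greedy_step(maze, g$pos, g$facing, home_target)
        }
      } else if (g$mode %in% c("scared", "flash")) {
        sm <- .scared_move(maze, g, s$rng, config$scared_rule)
        s$rng <- sm$rng
        dir <- sm$dir
      } else if (config$ghost_policy == "wander") {
        sm <- .scared_move(maze, g, s$rng, "random")
        s$rng <- sm$rng
        dir <- sm$dir
      } else {
        dir <- if (gn == "blinky") blinky_policy(maze, s) else clyde_policy(maze, s)
      }
      old_pos <- g$pos
      new_pos <- maze$neighbors[[old_pos, dir]]
      s$ghosts[[gn]]$pos <- new_pos
      s$ghosts[[gn]]$facing <- dir
      if (contact_rules && s$ghosts[[gn]]$mode != "dead") {
        swapped <- new_pos == pac_old && s$pacman == old_pos
        if (new_pos == s$pacman || swapped) resolve_contact(gn)
      }
      if (died) break
    }
  }

  # --- death: reset to starts, pellets unchanged ---------------------------
  if (died) {
    emit("death", 0, s$pacman)
    s$pacman <- maze$start_pacman
    s$pacman_facing <- .priority_order(available_directions(maze, s$pacman))[1L]
    s$ghosts$blinky <- .new_ghost("blinky", maze$start_blinky,
                                  .priority_order(available_directions(maze, maze$start_blinky))[1L])
    s$ghosts$clyde <- .new_ghost("clyde", maze$start_clyde,
                                 .priority_order(available_directions(maze, maze$start_clyde))[1L])
    s$round_index <- s$round_index + 1L
  }

  # --- timers (a timer set this very step starts counting next step) -------
  for (gn in setdiff(names(s$ghosts), just_scared)) {
    g <- s$ghosts[[gn]]
    if (g$mode %in% c("scared", "flash")) {
      timer <- g$scared_timer - config$step_seconds
      if (timer <= 0) {
        s$ghosts[[gn]]$mode <- "normal"
        s$ghosts[[gn]]$scared_timer <- 0
      } else {
        s$ghosts[[gn]]$scared_timer <- timer
        s$ghosts[[gn]]$mode <- if (timer <= rt$flash_duration) "flash" else "scared"
      }
    }
  }

  s$time_step <- t + 1L
  s$clock_seconds <- s$clock_seconds + config$step_seconds +
    if (died) rt$death_timeout_seconds else 0
  list(state = s, events = events)
}

#' Simulate a full episode
#'
#' Runs [new_game()] and a [step_game()] loop under a policy until the maze
#' is cleared or `max_steps` is reached, recording a behavior log.
#'
#' @param maze A `maze_graph`.
#' @param agent A policy: `function(state, maze)` returning a direction.
#' @param rt A [reward_table()].
#' @param config A [game_config()].
#' @param seed Integer seed controlling placement, agent sampling (through
#'   R's RNG), and ghost randomness; `NULL` uses the current RNG stream.
#' @param max_steps Step budget.
#' @return An object of class `behavior_log`: a list with `records` (one
#'   entry per step, each holding the `state` before the action, the chosen
#'   `action`, and the step's reward `events`), the `final_state`, and
#'   `meta` (maze id, seed, agent description, configuration).
#' @export
simulate_episode <- function(maze, agent, rt = reward_table(),
                             config = game_config(), seed = NULL,
                             max_steps = 500L) {
  if (!is.null(seed)) set.seed(seed)
  state <- new_game(maze, rt, config)
  records <- vector("list", max_steps)
  n <- 0L
  while (n < max_steps && !state$cleared) {
    a <- agent(state, maze)
    if (!(is.character(a) && length(a) == 1L && a %in% DIRECTIONS)) {
      stop("agent returned a non-direction: ", deparse(a))
    }
    res <- step_game(maze, state, a, rt, config)
    n <- n + 1L
    records[[n]] <- list(state = state, action = a, events = res$events)
    state <- res$state
  }
  structure(list(
    records = records[seq_len(n)],
    final_state = state,
    meta = list(maze_id = maze$id, seed = seed,
                agent = attr(agent, "label") %||% "custom",
                config = config, reward_table = rt, n_steps = n)
  ), class = "behavior_log")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.behavior_log <- function(x, ...) {
  drops <- sum(vapply(x$records, function(r) sum(r$events$drops), numeric(1)))
  cat(sprintf("<behavior_log> %d steps, %d round(s), %.0f drops, agent '%s', maze '%s'\n",
              length(x$records), x$final_state$round_index, drops,
              x$meta$agent, x$meta$maze_id))
  invisible(x)
}

#' Accessors for behavior logs
#'
#' Small helpers extracting aligned per-step vectors from a `behavior_log`.
#'
#' @param log A `behavior_log`.
#' @return `log_actions()`: character vector of chosen directions;
#'   `log_rounds()`: integer vector of round indices; `log_events()`: one
#'   data frame of all reward events.
#' @export
log_actions <- function(log) {
  vapply(log$records, function(r) r$action, character(1))
}

#' @rdname log_actions
#' @export
log_rounds <- function(log) {
  vapply(log$records, function(r) r$state$round_index, integer(1))
}

#' @rdname log_actions
#' @export
log_events <- function(log) {
  do.call(rbind, c(lapply(log$records, function(r) r$events),
                   list(make.row.names = FALSE)))
}

#' Total juice drops of a log
#'
#' @param log A `behavior_log`.
#' @return Cumulative drops over all reward events.
#' @export
total_drops <- function(log) {
  sum(log_events(log)$drops)
}
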