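# Independent oracles and fixture builders shared across the suite.
# These deliberately avoid the package's own graph machinery: the BFS oracle
# walks the neighbor table with a hand-rolled queue, and the path enumerator
# is a plain recursive walker.

# breadth-first-search distance oracle (tunnels included via the neighbor table)
bfs_dist <- function(maze, a, b) {
  if (a == b) return(0)
  dist <- rep(Inf, maze$n)
  dist[a] <- 0
  queue <- a
  while (length(queue) > 0L) {
    v <- queue[1L]
    queue <- queue[-1L]
    for (d in DIRECTIONS) {
      nb <- maze$neighbors[v, d]
      if (!is.na(nb) && dist[nb] > dist[v] + 1) {
        dist[nb] <- dist[v] + 1
        if (nb == b) return(dist[nb])
        queue <- c(queue, nb)
      }
    }
  }
  dist[b]
}

# brute-force enumerator of non-reversing walks of `depth` steps from p,
# keeping dead-end truncations, as a list of integer vectors per direction
brute_paths <- function(maze, p, depth) {
  res <- list()
  recurse <- function(pos, lastdir, acc) {
    if (length(acc) == depth) return(list(acc))
    dirs <- DIRECTIONS[!is.na(maze$neighbors[pos, ])]
    dirs <- dirs[dirs != opposite_direction(lastdir)]
    if (length(dirs) == 0L) return(list(acc))
    unlist(lapply(dirs, function(d) {
      recurse(maze$neighbors[[pos, d]], d, c(acc, maze$neighbors[[pos, d]]))
    }), recursive = FALSE)
  }
  for (d in DIRECTIONS[!is.na(maze$neighbors[p, ])]) {
    first <- maze$neighbors[[p, d]]
    res[[d]] <- recurse(first, d, first)
  }
  res
}

# random connected maze via depth-first carving on an odd-sized grid
random_maze <- function(seed, ncell_c = 5L, ncell_r = 5L) {
  set.seed(seed)
  nc <- 2L * ncell_c + 1L
  nr <- 2L * ncell_r + 1L
  wall <- matrix(TRUE, nr, nc)
  cell <- function(i, j) c(2L * i, 2L * j)        # 1-based grid row/col
  visited <- matrix(FALSE, ncell_r, ncell_c)
  stack <- list(c(1L, 1L))
  visited[1L, 1L] <- TRUE
  wall[2L, 2L] <- FALSE
  while (length(stack) > 0L) {
    cur <- stack[[length(stack)]]
    nbrs <- list(c(cur[1L] - 1L, cur[2L]), c(cur[1L] + 1L, cur[2L]),
                 c(cur[1L], cur[2L] - 1L), c(cur[1L], cur[2L] + 1L))
    nbrs <- Filter(function(x) {
      x[1L] >= 1L && x[1L] <= ncell_r && x[2L] >= 1L && x[2L] <= ncell_c &&
        !visited[x[1L], x[2L]]
    }, nbrs)
    if (length(nbrs) == 0L) {
      stack[[length(stack)]] <- NULL
      next
    }
    nxt <- nbrs[[sample.int(length(nbrs), 1L)]]
    a <- cell(cur[1L], cur[2L]); b <- cell(nxt[1L], nxt[2L])
    wall[b[1L], b[2L]] <- FALSE
    wall[(a[1L] + b[1L]) %/% 2L, (a[2L] + b[2L]) %/% 2L] <- FALSE
    visited[nxt[1L], nxt[2L]] <- TRUE
    stack[[length(stack) + 1L]] <- nxt
  }
  # knock out some extra walls to create loops and junctions
  interior <- which(wall[2:(nr - 1L), 2:(nc - 1L)], arr.ind = TRUE)
  if (nrow(interior) > 0L) {
    drop <- interior[sample.int(nrow(interior), min(8L, nrow(interior))), , drop = FALSE]
    wall[cbind(drop[, 1L] + 1L, drop[, 2L] + 1L)] <- FALSE
  }
  txt <- apply(wall, 1L, function(row) paste(ifelse(row, "#", " "), collapse = ""))
  # isolated pockets can appear after wall knockout; the loader warns
  suppressWarnings(load_maze(txt))
}

# a bordered straight corridor of n walkable tiles, with optional extras
corridor_maze <- function(n, extra = NULL) {
  mid <- paste(rep(" ", n), collapse = "")
  if (!is.null(extra)) mid <- extra
  load_maze(c(strrep("#", n + 2L),
              paste0("#", mid, "#"),
              strrep("#", n + 2L)))
}

# a corridor maze with a sealed two-tile pocket housing the ghosts, so that
# games can run ghost-free; the loader's unreachable-tile warning is expected
pocket_corridor_maze <- function(n = 9L) {
  top <- strrep("#", n + 2L)
  suppressWarnings(load_maze(c(
    top,
    paste0("#P", strrep(" ", n - 1L), "#"),
    top,
    paste0("#BC", strrep("#", n - 1L)),
    top
  )))
}

# open 4x4 room (every interior tile walkable)
open_room_maze <- function(k = 4L) {
  load_maze(c(strrep("#", k + 2L),
              rep(paste0("#", strrep(" ", k), "#"), k),
              strrep("#", k + 2L)))
}

# hand-assembled game state on a maze, bypassing new_game
make_state <- function(maze, pacman = NULL, pellets = integer(0),
                       energizers = integer(0), fruit = NULL,
                       blinky = NULL, clyde = NULL,
                       blinky_mode = "normal", clyde_mode = "normal",
                       blinky_timer = 0, clyde_timer = 0,
                       round_index = 1L, time_step = 0L, rng = 1) {
  pac <- pacman %||% maze$start_pacman
  first_dir <- function(p) available_directions(maze, p)[1L]
  mk_ghost <- function(name, pos, mode, timer) {
    list(name = name, pos = pos, facing = first_dir(pos), mode = mode,
         scared_timer = timer)
  }
  bpos <- blinky %||% (if (!is.na(maze$start_blinky)) maze$start_blinky else which(maze$walkable)[1L])
  cpos <- clyde %||% (if (!is.na(maze$start_clyde)) maze$start_clyde else which(maze$walkable)[1L])
  structure(list(
    pacman = pac, pacman_facing = first_dir(pac),
    ghosts = list(blinky = mk_ghost("blinky", bpos, blinky_mode, blinky_timer),
                  clyde = mk_ghost("clyde", cpos, clyde_mode, clyde_timer)),
    pellets = sort(unique(pellets)), energizers = sort(unique(energizers)),
    fruit = fruit, time_step = as.integer(time_step),
    round_index = as.integer(round_index), clock_seconds = 0,
    initial_pellets = max(length(pellets), 1L), cleared = FALSE, rng = rng
  ), class = "game_state")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# synthetic utility tensor drawn directly from the model family: random
# normalized utilities, all directions available, actions sampled from the
# softmax with known weights; used to test the MLE machinery in isolation
synthetic_tensor <- function(n, w, beta = 1, seed = 1, rounds = rep(1L, n)) {
  set.seed(seed)
  raw <- array(stats::runif(n * 6 * 4), dim = c(n, 6, 4),
               dimnames = list(NULL, STRATEGIES, DIRECTIONS))
  actions <- character(n)
  for (t in seq_len(n)) {
    Q <- as.vector((beta * w) %*% raw[t, , ])
    p <- exp(Q - max(Q)); p <- p / sum(p)
    actions[t] <- DIRECTIONS[sample.int(4L, 1L, prob = p)]
  }
  structure(list(
    raw = raw, norm = raw,
    available = matrix(TRUE, n, 4L, dimnames = list(NULL, DIRECTIONS)),
    rounds = rounds, actions = actions,
    params = utility_params(), n_steps = n
  ), class = "utility_tensor")
}

# minimal behavior-log shell wrapping an action/round sequence (for window
# logic that only needs actions, rounds, and consumption events)
stub_log <- function(actions, rounds = rep(1L, length(actions)),
                     consume_at = integer(0), consume_kind = "energizer") {
  records <- lapply(seq_along(actions), function(t) {
    ev <- if (t %in% consume_at) {
      data.frame(kind = consume_kind, drops = 4, time_step = t - 1L, pos = NA_integer_)
    } else {
      data.frame(kind = character(0), drops = numeric(0),
                 time_step = integer(0), pos = integer(0))
    }
    list(state = structure(list(round_index = rounds[t], time_step = t - 1L),
                           class = "game_state"),
         action = actions[t], events = ev)
  })
  structure(list(records = records, final_state = NULL,
                 meta = list(maze_id = "stub", seed = NULL, agent = "stub",
                             config = game_config(), reward_table = reward_table(),
                             n_steps = length(actions))),
            class = "behavior_log")
}

# bind two steps x 6 x 4 arrays along the step dimension
abind_rows <- function(a, b) {
  out <- array(NA_real_, dim = c(dim(a)[1L] + dim(b)[1L], dim(a)[2L], dim(a)[3L]),
               dimnames = c(list(NULL), dimnames(a)[-1L]))
  out[seq_len(dim(a)[1L]), , ] <- a
  out[dim(a)[1L] + seq_len(dim(b)[1L]), , ] <- b
  out
}
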