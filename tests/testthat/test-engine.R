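# Game engine: rewards, modes, ghost policies, resets, determinism.

rt <- reward_table()

test_that("consumption emits the printed juice values", {
  m <- pocket_corridor_maze(9L)
  p <- m$start_pacman
  right1 <- m$neighbors[[p, "right"]]
  right2 <- m$neighbors[[right1, "right"]]

  far_pellet <- tile_id(m, 9L, 1L)
  st <- make_state(m, pellets = c(right1, far_pellet))
  res <- step_game(m, st, "right", rt)
  expect_equal(res$events$kind, "pellet")
  expect_equal(res$events$drops, 2)
  expect_equal(res$state$pacman, right1)
  expect_equal(res$state$pellets, far_pellet)

  st <- make_state(m, pellets = right2, energizers = right1)
  res <- step_game(m, st, "right", rt)
  expect_equal(res$events$kind, "energizer")
  expect_equal(res$events$drops, 4)
  for (g in res$state$ghosts) {
    expect_equal(g$mode, "scared")
    expect_equal(g$scared_timer, 14)
  }

  st <- make_state(m, pellets = far_pellet,
                   fruit = list(pos = right1, kind = "melon"))
  res <- step_game(m, st, "right", rt)
  expect_equal(res$events$kind, "fruit")
  expect_equal(res$events$drops, 17)
  expect_null(res$state$fruit)
})

test_that("completion bonus follows the round schedule", {
  m <- pocket_corridor_maze(9L)
  right1 <- m$neighbors[[m$start_pacman, "right"]]
  for (cfg in list(c(round = 1L, drops = 20), c(round = 3L, drops = 20),
                   c(round = 4L, drops = 10), c(round = 6L, drops = 5))) {
    st <- make_state(m, pellets = right1, round_index = cfg[["round"]])
    res <- step_game(m, st, "right", rt)
    expect_setequal(res$events$kind, c("pellet", "completion_bonus"))
    expect_equal(res$events$drops[res$events$kind == "completion_bonus"],
                 cfg[["drops"]])
    expect_true(res$state$cleared)
  }
})

test_that("eating a scared ghost and dying on a normal one behave per the rules", {
  m <- default_maze()
  p <- m$start_pacman
  right1 <- m$neighbors[[p, "right"]]
  # scared ghost on the entered tile: eaten for 8 drops, goes dead
  st <- make_state(m, blinky = right1, blinky_mode = "scared", blinky_timer = 10)
  res <- step_game(m, st, "right", rt)
  expect_true("ghost" %in% res$events$kind)
  expect_equal(res$events$drops[res$events$kind == "ghost"], 8)
  expect_equal(res$state$ghosts$blinky$mode, "dead")
  expect_equal(res$state$round_index, 1L)
  # normal ghost on the entered tile: death, reset, pellets unchanged
  far <- setdiff(which(m$walkable), c(p, right1, m$home))[1:5]
  st <- make_state(m, pellets = far, blinky = right1)
  res <- step_game(m, st, "right", rt)
  expect_true("death" %in% res$events$kind)
  expect_equal(res$events$drops[res$events$kind == "death"], 0)
  expect_equal(res$state$round_index, 2L)
  expect_equal(res$state$pacman, m$start_pacman)
  expect_equal(res$state$ghosts$blinky$pos, m$start_blinky)
  expect_equal(res$state$ghosts$clyde$pos, m$start_clyde)
  expect_equal(res$state$pellets, sort(far))
})

test_that("scared timers count down, flash at 2 s, and expire", {
  m <- default_maze()
  step_s <- game_config()$step_seconds
  st <- make_state(m, blinky_mode = "scared", blinky_timer = 2.3,
                   clyde_mode = "scared", clyde_timer = 0.3)
  res <- step_game(m, st, available_directions(m, st$pacman)[1L], rt)
  expect_equal(res$state$ghosts$blinky$scared_timer, 2.3 - step_s)
  expect_equal(res$state$ghosts$blinky$mode, "flash")   # <= 2 s left
  expect_equal(res$state$ghosts$clyde$mode, "normal")   # timer crossed 0
  expect_equal(res$state$ghosts$clyde$scared_timer, 0)
})

test_that("scared ghosts advance on alternate steps (half speed)", {
  m <- corridor_maze(30L)
  # drive a lone scared ghost down a corridor; no starts needed for step logic
  st <- make_state(m, pacman = tile_id(m, 1L, 1L),
                   pellets = tile_id(m, 30L, 1L),
                   blinky = tile_id(m, 15L, 1L), blinky_mode = "scared",
                   blinky_timer = 14,
                   clyde = tile_id(m, 28L, 1L), clyde_mode = "scared",
                   clyde_timer = 14)
  start_pos <- st$ghosts$blinky$pos
  moved <- 0L
  for (i in 1:10) {
    res <- step_game(m, st, "left", rt)
    if (res$state$ghosts$blinky$pos != st$ghosts$blinky$pos) moved <- moved + 1L
    st <- res$state
  }
  expect_equal(moved, 5L)
})

test_that("ghost chase policies descend the true shortest-path distance", {
  m <- default_maze()
  st <- make_state(m)
  # exhaustive next-tile oracle for Blinky
  g <- st$ghosts$blinky
  cand <- setdiff(available_directions(m, g$pos), opposite_direction(g$facing))
  if (length(cand) == 0L) cand <- available_directions(m, g$pos)
  dists <- vapply(cand, function(d) {
    maze_distance(m, m$neighbors[[g$pos, d]], st$pacman)
  }, numeric(1))
  expect_equal(maze_distance(m, m$neighbors[[g$pos, blinky_policy(m, st)]], st$pacman),
               min(dists))
  # Clyde: beyond 8 tiles chases Pac-Man, within 8 heads to the lower-left corner
  ids <- which(m$walkable)
  d_to_pac <- vapply(ids, function(i) maze_distance(m, i, st$pacman), numeric(1))
  far_tile <- ids[which(d_to_pac > 8)[1L]]
  near_tile <- ids[which(d_to_pac > 0 & d_to_pac <= 8)[1L]]
  st_far <- make_state(m, clyde = far_tile)
  d0 <- maze_distance(m, far_tile, st_far$pacman)
  d1 <- maze_distance(m, m$neighbors[[far_tile, clyde_policy(m, st_far)]], st_far$pacman)
  expect_lt(d1, d0)
  st_near <- make_state(m, clyde = near_tile)
  corner <- m$corner_lower_left
  g_near <- st_near$ghosts$clyde
  cand_n <- setdiff(available_directions(m, near_tile),
                    opposite_direction(g_near$facing))
  if (length(cand_n) == 0L) cand_n <- available_directions(m, near_tile)
  best <- min(vapply(cand_n, function(d) {
    maze_distance(m, m$neighbors[[near_tile, d]], corner)
  }, numeric(1)))
  d1c <- maze_distance(m, m$neighbors[[near_tile, clyde_policy(m, st_near)]], corner)
  expect_equal(d1c, best)
})

test_that("normal-mode ghosts never reverse when an alternative exists", {
  m <- default_maze()
  set.seed(42)
  log <- simulate_episode(m, scripted_agents()$uniform_random, seed = 42,
                          max_steps = 400)
  for (gn in c("blinky", "clyde")) {
    for (t in 2:length(log$records)) {
      g0 <- log$records[[t - 1L]]$state$ghosts[[gn]]
      g1 <- log$records[[t]]$state$ghosts[[gn]]
      moved <- g1$pos != g0$pos
      if (moved && g0$mode == "normal" && g1$mode == "normal" &&
          !"death" %in% log$records[[t - 1L]]$events$kind) {
        alternatives <- setdiff(available_directions(m, g0$pos),
                                opposite_direction(g0$facing))
        if (length(alternatives) > 0L) {
          expect_false(g1$pos == m$neighbors[g0$pos, opposite_direction(g0$facing)] &&
                         g1$facing == opposite_direction(g0$facing))
        }
      }
    }
  }
})

test_that("new_game placement respects counts, quadrants, and determinism", {
  m <- default_maze()
  s1 <- new_game(m, rt, game_config(), seed = 11)
  s2 <- new_game(m, rt, game_config(), seed = 11)
  expect_identical(s1, s2)
  expect_length(s1$pellets, 88L)
  expect_length(s1$energizers, 4L)
  expect_length(intersect(s1$pellets, s1$energizers), 0L)
  s73 <- new_game(m, rt, game_config(n_pellets = 73L, n_energizers = 3L), seed = 2)
  expect_length(s73$pellets, 73L)
  expect_length(s73$energizers, 3L)
  # one quadrant empty, and empty about 1/4 of the time each (binomial 3 sigma)
  quad_of <- function(ids) {
    pos <- tile_pos(m, ids)
    1L + (pos$col >= m$ncol %/% 2L) + 2L * (pos$row >= m$nrow %/% 2L)
  }
  n_games <- 600L
  empties <- vapply(seq_len(n_games), function(seed) {
    s <- new_game(m, rt, game_config(), seed = seed)
    setdiff(1:4, quad_of(c(s$pellets, s$energizers)))[1L]
  }, integer(1))
  expect_false(any(is.na(empties)))
  p0 <- 0.25
  sigma <- sqrt(p0 * (1 - p0) / n_games)
  for (q in 1:4) {
    expect_lt(abs(mean(empties == q) - p0), 3 * sigma + 1e-9)
  }
})

test_that("episodes are deterministic, conserve drops, and replay losslessly", {
  m <- default_maze()
  log <- simulate_episode(m, scripted_agents()$greedy_local, seed = 5,
                          max_steps = 250)
  log2 <- simulate_episode(m, scripted_agents()$greedy_local, seed = 5,
                           max_steps = 250)
  expect_identical(log, log2)
  # conservation: total drops = item counts x table values + bonuses
  ev <- log_events(log)
  expected <- sum(ev$drops[ev$kind == "pellet"]) +
    sum(ev$drops[ev$kind == "energizer"]) +
    sum(ev$drops[ev$kind == "fruit"]) +
    sum(ev$drops[ev$kind == "ghost"]) +
    sum(ev$drops[ev$kind == "completion_bonus"])
  expect_equal(total_drops(log), expected)
  expect_equal(sum(ev$kind == "pellet") * rt$pellet,
               sum(ev$drops[ev$kind == "pellet"]))
  s0 <- log$records[[1L]]$state
  expect_equal(sum(ev$kind == "pellet"),
               length(s0$pellets) - length(log$final_state$pellets))
  # pellet count non-increasing; zero exactly at completion
  counts <- vapply(log$records, function(r) length(r$state$pellets), integer(1))
  expect_true(all(diff(counts) <= 0L))
  if (log$final_state$cleared) {
    expect_length(log$final_state$pellets, 0L)
    expect_equal(sum(ev$kind == "completion_bonus"), 1L)
  }
  # empty budget gives an empty log
  empty <- simulate_episode(m, scripted_agents()$greedy_local, seed = 5,
                            max_steps = 0)
  expect_length(empty$records, 0L)
})

test_that("behavior logs round-trip through the text format losslessly", {
  m <- default_maze()
  log <- simulate_episode(m, scripted_agents()$uniform_random, seed = 9,
                          max_steps = 120)
  path <- withr::local_tempfile()
  write_behavior_log(log, path)
  back <- read_behavior_log(path)
  expect_equal(back$records, log$records)
  expect_equal(back$final_state, log$final_state)
  expect_equal(back$meta$config, log$meta$config)
  expect_equal(back$meta$reward_table, log$meta$reward_table)
})

test_that("a corridor sweep banks the per-item drops plus the clearance bonus", {
  m <- pocket_corridor_maze(9L)
  pellet_tiles <- vapply(3:7, function(c0) tile_id(m, c0, 1L), integer(1))
  st <- make_state(m, pellets = pellet_tiles)
  drops <- 0
  for (i in 1:8) {
    res <- step_game(m, st, "right", reward_table())
    drops <- drops + sum(res$events$drops)
    st <- res$state
    if (st$cleared) break
  }
  expect_true(st$cleared)
  expect_equal(drops, 5 * 2 + 20)         # five pellets, round-1 bonus
})
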