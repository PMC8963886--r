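# ---------------------------------------------------------------------------
# Line-oriented text serialization of behavior logs.
#
# One line per time step carrying the pre-action state scalars, the action,
# and the step's reward events.  Pellet/energizer/fruit sets are stored once
# in the header and reconstructed on read by applying the consumption events,
# which makes the format compact while keeping the round trip lossless.
# ---------------------------------------------------------------------------

.fmt_num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)

.fmt_ghost <- function(g) {
  paste(g$pos, g$facing, g$mode, .fmt_num(g$scared_timer), sep = ",")
}

.parse_ghost <- function(name, s) {
  f <- strsplit(s, ",", fixed = TRUE)[[1]]
  list(name = name, pos = as.integer(f[1]), facing = f[2], mode = f[3],
       scared_timer = as.numeric(f[4]))
}

.fmt_events <- function(ev) {
  if (nrow(ev) == 0L) return("-")
  paste(sprintf("%s:%s:%s", ev$kind, .fmt_num(ev$drops),
                ifelse(is.na(ev$pos), "NA", ev$pos)), collapse = ";")
}

.parse_events <- function(s, t) {
  if (s == "-") return(.reward_event(character(0), numeric(0), integer(0), integer(0)))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  do.call(rbind, lapply(parts, function(p) {
    .reward_event(p[1], as.numeric(p[2]), t,
                  if (p[3] == "NA") NA_integer_ else as.integer(p[3]))
  }))
}

#' Write a behavior log to a text file
#'
#' @param log A `behavior_log`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_behavior_log()]
#' @export
write_behavior_log <- function(log, path) {
  s0 <- if (length(log$records) > 0L) log$records[[1L]]$state else log$final_state
  cfg <- log$meta$config
  rt <- log$meta$reward_table
  header <- c(
    "#pacstrat-log v1",
    paste0("#maze_id ", log$meta$maze_id),
    paste0("#seed ", log$meta$seed %||% "NA"),
    paste0("#agent ", log$meta$agent),
    paste0("#config ", paste(cfg$n_pellets, cfg$n_energizers, cfg$scared_rule,
                             cfg$ghost_contact, cfg$place_fruit,
                             .fmt_num(cfg$step_seconds))),
    paste0("#reward ", paste(.fmt_num(rt$pellet), .fmt_num(rt$energizer),
                             .fmt_num(rt$ghost),
                             paste(names(rt$fruit), .fmt_num(rt$fruit),
                                   sep = ":", collapse = ","),
                             paste(.fmt_num(rt$completion_bonus), collapse = ","),
                             .fmt_num(rt$scared_duration),
                             .fmt_num(rt$flash_duration),
                             .fmt_num(rt$death_timeout_seconds))),
    paste0("#pellets ", paste(s0$pellets, collapse = ",")),
    paste0("#energizers ", paste(s0$energizers, collapse = ",")),
    paste0("#fruit ", if (is.null(s0$fruit)) "-" else paste0(s0$fruit$pos, ",", s0$fruit$kind)),
    paste0("#initial_pellets ", s0$initial_pellets),
    "#fields t action pacman facing blinky clyde round clock rng cleared events"
  )
  lines <- vapply(log$records, function(r) {
    s <- r$state
    paste(s$time_step, r$action, s$pacman, s$pacman_facing,
          .fmt_ghost(s$ghosts$blinky), .fmt_ghost(s$ghosts$clyde),
          s$round_index, .fmt_num(s$clock_seconds), .fmt_num(s$rng),
          as.integer(s$cleared), .fmt_events(r$events))
  }, character(1))
  fs <- log$final_state
  footer <- paste("#final", fs$time_step, fs$pacman, fs$pacman_facing,
                  .fmt_ghost(fs$ghosts$blinky), .fmt_ghost(fs$ghosts$clyde),
                  fs$round_index, .fmt_num(fs$clock_seconds), .fmt_num(fs$rng),
                  as.integer(fs$cleared))
  writeLines(c(header, lines, footer), path)
  invisible(path)
}

#' Read a behavior log written by [write_behavior_log()]
#'
#' Reconstructs the full per-step game states by replaying the recorded
#' consumption events against the header's initial item sets; the round trip
#' write/read is lossless.
#'
#' @param path File path.
#' @return A `behavior_log`.
#' @export
read_behavior_log <- function(path) {
  lines <- readLines(path)
  if (lines[1L] != "#pacstrat-log v1") stop("not a pacstrat behavior log: ", path)
  hdr <- function(key) {
    ln <- grep(paste0("^#", key, " "), lines, value = TRUE)[1L]
    sub(paste0("^#", key, " "), "", ln)
  }
  cfgf <- strsplit(hdr("config"), " ", fixed = TRUE)[[1]]
  config <- game_config(n_pellets = as.integer(cfgf[1]),
                        n_energizers = as.integer(cfgf[2]),
                        scared_rule = cfgf[3], ghost_contact = cfgf[4],
                        place_fruit = as.logical(cfgf[5]),
                        step_seconds = as.numeric(cfgf[6]))
  rwf <- strsplit(hdr("reward"), " ", fixed = TRUE)[[1]]
  fr <- do.call(rbind, strsplit(strsplit(rwf[4], ",", fixed = TRUE)[[1]], ":", fixed = TRUE))
  rt <- reward_table(pellet = as.numeric(rwf[1]), energizer = as.numeric(rwf[2]),
                     ghost = as.numeric(rwf[3]),
                     fruit = stats::setNames(as.numeric(fr[, 2]), fr[, 1]),
                     completion_bonus = as.numeric(strsplit(rwf[5], ",", fixed = TRUE)[[1]]),
                     scared_duration = as.numeric(rwf[6]),
                     flash_duration = as.numeric(rwf[7]),
                     death_timeout_seconds = as.numeric(rwf[8]))
  parse_set <- function(s) if (nzchar(s)) as.integer(strsplit(s, ",", fixed = TRUE)[[1]]) else integer(0)
  pellets <- parse_set(hdr("pellets"))
  energizers <- parse_set(hdr("energizers"))
  fruit_s <- hdr("fruit")
  fruit <- if (fruit_s == "-") NULL else {
    f <- strsplit(fruit_s, ",", fixed = TRUE)[[1]]
    list(pos = as.integer(f[1]), kind = f[2])
  }
  initial_pellets <- as.integer(hdr("initial_pellets"))
  seed_s <- hdr("seed")

  body <- lines[!startsWith(lines, "#")]
  records <- vector("list", length(body))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], " ", fixed = TRUE)[[1]]
    t <- as.integer(f[1])
    state <- structure(list(
      pacman = as.integer(f[3]), pacman_facing = f[4],
      ghosts = list(blinky = .parse_ghost("blinky", f[5]),
                    clyde = .parse_ghost("clyde", f[6])),
      pellets = pellets, energizers = energizers, fruit = fruit,
      time_step = t, round_index = as.integer(f[7]),
      clock_seconds = as.numeric(f[8]),
      initial_pellets = initial_pellets,
      cleared = as.logical(as.integer(f[10])),
      rng = as.numeric(f[9])
    ), class = "game_state")
    events <- .parse_events(f[11], t)
    for (j in seq_len(nrow(events))) {
      kind <- events$kind[j]
      if (kind == "pellet") pellets <- setdiff(pellets, events$pos[j])
      if (kind == "energizer") energizers <- setdiff(energizers, events$pos[j])
      if (kind == "fruit") fruit <- NULL
    }
    records[[i]] <- list(state = state, action = f[2], events = events)
  }

  ff <- strsplit(grep("^#final ", lines, value = TRUE)[1L], " ", fixed = TRUE)[[1]][-1L]
  final_state <- structure(list(
    pacman = as.integer(ff[2]), pacman_facing = ff[3],
    ghosts = list(blinky = .parse_ghost("blinky", ff[4]),
                  clyde = .parse_ghost("clyde", ff[5])),
    pellets = pellets, energizers = energizers, fruit = fruit,
    time_step = as.integer(ff[1]), round_index = as.integer(ff[6]),
    clock_seconds = as.numeric(ff[7]),
    initial_pellets = initial_pellets,
    cleared = as.logical(as.integer(ff[9])),
    rng = as.numeric(ff[8])
  ), class = "game_state")

  structure(list(records = records, final_state = final_state,
                 meta = list(maze_id = hdr("maze_id"),
                             seed = if (seed_s == "NA") NULL else as.integer(seed_s),
                             agent = hdr("agent"),
                             config = config, reward_table = rt,
                             n_steps = length(records))),
            class = "behavior_log")
}
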