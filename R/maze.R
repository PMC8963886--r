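#' @importFrom stats runif setNames
#' @importFrom utils head tail
NULL

# ---------------------------------------------------------------------------
# Maze graph: walkable-tile graph of the game board.
#
# Tiles are the square grid cells of the board.  A tile is addressed either
# by a 0-based (col, row) pair (origin top-left, "up" decreases row) or by a
# 1-based linear id  row * ncol + col + 1.  All internal structures use ids.
# ---------------------------------------------------------------------------

# characters of the ASCII maze format
.MAZE_CHARS <- c("#", " ", ".", "o", "F", "P", "B", "C", "H", "T")

#' Convert between tile ids and (col, row) coordinates
#'
#' Tiles are addressed by 0-based `(col, row)` coordinates with the origin at
#' the top-left corner, or equivalently by the 1-based linear id
#' `row * ncol + col + 1`.
#'
#' @param maze A `maze_graph` object.
#' @param col,row 0-based tile coordinates (vectorized).
#' @param id 1-based linear tile id (vectorized).
#' @return `tile_id()` returns integer ids; `tile_pos()` returns a data frame
#'   with columns `col` and `row`.
#' @export
tile_id <- function(maze, col, row) {
  as.integer(row) * maze$ncol + as.integer(col) + 1L
}

#' @rdname tile_id
#' @export
tile_pos <- function(maze, id) {
  id0 <- as.integer(id) - 1L
  data.frame(col = id0 %% maze$ncol, row = id0 %/% maze$ncol)
}

#' Load a maze from its ASCII description
#'
#' Parses the plain-text maze format into a walkable-tile graph with
#' per-direction adjacency, tunnel teleports, and the named locations used by
#' the game engine.
#'
#' The format is one character per tile: `#` wall, space corridor, `.` pellet
#' slot, `o` energizer slot, `F` fruit slot, `P` Pac-Man start, `B`/`C` ghost
#' starts (Blinky / Clyde), `H` ghost-home interior, `T` tunnel mouth.
#' Tunnel mouths are paired left-to-right in reading order; traversing a
#' tunnel preserves the moving direction and relocates to the paired mouth.
#'
#' @param text The maze, either a single string with newlines or a character
#'   vector of rows.
#' @param id Optional identifier stored with the maze (defaults to a digest
#'   of the text).
#' @return An object of class `maze_graph`: a list with the grid size, the
#'   walkable set, the per-direction neighbor table, tunnel pairs, named
#'   start locations, and the item slots found in the text.
#' @examples
#' m <- load_maze(c("#####", "#...#", "#####"))
#' available_directions(m, tile_id(m, 2, 1))
#' @export
load_maze <- function(text, id = NULL) {
  if (length(text) == 1L && grepl("\n", text)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  widths <- nchar(text)
  if (length(unique(widths)) != 1L) {
    stop("maze grid is not rectangular (row widths ", paste(unique(widths), collapse = ", "), ")")
  }
  nr <- length(text)
  nc <- widths[1L]
  chars <- matrix(unlist(strsplit(text, "", fixed = TRUE)), nrow = nr, ncol = nc, byrow = TRUE)
  bad <- setdiff(unique(as.vector(chars)), .MAZE_CHARS)
  if (length(bad) > 0L) {
    stop("unknown maze character(s): ", paste(sQuote(bad), collapse = ", "))
  }

  n <- nr * nc
  # id = row * nc + col + 1 with 0-based row/col <=> row-major over the text
  ch <- as.vector(t(chars))                       # ch[id] is the tile character
  walkable <- ch != "#"

  neighbors <- matrix(NA_integer_, nrow = n, ncol = 4L,
                      dimnames = list(NULL, DIRECTIONS))
  ids <- which(walkable)
  col0 <- (ids - 1L) %% nc
  row0 <- (ids - 1L) %/% nc
  for (d in DIRECTIONS) {
    c2 <- col0 + .DIR_DCOL[[d]]
    r2 <- row0 + .DIR_DROW[[d]]
    ok <- c2 >= 0L & c2 < nc & r2 >= 0L & r2 < nr
    nid <- rep(NA_integer_, length(ids))
    nid[ok] <- r2[ok] * nc + c2[ok] + 1L
    nid[!is.na(nid) & !walkable[replace(nid, is.na(nid), 1L)]] <- NA_integer_
    neighbors[ids, d] <- nid
  }

  tun <- which(ch == "T")
  if (length(tun) %% 2L != 0L) stop("unpaired tunnel marker 'T'")
  tunnels <- if (length(tun) > 0L) {
    matrix(tun, ncol = 2L, byrow = TRUE)
  } else {
    matrix(integer(0), ncol = 2L)
  }
  # pairing is left-to-right: moving off the left mouth emerges at the right
  # mouth still moving left, and vice versa
  if (nrow(tunnels) > 0L) {
    for (k in seq_len(nrow(tunnels))) {
      a <- tunnels[k, 1L]; b <- tunnels[k, 2L]
      ca <- (a - 1L) %% nc; cb <- (b - 1L) %% nc
      if (ca > cb) { tmp <- a; a <- b; b <- tmp }   # a = left mouth
      neighbors[a, "left"] <- b
      neighbors[b, "right"] <- a
      tunnels[k, ] <- c(a, b)
    }
  }

  deg <- rowSums(!is.na(neighbors))
  if (any(walkable & deg == 0L)) {
    stop("walkable tile with no available direction at id ",
         which(walkable & deg == 0L)[1L])
  }

  find_one <- function(char) {
    w <- which(ch == char)
    if (length(w) == 0L) NA_integer_ else w[1L]
  }
  # lower-left corner target: walkable tile maximizing row then minimizing col
  cand <- which(walkable)
  ll <- cand[order(-((cand - 1L) %/% nc), (cand - 1L) %% nc)][1L]

  maze <- structure(list(
    ncol = nc, nrow = nr, n = n,
    chars = ch,
    walkable = walkable,
    neighbors = neighbors,
    tunnels = tunnels,
    tunnel_tiles = as.integer(tun),
    start_pacman = find_one("P"),
    start_blinky = find_one("B"),
    start_clyde = find_one("C"),
    home = sort(c(which(ch == "H"), which(ch == "B"), which(ch == "C"))),
    corner_lower_left = ll,
    pellet_slots = which(ch == "."),
    energizer_slots = which(ch == "o"),
    fruit_slots = which(ch == "F"),
    id = if (is.null(id)) sprintf("maze-%dx%d-%d", nc, nr, sum(walkable)) else id,
    cache = new.env(parent = emptyenv())
  ), class = "maze_graph")

  # connectivity report: unreachable walkable tiles are flagged, not fatal
  comp <- .reachable_from(maze, which(walkable)[1L])
  unreachable <- setdiff(which(walkable), comp)
  if (length(unreachable) > 0L) {
    warning(length(unreachable), " walkable tile(s) unreachable from the rest of the maze")
  }
  maze
}

#' @export
print.maze_graph <- function(x, ...) {
  cat(sprintf("<maze_graph> %dx%d grid, %d walkable tiles, %d tunnel pair(s)\n",
              x$ncol, x$nrow, sum(x$walkable), nrow(x$tunnels)))
  invisible(x)
}

# set of tile ids reachable from `from` (breadth-first over the neighbor table)
.reachable_from <- function(maze, from) {
  seen <- logical(maze$n)
  seen[from] <- TRUE
  frontier <- from
  while (length(frontier) > 0L) {
    nxt <- as.vector(maze$neighbors[frontier, , drop = FALSE])
    nxt <- unique(nxt[!is.na(nxt)])
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  which(seen)
}

#' Available joystick directions at a tile
#'
#' @param maze A `maze_graph`.
#' @param p A tile id (see [tile_id()]).
#' @return Character vector of direction names with a walkable continuation
#'   (a tunnel counts as a continuation).
#' @export
available_directions <- function(maze, p) {
  stopifnot(length(p) == 1L)
  if (!maze$walkable[p]) stop("tile ", p, " is not walkable")
  DIRECTIONS[!is.na(maze$neighbors[p, ])]
}

# neighbor id after moving in direction d from p, or NA
.move <- function(maze, p, d) maze$neighbors[p, d]

#' Shortest-path tile distance
#'
#' The length in tile steps of the shortest walkable path between two tiles,
#' tunnels included (a tunnel traversal costs one step).
#'
#' @param maze A `maze_graph`.
#' @param a,b Tile ids.
#' @return A nonnegative number of steps, or `Inf` if `b` is unreachable
#'   from `a`.
#' @export
maze_distance <- function(maze, a, b) {
  if (!maze$walkable[a] || !maze$walkable[b]) stop("both tiles must be walkable")
  .dist_matrix(maze)[match(a, .walk_ids(maze)), match(b, .walk_ids(maze))]
}

.walk_ids <- function(maze) {
  if (is.null(maze$cache$walk_ids)) maze$cache$walk_ids <- which(maze$walkable)
  maze$cache$walk_ids
}

# full all-pairs shortest-path matrix over walkable tiles (rows/cols indexed
# by .walk_ids ordering); computed once per maze via igraph
.dist_matrix <- function(maze) {
  if (is.null(maze$cache$dist)) {
    ids <- .walk_ids(maze)
    idx <- match(seq_len(maze$n), ids)          # tile id -> vertex index
    from <- rep(ids, times = 4L)
    to <- as.vector(maze$neighbors[ids, ])
    keep <- !is.na(to)
    edges <- cbind(idx[from[keep]], idx[to[keep]])
    g <- igraph::graph_from_edgelist(unique(t(apply(edges, 1L, sort))), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(ids) - igraph::vcount(g)))
    maze$cache$dist <- igraph::distances(g)
  }
  maze$cache$dist
}

# distances from every walkable tile to tile b, as a vector over tile ids
# (NA for walls); convenience wrapper used by ghost policies and features
.dist_to <- function(maze, b) {
  ids <- .walk_ids(maze)
  out <- rep(NA_real_, maze$n)
  out[ids] <- .dist_matrix(maze)[, match(b, ids)]
  out
}

#' Enumerate forward paths from a tile, grouped by first step
#'
#' Enumerates all walks of `depth` steps starting at `p` that never
#' immediately reverse (a walk never contains the move pair d, opposite(d)).
#' Walks that hit a dead end before `depth` steps are truncated there and
#' kept.  The result is the per-direction path set used by the basis-strategy
#' utilities: paths are grouped by their first step, and the groups for
#' distinct directions are disjoint.
#'
#' @param maze A `maze_graph`.
#' @param p Starting tile id (not included in the returned paths).
#' @param depth Maximum path length in steps (default 10).
#' @param simple_only If `TRUE`, paths may not revisit a tile (simple paths);
#'   by default loops are allowed, mirroring the movement constraint imposed
#'   on the game characters.
#' @return An object of class `path_set`: a list with `depth` and `dirs`, a
#'   named list mapping each available direction to an integer matrix with
#'   one row per path (tile ids of the successive steps, `NA`-padded for
#'   truncated paths).
#' @export
enumerate_paths <- function(maze, p, depth = 10L, simple_only = FALSE) {
  stopifnot(depth >= 1L)
  if (!maze$walkable[p]) stop("tile ", p, " is not walkable")
  key <- paste0(p, ":", depth, ":", simple_only)
  cache <- maze$cache
  if (is.null(cache$paths)) cache$paths <- new.env(parent = emptyenv())
  hit <- cache$paths[[key]]
  if (!is.null(hit)) return(hit)

  walk <- function(current, lastdir, path) {
    if (length(path) == depth) return(list(path))
    dirs <- DIRECTIONS[!is.na(maze$neighbors[current, ])]
    dirs <- setdiff(dirs, opposite_direction(lastdir))
    if (simple_only) {
      dirs <- dirs[!(maze$neighbors[current, dirs] %in% c(p, path))]
    }
    if (length(dirs) == 0L) return(list(path))   # dead end: truncate, keep
    out <- list()
    for (d in dirs) {
      nxt <- maze$neighbors[[current, d]]
      out <- c(out, walk(nxt, d, c(path, nxt)))
    }
    out
  }

  dirs0 <- DIRECTIONS[!is.na(maze$neighbors[p, ])]
  sets <- list()
  for (d in dirs0) {
    first <- maze$neighbors[[p, d]]
    paths <- walk(first, d, first)
    mat <- matrix(NA_integer_, nrow = length(paths), ncol = depth)
    for (i in seq_along(paths)) mat[i, seq_along(paths[[i]])] <- paths[[i]]
    sets[[d]] <- mat
  }
  res <- structure(list(depth = depth, start = p, dirs = sets), class = "path_set")
  cache$paths[[key]] <- res
  res
}

#' The bundled default maze
#'
#' Loads the maze layout shipped with the package: a 21x24 four-quadrant
#' maze with two tunnel pairs and a central single-exit ghost home.
#'
#' @return A `maze_graph`.
#' @export
default_maze <- function() {
  path <- system.file("extdata", "maze_default.txt", package = "pacstrat")
  load_maze(readLines(path), id = "default")
}
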