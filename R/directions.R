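#' Joystick directions
#'
#' The four joystick actions, in the fixed order used for all
#' direction-indexed vectors in the package.
#'
#' @format Character vector of length 4: `"left"`, `"right"`, `"up"`, `"down"`.
#' @export
DIRECTIONS <- c("left", "right", "up", "down")

# column/row displacement per direction; "up" decreases the row
# (0-based tile coordinates, origin at the top-left corner)
.DIR_DCOL <- c(left = -1L, right = 1L, up = 0L, down = 0L)
.DIR_DROW <- c(left = 0L, right = 0L, up = -1L, down = 1L)

# deterministic tie-break priority (classic-arcade convention):
# up > left > down > right
.DIR_PRIORITY <- c("up", "left", "down", "right")

#' Opposite of a direction
#'
#' @param d A direction name, one of [DIRECTIONS].
#' @return The opposite direction name.
#' @examples
#' opposite_direction("left")
#' @export
opposite_direction <- function(d) {
  c(left = "right", right = "left", up = "down", down = "up")[[d]]
}

# order a set of direction names by the fixed tie-break priority
.priority_order <- function(dirs) {
  dirs[order(match(dirs, .DIR_PRIORITY))]
}

# first direction (by priority) among those with the maximal value;
# `values` is a named numeric vector over direction names
.argmax_direction <- function(values) {
  finite <- values[is.finite(values)]
  if (length(finite) == 0L) stop("no finite direction value")
  best <- names(finite)[finite >= max(finite) - 1e-12]
  .priority_order(best)[1L]
}
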