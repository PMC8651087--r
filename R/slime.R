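# The slime field: an apolar trail-orientation grid deposited by gliding
# agents.  The engine carries its own grid; these functions provide the
# same rules on a plain R object for analysis, documentation and oracle
# tests, plus accessors for the grid a finished run returns.

#' Create an empty slime grid
#'
#' @param L_sim domain edge (um).
#' @param cell_size grid cell size (um).
#' @return An object of class `slime_grid`: orientation matrix (radians in
#'   `[0, pi)`, `NA` where empty), deposit-time matrix, visit-count matrix,
#'   and the geometry.  Row index is the y cell, column index the x cell.
#' @export
slime_grid <- function(L_sim, cell_size = 0.5) {
  G <- max(1L, round(L_sim / cell_size))
  structure(list(
    orientation = matrix(NA_real_, G, G),
    time = matrix(NA_real_, G, G),
    visits = matrix(0L, G, G),
    L_sim = L_sim, cell_size = L_sim / G, G = G),
    class = "slime_grid")
}

slime_cell_index <- function(grid, x, y) {
  cx <- pmin(grid$G, floor((x %% grid$L_sim) / grid$cell_size) + 1L)
  cy <- pmin(grid$G, floor((y %% grid$L_sim) / grid$cell_size) + 1L)
  cbind(cy, cx)
}

#' Deposit a trail mark
#'
#' Writes the apolar orientation (mod pi) of the depositing tail segment
#' into the grid cell under `(x, y)`; the latest writer wins.  A deposit
#' separated from the previous one by more than `revisit_gap` counts as a
#' distinct visit (trail reinforcement).
#'
#' @param grid a [slime_grid()].
#' @param x,y deposit position (um; wrapped into the domain).
#' @param orientation trail direction (radians; stored mod pi).
#' @param t deposit time (min).
#' @param revisit_gap minimal time gap (min) for a new distinct visit.
#' @return The updated grid.
#' @export
slime_deposit <- function(grid, x, y, orientation, t, revisit_gap = 1) {
  idx <- slime_cell_index(grid, x, y)
  o <- orientation %% pi
  prev <- grid$time[idx]
  grid$visits[idx] <- ifelse(is.na(prev) | t - prev > revisit_gap,
                             ifelse(is.na(prev), 1L, grid$visits[idx] + 1L),
                             grid$visits[idx])
  grid$orientation[idx] <- o
  grid$time[idx] <- t
  grid
}

#' Steering by a slime trail
#'
#' Rotates a heading toward whichever branch of the apolar trail axis
#' (`orientation` or `orientation + pi`) is angularly closer, by at most
#' `max_rotation`.  With `enabled = FALSE`, or with no trail
#' (`orientation = NA`), the heading is returned unchanged.
#'
#' @param heading current propulsion heading (radians).
#' @param orientation trail orientation (radians mod pi) or `NA`.
#' @param max_rotation maximal rotation this step (radians), typically
#'   `omega_s * dt`.
#' @param enabled slime-following switch.
#' @return Adjusted heading (radians, in `(-pi, pi]`).
#' @examples
#' slime_follow(30 * pi / 180, 0, 2 * pi / 180) * 180 / pi   # 28 degrees
#' @export
slime_follow <- function(heading, orientation, max_rotation,
                         enabled = TRUE) {
  wrap_pi <- function(a) ((a + pi) %% (2 * pi)) - pi
  if (!enabled || is.na(orientation)) return(wrap_pi(heading))
  d1 <- wrap_pi(orientation - heading)
  d2 <- wrap_pi(orientation + pi - heading)
  delta <- if (abs(d1) <= abs(d2)) d1 else d2
  wrap_pi(heading + max(-max_rotation, min(max_rotation, delta)))
}

#' Slime grid of a finished run, as a table
#'
#' Dense tabular dump (one row per visited cell) of the engine's final
#' slime field: cell indices, cell-center coordinates, orientation and
#' last deposit time.
#'
#' @param sim a `myxo_sim`.
#' @return Data frame with columns `cell_i` (y index), `cell_j` (x index),
#'   `x_um`, `y_um`, `orientation_rad`, `last_deposit_min`.
#' @export
slime_grid_table <- function(sim) {
  sl <- sim$slime
  G <- nrow(sl$orientation)
  filled <- which(!is.na(sl$time), arr.ind = TRUE)
  data.frame(
    cell_i = filled[, 1], cell_j = filled[, 2],
    x_um = (filled[, 2] - 0.5) * sl$cell_size,
    y_um = (filled[, 1] - 0.5) * sl$cell_size,
    orientation_rad = sl$orientation[filled],
    last_deposit_min = sl$time[filled])
}
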