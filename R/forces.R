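# Reference implementations of the per-agent force rules, in plain R.
# They operate on a single agent's N x 2 node matrix in free space (no
# periodic wrapping) and mirror the engine's force laws; the test suite
# uses them as independent oracles against the compiled path.

#' Propulsion forces of one agent
#'
#' Each node except the tail carries a force of magnitude `F_T / (N - 1)`
#' toward its forward neighbor; the head node's direction is its current
#' heading, optionally replaced by a steering-adjusted direction (random
#' turn or slime alignment).
#'
#' @param pos `N x 2` node coordinate matrix, ordered tail-to-head or
#'   head-to-tail according to `head`.
#' @param head index of the head node (1 or `N`, 1-based).
#' @param cfg a [myxo_config()].
#' @param heading optional override (radians) for the head node's
#'   propulsion direction.
#' @return `N x 2` matrix of forces (pN).
#' @examples
#' cfg <- myxo_config()
#' pos <- cbind(0:6, 0)          # straight agent along +x
#' f <- propulsion_forces(pos, head = 7, cfg)
#' f[7, ]                        # head node: ~ (9.167, 0)
#' @export
propulsion_forces <- function(pos, head, cfg, heading = NULL) {
  N <- nrow(pos)
  stopifnot(head %in% c(1L, N))
  Fp <- cfg$F_T / (N - 1)
  fwd <- if (head == N) 1L else -1L
  tail_i <- if (head == N) 1L else N
  out <- matrix(0, N, 2)
  for (j in seq_len(N)) {
    if (j == tail_i) next
    if (j == head) {
      dir <- if (is.null(heading)) {
        d <- pos[head, ] - pos[head - fwd, ]
        atan2(d[2], d[1])
      } else heading
      out[j, ] <- Fp * c(cos(dir), sin(dir))
    } else {
      d <- pos[j + fwd, ] - pos[j, ]
      nd <- sqrt(sum(d^2))
      if (nd < 1e-9)
        stop("degenerate geometry: coincident consecutive nodes")
      out[j, ] <- Fp * d / nd
    }
  }
  out
}

#' Viscous drag forces
#'
#' `F = -c v` per node.
#'
#' @param vel `N x 2` node velocity matrix (um/min).
#' @param c drag coefficient (pN min/um).
#' @return `N x 2` matrix of forces (pN).
#' @export
drag_forces <- function(vel, c) {
  -c * vel
}

#' Bending forces of an angular-spring chain
#'
#' Each interior joint resists deviation from the straight configuration
#' with restoring torque `-k_b * phi` (`phi` the signed bend angle); the
#' equivalent force triple on the three nodes of the joint is
#' momentum-free and torque-free.
#'
#' @param pos `N x 2` node coordinate matrix.
#' @param k_b angular spring constant (pN um/rad).
#' @return `N x 2` matrix of forces (pN).
#' @export
bending_forces <- function(pos, k_b) {
  N <- nrow(pos)
  out <- matrix(0, N, 2)
  for (j in 2:(N - 1)) {
    a <- pos[j, ] - pos[j - 1, ]
    b <- pos[j + 1, ] - pos[j, ]
    phi <- atan2(a[1] * b[2] - a[2] * b[1], sum(a * b))
    a2 <- sum(a^2); b2 <- sum(b^2)
    gm <- c(-a[2], a[1]) / a2        # d phi / d pos[j-1]
    gp <- c(-b[2], b[1]) / b2        # d phi / d pos[j+1]
    mom <- -k_b * phi
    out[j - 1, ] <- out[j - 1, ] + mom * gm
    out[j + 1, ] <- out[j + 1, ] + mom * gp
    out[j, ] <- out[j, ] - mom * (gm + gp)
  }
  out
}

#' Substrate focal-adhesion spring
#'
#' The node is tethered to its anchor by a linear spring that resists only
#' the displacement component transverse to the local body axis
#' (longitudinal gliding is unimpeded).  When the total displacement
#' reaches the break distance the anchor detaches and instantly reattaches
#' at the node position, returning zero force for that step.
#'
#' @param node length-2 node position (um).
#' @param anchor length-2 anchor position (um).
#' @param axis length-2 local body-axis direction (need not be unit).
#' @param k_a spring constant (pN/um).
#' @param d_a_max break distance (um).
#' @return List with `force` (length-2, pN) and `anchor` (possibly
#'   relocated).
#' @examples
#' substrate_adhesion(c(0, 0.3), c(0, 0), c(1, 0), 100, 0.5)$force  # (0, -30)
#' @export
substrate_adhesion <- function(node, anchor, axis, k_a, d_a_max) {
  disp <- node - anchor
  if (sqrt(sum(disp^2)) >= d_a_max)
    return(list(force = c(0, 0), anchor = node))
  u <- axis / sqrt(sum(axis^2))
  nrm <- c(-u[2], u[1])
  list(force = -k_a * sum(disp * nrm) * nrm, anchor = anchor)
}

#' Cell-cell adhesion force magnitude
#'
#' The piecewise bond force: zero at or below contact distance `w` and
#' beyond the bond reach, otherwise `k_adh * (d - w)/w * F_T`, i.e. a
#' spring anchored at the contact distance whose maximal pull is
#' `k_adh * F_T * (d_thr - w)/w` just before rupture.
#'
#' @param d node center distance (um).
#' @param k_adh adhesion force factor (see
#'   [pair_adhesion_coefficient()]).
#' @param cfg a [myxo_config()].
#' @param type `"end_end"` (reach `d_thr_ee`) or `"lateral"` (reach
#'   `d_thr_lat`).
#' @return Force magnitude (pN), directed toward the partner node.
#' @examples
#' cfg <- myxo_config()
#' adhesion_force(0.7, 0.1, cfg, "lateral")   # 2.2 pN
#' adhesion_force(1.0, 0.1, cfg, "end_end")   # 5.5 pN
#' @export
adhesion_force <- function(d, k_adh, cfg, type = c("end_end", "lateral")) {
  type <- match.arg(type)
  stopifnot(d >= 0)
  thr <- if (type == "end_end") cfg$d_thr_ee else cfg$d_thr_lat
  if (d > thr || d <= cfg$w) return(0)
  k_adh * (d - cfg$w) / cfg$w * cfg$F_T
}

#' Project node spacings back to the fixed segment length
#'
#' Gauss-Seidel sweeps of symmetric pair corrections, as applied by the
#' engine after every integration step; preserves the center of mass.
#'
#' @param pos `N x 2` node coordinate matrix.
#' @param target segment rest length (um); defaults to total length 6 um
#'   over `N - 1` segments.
#' @param tol convergence tolerance on the worst spacing error (um).
#' @param max_sweeps sweep cap.
#' @return Corrected `N x 2` matrix.
#' @export
enforce_length <- function(pos, target = 6 / (nrow(pos) - 1), tol = 1e-3,
                           max_sweeps = 100) {
  N <- nrow(pos)
  for (it in seq_len(max_sweeps)) {
    worst <- 0
    for (j in seq_len(N - 1)) {
      d <- pos[j + 1, ] - pos[j, ]
      nd <- sqrt(sum(d^2))
      if (nd < 1e-12) next
      worst <- max(worst, abs(nd - target))
      corr <- 0.5 * (nd - target) / nd * d
      pos[j, ] <- pos[j, ] + corr
      pos[j + 1, ] <- pos[j + 1, ] - corr
    }
    if (worst < tol) break
  }
  pos
}

#' Reversal-clock update
#'
#' One step of the contact-gated reversal clock.  If the clock has reached
#' the reversal period the reversal fires and the clock resets to zero;
#' otherwise it advances by `dt` minus the suppression contributed by
#' bonds older than the activation threshold (`dR_e` per end-end bond,
#' `dR_l` per lateral bond), floored at zero.  Counts must only include
#' bonds whose age exceeds `tau_thr`.
#'
#' @param r_t current clock value (min).
#' @param n_ee_active,n_lat_active numbers of suppressing end-end and
#'   lateral bonds (age above `tau_thr`).
#' @param dt time step (min).
#' @param cfg a [myxo_config()] (uses `tau_r`, `dR_e`, `dR_l`).
#' @return List with `r` (next clock value) and `fired` (logical).
#' @examples
#' cfg <- myxo_config()
#' reversal_clock_update(8, 0, 0, cfg$dt, cfg)$fired       # TRUE
#' reversal_clock_update(1, 1, 0, cfg$dt, cfg)$r           # frozen at 1
#' @export
reversal_clock_update <- function(r_t, n_ee_active, n_lat_active, dt, cfg) {
  if (n_ee_active < 0 || n_lat_active < 0)
    stop("bond counts must be non-negative")
  if (is.finite(cfg$tau_r) && r_t >= cfg$tau_r)
    return(list(r = 0, fired = TRUE))
  r <- r_t + dt * (1 - n_ee_active * cfg$dR_e - n_lat_active * cfg$dR_l)
  list(r = max(r, 0), fired = FALSE)
}
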