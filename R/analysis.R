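#' Mean reversal interval from tracking counts
#'
#' Converts a tracked-population summary (number of cells, observation
#' window, total reversal events) into the average time between reversals
#' per cell, in hours: `(n_cells * duration_min / n_events) / 60`.
#'
#' @param n_cells number of tracked cells.
#' @param duration_min observation window (min).
#' @param n_events total number of reversal events over all cells.
#' @return Mean interval in hours.  With `n_events = 0` the interval is
#'   undefined; the function warns ("no reversals observed") and returns
#'   `Inf`.
#' @examples
#' mean_reversal_interval(443, 60, 12)  # ~36.9 h
#' @export
mean_reversal_interval <- function(n_cells, duration_min, n_events) {
  stopifnot(n_cells >= 1, duration_min > 0, n_events >= 0)
  if (n_events == 0) {
    warning("no reversals observed: interval is undefined (returning Inf)")
    return(Inf)
  }
  (n_cells * duration_min / n_events) / 60
}

# Canonical per-agent centroid tracks: list(times, px, py (M x S), L_sim,
# plus per-agent labels).  Accepts a myxo_sim or a long trajectory table.
traj_tracks <- function(x) {
  if (inherits(x, "myxo_sim")) {
    cen <- centroid_matrix(x$x, x$y, x$N, x$cfg$L_sim)
    return(list(times = x$times, px = cen$px, py = cen$py, L = x$cfg$L_sim,
                strain = x$strain, allele = x$allele,
                suppressed = x$suppressed, sim = x))
  }
  if (is.data.frame(x)) {
    need <- c("time_min", "agent_id", "x_um", "y_um")
    if (!all(need %in% names(x)))
      stop("trajectory table needs columns ", paste(need, collapse = ", "))
    L <- attr(x, "L_sim")
    times <- sort(unique(x$time_min))
    agents <- sort(unique(x$agent_id))
    px <- matrix(NA_real_, length(agents), length(times))
    py <- px
    si <- match(x$time_min, times); ai <- match(x$agent_id, agents)
    if ("node_index" %in% names(x)) {
      # average nodes per agent/snapshot, unwrapping if domain size known
      for (k in split(seq_len(nrow(x)), paste(ai, si))) {
        a <- ai[k[1]]; s <- si[k[1]]
        vx <- x$x_um[k]; vy <- x$y_um[k]
        if (!is.null(L) && !is.na(L)) {
          ux <- diff(vx); ux <- ux - L * round(ux / L)
          uy <- diff(vy); uy <- uy - L * round(uy / L)
          vx <- vx[1] + c(0, cumsum(ux)); vy <- vy[1] + c(0, cumsum(uy))
          px[a, s] <- mean(vx) %% L; py[a, s] <- mean(vy) %% L
        } else {
          px[a, s] <- mean(vx); py[a, s] <- mean(vy)
        }
      }
    } else {
      px[cbind(ai, si)] <- x$x_um
      py[cbind(ai, si)] <- x$y_um
    }
    strain <- if ("strain_label" %in% names(x))
      x$strain_label[match(agents, x$agent_id)] else rep("WT", length(agents))
    allele <- if ("allele_id" %in% names(x))
      x$allele_id[match(agents, x$agent_id)] else rep(1L, length(agents))
    return(list(times = times, px = px, py = py,
                L = if (is.null(L)) NA_real_ else L,
                strain = strain, allele = allele,
                suppressed = NULL, sim = NULL))
  }
  stop("expected a myxo_sim object or a trajectory data frame")
}

mi_diff <- function(d, L) {
  if (is.na(L)) return(d)
  d - L * round(d / L)
}

#' Detect reversals from centroid tracks
#'
#' A reversal is called when an agent's displacement direction between
#' consecutive snapshots turns by more than `min_angle` and the new
#' direction persists for at least `persist` snapshot intervals.  Intervals
#' with displacement below `min_disp` are treated as stationary and skipped.
#'
#' @param x a `myxo_sim` or trajectory data frame (>= 3 snapshots).
#' @param min_angle direction-change threshold (degrees).
#' @param persist number of subsequent intervals that must stay within 90
#'   degrees of the reversed direction.
#' @param min_disp minimum displacement per interval (um) for a direction
#'   to be defined.
#' @return Data frame of events (`agent`, `time`), ordered by agent then
#'   time.
#' @export
detect_reversals <- function(x, min_angle = 150, persist = 2,
                             min_disp = 0.05) {
  tr <- traj_tracks(x)
  S <- length(tr$times)
  if (S < 3) {
    warning("fewer than 3 snapshots: no reversals detectable")
    return(data.frame(agent = integer(), time = numeric()))
  }
  cosmax <- cos(min_angle * pi / 180)
  out_a <- integer(); out_t <- numeric()
  for (a in seq_len(nrow(tr$px))) {
    dx <- mi_diff(diff(tr$px[a, ]), tr$L)
    dy <- mi_diff(diff(tr$py[a, ]), tr$L)
    dn <- sqrt(dx^2 + dy^2)
    ok <- dn >= min_disp
    # compare each valid interval against the last valid one: the interval
    # containing the turn itself is nearly stationary (displacements cancel)
    # and must not break the comparison chain
    last <- NA_integer_
    k <- 1
    while (k <= S - 1) {
      if (!ok[k]) { k <- k + 1; next }
      if (!is.na(last)) {
        cosang <- (dx[last] * dx[k] + dy[last] * dy[k]) / (dn[last] * dn[k])
        if (cosang < cosmax) {
          # persistence: later intervals stay within 90 deg of new direction
          persists <- TRUE
          upto <- min(S - 1, k + persist - 1)
          for (j in seq(k + 1, length.out = max(0, upto - k))) {
            if (!ok[j]) next
            cj <- (dx[k] * dx[j] + dy[k] * dy[j]) / (dn[k] * dn[j])
            if (cj < 0) { persists <- FALSE; break }
          }
          if (persists) {
            out_a <- c(out_a, a)
            out_t <- c(out_t, (tr$times[last + 1] + tr$times[k]) / 2)
            last <- k
            k <- k + persist      # refractory: do not recall the same event
            next
          }
        }
      }
      last <- k
      k <- k + 1
    }
  }
  data.frame(agent = out_a, time = out_t)
}

# Density-based clustering (DBSCAN) with periodic minimum-image metric.
dbscan_periodic <- function(px, py, L, eps, min_pts) {
  n <- length(px)
  if (n == 0) return(integer(0))
  dx <- outer(px, px, "-"); dy <- outer(py, py, "-")
  if (!is.na(L)) { dx <- dx - L * round(dx / L); dy <- dy - L * round(dy / L) }
  adj <- (dx^2 + dy^2) <= eps^2
  ncount <- rowSums(adj)                 # includes self
  core <- ncount >= min_pts
  labels <- rep(0L, n)                   # 0 = unvisited/noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i; labels[i] <- cl
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[j, ])
      newb <- nb[labels[nb] == 0L]
      labels[newb] <- cl
      queue <- c(queue, newb[core[newb]])
    }
  }
  labels
}

#' Detect circular aggregates
#'
#' Clusters agent centroids with density-based clustering (periodic
#' minimum-image metric), unwraps each cluster across the boundary, and
#' scores its collective rotation.  Two order parameters are computed over
#' the moving members (speed above `min_speed`), writing `p = v_hat . t_hat`
#' for the projection of each member's velocity direction onto the unit
#' tangent about the cluster center:
#' \itemize{
#'   \item `rotational_order = |mean(p)|` -- polar order, high when the
#'     cluster circulates in one direction;
#'   \item `tangential_order = 2 mean(p^2) - 1` -- nematic order, high
#'     whenever motion is tangentially organized, even if traffic runs both
#'     ways around the ring (apolar slime trails carry two-way traffic).
#' }
#' Both are near zero for disordered clumps and for straight streams.  A
#' cluster is called a circular aggregate when either order reaches
#' `order_threshold`; the rotation sense (CCW if the mean cross product
#' `r x v` is positive) is reported when the polar order does.
#'
#' @param x a `myxo_sim` or trajectory data frame, or a data frame with
#'   columns `x`, `y`, `vx`, `vy` (one row per agent) for a single
#'   pre-computed snapshot.
#' @param snapshot snapshot index at which to evaluate (default last).
#' @param velocity_lag number of snapshot intervals over which member
#'   velocities are measured (displacement from `snapshot - velocity_lag`
#'   to `snapshot`).  A few minutes of baseline suppresses positional
#'   jitter while circulating cells keep a near-tangential chord.
#' @param eps clustering neighborhood radius (um).
#' @param min_pts core-point density for the clustering (neighbors within
#'   `eps`, self included); calibrated on ring fixtures so that a swirl of
#'   rod centroids is one cluster while the dilute background is noise.
#' @param min_size minimum cluster size (agents) for a reported aggregate.
#' @param order_threshold rotational order required to call a CA.
#' @param L_sim domain size, only needed for plain `x/y/vx/vy` input.
#' @param min_speed members slower than this (um/min) have no defined
#'   direction of motion and are excluded from the order averages (they
#'   still count as members).
#' @return Data frame with one row per cluster: center, radius (90th
#'   percentile member distance), member count, rotational order,
#'   tangential order, rotation sense (`"CW"`, `"CCW"` or `"none"`), and
#'   `is_ca`.  Member indices are attached as the `members` attribute.
#' @export
detect_aggregates <- function(x, snapshot = NULL, eps = 3, min_pts = 8,
                              min_size = 20, order_threshold = 0.5,
                              min_speed = 0.05, velocity_lag = 1,
                              L_sim = NULL) {
  if (is.data.frame(x) && all(c("x", "y", "vx", "vy") %in% names(x))) {
    px <- x$x; py <- x$y; vx <- x$vx; vy <- x$vy
    L <- if (is.null(L_sim)) NA_real_ else L_sim
    strain <- rep("WT", length(px))
  } else {
    tr <- traj_tracks(x)
    S <- length(tr$times)
    if (is.null(snapshot)) snapshot <- S
    lag <- min(velocity_lag, snapshot - 1)
    if (lag < 1)
      stop("need a preceding snapshot to derive velocities")
    px <- tr$px[, snapshot]; py <- tr$py[, snapshot]
    dt <- tr$times[snapshot] - tr$times[snapshot - lag]
    vx <- mi_diff(px - tr$px[, snapshot - lag], tr$L) / dt
    vy <- mi_diff(py - tr$py[, snapshot - lag], tr$L) / dt
    L <- tr$L
    strain <- tr$strain
  }
  empty <- data.frame(aggregate_id = integer(), center_x = numeric(),
                      center_y = numeric(), radius = numeric(),
                      n_members = integer(), rotational_order = numeric(),
                      tangential_order = numeric(),
                      rotation_sense = character(), is_ca = logical())
  if (length(px) < min_size) return(empty)
  labels <- dbscan_periodic(px, py, L, eps, min_pts)
  ids <- setdiff(unique(labels), 0L)
  if (!length(ids)) return(empty)
  rows <- list(); members <- list()
  for (k in seq_along(ids)) {
    idx <- which(labels == ids[k])
    if (length(idx) < min_size) next
    ux <- px[idx]; uy <- py[idx]
    if (!is.na(L)) {
      # unwrap by minimum image about a provisional centroid, iterate once
      for (it in 1:2) {
        cx <- if (it == 1) ux[1] else mean(ux)
        cy <- if (it == 1) uy[1] else mean(uy)
        ux <- cx + mi_diff(px[idx] - cx, L)
        uy <- cy + mi_diff(py[idx] - cy, L)
      }
    }
    cx <- mean(ux); cy <- mean(uy)
    rx <- ux - cx; ry <- uy - cy
    rr <- sqrt(rx^2 + ry^2)
    vv <- sqrt(vx[idx]^2 + vy[idx]^2)
    use <- rr > 1e-9 & vv >= min_speed
    tang <- (rx * vy[idx] - ry * vx[idx])          # r x v (z component)
    proj <- (tang / (rr * vv))[use]                # v_hat . t_hat (signed)
    ord <- if (length(proj)) abs(mean(proj)) else 0
    nem <- if (length(proj)) 2 * mean(proj^2) - 1 else 0
    sense <- if (ord >= order_threshold)
      if (mean(proj) > 0) "CCW" else "CW"
    else "none"
    rows[[k]] <- data.frame(
      aggregate_id = k,
      center_x = if (is.na(L)) cx else cx %% L,
      center_y = if (is.na(L)) cy else cy %% L,
      radius = unname(quantile(rr, 0.9)),
      n_members = length(idx),
      rotational_order = ord,
      tangential_order = nem,
      rotation_sense = sense,
      is_ca = ord >= order_threshold || nem >= order_threshold)
    members[[k]] <- idx
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  members <- members[!vapply(members, is.null, TRUE)]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  ord_idx <- order(-out$n_members)
  out <- out[ord_idx, , drop = FALSE]
  out$aggregate_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "members") <- members[ord_idx]
  attr(out, "strain") <- strain
  out
}

#' Radial kinematic profile around an aggregate
#'
#' Bins agents by distance to the aggregate center and reports mean linear
#' speed and mean angular speed per ring.  Speeds use centered differences
#' of centroid positions; angular speed is the tangential speed divided by
#' the distance to the center.
#'
#' @param x a `myxo_sim` or trajectory data frame.
#' @param aggregate one row of [detect_aggregates()] output (or a list with
#'   `center_x`, `center_y`, `radius`).
#' @param bin_width ring width (um); 2 for simulated output, 5 matches
#'   experimental-style windows.
#' @param window time window (min) ending at `snapshot` over which samples
#'   are pooled.
#' @param snapshot snapshot index (default last).
#' @param r_max maximum distance from the center (default 1.25 x the
#'   aggregate radius).
#' @return Data frame with `bin_center` (um), `mean_speed` (um/min),
#'   `mean_angular_speed` (rad/min) and `n` per ring; empty rings are
#'   omitted.
#' @export
radial_kinematics <- function(x, aggregate, bin_width = 2, window = 10,
                              snapshot = NULL, r_max = NULL) {
  tr <- traj_tracks(x)
  S <- length(tr$times)
  if (S < 3) stop("need at least 3 snapshots for centered differences")
  if (is.null(snapshot)) snapshot <- S
  cx <- aggregate$center_x[1]; cy <- aggregate$center_y[1]
  if (is.null(r_max)) r_max <- 1.25 * aggregate$radius[1]
  s0 <- max(2, snapshot - ceiling(window / mean(diff(tr$times))))
  rs <- numeric(); sp <- numeric(); om <- numeric()
  for (s in seq(s0, min(snapshot, S - 1))) {
    dtc <- tr$times[s + 1] - tr$times[s - 1]
    vx <- mi_diff(tr$px[, s + 1] - tr$px[, s - 1], tr$L) / dtc
    vy <- mi_diff(tr$py[, s + 1] - tr$py[, s - 1], tr$L) / dtc
    rx <- mi_diff(tr$px[, s] - cx, tr$L)
    ry <- mi_diff(tr$py[, s] - cy, tr$L)
    rr <- sqrt(rx^2 + ry^2)
    keep <- rr <= r_max & rr > 1e-9
    rs <- c(rs, rr[keep])
    sp <- c(sp, sqrt(vx[keep]^2 + vy[keep]^2))
    tangential <- abs(rx[keep] * vy[keep] - ry[keep] * vx[keep]) / rr[keep]
    om <- c(om, tangential / rr[keep])
  }
  if (!length(rs))
    return(data.frame(bin_center = numeric(), mean_speed = numeric(),
                      mean_angular_speed = numeric(), n = integer()))
  bin <- floor(rs / bin_width)
  out <- data.frame(
    bin_center = (sort(unique(bin)) + 0.5) * bin_width,
    mean_speed = as.numeric(tapply(sp, bin, mean)),
    mean_angular_speed = as.numeric(tapply(om, bin, mean)),
    n = as.integer(table(bin)))
  rownames(out) <- NULL
  out
}

#' Contact-suppression summaries
#'
#' @param sim a `myxo_sim` (requires the engine's bond log).
#' @param window window before the end of the run (min) over which broken
#'   bond lifetimes are averaged.
#' @return A list: `suppressed_fraction_end` (fraction of agents with at
#'   least one bond older than `tau_thr` at the final snapshot),
#'   `mean_bond_lifetime` (mean lifetime of bonds that broke within the
#'   final `window` minutes; `NaN` if none broke) and `n_bonds_broken`.
#' @export
suppression_stats <- function(sim, window = 10) {
  if (!inherits(sim, "myxo_sim") || is.null(sim$bonds))
    stop("bond statistics need a myxo_sim with its bond log; ",
         "run the simulation with myxo_run()")
  S <- ncol(sim$suppressed)
  t_end <- max(sim$times)
  b <- sim$bonds
  recent <- !is.na(b$broke) & b$broke >= t_end - window
  list(
    suppressed_fraction_end = mean(sim$suppressed[, S]),
    mean_bond_lifetime = if (any(recent)) mean(b$lifetime[recent]) else NaN,
    n_bonds_broken = sum(recent))
}
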