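#' Run a simulation
#'
#' Integrates the agent population forward with overdamped node dynamics:
#' at every step the engine updates adhesion bonds, assembles propulsion
#' (with turn- and slime-adjusted head steering), bending, substrate-spring,
#' collision-repulsion and adhesion forces, moves each node by
#' `force / c * dt`, re-projects node spacings onto `L/(N-1)`, wraps
#' coordinates into the periodic domain, deposits slime under tail nodes and
#' advances the reversal and turn clocks.  A run is a pure function of
#' `(cfg, seed)`: repeated calls return bit-identical trajectories.
#'
#' @param cfg a [myxo_config()].
#' @param seed integer seed for the engine's private random stream.
#' @param init optional explicit initial state from [myxo_init_state()],
#'   bypassing random placement (used for small, controlled fixtures).
#' @param verbose print a one-line summary when done.
#' @return An object of class `myxo_sim` with components
#'   \describe{
#'     \item{times}{snapshot times (min)}
#'     \item{x, y}{node coordinate matrices, `(M*N)` rows (agent-major) by
#'       one column per snapshot, wrapped into `[0, L_sim)`}
#'     \item{head}{`M x S` matrix of head node indices (0 or `N-1`)}
#'     \item{clock}{`M x S` matrix of reversal-clock values (min)}
#'     \item{suppressed}{`M x S` logical matrix: agent had at least one
#'       bond older than `tau_thr` at that snapshot}
#'     \item{strain, allele}{per-agent labels}
#'     \item{events}{data frame of engine-logged reversals (agent, time)}
#'     \item{bonds}{data frame of adhesion bond lifetimes (type, formed,
#'       broke, lifetime); bonds alive at the end have `broke = NA`}
#'     \item{slime}{final slime grid (orientation in `[0, pi)`, last deposit
#'       time, `NA` where never visited)}
#'   }
#' @examples
#' cfg <- myxo_config(L_sim = 30, run_duration = 10,
#'                    strains = data.frame(strain = "NR", allele = 1L,
#'                                         fraction = 1))
#' sim <- myxo_run(cfg, seed = 1)
#' sim
#' @export
myxo_run <- function(cfg, seed = 1L, init = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "myxo_config"))
  ecfg <- unclass(cfg)
  ecfg$omega_s_rad <- cfg$omega_s * pi / 180
  ecfg$turn_curvature <- cfg$turn_curvature * pi / 180
  ecfg$agent_pair_counts <- identical(cfg$suppression_count, "agent")
  ecfg$composition <- list(
    strain_code = .strain_codes[as.character(cfg$strains$strain)],
    allele = as.integer(cfg$strains$allele),
    fraction = as.numeric(cfg$strains$fraction))
  ecfg$init <- init
  res <- run_engine(ecfg, as.integer(seed))
  G <- res$slime_dim
  slt <- matrix(res$slime_time, G, G, byrow = TRUE)
  slt[slt < 0] <- NA_real_
  slo <- matrix(res$slime_orientation, G, G, byrow = TRUE)
  slo[is.na(slt)] <- NA_real_
  bonds <- data.frame(
    agent_a = res$bond_agent_a, agent_b = res$bond_agent_b,
    type = c("lateral", "end_end")[res$bond_type + 1L],
    formed = res$bond_formed, broke = res$bond_broke)
  bonds$lifetime <- bonds$broke - bonds$formed
  sim <- structure(list(
    cfg = cfg, seed = as.integer(seed),
    times = res$times, x = res$x, y = res$y,
    head = res$head, clock = res$clock, suppressed = res$suppressed,
    strain = .strain_label(res$strain_code), allele = res$allele,
    M = res$M, N = res$N,
    events = data.frame(agent = res$reversal_agent, time = res$reversal_time),
    bonds = bonds,
    slime = list(orientation = slo, time = slt, cell_size = cfg$L_sim / G)),
    class = "myxo_sim")
  if (verbose)
    cat(sprintf("run complete: %d agents, %d snapshots, %d reversals\n",
                sim$M, length(sim$times), nrow(sim$events)))
  sim
}

#' Explicit initial state for controlled fixtures
#'
#' Places straight agents at given centers and orientations, bypassing the
#' random rejection-sampling initialization.  Node `N-1` of each agent lies
#' on the `+theta` side of its center.
#'
#' @param x,y agent center coordinates (um).
#' @param theta agent orientation (rad).
#' @param head 1 if the head is the node on the `+theta` end (the agent
#'   glides toward `+theta`), 0 for the opposite end.
#' @param strain,allele per-agent labels (recycled).
#' @param clock optional initial reversal-clock values (default: staggered
#'   randomly like the standard initializer).
#' @param turn_timer optional initial turn-timer values.
#' @return A list suitable for `myxo_run(init = ...)`.
#' @export
myxo_init_state <- function(x, y, theta, head = 1L, strain = "OE",
                            allele = 1L, clock = NULL, turn_timer = NULL) {
  M <- length(x)
  strain <- rep_len(strain, M)
  if (!all(strain %in% names(.strain_codes)))
    stop("unknown strain label; use WT, OE or NR")
  out <- list(x = as.numeric(x), y = as.numeric(y),
              theta = as.numeric(theta),
              head = as.integer(rep_len(head, M)),
              strain_code = unname(.strain_codes[strain]),
              allele = as.integer(rep_len(allele, M)))
  if (!is.null(clock)) out$clock <- as.numeric(rep_len(clock, M))
  if (!is.null(turn_timer)) out$turn_timer <- as.numeric(rep_len(turn_timer, M))
  out
}

#' @export
print.myxo_sim <- function(x, ...) {
  cat(sprintf("Gliding-agent simulation: %d agents x %d snapshots (t = %g..%g min)\n",
              x$M, length(x$times), min(x$times), max(x$times)))
  comp <- table(x$strain)
  cat("  strains  :", paste(sprintf("%s %d", names(comp), comp), collapse = ", "), "\n")
  cat(sprintf("  reversals: %d logged events\n", nrow(x$events)))
  sup <- mean(x$suppressed[, ncol(x$suppressed)])
  cat(sprintf("  suppressed at end: %.1f%% of agents\n", 100 * sup))
  invisible(x)
}

#' @export
summary.myxo_sim <- function(object, ...) {
  S <- length(object$times)
  cen <- agent_centroids(object, S)
  spd <- if (S >= 2) {
    p0 <- agent_centroids(object, S - 1)
    d <- pmin(abs(cen - p0), object$cfg$L_sim - abs(cen - p0))
    sqrt(rowSums(d^2)) / diff(object$times[(S - 1):S])
  } else NA_real_
  structure(list(
    M = object$M, n_snapshots = S, duration = max(object$times),
    strains = table(object$strain),
    n_reversals = nrow(object$events),
    mean_speed_end = mean(spd),
    suppressed_fraction_end = mean(object$suppressed[, S]),
    n_bonds_logged = nrow(object$bonds)),
    class = "summary.myxo_sim")
}

#' @export
print.summary.myxo_sim <- function(x, ...) {
  cat(sprintf("%d agents, %d snapshots over %g min\n", x$M, x$n_snapshots,
              x$duration))
  cat("strains:", paste(sprintf("%s %d", names(x$strains), x$strains),
                        collapse = ", "), "\n")
  cat(sprintf("reversal events: %d\n", x$n_reversals))
  cat(sprintf("mean speed over final interval: %.3f um/min\n", x$mean_speed_end))
  cat(sprintf("suppressed fraction at end: %.3f\n", x$suppressed_fraction_end))
  cat(sprintf("adhesion bonds logged: %d\n", x$n_bonds_logged))
  invisible(x)
}

#' Agent centroids at a snapshot
#'
#' Unwraps each agent's node chain across the periodic boundary (minimum
#' image along the chain) before averaging, then wraps the centroid back
#' into the domain.
#'
#' @param sim a `myxo_sim`.
#' @param snapshot snapshot index (1-based; default last).
#' @return `M x 2` matrix of centroid coordinates in `[0, L_sim)`.
#' @export
agent_centroids <- function(sim, snapshot = length(sim$times)) {
  cen <- centroid_matrix(sim$x[, snapshot, drop = FALSE],
                         sim$y[, snapshot, drop = FALSE],
                         sim$N, sim$cfg$L_sim)
  cbind(x = cen$px[, 1], y = cen$py[, 1])
}

# Centroids for all requested snapshots at once: unwrap each agent chain by
# minimum image along the chain, average, wrap back.  Returns M x S matrices.
centroid_matrix <- function(X, Y, N, L) {
  S <- ncol(X)
  M <- nrow(X) %/% N
  un <- function(mat) {
    m <- matrix(mat, nrow = N)              # N x (M*S), agent-major columns
    dv <- m[-1, , drop = FALSE] - m[-N, , drop = FALSE]
    dv <- dv - L * round(dv / L)
    cum <- dv
    if (N > 2)
      for (i in 2:(N - 1)) cum[i, ] <- cum[i - 1, ] + dv[i, ]
    cen <- (m[1, ] + colSums(rbind(0, cum)) / N) %% L
    matrix(cen, nrow = M)
  }
  list(px = un(X), py = un(Y))
}

#' Long-format trajectory table
#'
#' One row per node per snapshot with the columns `time_min`, `agent_id`,
#' `node_index`, `x_um`, `y_um`, `head_flag`, `reversal_clock_min`,
#' `suppressed_flag`, `strain_label`, `allele_id`.
#'
#' @param x a `myxo_sim`.
#' @param row.names,optional,... ignored (S3 signature).
#' @export
as.data.frame.myxo_sim <- function(x, row.names = NULL, optional = FALSE, ...) {
  S <- length(x$times)
  M <- x$M; N <- x$N
  agent <- rep(seq_len(M), each = N)
  node <- rep(seq_len(N) - 1L, times = M)
  data.frame(
    time_min = rep(x$times, each = M * N),
    agent_id = rep(agent, S),
    node_index = rep(node, S),
    x_um = as.vector(x$x),
    y_um = as.vector(x$y),
    head_flag = as.integer(rep(as.vector(x$head), each = N) == rep(node, S)),
    reversal_clock_min = rep(as.vector(x$clock), each = N),
    suppressed_flag = as.integer(rep(as.vector(x$suppressed), each = N)),
    strain_label = rep(rep(x$strain, each = N), S),
    allele_id = rep(rep(x$allele, each = N), S))
}

#' Write / read a trajectory table
#'
#' Tab-separated text with the canonical trajectory columns (see
#' [as.data.frame.myxo_sim()]).  `read_trajectory()` returns the table with
#' the domain size attached as attribute `L_sim` when present in the header
#' comment.
#'
#' @param sim a `myxo_sim` or a trajectory data frame.
#' @param file output path.
#' @export
write_trajectory <- function(sim, file) {
  df <- if (inherits(sim, "myxo_sim")) as.data.frame(sim) else sim
  con <- file(file, "w")
  on.exit(close(con))
  if (inherits(sim, "myxo_sim"))
    writeLines(sprintf("# L_sim=%g N=%d", sim$cfg$L_sim, sim$N), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(file) {
  first <- readLines(file, n = 1)
  Ls <- NA_real_
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("L_sim=([0-9.]+)", first))[[1]]
    if (length(m) == 2) Ls <- as.numeric(m[2])
  }
  df <- read.table(file, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  attr(df, "L_sim") <- Ls
  df
}

#' Render a snapshot
#'
#' Draws every agent as its node chain, colored by reversal-suppression
#' state (suppressed blue, active red) or by strain label.
#'
#' @param x a `myxo_sim`.
#' @param snapshot snapshot index (default last).
#' @param color_by `"suppression"` or `"strain"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.myxo_sim <- function(x, snapshot = length(x$times),
                          color_by = c("suppression", "strain"), ...) {
  color_by <- match.arg(color_by)
  L <- x$cfg$L_sim; N <- x$N
  xs <- matrix(x$x[, snapshot], nrow = N)
  ys <- matrix(x$y[, snapshot], nrow = N)
  cols <- if (color_by == "suppression") {
    ifelse(x$suppressed[, snapshot], "blue3", "red3")
  } else {
    c(WT = "red3", OE = "green4", NR = "blue3")[x$strain]
  }
  graphics::plot(NA, xlim = c(0, L), ylim = c(0, L), asp = 1,
                 xlab = "x (um)", ylab = "y (um)",
                 main = sprintf("t = %.0f min", x$times[snapshot]), ...)
  for (a in seq_len(x$M)) {
    vx <- xs[, a]; vy <- ys[, a]
    # split the polyline where it wraps around the boundary
    br <- which(abs(diff(vx)) > L / 2 | abs(diff(vy)) > L / 2)
    idx <- split(seq_len(N), findInterval(seq_len(N), br + 1L))
    for (seg in idx)
      if (length(seg) > 1)
        graphics::lines(vx[seg], vy[seg], col = cols[a], lwd = 2)
      else
        graphics::points(vx[seg], vy[seg], col = cols[a], pch = 16, cex = 0.3)
  }
  invisible(x)
}

#' Pairwise interaction forces for an explicit configuration
#'
#' Computes the adhesion-bond and excluded-volume repulsion forces the
#' engine would apply to a static node configuration.  `method = "hash"`
#' uses the production spatially indexed path, `method = "all_pairs"` the
#' brute-force double loop; both must agree exactly.
#'
#' @param cfg a [myxo_config()].
#' @param pos `(M*N) x 2` node coordinate matrix (agent-major).
#' @param heads per-agent head node index (0 or `N-1`).
#' @param strain,allele per-agent labels (recycled).
#' @param method spatial indexing or brute force.
#' @return `(M*N) x 2` force matrix (pN).
#' @export
interaction_forces <- function(cfg, pos, heads, strain = "OE", allele = 1L,
                               method = c("hash", "all_pairs")) {
  method <- match.arg(method)
  M <- length(heads)
  strain <- rep_len(strain, M)
  ecfg <- unclass(cfg)
  ecfg$omega_s_rad <- cfg$omega_s * pi / 180
  ecfg$turn_curvature <- cfg$turn_curvature * pi / 180
  ecfg$agent_pair_counts <- FALSE
  interaction_forces_engine(ecfg, pos, as.integer(heads),
                            unname(.strain_codes[strain]),
                            as.integer(rep_len(allele, M)),
                            method == "all_pairs")
}
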