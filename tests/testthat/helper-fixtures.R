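# Shared fixtures.  Expensive population runs are cached per test session so
# that several test files can score the same trajectories.

.sim_cache <- new.env(parent = emptyenv())

cached_run <- function(key, cfg, seed) {
  id <- paste0(key, "_", seed)
  if (is.null(.sim_cache[[id]]))
    .sim_cache[[id]] <- myxo_run(cfg, seed = seed)
  .sim_cache[[id]]
}

# single-strain population config at a reduced scale
pop_cfg <- function(strain = "OE", L_sim = 50, run_duration = 250, ...) {
  myxo_config(L_sim = L_sim, run_duration = run_duration,
              strains = data.frame(strain = strain, allele = 1L,
                                   fraction = 1), ...)
}

# two straight agents in a controlled geometry, everything stochastic off
duo_cfg <- function(run_duration = 1, L_sim = 30, ...) {
  myxo_config(L_sim = L_sim, run_duration = run_duration, tau_r = Inf,
              tau_t = Inf, slime_following = FALSE, ...)
}

# minimum distance between two agents' capsule segments at a snapshot
min_capsule_gap <- function(sim, snapshot = 1) {
  N <- sim$N; L <- sim$cfg$L_sim
  xs <- matrix(sim$x[, snapshot], nrow = N)
  ys <- matrix(sim$y[, snapshot], nrow = N)
  segdist <- function(p1, q1, p2, q2) {
    # dense sampling fallback oracle (independent of the engine's algebra)
    s <- seq(0, 1, length.out = 9)
    a <- cbind(p1[1] + s * (q1[1] - p1[1]), p1[2] + s * (q1[2] - p1[2]))
    b <- cbind(p2[1] + s * (q2[1] - p2[1]), p2[2] + s * (q2[2] - p2[2]))
    min(sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2))
  }
  mind <- Inf
  M <- sim$M
  for (a in seq_len(M - 1)) for (b in (a + 1):M) {
    for (i in seq_len(N - 1)) for (j in seq_len(N - 1)) {
      # bring b's segment into a's frame by minimum image of midpoints
      p1 <- c(xs[i, a], ys[i, a]); q1 <- c(xs[i + 1, a], ys[i + 1, a])
      p2 <- c(xs[j, b], ys[j, b]); q2 <- c(xs[j + 1, b], ys[j + 1, b])
      q1 <- p1 + ((q1 - p1) - L * round((q1 - p1) / L))   # unwrap segments
      q2 <- p2 + ((q2 - p2) - L * round((q2 - p2) / L))
      m1 <- (p1 + q1) / 2; m2 <- (p2 + q2) / 2
      sh <- (m2 - m1) - L * round((m2 - m1) / L) - (m2 - m1)
      mind <- min(mind, segdist(p1, q1, p2 + sh, q2 + sh))
    }
  }
  mind
}
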