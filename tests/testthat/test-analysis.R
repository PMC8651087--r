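test_that("mean reversal interval converts tracking counts to hours", {
  expect_equal(mean_reversal_interval(443, 60, 12), 443 * 60 / 12 / 60)
  expect_equal(mean_reversal_interval(443, 60, 12), 36.9, tolerance = 0.002)
  expect_equal(mean_reversal_interval(1, 60, 2), 0.5)
  expect_equal(mean_reversal_interval(10, 80, 1), 13.33, tolerance = 1e-3)
  expect_warning(out <- mean_reversal_interval(10, 60, 0), "no reversals")
  expect_identical(out, Inf)
  expect_error(mean_reversal_interval(0, 60, 1))
})

# helper: long-format track table from per-agent position functions
synth_traj <- function(fx, fy, times, n_agents = length(fx)) {
  do.call(rbind, lapply(seq_len(n_agents), function(a)
    data.frame(time_min = times, agent_id = a,
               x_um = fx[[a]](times), y_um = fy[[a]](times))))
}

test_that("reversal detection on constructed tracks", {
  times <- 0:60
  # straight constant-velocity track: no events
  tr <- synth_traj(list(function(t) 10 + 0.3 * t),
                   list(function(t) rep(5, length(t))), times)
  expect_equal(nrow(detect_reversals(tr)), 0)
  # scripted 180-degree turn at t = 30: exactly one event at 30 +- 1
  tr2 <- synth_traj(list(function(t) 10 + 0.3 * pmin(t, 30) -
                           0.3 * pmax(t - 30, 0)),
                    list(function(t) rep(5, length(t))), times)
  ev <- detect_reversals(tr2)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$time, 30, tolerance = 1)
  # a 90-degree turn is not a reversal
  tr3 <- synth_traj(list(function(t) 10 + 0.3 * pmin(t, 30)),
                    list(function(t) 5 + 0.3 * pmax(t - 30, 0)), times)
  expect_equal(nrow(detect_reversals(tr3)), 0)
  # too-short trajectories warn and return nothing
  expect_warning(out <- detect_reversals(tr[tr$time_min < 2, ]), "snapshots")
  expect_equal(nrow(out), 0)
})

test_that("reversal detector recovers engine-logged events in dilute runs", {
  # dilute WT population: reversals are the only direction changes > 150 deg
  cfg <- myxo_config(L_sim = 60, eta = 0.003, run_duration = 60,
                     tau_t = Inf,
                     strains = data.frame(strain = "WT", allele = 1L,
                                          fraction = 1))
  sim <- myxo_run(cfg, seed = 21)
  truth <- sim$events
  expect_gt(nrow(truth), 10)
  found <- detect_reversals(sim)
  # detectability: an agent stalled against a neighbor shows no centroid
  # displacement, so its reversal is invisible to any track-based detector;
  # require both flanking intervals to carry measurable motion
  S <- length(sim$times)
  pos <- lapply(seq_len(S), function(s) agent_centroids(sim, s))
  moving <- function(a, tt) {
    k <- findInterval(tt, sim$times)
    ks <- c(max(1, k - 1), min(S - 1, k + 1))
    all(vapply(ks, function(kk) {
      d <- pos[[kk + 1]][a, ] - pos[[kk]][a, ]
      d <- d - 60 * round(d / 60)
      sqrt(sum(d^2)) >= 0.05
    }, logical(1)))
  }
  # events in the last snapshots have no room to establish the reversed
  # direction; exclude them along with stalled-agent events
  in_window <- truth$time >= sim$times[2] + 1 &
    truth$time <= sim$times[S] - 2.5
  detectable <- in_window & vapply(seq_len(nrow(truth)), function(k)
    moving(truth$agent[k], truth$time[k]), logical(1))
  expect_gt(sum(detectable), 10)
  hit <- vapply(which(detectable), function(k) {
    f <- found[found$agent == truth$agent[k], "time"]
    length(f) > 0 && any(abs(f - truth$time[k]) <= 1.5)
  }, logical(1))
  expect_gte(mean(hit), 0.99)
  # no spurious extra events
  expect_lte(nrow(found), nrow(truth) * 1.05 + 1)
  # zero false positives on nonreversing agents
  cfgn <- myxo_config(L_sim = 60, eta = 0.003, run_duration = 60,
                      tau_t = Inf,
                      strains = data.frame(strain = "NR", allele = 1L,
                                           fraction = 1))
  simn <- myxo_run(cfgn, seed = 21)
  expect_equal(nrow(simn$events), 0)
  expect_equal(nrow(detect_reversals(simn)), 0)
})

ring_fixture <- function(n = 200, radius = 10, center = c(25, 25),
                         sense = 1, speed = 0.3, jitter = 0) {
  set.seed(99)
  th <- sort(runif(n, 0, 2 * pi))
  r <- radius * sqrt(runif(n, 0.1, 1))
  x <- center[1] + r * cos(th) + rnorm(n, 0, jitter)
  y <- center[2] + r * sin(th) + rnorm(n, 0, jitter)
  data.frame(x = x, y = y,
             vx = -sense * speed * sin(th), vy = sense * speed * cos(th))
}

test_that("aggregate detection scores rotating rings and rejects noise", {
  ring <- ring_fixture(sense = 1)
  agg <- detect_aggregates(ring, L_sim = 50)
  expect_equal(nrow(agg), 1)
  expect_true(agg$is_ca)
  expect_equal(agg$rotation_sense, "CCW")
  expect_gt(agg$rotational_order, 0.95)
  expect_equal(agg$center_x, 25, tolerance = 1)
  expect_lt(agg$radius, 10.5)
  # clockwise ring
  cw <- detect_aggregates(ring_fixture(sense = -1), L_sim = 50)
  expect_equal(cw$rotation_sense, "CW")
  # uniform random positions and headings: no cluster passes as a CA
  set.seed(3)
  noise <- data.frame(x = runif(300, 0, 50), y = runif(300, 0, 50),
                      vx = rnorm(300), vy = rnorm(300))
  aggn <- detect_aggregates(noise, L_sim = 50)
  if (nrow(aggn)) expect_true(all(aggn$rotational_order < 0.3))
  # empty input
  empty <- detect_aggregates(data.frame(x = numeric(), y = numeric(),
                                        vx = numeric(), vy = numeric()),
                             L_sim = 50)
  expect_equal(nrow(empty), 0)
})

test_that("aggregate detection is invariant to translation and wrapping", {
  ring <- ring_fixture()
  base <- detect_aggregates(ring, L_sim = 50)
  # translate so the ring straddles the periodic boundary
  shifted <- ring
  shifted$x <- (ring$x + 24) %% 50
  shifted$y <- (ring$y + 24) %% 50
  agg <- detect_aggregates(shifted, L_sim = 50)
  expect_equal(nrow(agg), 1)
  expect_equal(agg$n_members, base$n_members)
  expect_equal(agg$rotational_order, base$rotational_order, tolerance = 1e-6)
  expect_equal(agg$radius, base$radius, tolerance = 1e-6)
  expect_equal((agg$center_x - 24) %% 50, base$center_x, tolerance = 0.5)
})

test_that("radial kinematics distinguish rigid rotation from spiral flow", {
  # rigid-body disc: angular speed flat, linear speed ~ distance
  times <- 0:20
  om <- 0.05
  n <- 120
  set.seed(5)
  r0 <- 20 * sqrt(runif(n)); th0 <- runif(n, 0, 2 * pi)
  tr <- do.call(rbind, lapply(seq_len(n), function(a)
    data.frame(time_min = times, agent_id = a,
               x_um = 50 + r0[a] * cos(th0[a] + om * times),
               y_um = 50 + r0[a] * sin(th0[a] + om * times))))
  agg <- list(center_x = 50, center_y = 50, radius = 20)
  prof <- radial_kinematics(tr, agg, bin_width = 2, window = 10)
  expect_gt(nrow(prof), 5)
  expect_equal(prof$mean_angular_speed, rep(om, nrow(prof)),
               tolerance = 0.02)
  fit <- coef(lm(prof$mean_speed ~ prof$bin_center))
  expect_equal(unname(fit[2]), om, tolerance = 0.005)  # v = om * r
  # constant-linear-speed spiral: angular speed ~ v / r
  v <- 0.5
  tr2 <- do.call(rbind, lapply(seq_len(n), function(a) {
    th <- th0[a] + v * times / r0[a]
    data.frame(time_min = times, agent_id = a,
               x_um = 50 + r0[a] * cos(th),
               y_um = 50 + r0[a] * sin(th))
  }))
  prof2 <- radial_kinematics(tr2, agg, bin_width = 2, window = 10)
  keep <- prof2$bin_center > 4
  expect_equal(prof2$mean_angular_speed[keep] * prof2$bin_center[keep],
               rep(v, sum(keep)), tolerance = 0.1)
})

test_that("suppression summaries report fractions and bond lifetimes", {
  # adhesion disabled: no bonds, nothing suppressed
  simz <- cached_run("noadh_small",
                     pop_cfg("OE", L_sim = 30, run_duration = 20,
                             k_adh_oe = 0, k_adh_wt = 0, k_adh_cross = 0), 1)
  st <- suppression_stats(simz)
  expect_equal(st$suppressed_fraction_end, 0)
  expect_equal(st$n_bonds_broken, 0)
  # permanent end-end contact: both agents suppressed after tau_thr
  cfg <- duo_cfg(run_duration = 7, L_sim = 40)
  init <- myxo_init_state(x = c(16, 23.2), y = c(20, 20), theta = c(0, 0),
                          head = c(1, 1), strain = "OE", clock = 0,
                          turn_timer = 0)
  sim <- myxo_run(cfg, init = init, seed = 1)
  st2 <- suppression_stats(sim)
  expect_equal(st2$suppressed_fraction_end, 1)
  expect_error(suppression_stats(data.frame()), "bond")
})
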