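cfg0 <- myxo_config()

test_that("adhesion force follows the piecewise bond law", {
  expect_equal(adhesion_force(0.5, 0.1, cfg0, "lateral"), 0)   # d = w
  expect_equal(adhesion_force(1.6, 0.1, cfg0, "end_end"), 0)   # past reach
  expect_equal(adhesion_force(1.0, 0.1, cfg0, "lateral"), 0)   # lateral reach 0.9
  expect_equal(adhesion_force(0.7, 0.1, cfg0, "lateral"), 2.2)
  expect_equal(adhesion_force(1.0, 0.1, cfg0, "end_end"), 5.5)
  expect_equal(adhesion_force(0.7, 0.01, cfg0, "lateral"), 0.22)
  expect_equal(adhesion_force(0.2, 0.1, cfg0, "lateral"), 0)   # inside contact
})

test_that("reversal clock advances, freezes, rewinds and fires", {
  dt <- cfg0$dt
  # free agent: advances by exactly dt
  expect_equal(reversal_clock_update(1, 0, 0, dt, cfg0)$r, 1 + dt)
  # at the period: fires and resets
  up <- reversal_clock_update(8, 0, 0, dt, cfg0)
  expect_true(up$fired); expect_equal(up$r, 0)
  # one active end-end bond freezes the clock (dR_e = 1)
  expect_equal(reversal_clock_update(3, 1, 0, dt, cfg0)$r, 3)
  # one active lateral bond slows it to 0.96 dt
  expect_equal(reversal_clock_update(3, 0, 1, dt, cfg0)$r, 3 + 0.96 * dt)
  # two end-end bonds rewind, floored at zero
  expect_equal(reversal_clock_update(0.001, 2, 0, dt, cfg0)$r,
               max(0.001 - dt, 0))
  expect_equal(reversal_clock_update(0.001, 2, 0, dt, cfg0)$r, 0)
  expect_error(reversal_clock_update(1, -1, 0, dt, cfg0), "non-negative")
})

test_that("R clock recursion matches the engine's over a scripted timeline", {
  # 1,000 steps with a scripted contact history exercising all regimes
  set.seed(7)
  n_ee <- sample(0:2, 1000, replace = TRUE, prob = c(0.7, 0.2, 0.1))
  n_lat <- sample(0:30, 1000, replace = TRUE)
  r_ref <- 0.5; r_eng <- 0.5
  for (k in 1:1000) {
    a <- reversal_clock_update(r_ref, n_ee[k], n_lat[k], cfg0$dt, cfg0)
    b <- clock_update_engine(r_eng, n_ee[k], n_lat[k], cfg0$dt,
                             cfg0$tau_r, cfg0$dR_e, cfg0$dR_l)
    expect_identical(a$fired, b$fired)
    r_ref <- a$r; r_eng <- b$r
    if (abs(r_ref - r_eng) > 0) break
  }
  expect_identical(r_ref, r_eng)
})

test_that("an isolated agent reverses at the reversal period", {
  cfg <- myxo_config(L_sim = 40, run_duration = 25, tau_r = 8, tau_t = Inf,
                     slime_following = FALSE)
  init <- myxo_init_state(x = 20, y = 20, theta = 0, head = 1,
                          strain = "WT", clock = 0, turn_timer = 0)
  sim <- myxo_run(cfg, init = init, seed = 3)
  ev <- sim$events$time
  expect_equal(length(ev), 3)                       # t ~ 8, 16, 24
  expect_equal(ev[1], 8, tolerance = 3 * cfg$dt)
  expect_true(all(abs(diff(ev) - 8) <= 3 * cfg$dt))
  # displacement direction flips at the reversal
  tr <- traj <- sapply(seq_along(sim$times), function(s)
    agent_centroids(sim, s)[1])
  expect_gt(tr[8] - tr[1], 0)                       # moving +x before t=8
  expect_lt(tr[16] - tr[9], 0)                      # moving -x after
})

test_that("nonreversing agents log no reversals and clocks stay floored", {
  sim <- cached_run("nr_small",
                    pop_cfg("NR", L_sim = 30, run_duration = 30,
                            k_adh_wt = 0.1), 1)
  expect_equal(nrow(sim$events), 0)
  expect_true(all(sim$clock == 0))
  # clock bounded by tau_r + dt in a reversing crowded run
  simw <- cached_run("wt_small",
                     pop_cfg("WT", L_sim = 30, run_duration = 30), 1)
  expect_true(all(simw$clock >= 0))
  expect_true(all(simw$clock <= simw$cfg$tau_r + simw$cfg$dt))
  expect_gt(nrow(simw$events), 0)
})

test_that("bonds form by type, break past reach, and age resets on break", {
  # end-end: leader-follower convoy at gap 1.2, bond persists and ages
  cfg <- duo_cfg(run_duration = 7, L_sim = 40,
                 strains = data.frame(strain = "OE", allele = 1L,
                                      fraction = 1))
  init <- myxo_init_state(x = c(16, 23.2), y = c(20, 20), theta = c(0, 0),
                          head = c(1, 1), strain = "OE", clock = 0,
                          turn_timer = 0)
  sim <- myxo_run(cfg, init = init, seed = 1)
  live <- sim$bonds[is.na(sim$bonds$broke), ]
  expect_true(any(live$type == "end_end"))
  expect_gt(max(sim$times) - min(live$formed), 5)   # aged past tau_thr
  # both agents flagged suppressed once the bond is older than tau_thr
  S <- length(sim$times)
  expect_true(all(sim$suppressed[, S]))
  expect_false(any(sim$suppressed[, 2]))            # not before the gate

  # lateral: parallel WT x OE pair at 0.7 um forms a (weak) lateral bond
  cfg2 <- duo_cfg(run_duration = 1, L_sim = 40)
  init2 <- myxo_init_state(x = c(20, 20), y = c(20, 20.7), theta = c(0, 0),
                           head = c(1, 1), strain = c("WT", "OE"),
                           clock = 0, turn_timer = 0)
  sim2 <- myxo_run(cfg2, init = init2, seed = 1)
  expect_true(any(sim2$bonds$type == "lateral"))

  # weakly adhering parallel agents on diverging headings: lateral bonds
  # break once node distances pass the lateral reach, with logged lifetimes
  init3 <- myxo_init_state(x = c(20, 20), y = c(20, 20.7),
                           theta = c(0, 0.25), head = c(1, 1),
                           strain = "WT", clock = 0, turn_timer = 0)
  sim3 <- myxo_run(duo_cfg(run_duration = 4, L_sim = 40), init = init3,
                   seed = 1)
  broken <- sim3$bonds[!is.na(sim3$bonds$broke), ]
  expect_gt(nrow(broken), 0)
  expect_true(all(broken$lifetime >= 0))
  expect_true(all(broken$lifetime < 4))

  # incompatible alleles: no bonds at all
  init4 <- myxo_init_state(x = c(20, 20), y = c(20, 20.7), theta = c(0, 0),
                           head = c(1, 1), strain = "OE", allele = c(1L, 2L),
                           clock = 0, turn_timer = 0)
  sim4 <- myxo_run(cfg2, init = init4, seed = 1)
  expect_equal(nrow(sim4$bonds), 0)
})

test_that("bond-age gating: tau_thr = 0 suppresses immediately", {
  mkcfg <- function(tthr) duo_cfg(run_duration = 2, L_sim = 40,
                                  snapshot_interval = 0.5, tau_thr = tthr,
                                  strains = data.frame(strain = "OE",
                                                       allele = 1L,
                                                       fraction = 1))
  init <- myxo_init_state(x = c(16, 23.2), y = c(20, 20), theta = c(0, 0),
                          head = c(1, 1), strain = "OE", clock = 0,
                          turn_timer = 0)
  fast <- myxo_run(mkcfg(0), init = init, seed = 1)
  slow <- myxo_run(mkcfg(5), init = init, seed = 1)
  S <- length(fast$times)
  expect_true(all(fast$suppressed[, S]))            # immediate gate
  expect_false(any(slow$suppressed[, S]))           # 2 min < 5 min
})
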