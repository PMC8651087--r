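#' Simulation configuration
#'
#' Builds the full parameter set for a gliding-agent simulation.  Defaults
#' reproduce the reference parameterization of the model: 6-um flexible rods
#' of 7 nodes gliding at ~0.36 um/min on a 200 x 200 um periodic domain at a
#' density of 0.074 agents/um^2, with an 8-min reversal clock, 90-degree
#' random turns every 5 min, slime-trail following, and contact-mediated
#' reversal suppression gated by a 5-min bond-age threshold.
#'
#' Units are micrometres (um), minutes (min) and piconewtons (pN) throughout.
#'
#' @param L agent length (um).
#' @param w agent width (um); also the collision diameter of the capsule.
#' @param m agent mass (kg).  Documentary only: the dynamics are overdamped
#'   (inertia is negligible at these scales), so mass never enters the update.
#' @param N number of nodes per agent.
#' @param k_b angular spring constant resisting bending (pN um/rad).
#' @param F_T total propulsive force per agent (pN); each of the `N - 1`
#'   propelled nodes carries `F_T / (N - 1)`.
#' @param c viscous drag coefficient per node (pN min/um).
#' @param k_a substrate focal-adhesion spring constant (pN/um).
#' @param d_a_max substrate adhesion break distance (um); past it the anchor
#'   detaches and instantly reattaches at the node position.
#' @param tau_r reversal period (min): the clock value at which a reversal
#'   fires.  `Inf` disables reversals.
#' @param tau_t period of random 90-degree direction changes (min); `Inf`
#'   disables turns.
#' @param turn_duration duration of a random turn (min).
#' @param L_sim edge length of the square periodic domain (um).
#' @param eta agent density (agents/um^2); the population size is
#'   `round(eta * L_sim^2)`.
#' @param dt integration time step (min).
#' @param k_adh_wt,k_adh_oe adhesion force factors (dimensionless, relative
#'   to `F_T`) for WT-WT style contacts and for matched OE-OE contacts.
#' @param k_adh_mismatch adhesion factor for OE agents carrying different
#'   (incompatible) adhesin alleles; 0 means no bond forms at all.
#' @param k_adh_cross adhesion factor for OE paired with a non-OE agent.
#' @param dR_e,dR_l reversal-clock suppression weights of an active end-end
#'   and lateral bond, respectively.
#' @param tau_thr minimum bond age before a bond suppresses the clock (min).
#'   `0` makes every bond suppress from its first full step; `Inf` disables
#'   suppression entirely.
#' @param d_thr_ee,d_thr_lat maximal bond length for end-end (head-to-tail)
#'   and lateral bonds (um).
#' @param slime_following if `FALSE`, trails are still deposited but the
#'   head is never steered by them.
#' @param slime_cell grid cell size of the slime field (um).
#' @param omega_s maximal steering rate of the head propulsion direction
#'   toward a slime trail (degrees/min).  The default is fast relative to
#'   the body's reorientation mobility, so the head force aligns with a
#'   trail within a fraction of a grid-cell crossing.
#' @param slime_max_age trails older than this (min since last deposit) are
#'   ignored by the steering rule: only recently traveled, reinforced
#'   trails guide cells.  `Inf` makes trails permanent guides.
#' @param slime_min_visits number of distinct passes (deposits separated by
#'   more than a body transit time) a trail cell needs before it steers:
#'   reinforced traffic corridors guide cells, single-pass trails do not.
#'   Set to 1 to make every trail steer.
#' @param run_duration simulated time (min).
#' @param snapshot_interval recording interval (min).
#' @param k_rep stiffness of the penalty springs resolving collisions
#'   (pN/um); a numerical parameter, calibrated so that steady-state
#'   interpenetration stays below 10% of `w`.
#' @param turn_curvature spontaneous bend angle (degrees per joint) adopted
#'   by the two joints behind the head while a random turn is active: the
#'   cell steers by actively flexing its front, in addition to the rotated
#'   head propulsion.
#' @param suppression_count `"node"` to count every bond in the suppression
#'   sums (one flank neighbor may contribute several lateral terms) or
#'   `"agent"` to count distinct partner agents once per bond type.
#' @param place_attempt_factor rejection-sampling budget: at most
#'   `place_attempt_factor * M` placement attempts before initialization
#'   fails.
#' @param strains strain composition: a data frame with columns `strain`
#'   (`"WT"`, `"OE"` or `"NR"`), `allele` (integer) and `fraction`
#'   (summing to 1).
#'
#' @return An object of class `myxo_config` (a validated named list).
#' @seealso [myxo_run()], [pair_adhesion_coefficient()]
#' @examples
#' cfg <- myxo_config(L_sim = 40, run_duration = 5)
#' cfg$F_T / (cfg$N - 1)  # per-node propulsion, pN
#' @export
myxo_config <- function(L = 6, w = 0.5, m = 1.2e-15, N = 7L,
                        k_b = 10, F_T = 55, c = 22,
                        k_a = 100, d_a_max = 0.5,
                        tau_r = 8, tau_t = 5, turn_duration = 1,
                        L_sim = 200, eta = 0.074, dt = 0.0067,
                        k_adh_wt = 0.01, k_adh_oe = 0.1,
                        k_adh_mismatch = 0, k_adh_cross = 0.01,
                        dR_e = 1, dR_l = 0.04, tau_thr = 5,
                        d_thr_ee = 1.5, d_thr_lat = 0.9,
                        slime_following = TRUE, slime_cell = 0.5,
                        omega_s = 360, slime_max_age = 45, slime_min_visits = 2L,
                        run_duration = 250, snapshot_interval = 1,
                        k_rep = 1000, turn_curvature = 45,
                        suppression_count = c("node", "agent"),
                        place_attempt_factor = 100L,
                        strains = data.frame(strain = "OE", allele = 1L,
                                             fraction = 1)) {
  cfg <- list(
    L = L, w = w, m = m, N = as.integer(N), k_b = k_b, F_T = F_T, c = c,
    k_a = k_a, d_a_max = d_a_max, tau_r = tau_r, tau_t = tau_t,
    turn_duration = turn_duration, L_sim = L_sim, eta = eta, dt = dt,
    k_adh_wt = k_adh_wt, k_adh_oe = k_adh_oe,
    k_adh_mismatch = k_adh_mismatch, k_adh_cross = k_adh_cross,
    dR_e = dR_e, dR_l = dR_l, tau_thr = tau_thr,
    d_thr_ee = d_thr_ee, d_thr_lat = d_thr_lat,
    slime_following = isTRUE(slime_following), slime_cell = slime_cell,
    omega_s = omega_s, slime_max_age = slime_max_age,
    slime_min_visits = as.integer(slime_min_visits),
    run_duration = run_duration, snapshot_interval = snapshot_interval,
    k_rep = k_rep, turn_curvature = turn_curvature,
    suppression_count = match.arg(suppression_count),
    place_attempt_factor = as.integer(place_attempt_factor),
    strains = strains)
  class(cfg) <- "myxo_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  pos <- c("L", "w", "m", "k_b", "F_T", "c", "k_a", "d_a_max", "tau_r",
           "tau_t", "turn_duration", "L_sim", "eta", "dt", "d_thr_ee",
           "d_thr_lat", "slime_cell", "omega_s", "snapshot_interval", "k_rep")
  for (p in pos) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0)
      stop("config field '", p, "' must be a single positive number",
           call. = FALSE)
  }
  if (cfg$N < 3) stop("N must be at least 3", call. = FALSE)
  if (cfg$run_duration < 0) stop("run_duration must be non-negative",
                                 call. = FALSE)
  adh <- c("k_adh_wt", "k_adh_oe", "k_adh_mismatch", "k_adh_cross")
  for (p in adh)
    if (cfg[[p]] < 0) stop("adhesion factor '", p, "' must be >= 0",
                           call. = FALSE)
  if (cfg$tau_thr < 0) stop("tau_thr must be >= 0", call. = FALSE)
  if (cfg$eta * cfg$L_sim^2 < 1)
    stop("eta * L_sim^2 must place at least one agent", call. = FALSE)
  s <- cfg$strains
  if (!is.data.frame(s) || !all(c("strain", "allele", "fraction") %in% names(s)))
    stop("strains must be a data frame with strain, allele, fraction",
         call. = FALSE)
  if (!all(s$strain %in% names(.strain_codes)))
    stop("unknown strain label; use WT, OE or NR", call. = FALSE)
  if (abs(sum(s$fraction) - 1) > 1e-8)
    stop("strain fractions must sum to 1", call. = FALSE)
  invisible(cfg)
}

#' @export
print.myxo_config <- function(x, ...) {
  M <- round(x$eta * x$L_sim^2)
  cat("Gliding-agent simulation configuration\n")
  cat(sprintf("  domain     : %g x %g um periodic, %d agents (eta = %g/um^2)\n",
              x$L_sim, x$L_sim, M, x$eta))
  cat(sprintf("  agent      : L = %g um, w = %g um, N = %d nodes\n",
              x$L, x$w, x$N))
  cat(sprintf("  forces     : F_T = %g pN, c = %g, k_a = %g, k_b = %g\n",
              x$F_T, x$c, x$k_a, x$k_b))
  cat(sprintf("  clocks     : tau_r = %g min, tau_t = %g min (turn %g min)\n",
              x$tau_r, x$tau_t, x$turn_duration))
  cat(sprintf("  adhesion   : k_adh WT %g / OE %g, reach %g (ee) %g (lat) um\n",
              x$k_adh_wt, x$k_adh_oe, x$d_thr_ee, x$d_thr_lat))
  cat(sprintf("  suppression: dR_e = %g, dR_l = %g, tau_thr = %g min (%s pairs)\n",
              x$dR_e, x$dR_l, x$tau_thr, x$suppression_count))
  cat(sprintf("  slime      : following %s, cell %g um, omega_s %g deg/min\n",
              if (x$slime_following) "on" else "off", x$slime_cell, x$omega_s))
  cat(sprintf("  run        : %g min, dt = %g, snapshots every %g min\n",
              x$run_duration, x$dt, x$snapshot_interval))
  comp <- paste(sprintf("%s(allele %d) %.0f%%", x$strains$strain,
                        x$strains$allele, 100 * x$strains$fraction),
                collapse = ", ")
  cat("  strains    :", comp, "\n")
  invisible(x)
}

#' Adhesion coefficient of a strain/allele pair
#'
#' Matched OE-OE pairs adhere with the overexpression factor; OE pairs with
#' incompatible adhesin alleles do not adhere at all; every other pairing
#' uses the weak baseline factor.  Symmetric in its arguments.
#'
#' @param strain_a,strain_b strain labels (`"WT"`, `"OE"`, `"NR"`).
#' @param allele_a,allele_b integer adhesin allele identifiers.
#' @param cfg a [myxo_config()].
#' @return The dimensionless adhesion force factor `k_adh`.
#' @examples
#' cfg <- myxo_config()
#' pair_adhesion_coefficient("OE", 1, "OE", 1, cfg)  # 0.1
#' pair_adhesion_coefficient("OE", 1, "OE", 2, cfg)  # 0 (incompatible)
#' pair_adhesion_coefficient("WT", 1, "OE", 1, cfg)  # 0.01
#' @export
pair_adhesion_coefficient <- function(strain_a, allele_a, strain_b, allele_b,
                                      cfg = myxo_config()) {
  if (!strain_a %in% names(.strain_codes) || !strain_b %in% names(.strain_codes))
    stop("unknown strain label; use WT, OE or NR")
  if (strain_a == "OE" && strain_b == "OE") {
    if (allele_a == allele_b) return(cfg$k_adh_oe)
    return(cfg$k_adh_mismatch)
  }
  if (strain_a == "OE" || strain_b == "OE") return(cfg$k_adh_cross)
  cfg$k_adh_wt
}

#' Read or write a configuration file
#'
#' Flat YAML key-value documents mirroring the [myxo_config()] fields; the
#' strain composition is stored as a list of `(strain, allele, fraction)`
#' records.
#'
#' @param cfg a `myxo_config` object.
#' @param file path to a YAML file.
#' @return `read_config()` returns a `myxo_config`; `write_config()` returns
#'   `file` invisibly.
#' @export
write_config <- function(cfg, file) {
  stopifnot(inherits(cfg, "myxo_config"))
  x <- unclass(cfg)
  x$strains <- lapply(seq_len(nrow(cfg$strains)), function(i)
    list(strain = as.character(cfg$strains$strain[i]),
         allele = as.integer(cfg$strains$allele[i]),
         fraction = as.numeric(cfg$strains$fraction[i])))
  yaml::write_yaml(x, file)
  invisible(file)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  x <- yaml::read_yaml(file)
  strains <- do.call(rbind, lapply(x$strains, function(s)
    data.frame(strain = s$strain, allele = as.integer(s$allele),
               fraction = as.numeric(s$fraction))))
  x$strains <- NULL
  x$suppression_count <- x$suppression_count %||% "node"
  do.call(myxo_config, c(x, list(strains = strains)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
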