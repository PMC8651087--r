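#' Circular-aggregate verdict for a finished run
#'
#' Scores a run the way the phenotype experiments do: at several check
#' points near the end of the run, aggregates are detected and a check
#' "hits" when at least one cluster of `min_size`+ members reaches polar
#' rotational order `order_threshold` with member velocities measured over
#' `velocity_lag` snapshot intervals.  The run is called CA-positive when
#' at least `min_hits` checks hit — transient small mills flicker above
#' threshold for a single check, while genuine circular aggregates persist.
#'
#' @param sim a `myxo_sim`.
#' @param n_checks number of check points, spaced evenly over the final
#'   `window` minutes.
#' @param window length of the scoring window (min).
#' @param min_hits checks that must hit for a CA verdict.
#' @param min_size,order_threshold,velocity_lag,eps,min_pts passed to
#'   [detect_aggregates()].
#' @return A list: `is_ca`, `hits`, `n_checks`, `best_order`, `mixed`
#'   (both strain labels at 20%+ among members of some hitting cluster),
#'   and `aggregates`, the [detect_aggregates()] table of the last check
#'   augmented with a `hit` column.
#' @export
ca_verdict <- function(sim, n_checks = 4, window = 15, min_hits = 2,
                       min_size = 20, order_threshold = 0.6,
                       velocity_lag = 5, eps = 3, min_pts = 8) {
  S <- length(sim$times)
  t_end <- sim$times[S]
  checks <- unique(vapply(seq_len(n_checks), function(k) {
    tt <- t_end - window * (n_checks - k) / max(1, n_checks - 1)
    which.min(abs(sim$times - tt))
  }, integer(1)))
  checks <- checks[checks > velocity_lag]
  hits <- 0L
  best <- 0
  mixed <- FALSE
  last_agg <- NULL
  for (s in checks) {
    agg <- detect_aggregates(sim, snapshot = s, eps = eps, min_pts = min_pts,
                             min_size = min_size,
                             order_threshold = order_threshold,
                             velocity_lag = velocity_lag)
    hit_rows <- agg$is_ca & agg$rotational_order >= order_threshold
    # the polar order carries the verdict; the nematic score is reported
    # but a ring of two-way traffic alone does not flip a phenotype call
    if (nrow(agg)) best <- max(best, agg$rotational_order)
    if (any(hit_rows)) {
      hits <- hits + 1L
      mem <- attr(agg, "members")
      lab <- paste(sim$strain, sim$allele)
      for (k in which(hit_rows)) {
        fr <- table(lab[mem[[k]]]) / length(mem[[k]])
        if (length(fr) > 1 && sort(fr, decreasing = TRUE)[2] >= 0.2)
          mixed <- TRUE
      }
    }
    if (s == checks[length(checks)]) {
      agg$hit <- hit_rows
      last_agg <- agg
    }
  }
  list(is_ca = hits >= min_hits, hits = hits, n_checks = length(checks),
       best_order = best, mixed = mixed, aggregates = last_agg)
}

#' Canned experiment conditions
#'
#' The computational phenotype panel: each condition is a named
#' configuration override set with the qualitative outcome the full model
#' reproduces for it.
#'
#' @param L_sim domain size (um); 100 is the reduced scale used for desk
#'   runs, 200 the full scale.
#' @param run_duration simulated minutes.
#' @return Named list of conditions, each with `name`, `cfg` (a
#'   [myxo_config()]) and `expected` (`"CA"`, `"no_CA"` or `"mixed_CA"`).
#' @export
phenotype_conditions <- function(L_sim = 100, run_duration = 250) {
  one <- function(strain) data.frame(strain = strain, allele = 1L,
                                     fraction = 1)
  mix <- function(s1, s2, a1 = 1L, a2 = 1L)
    data.frame(strain = c(s1, s2), allele = c(a1, a2),
               fraction = c(0.5, 0.5))
  base <- function(...) myxo_config(L_sim = L_sim,
                                    run_duration = run_duration, ...)
  list(
    reversing_adhesive = list(
      name = "reversing_adhesive",
      cfg = base(tau_r = 8, k_adh_wt = 0.1, tau_thr = Inf,
                 strains = one("WT")),
      expected = "no_CA"),
    nonreversing = list(
      name = "nonreversing",
      cfg = base(k_adh_wt = 0, k_adh_oe = 0, k_adh_cross = 0,
                 strains = one("NR")),
      expected = "CA"),
    nonreversing_adhesive = list(
      name = "nonreversing_adhesive",
      cfg = base(k_adh_wt = 0.1, strains = one("NR")),
      expected = "CA"),
    nonreversing_no_slime = list(
      name = "nonreversing_no_slime",
      cfg = base(k_adh_wt = 0, k_adh_oe = 0, k_adh_cross = 0,
                 slime_following = FALSE, strains = one("NR")),
      expected = "no_CA"),
    wildtype = list(
      name = "wildtype",
      cfg = base(strains = one("WT")),
      expected = "no_CA"),
    overexpressor = list(
      name = "overexpressor",
      cfg = base(strains = one("OE")),
      expected = "CA"),
    wildtype_no_delay = list(
      name = "wildtype_no_delay",
      cfg = base(tau_thr = 0, strains = one("WT")),
      expected = "CA"),
    mixed_alleles = list(
      name = "mixed_alleles",
      cfg = base(strains = mix("OE", "OE", 1L, 2L)),
      expected = "mixed_CA"),
    oe_plus_wt = list(
      name = "oe_plus_wt",
      cfg = base(strains = mix("OE", "WT")),
      expected = "no_CA"),
    oe_plus_nr = list(
      name = "oe_plus_nr",
      cfg = base(strains = mix("OE", "NR")),
      expected = "mixed_CA"))
}

#' Run the phenotype matrix
#'
#' Runs each condition for each seed and applies the [ca_verdict()].  A
#' run that aborts is recorded as a failed condition (`NA` verdict), not
#' an error.
#'
#' @param conditions list from [phenotype_conditions()] (or a subset).
#' @param seeds integer seeds.
#' @param verdict_args list of overrides passed to [ca_verdict()].
#' @param verbose print one line per run.
#' @return Data frame with one row per condition x seed (verdict columns
#'   `is_ca`, `mixed`, `hits`, `best_order`, `suppressed_fraction`), plus
#'   a per-condition majority summary in the `summary` attribute.
#' @export
phenotype_matrix <- function(conditions = phenotype_conditions(),
                             seeds = 1:3, verdict_args = list(),
                             verbose = FALSE) {
  rows <- list()
  for (cond in conditions) {
    for (sd in seeds) {
      res <- tryCatch({
        sim <- myxo_run(cond$cfg, seed = sd)
        v <- do.call(ca_verdict, c(list(sim), verdict_args))
        data.frame(condition = cond$name, seed = sd,
                   expected = cond$expected,
                   is_ca = v$is_ca, mixed = v$mixed, hits = v$hits,
                   best_order = v$best_order,
                   suppressed_fraction =
                     mean(sim$suppressed[, length(sim$times)]))
      }, error = function(e) {
        warning("condition ", cond$name, " seed ", sd, " failed: ",
                conditionMessage(e))
        data.frame(condition = cond$name, seed = sd,
                   expected = cond$expected,
                   is_ca = NA, mixed = NA, hits = NA_integer_,
                   best_order = NA_real_,
                   suppressed_fraction = NA_real_)
      })
      if (verbose)
        cat(sprintf("%-22s seed %d: CA=%s hits=%s\n", cond$name, sd,
                    res$is_ca, res$hits))
      rows[[length(rows) + 1]] <- res
    }
  }
  out <- do.call(rbind, rows)
  agg <- lapply(split(out, out$condition), function(d) {
    data.frame(condition = d$condition[1], expected = d$expected[1],
               n_seeds = nrow(d),
               n_ca = sum(d$is_ca, na.rm = TRUE),
               n_mixed = sum(d$mixed, na.rm = TRUE),
               verdict = if (sum(d$is_ca, na.rm = TRUE) > nrow(d) / 2) {
                 if (sum(d$mixed, na.rm = TRUE) > nrow(d) / 2)
                   "mixed_CA" else "CA"
               } else "no_CA")
  })
  smry <- do.call(rbind, agg)
  rownames(smry) <- NULL
  attr(out, "summary") <- smry
  out
}

#' Reversal-period sweep
#'
#' Sweeps the reversal period for non-adhesive, slime-following agents
#' and reports the smallest period at which circular aggregates form in a
#' majority of seeds.
#'
#' @param periods reversal periods to test (min); `Inf` means nonreversing.
#' @param seeds integer seeds.
#' @param L_sim,run_duration scale of each run.
#' @param verdict_args list of overrides passed to [ca_verdict()].
#' @param verbose print one line per run.
#' @return List with `onset` (smallest CA-positive period, `NA` if none)
#'   and `table` (per period and seed verdicts).
#' @export
reversal_period_sweep <- function(periods = c(8, 20, 40, 70, 100),
                                  seeds = 1:3, L_sim = 100,
                                  run_duration = 250,
                                  verdict_args = list(),
                                  verbose = FALSE) {
  rows <- list()
  for (p in periods) {
    for (sd in seeds) {
      cfg <- myxo_config(L_sim = L_sim, run_duration = run_duration,
                         tau_r = p, k_adh_wt = 0, k_adh_oe = 0,
                         k_adh_cross = 0,
                         strains = data.frame(strain = "WT", allele = 1L,
                                              fraction = 1))
      sim <- myxo_run(cfg, seed = sd)
      v <- do.call(ca_verdict, c(list(sim), verdict_args))
      if (verbose)
        cat(sprintf("tau_r=%g seed %d: CA=%s (hits %d)\n", p, sd,
                    v$is_ca, v$hits))
      rows[[length(rows) + 1]] <-
        data.frame(tau_r = p, seed = sd, is_ca = v$is_ca, hits = v$hits,
                   best_order = v$best_order)
    }
  }
  tab <- do.call(rbind, rows)
  per <- vapply(split(tab, tab$tau_r),
                function(d) sum(d$is_ca) > nrow(d) / 2, logical(1))
  pvals <- as.numeric(names(per))
  onset <- if (any(per)) min(pvals[per]) else NA_real_
  list(onset = onset, table = tab)
}

#' Adhesion-strength sweep
#'
#' Runs single-strain populations across a range of adhesion force
#' factors and summarizes reversal suppression and bond persistence.
#'
#' @param k_adh_values adhesion factors to test (the WT and OE reference
#'   values are 0.01 and 0.1).
#' @param seeds integer seeds.
#' @param L_sim,run_duration scale of each run.
#' @param window final window (min) for the bond-lifetime summary.
#' @param verbose print one line per run.
#' @return Data frame with one row per k_adh x seed: suppressed fraction
#'   at the end and mean lifetime of bonds broken in the final window.
#' @export
adhesion_sweep <- function(k_adh_values = c(0.01, 0.025, 0.05, 0.075, 0.1),
                           seeds = 1:3, L_sim = 100, run_duration = 250,
                           window = 10, verbose = FALSE) {
  rows <- list()
  for (ka in k_adh_values) {
    for (sd in seeds) {
      cfg <- myxo_config(L_sim = L_sim, run_duration = run_duration,
                         k_adh_oe = ka,
                         strains = data.frame(strain = "OE", allele = 1L,
                                              fraction = 1))
      sim <- myxo_run(cfg, seed = sd)
      st <- suppression_stats(sim, window = window)
      if (verbose)
        cat(sprintf("k_adh=%g seed %d: suppressed %.3f lifetime %.2f\n",
                    ka, sd, st$suppressed_fraction_end,
                    st$mean_bond_lifetime))
      rows[[length(rows) + 1]] <- data.frame(
        k_adh = ka, seed = sd,
        suppressed_fraction = st$suppressed_fraction_end,
        mean_bond_lifetime = st$mean_bond_lifetime,
        n_bonds_broken = st$n_bonds_broken)
    }
  }
  do.call(rbind, rows)
}
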