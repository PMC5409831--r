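#' Bistability scan over rate parameters
#'
#' For every combination of `k_me`, `p_dem` and `f_max`, simulations are
#' initialized in each of the uniform me0 and me3 states and run for
#' `cycles` cell cycles; `P_ON` and `P_OFF` are accumulated over the last
#' hour of each cycle and averaged over all simulations of the combination,
#' and `B = 4 P_OFF P_ON` is reported.
#'
#' @param params_base base [chromatin_params()].
#' @param k_me_grid,p_dem_grid,f_max_grid parameter values to scan (any may
#'   have length 1).
#' @param n_rep_per_state simulations per initial state per combination.
#' @param cycles cell cycles per simulation.
#' @param base_seed seed; replicate seeds are derived per combination.
#' @return Long data frame with one row per combination: `f_max`, `k_me`,
#'   `p_dem`, `P_ON`, `P_OFF`, `B`.
#' @export
scan_bistability <- function(params_base = chromatin_params(),
                             k_me_grid = params_base$k_me,
                             p_dem_grid = params_base$p_dem,
                             f_max_grid = params_base$f_max,
                             n_rep_per_state = 20, cycles = 50,
                             base_seed = 1) {
  grid <- expand.grid(k_me = k_me_grid, p_dem = p_dem_grid,
                      f_max = f_max_grid, KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(g) {
    p <- update_params(params_base, k_me = grid$k_me[g],
                       p_dem = grid$p_dem[g], f_max = grid$f_max[g])
    acc <- matrix(0, 0, 2)
    for (init in c("uniform_me0", "uniform_me3")) {
      for (r in seq_len(n_rep_per_state)) {
        tr <- simulate_chromatin(p, initial_state = init, cycles = cycles,
                                 seed = base_seed + 7919L * g +
                                   1000L * (init == "uniform_me3") + r)
        acc <- rbind(acc, trajectory_p_on_off(tr))
      }
    }
    pm <- colMeans(acc)
    data.frame(f_max = grid$f_max[g], k_me = grid$k_me[g],
               p_dem = grid$p_dem[g], P_ON = pm[["P_ON"]],
               P_OFF = pm[["P_OFF"]], B = bistability(pm[["P_ON"]], pm[["P_OFF"]]))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Smallest maximum initiation rate supporting bistability
#'
#' Given a [scan_bistability()] result spanning several `f_max` values,
#' returns the smallest `f_max` at which any `(k_me, p_dem)` combination
#' reaches `B > B_cut`.
#'
#' @param scan data frame from [scan_bistability()].
#' @param B_cut bistability cutoff (default 0.5).
#' @return The threshold `f_max` (s^-1), or `NA` if none qualifies.
#' @export
bistability_threshold <- function(scan, B_cut = 0.5) {
  peak <- vapply(split(scan$B, scan$f_max), max, numeric(1))
  f <- as.numeric(names(peak))
  ok <- f[peak > B_cut]
  if (length(ok)) min(ok) else NA_real_
}

#' First-passage experiment from both initial states
#'
#' Estimates censored mean first-passage times from the uniform me0 and me3
#' states.  With `alpha != 1` the model is first equilibrated for
#' `equilibration_cycles` at `alpha = 1` from the uniform state, and the
#' passage clock starts when `alpha` switches.
#'
#' @inheritParams first_passage_times
#' @param params a [chromatin_params()] object.
#' @param alpha trans-activation multiplier during the measured epoch.
#' @param equilibration_cycles equilibration at `alpha = 1` applied when
#'   `alpha != 1`.
#' @return A data frame with one row per initial state: `initial_state`,
#'   `mean_t_fp_s`, `mean_t_fp_cycles`, `n_censored`, `n_rep`; the combined
#'   measure is attached as attribute `FP`.
#' @export
passage_experiment <- function(params, variant = "main", burst = NULL,
                               alpha = 1, n_rep = 50, censor_cycles = 400,
                               equilibration_cycles = 5, base_seed = 1) {
  p_run <- update_params(params, alpha = alpha)
  run_one <- function(init, seed_off) {
    if (alpha != 1) {
      times <- vapply(seq_len(n_rep), function(i) {
        eq <- simulate_chromatin(update_params(params, alpha = 1),
                                 variant = variant, burst = burst,
                                 initial_state = init,
                                 cycles = equilibration_cycles,
                                 record = "none",
                                 seed = base_seed + seed_off + i)
        thr <- passage_thresholds(params, variant)
        rule <- if (init == "uniform_me0") {
          list(dir = 1, threshold = thr$upper)
        } else {
          list(dir = -1, threshold = thr$lower)
        }
        tr <- simulate_chromatin(p_run, variant = variant, burst = burst,
                                 initial_state = "custom",
                                 initial_levels = eq$final$levels,
                                 cycles = censor_cycles, record = "none",
                                 stop_rule = rule, seed = NULL)
        if (isTRUE(tr$crossed)) tr$t_cross else censor_cycles * params$T_cc
      }, numeric(1))
      structure(times, censor_s = censor_cycles * params$T_cc,
                n_censored = sum(times >= censor_cycles * params$T_cc))
    } else {
      first_passage_times(p_run, variant = variant, burst = burst,
                          initial_state = init, n_rep = n_rep,
                          censor_cycles = censor_cycles,
                          base_seed = base_seed + seed_off)
    }
  }
  t0 <- run_one("uniform_me0", 0L)
  t3 <- run_one("uniform_me3", 100000L)
  censor_s <- attr(t0, "censor_s")
  out <- data.frame(
    initial_state = c("uniform_me0", "uniform_me3"),
    mean_t_fp_s = c(mean_first_passage(t0), mean_first_passage(t3)),
    n_censored = c(attr(t0, "n_censored"), attr(t3, "n_censored")),
    n_rep = n_rep
  )
  out$mean_t_fp_cycles <- out$mean_t_fp_s / params$T_cc
  attr(out, "FP") <- combined_first_passage(out$mean_t_fp_s[1],
                                            out$mean_t_fp_s[2], censor_s)
  attr(out, "censor_s") <- censor_s
  out
}

#' Noise-filtering experiment
#'
#' Measures the combined first-passage measure `FP` under fluctuating trans
#' activation for one or more chromatin dynamics regimes.  For each
#' `(k_me, p_dem)` row of `dynamics` and each burst size in `b_values`, the
#' chromatin SSA is coupled to a concurrently simulated two-stage regulator
#' and `FP` is computed from censored mean first-passage times out of both
#' uniform initial states.
#'
#' @param dynamics data frame with columns `k_me` and `p_dem`.
#' @param b_values regulator burst sizes (e.g. `c(1, 1000)` for low/high
#'   noise).
#' @param params_base base [chromatin_params()].
#' @param n_rep_per_state replicates per initial state.
#' @param cycles total simulated cell cycles per replicate (also the
#'   censoring bound).
#' @param mean_protein,d_R,d_P regulator parameters (hr^-1 decay rates).
#' @param base_seed seed.
#' @return Long data frame: `k_me`, `p_dem`, `b`, `cv_alpha_theory`,
#'   `t_fp_me0_cycles`, `t_fp_me3_cycles`, `FP`.
#' @export
noise_filtering_experiment <- function(dynamics, b_values = c(1, 1000),
                                       params_base = chromatin_params(),
                                       n_rep_per_state = 30, cycles = 20,
                                       mean_protein = 1000, d_R = 1 / 2,
                                       d_P = 1 / 12, base_seed = 1) {
  stopifnot(all(c("k_me", "p_dem") %in% names(dynamics)))
  combos <- merge(dynamics, data.frame(b = b_values))
  res <- lapply(seq_len(nrow(combos)), function(g) {
    p <- update_params(params_base, k_me = combos$k_me[g],
                       p_dem = combos$p_dem[g])
    rp <- regulator_params(combos$b[g], mean_protein, d_R, d_P)
    t0 <- first_passage_times(p, initial_state = "uniform_me0",
                              n_rep = n_rep_per_state,
                              censor_cycles = cycles, alpha_input = rp,
                              base_seed = base_seed + 7919L * g)
    t3 <- first_passage_times(p, initial_state = "uniform_me3",
                              n_rep = n_rep_per_state,
                              censor_cycles = cycles, alpha_input = rp,
                              base_seed = base_seed + 7919L * g + 100000L)
    T_tot <- cycles * p$T_cc
    m0 <- mean_first_passage(t0)
    m3 <- mean_first_passage(t3)
    data.frame(k_me = combos$k_me[g], p_dem = combos$p_dem[g],
               b = combos$b[g], cv_alpha_theory = regulator_cv_theory(rp),
               t_fp_me0_cycles = m0 / p$T_cc, t_fp_me3_cycles = m3 / p$T_cc,
               FP = combined_first_passage(m0, m3, T_tot))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
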