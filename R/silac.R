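#' Simulate a SILAC-style old/new histone labeling time course
#'
#' The model is initialized in the uniform me3 (repressed) state and
#' equilibrated for `equilibration_cycles` cell cycles at `alpha = 1`.  At the
#' replication ending the equilibration (defined as `t = 0` of the labeling
#' epoch) all resident histones are `old` and every histone deposited from
#' then on — at replication or through transcription-coupled exchange — is
#' labeled `new`.  The me3 content of each pool is reported as a fraction of
#' that pool's histone count at the requested sampling times.  The
#' cell-cycle-end total me3 fraction, averaged over the equilibration cycles
#' (excluding the first two, which still carry the relaxation from the
#' uniform me3 start), is returned as `P_me3_end` for downstream
#' normalization.
#'
#' @param params a [chromatin_params()] object.
#' @param equilibration_cycles repressed-state equilibration before labeling.
#' @param sample_hr sampling times in hours after labeling (default
#'   `c(0, 10, 24, 48)`).
#' @param seed integer seed.
#' @return A list with `series` (data frame `time_hr`, `pool`
#'   (`"old"`/`"new"`), `me3_fraction`) and `P_me3_end`.
#' @export
simulate_silac_timecourse <- function(params, equilibration_cycles = 5,
                                      sample_hr = c(0, 10, 24, 48),
                                      seed = NULL) {
  stopifnot(inherits(params, "chromatin_params"), equilibration_cycles >= 1)
  label_hr <- equilibration_cycles * params$cell_cycle_hr
  # cycle-end probes (just before the equilibration replications) plus the
  # labeled time points; the first two cycles are excluded from the probes so
  # the relaxation from the uniform me3 start does not inflate P_me3_end
  probe_cycles <- seq_len(equilibration_cycles)
  if (equilibration_cycles >= 3) probe_cycles <- probe_cycles[-(1:2)]
  probe_hr <- probe_cycles * params$cell_cycle_hr - 1 / 3600
  take_hr <- label_hr + sample_hr
  cycles <- (label_hr + max(sample_hr)) / params$cell_cycle_hr + 0.01
  tr <- simulate_chromatin(params, initial_state = "uniform_me3",
                           cycles = cycles, record = "none",
                           sample_times_hr = c(probe_hr, take_hr),
                           label_time_hr = label_hr, seed = seed)
  s <- tr$samples
  is_probe <- s$time_s < label_hr * 3600 - 0.5
  P_me3_end <- mean(s$n_me3[is_probe] / params$N)
  lab <- s[!is_probe, , drop = FALSE]
  lab <- lab[order(lab$time_s), , drop = FALSE]
  old_frac <- ifelse(lab$n_old > 0, lab$n_me3_old / lab$n_old, 0)
  new_frac <- ifelse(lab$n_new > 0, lab$n_me3_new / lab$n_new, 0)
  series <- data.frame(
    time_hr = rep(sample_hr, 2),
    pool = rep(c("old", "new"), each = length(sample_hr)),
    me3_fraction = c(old_frac, new_frac)
  )
  list(series = series, P_me3_end = P_me3_end)
}

#' Replicate-averaged simulated SILAC curve
#'
#' Averages [simulate_silac_timecourse()] over independent replicates.
#'
#' @inheritParams simulate_silac_timecourse
#' @param n_rep number of replicate simulations.
#' @param base_seed replicate `i` uses seed `base_seed + i`.
#' @return As [simulate_silac_timecourse()], with `me3_fraction` and
#'   `P_me3_end` averaged across replicates.
#' @export
silac_mean_curve <- function(params, n_rep = 8, equilibration_cycles = 5,
                             sample_hr = c(0, 10, 24, 48), base_seed = 1) {
  runs <- lapply(seq_len(n_rep), function(i) {
    simulate_silac_timecourse(params, equilibration_cycles, sample_hr,
                              seed = base_seed + i)
  })
  series <- runs[[1]]$series
  series$me3_fraction <- rowMeans(
    vapply(runs, function(r) r$series$me3_fraction,
           numeric(nrow(series)))
  )
  list(series = series,
       P_me3_end = mean(vapply(runs, `[[`, numeric(1), "P_me3_end")))
}

#' Normalize a simulated SILAC curve to the experimental anchor
#'
#' Genome-wide mass-spectrometry fractions and single-locus simulations live
#' on different scales; simulated time points are therefore multiplied by
#' `anchor / P_me3_end` so that the simulated cell-cycle-end me3 level maps
#' onto the measured old-histone me3 fraction at `t = 0` (0.301).  When the
#' repressed state was not maintained through equilibration (`P_me3_end`
#' below `min_P_me3_end`) the normalization is meaningless and the result is
#' flagged as failed.
#'
#' @param series data frame with a `me3_fraction` column.
#' @param P_me3_end average simulated cell-cycle-end total me3 fraction.
#' @param anchor experimental anchor value (default 0.301).
#' @param min_P_me3_end smallest `P_me3_end` considered a maintained
#'   repressed state.
#' @return A list with `series` (scaled, or `NULL` on failure), `factor`,
#'   and `failed`.
#' @export
normalize_silac <- function(series, P_me3_end, anchor = 0.301,
                            min_P_me3_end = 0.05) {
  stopifnot(anchor > 0, P_me3_end >= 0)
  if (P_me3_end < min_P_me3_end) {
    return(list(series = NULL, factor = NA_real_, failed = TRUE))
  }
  factor <- anchor / P_me3_end
  series$me3_fraction <- series$me3_fraction * factor
  list(series = series, factor = factor, failed = FALSE)
}

#' Sum of squared errors between a simulated curve and a SILAC table
#'
#' Each replicate measurement enters individually:
#' `SSE = sum over (time, pool, replicate) of (sim - data)^2`.
#'
#' @param sim_series normalized simulated curve (`time_hr`, `pool`,
#'   `me3_fraction`).
#' @param silac_table measurement table (`time_hr`, `pool`, `replicate`,
#'   `me3_fraction`), e.g. from [synthetic_silac()] or [read_silac_csv()].
#' @return The SSE.
#' @export
sse_score <- function(sim_series, silac_table) {
  stopifnot(all(c("time_hr", "pool", "me3_fraction") %in% names(sim_series)),
            all(c("time_hr", "pool", "replicate", "me3_fraction") %in%
                  names(silac_table)))
  key <- paste(sim_series$time_hr, sim_series$pool)
  idx <- match(paste(silac_table$time_hr, silac_table$pool), key)
  if (anyNA(idx)) {
    stop("silac table contains (time, pool) combinations absent from the simulation")
  }
  sum((sim_series$me3_fraction[idx] - silac_table$me3_fraction)^2)
}

#' Generate a synthetic SILAC measurement table
#'
#' Emulates a processed triple-SILAC me3 time course: the labeling protocol
#' of [simulate_silac_timecourse()] is run at the generating parameters, the
#' replicate-averaged curve is normalized, its `t = 0` old-pool mean is set
#' to the experimental anchor (0.301, definitional for the labeling scheme),
#' and independent Gaussian replicate noise (sd `sigma`, truncated to
#' `[0, 1]`) is added to produce `n_replicates` measurements per time point
#' and pool.  The `t = 0` new pool is identically zero before noise, by the
#' labeling definition.
#'
#' @param params generating [chromatin_params()].
#' @param sigma replicate noise standard deviation.
#' @param n_replicates biological replicates per time point (default 3).
#' @param n_rep_sim simulation replicates used for the mean curve.
#' @param sample_hr sampling times (hours).
#' @param anchor experimental anchor for the `t = 0` old pool.
#' @param seed integer seed.
#' @return A data frame (`time_hr`, `pool`, `replicate`, `me3_fraction`).
#' @export
synthetic_silac <- function(params = chromatin_params(), sigma = 0.02,
                            n_replicates = 3, n_rep_sim = 12,
                            sample_hr = c(0, 10, 24, 48), anchor = 0.301,
                            seed = NULL) {
  stopifnot(sigma >= 0, n_replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  mc <- silac_mean_curve(params, n_rep = n_rep_sim, sample_hr = sample_hr,
                         base_seed = if (is.null(seed)) 1 else seed)
  nrm <- normalize_silac(mc$series, mc$P_me3_end, anchor = anchor)
  if (nrm$failed) stop("generating parameters do not maintain the repressed state")
  series <- nrm$series
  series$me3_fraction[series$time_hr == sample_hr[1] & series$pool == "old"] <- anchor
  rows <- series[rep(seq_len(nrow(series)), each = n_replicates), ]
  rows$replicate <- rep(seq_len(n_replicates), nrow(series))
  noisy <- rows$me3_fraction + rnorm(nrow(rows), 0, sigma)
  rows$me3_fraction <- pmin(pmax(noisy, 0), 1)
  rownames(rows) <- NULL
  rows[, c("time_hr", "pool", "replicate", "me3_fraction")]
}

#' Grid fit of the chromatin model to a SILAC table
#'
#' For every grid point `(k_me, p_dem, P_T)` the labeling protocol is
#' simulated, the replicate-averaged curve normalized
#' ([normalize_silac()]; failed normalizations score `Inf`), and scored
#' against the table with [sse_score()].  Ties in the minimum SSE are broken
#' toward the slowest methylation rate.
#'
#' @param silac_table measurement table (`time_hr`, `pool`, `replicate`,
#'   `me3_fraction`).
#' @param params_base base [chromatin_params()]; grid values replace `k_me`,
#'   `p_dem`, `P_T`.
#' @param k_me_grid,p_dem_grid,P_T_grid grid coordinates.  Defaults are
#'   doubling steps in `k_me` around the fitted value, decade steps in
#'   `p_dem`, and `P_T` in `{1/3, 2/3, 1}` (smaller `P_T` values are not
#'   identifiable under the repressed-state protocol: transcription is
#'   already pinned at `f_min` for all of them; see the methods vignette for
#'   the weak identifiability of `p_dem` below the generating value).
#' @param n_rep_per_point simulation replicates per grid point.
#' @param equilibration_cycles repressed-state equilibration before labeling.
#' @param base_seed seed; each grid point derives its own replicate seeds.
#' @return An object of class `silac_fit`: list with `surface` (long data
#'   frame of `k_me`, `p_dem`, `P_T`, `sse`, `norm_factor`, `failed`), `best`
#'   (the argmin row), and the grids.
#' @export
grid_fit <- function(silac_table, params_base = chromatin_params(),
                     k_me_grid = 8e-6 * c(1 / 4, 1 / 2, 1, 2, 4),
                     p_dem_grid = 4e-3 * 10^(-2:2),
                     P_T_grid = c(1 / 3, 2 / 3, 1),
                     n_rep_per_point = 6, equilibration_cycles = 5,
                     base_seed = 1) {
  stopifnot(length(k_me_grid) >= 1, length(p_dem_grid) >= 1,
            length(P_T_grid) >= 1)
  sample_hr <- sort(unique(silac_table$time_hr))
  grid <- expand.grid(k_me = k_me_grid, p_dem = p_dem_grid, P_T = P_T_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$sse <- NA_real_
  grid$norm_factor <- NA_real_
  grid$failed <- FALSE
  for (g in seq_len(nrow(grid))) {
    p <- update_params(params_base, k_me = grid$k_me[g],
                       p_dem = grid$p_dem[g], P_T = grid$P_T[g])
    mc <- silac_mean_curve(p, n_rep = n_rep_per_point,
                           equilibration_cycles = equilibration_cycles,
                           sample_hr = sample_hr,
                           base_seed = base_seed + 1000 * g)
    nrm <- normalize_silac(mc$series, mc$P_me3_end)
    if (nrm$failed) {
      grid$failed[g] <- TRUE
      grid$sse[g] <- Inf
    } else {
      grid$norm_factor[g] <- nrm$factor
      grid$sse[g] <- sse_score(nrm$series, silac_table)
    }
  }
  ord <- order(grid$sse, grid$k_me)  # ties toward slower k_me
  best <- grid[ord[1], , drop = FALSE]
  structure(list(surface = grid, best = best, k_me_grid = k_me_grid,
                 p_dem_grid = p_dem_grid, P_T_grid = P_T_grid),
            class = "silac_fit")
}

#' @export
print.silac_fit <- function(x, ...) {
  cat(sprintf("SILAC grid fit over %d points\n", nrow(x$surface)))
  cat(sprintf("  best: k_me = %g, p_dem = %g, P_T = %.3g (SSE = %.4g)\n",
              x$best$k_me, x$best$p_dem, x$best$P_T, x$best$sse))
  if (any(x$surface$failed)) {
    cat(sprintf("  %d grid points failed normalization (unstable repressed state)\n",
                sum(x$surface$failed)))
  }
  invisible(x)
}
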