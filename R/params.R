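#' Chromatin model parameters
#'
#' Builds the parameter set of the chromatin/transcription model.  Primitive
#' rates are supplied; derived quantities (the 9:6:1 methylation ladder, the 5%
#' noise floors, the noisy demethylation rate, and the transcriptional
#' fold-change) are always recomputed from the primitives and never set
#' directly.
#'
#' Defaults are the fitted parameter set used throughout the analyses:
#' `k_me = 8e-6` histone^-1 s^-1 (about 0.6 histone^-1 per 22-hr cell cycle),
#' `p_dem = 4e-3` and `p_ex = 1e-3` per histone per transcription event,
#' `P_T = 1/3`, `f_min = 1e-4` and `f_max = 4e-3` s^-1 (fold-change F = 40).
#'
#' @param N number of H3 histones in the domain (even; nucleosomes are the
#'   pairs (1,2), (3,4), ...).  Default 60, about 5-6 kb of chromatin.
#' @param cell_cycle_hr cell-cycle duration in hours (DNA replicates once per
#'   cycle).
#' @param beta relative local PRC2 activity (recruitment strength); 1 for a
#'   typical PRC2 target.
#' @param k_me allosterically stimulated me2->me3 methylation rate
#'   (histone^-1 s^-1).  The me0->me1 and me1->me2 rates are 9 and 6 times
#'   `k_me` (relative PRC2 activity on me0/me1/me2 substrates of 9:6:1).
#' @param rho_me2 efficiency of PRC2 stimulation by a neighboring me2 mark
#'   relative to me3 (default 0.1).
#' @param f_min,f_max minimum/maximum transcription initiation rates (s^-1).
#' @param P_T repression-saturation threshold: the me2/me3 fraction at which
#'   transcription is fully repressed to `f_min`.
#' @param p_dem probability per histone per transcription event of losing one
#'   methyl group.
#' @param p_ex probability per histone per transcription event of
#'   transcription-coupled nucleosome exchange; a hit on either histone
#'   replaces the whole nucleosome with an unmethylated one.
#' @param f_cap absolute cap on the transcription initiation rate (s^-1),
#'   applied after trans activation; default 1/60.
#' @param alpha trans-activation multiplier (1 = neutral).
#' @param replication_survival probability that a nucleosome is retained at
#'   DNA replication (default 0.5; the complementary event replaces it with a
#'   new me0/me0 nucleosome).
#'
#' @return An object of class `chromatin_params`: a list of the primitive
#'   fields above plus derived fields `k_me0_1`, `k_me1_2`, `gamma_me0_1`,
#'   `gamma_me1_2`, `gamma_me2_3` (noise floors at 5% of the corresponding
#'   stimulated rate), `gamma_dem = f_min * p_dem`, `F = f_max / f_min`, and
#'   `T_cc` (cell-cycle duration in seconds).
#' @export
#' @examples
#' p <- chromatin_params()
#' p$F            # 40
#' p$gamma_dem    # 4e-7
chromatin_params <- function(N = 60, cell_cycle_hr = 22, beta = 1,
                             k_me = 8e-6, rho_me2 = 0.1,
                             f_min = 1e-4, f_max = 4e-3, P_T = 1 / 3,
                             p_dem = 4e-3, p_ex = 1e-3, f_cap = 1 / 60,
                             alpha = 1, replication_survival = 0.5) {
  stopifnot(
    N >= 2, N %% 2 == 0, cell_cycle_hr > 0, beta >= 0, k_me >= 0,
    rho_me2 >= 0, f_min > 0, f_max >= f_min, P_T > 0, P_T <= 1,
    p_dem >= 0, p_dem <= 1, p_ex >= 0, p_ex <= 1, f_cap > 0, alpha >= 0,
    replication_survival >= 0, replication_survival <= 1
  )
  p <- list(
    N = as.integer(N), cell_cycle_hr = cell_cycle_hr, beta = beta,
    k_me = k_me, rho_me2 = rho_me2, f_min = f_min, f_max = f_max,
    P_T = P_T, p_dem = p_dem, p_ex = p_ex, f_cap = f_cap, alpha = alpha,
    replication_survival = replication_survival
  )
  class(p) <- "chromatin_params"
  recompute_derived(p)
}

# derived quantities are a function of the primitives only
recompute_derived <- function(p) {
  p$T_cc <- p$cell_cycle_hr * 3600
  p$k_me0_1 <- 9 * p$k_me
  p$k_me1_2 <- 6 * p$k_me
  p$gamma_me0_1 <- p$k_me0_1 / 20
  p$gamma_me1_2 <- p$k_me1_2 / 20
  p$gamma_me2_3 <- p$k_me / 20
  p$gamma_dem <- p$f_min * p$p_dem
  p$F <- p$f_max / p$f_min
  p
}

#' Modify chromatin parameters
#'
#' Returns a copy of `params` with the given primitive fields replaced and all
#' derived fields recomputed.
#'
#' @param params a [chromatin_params()] object.
#' @param ... primitive fields to replace (e.g. `k_me = 1e-5`).
#' @return A `chromatin_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "chromatin_params"))
  repl <- list(...)
  primitives <- c(
    "N", "cell_cycle_hr", "beta", "k_me", "rho_me2", "f_min", "f_max",
    "P_T", "p_dem", "p_ex", "f_cap", "alpha", "replication_survival"
  )
  bad <- setdiff(names(repl), primitives)
  if (length(bad)) {
    stop("not primitive parameter fields: ", paste(bad, collapse = ", "))
  }
  args <- modifyList(params[primitives], repl)
  do.call(chromatin_params, args)
}

#' @export
print.chromatin_params <- function(x, ...) {
  cat("Chromatin model parameters\n")
  cat(sprintf("  N = %d histones, cell cycle = %g hr, beta = %g\n",
              x$N, x$cell_cycle_hr, x$beta))
  cat(sprintf("  k_me = %g /histone/s (ladder 9:6:1; noise floors at 5%%)\n",
              x$k_me))
  cat(sprintf("  f in [%g, %g] /s (F = %g), cap %g /s, P_T = %g, alpha = %g\n",
              x$f_min, x$f_max, x$F, x$f_cap, x$P_T, x$alpha))
  cat(sprintf("  p_dem = %g, p_ex = %g per histone per transcription; gamma_dem = %g /s\n",
              x$p_dem, x$p_ex, x$gamma_dem))
  cat(sprintf("  replication survival = %g\n", x$replication_survival))
  invisible(x)
}

#' Promoter-switching (bursty transcription) parameters
#'
#' Derives the parameters of the promoter-switching variant, in which
#' chromatin and trans factors regulate the closed-to-open promoter transition
#' rate `k_on` (burst frequency) while the open-state initiation rate `f_0`
#' and the closing rate `k_off` stay fixed.  Given `k_on_max` and `k_off`,
#' `k_on_min` is set so that the transcriptional fold-change between the fully
#' active and fully repressed chromatin states equals the main model's
#' `F = f_max / f_min = 40`, and `f_0` is set so that the repressed-state mean
#' initiation rate equals `f_min`.  When `f_0` exceeds the 1/60 s^-1
#' initiation cap, `k_on` is additionally capped at
#' `k_off / (60 * f_0 - 1)` so the mean initiation rate never exceeds 1/60.
#'
#' The analysis is restricted to `k_on_max <= k_off` (mean closed durations at
#' least as long as bursts), where regulation through `k_on` alone can achieve
#' the required fold-change.
#'
#' @param k_on_max maximal promoter opening rate (s^-1), attained in the fully
#'   active chromatin state.
#' @param k_off promoter closing rate (s^-1), constant.
#' @param f_min repressed-state mean initiation rate to match (s^-1).
#' @param fold_change required active/repressed transcriptional fold-change.
#' @return An object of class `burst_params` with fields `k_on_max`, `k_off`,
#'   `k_on_min`, `f_0`, `k_on_cap` and `fold_change` (the realized value of
#'   the fold-change identity, equal to `fold_change` by construction).
#' @export
#' @examples
#' bp <- burst_params(5e-4, 5e-3)
#' bp$fold_change  # 40
burst_params <- function(k_on_max = 5e-4, k_off = 5e-3, f_min = 1e-4,
                         fold_change = 40) {
  stopifnot(k_on_max > 0, k_off > 0, f_min > 0, fold_change > 1)
  if (k_on_max > k_off) {
    stop("promoter-switching analysis requires k_on_max <= k_off")
  }
  Fm1 <- fold_change - 1
  k_on_min <- k_on_max * k_off / (Fm1 * k_on_max + fold_change * k_off)
  f_0 <- f_min * (k_on_min + k_off) / k_on_min
  k_on_cap <- if (f_0 > 1 / 60) k_off / (60 * f_0 - 1) else Inf
  out <- list(
    k_on_max = k_on_max, k_off = k_off, f_min = f_min,
    k_on_min = k_on_min, f_0 = f_0, k_on_cap = k_on_cap,
    fold_change = burst_fold_change(k_on_max, k_on_min, k_off)
  )
  class(out) <- "burst_params"
  out
}

#' Transcriptional fold-change of the promoter-switching model
#'
#' The ratio of mean initiation rates between the fully active and fully
#' repressed chromatin states,
#' \deqn{F = \frac{k_{on(max)} (k_{on(min)} + k_{off})}
#'              {k_{on(min)} (k_{on(max)} + k_{off})}.}
#'
#' @param k_on_max,k_on_min,k_off promoter switching rates (s^-1).
#' @return The fold-change (dimensionless).
#' @export
burst_fold_change <- function(k_on_max, k_on_min, k_off) {
  stopifnot(k_on_max > 0, k_on_min > 0, k_off > 0)
  k_on_max * (k_on_min + k_off) / (k_on_min * (k_on_max + k_off))
}

#' @export
print.burst_params <- function(x, ...) {
  cat("Promoter-switching parameters\n")
  cat(sprintf("  k_on in [%.4g, %.4g] /s (cap %.4g), k_off = %.4g /s\n",
              x$k_on_min, x$k_on_max, x$k_on_cap, x$k_off))
  cat(sprintf("  f_0 = %.4g /s while open; fold-change = %.6g\n",
              x$f_0, x$fold_change))
  invisible(x)
}
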