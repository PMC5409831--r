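#' Time-weighted average of a piecewise-constant signal
#'
#' Trajectories are piecewise constant between reaction times: `value[i]`
#' holds on `[time[i], time[i+1])` and the last value holds from the last
#' time onward.  The time average over `[t0, t1]` is
#' \eqn{\sum_i x_i (t_{i+1} - t_i) / (t_1 - t_0)} with intervals clipped to
#' the window.
#'
#' @param time nondecreasing event times (seconds).
#' @param value signal values, same length as `time`.
#' @param t0,t1 averaging window; defaults to the full record.  `t1 > t0` is
#'   required.
#' @return The time-weighted mean.
#' @export
#' @examples
#' time_average(c(0, 2), c(1, 0), 0, 10)  # 0.2
time_average <- function(time, value, t0 = time[1], t1 = time[length(time)]) {
  stopifnot(length(time) == length(value), length(time) >= 1)
  if (!(t1 > t0)) stop("zero-length averaging segment (t1 must exceed t0)")
  step_integral(time, value, t0, t1) / (t1 - t0)
}

# integral of the right-continuous step function over [a, b]
step_integral <- function(time, value, a, b) {
  if (b <= a) return(0)
  if (a < time[1]) stop("window starts before the first record")
  ends <- c(time[-1], Inf)
  w <- pmax(0, pmin(ends, b) - pmax(time, a))
  sum(w * value)
}

#' Time-averaged ON/OFF state probabilities
#'
#' The gene is OFF when the chromatin-based regulation of transcription is in
#' its lower quartile, i.e. when the repressive-mark count is strictly above
#' `3 N P_T / 4`, and ON when it is strictly below `N P_T / 4`; exact ties
#' count as neither.  With `P_T = 1` these reduce to the threshold-free
#' definitions (repressive marks above 3N/4 / below N/4).  Because histones
#' deposited at DNA replication carry active-state (unmethylated) marks, the
#' probabilities are by default accumulated only over the last hour of each
#' completed cell cycle, letting slowly recovering repressed states register
#' as stable.
#'
#' @param time nondecreasing event times (seconds).
#' @param n_repressive repressive-mark counts (me2+me3; me3 for the two-state
#'   variant) at those times.
#' @param N histone count.
#' @param P_T repression-saturation threshold.
#' @param T_cc cell-cycle duration in seconds (required for
#'   `window = "last_hour"`).
#' @param window `"last_hour"` (default) or `"all"`.
#' @param t_end end of the record (defaults to the last event time).
#' @return Named numeric vector `c(P_ON = ..., P_OFF = ...)`.
#' @export
p_on_off <- function(time, n_repressive, N, P_T = 1 / 3, T_cc = NULL,
                     window = c("last_hour", "all"), t_end = max(time)) {
  window <- match.arg(window)
  stopifnot(length(time) == length(n_repressive), length(time) >= 1)
  hi <- 3 * N * P_T / 4
  lo <- N * P_T / 4
  off <- as.numeric(n_repressive > hi)
  on <- as.numeric(n_repressive < lo)
  if (window == "all") {
    return(c(P_ON = time_average(time, on, time[1], t_end),
             P_OFF = time_average(time, off, time[1], t_end)))
  }
  stopifnot(!is.null(T_cc), T_cc > 3600)
  n_cyc <- floor(t_end / T_cc + 1e-9)
  if (n_cyc < 1) stop("last-hour windowing needs at least one complete cell cycle")
  cyc_ends <- seq_len(n_cyc) * T_cc
  int_on <- int_off <- 0
  for (ce in cyc_ends) {
    int_on <- int_on + step_integral(time, on, ce - 3600, ce)
    int_off <- int_off + step_integral(time, off, ce - 3600, ce)
  }
  tot <- n_cyc * 3600
  c(P_ON = int_on / tot, P_OFF = int_off / tot)
}

#' ON/OFF probabilities of a simulated trajectory
#'
#' Convenience wrapper applying [p_on_off()] to a recorded trajectory, using
#' its own `N`, `P_T` and cell-cycle length (the two-state variant uses me3
#' counts with `P_T = 1`).
#'
#' @param traj a `chromatin_trajectory` with recorded events.
#' @param window `"last_hour"` or `"all"`.
#' @return Named numeric vector `c(P_ON = ..., P_OFF = ...)`.
#' @export
trajectory_p_on_off <- function(traj, window = "last_hour") {
  stopifnot(inherits(traj, "chromatin_trajectory"))
  if (is.null(traj$events)) stop("trajectory was run with record = \"none\"")
  ev <- traj$events
  if (traj$variant == "two_state") {
    n <- ev$n_me3
    P_T <- 1
  } else {
    n <- ev$n_me2 + ev$n_me3
    P_T <- traj$params$P_T
  }
  p_on_off(ev$time_s, n, N = traj$params$N, P_T = P_T,
           T_cc = traj$params$T_cc, window = window, t_end = traj$t_end)
}

#' Bistability measure
#'
#' `B = 4 * P_OFF * P_ON`: close to 1 when both expression states are
#' occupied with comparable probability over time, 0 for monostable systems.
#'
#' @param P_ON,P_OFF time-averaged state probabilities in `[0, 1]`.
#' @return `B` in `[0, 1]`.
#' @export
bistability <- function(P_ON, P_OFF) {
  stopifnot(all(P_ON >= 0 & P_ON <= 1), all(P_OFF >= 0 & P_OFF <= 1))
  4 * P_OFF * P_ON
}

#' Censored mean first-passage time
#'
#' Replicate first-passage times are bounded above by the total simulated
#' time; censored replicates contribute that bound to the mean, following the
#' bounded first-passage definition.
#'
#' @param times first-passage times (seconds), e.g. from
#'   [first_passage_times()].
#' @param censor_s censoring bound (defaults to the `censor_s` attribute).
#' @return Mean first-passage time in seconds.
#' @export
mean_first_passage <- function(times, censor_s = attr(times, "censor_s")) {
  stopifnot(length(times) >= 1, !is.null(censor_s))
  mean(pmin(times, censor_s))
}

#' Combined first-passage measure
#'
#' \deqn{FP = t_{FP(me0)} t_{FP(me3)} / T^2,} where the two factors are the
#' censored mean first-passage times from the uniform me0 and me3 initial
#' states and `T` is the total simulated time.  `FP` lies in `(0, 1]`; values
#' near 1 indicate long lifetimes of both chromatin states.
#'
#' @param t_fp_me0,t_fp_me3 censored mean first-passage times (seconds).
#' @param T_total total simulated time (seconds).
#' @return `FP` in `(0, 1]`.
#' @export
combined_first_passage <- function(t_fp_me0, t_fp_me3, T_total) {
  stopifnot(T_total > 0, t_fp_me0 > 0, t_fp_me3 > 0,
            t_fp_me0 <= T_total + 1e-9, t_fp_me3 <= T_total + 1e-9)
  t_fp_me0 * t_fp_me3 / T_total^2
}

#' Transcriptional output in a given cell cycle
#'
#' The number of transcription events within the `cycle_index`-th cell cycle
#' divided by the cell-cycle duration in hours.
#'
#' @param traj a `chromatin_trajectory`.
#' @param cycle_index 1-based cell-cycle index.
#' @return Events per gene per hour.
#' @export
transcriptional_output <- function(traj, cycle_index) {
  stopifnot(inherits(traj, "chromatin_trajectory"),
            cycle_index >= 1, cycle_index <= length(traj$tx_per_cycle))
  traj$tx_per_cycle[cycle_index] / traj$params$cell_cycle_hr
}

#' Time-averaged fraction of exchange-deposited (H3.3-like) histones
#'
#' Histones incorporated through transcription-coupled exchange are labeled
#' H3.3; histones incorporated at DNA replication are H3.1.
#'
#' @param traj a `chromatin_trajectory` with recorded events.
#' @return The time-averaged H3.3 fraction in `[0, 1]`.
#' @export
h33_fraction <- function(traj) {
  stopifnot(inherits(traj, "chromatin_trajectory"))
  if (is.null(traj$events)) stop("trajectory was run with record = \"none\"")
  ev <- traj$events
  time_average(ev$time_s, ev$n_exchange / traj$params$N, ev$time_s[1], traj$t_end)
}

#' Transcription-dependent H3.3 asymmetry
#'
#' `H = |<H3.3>_ON - <H3.3>_OFF|`: the absolute difference between the mean
#' time-averaged exchange-deposited histone fractions of simulations
#' initialized in the active state and those initialized in the repressed
#' state.  In the bistable regime, large `H` reflects transcription-dependent
#' H3.3 accumulation.
#'
#' @param on_trajs,off_trajs lists of `chromatin_trajectory` objects (or
#'   numeric vectors of per-replicate H3.3 fractions).
#' @return `H` in `[0, 1]`.
#' @export
h33_asymmetry <- function(on_trajs, off_trajs) {
  frac <- function(x) {
    if (is.numeric(x)) x else vapply(x, h33_fraction, numeric(1))
  }
  abs(mean(frac(on_trajs)) - mean(frac(off_trajs)))
}

#' Time-weighted coefficient of variation
#'
#' @param time nondecreasing times.
#' @param value piecewise-constant signal.
#' @return `sd / mean` under time-weighted averaging.
#' @export
signal_cv <- function(time, value) {
  mu <- time_average(time, value)
  sqrt(time_average(time, (value - mu)^2)) / mu
}
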