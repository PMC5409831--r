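#' Noisy trans-regulator parameters
#'
#' Two-stage gene-expression model of a trans-acting regulator:
#' DNA -> mRNA (rate `s_R`), mRNA decay (`d_R`), mRNA -> protein (`s_P` per
#' mRNA), protein decay (`d_P`).  At stationarity `<mRNA> = s_R / d_R` and
#' `<protein> = s_R b / d_P`, with burst size `b = s_P / d_R` the mean number
#' of proteins per transcript.  Synthesis rates are derived from the decay
#' rates, target mean and burst size as `s_R = d_P * mean_protein / b` and
#' `s_P = d_R * b`, so the stationary protein mean is `mean_protein` for every
#' `b`; only the noise changes with `b`.  The activation signal is
#' \eqn{\alpha(t) = r(t) / \langle r \rangle} with `r(t)` the protein count.
#'
#' Rates are given per hour (the field's convention) and stored internally in
#' s^-1.
#'
#' @param b burst size (dimensionless); around 1 gives a low-noise input
#'   (CV close to 0), around 1000 a high-noise input (CV close to 1).
#' @param mean_protein target stationary protein mean.
#' @param d_R mRNA decay rate (hr^-1), default 1/2.
#' @param d_P protein decay rate (hr^-1), default 1/12.
#' @return An object of class `regulator_params` with the primitive fields,
#'   the derived synthesis rates (`s_R`, `s_P`, per hour and per second), and
#'   the deterministic stationary initial condition `m0`, `p0` used to start
#'   simulations (no burn-in needed).
#' @export
#' @examples
#' rp <- regulator_params(b = 1000)
#' rp$s_R            # d_P * 1000 / b per hour
#' regulator_cv_theory(rp)  # about 0.93
regulator_params <- function(b, mean_protein = 1000, d_R = 1 / 2,
                             d_P = 1 / 12) {
  stopifnot(b > 0, mean_protein > 0, d_R > 0, d_P > 0)
  s_R <- d_P * mean_protein / b
  s_P <- d_R * b
  structure(list(
    b = b, mean_protein = mean_protein, d_R = d_R, d_P = d_P,
    s_R = s_R, s_P = s_P,
    s_R_per_s = s_R / 3600, d_R_per_s = d_R / 3600,
    s_P_per_s = s_P / 3600, d_P_per_s = d_P / 3600,
    m0 = as.integer(round(s_R / d_R)), p0 = as.integer(round(mean_protein))
  ), class = "regulator_params")
}

#' @export
print.regulator_params <- function(x, ...) {
  cat(sprintf("Two-stage regulator: b = %g, <protein> = %g\n", x$b, x$mean_protein))
  cat(sprintf("  s_R = %.4g, d_R = %.4g, s_P = %.4g, d_P = %.4g (hr^-1)\n",
              x$s_R, x$d_R, x$s_P, x$d_P))
  invisible(x)
}

#' Regulator reaction propensities
#'
#' @param m,p current mRNA and protein copy numbers.
#' @param rp a [regulator_params()] object.
#' @return Named rate vector (s^-1): `mrna_birth`, `mrna_death`,
#'   `protein_birth`, `protein_death`.
#' @export
regulator_propensities <- function(m, p, rp) {
  stopifnot(m >= 0, p >= 0)
  c(mrna_birth = rp$s_R_per_s,
    mrna_death = rp$d_R_per_s * m,
    protein_birth = rp$s_P_per_s * m,
    protein_death = rp$d_P_per_s * p)
}

#' Activation signal from a protein count
#'
#' \eqn{\alpha = r / \langle r \rangle}; zero is allowed transiently when the
#' protein count hits zero.
#'
#' @param r protein count.
#' @param mean_protein stationary mean protein count.
#' @return The dimensionless multiplier.
#' @export
alpha_of <- function(r, mean_protein) {
  stopifnot(mean_protein > 0, all(r >= 0))
  r / mean_protein
}

#' Simulate the regulator on its own
#'
#' Exact SSA of the two-stage model, started at the deterministic stationary
#' means (so no burn-in is required; an optional burn-in can still be
#' discarded).
#'
#' @param rp a [regulator_params()] object.
#' @param duration_hr simulated duration in hours.
#' @param seed integer seed; `NULL` continues the RNG stream.
#' @param burn_in_hr initial span to discard from the returned trace.
#' @return A data frame with columns `time_s`, `mRNA`, `protein`, `alpha`
#'   (one row per reaction, piecewise-constant between rows).
#' @export
simulate_regulator <- function(rp, duration_hr, seed = NULL, burn_in_hr = 0) {
  stopifnot(inherits(rp, "regulator_params"), duration_hr > 0,
            burn_in_hr >= 0, burn_in_hr < duration_hr)
  if (!is.null(seed)) set.seed(seed)
  raw <- cpp_regulator(rp$s_R_per_s, rp$d_R_per_s, rp$s_P_per_s, rp$d_P_per_s,
                       rp$m0, rp$p0, duration_hr * 3600)
  df <- data.frame(time_s = raw$time_s, mRNA = raw$mRNA, protein = raw$protein)
  df$alpha <- alpha_of(df$protein, rp$mean_protein)
  if (burn_in_hr > 0) {
    cut <- burn_in_hr * 3600
    keep <- df$time_s >= cut
    # keep the state holding at the cut
    first <- max(which(df$time_s <= cut))
    df <- rbind(transform(df[first, ], time_s = cut), df[keep, ])
    rownames(df) <- NULL
  }
  df
}

#' Simulated noise series of the activation signal
#'
#' Simulates \eqn{\alpha(t)} for a given burst size and returns its
#' time-weighted coefficient of variation along with the trace.  The CV is
#' computed with time-weighted (piecewise-constant) averaging.  A warning is
#' issued when the duration is shorter than 50 protein lifetimes, below which
#' CV estimates are unstable.
#'
#' @param b burst size.
#' @param duration_hr simulated duration in hours (default 2000).
#' @param mean_protein target protein mean.
#' @param seed integer seed.
#' @param d_R,d_P decay rates (hr^-1).
#' @return A list with `trace` (the data frame from [simulate_regulator()]),
#'   `cv` (time-weighted CV of alpha), `mean_alpha`, `mean_protein_hat`, and
#'   `b`.
#' @export
noise_series <- function(b, duration_hr = 2000, mean_protein = 1000,
                         seed = NULL, d_R = 1 / 2, d_P = 1 / 12) {
  rp <- regulator_params(b, mean_protein, d_R, d_P)
  if (duration_hr < 50 / d_P) {
    warning("duration shorter than 50 protein lifetimes; CV estimate may be unstable")
  }
  tr <- simulate_regulator(rp, duration_hr, seed = seed)
  mu <- time_average(tr$time_s, tr$alpha)
  v <- time_average(tr$time_s, (tr$alpha - mu)^2)
  list(trace = tr, cv = sqrt(v) / mu, mean_alpha = mu,
       mean_protein_hat = mu * mean_protein, b = b)
}

#' Closed-form CV of the two-stage regulator
#'
#' Small-noise analytic approximation for the stationary protein coefficient
#' of variation,
#' \deqn{CV^2 \approx \frac{1 + b / (1 + d_P / d_R)}{\langle P \rangle},}
#' used as an independent check on simulated noise series.
#'
#' @param rp a [regulator_params()] object.
#' @return The predicted CV.
#' @export
regulator_cv_theory <- function(rp) {
  sqrt((1 + rp$b / (1 + rp$d_P / rp$d_R)) / rp$mean_protein)
}
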