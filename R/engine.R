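VARIANTS <- c("main", "two_state", "processive_methylation",
              "processive_demethylation", "promoter_switching")

#' Constant trans-activation input
#'
#' @param value the constant multiplier \eqn{\alpha}.
#' @return An `alpha_input` object.
#' @export
alpha_constant <- function(value = 1) {
  stopifnot(value >= 0)
  structure(list(mode = "constant", alpha = value), class = "alpha_input")
}

#' Step trans-activation protocol
#'
#' \eqn{\alpha} is held at `before` (typically 1, during equilibration) and
#' switched permanently to `after` at `switch_hr` hours.
#'
#' @param before,after multipliers before/after the switch (positive).
#' @param switch_hr switch time in hours from the start of the run.
#' @return An `alpha_input` object.
#' @export
alpha_step <- function(before = 1, after, switch_hr) {
  stopifnot(before > 0, after >= 0, switch_hr >= 0)
  structure(list(mode = "step", before = before, after = after,
                 switch_hr = switch_hr), class = "alpha_input")
}

#' Simulate the chromatin model
#'
#' Runs the direct-method stochastic simulation of any model variant.  All
#' propensities are recomputed after every update; DNA replication interrupts
#' the algorithm deterministically once per cell cycle; identical `seed` and
#' configuration give bit-identical trajectories.  If every propensity is zero
#' between replications the simulation advances directly to the next boundary
#' (absorbed-state handling).
#'
#' @param params a [chromatin_params()] object.
#' @param variant model variant: `"main"`, `"two_state"`,
#'   `"processive_methylation"`, `"processive_demethylation"` or
#'   `"promoter_switching"`.
#' @param burst a [burst_params()] object; required for (and only valid with)
#'   the `promoter_switching` variant.
#' @param initial_state `"uniform_me0"`, `"uniform_me3"`, or `"custom"` (then
#'   supply `initial_levels`).
#' @param initial_levels integer vector of starting methylation levels when
#'   `initial_state = "custom"`.
#' @param cycles number of cell cycles to simulate (may be fractional).
#' @param alpha_input trans-activation input: an [alpha_constant()],
#'   [alpha_step()], or [regulator_params()] object (the latter couples the
#'   chromatin SSA with a concurrently simulated two-stage regulator whose
#'   protein count sets \eqn{\alpha(t) = r(t)/\langle r \rangle}).  `NULL`
#'   uses the constant `params$alpha`.
#' @param replicate_dna if `FALSE`, DNA replication is disabled (used e.g. for
#'   stationary-distribution checks).
#' @param record `"events"` records one row per reaction (and per replication
#'   boundary); `"none"` records only snapshots and final summaries.
#' @param sample_times_hr times (hours) at which to record full state
#'   snapshots, including old/new pool sizes and their me3 counts.
#' @param label_time_hr if non-`NULL`, histones deposited at or after this
#'   time (hours) are labeled `new`; all earlier histones remain `old`.
#' @param stop_rule optional first-passage stopping rule,
#'   `list(dir = +1 or -1, threshold = count)`: the run stops the first time
#'   the repressive-mark count (me2+me3; me3 alone for the two-state variant)
#'   is strictly above (`dir = +1`) or strictly below (`dir = -1`) the
#'   threshold.
#' @param seed integer seed for reproducibility; `NULL` continues the current
#'   RNG stream.
#' @return An object of class `chromatin_trajectory`: a list with `events`
#'   (data frame of per-reaction records, or `NULL`), `samples` (snapshot data
#'   frame), `final` (levels/origin/age/promoter/regulator copy numbers),
#'   `tx_per_cycle`, `t_end`, `crossed`/`t_cross`, and the resolved
#'   configuration (`params`, `variant`, `burst`, `alpha_input`, `seed`).
#' @export
#' @examples
#' p <- chromatin_params()
#' tr <- simulate_chromatin(p, initial_state = "uniform_me3", cycles = 2,
#'                          seed = 1)
#' head(tr$events)
simulate_chromatin <- function(params, variant = "main", burst = NULL,
                               initial_state = c("uniform_me0", "uniform_me3",
                                                 "custom"),
                               initial_levels = NULL, cycles = 1,
                               alpha_input = NULL, replicate_dna = TRUE,
                               record = c("events", "none"),
                               sample_times_hr = NULL, label_time_hr = NULL,
                               stop_rule = NULL, seed = NULL) {
  stopifnot(inherits(params, "chromatin_params"))
  variant <- match.arg(variant, VARIANTS)
  initial_state <- match.arg(initial_state)
  record <- match.arg(record)
  stopifnot(cycles > 0)

  if (variant == "promoter_switching") {
    if (is.null(burst)) {
      stop("the promoter_switching variant requires `burst = burst_params(...)`")
    }
    stopifnot(inherits(burst, "burst_params"))
  } else if (!is.null(burst)) {
    stop("`burst` parameters are only valid with variant = \"promoter_switching\"")
  }

  levels0 <- switch(initial_state,
    uniform_me0 = rep(0L, params$N),
    uniform_me3 = rep(3L, params$N),
    custom = {
      if (is.null(initial_levels)) {
        stop("initial_state = \"custom\" requires `initial_levels`")
      }
      as.integer(initial_levels)
    }
  )
  if (length(levels0) != params$N) stop("initial_levels must have length N")
  if (variant == "two_state" && !all(levels0 %in% c(0L, 3L))) {
    stop("two_state variant requires initial levels in {0, 3}")
  }

  if (is.null(alpha_input)) alpha_input <- alpha_constant(params$alpha)
  if (inherits(alpha_input, "regulator_params")) {
    reg <- alpha_input
    amode <- 2L
    a0 <- a1 <- 1
    t_sw <- -1
  } else {
    stopifnot(inherits(alpha_input, "alpha_input"))
    reg <- NULL
    if (alpha_input$mode == "constant") {
      amode <- 0L; a0 <- a1 <- alpha_input$alpha; t_sw <- -1
    } else {
      amode <- 1L; a0 <- alpha_input$before; a1 <- alpha_input$after
      t_sw <- alpha_input$switch_hr * 3600
    }
  }

  if (!is.null(stop_rule)) {
    stopifnot(is.list(stop_rule), stop_rule$dir %in% c(-1, 1),
              is.numeric(stop_rule$threshold))
  }

  t_end <- cycles * params$T_cc
  cfg <- list(
    N = params$N, T_cc = params$T_cc,
    replicate_dna = isTRUE(replicate_dna),
    replication_survival = params$replication_survival,
    beta = params$beta,
    k_me0_1 = params$k_me0_1, k_me1_2 = params$k_me1_2, k_me = params$k_me,
    gamma_me0_1 = params$gamma_me0_1, gamma_me1_2 = params$gamma_me1_2,
    gamma_me2_3 = params$gamma_me2_3,
    rho_me2 = params$rho_me2,
    f_min = params$f_min, f_max = params$f_max, P_T = params$P_T,
    p_dem = params$p_dem, p_ex = params$p_ex,
    gamma_dem = params$gamma_dem, f_cap = params$f_cap,
    variant = match(variant, VARIANTS) - 1L,
    k_on_max = if (is.null(burst)) 0 else burst$k_on_max,
    k_off = if (is.null(burst)) 0 else burst$k_off,
    k_on_min = if (is.null(burst)) 0 else burst$k_on_min,
    f_0 = if (is.null(burst)) 0 else burst$f_0,
    k_on_cap = if (is.null(burst)) Inf else burst$k_on_cap,
    t_end = t_end,
    alpha_mode = amode, alpha0 = a0, alpha1 = a1, t_switch = t_sw,
    s_R = if (is.null(reg)) 0 else reg$s_R_per_s,
    d_R = if (is.null(reg)) 0 else reg$d_R_per_s,
    s_P = if (is.null(reg)) 0 else reg$s_P_per_s,
    d_P = if (is.null(reg)) 0 else reg$d_P_per_s,
    mean_protein = if (is.null(reg)) 1 else reg$mean_protein,
    m0 = if (is.null(reg)) 0L else reg$m0,
    p0 = if (is.null(reg)) 0L else reg$p0,
    record_events = record == "events",
    sample_times = if (is.null(sample_times_hr)) numeric(0) else
      sort(sample_times_hr) * 3600,
    stop_dir = if (is.null(stop_rule)) 0L else as.integer(stop_rule$dir),
    stop_threshold = if (is.null(stop_rule)) 0 else stop_rule$threshold,
    label_time = if (is.null(label_time_hr)) -1 else label_time_hr * 3600,
    initial_levels = levels0,
    promoter0 = 0L
  )

  if (!is.null(seed)) set.seed(seed)
  raw <- cpp_simulate(cfg)

  events <- if (!is.null(raw$events)) {
    ev <- as.data.frame(raw$events)
    ev$event <- EVENT_NAMES[ev$event + 1L]
    ev
  }
  samples <- as.data.frame(raw$samples)

  structure(list(
    events = events, samples = samples,
    final = list(
      levels = raw$final_levels,
      origin = c("replication_deposited", "exchange_deposited")[raw$final_origin + 1L],
      age = c("old", "new")[raw$final_age + 1L],
      promoter = c("closed", "open")[raw$promoter + 1L],
      mRNA = raw$mRNA, protein = raw$protein
    ),
    t_end = raw$t_final, crossed = raw$crossed, t_cross = raw$t_cross,
    tx_total = raw$tx_total, tx_per_cycle = raw$tx_per_cycle,
    params = params, variant = variant, burst = burst,
    alpha_input = alpha_input, seed = seed
  ), class = "chromatin_trajectory")
}

EVENT_NAMES <- c("init", "methylation", "demethylation", "transcription",
                 "replication", "promoter_open", "promoter_close",
                 "mrna_birth", "mrna_death", "protein_birth", "protein_death",
                 "alpha_step", "end")

#' @export
print.chromatin_trajectory <- function(x, ...) {
  cat(sprintf("Chromatin trajectory (%s variant): %.3g hr, %d transcription events\n",
              x$variant, x$t_end / 3600, as.integer(x$tx_total)))
  n <- x$final$levels
  cat(sprintf("  final me0/me1/me2/me3 counts: %d/%d/%d/%d\n",
              sum(n == 0), sum(n == 1), sum(n == 2), sum(n == 3)))
  if (isTRUE(x$crossed)) {
    cat(sprintf("  stopped at first passage, t = %.3g hr\n", x$t_cross / 3600))
  }
  invisible(x)
}

#' First-passage thresholds for a parameter set
#'
#' The repressed-state entry threshold (repressive marks strictly above
#' `3 N P_T / 4`) and the active-state entry threshold (strictly below
#' `N P_T / 4`).  The two-state variant uses `P_T = 1` with me3 counts.
#'
#' @param params a [chromatin_params()] object.
#' @param variant model variant.
#' @return Named list with `upper` and `lower` count thresholds.
#' @export
passage_thresholds <- function(params, variant = "main") {
  P_T <- if (identical(variant, "two_state")) 1 else params$P_T
  list(upper = 3 * params$N * P_T / 4, lower = params$N * P_T / 4)
}

#' Replicated first-passage simulation
#'
#' Runs `n_rep` independent simulations from a uniform initial state and
#' records, for each, the first time the opposite chromatin state's threshold
#' is crossed (from uniform me0: repressive marks strictly above
#' `3 N P_T / 4`; from uniform me3: strictly below `N P_T / 4`).  Times are
#' censored at the total simulated time, which they enter as-is (the bounded
#' first-passage convention).
#'
#' @inheritParams simulate_chromatin
#' @param initial_state `"uniform_me0"` or `"uniform_me3"`.
#' @param n_rep number of replicate simulations.
#' @param censor_cycles total simulated time per replicate, in cell cycles.
#' @param base_seed replicate `i` runs with seed `base_seed + i`.
#' @return Numeric vector of first-passage times in seconds (censored values
#'   equal the total time), with attributes `censor_s` and `n_censored`.
#' @export
first_passage_times <- function(params, variant = "main", burst = NULL,
                                initial_state = c("uniform_me0", "uniform_me3"),
                                n_rep = 50, censor_cycles = 400,
                                alpha_input = NULL, base_seed = 1) {
  initial_state <- match.arg(initial_state)
  thr <- passage_thresholds(params, variant)
  rule <- if (initial_state == "uniform_me0") {
    list(dir = 1, threshold = thr$upper)
  } else {
    list(dir = -1, threshold = thr$lower)
  }
  censor_s <- censor_cycles * params$T_cc
  times <- vapply(seq_len(n_rep), function(i) {
    tr <- simulate_chromatin(params, variant = variant, burst = burst,
                             initial_state = initial_state,
                             cycles = censor_cycles,
                             alpha_input = alpha_input, record = "none",
                             stop_rule = rule, seed = base_seed + i)
    if (isTRUE(tr$crossed)) tr$t_cross else censor_s
  }, numeric(1))
  structure(times, censor_s = censor_s,
            n_censored = sum(times >= censor_s))
}
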