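fitted <- chromatin_params()

test_that("time averaging of piecewise-constant signals", {
  expect_equal(time_average(c(0, 2), c(1, 0), 0, 10), 0.2)
  expect_equal(time_average(c(0, 5, 9), c(3, 3, 3), 0, 9), 3)
  # additivity: whole window equals duration-weighted mean of two halves
  tm <- c(0, 1, 4, 6, 9)
  x <- c(2, 5, 1, 7, 7)
  whole <- time_average(tm, x, 0, 10)
  half <- (time_average(tm, x, 0, 5) * 5 + time_average(tm, x, 5, 10) * 5) / 10
  expect_equal(whole, half)
  expect_error(time_average(c(0, 1), c(1, 1), 3, 3), "zero-length")
})

test_that("ON/OFF probabilities use strict quartile thresholds with ties excluded", {
  N <- 60; P_T <- 1 / 3
  # pinned trajectories
  expect_equal(p_on_off(c(0, 1e5), c(60, 60), N, P_T, T_cc = 79200),
               c(P_ON = 0, P_OFF = 1))
  expect_equal(p_on_off(c(0, 1e5), c(0, 0), N, P_T, T_cc = 79200),
               c(P_ON = 1, P_OFF = 0))
  # exact ties (n = 15 upper, n = 5 lower) count as neither
  expect_equal(p_on_off(c(0, 1e5), c(15, 15), N, P_T, T_cc = 79200),
               c(P_ON = 0, P_OFF = 0))
  expect_equal(p_on_off(c(0, 1e5), c(5, 5), N, P_T, T_cc = 79200),
               c(P_ON = 0, P_OFF = 0))
})

test_that("constructed fixture spending 40% above and 40% below thresholds gives (0.4, 0.4)", {
  T_cc <- 79200
  # two cycles; each last-hour window: 40% of the time above 15, then 40%
  # below 5, then 20% in between
  tm <- c(0, T_cc - 3600, T_cc - 3600 + 0.4 * 3600, T_cc - 3600 + 0.8 * 3600,
          T_cc, 2 * T_cc - 3600, 2 * T_cc - 3600 + 0.4 * 3600,
          2 * T_cc - 3600 + 0.8 * 3600)
  n <- c(10, 20, 2, 10, 10, 20, 2, 10)
  res <- p_on_off(tm, n, 60, 1 / 3, T_cc = T_cc, t_end = 2 * T_cc)
  expect_equal(unname(res), c(0.4, 0.4))
  expect_equal(bistability(res[["P_ON"]], res[["P_OFF"]]), 0.64)
})

test_that("with P_T = 1 the thresholds reduce to the quarter-of-N definitions", {
  set.seed(5)
  tm <- sort(runif(200, 0, 79200 * 2))
  n <- sample(0:60, 200, replace = TRUE)
  a <- p_on_off(tm, n, 60, P_T = 1, T_cc = 79200, t_end = 2 * 79200)
  # explicit threshold-free definitions: OFF above 3N/4, ON below N/4
  off <- as.numeric(n > 45)
  on <- as.numeric(n < 15)
  wins <- rbind(c(79200 - 3600, 79200), c(2 * 79200 - 3600, 2 * 79200))
  integ <- function(v) {
    s <- 0
    for (w in 1:2) {
      s <- s + time_average(tm, v, wins[w, 1], wins[w, 2]) * 3600
    }
    s / 7200
  }
  expect_equal(a[["P_OFF"]], integ(off))
  expect_equal(a[["P_ON"]], integ(on))
})

test_that("last-hour windowing differs from whole-cycle averaging only with transients", {
  T_cc <- 79200
  # within-cycle transient: repressive marks dip right after 'replication'
  tm <- c(0, 3600 * 5, T_cc)
  n <- c(10, 55, 55)
  last <- p_on_off(tm, n, 60, 1 / 3, T_cc = T_cc, t_end = T_cc)
  whole <- p_on_off(tm, n, 60, 1 / 3, T_cc = T_cc, window = "all",
                    t_end = T_cc)
  expect_equal(last[["P_OFF"]], 1)
  expect_lt(whole[["P_OFF"]], 1)
  # no transient: identical
  flat <- p_on_off(c(0, T_cc), c(55, 55), 60, 1 / 3, T_cc = T_cc,
                   t_end = T_cc)
  flat_all <- p_on_off(c(0, T_cc), c(55, 55), 60, 1 / 3, T_cc = T_cc,
                       window = "all", t_end = T_cc)
  expect_equal(flat, flat_all)
})

test_that("bistability measure is bounded, symmetric and maximized at balance", {
  expect_equal(bistability(0.5, 0.5), 1)
  expect_equal(bistability(0, 1), 0)
  expect_equal(bistability(0.4, 0.4), 0.64)
  set.seed(1)
  for (r in 1:20) {
    a <- runif(1); b <- runif(1, 0, 1 - a)
    expect_equal(bistability(a, b), bistability(b, a))
    expect_gte(bistability(a, b), 0)
    expect_lte(bistability(a, b), 1)
    expect_lte(bistability(a, b), bistability((a + b) / 2, (a + b) / 2))
  }
})

test_that("combined first passage: censoring bounds and substitution identities", {
  T_tot <- 100
  expect_equal(combined_first_passage(100, 100, T_tot), 1)
  expect_equal(combined_first_passage(50, 100, T_tot), 0.5)
  expect_error(combined_first_passage(150, 100, T_tot))
  set.seed(2)
  for (r in 1:20) {
    t1 <- runif(1, 1, T_tot); t2 <- runif(1, 1, T_tot)
    fp <- combined_first_passage(t1, t2, T_tot)
    expect_gt(fp, 0)
    expect_lte(fp, 1)
  }
})

test_that("transcriptional output matches a rate-times-time oracle", {
  # constant-rate construction: two-state variant with methylation off keeps
  # f = f_max = 4e-3 /s, i.e. 14.4 events per hour in expectation
  p <- chromatin_params(k_me = 0, p_dem = 0, p_ex = 0, f_max = 4e-3, P_T = 1)
  counts <- vapply(1:60, function(i) {
    tr <- simulate_chromatin(p, variant = "two_state",
                             initial_state = "uniform_me0", cycles = 1,
                             record = "none", seed = 600 + i)
    transcriptional_output(tr, 1)
  }, numeric(1))
  expected <- 4e-3 * 3600                      # 14.4 per hour
  se <- sqrt(expected / 22) / sqrt(60)         # Poisson error of the mean
  expect_lt(abs(mean(counts) - expected), 3 * se)
  # zero events give zero output
  p0 <- chromatin_params(k_me = 0, p_dem = 0, p_ex = 0, alpha = 0)
  tr0 <- simulate_chromatin(p0, initial_state = "uniform_me0", cycles = 1,
                            record = "none", seed = 1)
  expect_equal(transcriptional_output(tr0, 1), 0)
})

test_that("H3.3 asymmetry vanishes without exchange and for identical pools", {
  p <- update_params(fitted, p_ex = 0)
  on <- lapply(1:3, function(i) {
    simulate_chromatin(p, initial_state = "uniform_me0", cycles = 2,
                       seed = 70 + i)
  })
  off <- lapply(1:3, function(i) {
    simulate_chromatin(p, initial_state = "uniform_me3", cycles = 2,
                       seed = 80 + i)
  })
  expect_equal(h33_asymmetry(on, off), 0)
  expect_equal(h33_asymmetry(off, off), 0)
})

test_that("transcription-dependent H3.3 accumulates in the active state", {
  on <- lapply(1:6, function(i) {
    simulate_chromatin(fitted, initial_state = "uniform_me0", cycles = 20,
                       seed = 900 + i)
  })
  off <- lapply(1:6, function(i) {
    simulate_chromatin(fitted, initial_state = "uniform_me3", cycles = 20,
                       seed = 950 + i)
  })
  H <- h33_asymmetry(on, off)
  expect_gt(H, 0.2)
  expect_gt(mean(vapply(on, h33_fraction, numeric(1))),
            mean(vapply(off, h33_fraction, numeric(1))))
})
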