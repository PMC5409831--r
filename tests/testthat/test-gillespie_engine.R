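fitted <- chromatin_params()

test_that("identical seed and configuration give bit-identical trajectories", {
  a <- simulate_chromatin(fitted, initial_state = "uniform_me3", cycles = 2,
                          seed = 99)
  b <- simulate_chromatin(fitted, initial_state = "uniform_me3", cycles = 2,
                          seed = 99)
  expect_identical(a$events, b$events)
  expect_identical(a$final, b$final)
})

test_that("histone count is conserved through every event, exchange and replication", {
  p <- update_params(fitted, p_ex = 0.05, p_dem = 0.1, k_me = 5e-5)
  tr <- simulate_chromatin(p, initial_state = "uniform_me3", cycles = 4,
                           seed = 12)
  ev <- tr$events
  expect_true(all(ev$n_me0 + ev$n_me1 + ev$n_me2 + ev$n_me3 == 60))
  expect_true(all(diff(ev$time_s) >= 0))
  expect_true(any(ev$event == "replication"))
  expect_true(any(ev$event == "transcription"))
})

test_that("replication fires exactly once per cell cycle in any rate regime", {
  for (p in list(fitted, update_params(fitted, k_me = 1e-4, p_dem = 0.1))) {
    tr <- simulate_chromatin(p, initial_state = "uniform_me0", cycles = 5.5,
                             seed = 4)
    repl_t <- tr$events$time_s[tr$events$event == "replication"]
    expect_equal(repl_t, (1:5) * p$T_cc)
  }
})

test_that("zero-propensity (absorbed) states advance through replication boundaries", {
  p <- update_params(fitted, k_me = 0, p_dem = 0, p_ex = 0, alpha = 0)
  tr <- simulate_chromatin(p, initial_state = "uniform_me0", cycles = 2.5,
                           seed = 1)
  kinds <- table(tr$events$event)
  expect_equal(sum(tr$events$event == "replication"), 2)
  expect_equal(nrow(tr$events), 4)  # init + 2 replications + end
  expect_equal(tr$tx_total, 0)
})

test_that("rescaled waiting times of a constant-rate regime are unit exponential", {
  # two-state variant with methylation off and p_dem = 0 from uniform me0:
  # the only reaction is transcription at constant rate f_max
  p <- chromatin_params(k_me = 0, p_dem = 0, p_ex = 0, f_max = 4e-3,
                        f_min = 1e-4, P_T = 1)
  tr <- simulate_chromatin(p, variant = "two_state",
                           initial_state = "uniform_me0", cycles = 40,
                           replicate_dna = FALSE, seed = 8)
  ev <- tr$events
  w <- diff(ev$time_s[ev$event %in% c("init", "transcription")])
  expect_gt(length(w), 2000)
  ks <- stats::ks.test(w * p$f_max, "pexp")
  expect_gt(ks$p.value, 0.01)
})

test_that("two-state variant stays on the me0/me3 lattice", {
  p <- chromatin_params(k_me = 1e-4, p_dem = 0.02, P_T = 1)
  tr <- simulate_chromatin(p, variant = "two_state",
                           initial_state = "uniform_me3", cycles = 3, seed = 5)
  expect_true(all(tr$final$levels %in% c(0L, 3L)))
  expect_true(all(tr$events$n_me1 == 0))
  expect_true(all(tr$events$n_me2 == 0))
})

test_that("processive methylation jumps straight to me3", {
  # from uniform me0 with demethylation off, no me1/me2 can ever appear
  p <- update_params(fitted, k_me = 1e-4, p_dem = 0, p_ex = 0)
  tr <- simulate_chromatin(p, variant = "processive_methylation",
                           initial_state = "uniform_me0", cycles = 2, seed = 31)
  expect_true(all(tr$events$n_me1 == 0))
  expect_true(all(tr$events$n_me2 == 0))
  expect_gt(sum(tr$events$event == "methylation"), 0)
})

test_that("processive demethylation jumps straight to me0", {
  # from uniform me3 with methylation and exchange off, no me1/me2 appears
  p <- update_params(fitted, k_me = 0, p_dem = 0.2, p_ex = 0)
  tr <- simulate_chromatin(p, variant = "processive_demethylation",
                           initial_state = "uniform_me3", cycles = 2,
                           replicate_dna = FALSE, seed = 32)
  expect_true(all(tr$events$n_me1 == 0))
  expect_true(all(tr$events$n_me2 == 0))
  expect_gt(sum(tr$events$n_me0[nrow(tr$events)]), 0)
})

test_that("methyl count is monotone when removal (or addition) is switched off", {
  # no demethylation, no exchange, no replication: non-decreasing
  p_up <- update_params(fitted, k_me = 5e-5, p_dem = 0, p_ex = 0)
  tr <- simulate_chromatin(p_up, initial_state = "uniform_me0", cycles = 2,
                           replicate_dna = FALSE, seed = 21)
  ev <- tr$events
  methyl <- ev$n_me1 + 2 * ev$n_me2 + 3 * ev$n_me3
  expect_true(all(diff(methyl) >= 0))

  # no methylation at all: non-increasing
  p_down <- update_params(fitted, k_me = 0, p_dem = 0.2, p_ex = 1e-3)
  tr2 <- simulate_chromatin(p_down, initial_state = "uniform_me3", cycles = 2,
                            replicate_dna = FALSE, seed = 22)
  ev2 <- tr2$events
  methyl2 <- ev2$n_me1 + 2 * ev2$n_me2 + 3 * ev2$n_me3
  expect_true(all(diff(methyl2) <= 0))
})

test_that("step protocol switches alpha at the requested time", {
  p <- update_params(fitted, k_me = 0, p_dem = 0, p_ex = 0)
  tr <- simulate_chromatin(p, initial_state = "uniform_me0", cycles = 2,
                           alpha_input = alpha_step(1, 3, switch_hr = 11),
                           seed = 2)
  ev <- tr$events
  expect_true("alpha_step" %in% ev$event)
  expect_true(all(ev$alpha[ev$time_s < 11 * 3600] == 1))
  expect_true(all(ev$alpha[ev$time_s >= 11 * 3600] == 3))
  # transcription rate tripled after the switch (Poisson counts)
  n1 <- sum(ev$event == "transcription" & ev$time_s < 11 * 3600)
  n2 <- sum(ev$event == "transcription" & ev$time_s >= 11 * 3600 &
              ev$time_s < 22 * 3600)
  expect_gt(n2, n1)
})

test_that("coupled regulator drives alpha as protein count over its mean", {
  p <- update_params(fitted, k_me = 0, p_dem = 0, p_ex = 0)
  rp <- regulator_params(b = 1)
  tr <- simulate_chromatin(p, initial_state = "uniform_me0", cycles = 2,
                           alpha_input = rp, seed = 14)
  ev <- tr$events
  expect_true(any(ev$event %in% c("protein_birth", "protein_death")))
  a_bar <- time_average(ev$time_s, ev$alpha)
  expect_equal(a_bar, 1, tolerance = 0.1)       # b = 1: CV ~ 0.04
  expect_lt(signal_cv(ev$time_s, ev$alpha), 0.1)
})

test_that("configuration errors are rejected with named messages", {
  expect_error(simulate_chromatin(fitted, variant = "two_state",
                                  burst = burst_params(5e-4, 5e-3),
                                  initial_state = "uniform_me0"),
               "promoter_switching")
  expect_error(simulate_chromatin(fitted, variant = "promoter_switching",
                                  initial_state = "uniform_me0"),
               "burst_params")
  expect_error(simulate_chromatin(fitted, initial_state = "custom"),
               "initial_levels")
  expect_error(simulate_chromatin(fitted, variant = "two_state",
                                  initial_state = "custom",
                                  initial_levels = rep(1L, 60)),
               "\\{0, 3\\}")
})

test_that("first-passage runs stop at the crossing and censor correctly", {
  # strong activation from the repressed state collapses quickly
  p <- update_params(fitted, alpha = 50)
  fp <- first_passage_times(p, initial_state = "uniform_me3", n_rep = 8,
                            censor_cycles = 50, base_seed = 9)
  expect_true(all(fp <= 50 * fitted$T_cc))
  expect_lt(mean(fp) / fitted$T_cc, 10)
  expect_equal(attr(fp, "n_censored"), 0)

  # fully censored runs return the bound
  p_frozen <- update_params(fitted, k_me = 0, p_dem = 0, p_ex = 0, alpha = 0)
  fp2 <- first_passage_times(update_params(p_frozen, replication_survival = 1),
                             initial_state = "uniform_me3", n_rep = 3,
                             censor_cycles = 5, base_seed = 2)
  expect_true(all(fp2 == 5 * fitted$T_cc))
  expect_equal(attr(fp2, "n_censored"), 3)
})
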