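fitted <- chromatin_params()

test_that("parameter derivations follow the model definitions", {
  expect_equal(fitted$k_me0_1, 9 * fitted$k_me)
  expect_equal(fitted$k_me1_2, 6 * fitted$k_me)
  expect_equal(fitted$gamma_me0_1, fitted$k_me0_1 / 20)
  expect_equal(fitted$gamma_me2_3, fitted$k_me / 20)
  expect_equal(fitted$gamma_dem, fitted$f_min * fitted$p_dem)
  expect_equal(fitted$gamma_dem, 4e-7)
  expect_equal(fitted$F, 40)
  expect_equal(fitted$T_cc, 22 * 3600)

  # derived fields always recomputed from primitives
  p2 <- update_params(fitted, k_me = 1e-5, f_min = 2e-4)
  expect_equal(p2$k_me0_1, 9e-5)
  expect_equal(p2$gamma_dem, 2e-4 * fitted$p_dem)
  expect_error(update_params(fitted, gamma_dem = 1), "primitive")

  expect_error(chromatin_params(N = 61), "N")
  expect_error(chromatin_params(p_dem = 1.5))
  expect_error(chromatin_params(f_min = 0))
  expect_error(chromatin_params(P_T = 0))
})

test_that("neighbor sets follow the odd/even nucleosome-pair rule with boundary truncation", {
  expect_equal(neighbor_indices(5, 60), c(3, 4, 6, 7, 8))
  expect_equal(neighbor_indices(1, 60), c(2, 3, 4))
  expect_equal(neighbor_indices(60, 60), c(57, 58, 59))
  expect_equal(neighbor_indices(6, 60), c(3, 4, 5, 7, 8))
  # every neighborhood is symmetric: j in M_i iff i in M_j
  for (i in 1:20) {
    for (j in neighbor_indices(i, 20)) {
      expect_true(i %in% neighbor_indices(j, 20))
    }
  }
})

test_that("feedback sum weights me2 by rho and me3 by one", {
  lv <- rep(0L, 60)
  expect_equal(feedback_sum(lv, 10), 0)
  lv[neighbor_indices(10, 60)] <- 3L
  expect_equal(feedback_sum(lv, 10), 5)
  lv2 <- rep(1L, 60)
  lv2[neighbor_indices(10, 60)] <- c(2L, 2L, 1L, 1L, 1L)
  expect_equal(feedback_sum(lv2, 10, rho_me2 = 0.1), 0.2)
})

test_that("methylation propensity matches the stimulated + noisy form", {
  lv <- rep(0L, 60)
  lv[10] <- 2L
  lv[11] <- 3L   # one me3 neighbor of histone 10 -> E = 1
  expect_equal(methylation_propensity(lv, 10, fitted),
               fitted$k_me / 20 + fitted$k_me)  # 8.4e-6
  lv[10] <- 3L
  expect_equal(methylation_propensity(lv, 10, fitted), 0)
  lv0 <- rep(0L, 60)
  expect_equal(methylation_propensity(lv0, 10, fitted), 9 * 8e-6 / 20)
  # beta scales the whole propensity
  pb <- update_params(fitted, beta = 2)
  expect_equal(methylation_propensity(lv0, 10, pb),
               2 * methylation_propensity(lv0, 10, fitted))
})

test_that("noisy demethylation is level-independent above me0", {
  lv <- c(0L, 1L, 2L, 3L, rep(0L, 56))
  expect_equal(noisy_demethylation_propensity(lv, 1, fitted), 0)
  expect_equal(noisy_demethylation_propensity(lv, 2, fitted), 4e-7)
  expect_equal(noisy_demethylation_propensity(lv, 4, fitted), 4e-7)
})

test_that("transcription rate interpolates, saturates at P_T, and is capped", {
  N <- 60
  expect_equal(transcription_propensity(rep(0L, N), fitted), 4e-3)
  lv <- c(rep(3L, 20), rep(0L, 40))     # P = 1/3 = P_T
  expect_equal(transcription_propensity(lv, fitted), 1e-4)
  lv2 <- c(rep(2L, 10), rep(0L, 50))    # P = 1/6
  expect_equal(transcription_propensity(lv2, fitted), 4e-3 - 0.5 * 3.9e-3)
  expect_equal(transcription_propensity(rep(0L, N), fitted, alpha = 10), 1 / 60)
  expect_equal(transcription_propensity(rep(3L, N), fitted, alpha = 0.5),
               0.5 * 1e-4)  # alpha scales below f_min too
})

test_that("two-state propensities use mean-field feedback and reject mixed levels", {
  p <- update_params(fitted, P_T = 1)
  tp <- two_state_propensities(rep(0L, 60), p)
  expect_equal(tp$transcription, p$f_max)
  expect_equal(tp$methylation, rep(p$gamma_me2_3, 60))
  tp3 <- two_state_propensities(rep(3L, 60), p)
  expect_equal(tp3$transcription, p$f_min)
  expect_equal(tp3$methylation, rep(0, 60))
  tp1 <- two_state_propensities(c(3L, 0L), update_params(p, N = 2))
  expect_equal(tp1$transcription, p$f_max - (p$f_max - p$f_min) / 2)
  expect_error(two_state_propensities(c(1L, 0L), p), "me0, me3")
})

test_that("processive variants jump to the endpoint, main model steps by one", {
  expect_equal(processive_update(1, "methylation", "processive_methylation"), 3L)
  expect_equal(processive_update(3, "demethylation", "processive_demethylation"), 0L)
  expect_equal(processive_update(1, "methylation", "main"), 2L)
  expect_equal(processive_update(2, "demethylation", "main"), 1L)
  expect_error(processive_update(3, "methylation"))
})

test_that("transcription-event effects: exchange resets pairs, demethylation steps once", {
  st <- chromatin_state(rep(3L, 60))
  p0 <- update_params(fitted, p_dem = 0, p_ex = 0)
  expect_identical(apply_transcription_event(st, p0)$levels, st$levels)

  p_ex1 <- update_params(fitted, p_ex = 1)
  out <- apply_transcription_event(st, p_ex1)
  expect_true(all(out$levels == 0L))
  expect_true(all(out$origin == "exchange_deposited"))

  p_dem1 <- update_params(fitted, p_dem = 1, p_ex = 0)
  out2 <- apply_transcription_event(st, p_dem1)
  expect_true(all(out2$levels == 2L))

  # exchange always resets complete nucleosome pairs
  set.seed(42)
  p_half <- update_params(fitted, p_ex = 0.3, p_dem = 0)
  for (r in 1:20) {
    out3 <- apply_transcription_event(chromatin_state(rep(3L, 60)), p_half)
    hit <- which(out3$levels == 0L)
    pairs <- matrix(seq_len(60), nrow = 2)
    for (k in seq_len(30)) {
      expect_equal(pairs[1, k] %in% hit, pairs[2, k] %in% hit)
    }
  }
})

test_that("per-histone loss rate through exchange is about 2 f p_ex", {
  set.seed(7)
  p <- update_params(fitted, p_ex = 0.02, p_dem = 0)
  n_ev <- 4000
  lost <- 0
  for (r in seq_len(n_ev)) {
    out <- apply_transcription_event(chromatin_state(rep(3L, 60)), p)
    lost <- lost + sum(out$levels == 0L)
  }
  per_event <- lost / n_ev / 60
  # replacement prob per histone = 1 - (1 - p_ex)^2 ~ 2 p_ex
  expect_equal(per_event, 2 * 0.02, tolerance = 0.05)
})

test_that("replication resets whole nucleosomes at the expected rate", {
  st <- chromatin_state(rep(3L, 60))
  keep_all <- update_params(fitted, replication_survival = 1)
  expect_identical(apply_replication(st, keep_all)$levels, st$levels)

  set.seed(11)
  reps <- 2000
  replaced <- numeric(reps)
  for (r in seq_len(reps)) {
    out <- apply_replication(st, fitted)
    replaced[r] <- sum(out$levels == 0L)
    hit <- which(out$levels == 0L)
    if (length(hit)) {
      expect_true(all(tapply(hit, (hit - 1) %/% 2, length) == 2))
    }
  }
  se <- sd(replaced) / sqrt(reps)
  expect_lt(abs(mean(replaced) - 30), 3 * se)
})

test_that("burst parameter derivations reproduce the fold-change identity", {
  bp <- burst_params(5e-4, 5e-3, f_min = 1e-4)
  expect_equal(bp$k_on_min, 5e-4 * 5e-3 / (39 * 5e-4 + 40 * 5e-3))
  expect_equal(bp$k_on_min, 1.139e-5, tolerance = 1e-3)
  expect_equal(bp$f_0, 4.40e-2, tolerance = 1e-2)
  expect_equal(bp$fold_change, 40)
  expect_equal(burst_fold_change(5e-4, bp$k_on_min, 5e-3), 40)
  # identity holds across admissible (k_on_max, k_off)
  for (km in c(1e-5, 1e-4, 1e-3)) {
    for (ko in c(1e-3, 1e-2)) {
      if (km > ko) next
      b <- burst_params(km, ko)
      expect_equal(b$fold_change, 40, tolerance = 1e-12)
    }
  }
  # cap applies only when f_0 exceeds the initiation limit
  expect_equal(bp$k_on_cap, 5e-3 / (60 * bp$f_0 - 1))
  slow <- burst_params(1e-3, 1e-2)   # k_on_min larger -> f_0 below 1/60
  expect_true(!is.finite(slow$k_on_cap) || slow$f_0 > 1 / 60)
  expect_error(burst_params(1e-2, 1e-3), "k_on_max <= k_off")
})

test_that("burst k_on mirrors the main-model transcription function", {
  bp <- burst_params(5e-4, 5e-3)
  expect_equal(burst_k_on(rep(0L, 60), fitted, bp), bp$k_on_max)
  expect_equal(burst_k_on(rep(3L, 60), fitted, bp), bp$k_on_min)
  # mean initiation rate at full repression equals f_min
  expect_equal(bp$f_0 * bp$k_on_min / (bp$k_on_min + bp$k_off), 1e-4)
})

test_that("propensity exclusions hold on random reachable states", {
  set.seed(3)
  for (r in 1:50) {
    lv <- sample(0:3, 60, replace = TRUE)
    i <- sample(60, 1)
    m <- methylation_propensity(lv, i, fitted)
    d <- noisy_demethylation_propensity(lv, i, fitted)
    expect_gte(m, 0)
    expect_gte(d, 0)
    if (lv[i] == 3L) expect_equal(m, 0)
    if (lv[i] == 0L) expect_equal(d, 0)
    expect_gt(transcription_propensity(lv, fitted), 0)
  }
})
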