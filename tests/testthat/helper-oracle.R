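# Exact-oracle utilities shared across test files.

# Generator matrix of the N = 4 chromatin model as a 256-state continuous-time
# Markov chain, built from the R-level propensity functions (independent of
# the C++ engine).  Requires p_ex = 0 and no replication; transcription jumps
# are enumerated over all subsets of methylated histones.
ctmc_generator_n4 <- function(params) {
  stopifnot(params$N == 4, params$p_ex == 0)
  nS <- 256
  idx <- function(s) sum(s * 4^(seq_along(s) - 1)) + 1
  states <- as.matrix(expand.grid(s1 = 0:3, s2 = 0:3, s3 = 0:3, s4 = 0:3))
  states <- states[order(states %*% 4^(0:3)), , drop = FALSE]
  Q <- matrix(0, nS, nS)
  for (k in seq_len(nS)) {
    s <- states[k, ]
    for (i in 1:4) {
      r <- methylation_propensity(s, i, params)
      if (r > 0) {
        s2 <- s; s2[i] <- s[i] + 1L
        Q[k, idx(s2)] <- Q[k, idx(s2)] + r
      }
      r <- noisy_demethylation_propensity(s, i, params)
      if (r > 0) {
        s2 <- s; s2[i] <- s[i] - 1L
        Q[k, idx(s2)] <- Q[k, idx(s2)] + r
      }
    }
    f <- transcription_propensity(s, params)
    meth <- which(s >= 1)
    if (length(meth)) {
      for (mask in seq_len(2^length(meth) - 1)) {
        bits <- as.integer(intToBits(mask))[seq_along(meth)]
        pr <- prod(ifelse(bits == 1, params$p_dem, 1 - params$p_dem))
        s2 <- s
        s2[meth[bits == 1]] <- s2[meth[bits == 1]] - 1L
        Q[k, idx(s2)] <- Q[k, idx(s2)] + f * pr
      }
    }
    Q[k, k] <- 0
  }
  diag(Q) <- -rowSums(Q)
  Q
}

ctmc_stationary <- function(Q) {
  nS <- nrow(Q)
  qr.solve(rbind(t(Q), rep(1, nS)), c(rep(0, nS), 1))
}

# Time-weighted per-state occupancy of the N = 4 engine, accumulated over
# chained segments (each segment is one batch for standard-error estimation).
ssa_occupancy_n4 <- function(params, n_seg = 50, t_seg = 3e4, seed = 1) {
  occ <- matrix(0, n_seg, 256)
  lv <- rep(0L, 4)
  set.seed(seed)
  for (sg in seq_len(n_seg)) {
    tr <- simulate_chromatin(params, initial_state = "custom",
                             initial_levels = lv, cycles = t_seg / params$T_cc,
                             replicate_dna = FALSE, seed = NULL)
    ev <- tr$events
    dt <- diff(ev$time_s)
    cd <- ev$state_code[-nrow(ev)]
    agg <- rowsum(dt, cd)
    occ[sg, as.integer(rownames(agg)) + 1] <- agg[, 1] / t_seg
    lv <- tr$final$levels
  }
  occ
}

# fast-mixing balanced parameter set used for the oracle comparison
oracle_params <- function() {
  chromatin_params(N = 4, k_me = 0.8, f_min = 1, f_max = 2, P_T = 1,
                   p_dem = 0.35, p_ex = 0, f_cap = 1e9, cell_cycle_hr = 1e6)
}
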