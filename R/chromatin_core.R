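#' Chromatin state
#'
#' A per-histone snapshot of the model state: methylation levels, deposition
#' origin (replication- vs exchange-deposited, used for H3.1/H3.3
#' bookkeeping), age (old vs new, used for SILAC-style labeling), the promoter
#' flag of the bursty variant, and the clock time.
#'
#' @param levels integer vector of methylation levels in 0..3, one per
#'   histone; length must be even (nucleosomes are consecutive pairs).
#' @param origin character vector, `"replication_deposited"` or
#'   `"exchange_deposited"`; recycled.
#' @param age character vector, `"old"` or `"new"`; recycled.
#' @param promoter `"open"` or `"closed"` (promoter-switching variant only).
#' @param t time in seconds.
#' @return An object of class `chromatin_state`.
#' @export
chromatin_state <- function(levels, origin = "replication_deposited",
                            age = "old", promoter = "closed", t = 0) {
  levels <- as.integer(levels)
  N <- length(levels)
  stopifnot(N >= 2, N %% 2 == 0, all(levels >= 0 & levels <= 3))
  origin <- rep_len(origin, N)
  age <- rep_len(age, N)
  stopifnot(all(origin %in% c("replication_deposited", "exchange_deposited")),
            all(age %in% c("old", "new")),
            promoter %in% c("open", "closed"), t >= 0)
  structure(list(levels = levels, origin = origin, age = age,
                 promoter = promoter, t = t),
            class = "chromatin_state")
}

#' Uniform initial states
#'
#' @param N histone count (even).
#' @param level methylation level 0..3 for all histones.
#' @return A [chromatin_state()].
#' @export
uniform_state <- function(N, level) chromatin_state(rep(as.integer(level), N))

#' Feedback neighborhood of a histone
#'
#' The histones whose me2/me3 marks allosterically stimulate PRC2 acting on
#' histone `i`: the partner histone of the same nucleosome and the four
#' histones of the two flanking nucleosomes.  With 1-based indexing and
#' nucleosomes (k, k+1) for odd k, this is \{i-3, i-2, i-1, i+1, i+2\} for
#' even `i` and \{i-2, i-1, i+1, i+2, i+3\} for odd `i`, truncated at the
#' domain boundary (boundary nucleosomes have one-sided recruitment).
#'
#' @param i 1-based histone index.
#' @param N histone count.
#' @return Integer vector of neighbor indices.
#' @export
#' @examples
#' neighbor_indices(5, 60)   # 3 4 6 7 8
#' neighbor_indices(1, 60)   # 2 3 4
neighbor_indices <- function(i, N) {
  stopifnot(length(i) == 1, i >= 1, i <= N)
  off <- if (i %% 2 == 0) c(-3L, -2L, -1L, 1L, 2L) else c(-2L, -1L, 1L, 2L, 3L)
  j <- i + off
  j[j >= 1 & j <= N]
}

#' Allosteric feedback sum for a histone
#'
#' \eqn{E_i = \sum_{j \in M_i} (\rho_{me2} [S_j = me2] + [S_j = me3])},
#' summed over the neighborhood from [neighbor_indices()].
#'
#' @param levels integer methylation levels (0..3).
#' @param i 1-based histone index.
#' @param rho_me2 me2 feedback efficiency relative to me3.
#' @return The dimensionless feedback sum.
#' @export
feedback_sum <- function(levels, i, rho_me2 = 0.1) {
  nb <- levels[neighbor_indices(i, length(levels))]
  sum(rho_me2 * (nb == 2L) + (nb == 3L))
}

#' Methylation propensity for a histone
#'
#' Rate of adding one methyl group to histone `i`:
#' \deqn{r_i^{me} = \beta\,(\delta_{S_i,me0}(\gamma_{me0-1} + k_{me0-1} E_i)
#'   + \delta_{S_i,me1}(\gamma_{me1-2} + k_{me1-2} E_i)
#'   + \delta_{S_i,me2}(\gamma_{me2-3} + k_{me} E_i)),}
#' zero for me3 histones.
#'
#' @param levels integer methylation levels.
#' @param i 1-based histone index.
#' @param params a [chromatin_params()] object.
#' @return Rate in s^-1.
#' @export
methylation_propensity <- function(levels, i, params) {
  E <- feedback_sum(levels, i, params$rho_me2)
  s <- levels[i]
  params$beta * switch(as.character(s),
    "0" = params$gamma_me0_1 + params$k_me0_1 * E,
    "1" = params$gamma_me1_2 + params$k_me1_2 * E,
    "2" = params$gamma_me2_3 + params$k_me * E,
    "3" = 0
  )
}

#' Noisy (transcription-independent) demethylation propensity
#'
#' Removal of one methyl group at rate `gamma_dem = f_min * p_dem` for any
#' methylated histone; zero for me0.
#'
#' @inheritParams methylation_propensity
#' @return Rate in s^-1.
#' @export
noisy_demethylation_propensity <- function(levels, i, params) {
  if (levels[i] >= 1L) params$gamma_dem else 0
}

#' Transcription initiation propensity
#'
#' With `P` the me2/me3 fraction of the domain, the initiation rate is linear
#' in `P` down to its floor at `P = P_T`, scaled by the trans-activation
#' multiplier and capped:
#' \deqn{f = \min(\alpha \max(f_{max} - (P/P_T)(f_{max}-f_{min}),\, f_{min}),\,
#'   f_{cap}).}
#'
#' @param levels integer methylation levels.
#' @param params a [chromatin_params()] object.
#' @param alpha trans-activation multiplier (defaults to `params$alpha`).
#' @return Rate in s^-1.
#' @export
#' @examples
#' p <- chromatin_params()
#' transcription_propensity(rep(0, 60), p)          # f_max = 4e-3
#' transcription_propensity(rep(3, 60), p)          # f_min = 1e-4
transcription_propensity <- function(levels, params, alpha = params$alpha) {
  P <- mean(levels >= 2L)
  f <- params$f_max - (P / params$P_T) * (params$f_max - params$f_min)
  min(alpha * max(f, params$f_min), params$f_cap)
}

#' Promoter opening rate of the bursty variant
#'
#' Mirrors the main model's initiation-rate function: chromatin and trans
#' activation modulate `k_on` between `k_on_min` and `k_on_max`, with the
#' cap that keeps the mean initiation rate below 1/60 s^-1.
#'
#' @param levels integer methylation levels.
#' @param params a [chromatin_params()] object (supplies `P_T` and `alpha`).
#' @param burst a [burst_params()] object.
#' @param alpha trans-activation multiplier.
#' @return Rate in s^-1.
#' @export
burst_k_on <- function(levels, params, burst, alpha = params$alpha) {
  P <- mean(levels >= 2L)
  k <- burst$k_on_max - (P / params$P_T) * (burst$k_on_max - burst$k_on_min)
  min(alpha * max(k, burst$k_on_min), burst$k_on_cap)
}

#' Propensities of the two-state variant
#'
#' In the reduced model histones are me0 or me3 only, PRC2 feedback is
#' long-range (mean-field over the whole domain), and transcription removes
#' me3 marks:
#' \deqn{r_i^{me} = \delta_{S_i,me0}(\gamma_{me} + (k_{me}/N) n_{me3}),
#'   \qquad r^{tx} = f_{max} - (n_{me3}/N)(f_{max}-f_{min}),}
#' with \eqn{\gamma_{me} = k_{me}/20}.  Each transcription event demethylates
#' each me3 histone to me0 with probability `p_dem`.  No trans multiplier or
#' initiation cap applies to this variant.
#'
#' @param levels integer methylation levels, all in \{0, 3\}.
#' @param params a [chromatin_params()] object.
#' @return A list with components `methylation` (per-histone rate vector) and
#'   `transcription` (scalar rate), both in s^-1.
#' @export
two_state_propensities <- function(levels, params) {
  if (!all(levels %in% c(0L, 3L))) {
    stop("two-state variant requires all levels in {me0, me3}")
  }
  N <- length(levels)
  n3 <- sum(levels == 3L)
  fb <- params$gamma_me2_3 + params$k_me * n3 / N
  list(
    methylation = ifelse(levels == 0L, fb, 0),
    transcription = params$f_max - (n3 / N) * (params$f_max - params$f_min)
  )
}

#' Endpoint of a selected reaction under the processive variants
#'
#' Propensity calculations are unchanged from the main model; only the
#' reaction product differs.  Under processive methylation a selected
#' methylation converts the histone directly to me3; under processive
#' demethylation a selected demethylation (including noisy demethylation)
#' converts it directly to me0.  Under the main model the level changes by
#' one.
#'
#' @param level current methylation level (0..3).
#' @param reaction `"methylation"` or `"demethylation"`.
#' @param variant one of `"main"`, `"processive_methylation"`,
#'   `"processive_demethylation"`.
#' @return The post-reaction methylation level.
#' @export
processive_update <- function(level,
                              reaction = c("methylation", "demethylation"),
                              variant = c("main", "processive_methylation",
                                          "processive_demethylation")) {
  reaction <- match.arg(reaction)
  variant <- match.arg(variant)
  level <- as.integer(level)
  if (reaction == "methylation") {
    stopifnot(level <= 2L)
    if (variant == "processive_methylation") 3L else level + 1L
  } else {
    stopifnot(level >= 1L)
    if (variant == "processive_demethylation") 0L else level - 1L
  }
}

#' Apply the chromatin effects of one transcription event
#'
#' Each histone draws an independent exchange Bernoulli with probability
#' `p_ex`; a hit on either histone of a nucleosome replaces the whole
#' nucleosome with an unmethylated one (origin `exchange_deposited`, age
#' `new_age`).  Each surviving methylated histone then loses one methyl group
#' with probability `p_dem` (all methyl groups, under processive
#' demethylation).  Exchange is resolved before demethylation so that methyl
#' groups are never removed from a histone that is discarded by the same Pol
#' II passage; the per-histone loss rate through exchange is then about
#' `2 * f * p_ex`.
#'
#' @param state a [chromatin_state()].
#' @param params a [chromatin_params()] object.
#' @param variant `"main"` or `"processive_demethylation"`.
#' @param new_age age label for exchange-deposited histones.
#' @return The updated `chromatin_state`.
#' @export
apply_transcription_event <- function(state, params, variant = "main",
                                      new_age = "old") {
  N <- length(state$levels)
  ex_hit <- stats::runif(N) < params$p_ex
  if (any(ex_hit)) {
    pair <- rep(seq_len(N / 2), each = 2)
    hit_pairs <- unique(pair[ex_hit])
    idx <- which(pair %in% hit_pairs)
    state$levels[idx] <- 0L
    state$origin[idx] <- "exchange_deposited"
    state$age[idx] <- new_age
  } else {
    idx <- integer(0)
  }
  can_dem <- state$levels >= 1L & !(seq_len(N) %in% idx)
  dem_hit <- can_dem & stats::runif(N) < params$p_dem
  state$levels[dem_hit] <- if (identical(variant, "processive_demethylation")) {
    0L
  } else {
    state$levels[dem_hit] - 1L
  }
  state
}

#' Apply DNA replication to a chromatin state
#'
#' Each nucleosome is independently replaced with a new me0/me0 nucleosome
#' with probability `1 - replication_survival` (origin
#' `replication_deposited`, age `new_age`); surviving nucleosomes keep their
#' methylation.  Only one daughter locus is followed.
#'
#' @inheritParams apply_transcription_event
#' @return The updated `chromatin_state`.
#' @export
apply_replication <- function(state, params, new_age = "old") {
  N <- length(state$levels)
  repl <- stats::runif(N / 2) >= params$replication_survival
  idx <- which(rep(repl, each = 2))
  state$levels[idx] <- 0L
  state$origin[idx] <- "replication_deposited"
  state$age[idx] <- new_age
  state
}
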