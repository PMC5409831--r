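---
title: "A stochastic model of transcription-antagonized Polycomb chromatin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic model of transcription-antagonized Polycomb chromatin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prc2mem)
```

## The model

`prc2mem` simulates the chromatin of a single PRC2 (Polycomb repressive
complex 2) target gene as a continuous-time Markov chain over the H3K27
methylation states of `N` histones (default 60, about 5-6 kb; nucleosomes are
consecutive histone pairs).  Each histone carries me0, me1, me2 or me3.  Two
opposing processes structure the dynamics:

* **Methylation by PRC2.**  Histone `i` gains one methyl group at rate
  \[
  r_i^{me} = \beta\left(\delta_{S_i,me0}(\gamma_{me0-1} + k_{me0-1} E_i)
    + \delta_{S_i,me1}(\gamma_{me1-2} + k_{me1-2} E_i)
    + \delta_{S_i,me2}(\gamma_{me2-3} + k_{me} E_i)\right),
  \]
  where \(E_i = \sum_{j \in M_i}(\rho_{me2}[S_j{=}me2] + [S_j{=}me3])\) is the
  allosteric stimulation of PRC2 by repressive marks on the five histones of
  `i`'s own and flanking nucleosomes (`neighbor_indices()`), truncated at the
  domain boundary.  The substrate preference of PRC2 for me0:me1:me2 is 9:6:1,
  so `k_me0_1 = 9 k_me` and `k_me1_2 = 6 k_me`; the noise floors
  \(\gamma = k/20\) put unstimulated activity at 5% of the allosterically
  activated rate.  PRC2 is non-processive: one methyl group per reaction.

* **Transcription.**  Initiation is a single reaction with rate
  \[
  f = \min\!\left(\alpha \max\!\left(f_{max} -
    \tfrac{P}{P_T}(f_{max}-f_{min}),\, f_{min}\right),\, f_{cap}\right),
  \]
  with \(P\) the me2/me3 fraction of the domain, so repressive marks anywhere
  in the gene repress initiation linearly down to \(f_{min}\), saturating at
  the threshold fraction \(P_T\); the trans input \(\alpha\) multiplies the
  chromatin-determined rate, and \(f \le 1/60\,\mathrm{s^{-1}}\) caps it.
  Each transcription event (one Pol II passage) then antagonizes silencing:
  every histone independently triggers nucleosome exchange with probability
  `p_ex` (either hit replaces the whole nucleosome by me0/me0), and every
  surviving methylated histone loses one methyl group with probability
  `p_dem`.  A transcription-independent demethylation channel runs at
  \(\gamma_{dem} = f_{min} p_{dem}\) per methylated histone, making total
  noisy demethylation in the repressed state 5% of the maximal
  transcription-coupled rate — the same signal-to-noise level as methylation.

* **DNA replication** interrupts the simulation once per cell cycle (22 hr):
  each nucleosome is replaced by an unmethylated one with probability 0.5,
  survivors keep their marks, and one daughter locus is followed.  Mitosis is
  treated as a pause and not modeled.

Simulation uses the direct Gillespie method with all `2N + 1` propensities
rebuilt after every update; if a projected waiting time crosses a replication
boundary, time advances to the boundary instead and the propensities are
rebuilt after the dilution.  The inner loop is compiled (Rcpp) and draws from
R's RNG stream, so `seed` makes trajectories exactly reproducible.

### Default parameters

The defaults of `chromatin_params()` are the fitted set used throughout:
`k_me = 8e-6` histone\(^{-1}\)s\(^{-1}\) (about 0.6 histone\(^{-1}\) per
cell cycle), `p_dem = 4e-3` and `p_ex = 1e-3` per histone per transcription,
`P_T = 1/3`, `f_min = 1e-4` and `f_max = 4e-3` s\(^{-1}\) (fold-change
`F = 40`), \(\beta = 1\), \(\rho_{me2} = 0.1\).  Derived rates are always
recomputed from these primitives and never set directly.

### Variants

* `two_state`: histones are me0/me3 only, feedback is mean-field over the
  whole domain, transcription removes me3 with probability `p_dem`.  The
  defining rate equations carry no trans multiplier or initiation cap, so
  none is applied; the noise floor is taken as `k_me/20` by analogy with the
  main model.  This reduced model is not bistable — the nonlinearity supplied
  by the intermediate me1/me2 states is what the full model's memory rests
  on.
* `processive_methylation` / `processive_demethylation`: identical
  propensities, but a selected reaction jumps directly to me3 (or me0;
  including the noisy demethylation channel, as the variant is defined).
* `promoter_switching`: transcription requires an open promoter.  Chromatin
  and \(\alpha\) regulate the opening rate `k_on` (burst frequency), mirroring
  the main model's `f` between `k_on_min` and `k_on_max`, while `k_off` and
  the open-state initiation rate `f_0` stay fixed.  `burst_params()` derives
  `k_on_min` so the active/repressed fold-change equals 40 and `f_0` so the
  repressed-state mean rate equals `f_min`; when `f_0 > 1/60` s\(^{-1}\) a cap
  `k_on <= k_off / (60 f_0 - 1)` keeps the mean initiation rate below the
  same 1/60 limit.  The published functional form of `k_on(\alpha, P)`
  resides in a supplementary figure we could not consult; mirroring the main
  model's `f` is adopted as the reconstruction, and the analysis is
  restricted to `k_on_max <= k_off`.

### The trans input

`regulator_params()` defines a two-stage birth-death regulator
(DNA → mRNA → protein with decay rates `d_R = 1/2` hr\(^{-1}\) and
`d_P = 1/12` hr\(^{-1}\)).  Synthesis rates are derived from the burst size
`b = s_P/d_R` and the target mean so that \(\langle r \rangle = 1000\) for
every `b`; only the noise changes, with
\(CV^2 \approx (1 + b/(1 + d_P/d_R))/\langle r\rangle\) (so `b = 1` gives
CV ≈ 0.03 and `b = 1000` CV ≈ 0.93).  When passed as `alpha_input`, the
regulator reactions join the chromatin SSA as one union process and
\(\alpha(t) = r(t)/\langle r\rangle\).  The regulator starts at its
deterministic stationary means — the defining study did not state a burn-in,
and stationary initialization avoids startup transients in CV estimates (an
optional burn-in is available).  CVs are time-weighted, consistent with the
piecewise-constant time-averaging used everywhere else.

## Metrics

All summary statistics are time-weighted over the piecewise-constant event
record.  The gene is OFF when the repressive-mark count is strictly above
`3 N P_T / 4` (the chromatin-determined rate in its lower quartile) and ON
strictly below `N P_T / 4`; exact ties count as neither, and with `P_T = 1`
the definitions reduce to the quarter-of-N thresholds.  Because replication
deposits active-state histones, `P_ON`/`P_OFF` are accumulated only over the
last hour of each cycle, so slowly recovering repressed states still register
as stable.  Bistability is `B = 4 P_OFF P_ON`.  First-passage times are
detected at event resolution (the state is constant between events), censored
at the total simulated time, and censored replicates contribute the bound to
the mean; the combined measure is `FP = t_FP(me0) t_FP(me3) / T^2 ∈ (0, 1]`.
Transcriptional output is events per hour in a designated cycle, and H3.3
asymmetry is `H = |<H3.3>_ON − <H3.3>_OFF|` over the exchange-deposited
histone fraction.

## The SILAC harness and its synthetic fixtures

The labeling protocol equilibrates the model in the repressed state for five
cycles at \(\alpha = 1\), marks all resident histones `old` at the
equilibration-ending replication (`t = 0`), labels every later deposit `new`,
and reports each pool's me3 content as a fraction of that pool at
`t = 0, 10, 24, 48` hr.  Because mass-spectrometry fractions are genome-wide
averages while the simulation is a single locus, simulated series are scaled
by `0.301 / P_me3_end`, anchoring the cell-cycle-end me3 level to the
measured `t = 0` old-pool value; `P_me3_end` is averaged over equilibration
cycle ends, excluding the first two cycles so the relaxation from the uniform
me3 start does not inflate it.  When the repressed state is lost during
equilibration (`P_me3_end < 0.05`) the normalization is meaningless and the
grid point is flagged as failed (`SSE = Inf`).  Fits minimize the plain sum
of squared errors over time points, pools and individual replicates; me1/me2
time courses are deliberately not scored.

The processed dataset this pipeline targets is not publicly deposited, so
`synthetic_silac()` generates emulated tables: the simulated mean curve at
the generating parameters, its `t = 0` old-pool mean set to the anchor, plus
independent Gaussian replicate noise truncated to `[0, 1]` (three replicates
per time point, the simplest model consistent with triple biological
replicates).  The fixtures reproduce the labeling structure, replicate
scatter and normalization of the real pipeline but none of its
peptide-level biases, so parameter-recovery results demonstrate correctness
of the fitting machinery, not accuracy on real mass-spectrometry data.

### What the fit can and cannot identify

Under this protocol `k_me` is strongly identified (doubling it visibly
accelerates new-pool me3 accrual), and `P_T` is identified upward (with
`P_T` well above the post-replication me2/me3 fraction, transcription stays
elevated after dilution, reshaping both curves).  `p_dem` below the
generating value is structurally almost unidentifiable: at the fitted point
post-replication transcription is already pinned at `f_min`, so `p_dem`
enters the labeled curves only through the tiny flux `f_min p_dem`, and the
`0.301/P_me3_end` normalization divides out its effect on the absolute
repressed level.  Measured noiselessly, SSE gaps between `p_dem` values one
and two decades below the generating point are of order `3e-4` — under the
Monte-Carlo floor of the curves themselves — versus `1.7e-2` for a single
`k_me` doubling.  Full three-parameter grid recovery therefore plateaus near
the rate at which ties among the degenerate `p_dem` values happen to fall on
the generating one, and the package's recovery tests document this rather
than hide it.  The default `p_dem` grid uses decade steps to keep the
degenerate set small.

## Problem sizes and numerical choices

Analyses in the tests and the reproduction script are run at desk scale:
bistability scans use 20 replicates per initial state (50-cycle windows, the
protocol's published duration) instead of 100; first-passage estimates use
60 replicates censored at 500 cycles instead of 1000 × 1500; the noise-
filtering comparison uses 30 replicates per state over 20 cycles.  These
sizes keep every experiment within minutes on one core while leaving
Monte-Carlo errors well inside the asserted margins.  Other numerical
choices: exchange draws are resolved before demethylation draws within one
transcription event (a methyl group is never removed from a histone the same
Pol II passage discards, and the per-histone loss rate stays ≈ `2 f p_ex`);
exchange probabilities are drawn per histone with either hit replacing the
pair, which reproduces the stated loss-rate bookkeeping; absorbing states
(all propensities zero) advance directly to the next replication boundary;
a run of `n` cycles ends just before the `n`-th replication is applied;
public reports index histones 1-based.

## Known limitations

The model is strictly one-dimensional and local: no explicit Pol II
elongation, no 3D chromatin contacts, no H3K4/K36 active-mark feedback, no
mitotic pause.  The bursty variant's `k_on` function is a reconstruction (see
above).  Two published pre-fit illustrations (the "bistable" versus
"demethylation-biased" example trajectories and the position of the
bistability onset along the `f_max` series) depend on parameter-table entries
we could not consult; with `f_max = 4e-3` s\(^{-1}\) this implementation
finds genuinely balanced bistability already at `f_max = 8e-4` and stable
repression at the quoted "biased" point, whereas both illustrations reproduce
qualitatively if those panels used `f_max` near the 1/60 s\(^{-1}\) cap.  The
reproduction script reports what this implementation computes.
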