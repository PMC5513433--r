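---
title: "A sequence-level transcription model with enhancer competition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A sequence-level transcription model with enhancer competition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciscompete)
```

## The problem

Developmental genes such as *Drosophila even-skipped* (*eve*) are controlled
by tens of kilobases of non-coding DNA organised into enhancers, each
driving part of the expression pattern. Thermodynamic models explain single
enhancers well, but an intact locus behaves differently from the sum of its
parts: enhancer-reporter patterns are broader than the stripes the locus
drives, and shadow enhancers combine non-additively. `ciscompete`
implements a mechanistic account of this discrepancy: only a bounded length
of DNA (a window of `alpha` bp, default 1 kb) can influence the promoter at
one time, so windows of the locus compete for promoter interaction in
proportion to the activation they carry.

## The model, stage by stage

**1. Binding sites and statistical weights.** The locus is scanned on both
strands with one log-odds PWM per transcription factor; every footprint
scoring above a threshold (default 0) is a candidate site. Site `i` of
factor `a` at axis position `x` has statistical weight

\[ q_i(x) = A_a \, [a](x) \, e^{(s_i - s_{\max,a})/\lambda_a}, \]

where `[a](x)` is the factor's concentration profile, `A_a` converts
fluorescence units and PWM scores into dimensionless binding weights, and
`lambda_a` sets how steeply score deficits translate into affinity losses
(large `lambda` compensates for over-specified PWMs learned from deeply
selected SELEX rounds).

**2. Equilibrium occupancy.** The fractional occupancy `f_i(x)` comes from
a partition function over all binding configurations in which no two
occupied footprints overlap (steric exclusion). One factor may additionally
bind cooperatively with itself: every pair of consecutively bound sites of
that factor whose edge-to-edge gap is at most `d_omega` (default 60 bp)
multiplies the configuration weight by `omega`. Exhaustive enumeration
scales as `2^n` and is kept as an oracle (`occupancy_bruteforce()`, guarded
to 20 sites); the production path (`occupancy_dp()`) is a forward-backward
dynamic program over sites sorted by footprint end, whose state tracks the
most recently bound cooperative site within the interaction range, giving
cost linear in the number of sites times the local interaction window. All
accumulation is log-domain log-sum-exp of positive terms, so the marginals
of rare configurations keep full relative precision and weights up to
`omega^n prod(q)` cannot overflow.

**3. Coactivation.** Some repressors (Hb in the fly network) activate when
bound near a bound coactivator (Bcd, Cad). A coactivated repressor site
splits its occupancy into an activating part

\[ f^{act}_k = f_k \, E^C \Big(1 - \prod_j (1 - f_j)\Big), \]

the product running over coactivator sites within `d_coact` (default
150 bp, centre-to-centre), and a repressing remainder
`f_rep = f - f_act`. The complement-product ("at least one coactivator
bound") combination rule is a design choice: it is bounded in `[0, 1]` and
reduces to the single-coactivator case exactly.

**4. Short-range quenching.** Each activating occupancy is attenuated by
every repressing site within `d_quench` (default 100 bp):

\[ F_k = f^{act}_k \prod_r \big(1 - E^Q_r \, f^{rep}_r\big). \]

Quenching acts on activating occupancy only; repressors do not quench one
another, and a coactivated site's own repressing part does not quench its
activating part. Coactivation is applied before quenching, without
feedback: a quenched coactivator still coactivates at its full occupancy.
The alternative (quenching feeding back into coactivation) is not
implemented; it would couple the two stages into a fixed-point iteration
the present data cannot distinguish.

**5. Adaptor recruitment and competition.** Every window `[m, m+alpha)` of
the locus — window starts run in single-nucleotide increments from
`-alpha` to `l-1`, so there are exactly `l + alpha` windows including the
edge windows that overhang the locus ends — recruits
`N = sum_k F_k E^A_{a_k}` transcriptional adaptors over the sites whose
footprint midpoint falls in the window (membership by midpoint makes every
site a member of exactly `alpha` windows, which keeps the sliding sums
exact). A window interacting with the promoter drives the Arrhenius rate

\[ R_{[m,m+\alpha]} = \frac{R_{\max}}{1 + e^{\theta - N_{[m,m+\alpha]}}}, \]

and the fraction of time it holds the promoter is

\[ T_{[m,m+\alpha]} = \frac{\beta N_{[m,m+\alpha]}}{1 + \sum_n \beta N_{[n,n+\alpha]}}. \]

The total transcription rate is `R_total = sum_m R T`, and predicted mRNA
equals `R_total`: message turnover is fast on the patterning timescale, so
level is proportional to rate, with the proportionality constant absorbed
into `Rmax`. Time fractions always sum to `S/(1+S) < 1` with
`S = sum(beta N)` — the remainder is promoter idle time — which is why two
enhancers on one locus drive strictly less than the sum of what each
drives alone. A `no_competition` mode replaces the window machinery with a
single window spanning the whole sequence.

**6. Chromatin accessibility.** Optionally, binding sites are only called
when their full footprint lies inside accessible chromatin (the union of
intervals read from BED files). Strict containment is the default reading
of "within accessible chromatin"; an any-overlap variant is available for
sensitivity analysis. Masking is applied after site calling, which under
the containment rule gives the same result as masking the sequence first.

## Parameters

| Parameter | Meaning | Range | Scale |
|---|---|---|---|
| `A_a` | concentration/affinity scale per factor | `1e-6`–`4` | log |
| `lambda_a` | score-to-affinity softness | `0.5`–`5` | linear |
| `E_A` | adaptor-recruitment efficiency | `0`–`25` | linear |
| `E_Q`, `E_C` | quenching / coactivation efficiency | `0`–`1` | linear |
| `omega` | cooperative pair weight | `1`–`1000` | log |
| `theta` | energy barrier to initiation | `5`–`25` | linear |
| `beta` | promoter-interaction weight per adaptor | `1e-6`–`1e2` | log |
| `Rmax` | maximal rate (data units) | `1e-2`–`1e4` | log |

The efficiency parameters `E_Q` and `E_C` multiply occupancies and live on
their natural 0–1 scale. `E_A` also sets the steepness of the promoter
response — near its upper bound the logistic becomes step-like. `theta`
below 5 would allow substantial transcription with no activation at all,
hence its lower bound. The `beta` and `Rmax` ranges are this package's
defaults (chosen to bracket the useful regime in 0–255 fluorescence-like
units by several orders of magnitude); they are configurable where a
dataset demands otherwise. Interaction ranges (`d_omega` 60 bp, `d_coact`
150 bp, `d_quench` 100 bp) are fixed, not fitted: short-range
protein-protein contact scales in this model family are of order
100–150 bp, and the data used here cannot resolve them further.

## Fitting

Parameters are estimated by minimising the sum of squared differences
between predicted and observed expression across axis positions.
`anneal()` is a seeded geometric-cooling simulated annealer: one-coordinate
proposals (multiplicative for log-scale parameters), reflection into the
printed bounds, Metropolis acceptance under a temperature estimated from a
short random walk and decayed geometrically, followed by a bounded
L-BFGS-B polish of the best state. The `kappa` knob trades accuracy for
moves exactly as an annealing accuracy parameter should: smaller `kappa`,
longer schedule. Two controls accompany every serious fit:

- `fit_known_optimum_control()` replaces the data with the model's own
  output, so the global minimum (zero SSE at the generating parameters) is
  known; recovery quality is summarised by the Spearman correlation
  between true and recovered parameter vectors.
- `permutation_control()` shuffles the non-coding sequence (preserving
  base composition and any excluded intervals) and refits; permuted fits
  scoring much worse than the real sequence indicate the model is reading
  genuine sequence information.

## The synthetic benchmark

All tests run on generated data; nothing is downloaded. The standing
benchmark (`make_benchmark()`) is a 6 kb locus with two planted enhancers
3 kb apart, six factors (a cooperative anterior-gradient activator, a
uniform activator, three pure repressors with bump/gradient profiles, and
a coactivated two-domain repressor), toy PWMs of length 10 at 1.6 bits per
position, and 58 axis positions from 35.5% to 92.5% embryo length at 1%
spacing with amplitudes on a 0–255 fluorescence-like scale — the problem
geometry of the fly blastoderm data the model family was built for, at
desk scale. Background sequence is i.i.d. at 40% GC.

What the benchmark emulates: planted high-affinity site clusters against a
motif-poor background, smooth graded inputs, and a target pattern with two
separated expression domains. What it does not emulate: correlated
genomic sequence composition (repeats, CpG structure), measurement noise,
embryo-to-embryo registration error, overlapping information-poor motifs,
and the 13 kb/8-factor scale of the real locus with its 32-parameter fit.
Passing the recovery control here shows the optimiser and model machinery
are sound at a problem size where the global optimum is reachable in
minutes (7 free parameters, 1000 moves and 5 restarts — a desk-scale
stand-in for a 20-coarse/80-fine cluster protocol); it does not certify
fits of the full biological problem.

The control's free parameters are chosen for identifiability, as a
fit-known-optimum control requires: the rate scale `Rmax` plus one
recruitment or quenching strength per factor. Parameters that are
structurally degenerate in this regime are held at their generating
values: `theta` trades off against the `E_A`s along ridges; `beta` is flat
once `S = beta * sum(N)` is large (here `S ~ 150`, so `T ~ N / sum(N)`
regardless of `beta`); the same-factor pair `(A, E_A)` compensate each
other; and `lambda` of the graded activator barely acts because the
planted sites are exact consensus (`s = s_max`). Fitting such parameters
would test the optimiser against non-identifiability rather than against
its ability to find a known optimum.

## Numerical choices

- Occupancy is computed in the log domain throughout; the DP is organised
  so that every accumulated quantity is a sum of positive terms (states
  that can no longer interact are folded into a frozen class rather than
  subtracted), keeping relative error near machine precision even for
  occupancies of order `1e-20` — verified against exhaustive enumeration
  at `1e-10` tolerance over hundreds of randomized instances.
- Window sums use exact sliding prefix sums; during fitting an equivalent
  run-length path over the at most `2n + 1` distinct window values avoids
  materialising the `(l + alpha) x positions` matrices. Both paths agree
  to machine precision and the full matrices remain available for maps.
- Derivatives for border attribution use a symmetric difference quotient
  where the concentration is positive (step clipped so levels stay
  non-negative) and a forward quotient at zero. For the border
  decomposition the default step equals each factor's own concentration
  change over the adjacent positions, so every term is the secant slope
  across the interval actually traversed and the per-factor sum tracks
  the between-position output change up to cross-factor interaction
  terms; estimates are in any case stable over fixed steps spanning many
  orders of magnitude (`derivative_convergence()`).
- The printed "change in level" factor of the border decomposition is
  typographically ambiguous in its source; the default is the central
  difference `([A]_{i+1} - [A]_{i-1})/2` (it makes uniform factors
  contribute zero, as "the amount the factor is changing" demands), and
  the literal-average reading is kept behind
  `delta_method = "literal_average"` for auditability.
- Ties and degenerate inputs: zero weights are handled exactly (a site
  with `q = 0` has `f = 0`); empty site tables short-circuit to basal
  output; an empty accessibility mask removes every site when masking is
  enabled.

## Known limitations

- The border decomposition is a first-order account: summed per-factor
  contributions reproduce the directional derivative of the rate exactly,
  but their agreement with the realised between-position change carries
  the third-order path curvature of the Arrhenius logistic — on the
  benchmark about 5% in aggregate, rising to ~11% at the single steepest
  stripe flank where several factors change together. Read cumulative
  border plots as attributions of the local trend, not as an exact
  budget of the change at the sharpest flanks.

- At most one cooperative factor is supported (the system it models has
  one); the DP state would need one slot per cooperative factor
  otherwise.
- Cooperativity is nearest-bound-neighbour and pairwise, the semantics a
  bounded-look-back DP supports; all-pairs cooperativity is deliberately
  out of scope.
- Coordinates are locus-local; BED inputs from other assemblies must be
  lifted externally.
- The annealer is a general-purpose geometric-cooling implementation, not
  a Lam-style adaptive schedule; it satisfies the same contract (seeded
  reproducibility, bound respect, recovery of known optima) and the
  schedule can be swapped behind `anneal()` without touching callers.
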