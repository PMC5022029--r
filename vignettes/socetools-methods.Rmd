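---
title: "Models and estimators in socetools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and estimators in socetools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socetools)
```

This vignette is the package's account of its science: the stochastic
model of store-operated channel assembly and its assumptions, the
microscopy and electrophysiology estimators, the synthetic-data forward
models, and the numerical choices that were genuinely open. Nothing here
states an empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## The stochastic channel-assembly model

### Biology being modelled

After ER Ca²⁺-store depletion, STIM1 clusters at ER–plasma-membrane
junctions and traps laterally diffusing Orai1. CRAC channels assemble in
place from Orai1 dimers: dimers pair into tetramers, and a tetramer plus a
further dimer completes the hexamer, the fully assembled conducting form
with the highest open probability. Tetramers are transitional, with a much
lower open probability; bare dimers do not conduct. Oxidation of Orai1
C195 locks a channel shut without preventing its assembly or trapping:
oxidized cells still show Orai1 clusters and STIM1 interaction, but almost
no current.

### State space and events

The plasma membrane is a square lattice of subvolumes of side `h`
(reflective boundaries). The simulator is an exact Gillespie sampler of
the reaction–diffusion master equation with events:

* free-dimer hop to a nearest neighbour, rate `4·D_O/h²` per dimer
  (blocked directions are executed as null events, which leaves the law of
  the process unchanged);
* trapping in a junction subvolume, propensity `k_trap · S_j · F_i`
  (`S_j` free STIM1 sites of junction j, `F_i` free dimers in the
  subvolume); each trapped dimer consumes `stim_per_dimer = 4` sites —
  two STIM1 per Orai1 monomer;
* untrapping (`k_untrap`), releasing the sites;
* dimer+dimer → tetramer at `k_dd` per co-resident trapped pair, and
  tetramer+dimer → hexamer at `k_td` per co-resident pair;
* disassembly (`k_dis_tet`, `k_dis_hex`) reversing one assembly step.

Oxidation flags live on dimers: the state tracks, for every channel, how
many constituent dimers are oxidized, a channel is locked iff that count
is positive, and disassembly restores the flags exactly. The current is
`I = i_unit·(P_hex·N_hex,unlocked + P_tet·N_tet,unlocked)`; a `P_dim`
parameter exists for conducting dimers but defaults to 0. Orai1 monomers
(`2·dimers + 4·tetramers + 6·hexamers`) are conserved; the engine asserts
this every 10⁴ events and aborts on violation. One seeded generator drives
each trajectory, so identical `(params, geometry, seed)` give
bit-identical traces.

Store depletion is a step: STIM1 sites appear at
`store_depletion_time` (default 0, since thapsigargin depletion precedes
recording); the waiting time is redrawn at the step, which is exact by
memorylessness.

### Why junctions default to a single subvolume

Channel assembly requires reactants in the *same* subvolume. If a junction
spans several subvolumes, its trapped material is split multinomially over
them by the arrival process, and that split — hence the final channel
composition — turns out to be independent of the Orai1:STIM1 expression
ratio: sweeping the ratio then yields a saturating plateau rather than an
optimum. With junctions of radius 0.1 µm (one subvolume at the default
`h = 0.2` µm, and about the size of a diffraction-limited STIM1 punctum),
the whole junction is one reaction volume and the *order and tempo of
arrivals* matter:

* near the stoichiometric ratio (0.5 on monomers, where the dimer count
  exactly matches the STIM1 site capacity), arrivals are slow and become
  progressively slower as both the free pool and the free sites deplete;
  each junction funnels sequentially through dimer → tetramer → hexamer;
* with excess Orai1, arrivals outpace the tetramer → hexamer step
  (`k_dd ≫ k_td`), pairs form exhaustively, and junctions are kinetically
  trapped as tetramer pairs with little current.

Below 0.5 the current falls simply because there is less Orai1 to trap.
The optimum at 0.5 therefore emerges from site stoichiometry (downward
limb) plus kinetic trapping of tetramers (upward limb).

### Calibration of the default kinetics

The study this model descends from reports outcomes, not rate constants,
so the defaults are calibration products, chosen once with
`tools/calibrate.R` and frozen:

* `D_O = 0.1` µm²/s — a typical lateral mobility for a plasma-membrane
  channel protein. (An alternative anchoring of `D_O` to the measured
  FRAP recovery constant of ~427 s in a 1-µm spot would give
  `D ≈ 1.5·10⁻⁴` µm²/s, at which no current could develop within 600 s;
  the measured τ is instead consistent with recovery over a ~10 µm
  region at this `D_O`.)
* `k_trap = 0.05` per site per dimer per s, `k_untrap = 0.001`/s — fills
  the junctions sigmoidally, near steady state at 600 s at ratio 0.5.
* `k_dd = 1.0`, `k_td = 0.01` per pair per s — fast pairing, slow
  completion: the separation creates the tempo-sensitivity described
  above.
* `k_dis_tet = k_dis_hex = 2·10⁻⁴`/s — channels are effectively stable
  over 600 s but can slowly reshuffle.
* `P_hex = 0.8`, `P_tet = 0.05`, `i_unit = 1` (arbitrary current units).

The calibration targets were: (i) sigmoid current near steady state at
600 s, (ii) ratio-sweep maximum at 0.5, (iii) insensitivity of I(600 s)
to changing only `D_O` by 0.66 (trapping is reaction-limited at these
rates, so a diffusion-only change does not move the current — matching
the observation that slowed diffusion alone cannot explain oxidant
inhibition). `tools/calibrate.R` reproduces the evidence; the acceptance
tests re-verify (i)–(iii) at every run.

The default full-size condition is a 10 µm patch with 20 junctions and
1200 STIM1 sites; sweeps use the reduced condition (5 µm, 8 junctions,
480 sites) so that 400 replicate trajectories complete in about a minute.
Problem sizes in the tests were chosen to keep the whole suite around a
minute while leaving every comparison statistically meaningful.

### Oxidation

`apply_oxidation()` scales `D_O` by 0.66, `k_dd`/`k_td` by 1/2.25 and
`k_trap` by 1.4 — the experimentally measured effect sizes — and sets the
oxidized-dimer fraction. It deliberately composes (applying it twice
scales twice). Whether "locked" should be flagged at channel or subunit
level was an open choice; the subunit (dimer) level is mechanistically
the natural one — one oxidized subunit suffices to jam the gate — and is
the default, with the channel-level fraction available as the observable
`O_inh/O_tot` and `fox_for_locked_fraction()` solving
`1 − c = q(1−f)³ + (1−q)(1−f)²` for the dimer-level `f` that realizes a
desired channel-level fraction `c` under random assortment (hexamer share
`q`, default 1 since baseline runs are hexamer-dominated).

## FRET

Three-cube sensitized emission with donor (A), FRET (B) and acceptor (C)
channels. The published estimator formula behind the acquisition software
is not reproducible from the available text, so the package adopts the
standard donor-normalized estimator and makes the synthetic generator its
exact forward model — self-consistency is then testable, while the
absolute convention remains an open question documented here:

* calibration (per experimental day, from single-labelled cells):
  `β = med(B/A)`, `δ = med(C/A)` over donor-only pixels; `γ = med(B/C)`,
  `α = med(A/C)` over acceptor-only pixels. Medians are taken over
  signal pixels only (above half the robust channel maximum): cluster
  pixels are a small fraction of the field, and including background
  pixels would corrupt the ratios.
* efficiency: `A' = A − α·C`, `C' = C − δ·A` (second-order cross-talk),
  `Fc = B − β·A' − γ·C'`, `E = Fc/(Fc + A')`, clipped to [0, 1], with
  `A' ≤ 0` pixels masked.
* cluster filter: clusters whose acceptor/donor ratio falls outside
  mean ± 1 SD of the day's distribution are excluded, removing
  expression-level outliers before averaging.

The generator composes images by the exact inverse of this estimator
(solving the 2×2 cross-talk system so the zero-noise round trip is exact
to machine precision), then adds background, multiplicative "shot-like"
and additive Gaussian noise. Default factors (α 0.02, β 0.12, γ 0.08,
δ 0.01) are typical for GFP/RFP filter sets; 5% multiplicative noise over
~30-pixel clusters gives day-level spreads comparable to reported
efficiencies' uncertainties.

## FRAP

`frap_normalize()` divides the bleached-region trace by the control
region (cancelling any shared acquisition bleaching exactly), then maps
the pre-bleach mean to 1 and the first post-bleach point to 0.
`frap_fit()` fits `R(t) = M(1 − exp(−t/τ))` by Levenberg–Marquardt.

Two numerical choices matter, both calibrated by simulation against the
generator's ground truth and then frozen:

* **Plateau bound.** A 5-minute recording of a recovery with τ of
  several hundred seconds barely curves, so τ and M are strongly
  anti-correlated. Unbounded, M̂ and τ̂ drift up the valley together;
  capped hard at 1, noise-driven overshoots are truncated one-sidedly
  and the mean τ̂ is biased low. M is constrained to [0.05, 1.08]: the
  8% headroom balances the two effects so that the mean fitted τ is
  unbiased for recovery constants of 400–700 s under the default
  protocol (1 Hz, 300 s, noise SD 0.02). `fix_M` fits with a pinned
  plateau instead; the M-free mode is the default because the recorded
  plateau genuinely is unknown.
* **Convergence.** The valley is shallow enough that default stopping
  tolerances make τ̂ depend on the starting values; the fitter uses
  `ftol = ptol = 10⁻¹⁴`, after which the estimate is start-independent
  to ~10⁻⁴ s.

Identifiability is honest in the summaries: `summary()` reports the τ–M
correlation, and the parameter-recovery test constrains per-cell bias
only where the recording spans most of a time constant. The same rising
exponential fitter serves for cluster-formation intensity curves, where
`1/τ` is the formation rate constant.

The generator emulates the acquisition protocol (7-s bleach treated as
instantaneous, 1 Hz sampling, 5 min recovery, 10 s baseline) with mobile
fraction 0.85, bleach depth 0.8, 10% acquisition autobleach and additive
noise SD 0.02 — values chosen once as realistic for a membrane protein
imaged confocally.

## Patch clamp

* `cd_trace()`: per sweep, the current at −130 mV (linear interpolation
  on the ramp's voltage grid), leak-subtracted against the first sweep
  after break-in (standard CRAC practice; optional), divided by `C_m` →
  pA/pF. `CD_max` is the extremum of the 3-sweep running median — the
  smoothing width is our choice, undocumented in the source protocols.
* `tail_po()`: each −100 mV tail is fitted with `A·exp(−t/τ) + c`,
  skipping the first 2 samples (residual capacitive transient) and
  refitting once on a window of 5 fitted time constants. The
  instantaneous amplitude is the exponential component `A` extrapolated
  to the step instant; since the driving force at −100 mV is common to
  all test potentials, amplitudes normalized to the largest give the
  apparent open probability. Tail fits use the Levenberg–Marquardt
  residual minimizer directly: on exactly noise-free tails the
  surrounding model-object construction can fail on a numerically
  rank-deficient gradient even though the coefficients are exact.
* The ramp generator produces an inward-rectifying, positively reversing
  (+60 mV) IV shape with a sigmoid (or simulator-driven) conductance and
  ohmic leak; divalent-free sweeps need no separate handling.

## What the synthetic data do and do not show

Every generator is the forward model of its analysis, with recorded seeds
and ground truth. Passing recovery tests therefore demonstrates that the
estimators invert their own forward models at realistic noise — it does
not validate the optical or electrical realism of those models. In
particular: cluster masks are taken as known (segmentation is a helper,
not a validated pipeline); no PSF, no drift, no series resistance, no
Ca²⁺-dependent inactivation kinetics inside the simulator; and the
simulator's rate constants are calibrated to reproduce reported outcomes,
not measured. The model also omits Ca²⁺ microdomains, ER store dynamics
and STIM1 oligomerization kinetics by design.

## Degenerate inputs and tie-breaks

Empty propensity sets absorb to `t_end`. Trapping requires at least
`stim_per_dimer` free sites in the junction. `E` pixels with non-positive
corrected donor are masked rather than clipped. A single FRET cluster is
always included by the ratio filter (its ratio equals the day mean).
FRAP traces need ≥ 3 pre-bleach frames and ≥ 20 post-bleach samples; the
bleach frame defaults to the largest single-frame drop with an override.
Failed tail fits flag their potential rather than aborting the protocol.
STIM1 sites are apportioned to junctions by largest remainder, so counts
differ by at most one site between equal-area junctions.
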