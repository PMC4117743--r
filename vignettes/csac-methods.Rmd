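---
title: "Confined self-avoiding chromatin chains: model, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confined self-avoiding chromatin chains: model, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csac)
```

## The model

`csac` implements the constrained self-avoiding chromatin (C-SAC) picture
of chromosome folding: a chromatin fiber is a self-avoiding chain of
30 nm beads, each carrying 3 kb of DNA, grouped into rigid persistence
units of 150 nm (five beads), growing inside a hard spherical
confinement that stands in for the nuclear sub-volume available to the
chromosome. Nothing else is put in -- no binders, no prescribed loops,
no target contact map. The claim the package lets you test is that
spatial confinement alone reproduces the observed scaling laws of
chromosome organisation:

* mean-square spatial distance $R^2(s) \sim s^{2\nu}$ with $\nu \approx
  0.33$ at sub-Mb separations and a leveling-off ($\nu \to 0$) at large
  $s$, as seen by FISH;
* contact probability $P_c(s) \sim s^{-\alpha}$ with $\alpha \approx 1$,
  as seen in Hi-C.

A chain of $N$ persistence units has
$N' = N + (N-1)(L_p/d_f - 1)$ beads; for the default geometry and
$N = 1000$ that is 4996 beads, about 15 Mb of DNA. The matching
confinement diameter comes from uniform nuclear DNA density:
$D = D_{nuc} (\mathrm{chain\ bp} / \mathrm{genome\ bp})^{1/3}$, giving
$D \approx 1.5\,\mu m$ for 15 Mb in an 11 um nucleus holding 6 Gb
(`confinement_diameter_for()`). Conversely ~400 such 15 Mb territories
pack into a sphere of $400^{1/3} D \approx 7.4 D \approx 11\,\mu m$.

## Chain growth by sequential importance sampling

Uniform sampling of long self-avoiding chains in severe confinement is
intractable by naive rejection, and Metropolis-style moves equilibrate
poorly at these densities. `grow_chain()` therefore grows chains one
persistence unit at a time. At each step a discrete set of $k = 100$
candidate directions (a Fibonacci-sphere construction, randomly rotated
once per chain to restore the isotropy a fixed set would break) is
tested for feasibility: the new unit-boundary bead *and* every
interpolated bead on the rigid 150 nm segment must avoid all existing
beads by at least one bead diameter and stay entirely inside the
sphere. One of the $m_t$ feasible directions is chosen uniformly, and
the Rosenbluth weight

$$ w(\mathbf{x}) = \prod_t \frac{m_t}{k} $$

corrects the selection bias so that weighted averages target the
uniform distribution over all realizable chains. A step with $m_t = 0$
is a dead end; the chain restarts from scratch with a fresh sub-seed
and the failure is logged as attrition. Restart-from-scratch keeps the
scheme plainly unbiased; enrichment/resampling variants (PERM and
relatives) are deliberately out of scope.

Design details worth knowing:

* Weights are stored as log-weights; raw products underflow around
  $N \gtrsim 500$. Normalized weights and the effective sample size
  $\mathrm{ESS} = (\sum w)^2 / \sum w^2$ are available via
  `ensemble_weights()` and `ess()`.
* The first bead is placed uniformly in the allowed sphere (confined)
  or at the origin (free space); the target distribution is preserved
  either way because the weight accounting starts after placement.
* Confinement is enforced on whole beads (centres within
  $D/2 - d_f/2$); `check_confinement(whole_bead = FALSE)` gives the
  centre-only reading.
* Self-avoidance exempts only directly bonded neighbours, whose spacing
  is exactly $d_f$ by construction; the numeric tolerance on the
  equality boundary is $10^{-6}$ nm.
* Neighbour searches run on a uniform cell grid. The grid is an
  optimisation only: tests require exact agreement with brute-force
  all-pairs oracles, so it is observationally invisible.
* All randomness derives from one integer master seed through
  counter-based sub-seeds (splitmix64), so ensembles are reproducible
  chain by chain and independent of execution order.

## Estimators and their failure modes

All ensemble observables are self-normalized importance-sampling
estimates: windows are pooled with equal weight within a chain, chains
combine by Rosenbluth weight, and independent ensembles combine with
equal weight (`msd_profile()`, `contact_probability()`,
`end_to_end()`).

Plain sequential importance sampling has a well-known pathology: the
variance of $\log w$ grows linearly with chain length, so the ESS of an
ensemble decays roughly exponentially in $N$. Two practical
consequences shape the package defaults:

* **Free-space end-to-end scaling.** With $10^3$--$3\times10^3$ chains
  per length, the weighted mean end-to-end distance is reliable up to
  $N \approx 500$ (ESS of order $10^2$) and becomes noisy and
  systematically biased toward the unweighted (compact-biased) mean
  beyond that. The free-space exponent $\nu$ is therefore fitted on
  $N \in [100, 500]$, where the estimator still has statistical
  support, rather than on the largest lengths. On these grids the
  package recovers $\nu \approx 0.58$ against the self-avoiding-walk
  reference value of about $0.59$.
* **Profile observables self-average.** $R^2(s)$ and $P_c(s)$ average
  over many windows within each chain before chains are combined, so
  they remain usable even when the ESS is small -- the price is that
  the estimate leans on the few highest-weight (most open, hence most
  representative of the uniform target) chains. The bootstrap
  (`bootstrap_ci()`, percentile over whole chains with weights carried)
  quantifies exactly this: intervals widen as the ESS shrinks.

When contact profiles pool several independent ensembles with equal
weight, an ensemble whose own ESS has collapsed contributes what is
effectively a one-chain estimate -- and since the surviving
highest-weight chains are systematically the most open ones, such
contributions are biased toward steeper contact decay, not merely
noisy. Pooled free-space contact fits therefore exclude ensembles
below an ESS floor (`contact_probability(min_ess = 30)`).

Confined ensembles at a fixed small $D$ are *uniformly*
weight-degenerate across lengths, so an ESS floor would discard
everything. For slope-sensitive confined estimates -- the pooled
contact profile and the plateau-onset detector's input -- the package
instead offers truncated importance sampling
(`weighting = "truncated"`): normalized weights are clipped at
$\bar{w}\sqrt{n}$ and renormalized, which bounds the estimator's
variance at the price of a bias that vanishes as $n$ grows. Contact
fractions are rare-event averages, so under plain weights a single
dominant open chain can set the whole profile (and its log-slope) by
itself; truncation restores a usable profile while staying as close to
the importance-weighted target as the sample allows. The `"uniform"`
rule (no reweighting at all, i.e. the raw growth ensemble) is provided
as a diagnostic bracket on the other side.

Per-chain *scalar* statistics -- substructure counts, interactive
fractions, compactness labels -- are the hardest case: unlike profiles
they contain no within-chain window averaging, so both plain and
truncated importance weighting reduce them to the few top-weight chains
and the estimate swings wildly between seeds. For these the validation
protocols report the growth-ensemble (uniform-weight) average, which is
seed-stable, with the known direction of its bias documented: the
growth ensemble over-represents compact chains, so substructure counts
and interactive fractions come out slightly high relative to the
uniform-target ensemble. Pooled multi-ensemble contact fits under
confinement sit in the same category in practice: even with truncated
weights each ensemble contributes a heavy-tailed few-chain estimate,
and the pooled slope occasionally jumps by half a unit between seeds,
so the confined contact-exponent protocol also averages over the
growth ensemble (where it is reproducible to ~0.02 across seeds). In
short: plain importance weights wherever the ESS supports them,
truncated weights for single-ensemble confined profile slopes and
plateau detection, and the explicit proposal-ensemble average for
per-chain scalars and pooled confined contact fits.

Contact statistics at large $s$ in free space are intrinsically sparse:
the expected number of raw contacts per grid point can fall below one.
Fits of the contact exponent therefore drop grid points with fewer than
`min_contacts` (default 5) raw contacts, and the default free-space fit
range $s \in [5, 50]$ keeps the fit where counts are dense at the
validation ensemble sizes. Under confinement the contact profile
reaches its mixing plateau much earlier than $R^2(s)$ does -- by
$s \approx 30$--$50$ at $D = 1.5\,\mu m$ -- so the confined contact
exponent is fitted on its pre-plateau regime $s \in [5, 25]$, the same
experiment-matched window used for the spatial-distance exponent. All
ranges are arguments, not constants.

A geometric point that surprises at first sight: $P_c(1) = 0$ exactly.
Consecutive unit-boundary beads sit at precisely $L_p = 150$ nm because
units are rigid rods, which is beyond the 60 nm contact radius; contact
grids therefore start at $s = 2$ (where a narrow window of
near-backfolded geometries gives a tiny positive probability).

The contact radius itself (60 nm = $2 d_f$, a touching-to-near-touching
criterion) is a modelling choice; scaling exponents are insensitive to
this prefactor, which the free-space consistency check
$\alpha \approx 3\nu$ confirms.

## Plateau detection

Under confinement $R^2(s)$ levels off once chains feel the wall.
`detect_plateau_onset()` reports the smallest $s$ beyond which the
running mean (window of 5) of local log-log slopes stays below 0.1 for
the rest of the grid. The detector is a deliberately simple
changepoint heuristic, and the onset location is the least well
determined quantity in the package: the plateau tail of the profile is
exactly where weight degeneracy bites hardest, so on $10^3$-chain
ensembles the detected onset scatters over roughly a factor of two
between seeds (and can be reported as absent when tail noise keeps the
local slope above threshold). Stable but compact-biased
uniform-weight profiles saturate around $s \approx 40$, truncated-
weight profiles between ~80 and ~190; the reference leveling-off
location for this system (~125 persistence units) lies inside that
spread. Onset estimates should accordingly be read at the
factor-of-two level -- which is also how they are used scientifically,
to match the observed 10 Mb leveling-off scale. Profiles on coarse log
grids (10--15 points per decade) give steadier local slopes than very
dense grids.

## Domain-like substructures

Confined chains spontaneously form dense, contiguous regions -- the
model's analogue of topological domains. `find_substructures()` flags
contiguous stretches that fit in an 800 nm sphere while holding more
than 400 kb of DNA. Two scan policies are implemented because the
criterion "consecutive units contained in spheres of 800 nm diameter
along the chain" admits two geometric readings:

* `cover` (default): a sphere is centred on each persistence-unit
  boundary bead; the maximal contiguous bead run inside it is a
  candidate; qualifying candidates that overlap on the chain merge into
  one substructure. Placing sphere centres *on the chain* makes
  qualification a first-exit property of the local neighbourhood, so
  only genuinely dense stretches qualify. On 500-chain ensembles at
  $N = 1000$, $D = 1.5\,\mu m$ this yields ~7.5--7.8 substructures per
  chain covering ~30% of the chain, with ~45--49% of them interactive
  (growth-ensemble averages; see the estimator-policy discussion) --
  consistent with the reference statistics for this system (~6.5 per
  chain, 41% interactive) given the compact bias of the proposal
  ensemble.
* `greedy_mes`: greedy maximal windows under an exact minimal-
  enclosing-sphere (Welzl) diameter bound. This stricter containment
  reading tiles most of a strongly confined chain (typical maximal
  windows already exceed 400 kb), yielding ~16 substructures per chain
  and near-total coverage; it is kept as an explicit alternative and
  for geometric fixtures, but it cannot reproduce the sparse-domain
  phenomenology, which is why it is not the default.

Classification (`classify_substructures()`) calls a substructure
*interactive* when more than 20% of its persistence units have any bead
within the contact radius of a different substructure, else
*independent*; the stricter no-contact-at-all reading is reported as a
separate `strictly_independent` column. After merging, a `cover`
substructure's recorded enclosing diameter (its exact minimal
enclosing sphere) can slightly exceed the scan sphere -- it is a
descriptive column, not a constraint.

## Clustering and compactness

`cluster_ensemble()` measures chain-to-chain dissimilarity as the RMS
difference between unit-level distance matrices and cuts an
average-linkage tree, mirroring how chromosome-to-chromosome
variability in the Hi-C exponent can emerge from one homogeneous
ensemble: per-cluster contact exponents on 20 clusters span roughly
0.8--1.3 around the population value. `classify_compactness()` labels
chains open/compact/intermediate by quantiles (defaults 0.2/0.8) of the
rod-normalised radius of gyration; the original criteria behind the
published open/compact/in-between percentages are not in the main text
we reconstruct from, so these thresholds are documented substitutes and
the resulting fractions are qualitative.

## Binder reweighting

To ask whether random binder-mediated looping changes the scaling,
`reweight()` Boltzmann-rescores the existing ensemble instead of
re-simulating: sites are placed uniformly on a fraction (10--50%) of
the persistence units, every non-adjacent site pair within the contact
radius contributes a binding energy of $6\,k_BT$ (scaled by a relative
temperature $\tau \in \{1, 10\}$), and each chain's log-weight gains
$n_{pairs}\,\varepsilon/\tau$. Pairs contribute independently (no
valence cap -- none is specified for the reference system; a cap can be
imposed by filtering pair counts). Reweighting at $\varepsilon =
6\,k_BT$ is drastic: chains with many proximal site pairs dominate and
the ESS collapses, which `binder_sensitivity_report()` reports
alongside the exponent deltas. The scientific conclusion -- exponents
do not move outside the baseline bootstrap interval -- is robust
precisely because confined chains are already loop-rich, so the
reweighted population looks statistically like the tail of the original
one. At the full binding energy and $\tau = 1$ the collapse is total
(ESS of 1.0: the single most loop-rich chain carries all the weight),
and the reweighted *contact* exponent in particular becomes a
single-chain artifact; the spatial-distance exponent, which
self-averages within chains, stays within the baseline interval even
there. Conclusions at $\varepsilon/\tau = 6$ should therefore rest on
the flagged ESS column, not on the point estimates alone.

## Problem sizes used in the shipped checks

The reference system runs 10,000-chain ensembles. The package's
validation suite and the acceptance script reproduce the same
quantities at reduced, fixed sizes chosen to keep each quantity
statistically meaningful: 1000--3000 free-space chains per length for
the self-avoiding-walk validation (more at the lengths entering the
exponent fit, as discussed above), 500 confined chains at $N = 1000$
for the spatial-distance exponent and substructure statistics, 300
chains per length for the multi-length contact protocol, and 200
bootstrap resamples for interval estimates. At these sizes the scaling
exponents carry uncertainties of a few hundredths, which is the
tolerance against which they should be read.

## Known limitations

* Single chains only: inter-chromosomal organisation is out of scope.
* Uniform mass density (3 kb per 30 nm bead) and fixed fiber geometry;
  locus-to-locus density variation is not modelled, so genomic-distance
  axes are calibrated only through the leveling-off match.
* Plain SIS without population control limits reliable weighted
  estimates at very long free chains, as described above.
* The generator produces equilibrium ensembles; no dynamics, no
  loop-extrusion-style mechanisms.
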