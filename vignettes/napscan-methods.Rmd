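---
title: "Models and methods behind napscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind napscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(napscan)
```

napscan analyzes the genome occupancy and ligand binding of a
c-di-GMP-controlled nucleoid-associated protein (NAP): a small
ribbon-helix-helix (RHH) protein that assembles into a tetramer, binds a
GC-rich 18-bp direct repeat at hundreds of chromosomal sites, and releases
DNA when the second messenger c-di-GMP occupies the same binding surface.
This vignette documents the models, their assumptions, the tunable
parameters, and the design choices made where reasonable alternatives
existed.

## ChIP enrichment and peak calling

Binding is quantified per genome position as

$$\mathrm{log2}\left(\frac{\mathrm{IP}_i \cdot s + c}{\mathrm{input}_i + c}\right),
\qquad s = \frac{\text{input library size}}{\text{IP library size}},$$

where `s` removes sequencing-depth differences by total-count scaling and
the pseudocount `c` (depth units, default 1 read) keeps the ratio finite at
zero-coverage positions. A 4-fold enrichment is log2 = 2, the peak-calling
threshold used throughout.

`call_peaks()` implements the stated fold rule directly: maximal runs of
positions at or above `threshold_log2`, with two morphology parameters that
commercial shape-based callers hide internally and we surface explicitly —
`merge_gap` (default 30 bp; sub-threshold gaps up to this length are
bridged, absorbing single-position Poisson dips) and `min_width` (default
20 bp; shorter runs are discarded as noise spikes). The summit is the
leftmost position of maximal enrichment (deterministic under plateau ties);
ranks order peaks by `max_log2`, ties broken by coordinate. These defaults
are our own explicit choices; a proprietary shape-learning caller would
draw somewhat different boundaries, which is why genome-scale peak counts
from real accessions are not a reproduction target of this package.

One subtlety: the number of peaks is *not* monotone in the threshold for
any run-based caller — a bimodal run can split into two runs as the
threshold rises. What is monotone, and what the tests assert, is the set of
above-threshold positions; peak counts are monotone only for isolated
unimodal peaks.

Replicate agreement is the squared Pearson correlation of per-position
log2 enrichment. Its value depends strongly on the fraction of positions
carrying signal: with 50 sites in 100 kb at depth 60 and 8-fold enrichment,
roughly 8% of positions carry shared signal of ~3 log2 units against
independent Poisson log-ratio noise (variance about `2/(depth ln^2 2)`),
giving an expected R² well above 0.5, whereas site-free simulations give
R² near 0. Those are the conditions used in the replicate-agreement tests,
chosen from this signal-to-noise calculation.

## Direct-repeat motif model and Monte-Carlo calibration

The motif is a fixed-width position probability matrix; the direct-repeat
constructor concatenates one 7-bp half-site block, a spacer whose columns
equal the background (4 bp), and the identical half-site block again —
18 bp total. Scoring is log-odds in bits,

$$S(x) = \sum_{j=1}^{w} \log_2 \frac{p_{j,x_j} + \varepsilon}{\pi_{x_j}},$$

with additive smoothing `epsilon = 0.01` (keeps zero-probability cells
finite; surfaced in every scanning function) and a 0-order background
parameterized by GC only: `P(G) = P(C) = gc/2`. For an ungapped fixed-width
motif, a profile HMM built from the same probability table assigns the same
likelihood to every width-`w` string, so the PWM scan is the exact
equivalent of scanning with such a model; we implement the PWM form.
Both strands are scanned; windows overlapping `N` are excluded (an `N`
makes the window score undefined, and excluding is the conservative
choice); overlapping hits and opposite-strand hits at one locus are each
reported, with no greedy merging.

Significance is calibrated empirically: `n` random sequences of the motif
width are drawn from the GC-matched background (forward strand only —
random sequences have no orientation), scored, and the p-value of an
observed score is the add-one tail fraction `(k + 1)/(n + 1)`, which is
never zero and is uniformly distributed under the null (a property the test
suite checks by Kolmogorov–Smirnov distance at n = 10^4). The genome scan
operates at the smallest score whose empirical p-value is at most the
target (default 0.00077); with 10^6 null samples that threshold leaves at
most 770 null scores at or above it. Targets below `1/(n + 1)` are
rejected as unattainable rather than silently clamped. The example motif
shipped with the package (`example_direct_repeat_motif()`) is a synthetic
GC-rich consensus with 0.85 per-column conservation — a stand-in for the
unpublished experimentally derived matrix, adequate for exercising and
calibrating the machinery but not a claim about the real binding
specificity.

## Peak–motif association and location classes

A motif is assigned to a peak if it lies within ±50 bp of the summit. The
source rule does not say which part of the hit must fall in the window; we
default to any-overlap of the hit footprint with the closed window (both
bounds inclusive) and surface the alternatives (`anchor = "start"` or
`"center"`) as options. Genic/intergenic classification uses the summit
position only — summits are the reference points for motif assignment, and
a single-point rule is unambiguous where whole-peak overlap would need an
arbitrary minimum-overlap convention. Under a random-placement null on an
annotation that is 10% intergenic, ~10% of summits classify intergenic;
enrichment of intergenic summits above that baseline is the biologically
meaningful signal.

## One-site ITC isotherm

The forward model is the standard single-site (Wiseman) isotherm. With
total macromolecule `M_t` and ligand `X_t` in the cell after an injection,
the occupied-site fraction solves

$$\Theta^2 - \Theta\left(1 + \frac{X_t}{nM_t} + \frac{K_d}{nM_t}\right) + \frac{X_t}{nM_t} = 0$$

(the root in [0, 1]; the tests verify it against mass-action bisection).
Cumulative heat is `Q_i = n * Theta_i * M_t * dH * V0` and the observed
injection heat carries the mid-point volume-displacement correction
`dq_i = Q_i − Q_{i−1} + (dv_i/V0)(Q_i + Q_{i−1})/2`. Concentrations are
updated by discrete displacement per injection
(`M → M(1 − dv/V0)`, `X → X(1 − dv/V0) + X_s dv/V0`); this convention and
the mid-point correction together make pre-saturation heats nearly constant
in the tight-binding limit, as they should be. The default protocol is a
200 µl cell at 25 µM titrated with 19 × 2 µl injections of 150 µM ligand.
The simulation ground truth used in demonstrations is `n = 0.5`,
`Kd = 83 nM` and `dH = −10 kcal/mol`; the enthalpy is a realistic
exothermic value chosen by us (the stoichiometry and affinity fix the
isotherm shape; `dH` only scales the heats).

Fitting runs Levenberg–Marquardt on `(n, log Kd, dH)` — the log transform
enforces `Kd > 0` — with heuristic starts (`dH` from the first-injection
heat per mole injected, `n` from the molar ratio where heats halve). On
noise-free data the round trip recovers all three parameters to well under
1% across a grid of stoichiometries, affinities and enthalpy signs.
Identifiability under noise is asymmetric and worth stating: at these
concentrations the Wiseman parameter `c = nM_t/K_d ≈ 150` makes the
isotherm nearly a step, so `n` (the equivalence point) is pinned to ~1%
even at 5%-of-maximum-heat noise, while `K_d` — carried almost entirely by
the curvature of one or two transition injections — has a median error
floor near 20% that no optimizer can beat (refitting from the true
parameters gives the same floor). The tests assert that floor honestly
rather than a tighter bound the data cannot support.

Derived thermodynamics use `ΔG = RT ln K_d` and `ΔS = (ΔH − ΔG)/T` at
25 °C.

## EMSA fraction-bound fitting

The shift-assay model is `f = P/(K_d + P)`: protein in large excess over
probe (no depletion), one non-cooperative site. The fit is least squares
with `K_d > 0` enforced on the log scale; degenerate curves (all-bound,
all-free, flat) raise an unidentifiable-data error rather than returning a
boundary estimate. The default concentration ladder spans 0.0625–4 µM in
doublings, bracketing dissociation constants in the 0.4–4 µM range. The
real assay shows super-shifting at high protein concentration
(multi-molecule binding); the model deliberately does not include a
multi-site term — lack of fit is the diagnostic for that regime.

## Mutually exclusive competition

With DNA and a competing ligand binding the same protein surface, the
retained protein–DNA complex fraction relative to the no-ligand baseline is

$$\frac{1 + P/K_{dna}}{1 + P/K_{dna} + (C/K_{lig})^m}.$$

Half-inhibition for `m = 1` occurs at `C = K_{lig}(1 + P/K_{dna})`, which
the tests verify numerically. `m = 2` is available for the
two-ligands-per-tetramer stoichiometry. This module is exploratory by
design: the measured system needs micromolar competitor despite nanomolar
ligand affinity, which simple competition does not explain (conformational
coupling between the two binding modes is the likely culprit), so the model
serves for hypothesis exploration, not for fitting the gel data.

## Copy numbers, standard curves, expression ratios

`copies_to_concentration()` is Avogadro arithmetic:
`(copies/subunits)/(N_A · V)`. The worked example — 7000 monomers per cell,
4 per tetramer, 1.32 fL cytoplasmic volume → 2.2 µM tetramer — uses a
volume consistent with a rod-shaped cell's cytoplasm; the package treats it
as an explicit input, since the conversion is only as good as the volume
estimate. Immunoblot quantification inverts a linear intensity–mass
standard fit (warning on extrapolation or non-monotone standards), and
size-exclusion masses interpolate `log10(mass)` linearly in elution volume
over a ladder. Comparative-Ct expression ratios are `2^(−ΔΔCt)`.

## Structure metric

`read_structure()` parses PDB ATOM records (via bio3d) into a flat atom
table, resolving alternate locations to the highest-occupancy conformer;
mmCIF is not supported (the relevant depositions exist in PDB format).
The tetramer geometry metric is the Cα–Cα distance between equivalent
residues (default residue 12) across the two dimers of a dimer-of-dimers.
Which of the chain pairings the original measurement used is ambiguous in
a four-chain assembly, so the report always lists both cross-dimer pairs
and their mean, with the pairing explicit in the call. Distances are
invariant under rigid motion of the coordinates (tested with random
rotations) and symmetric in their arguments.
`synthetic_tetramer_structure()` builds a labelled-synthetic Cα-only
fixture with an exact, chosen separation for testing the machinery.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes:

* genomes of i.i.d. bases at a target GC (default 0.69, matching the
  organism's composition) — no repeats, no skew, no real gene content;
* planted sites drawn from the motif's column distributions at
  non-overlapping positions on random strands (minus-strand instances
  inserted as reverse complements, so orienting the genome slice recovers
  the instance);
* coverage as per-position Poisson counts: input around `mean_depth`, IP
  around `mean_depth` times an enrichment profile that tapers linearly
  from `enrichment_at_sites × site_strength` at the site center to 1 at
  the edges of one mean fragment length (default fragments 200–400 bp,
  taper half-width 150 bp) — a triangular approximation of fragment
  pileup around a point source, chosen because the source data constrain
  the enrichment magnitude (≥4-fold at bound sites) but not the shape;
* annotations as alternating gene/gap tilings (gamma-distributed lengths,
  rescaled so the realized intergenic fraction matches the request, default
  10%).

Simulation is done at per-position coverage resolution, not by emitting
reads and aligning them: the per-position tracks are the actual substrate
of every downstream computation, and read-level artifacts (duplicates,
mappability) are out of scope. Every generator is a pure function of its
seed (one named RNG, seeded explicitly; determinism is promised within
this implementation, not across languages). Consequently, passing tests
demonstrate correct recovery of planted structure under the stated noise
model — they do not demonstrate robustness to GC skew along the replichore,
repeated sequence, copy-number variation in the input, or fragment-size
biases, none of which the generator produces.

## Problem sizes and numerical choices

The end-to-end recovery experiment runs on a 1 Mb genome with 50 planted
sites at 8-fold enrichment and depth 30 — a desk-scale stand-in for a
9.3 Mb genome with hundreds of sites, large enough that peak calling,
null calibration (10^5–10^6 samples) and two-strand scanning all run in
seconds to a couple of minutes while binomial fluctuations stay small.
Other fixed numerics: pseudocount 1 read; motif smoothing ε = 0.01;
summit ties leftmost; rank ties by coordinate; add-one empirical
p-values; alignment end gaps penalized (Needleman–Wunsch `type =
"global"`; note that the classic EMBOSS tool leaves end gaps free by
default, so identity/similarity of distantly related pairs can differ
slightly between the two conventions — the package's convention is
deterministic and oracle-tested by exhaustive enumeration on short
sequences, with identity and similarity both computed over the full
alignment length including gap columns).

## Known limitations

* The peak caller is the stated fold-threshold rule, not a shape-learning
  method; absolute peak counts on real data depend on the morphology
  parameters.
* The shipped motif is synthetic; analyses of real genomes should supply
  the experimentally derived matrix (MEME minimal format is read
  directly).
* The competition model ignores conformational coupling (see above).
* The EMSA model has no multi-site/super-shift term.
* Only PDB-format coordinates are read, and only the first model of
  multi-model files by default.
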