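---
title: "Designing knowledge-based scoring potentials for docking decoys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing knowledge-based scoring potentials for docking decoys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kbscore)
```

## The scoring problem

Rigid-body protein-protein docking samplers produce thousands of candidate
complex geometries ("decoys") per target, of which only a small fraction are
anywhere near the true bound structure. Re-scoring those decoys so that
near-native poses rise to the top of the ranking is a distinct problem from
sampling, and the potential that does it best depends on which decoys the
sampler produces and on the objective: finding the single best pose, or
enriching a subset worth refining. `kbscore` provides the machinery to
*design* such potentials: choose a functional form and an atom typing,
precompute per-decoy feature vectors once, and then train, re-score and
evaluate candidate parameterizations quickly enough to iterate.

## Potential forms and feature vectors

All shipped forms are linear in their parameters, so the score of a decoy is
a dot product between a parameter vector and a precomputed feature vector,
and re-scoring a whole ensemble is one matrix-vector product
(`score_decoys()`). Lower scores are better. Per unordered atom-type pair
$(A,B)$ (canonically indexed by `canonical_pair_index()`):

* **Step (contact) potentials** count receptor-ligand atom pairs in
  half-open distance bins $[d_k, d_{k+1})$; one parameter per (pair, bin).
  Typical choices are a single long-range $[0, 10)\,\mathrm{\AA}$ bin or two
  short-range bins $[0,4)$ and $[4,6)\,\mathrm{\AA}$.
* **Soft Lennard-Jones (vdw) potentials** score
  $E = \sum_{AB} \alpha_{AB} \sum r^{-8} - \beta_{AB} \sum r^{-6}$ with
  $\alpha = \varepsilon\sigma^8$ and $\beta = \varepsilon\sigma^6$. For a
  single pair the energy is $0$ at $r = \sigma$ and reaches its minimum
  $-\tfrac{27}{256}\varepsilon$ at $r = \sigma\sqrt{4/3}$; the tests verify
  this closed form against a dense grid search. Cross distances below the
  2 Å clash floor are shifted up to it, damping clashes that appear when
  coarse-grained sampling output is rebuilt at atomistic resolution.
* **Buried-surface-area (BSA) potentials** use, per heavy atom type, the
  solvent-accessible surface area lost upon complexation (probe radius
  1.4 Å), with each rigid partner in its docked conformation as the
  reference state, so the burial depends only on the interface.

The default atomistic representation is a 27-type grouped all-atom table
(23 heavy types, 4 grouped hydrogen types) that groups amino-acid atoms by
the chemical character of five residue classes (non-polar, polar, aromatic,
positively and negatively charged), with shared backbone N/CA/C/O types.
The table is a documented reconstruction of that grouping idea - it
preserves the dimensionalities (27 types; 23 heavy-type BSA parameters;
378 type pairs) rather than reproducing any published supplementary table
verbatim - and it is fully replaceable: any TSV read by
`read_typing_table()` works, which is also how the toy fixture tables are
wired in.

## Quality assessment

Decoys are assessed against the native complex with the community's
standard criteria: the fraction of native residue contacts `Fnat`
(heavy-atom cutoff 5 Å), the ligand RMSD after receptor superposition
(`compute_lrmsd()`), and the interface backbone RMSD (`compute_irmsd()`,
native interface residues at 10 Å, backbone N/CA/C/O). Star classes are
assigned hierarchically:

* 3 stars ("high"): Irmsd < 1 Å and Fnat > 0.5;
* 2 stars ("medium"): Irmsd < 2 Å and Fnat > 0.3;
* 1 star ("acceptable"): Irmsd < 4 Å and Fnat > 0.1;
* 0 otherwise.

The printed definition of the acceptable class carries an upper Fnat bound
of 0.3; we read that bound as the hand-off to the higher classes rather
than an exclusion, since a literal reading would deny any star to a decoy
with Fnat 0.4 and Irmsd 3 Å that every practitioner would call
near-native. All boundary inequalities are strict and frozen by tests.
On pseudo-atom fixtures, which have no backbone atom names, `compute_irmsd()`
falls back to all heavy atoms of the interface residues.

`make_quality_weights()` converts records into per-complex normalized
training weights (star values, Fnat, an indicator on an inserted native, or
a custom function); a complex whose raw weights are all zero is flagged
unusable rather than failing.

## Training

### Monte-Carlo annealing

`anneal()` maximizes the rank-based target
$t = \sum_c \sum_i w_q^{(i,c)} \, w_r(\mathrm{rank}_i)$, where $w_r$ rises
linearly or quadratically from the bottom of the ranking to 1 at rank 1.
The quadratic scheme concentrates the objective on the very top and is the
natural choice when the goal is enrichment of a small best-scored subset.
Each step perturbs one uniformly chosen parameter additively by
$\pm U(0, d)$ in its natural space (potential values; $\sigma/\varepsilon$
for vdw, clamped to $\sigma \in [1.5, 6]$ Å, $\varepsilon \in [0, 50]$),
re-scores every training complex from its feature grid (a rank-one score
update; no structure I/O happens inside the loop), and accepts with the
Metropolis probability $\min(1, e^{(t_\mathrm{new} - t_\mathrm{old})/T})$.

The temperature follows a "ziczac" schedule: it oscillates between two
decaying exponential envelopes,
$T(s) = T_\mathrm{hi}(s)\left(\tfrac1\rho + (1 - \tfrac1\rho)
\sin^2(\pi k s / S + \tfrac\pi2)\right)$ with
$T_\mathrm{hi}(s) = T_0 (T_\mathrm{end}/T_0)^{s/S}$, cooling from 50 to
0.05 (0.1 % of the start) by default. The oscillations periodically reheat
the chain, letting it escape local ranking optima while the envelope still
guarantees eventual quenching. The envelope ratio $\rho = 3$ and
oscillation count $k = 10$ are package choices satisfying the schedule's
defining properties (both endpoints met for even $k$; $T$ always within
$[T_\mathrm{hi}/\rho, T_\mathrm{hi}]$).

The move size $d$ starts at 1 and adapts every 100 steps: multiplied by 1.1
when the trailing acceptance rate exceeds 0.3 and by 0.9 otherwise - a
standard annealing heuristic targeting a productive acceptance rate. The
best-so-far parameters are returned. Early stopping watches the trailing
2,000-step window for a relative best-target improvement below $10^{-6}$,
but only over the second half of the schedule: during the hot phase the
best target routinely plateaus for thousands of steps purely
stochastically, and stopping there would quench the search before the
schedule has cooled. Given a seed, the whole trajectory is bit-reproducible.

### Linear regression

`train_lr()` fits parameters to regression targets built from the quality
records: `y = -q` for quality-increasing assessments (stars, Fnat) and
`y = -1/max(q, 1e-3)` for deviation-type ones (Irmsd, Lrmsd), so better
decoys always have more negative targets (the floor only caps the blow-up
as the deviation approaches zero). For step and BSA forms the feature rows
are fraction-normalized first - each row divided by its own sum - so
complexes with large interfaces do not dominate the fit; the tests verify
that this makes the fitted potential invariant to duplicating every
interface. Ordinary least squares runs through base R's QR path and
non-negative least squares through the Lawson-Hanson solver
(`pracma::lsqnonneg`); the vdw design matrix is $[f_8, -f_6]$ with
non-negative coefficients $(\alpha, \beta)$, keeping the attraction sign a
scoring-time convention rather than a fitting constraint.

### Cross-validation and combination

`crossval_average()` splits complexes into $k$ folds (default 5; a literal
leave-one-out over a hundred-plus complexes would produce that many
parameter sets, whereas five folds produce the five sets the combination
rules below expect). Step/BSA parameter sets are each divided by the
standard deviation of their own entries - the one scalar per set under
which "scaling by the standard deviation" is well defined - and averaged
elementwise; this removes the arbitrary overall scale of rank-based
training, under which the target function is invariant. For vdw potentials,
whose $(\sigma, \varepsilon)$ blocks do not average meaningfully, the
single fold with the best validation performance is kept.

## Evaluation

`evaluation_report()` computes the three standard assessments over a set of
scored ensembles: the per-complex best rank of a flagged decoy, success
fractions at top-1/10/100/500/1000, and mean enrichment fractions (the
share of all near-natives captured in the best-scored 0.1/1/2/5 %; the top
slice holds $\lceil qn \rceil$ decoys, at least one). Complexes without any
near-native are excluded from enrichment averages - their fraction is
undefined - but count as failures in success rates. `random_baseline()`
reports the same metrics under uniformly random rankings; its top-N success
converges to the hypergeometric $1 - \binom{n-m}{N}/\binom{n}{N}$ and its
enrichment to the percentile itself, which the tests check against $10^4$
shuffles.

For interpretation, `contribution_report()` decomposes a potential into
per-parameter class contributions $p = \sigma_{AB}\,
\overline{nc}^{\,\mathrm{class}}_{AB} / \overline{nc}^{\,\mathrm{tot}}_{AB}$
over native, near-native and incorrect decoys, the discriminating
contribution (absolute and signed difference between the incorrect and
near-native contributions), and flags for parameters whose sign contradicts
the mean-count ordering (false positive/negative contributions) - the
signature that separates trained potentials from purely statistical ones.

## The synthetic benchmark

`make_toy_complex()` builds two clash-free rigid clusters of typed
pseudo-atoms (one residue per atom, 1.8 Å radius) docked so the native
interface has at least three - preferably six or more - residue contacts at
5 Å and no cross distance below 2 Å. `make_decoy_set()` perturbs the ligand
rigidly in magnitude tiers and, on request, verifies via the quality module
that all four star classes are populated, drawing class-targeted
replacements as needed. `make_planted_benchmark()` adds a planted linear
energy model: decoy energies are `planted . features` plus Gaussian noise
(default sd 0.05), and the best 10 % of each complex by planted energy are
flagged "good" and given uniform normalized training weights.

This emulates the *structure* of a docking re-scoring benchmark - rigid
poses with a quality spectrum, per-complex ensembles, a recoverable signal -
not its physics: there are no side chains, no conformational strain, no
sampler-specific contact biases, and goodness is planted rather than
CAPRI-derived. Passing tests therefore demonstrate that the machinery
(featurization, target functions, optimizers, metrics) is correct and that
the training loop recovers a recoverable signal; they say nothing about how
well any particular potential form scores real decoy sets. Note also that
the label noise flips "good" flags near the decile boundary, so even the
generating potential does not reach perfect held-out enrichment; trained
potentials should be read against both the random baseline and that
ceiling (both reported by `scripts/acceptance.R`).

## Numerical choices and problem sizes

* Bins are half-open $[lo, hi)$; a distance exactly at an edge belongs to
  the bin it opens. Frozen so count features match their brute-force oracle
  exactly.
* The vdw sum needs an explicit cutoff for a well-defined neighbor search;
  12 Å by default, where the $r^{-6}$ tail is negligible against interface
  terms. The clash floor is 2 Å. Both configurable.
* SASA uses a deterministic golden-spiral quadrature (960 points/atom by
  default; "rolling probe" names the model, not an algorithm), with
  per-element radii from a small shipped table. An isolated sphere is exact
  by construction; overlapping configurations agree with an 8x refined
  quadrature to well under 2 %. Per-type burials are clamped at zero
  against quadrature noise.
* Ranking ties break by input order (stable), making top-N metrics
  reproducible.
* Annealing defaults follow the recipe above (300,000 steps for step/BSA
  forms, 100,000 for vdw, $T$: 50 to 0.05); the test suite and the
  acceptance script run desk-scaled versions (up to 10 complexes x 500
  decoys with a 4-type toy table and 20,000 annealing steps), which finish
  in seconds while leaving the signal recoverable.
* All randomness flows through explicit seeds; fixtures, annealing traces
  and baseline reports are bit-reproducible.

## Limitations

* The shipped 27-type table is a reconstruction of a grouping scheme, not
  a published mapping; users comparing against published potentials should
  supply their own TSV.
* Feature extraction is vectorized brute force over cross pairs, ample for
  ensembles of rigid poses at fixture-to-benchmark scale but not tuned for
  very large atom counts; SASA is quadrature-based, not analytic.
* `compute_irmsd()` follows the common backbone-RMSD convention but not
  any specific assessment pipeline's atom-selection details; small
  systematic offsets against other implementations are expected.
* Only linear-in-parameters potential forms are supported; composite
  scoring with trained combination weights is out of scope beyond summing
  compatible potentials.
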