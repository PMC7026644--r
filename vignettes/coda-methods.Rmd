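---
title: "Inferring RNA base pairs from deep mutational scanning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring RNA base pairs from deep mutational scanning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codarna)
```

## The problem

A self-cleaving ribozyme reports its own activity in a sequencing read:
cleaved and uncleaved molecules differ in length, so the cleaved
fraction of a variant's reads measures how well that variant folds and
cuts. An error-prone-PCR library subjected to such a selection yields
tens of thousands of variants with measured activities — a fitness
landscape dense enough to read the base-pairing structure out of,
because a mutation that breaks a base pair destroys activity while the
compensatory double mutation that restores a (possibly different)
canonical pair rescues it. `codarna` turns that covariation signal into
a full base-pairing structure: nested helices, pseudoknots, lone pairs
and, where the signal permits, noncanonical pairs.

The pipeline has four stages, each usable on its own:

1. **Activities** (`compute_ra()`, `merge_batches()`,
   `reduce_triples()`): relative activity of variant $v$ is
   $RA(v) = \frac{N_{cleaved}(v)\,N_{total}(wt)}{N_{total}(v)\,N_{cleaved}(wt)}$,
   computed for every variant with at least 5 reads (values above 1 are
   legitimate — some variants out-cleave the wild type). Batches are
   merged by averaging. Where a position pair has no direct double
   mutant, triple mutants XYZ with a near-neutral third mutation
   ($RA(Z) > 0.5$) are reduced to effective doubles
   $RA(XY) = RA(XYZ)/RA(Z)$, assuming Z does not covary with X or Y;
   multiple estimates for one key are averaged and a directly measured
   double is never overwritten.
2. **CODA scores** (`fit_independent_model()`, `coda_score()`): a
   support-vector regression (RBF kernel, $C = 2000$, $\gamma = 2$)
   fits the observed double-mutant RA as a function of its two
   single-mutant RAs — the independent-mutation model. The fit is
   unsupervised and uses *all* doubles, functional and nonfunctional;
   the ~1% of true-pair outliers barely perturb it. The covariation-
   induced deviation of activity is
   $CODA = (RA_{obs} - RA_{pred}) / (RA_{pred} + 0.2)$; the 0.2 shift
   guards against small predictions and results are insensitive to it
   over 0.1–0.5.
3. **Pairing scores** (`fit_mixture()`, `pairing_score()`,
   `score_all()`): the pooled CODA scores form a two-Gaussian mixture —
   a dominant component near 0 (independent mutations) and a minor,
   higher component (base pairs). Because the unpaired class dominates,
   de-mixing is one-pass: $a_1, sd_1$ from all scores, then
   $a_2, sd_2$ and the prior $P(paired)$ from the subset above
   $a_1 + 3\,sd_1$ (insensitive to the multiplier over 1–7). A naive
   Bayes score $Ps = \log p(CODA \mid paired) / p(CODA)$ (natural log)
   scores every double mutation; a position pair gets the maximum over
   its observed mutation combinations.
4. **Folding** (`anneal()`, `fold_ensemble()`): Metropolis simulated
   annealing over pair sets under
   $E = \Delta G_{37,stack} + \Delta G_{37,AU\,end} + \Delta G_{lone} +
   \Delta G_{noncanonical} - W \sum_{(i,j)} Ps(i,j)/m$,
   with Turner 2004 stacking free energies, a 0.45 kcal/mol terminal
   penalty per AU/GU helix end, a single 3 kcal/mol penalty shared by
   lone and noncanonical pairs, and the pairing-score restraint
   normalized by the mean positive per-position score $m$. Pairs may
   cross, so pseudoknots are first-class. One hundred annealing runs
   give pair frequencies; the consensus keeps pairs at frequency ≥ 0.5,
   greedily, one partner per base.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `min_reads` | 5 | reads | minimum coverage for an RA value |
| `ra_threshold` | 0.5 | RA | third-mutation neutrality cutoff in triple reduction |
| `C`, `gamma` | 2000, 2.0 | — | SVR regularization / RBF width; top pairs stable over C ∈ [1, 1e4], γ ∈ [0.01, 10] |
| `epsilon` | 0.1 | RA | SVR tube width; residuals are bounded by ≈ε |
| `shift` | 0.2 | RA | CODA denominator shift, robust over 0.1–0.5 |
| `k_sd` | 3 | sd | outlier cutoff multiplier, robust over 1–7 |
| `lone_penalty` | 3 | kcal/mol | lone/noncanonical penalty; MC-alone output stable over 2–5 |
| `weight` (W) | 2 | — | restraint weight; performance stable for W ≥ 2 |
| `t_initial`, `cooling_factor`, `t_final` | 10, 0.95, 0.1 | unitless T | annealing schedule; Metropolis uses $e^{-\Delta E/T}$ with ΔE in kcal/mol |
| `steps_per_temperature` | 500,000 | steps | production budget; see "Problem sizes" |

## The sampler

The move set is the standard insertion/deletion/shift kernel of RNA
folding-kinetics samplers, each proposed with probability 1/3:
removal of a uniformly random existing pair; a toggle of a candidate
position pair drawn uniformly from all loop-feasible pairs
($j - i - 1 \ge 3$) — removal if present, addition if both bases are
free; and a shift that keeps one endpoint of a random pair and moves
the other to a uniformly chosen free, loop-valid position. The shift
proposal is exactly symmetric (the kept endpoint's free-partner set
has the same size before and after), and the overlapping
removal/toggle sub-kernels carry the exact, O(1) Metropolis-Hastings
proposal ratio, so the fixed-temperature chain converges exactly to
the Boltzmann distribution — the suite checks the sampled pair
marginals on a 12-mer against exhaustive enumeration. The annealing
schedule is an optimizer rather than a sampler, so a run returns the
lowest-energy structure visited anywhere along the schedule; without
best-of-run bookkeeping, marginal minima (for example a lone two-pair
helix worth only a few tenths of a kcal/mol) freeze in or out of the
final state essentially at random under a scaled-down step budget,
because single-pair moves cannot renucleate them at low temperature.
Shift moves additionally let competing helix registers interconvert
without dismantling a full stem.
Noncanonical additions are allowed and penalized rather than forbidden;
the penalty alone keeps them (and lone pairs) out of unrestrained
predictions. Stacking across a noncanonical pair contributes nothing
(no nearest-neighbour parameters exist for it), a lone pair pays the
terminal AU/GU penalty once rather than twice, and stacking uses only
the $(i+1, j-1)$ adjacency rule, which stays well-defined in
pseudoknotted context.

Two normalization choices were genuinely open. The restraint
normalizer is the mean of the *positive* per-position pairing scores:
the raw mean is negative on real score distributions, which would flip
the restraint's sign. And per-position aggregation uses the maximum
over mutation combinations, preserving a single strong compensatory
rescue; the mean alternative is available via `aggregate = "mean"`.

## The synthetic benchmark

`make_default_benchmark()` plants a 50-nt ribozyme with 14 canonical
pairs: a 5-bp helix, a 6-bp helix, a 2-bp kissing-loop pseudoknot and a
lone pair, the latter three flagged tertiary. Activity is
multiplicative: a disrupted helix pair costs a factor 0.05, a disrupted
tertiary pair 0.2 (tertiary contacts give weaker covariation signals),
a mutated loop position contributes a seeded factor drawn from
U[0.3, 1.1], and a pair whose two bases still form *any* canonical pair
costs nothing — the compensatory-rescue mechanism the method exploits.
`simulate_library()` draws an epPCR-like library: per-base per-round
mutation with A/U positions mutating 2.5× faster than G/C (the AT bias
of error-prone PCR), a mean of ≈2 substitutions per molecule (the rate
that maximizes exact-double yield), lognormal read depth with median 50,
and binomial cleavage counts at
$p = \mathrm{clamp}(0.5 \cdot RA, 0, 0.98)$. Measurement noise enters
per library molecule (lognormal, sd 0.1), so aggregated variants — the
wild type above all — see it average out. The default 1e5 molecules
yield ≈30,000 distinct single-to-triple variants, the scale of a real
ribozyme scan.

Sequence-design rationale: unpaired positions are all A, so no spurious
canonical helix competes with the planted structure, and the tertiary
pairs sit in A/U context where the AT-biased spectrum gives dense
double-mutant coverage. The GC-rich helix pairs are covered sparsely —
as in real epPCR data — and rely on the stacking term to be filled in,
which is precisely the division of labour between the covariation
scores and the energy model.

What the generator does *not* emulate: sequencing errors, PCR
duplicates/jackpots, indels, long-range epistasis beyond pairs, and —
importantly — the fat-tailed score noise of real selections. The last
point has a visible consequence. On clean synthetic data nearly every
true-pair score saturates at the Bayes ceiling $-\log P(paired)$, so
the positive-score mean $m$ sits close to the ceiling and the
restraint for a saturated pair is ≈W. A lone pair costs
3 + 0.45 kcal/mol, so on clean synthetic data its inclusion requires
W above roughly that cost (the suite asserts it at W = 4) and is
marginal at the W = 2 default, while the helices and the pseudoknot
(which rides on its own stack) are recovered at W = 2 on every
benchmark seed. Real score distributions carry many moderate
positives that pull $m$ well below the ceiling, which is why lone
pairs are recoverable at W = 2 on experimental data. Passing the
synthetic suite therefore demonstrates the machinery, not the exact
W-threshold behaviour of a real library.

A second synthetic-vs-real gap is deliberate in the one-pass mixture
rule: the paired-component mean is estimated from the scores above
$a_1 + 3 sd_1$, a *truncated* subset, so it is biased upward whenever
the cutoff cuts into the paired component. Simulating from published
component parameters and re-fitting recovers the prior $P(paired)$
well but reproduces the subset mean (≈1.66 for components at 1.26), not
the component mean — the estimator is a classifier calibration, not a
consistent moment estimator, and the pairing scores that matter are
insensitive to the difference.

## Numerical choices and degenerate inputs

- Coordinates are 1-based and inclusive throughout; double keys are
  canonicalized with $i < j$.
- Reads whose length differs from the wild type are discarded (the
  variant model is substitution-only); barcodes without a strict >50%
  consensus are dropped.
- Counts reaching one substitution set through different barcodes are
  summed before RA computation.
- SVR predictions are clamped at 0 (RA is nonnegative) and symmetrized
  by averaging both argument orders.
- `fit_mixture()` refuses degenerate inputs (zero variance, fewer than
  100 scores, fewer than 2 outliers — "no covariation signal").
- Metric denominators of 0 yield 0 with a message; the negative-pair
  universe is all $\binom{L}{2}$ unordered position pairs.
- Max-MCC threshold ties break toward the larger cutoff (fewer
  predictions); consensus ties break by (i, j) lexicographic order.
- A published prior printed with an impossible negative sign is treated
  as a typographical sign error and never used numerically.

## Problem sizes used by the test and acceptance suites

The production annealing budget (500,000 steps per temperature, ~91
temperature rounds, 100 runs) is the published schedule. The suites
scale it down: 10,000 steps/temperature for the restrained benchmark
folds and the short-sequence oracle comparisons, and 50,000 for the
penalty- and weight-robustness folds, where stiffer penalties slow
helix nucleation and need the larger budget to equilibrate. Short
test sequences are ≤18 nt so that exhaustive enumeration over all
valid canonical pair sets is feasible as an independent oracle; the
end-to-end benchmark uses the full default library (1e5 molecules,
depth 50) over five seeds.

## Known limitations

- The activity model is multiplicative with pairwise rescue only; real
  ribozymes show higher-order epistasis the independence model can
  only absorb into its outlier tail.
- Triple reduction assumes the third mutation does not covary with the
  remaining pair; violations leak noise into reduced doubles.
- The energy model has no loop entropies, dangles, or coaxial
  stacking, and no pseudoknot-specific terms; it is deliberately the
  minimal model the restraints can steer.
- Noncanonical pairs are detectable only when their disruption leaves
  a covariation signature; pairs whose mutants stay active are
  invisible to any covariation method.
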