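---
title: "Kinome network propagation: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinome network propagation: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkanet)
```

## The problem

Engineered cell lines carrying a doxycycline-inducible activating construct
(the PKA catalytic subunit, gene symbol PRKACA) or an inhibiting construct
(a dominant-negative regulatory subunit) are profiled on two proteomic
platforms: kinase **activity inference** from phosphosite fold changes
(effect sizes) and kinase **abundance** from multiplex-inhibitor-bead
enrichment (log2 fold changes). The two platforms cover overlapping but
different parts of the kinome, use different units, and disagree in detail
across cell lines. `pkanet` harmonizes these profiles, spreads them over a
functional-interaction gene network, and asks which kinases adjacent to the
focus gene respond consistently to PKA perturbation across all lines.

## The integration and propagation model

Per cell line, the pipeline applies four steps:

1. **Unit-max scaling.** Each platform's score vector is divided by its
   maximum absolute value, so the largest magnitude is 1 and signs are
   preserved. This is our reading of normalizing each dataset "out of one";
   the alternative (min/max rescaling onto [-1, 1]) destroys the zero point
   for asymmetric score distributions and was rejected. Since the z-scoring
   that follows is affine-invariant, the choice only matters through the
   relative weighting of the two platforms at the merge step.
2. **Platform union.** The gene sets are unioned; genes measured on both
   platforms are averaged, genes on one platform are carried through.
3. **Within-line z-scoring** across genes (not across lines per gene): each
   line is standardized before propagation so lines contribute comparably.
   The sample (n - 1) standard deviation is used everywhere in the package.
4. **Propagation of |z|.** The absolute z-scores are diffused by random
   walk with restart, `F <- (1 - r) W F + r F0`, with restart probability
   `r = 0.2` and the column-stochastic walk operator `W = A D^-1`. The
   magnitude is propagated because both strong activation and strong
   inhibition are signal; signs re-enter only at the final scoring step.

"alpha = 0.2" is interpreted as the restart probability; the opposite
convention (0.2 as the retention weight, i.e. restart 0.8) is available via
`propagation_config(alpha_is_retention = TRUE)`. Isolated network nodes are
given a self-transition of 1, which keeps `W` stochastic, conserves total
heat, and lets an isolated measured gene keep its own heat rather than
silently losing it. Convergence is declared when the L1 change per
iteration falls below `tol = 1e-10` (at most `max_iter = 1000` iterations);
with `r = 0.2` the iteration contracts at rate 0.8, so the fixed point is
reached to that tolerance in roughly a hundred iterations and the remaining
error is bounded by `tol / r`.

Genes measured but absent from the network are dropped **after**
z-scoring, so the z distribution reflects the full measured kinome; the
dropped counts are recorded in the run report.

## Cross-line combination and significance

Propagated heats are multiplied across the cell lines sharing a construct.
The product rewards genes that are consistently hot in *every* line — one
cold line zeroes a gene out — which is the conservative behavior wanted for
a screen-seeding candidate list. Heats reached purely by diffusion (in a
line where the gene was not measured) participate in the product, since
propagation defines heat on every network node.

Significance is empirical. Under the default `LABEL_SHUFFLE` scheme each
permutation shuffles, independently per line, the measured input heats over
that line's measured genes, re-propagates, and re-multiplies; this breaks
the value-to-position association while holding the network, each line's
coverage, and each line's heat distribution fixed. `DEGREE_BINNED`
additionally restricts shuffles to network-degree deciles, a guard against
hub-adjacency inflation. With `B` permutations the p-value is the add-one
estimator `(1 + #{permuted >= observed}) / (1 + B)`, which lies in (0, 1]
and never reports an exact zero. `B = 1000` by default (the count is a
package choice; at least 100 is enforced, and the permutation null is
rebuilt per construct from an independently derived seed substream so the
whole run is reproducible from one seed).

Final signed scores average the per-construct mean z-scores after flipping
the sign of the inhibiting construct, so a gene that goes up under
activation and down under inhibition scores coherently positive. The
reported subnetwork is the focus gene plus its direct neighbors significant
(p below the 0.05 default) in at least one construct, with all
interconnections among them (the induced subgraph); an optional kinase
whitelist restricts membership when only kinases are of interest.

## The activity-inference step

The external kinase-activity inference used upstream of integration is
emulated by the field-standard substrate-enrichment z-statistic
(KSEA-style): for kinase K with m measured substrate sites,
`score_K = (mean(fc_K) - mean(fc)) * sqrt(m) / sd(fc)`. This is an
emulation chosen for its matching effect-size semantics, not a
reimplementation of any particular tool; kinases with fewer than
`min_substrates = 3` measured substrates are not scored. The statistic is
invariant to shifting or positively rescaling all fold changes, which is
why the downstream unit-max step does not need to know the platform's raw
scale.

## Screen statistics

* `plate_zscores()` standardizes each physical plate by the mean and
  sample sd of its **non-control** wells (controls would compress the
  spread; a flag includes them), then averages per agent across replicates.
  The statistic is invariant to per-plate affine transforms — exactly the
  internal normalization plate screens rely on.
* `differential_response()` normalizes each plate as log2 of the well value
  over the plate median (gentler than a z-score for small effects), takes
  the perturbed-minus-control difference of replicate means, and attaches a
  two-sided equal-variance Student's t-test (Welch optional), uncorrected
  for multiplicity by design. A zero pooled variance yields `p = NA` with a
  `degenerate` flag rather than a fabricated p-value; non-positive well
  values are errors, not clamped.
* Hit thresholds are strict inequalities (a z of exactly -1 is not a
  down-hit); defaults -1/+1 for proliferation screens, with the stricter
  ±2 used for compound calling.
* `fit_dose_response()` fits the four-parameter logistic on the log10-dose
  axis with Levenberg-Marquardt least squares; the fit reports whether the
  EC50 landed inside the tested dose range, since an out-of-range EC50 from
  a flat curve is not an estimate. `half_life()` is the log-linear fit
  `ln(v) = a - k t` with `t1/2 = ln 2 / k`; a non-positive `k` is flagged
  non-decaying instead of returning a negative half-life.
* `growth_auc()` is the trapezoidal area of confluence over time.

## What the synthetic generator emulates — and what it does not

`synthetic_scenario()` mirrors the study design: 3 activating and
2 inhibiting lines, two platforms each observing any given kinase with
probability 0.7, a planted module of 15 kinases wired to the focus gene in
a 300-node background network (Erdos-Renyi at mean degree 8 by default,
small-world as an alternative), planted effect 2.0 in units of the
measurement noise sd (1.0), Gaussian noise throughout. Plate screens get
352 agents plus controls per 384-well plate, random per-plate shifts and
scales, and spiked inhibitors expressed in plate-sd units; growth curves
are logistic, 120 h at 2 h cadence. Effect and noise magnitudes are package
choices (no noise model is published for these assays); 2 noise-sd is a
"clearly but not trivially detectable" planted effect, and detection
probability 0.7 reflects the partial, platform-specific kinome coverage
seen in such data.

Real data differ in ways the generator deliberately ignores: scale-free
rather than Erdos-Renyi topology, correlated (batch) noise across kinases,
heavy-tailed outliers, platform-specific biases that do not vanish under
unit-max scaling, and kinase modules that are not cleanly adjacent to the
focus gene. Passing the synthetic benchmarks therefore demonstrates the
statistical machinery — calibration of the permutation null, recovery of a
planted signal at realistic noise — not performance on any real kinome
dataset.

Module-recovery is scored against the method's actual membership call: the
extracted subnetwork minus the focus gene (significant direct neighbors).
The genome-wide significant set is the wrong yardstick here — genes
elsewhere in the graph that genuinely receive diffused heat are counted as
false positives even though the method never claims them as module
members.

## Benchmark sizes

The bundled checks run the null-calibration scenario once (300 genes,
B = 1000, 5 lines), the recovery scenario over 10 seeds, estimator-recovery
simulations over 20 seeds, and oracle comparisons over 100 random graphs of
up to 50 nodes — sizes chosen so the whole suite completes in well under a
minute on a laptop while keeping Monte-Carlo error comfortably inside the
asserted margins.

## Known limitations

* Gene identity is the upper-cased symbol string; no alias or identifier
  mapping is attempted, so networks and score tables must agree on
  nomenclature.
* The permutation null is built per construct from label shuffles; it does
  not model correlated measurement error between lines, which would widen
  the null.
* The spike-in recovery of a -3 plate-sd inhibitor with 3 replicates is
  itself stochastic: the replicate-averaged z has standard error near 0.6,
  so an individual planted agent clears a -2 threshold with probability
  about 0.95, and an occasional miss among 10 planted agents is expected
  behavior, not a defect.
* Directed or weighted networks, multi-focus queries, spatial plate
  artifacts (edge effects, B-scores) and FDR control are out of scope.

## A compact end-to-end run

```{r example, eval = FALSE}
sc  <- synthetic_scenario(seed = 1)
gen <- generate_network(sc)
sets <- generate_kinase_datasets(gen, sc)
res <- run_propagation_pipeline(sets, gen$network,
                                propagation_config(seed = 1))
res
module_recovery(res, gen$module)
```
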