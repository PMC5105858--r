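---
title: "Simulation-based inference for bulk segregant analysis: models and methods"
author: "sibsam package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation-based inference for bulk segregant analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The mapping designs and their statistics

`sibsam` simulates and analyses two classical QTL-mapping designs for
organisms, such as *Drosophila*, where hundreds to thousands (but not
millions) of offspring can be bred.

In **bulk segregant analysis (BSA)**, the F1 offspring of reciprocal
crosses between a high- and a low-phenotype parental strain interbreed
freely for `G` generations. Only the final generation is phenotyped; the
top and bottom `q` tails are pooled and sequenced. For every genomic
window the statistic is the **ancestry difference**

$$a_d = \hat p_{\text{high}} - \hat p_{\text{low}},$$

the difference between the pools in estimated ancestry fraction from the
high parental strain. Away from causative loci $a_d$ fluctuates around
zero; near a QTL it rises.

In **introgression mapping (IM)**, trait-selected individuals are
backcrossed to one parental strain in every second generation, so
neutral ancestry from the non-backcross parent dilutes geometrically
(at generation $G$ the neutral expectation is $0.5^{G/2}$) while
selected regions retain it. The statistic is the **ancestry proportion**
$a_p$ of the selected pool.

## The forward model

Individuals carry, per chromosome copy, a list of ancestry tracts
delimited by recombination breakpoints in genetic (cM) coordinates.
Each female meiosis draws a Poisson number of crossovers with mean equal
to the chromosome's length in Morgans, at uniform positions; crossover
interference is not modelled. Males do not recombine and transmit a
random whole copy — a *Drosophila* convention that halves effective
recombination. One chromosome may be flagged as the X: males carry a
single maternal copy, daughters additionally receive the father's X.
Each offspring draws an independent random mother and father from the
previous generation, and sex 50/50; the census size `N` is constant.
These choices are deliberately minimal: no overlapping generations, no
assortative mating, no unintended laboratory selection.

Phenotypes are additive: each causative locus adds its per-allele effect
`f` times the number of high-strain alleles carried at its position
(0–2, or 0–1 for the hemizygous male X), plus Gaussian noise. Two noise
conventions are used:

* **inference stage** (`noise = "sibsam"`): SD fixed at 0.5, i.e. a
  `0.5 * N(0,1)` residual. Under this anchor a locus with `f = 1`
  corresponds to **strength** `s = 0.5`, and generally
  `s = f / (1 + f)` with inverse `f = s / (1 - s)`
  (`strength_to_effect()`). Strength is the model's working measure of
  the fraction of phenotypic variance attributed to a QTL; note that it
  is an operational scale anchored to the `f = 1` reference locus
  rather than a literal variance ratio.
* **design evaluation** (`noise = "exploratory"`): SD equal to the
  design-mean trait value (each locus contributes one high allele in
  expectation, so five `f = 1` loci give mean 5 and noise SD 5).

Pooled sequencing is modelled in two stages: the pool's true window
frequency is computed over all chromosome copies of its members at the
window midpoint, and the observed frequency is a Binomial(depth, p)
draw divided by depth. Both individual sampling and read sampling
therefore contribute noise, with the pool-size term dominating at
realistic depths.

## Windowed genome maps

All computation happens on user-defined windows with physical (bp) and
genetic (cM) coordinates, half-open `[start, end)` with the chromosome's
last window closed on the right. `make_synthetic_map()` generates
Drosophila-scale maps (X ≈ 73 cM, chromosome 2 ≈ 108 cM, chromosome 3 ≈
110 cM by default — configurable, not constants) with window cM widths
drawn as symmetric Dirichlet shares (concentration 3) to emulate the
heterogeneous per-window recombination of maps built from real
polymorphism data. What the generator does **not** emulate: windows
defined by fixed SNP counts from population data, empirical
recombination-map structure (centromeric suppression, hotspots),
interference, or depth variation between windows. Tests that pass on
synthetic maps therefore establish the correctness of the machinery and
the self-consistency of the inference, not the field realism of any
particular map.

## Peak identification

Profiles are smoothed by a triangular weighted average: the focal window
has weight `m + 1`, neighbours at distance `d` weight `m + 1 - d`, out
to the `m`-th window (default `m = 4`). Smoothing never crosses a
chromosome boundary; at chromosome edges the weights are renormalized
over the available windows (zero-padding was rejected because it biases
edge values toward zero). Empirical and simulated profiles always pass
through the identical smoothing path.

A **primary peak** is the maximum of a maximal run of windows with
smoothed $a_d > 0$, retained when it exceeds the height threshold
$a_{dt}$ (default 0.1). **Secondary peaks** are found by scanning
outward from the primary within its run: a recovery strictly beyond
$v_t$ (default 0.1) above the running minimum opens a peak, a drop
strictly beyond $v_t$ below its running maximum closes it; a peak still
open when the run ends is recorded. Each secondary's **deviation** `v`
is then assigned under a taller-first priority rule: the tallest
secondary on a side measures its `v` down to the lowest point between
itself and the primary (ignoring shorter peaks in between), while a
shorter secondary sandwiched between taller peaks takes its height minus
the higher of its two flanking valleys. This prevents a small
near-primary shoulder from out-ranking a taller peak beyond it.
Deterministic tie-breaks: argmax ties take the lowest window index.

## The three inference stages

**Null stage.** No-QTL replicates of the matched experiment (same map,
N, G, q, depth, phenotyped count) yield the null distribution of primary
peak heights above $a_{dt}$. For an observed peak of height `h` the
enrichment is
$e = \text{count}_{\text{obs}}(\ge h) \,/\, \overline{\text{count}}_{\text{null}}(\ge h)$
using per-genome-scan counts, and the significance estimate is
$P = 1/e$ when $e > 1$ (else 1); peaks with `P < 0.05` advance. When no
null peak reaches `h`, the finite-replicate floor
`1/(n_reps * count_obs)` is reported and flagged rather than `P = 0`.

**Single-QTL stage.** For each significant primary, QTL are simulated at
the empirical peak window with strength drawn from a Uniform(0, 1)
prior. One population is simulated per replicate and reused across peak
positions (phenotyping, selection and read sampling are redone per
position) — a large saving at no cost, since positions only affect the
genotype lookup. Each record stores the maximum smoothed $a_d$, its
window, and the maximum adjusted secondary deviation. Rejection
sampling keeps records whose maximum is within a tolerance (default
0.025) of the observed height; accepted strengths give the posterior
median and 0.05/0.95 interval, and accepted peak-location offsets —
re-centred on the empirical peak — give the genomic confidence interval.
This relies on a transitivity assumption: simulated distances from a
true QTL to its observed maximum stand in for empirical distances from
the observed maximum back to the unknown QTL. Secondary-peak P-values
are the fraction of *accepted* records whose maximum deviation exceeds
the observed `v`; conditioning on height-matched records removes the
unknown primary strength as a nuisance parameter.

**Cluster stage.** A primary with significant secondaries defines a
linked cluster. All members are simulated jointly at their empirical
windows; per replicate a cluster strength is drawn uniformly and
apportioned by a symmetric Dirichlet(1, …, 1) draw (uniform on the
simplex — the maximally uninformative split), each member's effect
being `f = s/(1-s)` of its share. Every member owns an analysis zone
bounded by the empirical valleys between member peaks and by the
chromosome ends outside; a replicate is accepted only when every zone's
local maximum matches its empirical height within the (wider, default
0.05) tolerance. Member posteriors from accepted replicates replace the
single-QTL estimates, correcting for linked peaks inflating each other.
Cluster genomic intervals are not clipped to the member's zone.

**Numerical policies.** Acceptance starvation (fewer than `min_accept`,
default 200, accepted replicates) doubles the tolerance once with a
warning; zero acceptances flag the peak with undefined intervals.
Quantiles use R's default linear interpolation. All stages consume the
single R RNG stream, so one `set.seed()` reproduces a whole analysis
bit-for-bit.

## Design evaluation

`run_scenario()` reproduces the exploratory design study: equal-effect
QTL placed uniformly per chromosome arm at relative positions
`(2i-1)/(2n)` with analysis zones `[(i-1)/n, i/n]`, exploratory noise,
and per-QTL scoring by the cM distance between the zone's statistic
maximum and the true position (plus a 0.5 cM "hit" rate). The package's
tests reproduce the qualitative design findings: BSA localizes better
than IM under a shared design, and more generations improve
localization. Note that under the exploratory noise recipe the genetic
variance share is an emergent property of the locus count and effects,
not a dial; five unit-effect loci give a heritability near 9%, which is
what makes the exploratory signals modest.

## Problem sizes and calibration behaviour

The shipped tests and the acceptance script run at desk scale: 400
windows per chromosome, null distributions of 300–1000 replicates,
prior pools of 2000–2500 replicates, and 100–500 test replicates per
scenario — sizes at which the full suite completes in minutes on one
CPU. Smoothed peak statistics were checked to be insensitive to window
count between 400 and 4700 windows per chromosome, because pool-sampling
noise (not window-level read noise) dominates smoothed peak heights.

Two calibration behaviours of the method itself are worth knowing.
First, the significance procedure is self-calibrating — both the
observed scan and the null replicates pass through one code path — so
its false-positive rate is near the nominal level by construction, and
the package's null-calibration test verifies this directly. Second, the
fixed peak-calling floor $a_{dt} = 0.1$ becomes the binding constraint
in very large experiments: when population size, phenotyped count and
depth are all scaled up ~16-fold, sampling noise shrinks until weak-QTL
peaks (s ≈ 0.05) frequently fall below the floor itself, truncating
power even though such peaks would be highly significant against the
matched null. Lowering $a_{dt}$ (and $v_t$) proportionally to the
experiment's noise scale is the appropriate response for such designs.

## Known limitations

* Crossover interference, epistasis, dominance beyond codominance, and
  laboratory-selection ancestry shifts are out of scope of the forward
  model.
* Strength estimates are rough: the suite reproduces a winner's-curse
  overestimate for weak QTL (only lucky-tall peaks get detected), an
  upward bias when the residual phenotypic variance comes from other
  strong unlinked QTL rather than Gaussian noise, and saturation of the
  $a_d$ statistic for very strong QTL.
* Genomic confidence intervals inherit the transitivity assumption of
  the rejection step; with strongly asymmetric local recombination the
  simulated-offset distribution can misrepresent the empirical one.
* The uniform strength prior and the Dirichlet apportioning are
  uninformative conventions; informative priors would need only a
  change to the draw in `single_qtl_stage()`/`cluster_stage()`.
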