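---
title: "Measuring genetic-code optimality by simulated evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring genetic-code optimality by simulated evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CodeOptimality)
```

## The question

The canonical genetic code is not a random mapping of 64 codons onto 20
amino acids and 3 stop signals: codons that differ by a single base tend to
encode amino acids with similar physicochemical properties, so point
mutations and mistranslations tend to cause small phenotypic changes.  Two
schools quantify *how* optimized the code is.  The **statistical approach**
asks what fraction of randomly generated alternative codes outperform the
canonical one; the **engineering approach** asks how far the canonical code
sits from the best achievable code, summarized by the *percentage distance
minimization* (p.d.m.).  This package implements both measures and uses a
genetic algorithm (GA) as the search engine that supplies the "best
achievable" anchor — the difficulty the GA has in beating the canonical code
is itself informative about the code's adaptation.

## The error model

A code's quality is the mean-square (MS) change in an amino-acid property
over *all* single-base substitutions in *all* codons:

$$\Delta^2 \;=\; \frac{\sum_{ij} N_{ij}\,(X_i - X_j)^2}{\sum_{ij} N_{ij}}$$

where $X_i$ is the property value of amino acid $i$ and $N_{ij}$ counts the
single-base codon changes turning amino acid $i$ into $j$.  Substitutions
from or to stop codons are ignored; synonymous substitutions are included
(zero numerator contribution, counted in the denominator).  The property is
Woese's **polar requirement**, a hydrophobicity-related scale derived from
partitioning amino acids in a water/pyrimidine system.  The package embeds
the classical values (`polarRequirement()`); under them the canonical code
scores

```{r}
ms(canonicalCode())
```

the 5.19 of the load-minimization literature.  Events are enumerated as
*ordered* pairs: with canonical stop codons that is 61 × 9 − 23 = 526
events.  Because $(X_i - X_j)^2$ is symmetric, counting both directions
doubles numerator and denominator and leaves $\Delta^2$ unchanged; we keep
the ordered convention so the 526-event count is directly reproducible from
`substitutionEvents()`.  The reported statistic is $\Delta^2$ itself, not
its square root — that is the convention under which the canonical value
5.19 is quoted.

The **tMS** variant weights each substitution by codon position and by
transition/transversion class, using the empirical mistranslation
quantification (transitions 1, 0.5, 1; transversions 0.5, 0.1, 1 for
positions 1–3; `mistranslationWeights()`), and takes the *weighted* mean.
With unit weights tMS collapses to MS exactly, which the test suite asserts.

## Two models of hypothetical codes

**Model 1 (restrictive codes).** The 64 codons are partitioned into the 21
canonical sets — for each amino acid, all codons encoding it in the standard
code, plus the stop set — and an alternative code is a bijection of the 20
amino acids onto the 20 sense sets, stops fixed.  The space has
$20! \approx 2.43\times10^{18}$ members (`codeSpaceSize(1)`).  The GA varies
these codes with a **swap operator** that exchanges the amino acids of two
randomly chosen blocks.

**Model 2 (codon-reassignment codes).** Known natural code variants do not
swap blocks; they reassign *single codons* to the amino acid of a one-base
neighbor.  Here an individual is the full 61-long assignment of sense codons
to amino acids (stops fixed), varied by a **reassignment operator**: pick a
random sense codon, copy its amino acid onto a random one-base sense
neighbor.  If the amino acid about to be overwritten is the sole instance in
the code, the operator is not applied — this guard keeps all 20 amino acids
present.  Model 2's space contains every model-1 code, so its optima can
only be better.

Random initial codes: model 1 draws a uniform permutation; model 2 draws the
61 sense assignments i.i.d. uniformly over the 20 amino acids, conditioned
on all 20 being present (rejection sampling).  The uniform-conditional
initialization is our choice of the maximally agnostic distribution over the
model-2 space; nothing beyond "three codons are reserved for stop" and
"random initial populations" constrains it.  Stop codons sit at the
canonical positions in both models (the `stopCodons` argument of
`randomReassignmentCode()` generalizes this for exploration); keeping them
canonical mirrors the treatment of model 1, where the stop set is explicitly
invariant.

## The genetic algorithm

`evolveCodes()` runs, per replicate: a random initial population (default
1000 individuals), then per generation (i) the single best individual is
copied unchanged into the next generation (elitism; ties broken to the first
individual attaining the minimum), and (ii) the remaining slots are filled
by **tournament selection** — the fittest of a window of individuals drawn
uniformly with replacement, window = 3% of the population (30 at default
size), ties to the lowest index — followed by exactly one application of the
model's operator (probability 1 by default; the operator-per-offspring
convention is the natural reading of "operators are applied to the selected
individuals").  Elitism makes the best-fitness trace non-increasing, which
is asserted for every run in the tests.

**Stopping.** Runs end at a generation cap (100 for model 1, 300 for
model 2, which needs a longer search) or earlier once the best fitness has
not improved for 25 consecutive generations.  Model-1 runs typically
plateau near generation 40–60 at the default population; model-2 runs near
80–120.  These caps are chosen so every run reaches its plateau rather than
being truncated.

**Reproducibility.** A base seed plus the replicate number deterministically
yields a per-replicate stream seed, so replicates are independent and
individually reproducible; identical configurations produce bit-identical
traces.

Performance note: fitness is evaluated for whole populations at once.  For
model 1 the 526 events aggregate into a quadratic form over block pairs
(computed once per run), and for model 2 the sense-pair list is fixed by the
stop layout, so a generation costs two matrix operations rather than 64 × 9
loops per individual.  The single-code `ms()`/`tms()` methods use the
general enumeration path and are cross-checked against an independent
brute-force oracle (and against each other through the GA) in the tests.

## Optimality measures

`sampleRandomCodes()` scores n random codes of either model;
`fractionBetter()` gives the statistical-approach probability (strictly
lower error counts as better; ties do not).  Among 10,000 random model-1
codes, on the order of a couple beat the canonical code's 5.19 — the classic
"only two in 10,000" observation; the tests accept 0–8, the central 99%
interval of a Poisson with mean 2.

`pdm(delta_mean, delta_code, delta_low)` computes
$100\,(\Delta_{mean}-\Delta_{code})/(\Delta_{mean}-\Delta_{low})$.
`optimalityAnalysis()` assembles one experimental arm end-to-end:
$\Delta_{mean}$ from 10,000 random codes of the arm's model (the model-2
arms use model-2 random codes — the per-model reading of the measure),
$\Delta_{code}$ from the canonical code, $\Delta_{low}$ as the minimum over
the GA replicates.  The p.d.m. is invariant under affine rescaling of the
three deltas (property-tested).

Typical values at the defaults: model 1/MS ≈ 71%, model 2/MS ≈ 69–72%,
model 1/tMS ≈ 81–84%, model 2/tMS ≈ 87–89% — the mistranslation weighting
consistently *raises* the canonical code's standing, and the tests assert
that ordering per model.  The model-2 MS arm is the most sensitive to how
deep the GA digs (its $\Delta_{low}$ keeps improving slowly for a long
time), so its p.d.m. moves by a few points with the stopping rule; we keep
the plateau rule fixed rather than running to exhaustion.

`fitnessHistogram()` bins a sample into equal-width bins spanning its range
(last bin right-closed) and locates the canonical code's bin — the vertical
marker of the classic histogram figures.  The default of 30 bins is purely
cosmetic.

`patternScores()` provides quantitative proxies for the two regularities of
well-adapted codes, which the literature inspects visually; the numeric
definitions are ours.  *Pattern I* (similarity along the first codon
position): mean within-group property variance when sense codons are grouped
by bases 2+3 (so base 1 varies within groups) minus the same with grouping
by bases 1+3; negative means the first position is the more forgiving one.
Groups need at least two sense codons to contribute a variance (sample
variance, n−1).  *Pattern II* (second-base pyrimidine/purine structure):
mean squared property difference between sense codons across the second-base
U,C vs A,G boundary minus the pooled within-set mean over unordered pairs;
positive means within-set similarity.  Both vanish identically under a
constant scale.  For the canonical code pattern1 < 0 and pattern2 > 0.

## What the experiments do and do not show

All inputs here are embedded constants plus seeds, so "synthetic data" means
the random codes themselves; they emulate the null models of the two
optimality measures, not biology.  In particular (i) the polar requirement
scale is a single linear property — error minimization with respect to it
does not capture amino-acid frequency, codon usage, or substitution-matrix
similarity, all of which are deliberately out of scope; (ii) model 2
liberalizes *which* codes exist but not *how often* reassignments occur in
nature; and (iii) the GA's best value is a lower bound on the true optimum,
so every p.d.m. reported here is an estimate whose $\Delta_{low}$ anchor is
approximate (a deeper search can only lower $\Delta_{low}$ and hence lower
the p.d.m. slightly).

## Numerical choices

Summation order in the fitness is fixed by the codon enumeration (first base
slowest, base order U, C, A, G), so results are stable to well below 1e-9
across runs.  Degenerate inputs fail loudly: codes without sense-sense
events, all-zero weight tables, and p.d.m. calls with
$\Delta_{mean} \le \Delta_{low}$ are rejected.  Serialization uses the
64-character amino-acid string in the declared codon order (the NCBI
"ncbieaa" convention); `parseCodeTable()` names the violated invariant on
bad input, and round-tripping is the identity for every valid code.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run the four experimental arms
at the default population of 1000 with 10 GA replicates per arm (the
original experiments used 50) and 10,000 random codes per arm; at these
sizes the mean best-of-run model-1 MS reproduces 3.506 to well within one
part in thirty and each arm completes in well under a minute.  Property
suites draw 1,000 codes per generator and 10,000 draws for the uniformity
chi-squares.
```
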