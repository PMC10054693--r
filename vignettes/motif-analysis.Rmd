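---
title: "Comparing RNA structure ensembles by motif counts and abstract shapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing RNA structure ensembles by motif counts and abstract shapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

The RNA sequence-to-secondary-structure map is strongly *biased*: a small
fraction of possible structures absorbs most of sequence space, so uniform
random sampling of sequences ("G-sampling") concentrates on a few
high-probability phenotypes. A recurring observation in the
genotype–phenotype-map literature is that the structures of natural
non-coding RNA look remarkably like the structures of random sequences of
the same length — evidence that map bias, not only selection, shapes the
repertoire of natural RNA. At the same time, small systematic differences
between natural and random structures remain, and those differences are
informative: simple per-structure motif counts support machine-learning
classification of natural versus random RNA.

`rnamotifs` implements this analysis pipeline end to end:

1. parse dot-bracket structures into a loop-decomposition tree and count
   the five classical motifs — bonds, helices, hairpin loops, bulges and
   junctions;
2. coarse-grain structures to abstract shapes (level 5) and compare shape
   frequency spectra across ensembles;
3. fit linear length trends `count = a·L + b` per motif per ensemble, with
   bootstrap confidence intervals;
4. classify ensembles from the five motif counts with cross-validated kNN
   and PLS-DA.

## Structures, trees and motif definitions

A dot-bracket string is parsed into a pair table and decomposed into the
unique tree of faces: maximal helices (runs of stacked pairs), and the loop
face each helix's innermost pair closes. The motif definitions used
everywhere are:

* **bond** — one base pair;
* **helix** — a maximal run of stacked pairs (i,j), (i+1,j−1), …;
* **loop** — a hairpin loop (a face enclosing no helix);
* **bulge** — a face with exactly one enclosed helix and unpaired bases on
  exactly one side;
* **junction** — a multiloop, a face enclosing two or more helices.

Two-sided single-helix faces are *internal loops*. They are counted
separately (column `internals`) and belong to none of the five features:
with this assignment the tree identity `helices = loops + bulges +
junctions + internals` holds exactly (every helix closes exactly one
loop-type face), and the five-feature rates are mutually consistent — the
helix-count growth rate is, as it must be, the sum of the growth rates of
the face types that terminate helices. Treating internal loops as a sixth
hidden category (rather than folding them into "loops" or "bulges") is the
only assignment consistent with the observed slope ordering (helices ≈
0.073 per nt versus loops + bulges + junctions ≈ 0.04 per nt on random
sequences; the residual is the internal-loop rate). A sensitivity switch is
unnecessary at the API level because `internals` is always reported
alongside the five features.

The exterior region contributes to no motif count: its helices are already
counted, and the near-zero intercepts of the fitted length trends support
excluding it as a loop type. Pair tables are 1-based throughout (the
natural indexing in R). The parser accepts any balanced string — minimum
hairpin sizes are a property of folding engines, not of the
representation — so unusual natural inputs survive ingestion.

`motif_counts_scan()` recomputes all counts by direct pair-table scanning
without building a tree; the two independent routes are checked against
each other over the exhaustive enumeration of all valid structures up to
length 14 (`enumerate_structures()`, itself validated against brute-force
filtering of all strings at small lengths).

## Abstract shapes

Level-5 shapes are computed operationally from the tree: every maximal
chain of helices connected only through bulges or internal loops collapses
to a single `[` `]` pair; a chain ending in a hairpin renders `[]`; a chain
ending in a multiloop wraps the concatenation of its branch shapes; the
exterior concatenates its branches; a pair-free structure renders the
sentinel `"_"` (distinct from the empty string so frequency tables stay
well-defined). This operational rule needs no external RNAshapes binary and
reproduces the published level-5 literals (e.g. `[][]` for two exterior
hairpins). Levels 1–4 are provided for illustrating the abstraction ladder
and are implemented best-effort; level 5 is the normative, fully tested
path. Two invariants pin the semantics down: the number of `[` in a level-5
shape equals hairpins + junctions, and shapes compose over exterior-level
concatenation.

The analytic size of the level-5 shape space, `2.44 · 1.32^L · L^(−3/2)`
(minimum hairpin 3, minimal ladder length), is exposed as
`shape_space_size()`. Note the asymptotic form is non-monotone below L ≈ 6,
where it has no practical meaning anyway; the package tests monotonicity
from L = 6 up.

## Folding engines

The `vienna` engine adapts the `RNAfold` program (MFE structure, package
defaults: 37 °C, default dangles, no constraints — no parameter deviations
are warranted) and records the program version with every run for
provenance. The built-in `nussinov` engine maximises the number of
Watson–Crick + GU-wobble pairs under a minimum hairpin size of 3, with a
fully deterministic traceback (prefer leaving the leftmost base unpaired;
among optimal pairings choose the smallest partner). The Nussinov engine is
a combinatorial baseline, not an energy model: it exists so that unit tests
and the synthetic benchmark are fast and dependency-free, and its bond
counts are verified against an independent exhaustive search at small
lengths. All headline analyses use the vienna engine.

## Random sequences, scrambling, ingestion

`random_sequences()` draws i.i.d. residues from a `composition_spec()`
(explicit A/C/G/U probabilities or a GC fraction split evenly within pair
classes). `scramble_sequences()` permutes each sequence uniformly,
preserving its exact residue multiset — the standard GC-content control
when comparing natural against random sequences, since natural RNA is
composition-biased. FASTA ingestion normalises `T`→`U`, skips records with
ambiguity codes (random resolution would perturb folding), and filters to
exact length strata by default (`tol = 0`; the analyses are stratified by
fixed length). Deduplication is off by default — public databases contain
duplicates, and removing them is an analysis choice, exposed as a flag.

Every stochastic stage takes a seed; pipeline stages derive named
substreams from the single run seed (`substream_seed`), so a full run is
reproducible from one integer.

## The synthetic pseudo-natural generator

Desk-scale testing needs a stand-in for a natural database. The generator
(`pseudo_natural_spec()` / `generate_pseudo_natural()`) emulates the two
statistical signatures the analysis relies on, with tunable strength:

* **composition heterogeneity** — each pseudo-natural sequence draws its
  own GC fraction from `Beta(gc_alpha, gc_beta)`; the default `Beta(12,12)`
  (mean 0.5, s.d. ≈ 0.1) is a realistic spread of per-molecule GC content
  while keeping the class mean equal to the random class;
* **motif-count shifts** — for each pseudo-natural slot,
  `candidates_per_accept` candidate sequences are folded and the candidate
  whose motif-count vector has the largest inner product with the effect
  vector δ is kept (*selection by resampling*). Selection acts on fold
  outcomes, the way natural selection acts on phenotypes, so kept sequences
  remain ordinary foldable sequences. The default δ (fewer bulges, more
  hairpin loops, slightly fewer bonds) points in the direction of the
  natural-versus-random contrasts seen in real data; its magnitude is a
  configuration knob, not an empirical claim.

With δ = 0 and a symmetric, concentrated GC law the two classes are
exchangeable by construction, which gives a sharp null: any downstream
classifier must land inside the permutation null band around AUC 0.5. With
growing ‖δ‖ the classes separate monotonically. These two properties — the
null and the monotone parameter recovery — are what passing tests certify.
What the generator does *not* emulate: phylogenetic relatedness and family
structure among natural sequences, length heterogeneity within a stratum,
and real databases' annotation biases. Results on synthetic data therefore
validate the machinery, not the biological effect sizes.

## Trend fits and bootstrap

`motif_trend_fit()` fits ordinary least squares of per-structure count on
length, one fit per motif per ensemble — per-structure points, not
per-length means, so that bootstrap resampling over points is meaningful.
Confidence intervals are nonparametric bootstrap percentile intervals
(B = 1000 by default) over points; a resample that collapses to a single
length stratum is redrawn. On noiseless collinear points the intervals
collapse to zero width; on Gaussian noise their width agrees with the
analytic OLS standard-error band within a factor of two (both tested).

The default length grid {50, 100, 200, 300, 400, 600, 800, 1000, 1500,
2000, 2500, 3000} spans the 50–3000 nt range of interest with affordable
cost at the large-L end. The package's own reference runs use 25 sequences
per length (300 structures, 1500 motif points) — enough for slope standard
errors well under the 15% bands used in the checks, since the fits are
dominated by the wide length leverage.

## Classification

Features are exactly the five motif counts per structure; labels are
binary. Both classifiers run under stratified five-fold cross-validation
with a single CV repetition, all folds derived deterministically from the
seed. Features are z-scored with training-fold statistics only — bond
counts dwarf junction counts, and both kNN distances and PLS weights are
scale-sensitive.

* **kNN** (`knn_cv`, default k = 5 — conventional, exposed as a setting):
  a held-out record's score is the fraction of its k nearest training
  neighbours (Euclidean distance) labelled 1.
* **PLS-DA** (`plsda_cv`, default 2 components of 5): labels encoded ±1, a
  PLS regression fitted per training fold; held-out records scored by the
  continuous prediction. Signed variable importances are the fold-averaged
  regression coefficients on standardized features; unsigned VIP scores are
  reported alongside, since both conventions are in circulation.

ROC AUC is computed in the rank (Mann–Whitney) form with the
half-credit-per-tie convention, verified against exhaustive pair counting;
its 95% interval is a percentile bootstrap over the pooled out-of-fold
(score, label) pairs, with single-class resamples redrawn. On data with a
genuine linear contrast the flexible kNN typically edges out the linear
PLS-DA by a small margin, the ordering seen in published comparisons of the
two on this problem.

## Shape statistics

Shape frequency tables carry counts, probabilities and ranks (ties broken
lexicographically, so tables are byte-stable). The cross-ensemble
correlation of log10 shape probabilities is computed over the shapes shared
by both tables — shapes absent from one ensemble have no defined log
frequency; an add-one pseudocount option over the union is available but
off by default. p-values use the standard t transform of Pearson r with no
multiple-testing correction (a handful of length strata at most).
`coverage_fraction()` reports the fraction of one ensemble's unique shapes
recovered by another.

## Worked example

```{r, eval = FALSE}
library(rnamotifs)

eng <- folding_engine("nussinov")    # swap for folding_engine("vienna")

# motif trends on random sequences
pts  <- build_length_grid_dataset(eng, c(50, 100, 200, 400), 25, seed = 1)
fits <- motif_trend_fit(pts, B = 1000, seed = 1)
tidy(fits)
autoplot(fits)

# pseudo-natural vs random classification
d  <- generate_pseudo_natural(pseudo_natural_spec(L = 100, n = 200), eng, seed = 1)
f  <- make_feature_dataset(d)
kn <- knn_cv(f[1:5], f$label, seed = 1)
pl <- plsda_cv(f[1:5], f$label, seed = 1)
glance(kn); glance(pl)
tidy(pl)                              # signed importances + VIP
```

## Numerical choices and degenerate inputs

* Trend fits require ≥ 3 points over ≥ 2 distinct lengths; an all-one-length
  design raises a degenerate-design error rather than returning `NA`s.
* Frequency-table ranks: descending probability, lexicographic tie-break.
* Bootstrap: percentile method, 2.5/97.5, B ≥ 100 enforced.
* Zero-variance features are given unit scale during z-scoring rather than
  producing `NaN` distances.
* The empty structure and pair-free structures are valid everywhere
  (`"_"` shape, all-zero motif counts); the empty *string* is rejected at
  parse time.

## Problem sizes used in the packaged checks

The packaged test suite runs the shape-sampling analysis at its full
30,000-sequence size for L = 100 and the trend analysis at 15 sequences per
length over the full 50–3000 grid; the reference script
(`scripts/acceptance.R`) uses 25 per length. These sizes give sampling
noise comfortably inside the tolerance bands discussed above while keeping
a complete run in the minutes range on one core. Larger runs only tighten
the intervals.

## Known limitations

* Pseudoknots are out of scope end to end: the parser rejects crossing
  pairs and both engines predict nested structures only.
* One structure per sequence (the MFE or max-pairing optimum); Boltzmann
  suboptimal ensembles and co-transcriptional kinetics are ignored.
* Levels 1–4 of the shape abstraction are illustrative, not normative.
* The synthetic generator validates the pipeline's statistical machinery;
  classification accuracy on it says nothing quantitative about accuracy
  on curated natural databases, which require user-supplied FASTA input.
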