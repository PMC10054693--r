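# rnamotifs

Structural motif and abstract shape analysis of RNA secondary structures.

Non-coding RNA structure is shaped not only by selection but by the strong
bias of the sequence-to-structure map: uniformly random sequences fold into
a small set of high-probability structures, and natural RNA turns out to
use largely the same repertoire. `rnamotifs` is a toolkit for making this
comparison quantitative — and for exploiting the small residual differences
to tell natural-like from random RNA. It is aimed at researchers in RNA
bioinformatics and genotype–phenotype-map evolution who want a tested,
scriptable pipeline rather than one-off analysis code.

The package

- parses dot-bracket structures into their loop-decomposition tree and
  counts the five classical motifs per structure: **bonds** (base pairs),
  **helices** (maximal stacks), **loops** (hairpin loops), **bulges**
  (one-sided interior faces) and **junctions** (multiloops), plus the
  auxiliary internal-loop count — the tree identity
  `helices = loops + bulges + junctions + internals` holds exactly;
- coarse-grains structures to RNAshapes-style abstract shapes; level 5
  (helix nesting/adjacency only, e.g. `[][]`, `[[][]]`) is fully
  specified and tested, with the analytic level-5 shape-space size
  `s5(L) ≈ 2.44 · 1.32^L · L^(−3/2)`;
- folds sequences through a ViennaRNA (`RNAfold`) adapter or a built-in
  deterministic Nussinov baseline;
- builds shape frequency tables (count, probability, rank), coverage
  fractions between ensembles, and the Pearson correlation of log10 shape
  probabilities across ensembles;
- fits per-motif linear length trends `count = a·L + b` by OLS over
  per-structure points with percentile-bootstrap 95% intervals;
- classifies two ensembles from the five motif counts with stratified
  five-fold cross-validated kNN and PLS-DA, reporting Mann–Whitney ROC
  AUC with bootstrap intervals and signed variable importances;
- generates labelled synthetic "pseudo-natural vs random" benchmarks
  (per-sequence GC heterogeneity + selection-by-resampling motif shifts)
  so the full pipeline is testable without downloading a database.

All user-facing functions take data frames first and return tibbles, so
pipelines compose with the pipe; fitted objects support `tidy()`,
`glance()` and `autoplot()`.

## Worked example

```r
library(rnamotifs)

eng  <- folding_engine("nussinov")   # fast baseline; use "vienna" for MFE analyses

# Per-motif linear length trends on random sequences
pts  <- build_length_grid_dataset(eng, c(50, 100, 200, 400), 25, seed = 1)
fits <- motif_trend_fit(pts, B = 1000, seed = 1)
tidy(fits)
#> # A tibble: 5 × 9
#>   motif     ensemble  slope intercept n_points slope_lo slope_hi ...
#> 1 bonds     random   0.392     -2.76       100   0.388    0.394
#> 2 bulges    random   0.0952    -0.123      100   0.0896   0.101
#> 3 helices   random   0.152      0.948      100   0.148    0.157
#> 4 junctions random   0.0256    -0.263      100   0.0233   0.0279
#> 5 loops     random   0.0264     1.22       100   0.0244   0.0284
```

Each row is one motif's growth rate with length: Nussinov pair-maximising
folds add ~0.39 bonds and ~0.15 helices per extra nucleotide, with tight
bootstrap intervals. (MFE folds via the vienna engine give the flatter
rates characteristic of thermodynamic structures: ≈ 0.32 bonds/nt,
0.073 helices/nt.)

```r
# Synthetic pseudo-natural vs random benchmark, then classification
d  <- generate_pseudo_natural(pseudo_natural_spec(L = 100, n = 200), eng, seed = 1)
f  <- make_feature_dataset(d)
glance(knn_cv(f[1:5], f$label, seed = 1))
#>   method   auc ci_lo ci_hi     n n_folds
#> 1 knn    0.670 0.619 0.721   400       5
pl <- plsda_cv(f[1:5], f$label, seed = 1)
glance(pl)
#>   method   auc ci_lo ci_hi     n n_folds
#> 1 plsda  0.728 0.678 0.777   400       5
tidy(pl)
#>   feature   importance   vip
#> 1 bulges       -0.220  1.47
#> 2 loops         0.139  1.12
#> 3 junctions     0.0731 1.02
#> 4 helices      -0.117  0.697
#> 5 bonds        -0.0176 0.266
```

The generator injected "fewer bulges, more loops" into the pseudo-natural
class; both classifiers detect it (AUC ≈ 0.7 against a 0.5 null), and the
signed PLS-DA importances recover the direction: negative on bulges,
positive on loops.

End-to-end studies (`run_shape_study()`, `run_trend_study()`,
`run_classification_study()`) run from a single `run_config()` or YAML
file and write TSV/JSON artifacts with a provenance sidecar; a thin CLI
wrapper lives at `inst/cli/rnamotifs.R`.

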