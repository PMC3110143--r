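---
title: "Scanning genome-scale sequences for probable miRNA coding regions"
author: "mircand"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning genome-scale sequences for probable miRNA coding regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

Mature microRNAs are ~22-nt RNAs excised from one arm of a stem-loop
(hairpin) precursor. Ab initio prediction from sequence alone therefore has
two coupled sub-problems: find hairpins that look like pri-miRNA substrates,
and decide *where on the hairpin* a Drosha/Dicer-processed mature could sit.
`mircand` treats the second problem as the primary classification task:
every possible mature placement inside a hairpin is enumerated (both arms,
all lengths in a configurable 18–26-nt range, 1-nt steps, at most 3 nt
protruding into the terminal loop), each placement is described by a catalog
of structural, compositional and thermodynamic parameters of its
(ppri-miRNA, pre-miRNA, miRNA) triple, and an RBF-kernel support vector
machine classifies the placement. Overlapping positive placements are then
consolidated into *most probable miRNA coding regions*, which is the level
of resolution at which this class of predictor is reliable: the exact
cleavage site is not claimed, the region hosting it is.

The geometric backbone is the five-component decomposition of a pri-miRNA
relative to a candidate mature: Basal Segment (unpaired residues below the
outermost retained pair), Lower Stem (duplex between basal segment and the
mature), Upper Stem (duplex spanned by the mature and its partner region),
Top Stem (duplex between the mature and the loop) and Terminal Loop. Not
every component exists for every placement — a mature flush against the
loop has no top stem — but upper stem and terminal loop always do. Absent
components take an undefined-feature marker (`NA`), which the SVM scaler
maps to the dedicated component-absent value −1.

## Coordinates

All internal coordinates are 1-based closed intervals, the R and
Bioconductor (IRanges) convention; user-facing output (GFF3, TSV) is 1-based
inclusive as well. Every string and vector primitive in R is 1-based, so
carrying a 0-based half-open convention internally would manufacture
off-by-one opportunities rather than remove them.

# Folding

Secondary structures are minimum-free-energy nested structures produced by a
pluggable backend. Two backends ship:

* `rnafold` (default): the external ViennaRNA `RNAfold` executable, called
  in batch. Default temperature and ionic parameters are used.
* `inprocess`: a self-contained simplified nearest-neighbour thermodynamic
  folder (Zuker-style dynamic programme with stacking energies,
  hairpin/bulge/internal-loop size penalties and an affine multiloop cost),
  compiled with the package. Its energies are deliberately simplified; it
  exists so the package runs with no external dependency and so tests have
  a second, independent folding path.

Feature values depend on the folder, so every trained model bundle pins its
backend id and prediction refuses nothing silently: the same sequence,
backend and version always give the same dot-bracket. Structures are
validated as involutions (partner-of-partner identity) and are pseudoknot
free by construction of the dot-bracket representation.

Hairpins are extracted from a pair table by walking outward from each
terminal loop through stacks, bulges and internal loops, stopping at
multibranch loops ("budding stems") or the exterior. The stem cap — at most
60 *pair levels*, trimming from the base — reflects the instability of
deep basal pairing; "stem length" is read as duplex depth, not nucleotide
count, since a bulged stem of 60 nt per strand would otherwise be capped
asymmetrically. Internal loops and bulges within arms are tolerated; only
multibranching disqualifies a region.

# The parameter catalog

`default_catalog()` reconstructs a 68-parameter catalog in five categories:
Descriptive (identifier, sequence and structure strings), Size (lengths and
paired-base counts of the mature, pre-miRNA, ppri-miRNA and the five
components), Stability (pre-miRNA and ppri-miRNA folding energies, kcal/mol),
Sequence (A/C/G/U/GC contents and the mature's first base, one-hot encoded
for SVM use) and Structure (unpaired counts and rates, G·U wobbles,
internal-loop statistics per duplex scope, and the 3' overhang at the
pre-miRNA base, canonically 2 nt for a Drosha product). 53 parameters are
SVM-eligible; descriptive, categorical and ppri-miRNA-scoped parameters are
not — decoys share their positive's ppri-miRNA, so ppri-scoped values
cannot discriminate. The catalog is configuration-driven (YAML) so that an
alternative reconstruction is a drop-in replacement.

Conventions chosen where the defining material is ambiguous, applied
uniformly:

* Two-sided component *lengths* are the length of the strand on the
  mature's side of the duplex (a mature-length-like 20–27 nt for the upper
  stem), the basal segment reports both flanks summed, and the loop its own
  length.
* Internal loops are maximal runs of unpaired positions within the
  feature's strand interval(s); the terminal loop is excluded (for pre/ppri
  scopes the interval is split at the loop), so an apical loop never counts
  as an internal loop.
* Mature-scope unpaired statistics count the mature's own strand only
  ("proportion of unpaired bases in a feature" is read per feature, not per
  duplex).
* The pre-miRNA MFE is obtained by refolding the pre-miRNA subsequence with
  the pinned backend (batched and cached per unique interval).

# Corpus construction

Training corpora follow the standard recipe for this family of tools:
experimentally supported precursor records (miRBase-style: precursor
sequence + mature coordinates + taxonomy group) are refolded with the
pinned backend and filtered — records whose mature is not coverable by a
single stem-loop, or overlaps the terminal loop by more than 3 nt, are
excluded. Negatives are *random-start* decoys: the identical ppri-miRNA
with the putative mature start shifted by at least 5 nt on the same arm,
same length, drawn uniformly without replacement. Because positive and
negative share the precursor byte-for-byte, the classifier is forced to
learn placement geometry, not precursor identity. Level-k datasets pair
each positive with k decoys (k = 1..20); level 1 is the default for
prediction.

The 3-nt loop-overlap tolerance reads "mature located in the terminal
loop" as majority-in-loop: real matures occasionally abut the loop, and a
hard zero would discard them. A precursor with both 5p and 3p matures
contributes one training row per mature.

# Training

* **Range filter.** Per-parameter closed windows between the 0.1% and
  99.9% empirical quantiles of the positive examples (linear interpolation
  between order statistics, `quantile(type = 7)`), with one override: the
  ppri-miRNA MFE must be below −20 kcal/mol, which removes unstable
  structures decisively. Windows cover the SVM-eligible parameters —
  ppri-scoped parameters other than the MFE override measure how much
  flanking sequence a record happens to carry, not the candidate, and are
  excluded from both filtering and classification. Undefined markers
  always pass: absence is legal.
* **Scaling.** Min–max to [−1, 1] from training data (standard for RBF
  SVMs); markers map to −1; prediction-time values are clipped after
  scaling (the range filter already rejects gross outliers).
* **SVM.** libsvm (via e1071), RBF kernel, grid search over
  C ∈ 2^(−5,−3,…,15), γ ∈ 2^(−15,−13,…,3) by stratified k-fold
  cross-validated accuracy, ties to the smaller C then γ; refit on the
  full dataset at the optimum. No class weights — the level mechanism is
  the imbalance treatment. Bundles are serialized as lossless JSON
  (support vectors, coefficients, ρ, γ, scaler, range filter, backend id),
  and the decision function is computed in-package from the stored support
  vectors, so a bundle file is a complete, portable classifier.
* **Greedy chain selection.** Single parameters are scored by mean
  cross-validated accuracy over three positive/negative dataset pairings;
  the best 10 seed a beam search that extends chains one parameter at a
  time, keeping the 10 best per length until the pool is exhausted. The
  accuracy-versus-length curve is reported, never assumed monotone (it
  characteristically declines past ~30 parameters). Chains that contain
  the same parameter set in different orders receive identical scores, so
  duplicates are collapsed to keep beam slots diverse; ties at the beam
  boundary break lexicographically, making the search deterministic.
  During the search the SVM runs at fixed C = 1 and the libsvm default γ
  with few folds — the search compares parameter sets, and the final model
  is re-grid-searched afterwards.

# Prediction pipeline

Long queries are cut into 500-nt windows overlapping by 200 nt (precursor
fragments are almost always shorter than 200 nt, so every hairpin appears
intact in at least one window). Each window is folded; discovered
stem-loops are *refined to a fixed point* by refolding the span ±20 nt cut
from the parent sequence and re-extracting, so two windows that saw the
same hairpin converge to one canonical anchor regardless of where their
boundaries fell. Candidates are enumerated on the refined hairpin; each
candidate's features are computed in a ppri context window anchored on its
own pre-miRNA interval ±40 nt — the amount of flanking sequence a typical
precursor record carries — which makes prediction-time feature
distributions comparable with record-based training corpora and makes the
output provably independent of window placement (the pipeline's
shift-invariance is asserted by test). Duplicate placements keep the higher
score; verdicts require both a range-filter pass and a positive decision
value; positive placements merge into coding regions by single-linkage
interval union per arm. Forward strand by default; `both_strands` folds
the reverse complement and reports strand.

Matching for evaluation tolerates up to 3 nt missing from either end of
the true mature; ROC curves sweep the SVM decision threshold over
range-passing candidates, with unmatched truths counted as false negatives
at every threshold.

# The synthetic data generator

`hairpin_recipe()` emulates miRBase-style precursor records: a GC-biased 5'
arm (35–50 nt), a reverse-complement 3' arm with ~10% mismatches and ~3%
1-nt bulges, a 4–12-nt loop, 10–30-nt unstructured flanks per side, and a
20–24-nt mature planted 0–4 nt from the loop on either arm, favouring a 5'
U half of the time — the geometry of a Drosha substrate. Records are
verified to refold into a single mature-hosting stem-loop (regenerating on
failure within a bounded retry budget). Genomes plant such records at
non-overlapping uniform positions in background sampled from an order-2
Markov model fitted to the shuffled record composition, which keeps local
composition realistic while suppressing accidental strong hairpins so the
false-positive baseline stays measurable.

What the generator does *not* emulate: the heterogeneity of real clades
(every record comes from one recipe), conservation signal, G/C asymmetries
of real arms, multi-loop pri-miRNA clusters, and genomic repeat structure.
Passing tests on this corpus therefore demonstrate that the machinery —
features, decoys, filter, SVM, windowing, consolidation — behaves as
specified, not that real-genome accuracy matches any particular figure;
real corpora are substantially harder and more diverse.

# Problem sizes and numerical choices

The documented synthetic study conditions are: 200 positive records at
level 1 (400 examples) for cross-validation and the permutation null (20
label permutations); 1,000 random triples for feature-oracle equivalence;
1,000 random folded sequences for structural invariants; 10 seeded runs of
the selection search on 40-parameter pools with 3 planted signals (beam 10,
chains to length 6, 2-fold scoring, 3 pairings of 80 examples per class);
and a 10-kb genome with 5 planted precursors for the end-to-end scan.
These sizes give stable statistics while keeping a full run desk-fast.

Degenerate inputs are handled explicitly: homopolymers fold to zero pairs
and yield no hairpins; candidates with no paired base cannot be segmented
and are not enumerated; constant parameters produce collapsed (but legal)
range windows and scale to 0; empty truth sets make sensitivity undefined
and are reported as such rather than as 0.

# Known limitations

* The in-process folder's simplified energy model is not
  ViennaRNA-equivalent; bundles trained under one backend must not be
  applied under the other (the bundle refuses by construction, since the
  backend id is pinned).
* Range windows estimated from small corpora are tight by construction
  (the 0.1%/99.9% window of n samples approaches the sample extremes), so
  small-corpus bundles filter aggressively; a production corpus should
  supply hundreds to thousands of positives.
* Candidate-level ROC treats every enumerated placement as a unit, so AUC
  values are not comparable across tools that score per-sequence.
* Only single stem-loops are modelled; matures processed from multibranch
  precursors are outside scope.
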