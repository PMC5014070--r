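---
title: "Compressive motif discovery and compressibility phenotyping of behavioural sequences"
author: "cgram"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compressive motif discovery and compressibility phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgram)
```

## The data model

`cgram` operates on discrete behavioural sequences: ordered integer labels
drawn from a fixed alphabet of states. The motivating representation is
worm locomotion, where every video frame's midline shape (49 tangent
angles) is assigned the label of its nearest posture template out of a
canonical set of 90, but nothing in the package is specific to worms —
any ethogram or discretized time series works.

Two preprocessing steps define the canonical input, the `WarpedSequence`:

* **Discretization** (`discretize()`): each frame is assigned the 1-based
  index of the template minimizing Euclidean distance. The choice of
  Euclidean distance is a design decision — it matches the k-means
  objective under which such template sets are usually learned — and exact
  ties go to the lowest template index so that the assignment is
  deterministic. Template learning itself is out of scope; `TemplateSet`
  accepts any matrix of descriptors.
* **Non-uniform time warping** (`collapseRepeats()`): runs of identical
  labels collapse to a single element that records the run's dwell
  duration (in frames, or multiplied by a frame interval). Behaviours
  executed at different speeds thereby map to the same label sequence
  while no temporal information is lost: expanding by the durations
  reproduces the raw stream exactly. A warped sequence therefore never
  contains two equal adjacent labels, which is enforced by the class
  validity method.

## The compression algorithm

The dictionary is built by an offline, greedy, iterated replacement. At
each iteration, every unique contiguous subsequence of the *current*
sequence with length $2 \le W \le W_{\max}$ and at least two occurrences
is a candidate. Its saving is

$$S = WN - (W + 1 + N),$$

where $N$ is the number of occurrences: replacement removes $WN$ symbols
from the sequence, but adds $W+1$ symbols to the dictionary and $N$ new
symbols to the sequence. The candidate maximizing $S$ is replaced by a
fresh symbol (numbered consecutively from `alphabetSize + 1`), the rule is
recorded, and the procedure recurses on the shortened sequence until no
candidate achieves $S \ge 1$. Because every accepted rule strictly reduces
total description length, termination is guaranteed; because bodies may
contain earlier rule symbols, the dictionary is hierarchical, and a fully
expanded rule is a *c-gram* — a compressive behavioural motif.

Three conventions that the procedure's description leaves open are fixed
as follows:

* **Occurrence counting is greedy, left-to-right and non-overlapping**
  (`countNonoverlapping()`): after a match at position $p$ the scan
  resumes at $p + W$. For a fixed pattern this maximizes the
  non-overlapping match count, and it makes the worked two-symbol
  example's arithmetic (7 symbols saved out of 19) come out exactly.
* **Ties are broken canonically**: among equally compressive candidates
  the one appearing first in the sorted list of unique subsequences wins,
  with "sorted" made concrete as ascending length, then lexicographic by
  integer labels. The order is total, so identical input and
  configuration always give identical output. Note that for tied
  candidates total savings are invariant to the choice; the canonical
  order is a determinism device, not a claim about optimality.
* **Counts are not re-estimated during an iteration**: $N$ is measured on
  the sequence as it exists at the start of the iteration, matching the
  offline whole-sequence formulation.

$W_{\max}$ (default 10) bounds the candidate length per iteration purely
for speed. Longer motifs still emerge through nesting. On 200 synthetic
Markov sequences of length 500 the package's test suite requires
compressibility under $W_{\max}=10$ and $15$ to agree in at least 90% of
cases (the observed agreement is higher), mirroring the robustness
expected of the bound.

The **compressibility** of a sequence of uncompressed length $l$ is
$\sum_i S_i / l \in [0, 1)$. The accounting identity
$l = |\text{compressed}| + \sum_i (W_i + 1) + \sum_i S_i$ holds exactly
and is enforced by the `CompressionResult` validity method; decoding
(`decompress()`) is exact by construction and property-tested on random
inputs.

Occurrence positions are tracked through replacements so that
`arcDiagram()` can connect adjacent occurrences of each motif in
*original* sequence coordinates (the natural coordinate system for
visualization); the arc width is the expanded motif length.
`cgramDendrogram()` and `nestingDepth()` expose the hierarchy (depth 0
for base labels, $1 + \max$ child depth otherwise), with each node
carrying the occurrence count recorded at its creation.

The inner loop (candidate enumeration with hashing, greedy selection,
replacement) is implemented in C++ via Rcpp; an independent pure-R
exhaustive oracle in the test suite verifies the selected candidate on
short sequences.

## The compressibility phenotype

Compressibility grows with sequence length (longer sequences offer more
opportunities for repeats), so individuals are compared on fixed-length
chunks: `chunkedPhenotype()` cuts a warped sequence into consecutive
non-overlapping chunks of exactly `chunkLen` labels (default 500),
discarding the trailing partial chunk, and reports per chunk the
compressibility and the mean state duration — the average dwell across
the chunk's postures. The two axes separate stereotypy from overall
activity.

Null models place observed values on a scale:

* `uniformRandomSequence()` — i.i.d. labels; essentially incompressible at
  alphabet 90 (the acceptance suite checks the mean over 100 length-1000
  draws against the $10^{-4}$ scale). Adjacent repeats are allowed (each
  arises with probability $1/90$ per step), so the output is a plain
  vector rather than a `WarpedSequence`; their effect on compressibility
  is negligible at this alphabet size.
* `cyclicSequence()` — the symbols $1..k$ repeated; the ordered extreme
  (compressibility 0.8808 at $k = 90$, length 990).
* `shuffleSequence()` / `sortLabels()` — bounds with the label
  frequencies of a given sequence held fixed. A random permutation can
  create adjacent equal labels, so these also return plain vectors.
* `fitMarkov()` / `simulateMarkov()` — a first-order model with
  transition probabilities estimated from observed sequences. The
  diagonal is zero because warped sequences contain no self-transitions,
  and simulation therefore never reintroduces them. States with no
  outgoing observations (only possible for a terminal state) receive a
  uniform row over the other states so simulation is defined at any
  length; this is logged. The initial state is drawn from the empirical
  label distribution. `fitMarkov()` accepts a list of sequences and pools
  transition counts: at alphabet 90 a fit to a single sequence of a few
  thousand symbols is badly overfit (each row rests on a handful of
  observations, making rows spuriously spiky and the simulations *more*
  compressible than their source); the pooled fit is the appropriate
  estimator for a cohort and restores the expected ordering
  uniform $\le$ Markov $\le$ source.

`compressibilityCurve()` tabulates mean ± s.d. of compressibility over
replicates at a ladder of lengths for any generator.

## Cross-condition motif statistics

To ask which motifs distinguish experimental conditions,
`poolCgrams()` expands every rule of every individual's dictionary to
base labels, keeps the unique motifs, and recounts each motif in *every*
individual's sequence (greedy non-overlapping count). A motif's
**frequency** in an individual is its count divided by the individual's
warped-sequence length; the procedure's source description never fixes
this definition, and count-per-symbol is chosen because it cancels
overall activity differences between individuals. The result is a
`MotifTable`, a `SummarizedExperiment` with `count` and `frequency`
assays, motif metadata in `rowData` and condition labels in `colData`.

Two n-gram controls share the container: `enumerateNgrams()` pools every
distinct subsequence up to `maxLen` (the exhaustive, much larger pool)
and `topFrequentNgrams()` keeps only the `k` most frequent n-grams per
individual and length (the frequency-biased pool; ties broken by the
canonical motif order).

`compareConditions()` runs a two-sided Wilcoxon rank-sum test per motif
and unordered condition pair on the per-individual frequencies, then
applies a single Benjamini–Yekutieli adjustment across the *whole*
family — all motifs × all pairs. Pooling into one family is the
conservative reading of controlling one FDR level over multi-condition
comparisons. BY is used rather than BH because motif frequencies are
strongly dependent (nested motifs, shared individuals); `byAdjust()`
wraps `stats::p.adjust(method = "BY")` and is verified in the tests
against a hand-computed step-up example. Frequencies constant across
both groups give $p = 1$; otherwise `wilcox.test()` decides between the
exact distribution (small, tie-free samples) and the tie-corrected
normal approximation — zero-inflated frequencies are tie-heavy, so the
approximation is the common path. A motif is a **hit** when its q-value
is at or below the FDR level (default 0.05) in at least one pair.
`hitSummary()` stratifies hit fractions by motif length and origin, and
`frequencyRankDistribution()` reports each hit's best frequency rank
across individuals (rank 1 = an individual's most frequent motif), which
shows whether hits concentrate among frequent motifs or spread across
the frequency spectrum.

## The synthetic study design

`generateCohort()` makes every stage testable without external data. A
`CohortSpec` declares: conditions and individuals per condition (default
2 × 20), alphabet size (default 90), warped-sequence length (default
2000), a base model, planted motifs with per-condition insertion rates,
and a master seed from which every random choice flows.

* **Base model**: `defaultBaseModel()` is a first-order Markov chain in
  which each state puts 70% of its mass on 5 preferred successors
  (chosen reproducibly) and the rest uniformly on the others — enough
  short-range order to be clearly more compressible than noise, while
  remaining far from deterministic. A `"uniform"` base (adjacent repeats
  forbidden) is available for strict nulls.
* **Planted motifs**: for each motif and individual, a Poisson number of
  insertions (rate × length) is spliced at uniform positions. Where a
  splice would create an adjacent repeat at a boundary, the flanking
  *base* symbol is dropped, so the planted motif itself is always intact.
  The sequence is trimmed back to the specified length. Tests confirm the
  realized occurrence count matches the nominal rate within Poisson
  error.
* **Dwell durations**: log-normal with median 3 frames
  (`sdlog = 0.6`) — a right-skewed dwell distribution of the kind seen in
  dwelling/roaming behaviour, chosen once as a plausible default since no
  canonical distribution is prescribed.
* **Descriptor streams**: `generateDescriptorStream()` emits each
  frame's template vector plus isotropic Gaussian noise, for exercising
  the discretization end of the pipeline.

What the generator does *not* emulate: biomechanically realistic posture
dynamics, eigenworm geometry, long-range non-Markovian structure,
individual-to-individual parameter variation, or tracking artefacts.
Passing tests on these cohorts therefore demonstrate correctness and
statistical calibration of the machinery — FDR control under the null,
power to recover planted condition differences, the
uniform ≤ Markov ≤ structured compressibility ladder — not that any
particular biological dataset will show particular values.

## Problem sizes and numerical choices

The test and acceptance suites use problem sizes chosen as sensible desk
scales for the properties being checked: 100 replicates of length-1000
uniform sequences for the random control; 200 Markov sequences of length
500 for the $W_{\max}$ robustness rate; 1000 random inputs for
losslessness and the accounting identity; exhaustive-oracle comparisons
on sequences up to length 30; 200 reduced null cohorts (2 × 6
individuals, length 300) for the realized false-hit fraction; and one
cohort at the full default scale (2 × 20, length 2000, insertion rate
0.02 vs 0) for planted-motif recovery.

Other numerical details: compressibility is compared exactly where the
construction is deterministic (the cyclic control's value is frozen as a
regression constant after a hand audit of its first iteration: any
10-gram of the cycle occurs 11 times, $S = 10\cdot11 - 22 = 88$);
near-ties in template distances are snapped with a relative tolerance of
$10^{-9}$ before the lowest-index rule applies; Markov rows are
renormalized after text serialization to absorb rounding; and all
file writers emit atomically (write-then-rename) with a version-stamped
provenance header.

## Limitations

The greedy heuristic does not find the globally optimal grammar — ties
and local choices can shadow better joint replacements; this is inherent
to the approach and shared by its antecedents. Compressibility depends
on the alphabet size (coarser representations are more compressible), so
values are only comparable at a fixed template set, fixed chunk length
and fixed $W_{\max}$. The rank-sum/BY machinery treats individuals as
exchangeable within condition and tests motifs marginally;
motif-to-motif dependence is handled only through the conservativeness
of BY. Finally, the package deliberately stops at the label-sequence
boundary: skeletonization, template learning from video, and real strain
databases are outside its scope.
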