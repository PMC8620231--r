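---
title: "Combining gene prediction sets by extrinsic-evidence support"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining gene prediction sets by extrinsic-evidence support}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txcombine)
```

## The problem

Eukaryotic gene predictors supported by a single evidence type — RNA-seq in
one run, cross-species protein alignments in another — produce annotations
whose union has good sensitivity but poor specificity: at many loci several
mutually incompatible transcript structures are predicted and at most one
can be right. `txcombine` selects, from the union of arbitrarily many
prediction sets, the transcripts whose structure is best supported by the
combined extrinsic evidence, and reassembles the survivors into genes. The
output is a single annotation that is more specific than the union at
little cost in sensitivity.

## The model

### Evidence

All evidence is expressed as *hints*: intron intervals or start/stop codon
positions obtained from spliced alignments, each carrying a source label
`src` (e.g. `E` for an EST/RNA-seq database, `P` for proteins, `C` for a
combined database, `M` for manual anchors) and a multiplicity `mult`, the
number of alignments from that source supporting the same position. A hint
supports a transcript feature only when every identifying characteristic
matches exactly — sequence name, start, end, feature type and strand. There
is deliberately no tolerance window: a misplaced splice site is exactly the
kind of error the evidence should expose.

### Transcript scores

For a transcript with feature set $F$ split into introns $F_i$ and
start/stop codons $F_s$, and evidence set $E$:

$$r_f = \frac{|F_f \cap E|}{|F_f|}, \qquad
  a_f = \sum_{h \in E \cap F_f} w_{src(h)} \cdot mult(h), \qquad
  f \in \{i, s\}$$

giving the score vector $(s_1, s_2, s_3, s_4) = (r_i, r_s, a_i, a_s)$:
the *fraction* of introns and of codons with any support, and the
*weighted amount* of support behind them. $r_f$ counts each feature at
most once however many sources confirm it; $a_f$ accumulates all sources,
scaled by per-source weights $w_o$ that express how trustworthy a source
is (defaults $w_P = 0.1$, $w_E = 10$, $w_C = 5$, $w_M = 1$: one protein
alignment counts far less than one assembled-transcript alignment).

For a single-CDS transcript $F_i$ is empty and $r_i$ is undefined by the
formula; this package defines $r_i = 1$ there ($a_i = 0$ still), so that
intron-less genes are not automatically classed as unsupported — they are
then judged on their codon support alone. $F_s$ holds start and stop as two
separate features, so $r_s \in \{0, \frac12, 1\}$.

### The pairwise comparison rule

Scores are never thresholded globally. Instead every pair of transcripts
whose coding regions overlap — at least three adjacent coding nucleotides
shared on the same strand in the same reading frame — is compared score by
score, in the fixed order $s_1, s_2, s_3, s_4$ against thresholds
$(\epsilon_1, \epsilon_2, \epsilon_3, \epsilon_4) = (0, 0.5, 25, 10)$ by
default. At the first index $j$ where $|s_j^{(1)} - s_j^{(2)}| >
\epsilon_j$ the transcript with the smaller $s_j$ is marked for removal
and the comparison stops; if no index triggers, neither is marked. The
comparison is strict: a difference exactly equal to its threshold does not
trigger. With $\epsilon_1 = 0$, any difference in the fraction of
supported introns is already decisive — the ordering encodes that *which*
introns are supported matters more than *how much* support they have.

Marks are accumulated over all pairs of the original union and applied
once, at the end: a transcript that is already doomed still eliminates
weaker competitors. This makes the outcome independent of the order in
which pairs are examined (verified by permutation tests), and it is what
distinguishes the procedure from simple score filtering — a discarded
transcript may have strong absolute support, just weaker than an
overlapping rival.

After the pairwise round, any transcript whose supported-intron fraction
is below 0.75 **and** whose supported-codon fraction is below 1.0 is
removed as having low evidence support. The conjunctive reading matters:
with the default start/stop threshold of 1.0, a disjunctive rule would
discard every transcript with one unsupported codon, which would gut
recall on loci with RNA-seq-only evidence (RNA-seq produces no codon
hints). The predicate is isolated in `low_support()` so the alternative
reading is a one-line change.

Survivors are clustered into genes by single linkage over the same coding
overlap relation; each cluster is one output gene and its members are the
gene's isoforms. Reading-frame agreement is part of the overlap predicate,
so nested or antisense ORFs do not fuse genes.

### Special cases and degenerate inputs

* One prediction file: the same pipeline acts as a filter, returning the
  evidence-supported subset of that file.
* Structurally identical transcripts from different files are merged before
  scoring (representative: lowest file index) so a duplicate never competes
  against itself.
* A start or stop codon split by an intron is represented by the genomic
  span of its three coding nucleotides; a 3-nt hint can then never match
  it, which is conservative but unambiguous.
* CDS chains with abutting intervals (a zero-length intron) are rejected at
  construction rather than silently producing an empty feature.
* Stop codons: if the input GTF carries an explicit `stop_codon` row it is
  authoritative; otherwise the terminal three coding nucleotides of the
  CDS chain are used (BRAKER-style GTF includes the stop codon in the
  CDS). The output preserves explicit stop rows so that re-filtering the
  output reproduces it byte-identically.

## Tunable parameters

| name | meaning | default | unit |
|---|---|---|---|
| `w_P, w_E, w_C, w_M` | per-source evidence weights in $a_f$ | 0.1, 10, 5, 1 | weight per alignment |
| `e_1` | threshold on $\Delta s_1$ (intron fraction) | 0 | fraction |
| `e_2` | threshold on $\Delta s_2$ (codon fraction) | 0.5 | fraction |
| `e_3` | threshold on $\Delta s_3$ (weighted intron support) | 25 | weight units |
| `e_4` | threshold on $\Delta s_4$ (weighted codon support) | 10 | weight units |
| `intron_support` | low-support cutoff on $s_1$ | 0.75 | fraction |
| `stasto_support` | low-support cutoff on $s_2$ | 1.0 | fraction |

All of these can be overridden from a flat `name value` configuration
file (`read_config()`). The defaults are intended for combining an
RNA-seq-supported with a protein-supported prediction and were not retuned
here.

## Accuracy metrics

`annotation_accuracy()` compares two annotations with exact-match
semantics at three levels. A CDS matches when sequence, strand and both
coordinates are identical; a transcript matches when the CDS sets agree
completely; a predicted gene is correct when at least one isoform matches
one isoform of a reference gene. Sensitivity is TP over reference count,
specificity TP over prediction count (both percent), F1 their harmonic
mean. CDS and transcript units are deduplicated structures within each
annotation, which keeps the counts well defined when two isoforms share a
CDS and makes swapping prediction and reference exactly exchange Sn and
Sp. Gene-level TPs pair genes one-to-one, greedily in coordinate order
with an ordering symmetric in the two annotations, so the same swap
symmetry holds there.

## The synthetic fixture generator

`generate_fixture()` builds desk-scale datasets with a known answer: gene
loci on artificial contigs, each with one or two "true" isoforms; planted
duplicates of true transcripts in a second prediction file (exercising the
merge step); and "decoy" transcripts — the true structure shifted by a
small multiple of 3 so that decoy and truth overlap in frame by
construction, with separately controllable hint coverage. A configurable
fraction of decoys is instead shifted out of frame, exercising the
reading-frame side of the overlap predicate. All CDS lengths are multiples
of 3, which guarantees that isoforms sharing their first CDS overlap in
frame on either strand; real CDS intervals are not individually
codon-aligned, but frame arithmetic is exercised independently against a
per-nucleotide labeling oracle in the tests.

Every fixture's truth table records which transcripts should survive, and
that column is computed by `oracle_select()` — a deliberately naive
re-implementation of the whole workflow (per-nucleotide overlap tests,
linear scans over all hints, all transcript pairs) kept structurally
independent of `run_selection()` so the two can arbitrate each other. The
test suite checks exact survivor-set equality on 200 random fixtures, and
run determinism (input permutation, re-selection idempotence) on 50 more.

What the fixtures do **not** emulate: splice-site sequence context,
alignment noise at exon boundaries (hints either match exactly or miss),
UTRs, overlapping real genes, and realistic hint multiplicity
distributions (multiplicities are 1 + Poisson). Passing the fixture suite
therefore shows the selection logic is implemented exactly as specified,
not that the default hyperparameters are optimal for any particular
genome.

## Problem sizes and numerical choices

The bundled experiments use fixtures of 100 loci (recovery and
specificity-gain experiments) and 3–8 loci (oracle-equivalence fleet of
200), sizes chosen so the brute-force reference remains tractable while
every code path — merging, both overlap outcomes, all four decisive score
indices, low-support removal, multi-isoform clustering — is exercised.
Score comparisons use plain double arithmetic; all threshold comparisons
are strict inequalities, and the only tie-breaks in the system are
deterministic orderings (file index then identifier at the merge step,
coordinate-then-identifier order in the output), so identical inputs give
byte-identical output files.

## Worked example

```{r example}
fx <- generate_fixture(fixture_spec(seed = 42, n_loci = 4))
sel <- run_selection(fx$transcripts, fx$hints)
attr(sel, "stats")
head(attr(sel, "scores"))
```

## Known limitations

* Transcripts are kept or dropped whole; boundaries are never adjusted and
  non-identical transcripts are never merged.
* Scores are not recomputed after removals, and selection is single-pass
  by design (its output is a fixed point).
* Exon-body (coverage) evidence and probabilistic/quality-weighted scoring
  are out of scope; only intron and codon hints are used.
* Evaluation is CDS-based: UTR agreement is not assessed.
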