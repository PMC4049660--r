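---
title: "Pooled cosmid clone sequencing: models, parameters and design choices"
author: "pooltag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled cosmid clone sequencing: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Functional metagenomic screens isolate large-insert cosmid clones — a
circular vector backbone carrying a ~25–47 kb fragment of environmental DNA,
propagated in a bacterial host. Characterizing a screen's hits requires the
full insert sequences. Barcoding every clone for individually indexed
sequencing is accurate but costly, because sample preparation scales
linearly with clone number. The pooled alternative sequences all clones as
one unbarcoded mixture, assembles the mixed reads, and afterwards recovers
each clone's contig from the assembly by querying it with the clone's two
Sanger *end-tags* — reads taken at the vector–insert junctions. The open
questions are quantitative: how accurate are the retrieved sequences, how
complete are they, and which pool properties (read depth, inter-clone
sequence similarity, host DNA contamination, genuinely overlapping clones)
make clones unrecoverable.

`pooltag` implements this whole workflow at desk scale with a fully
truth-tracked simulator, so that every claim the pipeline makes can be
scored against known ground truth:

1. **simulate** — sources, vector, clone pool, end-tags, paired-end reads;
2. **subtract** — screen vector-derived read pairs, estimate host
   contamination;
3. **assemble** — canonical k-mer de Bruijn unitig assembly;
4. **retrieve** — end-tag queries against the contig pool, clone typing,
   delineation of clones inside consensus contigs;
5. **evaluate** — identity, retrieved vs. actual coverage, pairwise clone
   similarity, per-base read depth.

`runAll()` executes the five stages as one reproducible run.

## The simulator and what it emulates

The generator's defaults mirror the study design the package emulates:

| parameter | default | meaning |
|---|---|---|
| `insertLenMean/Sd/Min/Max` | 33 500 / 5 000 / 25 000 / 47 000 bp | truncated-normal insert lengths, matching the observed span of reference clone assemblies (largest 47.2 kb); the sd is not reported anywhere and 5 000 bp was chosen once as a realistic spread |
| `readLen` | 90 bp | pooled paired-end read length |
| `depth` | 900× | pooled fold-coverage per cosmid (examples and tests use 25–60× so that runs finish in seconds to minutes; problem sizes are listed below) |
| `barcodedDepthFactor` | 10 | the barcoded (reference) arm is sequenced ~10× deeper than the pool |
| `tagLen` | 700 bp | Sanger end-tag length; read lengths of the chemistry are not reported, 700 bp is a typical good Sanger read and is configurable |
| `tagFailProb` | 0.313 | independent per-end failure; chosen so the expected fraction of clones with at least one usable tag is `1 − 0.313² ≈ 83/92` |
| `errorRate` | 0.001 | per-base substitution probability; no indels (see below) |
| `contaminationFrac` | 0.05 | fraction of read pairs drawn from the host genome |
| `kAssembly` / `kBarcoded` | 31 / 63 | pooled / per-clone assembly k-mer sizes |
| `minContigLen` | 500 bp | emitted-contig floor |

Reads are drawn from the *circular* cosmid: fragments may span the
vector–insert junctions, which is exactly what makes vector subtraction
non-trivial at the boundaries. Mate 2 is the reverse-complement strand of
the fragment end; pairs flip orientation at random. Per-clone pair counts
are Poisson around `depth × L / (2 × readLen)`.

**Truth labels.** Every simulated pair records its origin
(`clone:<id>`, `host`, or `vector`). A pair is labelled `vector` when
either mate lies wholly in the backbone portion of the circle — or when a
junction-spanning mate is *sequence-identical* to the backbone (a mate
overlapping the insert by a single base equals a backbone substring with
probability 1/4). Without the second clause no screening rule could reach
exact precision against the labels, because the label would distinguish
reads that are byte-identical.

**What the simulator does not model:** indels and quality-dependent errors
(the downstream pipeline is quality-blind, and substitutions suffice to
exercise every identity metric), GC/PCR bias, chimeric library molecules,
repeats within a source genome (sources are uniform-random), and realistic
host genome structure (contamination counting is identity-based, so a
uniform-random 2 Mb host is sufficient). Tests passing on these simulations
therefore demonstrate the pipeline's correctness contracts, not its
performance on real libraries, where repeat content and coverage bias would
lower assembly contiguity further.

**Clone placement.** Clones not assigned to an `overlapGroups` entry are
placed in *disjoint* source windows (rejection sampling): incidental
overlap would silently reproduce the consensus-assembly phenomenon in runs
meant to be controls, and `overlapGroups` is the explicit mechanism for
overlapping clones. Group members tile nested windows with step
`(min(len) − overlap) / (size − 1)`, which guarantees all pairwise overlaps
are at least `overlap` bp. Shared-similarity segments are injected by
copying a segment from one insert into another at a configurable per-base
identity.

## Assembly: canonical k-mer unitigs

`countKmers()` counts k-mers in canonical form (the lexicographic minimum
of a k-mer and its reverse complement); k must be odd so no k-mer is its
own reverse complement, which is why the barcoded arm uses k = 63 rather
than the common 64 of string-graph assemblers. `extractUnitigs()` emits the
maximal non-branching paths of the bidirected de Bruijn graph. There is no
tip clipping, bubble popping or scaffolding — the single cleaning device is
the count floor `minKmerCount` (2 when `errorRate > 0`, else 1), which
removes singleton error k-mers without any coverage model. The phenomena
of interest (coverage gaps, breakage at shared-similarity boundaries,
consensus assembly of overlapping clones, depth inflation) all emerge at
unitig level, and unitigs keep every step independently testable: the
surviving k-mer multiset equals the contig k-mer multiset exactly, and
assembly is invariant to read order.

Determinism rules: contigs are reported in the lexicographically smaller of
their two orientations, ordered by descending length then sequence, and
named `ctg00001…`. A clone whose graph closes into a cycle (a complete
circular cosmid) is cut at its lexicographically smallest k-mer and
emitted once, as a linear contig of length `L + k − 1`.

A consequence worth knowing: at high depth the expected number of
*duplicated* sequencing errors grows quadratically, so more error k-mers
survive the count floor and fragment unitigs. Deeply over-sequenced regions
(e.g. a segment shared by four clones) therefore assemble into *more,
shorter* pieces — many below `minContigLen` — which is precisely the
depth-high/coverage-low signature the evaluation stage measures.

## Vector subtraction at 100 % identity

`screenVector()` removes a pair when either mate is an exact full-length
substring of the doubled circular backbone or its reverse complement — the
strict, parameter-free reading of a "100 % identity" criterion. Host reads
are counted (`estimateContamination()`, mate 1 against the host genome,
k-mer index plus full verification) but never removed: contamination's
effect on assembly is part of what the toolkit demonstrates. Two documented
consequences of strictness: with substitution rate *e*, screened-vector
recall is `(1 − e)^readLen` (each mate must be error-free to match), and
the same factor depresses the contamination estimate (≈ 4.6 % measured for
5 % seeded contamination at *e* = 0.001).

Junction-spanning mates survive the read screen by design — they contain
insert bases. Left alone, their partial-vector k-mers would attach every
clone's insert ends to the shared backbone sequence and, worse, create a
branch *into* the middle of a consensus contig at every interior
vector–insert junction of an overlapping clone group. `assemblePool()`
therefore performs the k-space counterpart of pre-assembly vector
subtraction when given the backbone: (i) each read end is trimmed of its
longest prefix/suffix that matches the backbone sequence approaching or
leaving the cloning site, on either strand — on a circular cosmid the
vector part of any junction mate is anchored at the site, so this trim is
exact; (ii) any k-mer occurring in the doubled backbone is masked from the
graph. False trims (a read coincidentally matching the junction context for
a base or two) merely thin coverage by a fraction of a base per read end.
The result is that an isolated clone assembles to its insert *exactly*, and
overlapping clones assemble to one consensus contig spanning their union.

## Alignment and retrieval

`smithWaterman()` is an exact affine-gap local aligner (gap of length *g*
costs `gapOpen + g·gapExtend`) with a deterministic traceback (ties prefer
diagonal, then up, then left). It is the oracle; `seedExtend()` is the
workhorse: exact shared 28-mers seed an ungapped x-drop extension
(default x-drop 20), refined by banded gapped alignment (band half-width
40) in a window around the ungapped segment. Because any banded-window
alignment is also a valid local alignment of the full pair, `seedExtend()`
can never score above the `smithWaterman()` optimum — an invariant the
tests assert on hundreds of random instances. Default scoring
(+1/−2, gap −5 −2/base) is Megablast-like; the scoring scheme, seed length
and x-drop are arguments everywhere. Thresholds replace E-values: a
qualifying retrieval hit needs ≥ 95 % identity over ≥ 50 % of the tag
(both arguments), and the similarity statistic counts HSPs of ≥ 50 bp at
≥ 80 % identity — at these lengths strictly more conservative than the
E-value cutoff it stands in for. One caveat: exact 28-mer seeding loses
sensitivity below ~85 % identity; the injected-similarity scenarios this
package targets are ≥ 95 % identical, well inside the safe range.

Retrieval queries the pool with each usable end-tag (`queryPool()`); the
best hit maximizes score, ties broken by longer alignment then
lexicographic contig id; multi-HSP hits score by their best single HSP.
Clone types follow the retrieval outcome: **A** both tags, same contig;
**B** both tags, different contigs; **C** two tags, one hit; **D** one
usable tag, one hit; plus `unretrieved` (usable tags, no hits) and
`excluded` (no usable tags) so that classification is total. Type B is
assigned without verifying that the two contigs belong to the same clone —
that verification is what the evaluation stage does with reference
sequences. When both tags hit one contig, `delineateInConsensus()` reports
the interval between the outermost HSP coordinates, which recovers a
clone's extent inside a multi-clone consensus contig.

## Evaluation metrics

For each clone, the retrieved contigs and the full contig pool are aligned
to the clone's reference (the simulator truth, or the barcoded-arm
assembly when truth is withheld):

* **identity** — column-weighted `Σ matches / Σ columns` over qualifying
  HSPs (≥ 250 bp). Column-weighting is a choice; a best-HSP alternative is
  provided (`aggregate = "best-hsp"`) since the aggregation used for the
  original one-number-per-clone summaries is not recorded.
* **retrieved coverage** — reference bases covered by HSPs of the
  *retrieved* contigs passing the 250 bp / 99.6 % filter, after interval
  merging, over the reference length.
* **actual coverage** — the same computation against *every* pool contig:
  the correction for clone fragments that exist in the assembly but were
  not reached by an end-tag. The 250 bp / 99.6 % filter is stated only for
  this correction in the source material; applying it to retrieved
  coverage as well makes `retrieved ≤ actual` provable (superset evidence),
  and the pipeline asserts it on every run.
* **similarity** — per pair, qualifying HSPs are merged on the shorter
  clone; similarity is covered bases over the shorter length, in [0, 1] by
  construction, 0 when nothing aligns; the matrix is computed once per pair
  and mirrored, hence exactly symmetric.
* **depth** — each mate is anchored by its first exact 31-mer with an
  index hit (non-overlapping windows are probed, then the final window)
  and verified ungapped with ≤ 4 mismatches; a mate anchoring at several
  loci counts at each. This is deterministic and dependency-free;
  it under-counts only reads whose every probed window carries an error.

Coverage histograms use half-open ten-percent bins with a closed top bin,
so a clone at exactly 90 % falls in the 90–100 bin and 100 % is not lost.

## Reproducibility and numerical conventions

One master seed governs a run; every stage derives its own sub-stream
(`seed + fixed offset`), so stages can be rerun independently and a
re-executed configuration reproduces byte-identical FASTA/FASTQ/TSV
outputs. All coordinates in HSPs, intervals and delineations are 0-based
half-open; minus-strand HSPs are reported in plus coordinates of the
subject. Report tables render floating-point values with fixed 4-decimal
precision for bit-stable diffs. Degenerate inputs are defined, not
accidental: empty read sets assemble to empty contig sets, a pool with all
tags failed classifies every clone `excluded`, zero-width intervals merge
to zero coverage, and a `seedExtend()` seed longer than either sequence
returns an empty hit list rather than an error.

## Problem sizes used by the tests

The unit tests run pools of 1–6 clones with 5–7 kb inserts at 20–60×; the
end-to-end property checks use 10 clones × 10 kb at 30× (clean recovery),
3 × 30 kb overlapping clones at 40× (consensus and delineation), and three
seeds of 20 clones × ~33.5 kb at 60× with an identical 15 kb segment
shared by four clones (similarity/coverage/depth interaction). These sizes
were chosen so the full suite completes in minutes on one core while every
phenomenon of interest — junction handling, cycle emission, error-k-mer
fragmentation, consensus assembly, depth inflation — still occurs.

## Known limitations

* Unitig-only assembly understates the contiguity a paired-end scaffolder
  would reach; retrieved coverage at desk scale is correspondingly
  depth-sensitive (more depth ⇒ more surviving duplicated-error k-mers ⇒
  more, shorter unitigs).
* The substitution-only error model cannot exercise gapped-alignment
  corner cases in real data, though the aligner itself is gap-capable and
  oracle-checked.
* Exact-seed methods (retrieval, depth, screening) assume high sequence
  fidelity; they are not sensitive decontamination or mapping tools.
* The barcoded arm concatenates multi-contig reference assemblies in
  descending length order; coordinates within such references are then not
  collinear with the physical insert.
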