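---
title: "Measuring mRNA vaccine quality attributes from aligned sequencing reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring mRNA vaccine quality attributes from aligned sequencing reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrnaqc)
```

# Scope and model

Synthetic mRNA drugs are made by in vitro transcription (IVT) of a
linearised plasmid template. The product must be checked for sequence
identity, integrity (full-length, translatable molecules), poly(A) tail
length, and purity (antisense RNA, readthrough, cryptic initiation,
residual host DNA). Long-read sequencing of the product — and of the
template before transcription — can measure all of these in one assay,
provided the analytics are careful about the systematic errors of the
platform, above all homopolymer deletions inside the poly(A) tail.

`mrnaqc` implements that analytic layer. It consumes aligned reads
(SAM/BAM) against an annotated construct reference and computes:

* a per-nucleotide error profile (mismatch, deletion, insertion) with
  optional subtraction of a template (plasmid) baseline;
* a pileup-majority consensus with a variant list;
* an integrity classification of every read against the target interval;
* an alignment-space poly(A) tail length per read, corrected for the
  tail deletion rate;
* antisense, contaminant, cryptic-start and readthrough accounting;
* a basecall-signature scan for N1-methylpseudouridine.

All coordinates in the API are 0-based half-open (the BED convention);
1-based coordinates appear only in rendered text. A single convention
end to end removes the most common class of off-by-one defects in this
kind of pipeline.

# The construct model

A `ConstructLayout` holds the reference sequence and a named region table
(`promoter`, `utr5`, `kozak`, `cds`, `utr3`, `linker`, `polya`,
`restriction_site`, `backbone`). Two derived intervals drive everything
downstream:

* the **transcript interval** `[TSS, polya.end)`, with the transcription
  start site taken as the first base after the promoter — constructs are
  annotated by region, not by a numeric TSS, so the promoter boundary is
  the natural definition;
* the **target interval** `[kozak.start, utr3.end)`, the span a read must
  cover to count as a full-length, translatable molecule. Where no
  separate Kozak row is annotated, the CDS start is used: the two
  conventions alias in practice and we accept either.

`validateLayout()` returns violations as data rather than raising, so a
malformed layout can be inspected; loading through `loadConstruct()`
enforces validity. The annotated poly(A) region must be at least 90%
adenosine by default: segmented tail designs place short linkers between
A-blocks, and the slack admits annotations that include them.

```{r layout}
lay <- syntheticConstruct()
lay
```

The shipped synthetic construct mirrors a typical reporter-mRNA template:
a 20 nt T7 promoter, 47 nt 5' UTR, 10 nt Kozak, 720 nt CDS, 245 nt
3' UTR, 5 nt linker, a 126 nt encoded poly(A) tail, a 6 nt restriction
site used for linearisation, and a backbone remainder; the transcript is
1153 nt. These dimensions were chosen once to match the geometry of a
realistic eGFP-class construct and are not tuned thereafter.

# The read simulator and its truth channel

Every analytic in the package is validated against simulated reads whose
truth is known *exactly*, not just statistically: the simulator generates
reads in reference space, so each construct read carries an edit walk
(CIGAR) that reproduces its sequence from the reference, and a truth
record (species, true interval, strand, true tail length, realised edit
counts). Truth alignments are written as SAM; no external aligner is
involved anywhere in the test chain.

Species and their geometry:

* `full_length` reads run from the TSS to the end of the encoded tail;
* `trunc5` reads start uniformly inside `(kozak.start, utr3.start)` and
  reach the tail end (RNase degradation produces molecules missing 5'
  sequence but retaining the tail);
* `trunc3` reads start at the TSS and end uniformly inside
  `(cds.start, utr3.end)` with no tail (abortive transcription);
* `trunc_both` reads are truncated at both ends (hydrolysis);
* `antisense` reads are reverse-complement fragments uniform along the
  transcript — the data only quantify, not localise, antisense RNA, so a
  uniform breakpoint model is the neutral choice (the same reasoning
  gives uniform truncation breakpoints above);
* `cryptic_tss` reads initiate at planted positions upstream of the tail;
* `readthrough` reads run past the tail into the backbone;
* `contaminant` reads are fragments of a second reference and appear as
  unmapped records.

The error model applies independent per-base substitution, insertion and
deletion probabilities, with a separate deletion rate inside the poly(A)
region. Defaults reflect measured direct-RNA nanopore composition
(2.61% mismatch, 5.18% deletion, 1.43% insertion) with 13% tail
deletions. Base qualities are a constant Q12 — above the usual Q>9 pass
gate — because quality modelling is not the subject here; the value is
configurable.

Two deliberate truth-channel properties:

* **Edge deletions are kept in the CIGAR.** An aligner would trim a
  deletion at a read end; the truth writer does not, because trimming
  would silently censor reads whose terminal tail base was deleted and
  bias deletion rates at region edges. htslib accepts such records.
* **`polyadenylateAll`** emulates the enzymatic tailing of all RNA 3'
  termini before library preparation: every species receives a fresh
  geometric tail (mean 30 nt, configurable), carried as soft-clipped
  bases. The companion knob `nonPolyaCaptureRate` (default 1 = off)
  models oligo-dT selection against tail-less species in the standard
  protocol, which the tailing step rescues — this is what makes the extra
  step reveal more off-target reads.

What the generator does **not** emulate: raw-signal behaviour, coupled
quality/error statistics, PCR duplicates, chimeras, or any aligner's
soft-clipping decisions. Tests passing on this generator therefore
demonstrate the correctness of the analytics' arithmetic and their
statistical recovery under the stated error processes — not robustness
to every artefact of real libraries.

All randomness flows from one integer seed through R's default RNG, and
identical configurations produce byte-identical FASTQ/SAM output.

# Pileup and error-profile conventions

`buildPileup()` tallies, per reference position, the aligned A/C/G/T
calls, spanning deletions, and insertion *events* anchored at the
position left of the inserted bases (one count per event regardless of
length — matching per-position variation-style reporting). Soft clips
contribute nothing. The implementation is vectorised over CIGAR ranges;
the test suite holds it equal to a naive per-read replay oracle on every
instance tried.

Error rates divide by the spanning depth (`aligned + deleted` reads):
`m = (depth - del - refbase)/depth`, `d = del/depth`, `s = ins/depth`.
Because insertion events appear only in the numerator, `s` can exceed 1
in pathological pileups; plots cap it at 1, tables do not. Positions
below `minDepth` (default 20) are flagged absent rather than reported
as zero.

Baseline subtraction (`subtractBaseline()`) removes template-borne and
platform-borne error from a product profile position by position and
type by type, flooring at zero — a negative corrected rate has no
physical reading, and the floor keeps the operation monotone.

`callConsensus()` takes, per position, the majority of
{A, C, G, T, deletion} when its fraction reaches `minFraction` (0.5) at
depth `minDepth` (20), else masks with `N`; zero-coverage positions are
always masked. Ties prefer the reference allele when it is among the
tied set, else the first of A < C < G < T < del, and are flagged — a
deterministic, documented rule in place of a variant caller's internal
tie-breaking.

# Poly(A) tail estimation

Nanopore basecalling deletes bases inside long homopolymers at a high,
reproducible rate, so the aligned tail is systematically short. The
estimator:

1. `tailLengths()` counts, per sense read, the read bases in M and I
   operations anchored inside the annotated tail region (insertions are
   real called bases and count; linker bases count only if the BED puts
   them inside the tail region — the annotation decides);
2. `tailDeletionRate()` measures `sum(del)/sum(depth)` over the tail
   columns of the pileup;
3. `correctTailLengths()` rescales raw lengths by `1/(1 - d)`.

Reads whose alignment does not reach the tail's 3' end carry *censored*
tails (the protocol anchors the primer at the 3' terminus, so a complete
read covers the tail end) and are excluded from summaries.

Estimator properties worth knowing:

* At deletion rate `d` the raw mean is `E(1 - d) + E·s` for an encoded
  length `E` and tail insertion rate `s`; the correction divides by
  `(1 - d)` only, so the corrected mean overshoots by roughly `E·s/(1-d)`
  (about 2.6 nt at `E = 126`, `s = 0.018`). A joint indel correction is
  possible but was not adopted: the single-rate form is transparent, and
  the residual bias is visible and documented.
* The per-read correction and the correction of the mean coincide up to
  this linearity, so both readings of "mean underestimation" are
  reported by the summary (`mean_raw` vs `mean`).
* The m-shaped positional deletion profile across the tail is visible in
  the error profile but is deliberately not modelled; the correction
  uses one region-wide rate.

# Purity analytics

**Integrity classes.** With target interval `T` and tolerance `t`
(default 0 nt — strict coordinate overlap; 5–10 nt is warranted when
adaptor trimming leaves ragged ends): full-length iff the read covers
both `T.start + t` and `T.end - t`; 5'-truncated iff it reaches the end
but not the start; 3'-truncated for the converse; doubly truncated
otherwise. Sense reads lying wholly outside the transcript are reported
as upstream/downstream off-target and excluded from the truncation
partition, which is about the product itself.

**Cryptic starts.** The 5'-start histogram of sense reads is scanned
outside a ±25 nt window around the TSS; positions whose count reaches
`minFraction` of reads seed clusters merged across gaps ≤ 10 nt. One
calibration matters: in a library with heavy 5' degradation the
truncation background itself puts reads at every position
(`0.313 · n / span` per position), and `minFraction` must sit above that
background's Poisson fluctuations. At n = 20,000 over a ~730 nt span the
background is ~9.5 reads/position, so the analysis runs use
`minFraction = 0.002` (40 reads); the default 0.001 suits libraries with
less degradation.

**Contaminant triage** replaces a second alignment pass with canonical
k-mer containment (k = 21 by default): a read is labelled with the
argmax-containment reference when the maximum reaches `minContainment`,
else unclassified — the residual bucket that a homology search would
otherwise chase. Calibration rule: the expected containment of a read
with per-base error `e` is `(1-e)^k` (0.34 at 5% error, k = 21), while
cross-reference collisions sit near zero, so the threshold belongs well
below `(1-e)^k` and above ~0.05; the analyses here use 0.1 for 5%-error
reads. The shipped default of 0.5 is appropriate only for low-error
(short-read or consensus) input.

**Antisense fraction.** For long single-end reads the alignment strand
flag is trusted (orientation is resolved upstream by the strand-switch
chemistry). For paired stranded libraries the mate/strand truth table
applies: a fragment originates from the sense strand iff its
second-in-pair mate maps forward or its first-in-pair mate maps reverse;
the converse combinations are antisense. The antisense fraction is an
indirect proxy for dsRNA burden.

# Modified-nucleoside signature

N1-methylpseudouridine is miscalled as cytosine at a characteristic
rate. The scan scores every reference-U transcript position with depth
≥ 50 by `f_C / (f_C + f_U)` over called bases — conditioning on C/U
calls insulates the score from the deletion-rate elevation that
accompanies modification and is reported separately. A position is
flagged at score ≥ 0.3 (between the unmodified mismatch baseline of a
few percent and the typical 0.62 signature) and, when a matched
unmodified control is supplied, only if it exceeds the control score by
half the threshold — the differential mode is preferred whenever a
matched run exists. Flags are a subset of U positions by construction.
The simulator draws per-position miscall probabilities i.i.d. around the
aggregate (the per-position variability is not characterised, so a
normal spread of 0.05 is assumed). No basecaller retraining is involved.

# Reports

`runPlasmidReport()` (template mode: filter → pileup → error profile →
consensus → lengths → unmapped triage) and `runMrnaReport()` (the full
product chain, plus integrity, size fraction, poly(A), antisense,
cryptic starts and the optional modification scan) emit a
schema-versioned JSON report plus per-section TSVs. Absent analyses are
explicit nulls, never silently missing; timestamps are excluded so
identical inputs give byte-identical reports. `validateQCReport()`
checks a report against the shipped schema
(`inst/schema/qcreport-1.0.json`). A thin command-line wrapper with
`plasmid` and `mrna` verbs is installed at `exec/mrnaqc`.

```{r report}
td <- tempdir()
sim <- simulateReads(lay, simulationConfig(nReads = 500, seed = 1))
writeConstruct(lay, file.path(td, "ref.fa"), file.path(td, "ref.bed"))
writeTruthAlignments(sim, file.path(td, "reads.sam"))
rep <- runMrnaReport(file.path(td, "reads.sam"), file.path(td, "ref.fa"),
                     file.path(td, "ref.bed"))
rep
```

# Problem sizes, tolerances and degenerate inputs

The validation suite runs entirely on simulated data at desk scale,
chosen so the whole suite completes in well under a minute: most unit
checks use a 246 nt construct with 60–600 reads; the statistical
recovery checks use the 2179 nt construct with 2,000 reads (tail
correction), 20,000 reads (integrity fractions), 50,000 reads
(antisense at 0.6%), and 2 × 1,000 reads (triage). Stochastic
recoveries are asserted within 3 binomial standard errors of the
configured truth (one simulator unit check uses a chi-square
goodness-of-fit at α = 10⁻⁴, which is seed-robust where a fixed-seed
per-class 3-SE band is not); arithmetic identities (pileup vs replay,
truth-edit accounting, consensus on clean reads) are asserted exactly.

Degenerate inputs are defined, not accidental: empty read sets produce
empty outputs and a failed (`success = FALSE`) report with zeroed
mapping counts; zero-coverage positions are masked `N`; reads shorter
than k are unclassified but counted; an all-deleted tail column yields
deletion rate 1; `subtractBaseline` of a profile from itself is
identically zero.

# Known limitations

* The tail correction is alignment-space only; raw-signal estimators
  are out of scope, and the insertion-driven overshoot described above
  is inherent to the single-rate form.
* Truncations arising during IVT cannot be distinguished from
  library-prep artefacts by these analytics (or by the assay itself);
  the simulator treats them as one class parameter per truncation side.
* The antisense flag logic presumes correct upstream orientation
  (long reads) or a stranded protocol (short reads).
* Variable true tail lengths shorter than the encoded tail are treated
  as censored by the spanning rule and excluded from summaries.
* The modification scan detects the C-miscall signature only; other
  modifications and signal-space calling are out of scope.
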