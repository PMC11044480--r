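---
title: "Methods: detecting active LTR retrotransposons from eccDNA and WGS long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting active LTR retrotransposons from eccDNA and WGS long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The biological problem

Transpositionally active LTR retrotransposons (LTR-RTEs) excise circular DNA
intermediates — extrachromosomal circular DNA (eccDNA) — when they complete
their life cycle. Mobilome-seq enriches these circles by exonuclease digestion
of linear DNA, amplifies them by rolling-circle amplification (RCA), and
sequences the amplicons with nanopore long reads. Because RCA turns one circle
into a linear tandem concatemer, a single read can contain several complete
copies ("monomers") of the originating circle. That redundancy is the central
asset of the assay: it lets us (i) count reads per annotated element and test
for condition-dependent activity, (ii) reconstruct the circle's structure and
a within-read consensus sequence, and (iii) distinguish genuinely truncated
circles from random read breakage, because a true structural boundary recurs
at every monomer junction.

`mobilomeR` implements this analysis end to end, together with the
complementary whole-genome questions: where does the genome of the studied
line deviate from the reference at high SNP density (interspecific
introgressions), and where have elements re-inserted (non-reference TE
insertions, TEIs, recognisable by split reads and target-site duplications).

## Alignment core

All stages share one alignment engine, a classical seed–chain–extend local
aligner plus a banded global aligner for percent identity:

* **Seeds** are exact k-mers (default `k = 13`). The reference index stores
  forward-strand k-mer positions; queries are searched on both strands.
  Seeds occurring more than `max_occ = 200` times are skipped (repeat
  masking), which matters in a genome deliberately seeded with high-copy
  elements.
* **Chains**: anchors are clustered by diagonal (`band_width = 100` bp),
  chained co-linearly, and split where consecutive anchors are more than
  `max_seed_gap = 500` bp apart. Chain strength is measured by exact-matched
  bases; only the strongest chains are converted to base-level alignments,
  but a chain covering a query region that no accepted chain covers is always
  admitted (`max_split_hits`) — this is what exposes the flank alignments of
  reads spanning a repeat insertion.
* **Extension and gap fill** use banded affine-gap dynamic programming
  (match +1, mismatch −2, gap open 2, gap extend 1). Extensions stop when
  the best score has not improved for 50 rows. Equal-length gaps of up to
  6 bp are resolved on the diagonal directly, which is provably optimal under
  these scores.
* **Identity** is defined as `100 × matches / alignment columns`, gap columns
  included — the "BLAST identity" convention of PAF, monotone under added
  gaps. `global_identity()` orders its two arguments canonically before
  aligning, so it is exactly symmetric. If a requested band cannot hold the
  optimal path it is widened automatically with a warning.

Coordinates are 0-based half-open internally; BED output stays 0-based,
VCF and reported insertion positions are converted to 1-based at the I/O
boundary. Ties for the primary alignment break deterministically by lowest
(target name, target start).

The scoring parameters are adequate for the ~10% per-base error of the
simulated nanopore-like reads; the aligner is the tested reference path of
the package rather than a wrapper around an external mapper, so the whole
pipeline is reproducible from a single install.

## Synthetic mobilome generator

The generator emulates every input the pipeline consumes, at desk scale,
with machine-readable truth:

* **Reference**: two chromosomes (400 and 300 kb of random host sequence at
  GC 0.36) carrying five LTR-RTE families of eight copies each — about 30%
  repeat content, in the range of TE-dense plant genomes. Families are
  generated independently (far below the 80% family-linkage threshold);
  copies diverge from the family consensus by 1–5% substitutions, so
  within-family identity stays above 90%. Every copy is inserted with a 5 bp
  target-site duplication (typical for Copia-type elements; configurable
  4–6 bp). LTR lengths are drawn from 400–600 bp and internal regions from
  3,800–4,600 bp, giving full elements of roughly 4.6–5.8 kb.
* **Reading frames**: family 1 carries a planted 1302-codon ORF, family 2 a
  352 + 1173-codon pair (the reported frame lengths of the two active
  families this scenario mirrors); further families recycle the list. Each
  ORF is preceded by an in-frame stop so the planted length is exact.
* **Activity**: families 1 and 2 each contain one intact master copy
  (unmutated, LTR identity 100) that produces the eccDNA. This mirrors the
  common situation where a single autonomous copy drives a family's
  activity. The eccDNA of each master derives from a *donor allele* carrying
  55 planted substitutions — the circles come from a copy that is not the
  reference copy, which is exactly the situation that motivates divergence
  analysis and origin assignment.
* **eccDNA reads**: each read picks an element (active elements weighted
  10× under treatment, uniform under control), a structural class from the
  mix solo_LTR 0.15 / full_1LTR 0.55 / full_2LTR 0.15 / truncated 0.15,
  builds the circle, and emits a tandem concatemer from a uniform random
  phase with lognormal length (median 3 kb), random orientation, and
  per-base errors (substitution 5%, insertion 2.5%, deletion 2.5% — about
  10% edits per base). 5,000 reads per condition.
* **WGS reads**: a donor haplotype differs from the reference by background
  SNPs (5 × 10⁻⁴ per bp), one introgressed segment at 20× that rate
  (chr1:100–300 kb — about 1% divergence, a realistic interspecific level),
  and four non-reference TE insertions (three of family 1, one of family 2)
  spliced in with 5 bp TSDs. Reads at 20× coverage, lognormal length
  (median 8 kb). Insertion sites are chosen so that neither insert end
  coincidentally matches its flank — this keeps the planted TSD length
  well-defined (with micro-homology the "exact" breakpoint is genuinely
  ambiguous).

What the generator deliberately does **not** model: homopolymer-biased or
quality-correlated nanopore errors, RCA chimeras and branching artifacts,
diploid genotypes, nested or fragmented TE copies, and structural variants
other than TE insertions. Truncated circles are simulated as genuine circles,
so the junction-support rule of the decomposer is testable. Tests passing on
this generator therefore demonstrate algorithmic correctness under idealised
noise, not performance on real flow-cell data.

Scenario sizes were chosen so the whole simulate–map–test cycle runs in
minutes on one CPU: two chromosomes totalling ~0.9 Mb after insertion,
40 elements, 10,000 eccDNA reads and ~2,200 WGS reads per scenario.

## eccDNA activity calling

Reads are mapped and counted by their primary alignment only; each read
counts at most once, toward the element with the largest overlap
(minimum 100 bp; ties to the leftmost element). Normalisation is
`100,000 × count / library reads` — the denominator is all sequenced reads,
not mapped reads. Differential activity per element uses a two-sided Fisher
exact test on the 2×2 table of (element reads, remaining reads) ×
(treatment, control), Benjamini–Hochberg correction over elements with more
than `min_reads = 10` combined reads (Bonferroni available), and a
significance rule requiring adjusted p < 0.01 *and* a normalised count
higher under treatment. The two-sided test plus directional filter was
chosen over a one-sided test so that depletion is never reported as
activity while the p-value remains the standard symmetric one. There is no
manual curation step: the filters are explicit so results are reproducible
without a human.

## Concatemer decomposition and structure classes

`decompose_concatemer()` aligns the element against the read (read as
target). Tandem hits define monomer copies:

* the **monomer length** is the median spacing between hits of the same
  element segment, corrected by their query-offset difference so terminal
  partial copies do not bias the period. When fewer than two full periods
  are present the period follows from the offset-corrected spacing of
  adjacent hits. Because the two element LTRs are (near-)identical, circle
  segments can alternate between 5′- and 3′-LTR interpretations; a
  reference-free k-mer periodicity estimate guards against the resulting
  period doubling, and the same estimator (`estimate_circle_period()`) is
  available on its own for circles whose element is absent from the
  reference.
* the read is tiled into monomer windows from the first hit; a window
  covered over 90% of its span is a **full monomer**. Window boundaries
  are junction-supported when the coverage gap across them is under 50 bp.
* the **consensus** is the per-column majority of full-monomer alignments
  projected onto element coordinates (at least two full monomers required),
  capped at one monomer's worth of columns. Terminal partial copies are
  excluded from the consensus but counted in coverage.

`classify_structure()` is a pure function of internal-region coverage and
LTR copies per monomer: internal ≤ 0.1 with an LTR is a solo-LTR circle;
internal ≥ 0.9 with one (two) LTR copies is full-length with one (two)
LTRs; intermediate coverage is truncated; everything else "other". LTR
copies are counted on *read* positions, because both identical element LTRs
align to the same read segment and element-projected depth would double
count a single circle LTR. Uncovered internal gaps of ≥ 20 bp inside the
covered span are reported as deletions.

## Divergence and origin

`consensus_divergence()` piles full-monomer copies from many reads onto
element coordinates and calls a SNP where a single base reaches agreement
≥ 0.8 at coverage ≥ 5 and differs from the reference; deletion-majority or
ambiguous columns are never SNPs. Seeds cannot span a mismatch against the
reference, so divergent columns always fall in gap-filled alignment regions
with ambiguous placement; a second pass realigns every read against the
first-pass consensus template (a polishing step in the racon tradition),
restoring exact anchoring across divergent sites. LTRs are flagged
uncovered when their mean depth is below 1, and a contiguous
uncovered-or-deleted stretch of ≥ 20 bp inside an otherwise covered LTR is
reported as an LTR deletion.

`assign_origin()` takes a consensus LTR, finds its best locus in each panel
genome with the local aligner, pads the locus by the clipped query amounts
and computes a banded global identity over it. The top genome is assigned
when its identity reaches the floor (default 96%, the working threshold for
a confident species-of-origin call) and leads the runner-up by at least
1 point; otherwise the call is ambiguous. Ties break by genome name.

## Whole-genome module

SNPs are called by a naive per-column pileup of primary alignments (allele
fraction ≥ 0.7 at depth ≥ 5 — haploid-style, matched to the synthetic donor;
a VCF reader accepts externally called variants instead). Densities are
computed in fixed windows (1 Mb at chromosome scale; 10 kb in the desk
scenario), the last partial window scaled by its true width, and the genome
median taken over full windows. Introgressions are maximal runs of windows
at ≥ 5× the median density, bridging at most one sub-threshold window, at
least three windows long — declared defaults, since no published windowing
rule exists for this decision. A zero median falls back to an absolute
threshold with a warning.

TEI calling collects three kinds of evidence per read: split alignments
whose query intervals are separated by ≥ 500 bp while the reference
intervals nearly abut (the small negative reference gap being the TSD);
cigar insertion operations ≥ 500 bp; and clipped tails ≥ 500 bp that
re-align to the TE library *at the breakpoint-proximal edge* (a TE merely
embedded in flanking sequence does not qualify). Secondary records that
re-map the same read stretch to sister repeat copies are removed before
pairing — without this, multi-mapping inside a repeat family fabricates
split evidence at unrelated family loci. Breakpoints cluster within 50 bp;
a call needs 3 supporting reads. Because alignment ends slide across
junctions whenever the insert boundary resembles the flank, the exact site
and TSD are recovered afterwards from the duplicated flank as it appears on
the reads themselves, constrained by the observed junction span — split
evidence alone, clip evidence from two different reads, or a mixture all
work. The reported position is the reference base immediately left of the
insertion (1-based in VCF-style output, 0-based internally). Families are
assigned at ≥ 80% identity over ≥ 80% of a library element.

`flank_check()` reduces the locus-comparison question ("is this element at
the same place in another assembly?") to two searches: the element with
2 kb flanks, and the flank-joined empty site.

## Numerical and design choices worth knowing

* Multiple-testing correction is Benjamini–Hochberg by default — the method
  is monotone and standard; the original analysis protocol names no method.
* Counting is primary-only and once-per-read; whether one read may count
  toward several elements is genuinely underdetermined by the assay, and
  once-per-read is the conservative choice.
* For read counting the mapper is run with `max_hits = 1, max_split_hits
  = 0`: secondaries are irrelevant to primary-only counting, and skipping
  their base-level alignment costs nothing measurable in accuracy (solo-LTR
  reads can hop between near-identical sister loci either way).
* The banded global aligner widens its band automatically rather than
  failing; the identity convention (gap columns in the denominator) makes
  identities comparable across indel content.
* Determinism: every stochastic step draws from R's RNG under the
  configured seed, including the compiled read-corruption loop, so a fixed
  seed reproduces every output byte-for-byte.

## Limitations

The error model is i.i.d. per base; real nanopore error is structured, and
thresholds tuned here (agreement 0.8, allele fraction 0.7) would need
re-examination on real data. eccDNA reads from elements absent from the
reference can only be decomposed in reference-free mode, which yields a
period but no structure class. The divergence caller reports substitutions
only; insertions relative to the element are folded into the alignment and
not emitted as variants. TEI detection assumes the inserted sequence is
library-recognisable; entirely novel insertions surface only through split
evidence. Replicate-aware count modelling is out of scope — the assay this
package models has one library per condition.
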