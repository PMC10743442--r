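---
title: "Detecting DGR cassettes and quantifying adenine-specific hypermutation"
author: "DGRtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting DGR cassettes and quantifying adenine-specific hypermutation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DGRtools)
```

## The biological model

A diversity-generating retroelement (DGR) is a prokaryotic/phage module that
mutagenises a defined locus of a target gene. Its cassette carries a
reverse-transcriptase (RT) gene, usually an accessory (Avd-like) gene, a
non-coding *template repeat* (TR, canonically 100–150 bp) and one or more
target genes, each containing a *variable repeat* (VR) homologous to the TR.
During retrohoming an RNA copy of the TR is reverse-transcribed with errors
confined to adenine positions, and the mutagenised cDNA overwrites the VR.
The observable signature is therefore an asymmetric divergence pattern: at
alignment columns where the TR carries A, the VR frequently differs
("A-substitutions"), while columns with a non-adenine template base are
almost always conserved; the rare exceptions ("B-substitutions", from bases
B = C/G/T) reflect ordinary background mutation, not DGR activity.

Some phage cassettes carry **two** target genes sharing one TR: a
tentaclin-like gene with the VR near its 5′ end and a second target with the
VR at its 3′ end. DGRtools detects such cassettes, quantifies the
substitution process at nucleotide, codon and amino-acid level, and provides
a conservation-profile toolkit for the conserved C-terminal Ig ("Cterm-Ig")
anchor domain that defines the tentaclin family.

## Repeat-pair detection

`findRepeatPairs()` implements a seed-and-extend scan under an
*adenine-asymmetric mismatch model*:

* **Seeds.** Exact 12-mer matches restricted to adenine-free windows of the
  putative template copy. Because the mutagenesis touches only template
  adenines, an adenine-free stretch of the TR is expected to be copied into
  the VR verbatim; a 12-mer is long enough that chance duplicates in a
  ~30–50 kb genome are rare, and short enough that a 100 bp repeat with up
  to ~10% background noise almost surely contains one clean window. For the
  minus-strand reading the same argument applies to thymine-free windows, so
  seeds free of A *or* free of T are collected. `k` is configurable.
* **Extension.** Ungapped, two-sided, scored +1 for a match, 0 for a
  mismatch that the model expects (a column involving the mutable base of
  the assumed reading strand: A for plus, T for minus) and −2 otherwise,
  with an X-drop of 20. The extension is run once per reading strand:
  scoring the union of both hypotheses at once would make the expected
  column score in unrelated sequence non-negative and extensions would
  drift arbitrarily far. Ties in the running maximum prefer the longer
  extension so that boundary columns whose mismatch is model-consistent
  stay inside the repeat. The search is ungapped by design — observed TR/VR
  alignments show substitutions only — so repeat pairs containing indels
  are not detected, and this limitation is deliberate.
* **Designation.** The copy designated TR is the one in which at least 80%
  of mismatched columns carry an adenine (in the chosen reading). The
  threshold is a design decision: the mechanism itself only dictates that
  *template adenines* mutate, and 80% tolerates a few background changes
  while rejecting VR–VR pairs (two VRs of one cassette resemble each other,
  but their mismatches scatter over both copies and neither reaches 80%).
  Identical copies cannot be designated and are reported with the leftmost
  copy as TR, only when `minASub = 0` permits reporting them at all.
* **Filters.** Reported pairs must have length within `[minLen, maxLen]`
  (default 100–150 bp), a B-substitution fraction of at most 10%, and at
  least `minASub = 3` A-substitutions. Overlapping candidates are merged
  keeping the highest-scoring extension. Direct and inverted orientations
  are both scanned.

`assembleCassettes()` groups pairs whose TR intervals reciprocally overlap
by ≥ 90% into one cassette (this is how a dual-target cassette with a
full-length VR1 and a shorter VR2 is recognised as a single unit), assigns
each VR the annotated ORF that fully contains it (longest on ties),
classifies the VR position by the thirds of the ORF (5′/3′/internal, by VR
midpoint), computes the reading-frame offset of the VR within its ORF, and
attaches the RT and accessory ORFs by annotation label within 5 kb of the
TR. RT identification deliberately relies on user annotation labels rather
than a homology search, which would require an external profile database.

## Hypermutation profiling

`alignTrVr()` pairs equal-length repeats positionally; when the VR is
shorter (or longer), the shorter sequence is placed semi-globally inside
the longer one (match +1, mismatch at a template adenine 0, other mismatch
−2, gap −4) and only overlap columns are analysed. Columns are classed
`match`, `A_sub` (TR = A, VR differs), `B_sub` (TR ∈ {C,G,T}, VR differs)
or `ambiguous` (N or gap on either side); ambiguous columns are excluded
from all substitution counts.

`substitutionProfile()` translates template and variable repeat over the
codon grid inherited from the VR's placement in its target ORF (the TR
itself is non-coding; its "reading frame" is defined by the target).
Codons only partially covered by the aligned span, and codons containing an
ambiguous column, are skipped. An amino-acid substitution is counted
per position where the two translations differ; each is labelled with
whether adenine substitutions alone explain it (`adenine_only`), so both
the total and the adenine-only subtotal are available. Substituted residues
are placed into six disjoint physicochemical categories (aromatic F/W/Y;
negative D/E; positive K/R/H; cysteine; hydrophobic non-aromatic
A/V/L/I/M/P/G; hydrophilic uncharged S/T/N/Q). Histidine is counted as
positively charged, not aromatic, to keep the partition disjoint; the
choice is configurable in reporting because conventions differ.

Two codon-level summaries matter for the biology:

* `achievableResidues()` enumerates every codon reachable from a template
  codon by substituting its adenines independently with any base. For the
  Asn codons AAC and AAT — template adenines cluster in such pairs — the
  repertoire is 15 residues; Gln, Met, Lys, Glu and Trp are unreachable.
* `codonPositionBias()` aggregates A→C/G/T counts at codon positions 1
  and 2 of template AAC/AAT codons, exposing the observed asymmetry by
  which the second adenine of AAC rarely becomes cytosine.

`compareVrPair()` reports, for every template adenine covered by both VRs
of one cassette, the base observed in each VR, summarising how often the
two targets mutated the same position (and to the same base) — the question
of whether the two targets sample hypermutation independently.

## Conservation profiles for the Cterm-Ig signature

`buildProfile()` computes per-column residue frequencies over an aligned
domain set and calls conserved columns at a threshold (default 1.0, i.e.
invariant columns). The module is generic — the profile is learned from a
user-supplied alignment rather than hard-coded — because the family
signature is a property of whichever sequence set the user curates.
`scanProtein()` slides the profile ungapped over the last 100 residues of a
protein (the anchor domain sits at the C-terminus); a protein carries the
signature iff some offset matches every conserved column exactly. Offsets
are also scored by mean per-column log-odds against a uniform background
with a small additive pseudocount (0.01) so that residues unseen in the
profile stay finite. Multiple sequence alignment of the domain set itself
is out of scope; any standard aligner's output is accepted as input.

## The forward simulator

`simulateGenome()` emits a linear genome (default 30 kb, valid range
20–50 kb) with the full cassette layout on the plus strand: marker ORFs
(large terminase subunit, portal protein), an RT ORF, an accessory ORF, a
non-coding TR, a tentaclin-like target1 whose VR sits in the first third of
the ORF, and a target2 with a 5′-trimmed VR in the last third. Defaults
were chosen to match the observed cassettes: TR of 120 bp with 12 adenine
pairs laid out as AAC/AAT codons in the target frame (24 adenines; the
`nd4like` preset uses AAC only, `nd12like` uses a 126 bp TR with 14 mixed
pairs), a per-adenine substitution probability `pSub`, uniform replacement
weights over C/G/T (optionally per codon position — the real distribution
is not quantified, so it is exposed as a free parameter), zero background
rate by default, and `vr2TrimCodons = 3` so VR2 covers fewer template
adenines, as real second targets do, while keeping the ≥ 90% TR-overlap
grouping rule satisfiable.

Two generator choices make ground truth well defined:

* **Sharp boundaries.** The TR is flanked by GGG-GGG and each VR by
  CCC-CCC codon pairs, so every repeat edge abuts six adenine-free
  mismatching columns. Without this, the "true" repeat interval would be
  ill-posed whenever flanking bases matched by chance, and interval-exact
  validation would be meaningless.
* **A seedable window.** The adenine-pair layout is rejection-sampled so
  that at least one run of five adenine-free codons lies clear of the VR2
  trim, guaranteeing each repeat contains an exact adenine-free 12-mer.
  Real TRs concentrate their adenines in the hairpin-coding stretch and
  retain conserved runs, so this mirrors, rather than idealises, the data.

Stop codons cannot arise from adenine substitution inside AAC/AAT codons,
but background mutation can create them; with `forbidStop` each offending
codon is resampled (up to 100 attempts, then reverted), reflecting that
functional target proteins survive selection. Every simulation is
deterministic given its seed, records a `SimulationTruth` object (intervals,
per-position substitutions, amino-acid changes, ORF coordinates), and
restores the caller's RNG state. `expectedSpectrum()` provides the
closed-form companion: A-substitution counts are Binomial(covered adenines,
`pSub`) and background counts Binomial(covered non-adenine sites,
`qBackground`).

What the simulator does *not* emulate: indels between TR and VR, multiple
retrohoming generations or selection dynamics, cassettes split across
contigs, GC-content heterogeneity, and sequencing error. Tests passing on
simulated genomes therefore demonstrate correctness of the detection and
profiling algorithms under the substitution-only model, not robustness to
assembly artefacts in real metagenomes.

## Numerical and interface conventions

* Coordinates are 1-based inclusive everywhere (the GenBank and
  Bioconductor convention), including internal interval arithmetic.
* The genetic code defaults to table 11 (bacterial/archaeal/plant-plastid),
  appropriate for gut phages, and is configurable throughout.
* `pairwiseIdentity()` uses global Needleman–Wunsch (+1/−1 for nucleotides,
  BLOSUM62 for proteins; gap opening 10, extension 0.5) and defines
  identity as identical columns over the full alignment length including
  gap columns. Published identity values computed with other tools use
  unstated conventions, so this definition is fixed and documented rather
  than tuned to reproduce any particular printed number. Arguments are
  ordered canonically before alignment, making the value exactly symmetric
  even when co-optimal alignments exist.
* ORF calling reports complete ORFs only (start codon ATG/GTG/TTG, first
  start after the previous in-frame stop, terminating stop required).
* Ambiguous bases (N) are tolerated in genomes; any alignment column
  containing N is classed ambiguous and excluded from substitution counts.
* Ties in detection (identical-copy designation, equal-scoring extensions)
  resolve toward the leftmost/longer alternative deterministically.

## Validation strategy and problem sizes

The test suite validates each algorithm against an independent oracle:
exhaustive enumeration for the codon repertoire (all 64 codons),
a brute-force 6-frame scan for ORF calling (100 random 1 kb genomes), and
quadratic-space dynamic-programming references for the global and
semi-global alignments (100 random pairs; scores are compared, since
co-optimal alignments may differ in layout). Pipeline closure is checked on
50 simulated dual-target genomes (seeds 0–49, `pSub = 0.5`, zero
background): detection, assembly and profiling must reproduce the recorded
truth — intervals, substitution counts and amino-acid lists — exactly in at
least 49 of 50. Monte-Carlo consistency uses 1000 draws of the mutation
kernel against the closed-form binomial moments at three standard
deviations of the mean. Conservation-profile recovery plants seven
invariant columns among 29 random sequences (the probability of a chance
monomorphic column, 20 × 20^−29 per column, makes false positives
negligible) and calibrates the null scan rate over 10,000 random proteins
against its binomial expectation. These sizes keep the whole suite under a
minute while leaving the statistical bands far from their thresholds.

## A worked run

```{r example, eval = FALSE}
sim <- simulateGenome(simulationParams(preset = "nd4like", seed = 42))
pairs <- findRepeatPairs(sim$genome)
cassettes <- assembleCassettes(sim$genome, pairs, sim$orfs)
cassettes[[1]]

tr <- cassetteTR(cassettes[[1]])
tg <- cassetteTargets(cassettes[[1]])
trSeq <- substr(genomeSeq(sim$genome), GenomicRanges::start(tr),
                GenomicRanges::end(tr))
vrSeq <- substr(genomeSeq(sim$genome), tg$vr_start[1], tg$vr_end[1])
prof <- substitutionProfile(alignTrVr(trSeq, vrSeq))
prof
codonPositionBias(prof)
```

The same flow, end to end with TSV/JSON reports, is `runPipeline()`; a thin
command-line wrapper lives at `system.file("scripts", "dgr.R",
package = "DGRtools")`.

## Known limitations

* Indel-containing repeat pairs are invisible to the ungapped detector.
* RT/Avd assignment requires annotation labels; unannotated genomes yield
  cassettes with `rt = "unassigned"`.
* The detector reports the maximal model-consistent repeat; when flanking
  sequence happens to extend the repeat pattern (e.g. complementary flanks
  around an inverted copy), the reported interval can exceed the
  biologically "intended" one — boundaries are only as sharp as the data.
* Published identity percentages from other alignment tools are treated as
  non-binding references; only this package's own stated convention is
  reproduced.
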