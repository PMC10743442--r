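# DGRtools

Detection and hypermutation analysis of diversity-generating retroelements
(DGRs) in phage and prophage genomes.

DGRs mutagenise a defined locus of a target gene: an RNA copy of a
non-coding **template repeat** (TR, ~100–150 bp) is reverse-transcribed
with errors confined to **adenine** positions, and the mutated cDNA
overwrites the homologous **variable repeat** (VR) inside the target gene
(retrohoming). Some phage cassettes drive *two* target genes from one TR —
a tentaclin-like receptor-binding protein with its VR near the 5′ end of
the gene, and a second target with the VR at the 3′ end. DGRtools is for
researchers who want to find such cassettes in assembled genomes and
quantify the mutagenesis they record.

The package provides:

* **Detection** — `findRepeatPairs()`: seed-and-extend scan for TR/VR
  pairs under an adenine-asymmetric mismatch model (exact adenine-free
  k-mer seeds; extension scores match +1, mismatch-at-template-adenine 0,
  other mismatch −2; the copy with ≥ 80% of mismatches at adenines is the
  TR). `assembleCassettes()` groups pairs sharing a TR into (possibly
  dual-target) cassettes with RT/accessory ORF assignment.
* **Hypermutation profiling** — `alignTrVr()` classifies each column as
  `match`, `A_sub` (TR = A, VR differs — the DGR signal), `B_sub`
  (background) or `ambiguous`; `substitutionProfile()` adds codon- and
  amino-acid-level spectra with physicochemical categories;
  `achievableResidues()` enumerates the residue repertoire reachable from
  a codon by adenine substitution; `codonPositionBias()` measures the
  A→C asymmetry between positions 1 and 2 of AAC/AAT template codons;
  `compareVrPair()` asks whether two VRs of one cassette mutated the same
  positions.
* **Conservation profiles** — `buildProfile()` / `scanProtein()` for the
  invariant-column signature of the tentaclin C-terminal Ig anchor domain
  (scanned over the last 100 residues of a protein).
* **A forward simulator** — `simulateGenome()` emits 20–50 kb genomes with
  a full DGR cassette and a ground-truth record of every substitution, so
  the whole pipeline is testable without downloads; `expectedSpectrum()`
  is its closed-form binomial companion.
* **I/O and plumbing** — FASTA and GenBank flat-file readers, six-frame
  ORF calling, translation (genetic code table 11 by default), global
  pairwise identity, and `runPipeline()` writing TSV/JSON reports. A thin
  CLI lives at `inst/scripts/dgr.R`.

## Worked example

```r
library(DGRtools)

sim <- simulateGenome(simulationParams(preset = "nd4like", seed = 42))
pairs <- findRepeatPairs(sim$genome)
cassettes <- assembleCassettes(sim$genome, pairs, sim$orfs)
cassettes[[1]]
#> DgrCassette in 'sim_seed42': TR 4718-4837 (+), 2 target(s); RT assigned
#>   target 1: VR 5266-5385 (+), five_prime, frame 0, A-sub 10, B-sub 0
#>   target 2: VR 6962-7072 (+), three_prime, frame 0, A-sub 7, B-sub 0
```

One cassette: a 120 bp TR whose two VRs sit in the 5′ third of target1 and
the 3′ third of target2, with 10 and 7 adenine substitutions and no
background ("B") substitutions. Profiling the first target:

```r
tr <- cassetteTR(cassettes[[1]]); tg <- cassetteTargets(cassettes[[1]])
trSeq <- substr(genomeSeq(sim$genome), GenomicRanges::start(tr), GenomicRanges::end(tr))
vrSeq <- substr(genomeSeq(sim$genome), tg$vr_start[1], tg$vr_end[1])
prof <- substitutionProfile(alignTrVr(trSeq, vrSeq))
prof
#> SubstitutionProfile: 10 A-substitutions (24/24 TR adenines covered),
#>   0 B-substitutions, 8 aa substitution(s)
#>   categories: aromatic=1, negative=1, hydrophobic_nonaromatic=4, hydrophilic_uncharged=2

head(aaSubstitutions(prof)[, c("codon_index", "tr_codon", "vr_codon", "aa_tr", "aa_vr")])
#>   codon_index tr_codon vr_codon aa_tr aa_vr
#> 1           7      AAC      GAC     N     D
#> 2           9      AAC      AGC     N     S
#> 3          12      AAC      GGC     N     G
#> ...
```

All 24 template adenines are covered by VR1; 10 were substituted, changing
8 residues (every one an Asn replaced, since template adenines sit in
AAC codon pairs). The reachable repertoire of such codons:

```r
achievableResidues("AAC")
#>  [1] "A" "C" "D" "F" "G" "H" "I" "L" "N" "P" "R" "S" "T" "V" "Y"
```

15 residues — adenine-restricted mutagenesis can never produce Gln, Met,
Lys, Glu or Trp from an AAC/AAT codon.

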