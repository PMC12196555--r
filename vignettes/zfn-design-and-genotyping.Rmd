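---
title: "Designing, screening and genotyping zinc-finger nucleases with ZFNtools"
author: "ZFNtools authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing, screening and genotyping zinc-finger nucleases with ZFNtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ZFNtools)
```

## Scope and model

A zinc-finger nuclease (ZFN) is a chimeric enzyme: a three-finger
zinc-finger protein (ZFP) array that reads a 9-bp *half-site* (3 bp per
finger), fused to the FokI nuclease domain. FokI cuts only as a dimer, so a
cleavable target consists of two half-sites on opposite strands in
tail-to-tail orientation, separated by a *spacer* of a few unread
nucleotides over which the two FokI domains meet. Repair of the resulting
double-strand break by non-homologous end joining (NHEJ) is error-prone and
leaves small insertions, deletions, substitutions and mixed (complex)
changes around the cut.

ZFNtools covers the three computational stages of such an experiment in a
plant (or any diploid) gene:

1. **Design** (`selectHalfSitePairs()`, `assembleZfp()`,
   `reverseTranslateOptimize()`, `designZfnPair()`): find paired 9-bp
   half-sites on a coding sequence, assemble the ZFP amino-acid sequences
   from a recognition-helix table, and produce codon-optimised DNA for
   synthesis.
2. **Off-target screening** (`enumeratePatterns()`, `scanGenome()`):
   enumerate every composite pattern the pair could cleave and scan a
   genome on both strands with a mismatch budget.
3. **Genotyping** (`genotypeClones()`, `summarizeSpectrum()`): call edits
   in amplicon clone sequences against the reference CDS, classify their
   protein-level consequence and summarise the mutation spectrum.

A deterministic fixture module (`makeSyntheticGenome()`,
`makeMutantClones()`) generates inputs with machine-readable truth tables;
it is how the test suite validates every stage end to end.

## Coordinates and codon arithmetic

CDS positions are 1-based and inclusive, with the A of the start ATG at
position 1; nucleotide $p$ lies in codon $\lceil p/3 \rceil$. Genomic
intervals follow the Bioconductor convention (1-based inclusive in R,
converted to 0-based half-open only at the BED boundary by rtracklayer;
GFF3 input is 1-based inclusive). These choices reproduce standard
published arithmetic of the form "position 692 is codon 231" and "position
524 lies 165 nt upstream of a window starting at 689" exactly:

```{r}
cdsPositionToCodon(c(692, 524))
distanceToWindow(c(524, 769), c(689, 713))
```

For a frameshifting edit there is no universally agreed residue number: the
codon containing the first changed nucleotide is already corrupted, but
reports often cite the last unaffected residue. Rather than guessing a
convention, `classifyConsequence()` reports **both** `last_intact_codon`
(complete codons strictly before the first edited base) and
`first_affected_codon`.

When a gene has several predicted isoforms, an edit should hit all of them.
`findSharedExons()` declares an exon shared only when an **identical**
genomic interval occurs in every isoform — structural identity, not mere
overlap — because an overlap-tolerant rule would admit exons whose
alternative boundaries change the reading frame in some isoforms.
`cdsWindowsFromSharedExons()` maps shared exons to CDS windows assuming the
anchor isoform's CDS is the concatenation of its exons in transcription
order; genes with UTR-containing exon structures need explicit CDS features
and are outside this toy mapping.

## The assembly grammar

A three-finger array is assembled from constants and the three 7-residue
recognition helices:

```
N-terminus  LEPGEKP
finger_i    YKCPECGKSFS + helix_i + HQRTH
linker      TGEKP            (between consecutive fingers)
C-terminus  TGKKTS
```

giving $7 + 3(11+7+5) + 2\cdot5 + 6 = 92$ residues for every three-finger
array — a structural invariant the tests enforce. The seeded helix table
covers the six triplets of the reference half-site pair
(5'-GCTCTACCC-3' / 5'-AGGACGCTT-3'); further triplet assignments are
supplied as a two-column file, not predicted: helix prediction for novel
triplets is deliberately out of scope.

**Finger order.** Structurally, finger F1 of an array contacts the 3'-most
triplet of its bound strand (the antiparallel convention), but design
listings sometimes enumerate helices 5' to 3'. Both appear in practice, and
published tables are not always internally consistent — the reference
design this package reproduces lists the left array 5'→3' (GCT, CTA, CCC)
and the right array 3'→5' (CTT, ACG, AGG). `assembleZfp()` therefore takes
an explicit `fingerOrder` argument (`"five_prime"` / `"three_prime"`), and
`designZfnPair()` defaults to `five_prime` for the left and `three_prime`
for the right array to match that listing; both are overridable. The choice
permutes helices within the array; it never changes length or constants.

A related inconsistency worth knowing about: a design figure may print the
left ZFN's bottom-strand binding sequence, which should be the reverse
complement of the left half-site but in our reference is not
(5'-CCCATCTCG-3' vs 5'-GCTCTACCC-3'). The methods-table half-sites are
treated as authoritative throughout.

## Codon optimisation

Coding sequences for synthesis are produced by reverse translation
optimised under the **Codon Adaptation Index** (CAI, Sharp & Li): each
codon's relative adaptiveness is $w = f / \max f_{\text{synonymous}}$ and
CAI is the geometric mean of $w$ over the coding sequence, excluding the
single-codon amino acids Met and Trp (their $w$ is identically 1 and would
only dilute the index). Codons missing from a user-supplied usage table get
a 0.5 pseudo-count before $w$ is formed, so $w$ is never 0 and the
geometric mean is well defined; CAI is invariant to the table's scale
(counts, fractions or per-thousand all work).

The optimiser is greedy-with-repair: take the maximum-$w$ codon at every
position, then scan the construct (`flank5 + coding + flank3`) for
forbidden motifs on either strand, and for each violation overlapping the
coding region re-choose the overlapping codons (widening by one codon if
needed), preferring the highest-CAI motif-free combination with
alphabetical tie-breaks. The procedure is deterministic and auditable, and
on short proteins it provably reaches the exhaustive optimum (the test
suite checks equality against full enumeration for proteins up to 4
residues). The default forbidden motifs are the XbaI (TCTAGA) and BamHI
(GGATCC) sites, which also serve as the default flanks — the construct can
then be subcloned by XbaI/BamHI digestion without internal re-cutting.
Occurrences lying entirely inside a flank are the cloning sites themselves
and are allowed; occurrences overlapping the coding region, including ones
spanning a flank/coding junction, are repaired. mRNA-stability optimisation
beyond codon bias (secondary structure, motif content) is not modelled: no
reproducible procedure exists for it at this scale, and CAI is the stated
criterion.

The packaged `syntheticCodonUsage()` table is **synthetic** (geometrically
decaying usage within each synonymous family, alphabetical order); it
exists so that examples and tests are self-contained, and any real
organism table supplied via `readCodonUsage()` should be used for actual
designs.

## Off-target pattern enumeration

A screening pipeline that works by exact text matching needs explicit
pattern strings. Patterns are composites `a + N^s + b`, where `a` and `b`
are oriented copies of the half-sites and the `N` run is the spacer
(unread, hence fully degenerate). The default scheme enumerates every
ordered heterodimeric pairing of the two half-sites in either orientation
— $\{L, \mathrm{rc}(L)\} \times \{R, \mathrm{rc}(R)\}$ in both orders,
8 arrangements — times spacer lengths 4–10 nt, giving $8 \times 7 = 56$
distinct patterns for two distinct non-palindromic half-sites:

```{r}
pats <- enumeratePatterns("GCTCTACCC", "AGGACGCTT")
nrow(pats)
head(as.data.frame(pats), 3)
```

This set contains the FokI-cleavable tail-to-tail composite
(`rc(L) + N^s + R`) and its bottom-strand image, plus every other
orientation pairing an exhaustive single-strand text screen would
enumerate; screening is deliberately conservative, since the cost of a
false pattern is only scan time. Note that tail-to-tail composites alone
cannot yield 56: they are closed under reverse complement
($\mathrm{rc}(\mathrm{comp}(A,B)) = \mathrm{comp}(B,A)$, homodimeric
composites being self-complementary), so deduplication would collapse them
to $4 \times 7 = 28$. Homodimeric pairings (a half-site with itself, the
geometry of unwanted single-ZFN cutting) are available with
`includeHomodimers = TRUE`.

`scanGenome()` matches every pattern on both strands of every contig.
Mismatches are counted **only over the 18 half-site positions**; spacer Ns
match anything, and an ambiguous genome base (N) never matches a half-site
position — conservative in the direction that matters for screening. All
matches within the budget are reported, overlapping ones included (no
greedy consumption: screening must be exhaustive), in top-strand
coordinates. Divergence from the intended site is expressed as
`variationPercent()` = $100 m / 18$; budgets of 2–8 mismatches correspond
to the 11–44% variation band typically screened. Candidate windows are
located with `Biostrings::matchPattern()` and re-scored exactly by the
package's own counting rule, so Biostrings' liberal ambiguity matching can
only propose windows, never admit them. Context for primer design is
reported as separate upstream/downstream flanks (default 100 nt each, 200
nt combined) plus the match, with a `truncated` flag at contig edges —
separating the pieces removes the ambiguity of whether a "200 bp region"
includes the match itself. Gapped (alignment-based) off-target search and
cleavage-likelihood scoring are non-goals; hits carry enough context for
external verification with BLAST or similar.

## Genotyping model

Each clone is aligned globally to the reference CDS (Needleman–Wunsch with
affine gaps via `Biostrings::pairwiseAlignment`; defaults match 2,
mismatch −1, gap open −4, gap extend −1 — conventional for short, highly
similar amplicons; scores are verified against an independent dynamic
programming oracle in the tests). Maximal runs of difference columns become
calls:

* isolated substitution → **SNV**;
* pure gap run → **insertion**/**deletion**, left-aligned within
  homopolymer/repeat context (VCF-style normalisation, so identical
  mutations always yield identical calls regardless of where the aligner
  placed the gap);
* anything mixed (or a multi-nucleotide substitution run) → **complex**.

Applying the calls back to the reference reconstructs the clone exactly — a
round-trip property tested on hundreds of random clones. Consequence
classification translates both sequences: a stop codon appearing before the
original terminus is **loss-of-function**; otherwise net indel length
$\not\equiv 0 \pmod 3$ is a **frameshift** (this equivalence is itself a
tested invariant); then in-frame indel, missense (with `231A>V`-style
notation for single-codon changes) or synonymous. Frameshift and
loss-of-function are overlapping annotations over a clone set, not spectrum
categories.

`summarizeSpectrum()` reports SNV/indel/complex proportions. Published
spectra of this kind are usually proportions **per sequence**, but "most
frequent mutation type" is ambiguous between per-sequence and per-mutation
counting, so both are implemented (`counting =` `"per_sequence"`, with
category precedence complex > indel > SNV within a clone, or
`"per_mutation"`). Percent identity to the reference counts gap columns in
the denominator by default (the conservative reading of "similarity of
coding sequences"); `countGaps = FALSE` restricts to gap-free columns.

## What the synthetic fixtures emulate — and what they do not

`makeSyntheticGenome()` draws a uniform-composition background and writes
composite sites at fixed offsets, with exact control of half-site
corruptions; for composites of ≥ 20 informative positions, chance
background hits are negligible at the 10-kb scale used in tests, so truth
tables are exact. Uniform composition is the simplest null for
false-positive analysis; real genomes have GC skew and repeats, so a clean
scan of a fixture does not bound the hit count on a real genome — it
validates the scanner's correctness, not a genome's cleanliness.

`makeMutantClones()` gives each clone one primary edit drawn from
configurable category proportions, at a position uniform over configurable
CDS windows. The defaults are anchored to a published ZFN mutagenesis
cohort in tomato: 51.5% SNV / 39.4% indel / 9.1% complex, with edits placed
in the nuclease window (CDS 689–713) and a downstream repair hotspot
(873–935); indel lengths default to 1–3 nt with decaying probability
(0.6/0.25/0.15), the short-indel regime characteristic of NHEJ. Those
anchor percentages come from a cohort of >90 clone sequences that were
never deposited, so they are generator defaults to be recovered within
sampling error — never values the package claims to reproduce exactly; the
same applies to that study's 86.9–98.21% identity range. The generator
makes one edit per clone by default to keep truth consequences unambiguous,
and does not simulate sequencing error, chromatograms or heterozygous
mixtures.

With $n = 500$ clones the binomial standard error on a 50% category is
$\approx 2.2$ points, so the test suite's ±4-point recovery band is a
\~1.8-SE check under its fixed seed.

## Numerical and degenerate-input choices

* Deterministic everywhere: generators take explicit seeds; the optimiser
  breaks ties alphabetically; hits sort by (contig, start, strand,
  pattern id); candidate sites by (offset, spacer).
* `computeCai()` on a sequence consisting only of Met/Trp codons returns 1
  (empty geometric mean is neutral); internal stops are an error, a single
  terminal stop codon is ignored.
* Alignment tie-breaks among equal-score alignments follow
  Biostrings' deterministic traceback; calls are then normalised by
  left-alignment, so call tables are stable across equivalent alignments
  in repeat context.
* An empty scan result is a valid empty BED file, not an error; a pattern
  longer than every contig yields no hits.
* Problem sizes in the shipped tests — fixture genomes of 1–10 kb, clone
  cohorts of up to 500 on a ~1 kb CDS — were chosen so the whole validation
  suite reflects desk-scale analysis; the same code paths scale linearly
  for chromosome-scale scans.

## Known limitations

* No binding-affinity or specificity model: a candidate site is one whose
  triplets are covered by the helix table, nothing more.
* The shared-exon → CDS-window mapping assumes the anchor isoform's CDS is
  exactly its exon concatenation (no UTRs in the supplied exon intervals).
* Off-target scanning is ungapped; a bulged off-target site will be
  missed.
* Genotyping assumes clonal (single-haplotype) amplicon sequences; mixed
  traces must be resolved upstream.
* The 2^−ΔΔCt utility applies no amplification-efficiency correction, by
  design.
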