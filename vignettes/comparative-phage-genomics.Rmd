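---
title: "Comparative phage genomics with phageMosaic: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative phage genomics with phageMosaic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phageMosaic)
```

# Scope

phageMosaic reimplements, as a tested pipeline, the comparative-genomic
inferences used to characterize clusters of closely related temperate
phages: genome relatedness (fragment ANI and shared-gene phamilies),
discovery and classification of mobile intervening elements (group I
introns, inteins, transposons with target-site duplications,
free-standing homing endonucleases), attP/attB integration-site
discovery, and icosahedral capsid stoichiometry. Because the real
deposited genomes cannot ship with a package, every inference is
exercised end-to-end on synthetic genomes carrying planted elements with
a machine-readable truth log.

This vignette explains the models, the tunable parameters and why their
defaults are what they are, the synthetic-data generator's design, and
the numerical choices made where the methods were genuinely open.

# Genome relatedness

## Fragment ANI

Average nucleotide identity is computed with a Goris-style fragment
dialect: the query genome is cut into consecutive, non-overlapping 1 kb
fragments; each fragment's best Smith–Waterman alignment (match +2,
mismatch −3, gap open −5, extend −2) against the other genome is
retained when it reaches at least 70% identity over at least 70% of the
fragment length; the direction value is the mean identity of retained
fragments, and the reported ANI is the mean of the two directions — so
`ani(a, b) == ani(b, a)` exactly, by construction. The best local hit is
located by shared 13-mer diagonal voting before alignment; for genomes
in the 0.8–1.0 identity range this band always contains the true
optimum. On synthetic pairs the measured ANI tracks the planted per-site
identity to within ~0.001–0.002; the package's acceptance tolerance of
±0.015 leaves room for edge-trimming bias at the distant end of the
range.

Identity of a local alignment is identical pairs over alignment
columns. For *global protein* alignments (Needleman–Wunsch, BLOSUM62,
gap open 11, extend 1) identity is identical pairs over the *shorter*
sequence length, which keeps the quoted identity of two homologs stable
when one carries an intein or a terminal extension.

## Phamilies

Proteins are sorted into phamilies ("phams") by single-linkage
clustering: an edge joins two proteins when global identity ≥ 0.325
**or** the local-alignment E-value ≤ 1e-50 (both thresholds inclusive;
the E-value threshold is stated as "or less" in the field's convention,
and the identity threshold is made inclusive by symmetry). Components of
the edge graph are phams; isolated proteins are orphams. E-values use
Karlin–Altschul statistics with the standard gapped BLOSUM62 11/1
constants (λ = 0.267, K = 0.041); the nucleotide local-alignment E-value
uses fixed ungapped constants (λ = 1.28, K = 0.46). The thresholds are
so extreme that the exact constants cannot flip a classification outside
a negligible boundary band.

Pairs are pre-screened with a shared 4-residue word requirement before
alignment — the seed heuristic of BLAST-style search. Pham ids are
assigned by each component's lexicographically smallest (genome, gene)
member so output is stable across runs. Shared-gene counts are
directional (a paralog pair in one genome matching a single gene in the
other counts twice from one side, once from the other); this asymmetry
is intentional and tested.

# Mobile-element detection

## Finding insertions

Two related genomes are compared by chaining unique shared 15-mers into
a collinear backbone (longest increasing subsequence on reference
positions). An anchor gap where the carrier advances substantially more
than the reference is refined under a single-event model: the carrier
window is prefix + element + suffix, the reference window is prefix +
lost-target (d bases) + suffix, with the flanks differing only by point
substitutions. The junction and the target-loss d are chosen to minimize
flank mismatches plus a penalty of half a mismatch per deleted target
base; ties prefer smaller d, then the larger junction offset. Boundaries
are then left-normalized (shifted to the smallest start compatible with
the flanking repeat, the VCF indel convention), and the reference bases
absent from the carrier are recorded as evidence.

Two deliberate deviations from the simplest formulation:

* The reference is allowed to advance up to `max_ref_gap = 50` bp at the
  target rather than ~10 bp, because deletion-associated endonuclease
  acquisitions (tens of bases lost from the target) must be reported as
  insertions with evidence, not silently dropped.
* Refinement is mismatch-tolerant rather than extending exact matches
  inward from the anchors; exact extension truncates at the first
  substitution near a junction and cannot deliver exact boundaries on
  diverged pairs.

The λ = 0.5 deletion penalty sits between the expected mismatch rate of
homologous flanks (a few percent up to ~20% in the supported range) and
that of unrelated sequence (~75%), so the inferred d is driven by the
real signal on both sides of the junction.

## Classifying insertions

Evidence is computed for every call — splice restoration, protein-level
intein comparison, target-site-duplication search, internal ORFs, target
reconstruction — and combined with fixed precedence:

1. **intron**: inside a CDS, disrupts its reading frame (length not a
   multiple of 3, or an in-frame stop), and some excision within ±10 bp
   of the call fuses the exons into a protein with ≥ 0.8 identity to the
   best reference homolog at the reference protein's exact length.
2. **intein**: an in-frame CDS insertion (frame intact, no stop) whose
   translated product carries an internal run of ≥ 100 residues aligned
   to gaps in the intein-less homolog.
3. **transposon**: a ≥ 2 bp target-site duplication flanks the element
   and it encodes an ORF of ≥ 200 aa (transposase-sized).
4. **endonuclease**: any remaining element with an ORF ≥ 100 aa
   (free-standing homing endonucleases are typically 150–250 aa).

The frame-disruption requirement in rule 1 is a deliberate addition: an
in-frame intein insertion trivially admits a perfect DNA-level "splice",
so without it every intein would be called an intron. Biologically the
distinction is exactly frame integrity — introns break the reading
frame and are repaired at the RNA level; inteins keep it and are excised
at the protein level.

Splice-candidate selection scores each in-frame, stop-free excision by
junction-anchored matches divided by the *longer* of the candidate and
reference lengths; dividing by the shorter length (the package-wide
identity definition, reported for the winner) would let a truncating
excision outscore the full-length restoration. Ties prefer candidates
with both group I hallmarks (exon 1 ending U/T, intron ending G), then
exact length match, then the leftmost excision. A fusion with an
internal stop codon is never scored, so a restored identity above zero
always corresponds to a translatable product.

The TSD search tries duplication lengths d from 15 down to 1 over the
placement family a length-d duplication generates within its repeat
(0..d bases right of the left-normalized call start), requiring
identical d-mers flanking the element, string-equivalence of the
excision with the original call, and exactly one copy of the word at the
reference junction. The rule is defined on strings, so content
coincidences (e.g. a planted 5-mer duplication whose element happens to
continue like the reference) genuinely extend the duplication; the
generator forbids such coincidences when planting so truth stays unique.

`LAGLIDADG` as a literal substring is the only motif test anywhere;
"HNH endonuclease" calling is structural (ORF size and context), not
profile-based.

## In-silico PCR

Primer sites allow ≤ 2 mismatches with an exact 3'-terminal 5-mer;
products run between primer 5' ends inclusive. When a splice interval is
supplied the product of the spliced template is also reported, shorter
by the excised interval length — the arithmetic used to predict the
size difference between genomic and cDNA amplicons across an intron.

# Integration sites

The attP/attB common core is the longest exact substring (both strands)
shared between the 1 kb window downstream of the integrase 3' end and
the host chromosome. The 1 kb window is a safe envelope around the
~100 bp spacing expected between the integrase stop and the core;
`min_core = 25` makes a chance hit against a multi-megabase host
vanishingly unlikely (expected longest random match ≈ log₄(n·m) ≈ 16 bp
at phage × host scale) while comfortably admitting real 40–50 bp cores.
Overlap with an annotated host tRNA is reported but never required.

Arm-type integrase-binding sites follow the degenerate 10-mer consensus
`TGCATACg/tPuPy`: the five conserved positions (2,3,5,6,7 = G,C,T,A,C)
are mandatory, and at most one violation is allowed by default among the
scored positions (1 = T, 4 = A, 8 ∈ {G,T}, 9 ∈ {A,G}, 10 ∈ {C,T}).
The consensus gives no numeric matrix, so mismatch counting over the
non-conserved positions is this package's scheme. The two direct hits
nearest the core on each side are named P1, P2 (left, in left-to-right
order) and P3, P4 (right) — naming is positional because binding order
is not observable from sequence.

attL/attR junctions are host-left + core + phage-right and phage-left +
core + host-right with 200 bp of context, orientation-normalized when
the host carries the core on the minus strand. The integration-vector
fragment spans integrase start − margin through core end + margin
(default margin 300 bp), the segment an integration-proficient plasmid
needs.

# Capsid stoichiometry

An icosahedral lattice with indices (h, k) has triangulation number
T = h² + hk + k² and 60T subunits (12 pentamers, the rest hexamers). In
tailed phages one pentameric vertex is replaced by the portal, so the
virion carries 60T − 5 copies of the major capsid subunit — for T = 13,
775 copies. The −5 portal correction is stated explicitly because the
copy number is usually quoted without its derivation. T alone does not
fix handedness: T = 13 admits the chiral classes (3,1) and (1,3), and
reports list both.

# The synthetic-data generator

The generator is first-class, tested code; it defines the conditions
under which detection is validated.

* **Ancestor**: i.i.d. background at 61% GC (the GC range of high-GC
  actinobacteriophages), a gene grid alternating stop-free CDSs
  (Normal(900, 180) bp, floored to a codon multiple, min 150 bp) and
  1–100 bp intergenic gaps, with genes in alternating strand blocks of
  3–8 to mimic leftwards/rightwards operon layout. Removing stop codons
  from coding sequence raises realized GC by under 0.01.
* **Evolution**: per-site substitutions and Poisson indels with
  geometric sizes. Substitutions that would create an in-frame stop (or
  destroy a terminal stop) in a CDS are redrawn — neutral simulation
  with selection against nonsense — so orthologous proteins stay
  full-length and protein-level ground truth is well defined. Indels
  stay 10 bp clear of CDS boundaries and are coerced to codon multiples
  inside CDSs, for the same reason. No codon model, no selection beyond
  nonsense suppression, no recombination: the process reproduces
  divergence *levels*, not mechanisms, and is labeled a stand-in.
* **Cohort** (`cluster_j_like`): six ~110 kb descendants of one ancestor
  on a star phylogeny with branch substitution rates (0.0155, 0.0155,
  0.04, 0.04, 0.04, 0.17), giving pairwise planted identities of about
  0.80–0.97 — the ANI range observed in real clusters of six related
  temperate phages — with one distant outlier lineage supplying the low
  end. Planted: one 819 bp intron with the U/G boundary hallmarks and a
  reverse-strand 150-codon LAGLIDADG ORF; one 340 aa intein at residue
  104 of a large early gene; one 1.5 kb transposon with a 5 bp
  target-site duplication; one precise and one deletion-associated
  (35 bp) free-standing endonuclease; and one 44 bp att common core
  written identically into every phage ~100 bp downstream of its
  integrase and into the anticodon loop of the 50 kb host's tRNA-Leu,
  flanked by arm-type repeats P1–P4 plus an inverted pair near the
  integrase start. Each element is planted into a genome whose closest
  relative lacks it, mirroring how such elements are found in real
  cohorts (between the closest relatives that differ).
* **Truth uniqueness**: planting junctions are chosen where the carrier
  and the designated reference are locally identical (8 bp per side),
  element edge bases are forced to differ from the adjacent target or
  lost-target bases, and the att core's flanking bases are forced to
  differ between phage and host. Without these guards the planted
  boundaries are *genuinely ambiguous at the string level* — no detector
  could recover them exactly — which would make "exact recovery" an
  ill-posed test rather than a stricter one. Indels likewise never
  split planted elements.
* **Determinism**: one root seed; every stage draws from a stream
  derived by a fixed offset, so adding an element class does not perturb
  earlier draws, and identical inputs give byte-identical outputs
  including the truth log.

What passing recovery tests shows — and what it does not: the detector
recovers planted elements essentially perfectly under substitution-plus-
rare-indel divergence with unambiguous junctions. Real genomes add
repeats, mosaicism from recombination, annotation errors, and elements
much older than their flanks; performance there is bounded above by
these results.

Genome termini are modeled blunt; the short 3' single-stranded overhangs
of real virion DNA would be metadata, not sequence.

# Problem sizes used in the test suite

Unit tests run on 12–40 kb genomes. The acceptance suite validates
recovery on twenty full-size cohorts (six 110 kb genomes plus a 50 kb
host each), checks one att cassette and one ANI pair per cohort
(rotating through pairs that span the identity range), and compares
every algorithmic core against an independent brute-force oracle on
200–500 random instances. These sizes were chosen so the whole suite
completes in minutes while every claim is exercised at the study scale.

# Known limitations

* The insertion finder assumes a single event per anchor gap; two
  elements inserted within ~15 bp of each other would be merged.
* Deletion-associated target loss is only identifiable up to content
  coincidences between the element's edge and the lost bases; the
  detector resolves ties toward the larger loss, which is correct
  whenever the junctions themselves are unambiguous.
* The pham seed prefilter can skip a hypothetical pair at the identity
  threshold whose matches are all isolated residues — the standard trade
  of seeded homology search.
* `join()` (multi-segment) gene models, multi-contig assemblies,
  ambiguity codes beyond N, and circular-coordinate features are out of
  scope.
* Programmed frameshifts (tail-assembly chaperones) are not modeled; a
  frameshifted gene would need its `joined/frameshifted` annotation
  handled upstream.
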