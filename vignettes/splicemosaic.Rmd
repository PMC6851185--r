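---
title: "Modelling mutually exclusive alternative splicing with splicemosaic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mutually exclusive alternative splicing with splicemosaic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicemosaic)
```

## The problem

Dscam-family immune receptors in arthropods achieve antibody-like diversity
without somatic recombination. The locus carries tandem arrays of
near-duplicate exons ("clusters") of which the spliceosome retains exactly
one per mature mRNA, a set of optional exons that can be included or
skipped, and alternative ways to end translation: terminal exon variants
that carry the stop codon, or a retained intron with its own in-frame stop
and polyadenylation signal, which yields a secreted, tail-less receptor.
Characterizing such a locus involves a fixed repertoire of analyses —
counting the isoform space, translating isoforms across frame-shifting
junctions, inferring exon types from cDNA contigs, finding the exon arrays
in genomic DNA, surveying which variants tissues actually use, and
quantifying conservation across variant alignments. `splicemosaic`
implements that repertoire as one package around a single validated
gene-model container.

## The gene model

A `gene_model()` is an ordered list of *slots*, each `constitutive`,
`optional`, `cluster` (≥ 2 mutually exclusive variants) or `placeholder`
(a slot known to exist but never sequenced; it counts as a slot but
contributes no exon record and no coding sequence). Exon records carry
1-based closed genomic coordinates (GFF3 convention; minus-strand sequences
are reverse-complemented on extraction), an optional nucleotide sequence and
peptide, and a `frame_offset` used only by overlapping terminal variants.
Two further ingredients define the valid isoform space:

* **splice constraints** — `implies` / `forbids` pairs over exon or slot
  ids, evaluated purely on the selection ("if exon 43 is included it is
  always followed by variant 44.1");
* **terminators** — `stop_variant` entries naming terminal variants whose
  stop codon ends translation, and `retained_intron` entries giving the slot
  after which the intron (stored with the terminator) is read through.

`validate_model()` returns violations as data rather than throwing, so a
curation pipeline can collect everything wrong with a draft model at once.

## Counting and enumerating isoforms

`count_isoforms()` partitions slots into groups connected by constraints.
Unconstrained groups contribute closed-form factors — cluster arity, 2 per
optional exon, 1 otherwise — and each constrained group is counted by
exhaustively filtering its own (small) Cartesian product. The product over
groups gives the joint count. Tail-less isoforms are counted over the slots
up to the retained intron; a constraint whose consequent lies beyond the
retained intron simply forbids its antecedent there, since the consequent
exon cannot be spliced into a transcript that ended earlier. Counts are held
in doubles, which are exact integers up to 2^53 — comfortably beyond any
tandem-array gene (the packaged model needs 2.1 × 10^7).

`enumerate_isoforms()` yields each valid isoform exactly once in a defined
order (slot-major; cluster variants in model order; optional exons excluded
before included; membrane-bound isoforms before tail-less ones), so
downstream golden files are stable. Enumeration length equals the count;
the suite verifies both against an independent Cartesian-product-plus-filter
oracle on hundreds of random models.

For the packaged shrimp Dscam model this machinery reproduces the published
arithmetic exactly:

```{r}
count_isoforms(pmdscam_model())
```

## Translation across junctions

`splice_isoform()` concatenates the selected exon sequences in slot order;
`translate_cds()` applies the standard genetic code from position 1 to the
first stop. The interesting bookkeeping is *where* the stop comes from:
`mature_transcript()` attributes the stop codon to the exon contributing its
final base, so a stop created by a frame-shifting junction is credited to
the downstream exon. In the packaged model, optional exon 43 is 17 nt long;
including it shifts the frame so the first codon spanning the 43/44.1
junction is TAA — the stop sits at the very first position of variant 44.1
and none of 44.1 is translated.

Terminal variant 44.2 is encoded *inside* variant 44.1's genomic span in a
shifted reading frame. The fixture constructs this with
`encode_dual_frame()`, a deterministic backtracking search over synonymous
codons. Full overlap of both coding regions is infeasible for these two
peptides (the search proves it), which matches the locus's actual layout:
the terminal exon span continues past the stop codon as 3'-UTR, and 44.2's
coding region overlaps 44.1's stop and extends into that untranslated tail
(offset 64, frame 1 in the fixture).

Motif scanning uses consensus strings over residue classes (`X` any,
`[VL]` alternatives, trailing `$` for C-terminal anchoring) and reports all
overlapping matches with 1-based spans. ITAM (`YXXL`), ITIM
(`[ISVL]XYXX[VL]`) and RGD are standard consensi; the SH2, polyproline and
PDZ defaults in `motif_patterns()` are package choices, flagged
`verbatim = FALSE` in output so reports distinguish them. On the model's
published tail peptides the scan finds an ITAM in exon 34 (in the MYEEL
stretch) and no ITIM in any tail exon. A naive `YXXL` scan also fires inside
exon 32.1 (YLNL); the package asserts presence in exon 34, not exclusivity,
since domain-context filters are out of scope.

## Inferring exon types from transcript evidence

Given observed exon chains (cDNA contigs), `classify_exons()` applies
definitional rules per slot, with each chain voting only on slots inside its
span (partial contigs covering only the cytoplasmic tail then say nothing
about extracellular slots): one id present in every spanning chain →
constitutive; present in some, absent in others → optional; several ids,
never two in one chain, exactly one per spanning chain → cluster.
`infer_implications()` emits `A implies B` when every A-containing chain
spanning B's slot contains B. Two guards keep this from degenerating: a
support threshold (default 3 chains — pairs seen once or twice in an
evidence set of tens of contigs are too weak to call), and skipping
consequents that are present in every chain spanning their slot, because
"A implies constitutive-B" is vacuously true and carries no information.
Chains exhaustively enumerating the packaged tail sub-model recover exactly
the published classification and the single 43 → 44.1 implication at full
support.

## Finding exon arrays in genomic DNA

`discover_array()` searches a region delimited by conserved anchors (exact
nucleotide motifs, or peptide motifs matched in all three frames) for
windows bounded by a canonical splice acceptor (AG immediately upstream) and
donor (GT immediately downstream) within a length band — by default the
profile's median coding length ± 40%, widenable to ± 80% with a `relaxed`
flag so array members of unusual length (the packaged Ig7 array contains
one) remain reportable. Windows are translated and scored with
`profile_similarity()`: best Smith–Waterman local alignment (unit
match/mismatch/gap scores) against the profile members, normalized by the
*member's* length. That denominator is deliberate: normalizing by the
shorter sequence would let a cleanly conserved fragment of an exon outscore
the full exon. Overlaps are resolved greedily by score, ties broken leftmost
then longest, and survivors are numbered by genomic position — the
convention of naming variants by their order along the gene. Both strands
are scanned; minus-strand candidates come back in plus coordinates, so
discovery on a reverse-complemented genome yields mirrored coordinates.

All scanner thresholds are package decisions (the similarity default of 0.5
accepts anything scoring better than the midpoint between random and
identical) and are exposed as arguments.

## Clone surveys

`assign_clone()` votes per cluster: each variant is locally aligned to the
clone; a variant covered over ≥ 90% of its length competes, identity is
matches over the variant length, and the unique best hit at ≥ 0.95 identity
is assigned. Ties are `ambiguous`, sub-threshold best hits `unassigned`,
non-competing clusters `uncovered`; only assignments enter the
`tally_matrix()` counts, with everything else reported separately, so
detected/undetected calls are never inflated by unassignable clones. The
0.95 default tolerates the few per-clone substitutions expected from
amplicon cloning while staying far above between-variant similarity.

## Conservation profiles and epitope windows

`column_profiles()` computes per-column residue frequencies over non-gap
characters, Shannon entropy, and information content IC = log2(20) − H in
bits, with occupancy (non-gap fraction) reported separately — the standard
sequence-logo convention. A WebLogo-style small-sample correction
(e_n = 19 / (2 ln 2 · n)) is available behind a flag, off by default.

`extract_epitopes()` cuts fixed-length windows anchored on conserved
features. An anchor is either a conserved residue at an ungapped sequence
position or a literal motif. Positional anchors are resolved per sequence
(the column holding each sequence's k-th residue, then the modal column)
rather than as fixed alignment columns: this keeps the windows invariant
under uninformative alignment changes such as inserting a gap column, and
matches what "the conserved residue 16I" means for a set of variants.
Sequences failing the anchor are flagged in the result, never silently
dropped. The packaged rules (`pmdscam_epitope_rules()`) encode the epitope
I/II window definitions for the two extracellular clusters: 12 residues
before position-16 I and 13 after position-41 V (exon 4), 8 after
position-9 K/R and 8 before the LLC motif (exon 6). "Approximately 12" in
the source material is implemented as exactly 12, with the window length
configurable per rule.

## The synthetic-data generator

`simulate_gene()` emulates the architecture the package analyses:
alternating constitutive exons and clusters whose variants are mutated
copies of a cluster ancestor, optionally followed by optional tail exons, a
2-variant stop-carrying terminal cluster and a retained-intron terminator,
all bounded by canonical GT–AG introns, with conserved flanks recorded as
anchors and a complete truth record. Default design parameters mirror a
hypervariable-receptor study: clusters of 26, 81 and 26 variants and a
two-tissue survey of 10 individuals × 20 clones per sample
(`simulate_clone_survey()`, substitution-only errors).

Three generator choices matter for interpreting test results:

* **Identity is peptide-level and deterministic.** A variant differs from
  its ancestor at exactly `round((1 − identity) · length)` interior
  residues. Planted similarity is then exactly 2·identity − 1 under the
  unit-score alignment, so recovery thresholds behave predictably.
* **Splice-proximal termini are conserved.** The two residues at each end
  of every variant stay ancestral. Real tandem arrays are most conserved
  near their splice sites; it also guarantees that truncating a planted
  exon always loses alignment score, making exact-boundary recovery
  well-defined.
* **Intron interiors avoid G.** The only AG/GT dinucleotides in intronic
  sequence are the planted splice sites, and introns must be longer than
  the candidate length band (enforced by `sim_config()`). Real genomes
  contain decoy splice sites; the simulation therefore measures the
  scanner's behavior under unambiguous boundaries, not its specificity
  against decoys. Passing recovery tests shows the geometry and scoring are
  right, not that the default thresholds are tuned for real genomic noise.

Under these conditions planted-array recovery is exact (recall and
precision 1.0) at ≥ 0.8 identity; at 0.7 and 0.5 identity the planted
similarity (0.4 and 0.0) falls below the default 0.5 threshold and recall
collapses — reported by the suite rather than asserted, since it is a
property of the threshold, not a defect.

Clone errors are substitution-only by default: single-base cloning errors
are the reason single-residue differences between putative variants are
better collapsed than counted, and the generator exposes exactly that
failure mode.

## The packaged PmDscam model

`pmdscam_model()` assembles the shrimp Dscam worked example: 44 slots, the
placeholder exon 1 (the unidentified 5'-UTR exon — modelled as a slot so
"44 exons" and "175 exon records" are simultaneously true), clusters
4/6/15/32/44 of sizes 26/81/26/2/2, optional tail exons 34, 36, 37, 39, 41,
42, 43, the 43 → 44.1 implication, stop-variant terminators for 44.1/44.2
and the retained intron after exon 31. Tail nucleotide sequences are
deterministic reverse-translations of the published tail peptides (exon 43
gets two extra bases, making its length 17 nt, so the junction codon into
44.1 is TAA); extracellular sequences are synthetic stand-ins generated
under a fixed internal seed and clearly flagged as such — the real
sequences are available from NCBI accession MK838771 but are not shipped.
Exon 32's two transmembrane variants are modelled as a 2-cluster, which
contributes the same factor of 2 as treating it as a presence/absence bit
but keeps "exactly one variant per cluster" semantics uniform.

## Numerical and degenerate-input behavior

Counting returns 0 with a diagnostic naming the slot group when constraints
are unsatisfiable; enumeration past `limit` sets a `truncated` attribute,
never silently. Translation rejects ambiguous bases listing their
positions; ragged alignments, empty genomes, unmatched anchors and
malformed motif patterns all produce named errors (or warnings plus empty
results where an empty answer is meaningful, as for unmatched anchors).
Ties in clone
assignment are ambiguous, not arbitrarily broken. The dual-frame encoder
searches offsets in order of decreasing overlap under a fixed node budget,
so its output is reproducible; the budget caps worst-case search time at a
few seconds.

## Problem sizes used by the test suite

The suite runs everything at desk scale, chosen so the full run takes about
a minute: oracle equivalence on 200 random models of ≤ 6 slots, planted
array recovery on 50 seeded genomes of one 5-variant cluster (~2 kb each),
evidence recovery from the 384 exhaustively enumerated tail isoforms, and
clone surveys of a few dozen clones. The study-scale defaults (26/81/26
clusters, 400 clones) are exercised where cheap — model construction,
counting, survey generation — while alignment-heavy paths use the smaller
designs.

## Known limitations

* No probabilistic isoform-usage model: counts and enumeration treat all
  valid isoforms as equally interesting; no expression quantification.
* The array scanner requires canonical GT–AG boundaries and is a
  single-exon-window scanner, not a spliced aligner; non-canonical splice
  sites and trans-splicing are invisible to it.
* Constraint evaluation covers pairwise implies/forbids; higher-order
  dependencies would need to be encoded as multiple pairwise rules.
* Motif scanning is consensus-based; it neither replaces HMM/profile domain
  detection nor uses structural context, which is why presence (not
  exclusivity) is the tested claim.
* `assign_clone()` assumes primer-bounded amplicons containing cluster
  variants essentially end-to-end; fragmented or chimeric clones surface as
  `uncovered`/`ambiguous` rather than being rescued.
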