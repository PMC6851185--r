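# splicemosaic

Combinatorics and analysis of mutually exclusive alternative splicing in
hypervariable receptor genes.

Arthropod Dscam (Down syndrome cell adhesion molecule) genes generate
enormous protein diversity from a single locus: tandem arrays of
near-duplicate exons are spliced mutually exclusively (exactly one variant of
each array per mature mRNA), optional exons are included or skipped, and
alternative terminators — terminal exon variants carrying their own stop
codons, or a retained intron with an early stop and poly(A) signal — select
between membrane-bound and secreted (tail-less) forms. `splicemosaic` turns
the analyses such a gene demands into a reusable toolkit, for genome
annotators and immunologists characterizing Dscam-like loci:

- **gene models** (`gene_model()`, `validate_model()`, `exon_census()`,
  `save_model()`/`load_model()`): ordered exon slots (constitutive /
  optional / mutually exclusive cluster / placeholder), splice constraints,
  terminators; GFF3 + FASTA + YAML serialization.
- **isoform space** (`count_isoforms()`, `enumerate_isoforms()`,
  `classify_isoform()`): exact counts and deterministic enumeration under
  constraints. For constraint-connected slot groups the count is obtained by
  exhaustive filtering; independent groups contribute closed-form factors
  (cluster arity, 2 per optional exon), so a gene with clusters of sizes
  `n1..nk` and `m` free optional exons has `prod(n) * 2^m` isoforms per
  terminator class.
- **mature transcripts** (`splice_isoform()`, `translate_cds()`,
  `mature_transcript()`, `scan_motifs()`): CDS assembly in slot order,
  standard-code translation, attribution of stop codons to the exon that
  completes them (junction-generated stops included), and consensus motif
  scans (ITAM `YXXL`, ITIM `[ISVL]XYXX[VL]`, RGD, and configurable
  SH2/polyproline/PDZ patterns).
- **evidence inference** (`classify_exons()`, `infer_implications()`):
  recover exon types and implication constraints from observed transcript
  exon chains; chains vote only on slots they span.
- **array discovery** (`discover_array()`, `profile_similarity()`): find
  tandem arrays of near-duplicate exons in genomic DNA from conserved
  anchors, canonical GT–AG boundaries and local-alignment similarity to a
  peptide profile.
- **clone surveys** (`assign_clones()`, `tally_matrix()`): assign amplicon
  clone sequences to cluster variants by alignment identity and build
  per-tissue detection matrices with undetected-variant reports.
- **conservation profiles** (`column_profiles()`, `extract_epitopes()`):
  per-column information content `IC = log2(20) − H` in bits and
  anchor-based epitope-window extraction.
- **synthetic data** (`sim_config()`, `simulate_gene()`,
  `simulate_transcripts()`, `simulate_clone_survey()`): seeded generators
  with complete truth records, so every stage is testable without downloads.

The packaged worked example, `pmdscam_model()`, is the *Penaeus monodon*
(black tiger shrimp) Dscam gene: 44 exon slots, extracellular clusters of
26, 81 and 26 variants (N-terminal Ig2, N-terminal Ig3, entire Ig7), 2-variant
clusters for the transmembrane exon 32 and stop-codon exon 44, seven optional
tail exons, the constraint that exon 43 forces variant 44.1 (placing a stop
codon at 44.1's very first position via a frame shift), and a retained-intron
terminator after exon 31 producing the tail-less form. Tail sequences derive
from the published exon peptides; extracellular nucleotide sequences are
synthetic stand-ins (the real ones live under NCBI accession MK838771).

## Worked example

```r
library(splicemosaic)

m <- pmdscam_model()
exon_census(m)[c("n_slots", "n_variant_records", "n_exon_records")]
#> $n_slots        [1] 44
#> $n_variant_records [1] 137
#> $n_exon_records [1] 175

count_isoforms(m)
#> isoform count
#>   extracellular combinations: 54,756
#>   tail combinations:          384
#>   membrane-bound isoforms:    21,026,304
#>   tail-less isoforms:         54,756
#>   total:                      21,081,060
```

54,756 = 26 × 81 × 26 extracellular combinations; 384 = 2 × 2⁶ × 3 tail
combinations (transmembrane cluster, six free optional exons, three valid
exon-43/44 endings); each extracellular combination also occurs once as a
tail-less isoform, giving 54,756 × 384 + 54,756 = 21,081,060 isoforms.

The junction-generated stop codon is directly inspectable:

```r
tail <- pmdscam_model("tail")
sp <- Filter(function(s) 43 %in% s$optional_included,
             enumerate_isoforms(tail))[[1]]
mature_transcript(tail, sp)
#> <mature_transcript> 1028 nt, 305 aa, stop at codon 306 in exon 44.1
```

A shell entry point with the same functionality is installed at
`inst/scripts/splicemosaic` (subcommands `validate`, `count`, `enumerate`,
`translate`, `scan-array`, `classify-evidence`, `assign-clones`, `logo`,
`simulate`, `fixture`), e.g.
`Rscript inst/scripts/splicemosaic count --fixture pmdscam`.

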