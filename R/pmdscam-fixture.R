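## The packaged worked example: a gene model of the Penaeus monodon Dscam
## (PmDscam) locus. The slot structure, cluster sizes, optional exons, the
## tail peptides, the 43 -> 44.1 implication and the terminator layout follow
## the published gene organization; extracellular nucleotide sequences are
## synthetic stand-ins (deterministically generated; the real sequences live
## under NCBI accession MK838771), and tail nucleotide sequences are
## deterministic reverse-translations of the published peptides.

## cytoplasmic tail peptides, exons 31-44 (stop codons stripped; the stop is
## modelled by the terminator layout, not the peptide)
PMDSCAM_TAIL_PEPTIDES <- c(
  "31"   = "VAEYEVATLTLTG",
  "32.1" = "GTIAPAREVPAFGAGDLPIYLNLNLIVPVVSAVVVIVLAIVIICYLRGRNTPIK",
  "32.2" = "ATLPPTVSDSRVTWLPDWWPKWLDLNVLVPVIATIVVIIVGIVVICVAVTRRKNGIENLR",
  "33"   = "EEVYQQYQYNASMPPPSTMDKRHPGFREELGYIPPPNRKLPPVPGSQYNTCDRIKR",
  "34"   = "GGGSGRGTHATWDPRRPMYEELSLHPPPGRRIPLGGPPQPLGSQDTLRS",
  "35"   = "GGDDEICPYATFHLLGFREEMDPQQAGNNFQTFPHQNGHGSQQHFVNSPASRSM",
  "36"   = "PRHGSGNYYSCVSGDYTCGHTPNEGHQ",
  "37"   = "PRHGSGNYYSCVAGEYGPGG",
  "38"   = "PPSSTYYSTVPGDMTASRMSNSTFSPTYDDPARSDEESDQYGGSTYSGGGPYARAIDSVSQSGTAKRLS",
  "39"   = "NGGHPPGAPVSGPQPSNHRFICK",
  "40"   = "RGSTSGSAGQGSPEPLPLDSSGLGSSLNDSNNSTASNQFSEAECDHDLVQRNYG",
  "41"   = "RHCAQTKP",
  "42"   = "VKATKSTEEMRKLLDK",
  "43"   = "KLNKT",
  "44.1" = "NEAAAHIQNGGLRMVSDEMNV",
  "44.2" = "EMKQLPTFKMEA")

#' Cytoplasmic tail peptides of the PmDscam model
#'
#' The published amino-acid sequences of tail exons 31-44 (both variants of
#' the mutually exclusive exons 32 and 44), without stop characters.
#'
#' @return named character vector (names are exon ids).
#' @export
pmdscam_tail_peptides <- function() PMDSCAM_TAIL_PEPTIDES

.pmdscam_cache <- new.env(parent = emptyenv())

#' The PmDscam gene model
#'
#' A 44-slot model of the shrimp Dscam locus: a placeholder slot 1 (the
#' unidentified 5'-UTR exon, excluded from exon-record counts), extracellular
#' clusters at slots 4, 6 and 15 with 26, 81 and 26 mutually exclusive
#' variants (N-terminal Ig2, N-terminal Ig3, entire Ig7), a cytoplasmic tail
#' with 2-variant clusters at slots 32 (transmembrane) and 44 (alternative
#' stop codons), seven optional tail exons (34, 36, 37, 39, 41, 42, 43), the
#' implication that including exon 43 forces variant 44.1 (whose very first
#' codon then becomes a stop via the frame shift introduced by exon 43), and
#' a retained-intron terminator after slot 31 producing the secreted
#' tail-less form. Variant 44.2's coding region lies inside variant 44.1's
#' genomic span in a shifted reading frame ([encode_dual_frame()]).
#'
#' The census is 31 constitutive + 7 optional + 137 cluster variants = 175
#' exon records, and the isoform space factorizes as 26 x 81 x 26 = 54,756
#' extracellular combinations times 2 x 2^6 x 3 = 384 tail combinations, plus
#' one tail-less isoform per extracellular combination.
#'
#' @param part `"full"` (default) or a convenience sub-model: `"tail"` (slots
#'   31-44), `"terminal"` (slots 43-44), `"extracellular"` (slots 1-30).
#' @return a validated [gene_model()].
#' @examples
#' exon_census(pmdscam_model())
#' count_isoforms(pmdscam_model("tail"))
#' @export
pmdscam_model <- function(part = c("full", "tail", "terminal", "extracellular")) {
  part <- match.arg(part)
  if (is.null(.pmdscam_cache$model))
    .pmdscam_cache$model <- build_pmdscam()
  m <- .pmdscam_cache$model
  switch(part,
         full = m,
         tail = subset_model(m, 31:44),
         terminal = subset_model(m, 43:44),
         extracellular = subset_model(m, 1:30))
}

build_pmdscam <- function() {
  cluster_sizes <- c("4" = 26L, "6" = 81L, "15" = 26L)
  extracellular_slots <- 1:30
  tail_constitutive <- c(31L, 33L, 35L, 38L, 40L)
  tail_optional <- c(34L, 36L, 37L, 39L, 41L, 42L, 43L)

  sl <- data.frame(slot = 1:44, kind = "constitutive",
                   region = ifelse(1:44 <= 30, "extracellular", "tail"),
                   stringsAsFactors = FALSE)
  sl$kind[sl$slot == 1L] <- "placeholder"
  sl$kind[sl$slot %in% c(4L, 6L, 15L, 32L, 44L)] <- "cluster"
  sl$kind[sl$slot %in% tail_optional] <- "optional"

  ## deterministic synthetic stand-ins for the extracellular region
  with_seed(20191112L, {
    variant_peps <- list()
    for (s in names(cluster_sizes)) {
      len <- switch(s, "4" = 48L, "6" = 42L, "15" = 90L)
      anc <- random_peptide(len)
      peps <- vapply(seq_len(cluster_sizes[[s]]), function(v)
        mutate_peptide(anc, 0.8), "")
      ## one array member of unusual length, as observed in the Ig7 array
      if (s == "15")
        peps[20L] <- paste0(peps[20L], random_peptide(30L))
      variant_peps[[s]] <- peps
    }
    const_peps <- stats::setNames(
      vapply(seq_len(30), function(i) random_peptide(40L), ""),
      as.character(1:30))
    intron_pool <- vapply(seq_len(220), function(i) random_intron(80L), "")
  })

  dual <- encode_dual_frame(PMDSCAM_TAIL_PEPTIDES[["44.1"]],
                            PMDSCAM_TAIL_PEPTIDES[["44.2"]])
  if (is.null(dual)) stop("internal error: dual-frame construction failed")

  exon_seq <- function(id) {
    slot <- as.integer(sub("\\..*$", "", id))
    if (slot <= 30L) {
      if (grepl("\\.", id)) {
        v <- as.integer(sub("^.*\\.", "", id))
        pep <- variant_peps[[as.character(slot)]][v]
      } else pep <- const_peps[[as.character(slot)]]
      return(list(nt = reverse_translate(pep), pep = pep))
    }
    pep <- PMDSCAM_TAIL_PEPTIDES[[id]]
    if (id == "43") {
      ## two extra bases shift the frame so the next junction codon (TA + the
      ## first base of 44.1) is a stop
      return(list(nt = paste0(reverse_translate(pep), "TA"), pep = pep))
    }
    if (id == "44.1") return(list(nt = dual$sequence, pep = pep))
    if (id == "44.2") {
      nt <- substr(dual$sequence, dual$offset + 1L,
                   dual$offset + 3L * (nchar(pep) + 1L))
      return(list(nt = nt, pep = pep))
    }
    list(nt = reverse_translate(pep), pep = pep)
  }

  exons <- list(); pieces <- character(); pos <- 0L; intron_i <- 0L
  emit <- function(x) { pieces[[length(pieces) + 1L]] <<- x; pos <<- pos + nchar(x) }
  next_intron <- function() { intron_i <<- intron_i + 1L; emit(intron_pool[intron_i]) }
  add_exon <- function(id, slot, variant, nt, pep, frame_offset = 0L,
                       start = NULL, end = NULL, unknown = FALSE) {
    if (is.null(start)) { start <- pos + 1L; end <- pos + nchar(nt); emit(nt) }
    exons[[length(exons) + 1L]] <<- data.frame(
      id = id, slot = slot, variant = variant, start = start, end = end,
      strand = "+", frame_offset = frame_offset,
      sequence = if (unknown) NA_character_ else nt,
      peptide = pep, stringsAsFactors = FALSE)
  }

  emit(strrep("ACT", 20L))                      # 5' flank
  add_exon("1", 1L, NA_integer_, strrep("N", 100L), NA_character_,
           unknown = TRUE)
  retained_intron <- NULL
  for (s in 2:44) {
    kind <- sl$kind[s]
    if (s == 32L) {
      ## the intron after exon 31 is the retained-intron terminator: read
      ## through from exon 31 it presents an in-frame stop codon ("GTA TAA")
      ## followed by a polyadenylation signal
      ri <- paste0("GTA", "TAA", strrep("CAT", 8L), "AATAAA",
                   strrep("CT", 10L), "AG")
      retained_intron <- ri
      emit(ri)
    } else {
      next_intron()
    }
    if (kind == "cluster") {
      n_var <- if (s <= 30L) cluster_sizes[[as.character(s)]] else 2L
      for (v in seq_len(n_var)) {
        id <- paste0(s, ".", v)
        es <- exon_seq(id)
        if (id == "44.2") {
          ## contained within 44.1's span, shifted reading frame; no intron
          ## separates the two records
          prev <- exons[[length(exons)]]
          add_exon(id, s, v, es$nt, es$pep,
                   frame_offset = dual$offset %% 3L,
                   start = prev$start + dual$offset,
                   end = prev$start + dual$offset + nchar(es$nt) - 1L)
        } else {
          add_exon(id, s, v, es$nt, es$pep)
          if (v < n_var && id != "44.1") next_intron()
        }
      }
    } else {
      es <- exon_seq(as.character(s))
      add_exon(as.character(s), s, NA_integer_, es$nt, es$pep)
    }
  }
  emit(strrep("T", 40L))                         # 3' flank

  constraints <- data.frame(kind = "implies", antecedent = "43",
                            consequent = "44.1", stringsAsFactors = FALSE)
  ## translation ends either in the retained intron after exon 31 (tail-less
  ## secreted form) or at the stop codon of the chosen terminal variant
  terminators <- data.frame(
    kind = c("retained_intron", "stop_variant", "stop_variant"),
    after_slot = c(31L, NA_integer_, NA_integer_),
    variant = c(NA_character_, "44.1", "44.2"),
    sequence = c(retained_intron, NA_character_, NA_character_),
    stringsAsFactors = FALSE)

  model <- gene_model("PmDscam", sl, do.call(rbind, exons),
                      constraints, terminators,
                      genome = paste(pieces, collapse = ""),
                      genome_ref = "PmDscam_locus")
  stop_if_invalid(model)
  model
}
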