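make_two_exon_model <- function(seq1, seq2) {
  gene_model(
    "twoexon",
    data.frame(slot = 1:2, kind = "constitutive", region = "extracellular"),
    data.frame(id = c("1", "2"), slot = 1:2, variant = NA_integer_,
               start = c(1L, 20L),
               end = c(nchar(seq1), 19L + nchar(seq2)),
               strand = "+", frame_offset = 0L,
               sequence = c(seq1, seq2), stringsAsFactors = FALSE))
}

test_that("splicing concatenates selected exon sequences in slot order", {
  m <- make_two_exon_model("ATGGA", "ATAA")
  spec <- enumerate_isoforms(m)[[1]]
  parts <- splice_isoform(m, spec)
  expect_equal(unname(paste(parts, collapse = "")), "ATGGAATAA")
  expect_equal(names(parts), c("1", "2"))

  ## optional exon changes the CDS length by exactly its own length
  tail <- pmdscam_model("tail")
  specs <- Filter(function(s) !s$tail_less &&
                    identical(s$cluster_choices[["44"]], "44.1"),
                  enumerate_isoforms(tail))
  with43 <- Filter(function(s) 43 %in% s$optional_included, specs)[[1]]
  base_opts <- setdiff(with43$optional_included, 43)
  without43 <- Filter(function(s) identical(s$optional_included, base_opts) &&
                        identical(s$cluster_choices, with43$cluster_choices),
                      specs)[[1]]
  len43 <- nchar(tail$exons$sequence[tail$exons$id == "43"])
  cds_a <- paste(splice_isoform(tail, with43), collapse = "")
  cds_b <- paste(splice_isoform(tail, without43), collapse = "")
  expect_equal(nchar(cds_a) - nchar(cds_b), len43)
})

test_that("splicing a selected exon with unknown sequence is an error", {
  m <- make_two_exon_model("ATGGA", "ATAA")
  m$exons$sequence[2] <- NA_character_
  spec <- enumerate_isoforms(m)[[1]]
  expect_error(splice_isoform(m, spec), "unknown-sequence")
})

test_that("translation follows the standard code and flags missing stops", {
  tr <- translate_cds("ATGGAATAA")
  expect_equal(tr$protein, "ME")
  expect_equal(tr$stop_codon, 3L)
  expect_false(tr$no_stop)

  tr2 <- translate_cds("ATGGAAGCT")
  expect_equal(tr2$protein, "MEA")
  expect_true(tr2$no_stop)

  expect_error(translate_cds("ATGNNA"), "position")
  expect_error(translate_cds("AT"), "shorter")

  ## random CDS against an independent translation path
  set.seed(42)
  for (i in 1:25) {
    n <- sample(2:60, 1)
    cds <- paste(sample(c("A", "C", "G", "T"), 3 * n, replace = TRUE),
                 collapse = "")
    mine <- translate_cds(cds)
    ref <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                              no.init.codon = TRUE))
    ref_stop <- regexpr("*", ref, fixed = TRUE)
    if (ref_stop > 0) {
      expect_equal(mine$protein, substr(ref, 1, ref_stop - 1))
      expect_equal(mine$stop_codon, as.integer(ref_stop))
    } else {
      expect_equal(mine$protein, ref)
      expect_true(mine$no_stop)
    }
  }
})

test_that("a junction stop is attributed to the downstream exon", {
  tail <- pmdscam_model("tail")
  specs <- Filter(function(s) !s$tail_less && 43 %in% s$optional_included,
                  enumerate_isoforms(tail))
  for (sp in specs[c(1, length(specs))]) {
    mt <- mature_transcript(tail, sp)
    expect_equal(mt$stop$source_exon, "44.1")
    ## translation stops right at the junction: the protein ends with the
    ## exon-43 peptide and contains none of 44.1's residues
    expect_match(mt$protein, "KLNKT$")
  }
})

test_that("overlapping terminal variants translate to their own peptides", {
  tail <- pmdscam_model("tail")
  specs <- Filter(function(s) !s$tail_less && !(43 %in% s$optional_included),
                  enumerate_isoforms(tail))
  peps <- pmdscam_tail_peptides()
  sp1 <- Filter(function(s) identical(s$cluster_choices[["44"]], "44.1"),
                specs)[[1]]
  sp2 <- Filter(function(s) identical(s$cluster_choices[["44"]], "44.2"),
                specs)[[1]]
  expect_match(mature_transcript(tail, sp1)$protein,
               paste0(peps[["44.1"]], "$"))
  expect_match(mature_transcript(tail, sp2)$protein,
               paste0(peps[["44.2"]], "$"))

  ## the two peptides come from one genomic span read in two frames
  ex <- pmdscam_model()$exons
  v1 <- ex[ex$id == "44.1", ]; v2 <- ex[ex$id == "44.2", ]
  expect_true(v2$start >= v1$start && v2$end <= v1$end)
  expect_equal((v2$start - v1$start) %% 3, v2$frame_offset)
  expect_true(v2$frame_offset != 0)
  expect_equal(translate_cds(v1$sequence)$protein, peps[["44.1"]])
  expect_equal(translate_cds(v2$sequence)$protein, peps[["44.2"]])
})

test_that("planted stops terminate translation on every enumerated isoform", {
  ## synthetic model whose terminal cluster variants both carry a stop codon
  cfg <- sim_config(seed = 5, cluster_sizes = c(2L, 2L), n_optional = 2L,
                    terminal_cluster = TRUE)
  m <- simulate_gene(cfg)$model
  for (sp in Filter(function(s) !s$tail_less, enumerate_isoforms(m))) {
    mt <- mature_transcript(m, sp)
    expect_false(mt$no_stop)
    expect_equal(mt$stop$source_exon, sp$cluster_choices[[length(sp$cluster_choices)]])
  }
})

test_that("motif scanning matches the printed tail peptides", {
  peps <- pmdscam_tail_peptides()
  hits <- scan_motifs(peps, motif_patterns())
  itam34 <- hits[hits$motif == "ITAM" & hits$seq == "34", ]
  expect_gte(nrow(itam34), 1)
  ## the match sits inside the documented MYEEL stretch
  expect_true(any(itam34$match == "YEEL"))
  expect_equal(sum(hits$motif == "ITIM"), 0)
})

test_that("motif scanning is a faithful sliding-window matcher", {
  ## all overlapping matches, 1-based closed spans
  rgd <- scan_motifs(c(x = "AARGDAA"), c(RGD = "RGD"))
  expect_equal(rgd[, c("start", "end")],
               data.frame(start = 3L, end = 5L))
  ov <- scan_motifs(c(x = "PPPP"), c(PP = "PXXP"))
  expect_equal(ov$start, 1L)
  ## C-terminal anchored patterns match only at the end
  pdz <- scan_motifs(c(x = "ASTVASTV"), c(PDZ = "X[ST]X[VIL]$"))
  expect_equal(pdz$start, 5L)
  expect_error(scan_motifs(c(x = "AAA"), c(bad = "[AB")), "pattern-syntax")

  ## random strings against a naive character-class oracle
  set.seed(7)
  classes <- list(ITIM = list("ISVL", NULL, "Y", NULL, NULL, "VL"),
                  ITAM = list("Y", NULL, NULL, "L"))
  consensus <- c(ITIM = "[ISVL]XYXX[VL]", ITAM = "YXXL")
  for (i in 1:20) {
    s <- rand_pep(40)
    for (nm in names(classes)) {
      toks <- classes[[nm]]
      L <- length(toks)
      naive <- integer()
      for (p in seq_len(nchar(s) - L + 1)) {
        ok <- TRUE
        for (k in seq_len(L)) {
          if (!is.null(toks[[k]]) &&
              !grepl(substr(s, p + k - 1, p + k - 1),
                     toks[[k]], fixed = TRUE)) { ok <- FALSE; break }
        }
        if (ok) naive <- c(naive, p)
      }
      got <- scan_motifs(c(s = s), consensus[nm])
      expect_equal(got$start, naive, info = paste(nm, s))
    }
  }
})
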