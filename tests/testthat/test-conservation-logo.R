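AA_ALL <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

test_that("information content has its closed forms", {
  ## invariant column
  inv <- column_profiles(c(a = "AAA", b = "AAA", c = "AAA"))
  expect_equal(inv$ic, rep(log2(20), 3))
  expect_equal(inv$entropy, rep(0, 3))
  ## uniform over the 20 residues
  uni <- column_profiles(stats::setNames(AA_ALL, paste0("s", 1:20)))
  expect_equal(uni$ic, 0)
  expect_equal(uni$entropy, log2(20))
  ## two equiprobable residues
  two <- column_profiles(c(a = "A", b = "C"))
  expect_equal(two$ic, log2(20) - 1)
  ## bounds on arbitrary columns
  set.seed(2)
  aln <- stats::setNames(vapply(1:8, function(i) rand_pep(12), ""),
                         paste0("s", 1:8))
  cp <- column_profiles(aln)
  expect_true(all(cp$ic >= 0 & cp$ic <= log2(20)))
  expect_true(all(abs(colSums(attr(cp, "frequencies")) - 1) < 1e-12))
})

test_that("gaps reduce occupancy, not residue frequencies", {
  cp <- column_profiles(c(a = "A-", b = "A-", c = "AC"))
  expect_equal(cp$occupancy, c(1, 1 / 3))
  expect_equal(cp$ic[2], log2(20))        # single residue among the non-gaps
})

test_that("duplicating a sequence never changes the IC", {
  set.seed(5)
  aln <- stats::setNames(vapply(1:6, function(i) rand_pep(15), ""),
                         paste0("s", 1:6))
  cp1 <- column_profiles(aln)
  cp2 <- column_profiles(c(aln, dup = aln[[1]]))
  ## frequencies shift, but an identical duplicate of an existing sequence
  ## leaves single-residue columns untouched; check the invariant on a
  ## constant alignment where it is exact
  const <- c(a = "MKV", b = "MKV")
  expect_equal(column_profiles(const)$ic,
               column_profiles(c(const, c = "MKV"))$ic)
  expect_true(all(is.finite(cp2$ic)))
  expect_error(column_profiles(c(a = "ABC", b = "AB")), "ragged")
})

test_that("small-sample correction subtracts the expected term", {
  aln <- c(a = "AA", b = "AA", c = "AA", d = "AA")
  plain <- column_profiles(aln)
  corr <- column_profiles(aln, small_sample_correction = TRUE)
  expect_equal(plain$ic - corr$ic, rep(19 / (2 * log(2) * 4), 2))
})

## build an anchored synthetic alignment: fixed residues at anchor positions
anchored_alignment <- function(n = 6, len = 60, fix = list()) {
  set.seed(17)
  base <- strsplit(rand_pep(len), "")[[1]]
  vapply(seq_len(n), function(i) {
    x <- base
    mut <- sample(setdiff(seq_len(len), unlist(lapply(fix, `[[`, "pos"))), 6)
    for (p in mut) x[p] <- sample(AA_ALL, 1)
    for (f in fix) x[f$pos] <- f$res[1 + (i %% length(f$res))]
    paste(x, collapse = "")
  }, "") -> seqs
  stats::setNames(seqs, paste0("v", seq_len(n)))
}

test_that("epitope windows have the rule-specified lengths and positions", {
  aln4 <- anchored_alignment(fix = list(list(pos = 16, res = "I"),
                                        list(pos = 41, res = "V")))
  ep4 <- extract_epitopes(aln4, pmdscam_epitope_rules("4"))
  expect_equal(ep4$epitope_I$columns, c(4, 15))
  expect_equal(ep4$epitope_II$columns, c(42, 54))
  expect_true(all(nchar(ep4$epitope_I$alignment) == 12))
  expect_true(all(nchar(ep4$epitope_II$alignment) == 13))

  aln6 <- anchored_alignment(fix = list(list(pos = 9, res = c("K", "R")),
                                        list(pos = 30, res = "L"),
                                        list(pos = 31, res = "L"),
                                        list(pos = 32, res = "C")))
  ep6 <- extract_epitopes(aln6, pmdscam_epitope_rules("6"))
  expect_equal(ep6$epitope_I$columns, c(10, 17))
  expect_equal(ep6$epitope_II$columns, c(22, 29))
  expect_true(all(nchar(ep6$epitope_I$alignment) == 8))
  expect_length(ep6$epitope_I$failed, 0)
})

test_that("shifting the alignment by a gap column shifts the windows", {
  aln6 <- anchored_alignment(fix = list(list(pos = 9, res = "K"),
                                        list(pos = 30, res = "L"),
                                        list(pos = 31, res = "L"),
                                        list(pos = 32, res = "C")))
  ep <- extract_epitopes(aln6, pmdscam_epitope_rules("6"))
  shifted <- stats::setNames(paste0("-", aln6), names(aln6))
  eps <- extract_epitopes(shifted, pmdscam_epitope_rules("6"))
  expect_equal(eps$epitope_I$columns, ep$epitope_I$columns + 1)
  expect_equal(eps$epitope_II$columns, ep$epitope_II$columns + 1)
})

test_that("unresolvable anchors are rule errors naming the anchor", {
  aln <- anchored_alignment(fix = list(list(pos = 9, res = "K")))
  ## no LLC motif anywhere
  expect_error(extract_epitopes(aln, pmdscam_epitope_rules("6")),
               "LLC")
  ## anchor residue absent and not dominant
  aln4 <- anchored_alignment(fix = list(list(pos = 16, res = "W"),
                                        list(pos = 41, res = "V")))
  expect_error(
    suppressWarnings(extract_epitopes(aln4, pmdscam_epitope_rules("4"))),
    "anchor|dominant")
  ## sequences failing a motif anchor are flagged, not dropped
  aln6 <- anchored_alignment(fix = list(list(pos = 9, res = "K"),
                                        list(pos = 30, res = "L"),
                                        list(pos = 31, res = "L"),
                                        list(pos = 32, res = "C")))
  broken <- aln6
  substr(broken[[1]], 30, 32) <- "AAA"
  ep <- extract_epitopes(broken, pmdscam_epitope_rules("6"),
                         min_anchor_occupancy = 0.8)
  expect_equal(ep$epitope_II$failed, names(broken)[1])
})
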