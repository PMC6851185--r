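## Discovery of tandem arrays of near-duplicate exon variants in genomic DNA.
##
## Candidate internal exons are windows bounded by a canonical splice
## acceptor (AG immediately upstream) and donor (GT immediately downstream),
## within a length band around the profile median. Each candidate is
## translated and scored against the profile by normalized local-alignment
## similarity; overlaps are resolved greedily by score, and surviving
## candidates are numbered by genomic position (matching the convention of
## naming variants by their order along the gene).

#' Describe a conserved anchor
#'
#' Anchors delimit the genomic region searched for an exon array: the region
#' between the first `upstream` anchor match and the first `downstream`
#' anchor match downstream of it. `nt` anchors are exact nucleotide matches;
#' `peptide` anchors are matched against all three forward reading frames.
#'
#' @param name anchor label.
#' @param motif nucleotide or peptide motif (non-empty).
#' @param side `"upstream"` or `"downstream"` of the array.
#' @param type `"nt"` or `"peptide"`.
#' @export
anchor <- function(name, motif, side = c("upstream", "downstream"),
                   type = c("nt", "peptide")) {
  side <- match.arg(side); type <- match.arg(type)
  stopifnot(nzchar(motif))
  structure(list(name = name, motif = toupper(motif), side = side, type = type),
            class = "array_anchor")
}

## first match position (start, end in nt coords) of an anchor in genome
anchor_hit <- function(genome, a) {
  if (a$type == "nt") {
    p <- regexpr(a$motif, genome, fixed = TRUE)
    if (p < 0L) return(NULL)
    return(c(start = as.integer(p), end = as.integer(p) + nchar(a$motif) - 1L))
  }
  for (f in 0:2) {
    sub <- substring(genome, 1L + f)
    sub <- substring(sub, 1L, (nchar(sub) %/% 3L) * 3L)
    if (nchar(sub) < 3L) next
    pep <- translate_string(sub)
    p <- regexpr(a$motif, pep, fixed = TRUE)
    if (p > 0L) {
      s <- f + (as.integer(p) - 1L) * 3L + 1L
      return(c(start = s, end = s + 3L * nchar(a$motif) - 1L))
    }
  }
  NULL
}

## permissive translation (ambiguity-free assumed; stops as '*')
translate_string <- function(x) {
  chars <- strsplit(x, "")[[1L]]
  n <- length(chars) %/% 3L
  idx <- 3L * seq_len(n)
  codons <- paste0(chars[idx - 2L], chars[idx - 1L], chars[idx])
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

## amino-acid substitution matrix: +1 identity / -1 otherwise, over the
## 20 residues plus 'X' and '*'
aa_unit_matrix <- function() {
  letters_aa <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], "X", "*")
  m <- matrix(-1L, length(letters_aa), length(letters_aa),
              dimnames = list(letters_aa, letters_aa))
  diag(m) <- 1L
  m
}

#' Similarity of a peptide to a cluster profile
#'
#' Best normalized Smith-Waterman similarity against the profile members:
#' local alignment with unit match score, unit mismatch and unit linear gap
#' penalties, divided by the profile member's length. Normalizing by the
#' member (not the shorter sequence) means a truncated candidate can never
#' outscore the full-length one. 1 for identical sequences, 0 for sequences
#' sharing no residue.
#'
#' @param peptide candidate peptide (character scalar or vector).
#' @param profile character vector of profile member peptides.
#' @return numeric in `[0, 1]` (max over members), one per candidate.
#' @export
profile_similarity <- function(peptide, profile) {
  stopifnot(length(profile) >= 1L, all(nzchar(profile)), all(nzchar(peptide)))
  mat <- aa_unit_matrix()
  pat <- Biostrings::AAStringSet(peptide)
  best <- rep(0, length(peptide))
  for (member in profile) {
    sc <- Biostrings::pairwiseAlignment(
      pat, Biostrings::AAString(member), type = "local",
      substitutionMatrix = mat, gapOpening = 0, gapExtension = 1,
      scoreOnly = TRUE)
    best <- pmax(best, pmax(sc, 0) / nchar(member))
  }
  pmin(best, 1)
}

#' Discover a tandem exon array in genomic DNA
#'
#' @param genome nucleotide string (or [Biostrings::DNAString]).
#' @param profile character vector of seed peptides for the array (e.g. the
#'   cluster ancestor or known members).
#' @param anchors optional list of [anchor()]s restricting the search region;
#'   when no anchor matches, an empty result is returned with a warning.
#' @param min_similarity minimum profile similarity to report (default 0.5).
#' @param length_band candidate nucleotide length range; default is the
#'   profile median coding length +/- 40%. With `relax_band = TRUE` the band
#'   is widened to +/- 80% and out-of-band candidates are flagged in the
#'   `relaxed` column, so array members of unusual length remain reportable.
#' @param relax_band widen the band as described above.
#' @param both_strands also scan the reverse complement; minus-strand
#'   candidates are reported in plus-strand coordinates with `strand = "-"`,
#'   so an array is found at mirrored coordinates whichever orientation the
#'   genome is supplied in.
#' @return data.frame of candidates ordered by position: `start`, `end`
#'   (1-based closed), `strand`, `acceptor`, `donor`, `peptide`, `score`,
#'   `relaxed`, `variant` (positional rank after overlap resolution).
#' @export
discover_array <- function(genome, profile, anchors = NULL,
                           min_similarity = 0.5, length_band = NULL,
                           relax_band = FALSE, both_strands = TRUE) {
  genome <- toupper(as.character(genome))
  if (!nzchar(genome)) stop("empty genome")
  stopifnot(length(profile) >= 1L)
  plus <- scan_one_strand(genome, profile, anchors, min_similarity,
                          length_band, relax_band)
  if (both_strands) {
    L <- nchar(genome)
    minus <- suppressWarnings(
      scan_one_strand(revcomp(genome), profile, anchors,
                      min_similarity, length_band, relax_band))
    if (nrow(minus)) {
      new_start <- L - minus$end + 1L
      minus$end <- L - minus$start + 1L
      minus$start <- new_start
      minus$strand <- "-"
    }
    plus <- rbind(plus, minus)
  }
  resolve_candidates(plus)
}

scan_one_strand <- function(genome, profile, anchors, min_similarity,
                            length_band, relax_band) {

  region <- c(1L, nchar(genome))
  if (!is.null(anchors)) {
    ups <- Filter(function(a) a$side == "upstream", anchors)
    dns <- Filter(function(a) a$side == "downstream", anchors)
    hits_u <- if (length(ups)) anchor_hit(genome, ups[[1L]]) else NULL
    hits_d <- if (length(dns)) anchor_hit(genome, dns[[1L]]) else NULL
    if ((length(ups) && is.null(hits_u)) || (length(dns) && is.null(hits_d))) {
      warning("no anchor match; returning empty candidate set")
      return(empty_scan())
    }
    if (!is.null(hits_u)) region[1L] <- hits_u[["end"]] + 1L
    if (!is.null(hits_d)) region[2L] <- hits_d[["start"]] - 1L
    if (region[1L] >= region[2L]) {
      warning("anchors delimit an empty region")
      return(empty_scan())
    }
  }

  med <- stats::median(3L * nchar(profile))
  band <- length_band %||% c(floor(med * 0.6), ceiling(med * 1.4))
  wide <- if (relax_band) c(floor(med * 0.2), ceiling(med * 1.8)) else band

  sub <- substring(genome, region[1L], region[2L])
  off <- region[1L] - 1L
  ## acceptor AG immediately upstream of candidate start, donor GT just after end
  ag <- gregexpr("AG", sub, fixed = TRUE)[[1L]]
  gt <- gregexpr("GT", sub, fixed = TRUE)[[1L]]
  starts <- ag[ag > 0L] + 2L          # candidate start (after the AG)
  ends <- gt[gt > 0L] - 1L            # candidate end (before the GT)
  if (!length(starts) || !length(ends)) return(empty_scan())

  cand <- list()
  ends_sorted <- sort(ends)
  for (s in starts) {
    lo <- s + wide[1L] - 1L; hi <- s + wide[2L] - 1L
    es <- ends_sorted[ends_sorted >= lo & ends_sorted <= hi]
    for (e in es) {
      cand[[length(cand) + 1L]] <- c(s, e)
    }
  }
  if (!length(cand)) return(empty_scan())
  cm <- do.call(rbind, cand)
  peps <- vapply(seq_len(nrow(cm)), function(i) {
    w <- substring(sub, cm[i, 1L], cm[i, 2L])
    translate_string(substring(w, 1L, (nchar(w) %/% 3L) * 3L))
  }, "")
  keep <- nzchar(peps)
  cm <- cm[keep, , drop = FALSE]; peps <- peps[keep]
  if (!nrow(cm)) return(empty_scan())

  score <- profile_similarity(peps, profile)
  sel <- score >= min_similarity
  cm <- cm[sel, , drop = FALSE]; peps <- peps[sel]; score <- score[sel]
  if (!nrow(cm)) return(empty_scan())

  data.frame(start = cm[, 1L] + off, end = cm[, 2L] + off,
             strand = "+", acceptor = "AG", donor = "GT",
             peptide = peps, score = score,
             relaxed = cm[, 2L] - cm[, 1L] + 1L < band[1L] |
               cm[, 2L] - cm[, 1L] + 1L > band[2L],
             stringsAsFactors = FALSE)
}

resolve_candidates <- function(df) {
  if (!nrow(df)) return(empty_candidates())
  ## greedy overlap resolution: best score first, ties leftmost then longest
  df <- df[order(-df$score, df$start, -df$end), , drop = FALSE]
  kept <- logical(nrow(df))
  occ_start <- integer(); occ_end <- integer()
  for (i in seq_len(nrow(df))) {
    if (!any(df$start[i] <= occ_end & df$end[i] >= occ_start)) {
      kept[i] <- TRUE
      occ_start <- c(occ_start, df$start[i]); occ_end <- c(occ_end, df$end[i])
    }
  }
  df <- df[kept, , drop = FALSE]
  df <- df[order(df$start), , drop = FALSE]
  df$variant <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

empty_candidates <- function() {
  data.frame(start = integer(), end = integer(), strand = character(),
             acceptor = character(), donor = character(),
             peptide = character(), score = numeric(), relaxed = logical(),
             variant = integer(), stringsAsFactors = FALSE)
}

empty_scan <- function() {
  data.frame(start = integer(), end = integer(), strand = character(),
             acceptor = character(), donor = character(),
             peptide = character(), score = numeric(), relaxed = logical(),
             stringsAsFactors = FALSE)
}
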