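## Mature transcript assembly, translation across splice junctions, and
## consensus motif scanning.

#' Assemble the CDS of an isoform
#'
#' Concatenates the selected exon sequences in slot order: constitutive exons
#' always, optional exons when included, and the chosen variant of each
#' cluster. For a tail-less isoform only slots up to the retained intron are
#' used and the retained-intron sequence (which carries the in-frame stop
#' codon) is appended when the model stores it. Placeholder slots are
#' untranslated leader exons and never contribute to the CDS; a selected
#' coding exon with unknown sequence is an error.
#'
#' Overlapping terminal variants need no special casing here: each variant
#' record carries its own genomic interval and sequence, and its
#' `frame_offset` documents the reading frame of that interval relative to
#' the frame of the enclosing variant's span.
#'
#' @param model a [gene_model()].
#' @param spec an `isoform_spec` (see [enumerate_isoforms()]).
#' @return named character: one element per contributing exon, in order.
#'   `paste(..., collapse = "")` of the result is the CDS; [mature_transcript()]
#'   does this plus translation and bookkeeping.
#' @export
splice_isoform <- function(model, spec) {
  stopifnot(inherits(spec, "isoform_spec"))
  sl <- model$slots
  slots <- sl$slot
  if (isTRUE(spec$tail_less)) {
    r <- spec$terminator$after_slot
    if (is.null(r)) stop("tail-less spec without retained-intron terminator")
    slots <- slots[slots <= r]
  }
  parts <- character(); ids <- character()
  for (s in slots) {
    kind <- sl$kind[sl$slot == s]
    if (kind == "placeholder") next
    if (kind == "optional" && !s %in% spec$optional_included) next
    id <- if (kind == "cluster") {
      ch <- spec$cluster_choices[[as.character(s)]]
      if (is.null(ch)) stop("no cluster choice for slot ", s)
      ch
    } else as.character(s)
    seq <- model$exons$sequence[model$exons$id == id]
    if (length(seq) != 1L) stop("unknown exon id '", id, "'")
    if (is.na(seq))
      stop("unknown-sequence error: exon ", id, " has no sequence")
    parts <- c(parts, seq); ids <- c(ids, id)
  }
  if (isTRUE(spec$tail_less)) {
    tm <- model$terminators
    ri <- tm[tm$kind == "retained_intron" &
               tm$after_slot == spec$terminator$after_slot, , drop = FALSE]
    if (nrow(ri) && !is.na(ri$sequence[1L])) {
      parts <- c(parts, ri$sequence[1L])
      ids <- c(ids, paste0("intron_after_", ri$after_slot[1L]))
    }
  }
  stats::setNames(parts, ids)
}

#' Translate a CDS with the standard genetic code
#'
#' Translates from position 1 to the first stop codon. Trailing nucleotides
#' that do not fill a codon are ignored. A CDS with no stop codon is legal
#' but flagged.
#'
#' @param cds nucleotide string (A/C/G/T only).
#' @return list with `protein` (residues before the stop), `stop_codon`
#'   (codon index of the stop, NA when absent) and `no_stop` flag.
#' @export
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  if (nchar(cds) < 3L) stop("CDS shorter than one codon")
  chars <- strsplit(toupper(cds), "")[[1L]]
  bad <- which(!chars %in% c("A", "C", "G", "T"))
  if (length(bad))
    stop("ambiguous bases at position(s) ", paste(bad, collapse = ", "))
  n_codons <- length(chars) %/% 3L
  idx <- 3L * seq_len(n_codons)
  codons <- paste0(chars[idx - 2L], chars[idx - 1L], chars[idx])
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  stop_at <- which(aa == "*")[1L]
  if (is.na(stop_at)) {
    list(protein = paste(aa, collapse = ""), stop_codon = NA_integer_,
         no_stop = TRUE)
  } else {
    list(protein = paste(aa[seq_len(stop_at - 1L)], collapse = ""),
         stop_codon = stop_at, no_stop = FALSE)
  }
}

#' Build the mature transcript of an isoform
#'
#' Splices, translates, locates the stop codon and attributes it to the exon
#' whose nucleotide completes it. A stop codon generated across a splice
#' junction is therefore attributed to the downstream exon: when a
#' frame-shifting optional exon makes the very first codon after the junction
#' a stop, the stop source is the terminal variant, not the optional exon.
#'
#' @param model a [gene_model()].
#' @param spec an `isoform_spec`.
#' @param patterns optional motif patterns (see [motif_patterns()]) scanned
#'   against the protein.
#' @return `mature_transcript`: list with `cds`, `protein`, `stop`
#'   (`position` = codon index, `source_exon`), `no_stop`, `exon_widths`, and
#'   `annotations` (motif hits, NULL unless `patterns` given).
#' @export
mature_transcript <- function(model, spec, patterns = NULL) {
  parts <- splice_isoform(model, spec)
  cds <- paste(parts, collapse = "")
  tr <- translate_cds(cds)
  widths <- nchar(parts)
  src <- NA_character_
  if (!tr$no_stop) {
    last_nt <- 3L * tr$stop_codon          # base completing the stop codon
    src <- names(parts)[findInterval(last_nt, cumsum(widths) + 1L) + 1L]
  }
  ann <- if (!is.null(patterns))
    scan_motifs(stats::setNames(tr$protein, "protein"), patterns)
  structure(list(cds = cds, protein = tr$protein,
                 stop = list(position = tr$stop_codon, source_exon = src),
                 no_stop = tr$no_stop,
                 exon_widths = widths, annotations = ann),
            class = "mature_transcript")
}

#' @export
print.mature_transcript <- function(x, ...) {
  cat("<mature_transcript> ", nchar(x$cds), " nt, ",
      nchar(x$protein), " aa", sep = "")
  if (x$no_stop) cat(" (no stop codon)")
  else cat(", stop at codon ", x$stop$position, " in exon ",
           x$stop$source_exon, sep = "")
  cat("\n")
  invisible(x)
}

## ---- motif scanning --------------------------------------------------------

#' Default consensus motif patterns
#'
#' Consensus strings use one-letter residue codes, `X` for any residue,
#' bracketed alternatives (`[VL]`), and a trailing `$` for motifs anchored at
#' the C-terminus. ITAM (`YXXL`), ITIM (`[ISVL]XYXX[VL]`) and RGD are
#' standard immunoreceptor/cell-attachment consensi; the SH2-binding,
#' polyproline and PDZ class patterns are configurable defaults, not
#' literature consensi, and are flagged `verbatim = FALSE` so reports label
#' them as such.
#'
#' @return data.frame with columns `name`, `consensus`, `verbatim`.
#' @export
motif_patterns <- function() {
  data.frame(
    name = c("ITAM", "ITIM", "RGD", "SH2", "polyproline", "PDZ"),
    consensus = c("YXXL", "[ISVL]XYXX[VL]", "RGD",
                  "YXX[LIV]", "PXXP", "X[ST]X[VIL]$"),
    verbatim = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

## parse a consensus into tokens; returns list(regex, length, anchored_end)
parse_consensus <- function(consensus) {
  chars <- strsplit(consensus, "")[[1L]]
  tokens <- character(); i <- 1L; anchored <- FALSE
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- which(chars == "]" & seq_along(chars) > i)[1L]
      if (is.na(j)) stop("pattern-syntax error in '", consensus, "': unclosed [")
      inner <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      if (!nzchar(inner) || !grepl("^[A-Z]+$", inner))
        stop("pattern-syntax error in '", consensus, "': bad class [", inner, "]")
      tokens <- c(tokens, paste0("[", inner, "]"))
      i <- j + 1L
    } else if (ch == "X") {
      tokens <- c(tokens, "."); i <- i + 1L
    } else if (ch == "$") {
      if (i != length(chars))
        stop("pattern-syntax error in '", consensus, "': $ must be last")
      anchored <- TRUE; i <- i + 1L
    } else if (grepl("^[A-Z]$", ch)) {
      tokens <- c(tokens, ch); i <- i + 1L
    } else {
      stop("pattern-syntax error in '", consensus, "': unexpected '", ch, "'")
    }
  }
  if (length(tokens) < 1L)
    stop("pattern-syntax error: empty consensus")
  list(regex = paste(tokens, collapse = ""), length = length(tokens),
       anchored_end = anchored)
}

#' Scan peptides for consensus motifs
#'
#' Reports every (possibly overlapping) match of each pattern in each
#' sequence, with 1-based spans. Suitable both for whole-protein scans and
#' for per-exon peptide tables.
#'
#' @param x named character vector of residue sequences.
#' @param patterns data.frame as from [motif_patterns()], or a named
#'   character vector of consensus strings.
#' @return data.frame with columns `seq`, `motif`, `start`, `end`, `match`,
#'   `verbatim`.
#' @export
scan_motifs <- function(x, patterns = motif_patterns()) {
  stopifnot(is.character(x))
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  if (is.character(patterns)) {
    patterns <- data.frame(name = names(patterns) %||% patterns,
                           consensus = unname(patterns),
                           verbatim = NA, stringsAsFactors = FALSE)
  }
  out <- list()
  for (p in seq_len(nrow(patterns))) {
    pc <- parse_consensus(patterns$consensus[p])
    rx <- if (pc$anchored_end) paste0("(?=", pc$regex, "$)")
          else paste0("(?=", pc$regex, ")")
    for (s in seq_along(x)) {
      m <- gregexpr(rx, x[[s]], perl = TRUE)[[1L]]
      starts <- m[m > 0L]
      if (!length(starts)) next
      out[[length(out) + 1L]] <- data.frame(
        seq = names(x)[s], motif = patterns$name[p],
        start = starts, end = starts + pc$length - 1L,
        match = substring(x[[s]], starts, starts + pc$length - 1L),
        verbatim = patterns$verbatim[p],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(seq = character(), motif = character(),
                      start = integer(), end = integer(),
                      match = character(), verbatim = logical(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
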