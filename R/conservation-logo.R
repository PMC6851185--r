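## Per-column conservation profiles of variant alignments and extraction of
## epitope windows anchored on conserved residues or motifs.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

## alignment input -> character matrix (rows = sequences, cols = columns)
as_alignment_matrix <- function(alignment) {
  if (inherits(alignment, "AAStringSet") || inherits(alignment, "BStringSet"))
    alignment <- stats::setNames(as.character(alignment), names(alignment))
  stopifnot(is.character(alignment), length(alignment) >= 2L)
  w <- unique(nchar(alignment))
  if (length(w) != 1L)
    stop("ragged alignment: sequence lengths ", paste(w, collapse = ", "))
  if (is.null(names(alignment))) names(alignment) <- paste0("seq", seq_along(alignment))
  m <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(m) <- names(alignment)
  m
}

#' Per-column conservation profiles of a protein alignment
#'
#' For every column: residue frequencies over the non-gap residues, Shannon
#' entropy H in bits, information content IC = log2(20) - H, and occupancy
#' (the non-gap fraction). Gap characters (`-`, `.`) are excluded from the
#' frequencies, which therefore sum to 1 over the 20-letter alphabet. The
#' optional small-sample correction subtracts the WebLogo-style term
#' e_n = 19 / (2 ln(2) n) from the IC (off by default).
#'
#' @param alignment equal-length aligned sequences: named character vector or
#'   [Biostrings::AAStringSet] (at least 2 sequences).
#' @param small_sample_correction apply the e_n correction.
#' @return data.frame with `column`, `n` (non-gap count), `occupancy`,
#'   `entropy`, `ic`; the residue-frequency matrix (20 x columns) is attached
#'   as attribute `"frequencies"`.
#' @export
column_profiles <- function(alignment, small_sample_correction = FALSE) {
  m <- as_alignment_matrix(alignment)
  gap <- c("-", ".")
  bad <- setdiff(unique(as.vector(m)), c(AA20, gap))
  if (length(bad))
    stop("alignment contains non-standard residue(s): ",
         paste(bad, collapse = ", "))
  ncolm <- ncol(m)
  freqs <- matrix(0, nrow = 20L, ncol = ncolm, dimnames = list(AA20, NULL))
  out <- data.frame(column = seq_len(ncolm), n = 0L, occupancy = 0,
                    entropy = NA_real_, ic = NA_real_)
  for (j in seq_len(ncolm)) {
    col <- m[, j]
    res <- col[!col %in% gap]
    out$n[j] <- length(res)
    out$occupancy[j] <- length(res) / nrow(m)
    if (!length(res)) next
    p <- table(factor(res, levels = AA20)) / length(res)
    freqs[, j] <- as.numeric(p)
    nz <- p[p > 0]
    h <- -sum(nz * log2(nz))
    ic <- log2(20) - h
    if (small_sample_correction) ic <- ic - 19 / (2 * log(2) * length(res))
    out$entropy[j] <- h
    out$ic[j] <- max(ic, 0)
  }
  attr(out, "frequencies") <- freqs
  out
}

#' Define an epitope extraction rule
#'
#' A rule anchors a fixed-length window on a conserved feature of the
#' alignment: either a conserved residue at an ungapped sequence position
#' (`anchor_position` + `anchor_residues`, e.g. position 16, residue I) or a
#' conserved motif (`anchor_motif`, e.g. LLC). The window of `length` columns
#' sits immediately `"before"` or `"after"` the anchor.
#'
#' @param name rule label (e.g. `"epitope_I"`).
#' @param length window length in columns (> 0).
#' @param side `"before"` or `"after"` the anchor.
#' @param anchor_position 1-based residue position (counted over non-gap
#'   characters of each sequence).
#' @param anchor_residues accepted residues at the anchor (e.g. `c("K","R")`).
#' @param anchor_motif literal motif as an alternative anchor.
#' @export
epitope_rule <- function(name, length, side = c("before", "after"),
                         anchor_position = NULL, anchor_residues = NULL,
                         anchor_motif = NULL) {
  side <- match.arg(side)
  stopifnot(length > 0)
  if (is.null(anchor_motif) && (is.null(anchor_position) || is.null(anchor_residues)))
    stop("rule needs either anchor_motif or anchor_position + anchor_residues")
  structure(list(name = name, length = as.integer(length), side = side,
                 anchor_position = anchor_position,
                 anchor_residues = toupper(anchor_residues %||% character()),
                 anchor_motif = if (is.null(anchor_motif)) NULL else toupper(anchor_motif)),
            class = "epitope_rule")
}

## column of the k-th non-gap residue for each row; NA when too short
residue_column <- function(m, k) {
  apply(m, 1L, function(row) {
    pos <- which(!row %in% c("-", "."))
    if (length(pos) < k) NA_integer_ else pos[k]
  })
}

## resolve a rule's anchor to (start_col, end_col); errors name the anchor
resolve_anchor <- function(m, rule, min_occupancy) {
  if (!is.null(rule$anchor_motif)) {
    mot <- strsplit(rule$anchor_motif, "")[[1L]]
    L <- length(mot)
    frac <- vapply(seq_len(ncol(m) - L + 1L), function(c0) {
      mean(apply(m[, c0:(c0 + L - 1L), drop = FALSE], 1L,
                 function(r) all(r == mot)))
    }, 0)
    best <- which.max(frac)
    if (frac[best] < min_occupancy)
      stop("anchor motif '", rule$anchor_motif, "' resolved in only ",
           round(100 * frac[best]), "% of sequences (rule ", rule$name, ")")
    failed <- rownames(m)[!apply(m[, best:(best + L - 1L), drop = FALSE], 1L,
                                 function(r) all(r == mot))]
    list(start = best, end = best + L - 1L, failed = failed)
  } else {
    cols <- residue_column(m, rule$anchor_position)
    ok <- !is.na(cols)
    if (!any(ok))
      stop("anchor position ", rule$anchor_position,
           " beyond every sequence (rule ", rule$name, ")")
    col <- as.integer(names(which.max(table(cols[ok]))))
    at_col <- m[, col]
    match_res <- at_col %in% rule$anchor_residues
    frac <- mean(match_res)
    if (frac < min_occupancy) {
      ## tolerate a degraded anchor as long as the stated residues still
      ## dominate the column; otherwise the rule is unusable
      top <- names(sort(table(at_col[!at_col %in% c("-", ".")]),
                        decreasing = TRUE))[1L]
      if (!is.null(top) && top %in% rule$anchor_residues) {
        warning("anchor ", rule$anchor_position,
                paste(rule$anchor_residues, collapse = "/"),
                " matched by only ", round(100 * frac),
                "% of sequences (rule ", rule$name, ")")
      } else {
        stop("anchor ", rule$anchor_position,
             paste(rule$anchor_residues, collapse = "/"),
             " not dominant at column ", col, " (rule ", rule$name, ")")
      }
    }
    list(start = col, end = col, failed = rownames(m)[!match_res])
  }
}

#' Extract epitope windows from a variant alignment
#'
#' Applies each [epitope_rule()]: resolves its anchor on the alignment, then
#' cuts the window of rule-specified length immediately before or after the
#' anchor. Sequences failing the anchor check are reported in `failed`, never
#' silently dropped.
#'
#' @param alignment aligned sequences (see [column_profiles()]).
#' @param rules list of [epitope_rule()]s.
#' @param min_anchor_occupancy fraction of sequences that must carry the
#'   anchor (default 0.9).
#' @return named list (one element per rule): `columns` (window column
#'   range), `alignment` (the sub-alignment as a named character vector),
#'   `anchor` (resolved columns), `failed` (sequence names failing the
#'   anchor).
#' @export
extract_epitopes <- function(alignment, rules, min_anchor_occupancy = 0.9) {
  m <- as_alignment_matrix(alignment)
  if (inherits(rules, "epitope_rule")) rules <- list(rules)
  out <- list()
  for (rule in rules) {
    a <- resolve_anchor(m, rule, min_anchor_occupancy)
    win <- if (rule$side == "before") {
      c(a$start - rule$length, a$start - 1L)
    } else {
      c(a$end + 1L, a$end + rule$length)
    }
    if (win[1L] < 1L || win[2L] > ncol(m))
      stop("window of rule ", rule$name, " (columns ", win[1L], "-", win[2L],
           ") falls outside the alignment")
    sub <- apply(m[, win[1L]:win[2L], drop = FALSE], 1L, paste, collapse = "")
    out[[rule$name]] <- list(columns = win,
                             alignment = sub,
                             anchor = c(start = a$start, end = a$end),
                             failed = a$failed)
  }
  out
}

#' Epitope rules for the packaged shrimp Dscam model
#'
#' Window definitions for the two hypervariable extracellular clusters: in
#' the exon-4 (Ig2) variants, epitope I is the 12 residues before the
#' conserved position-16 isoleucine and epitope II the 13 residues after the
#' conserved position-41 valine; in the exon-6 (Ig3) variants, epitope I is
#' the 8 residues after the conserved position-9 lysine/arginine and epitope
#' II the 8 residues before the conserved LLC motif.
#'
#' @param exon `"4"` or `"6"`.
#' @return list of two [epitope_rule()]s.
#' @export
pmdscam_epitope_rules <- function(exon = c("4", "6")) {
  exon <- match.arg(exon)
  if (exon == "4") {
    list(epitope_I = epitope_rule("epitope_I", length = 12, side = "before",
                                  anchor_position = 16, anchor_residues = "I"),
         epitope_II = epitope_rule("epitope_II", length = 13, side = "after",
                                   anchor_position = 41, anchor_residues = "V"))
  } else {
    list(epitope_I = epitope_rule("epitope_I", length = 8, side = "after",
                                  anchor_position = 9,
                                  anchor_residues = c("K", "R")),
         epitope_II = epitope_rule("epitope_II", length = 8, side = "before",
                                   anchor_motif = "LLC"))
  }
}
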