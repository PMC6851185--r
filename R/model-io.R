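## Serialization of gene models: a YAML config (slot kinds, constraints,
## terminators), a GFF3 file of exon features, and a FASTA genome.
## Coordinates follow the GFF3 convention throughout: 1-based, closed.

#' Save a gene model to disk
#'
#' Writes three files under `dir`: `<prefix>.yaml` (slot kinds, regions,
#' constraints, terminators), `<prefix>.gff3` (exon features with `slot`,
#' `variant`, `kind` and `frame_offset` attributes) and, when the model
#' carries a genome, `<prefix>.fa`. [load_model()] restores a field-identical
#' model from these files.
#'
#' @param model a validated [gene_model()].
#' @param dir output directory (created if needed).
#' @param prefix file name stem; defaults to the model name.
#' @return invisibly, a named list of the written paths.
#' @export
save_model <- function(model, dir, prefix = model$name) {
  stop_if_invalid(model)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(config = file.path(dir, paste0(prefix, ".yaml")),
                gff3 = file.path(dir, paste0(prefix, ".gff3")),
                fasta = if (!is.null(model$genome)) file.path(dir, paste0(prefix, ".fa")))

  sl <- model$slots
  cfg <- list(
    name = model$name,
    genome_ref = model$genome_ref,
    slots = lapply(seq_len(nrow(sl)), function(i)
      list(slot = sl$slot[i], kind = sl$kind[i], region = sl$region[i])),
    constraints = apply_rows(model$constraints, function(r)
      list(kind = r$kind, antecedent = r$antecedent, consequent = r$consequent)),
    terminators = apply_rows(model$terminators, function(r) {
      out <- list(kind = r$kind)
      if (!is.na(r$after_slot)) out$after_slot <- r$after_slot
      if (!is.na(r$variant)) out$variant <- r$variant
      if (!is.na(r$sequence)) out$sequence <- r$sequence
      out
    }))
  yaml::write_yaml(cfg, paths$config)

  ex <- model$exons
  if (any(is.na(ex$start) | is.na(ex$end)))
    stop("cannot serialize exon records without coordinates")
  gr <- GenomicRanges::GRanges(
    seqnames = model$genome_ref,
    ranges = IRanges::IRanges(ex$start, ex$end),
    strand = ex$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "splicemosaic", type = "exon",
    ID = ex$id, slot = ex$slot, variant = ex$variant,
    kind = model$slots$kind[match(ex$slot, model$slots$slot)],
    frame_offset = ex$frame_offset,
    sequence_unknown = is.na(ex$sequence),
    peptide = ex$peptide)
  rtracklayer::export(gr, paths$gff3, format = "gff3")

  if (!is.null(model$genome)) {
    write_fasta(stats::setNames(model$genome, model$genome_ref), paths$fasta)
  }
  invisible(paths)
}

apply_rows <- function(df, f) {
  if (!nrow(df)) return(list())
  lapply(seq_len(nrow(df)), function(i) f(df[i, , drop = FALSE]))
}

#' Load a gene model from disk
#'
#' Reads the files written by [save_model()]. Exon sequences are extracted
#' from the genome using the GFF3 coordinates (1-based, closed); features on
#' the minus strand are reverse-complemented. Records flagged
#' `sequence_unknown` keep an NA sequence.
#'
#' @param config_path YAML config path.
#' @param gff3_path GFF3 exon feature path.
#' @param fasta_path optional genome FASTA; without it the model has no
#'   genome and exon sequences are left unknown.
#' @return a [gene_model()].
#' @export
load_model <- function(config_path, gff3_path, fasta_path = NULL) {
  if (!file.exists(config_path)) stop("config file not found: ", config_path)
  if (!file.exists(gff3_path)) stop("GFF3 file not found: ", gff3_path)
  cfg <- tryCatch(yaml::read_yaml(config_path),
                  error = function(e) stop("malformed config (", config_path, "): ",
                                           conditionMessage(e), call. = FALSE))
  gr <- tryCatch(rtracklayer::import(gff3_path, format = "gff3"),
                 error = function(e) stop("malformed GFF3 (", gff3_path, "): ",
                                          conditionMessage(e), call. = FALSE))
  mc <- S4Vectors::mcols(gr)
  n <- length(gr)
  col_or <- function(x, default) {
    if (is.null(x)) rep(default, n) else x
  }
  ex <- data.frame(
    id = as.character(col_or(mc$ID, NA_character_)),
    slot = as.integer(col_or(mc$slot, NA_integer_)),
    variant = suppressWarnings(as.integer(col_or(mc$variant, NA_integer_))),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    frame_offset = as.integer(col_or(mc$frame_offset, 0L)),
    sequence = rep(NA_character_, n),
    peptide = as.character(col_or(mc$peptide, NA_character_)),
    stringsAsFactors = FALSE)
  if (any(ex$start > ex$end))
    stop("range error: exon with end < start in ", gff3_path)
  unknown <- if (!is.null(mc$sequence_unknown))
    as.logical(mc$sequence_unknown) else rep(FALSE, nrow(ex))

  genome <- NULL
  if (!is.null(fasta_path)) {
    fa <- read_fasta(fasta_path)
    genome <- unname(fa[[1L]])
    if (any(ex$end > nchar(genome) | ex$start < 1L))
      stop("range error: exon coordinates outside genome in ", gff3_path)
    seqs <- substring(genome, ex$start, ex$end)
    minus <- ex$strand == "-"
    if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
    ex$sequence <- ifelse(unknown, NA_character_, seqs)
  }

  sl <- do.call(rbind, lapply(cfg$slots, function(s)
    data.frame(slot = as.integer(s$slot), kind = s$kind, region = s$region,
               stringsAsFactors = FALSE)))
  cn <- if (length(cfg$constraints)) {
    do.call(rbind, lapply(cfg$constraints, function(s)
      data.frame(kind = s$kind, antecedent = as.character(s$antecedent),
                 consequent = as.character(s$consequent), stringsAsFactors = FALSE)))
  } else empty_constraints()
  tm <- if (length(cfg$terminators)) {
    do.call(rbind, lapply(cfg$terminators, function(s)
      data.frame(kind = s$kind,
                 after_slot = if (is.null(s$after_slot)) NA_integer_ else as.integer(s$after_slot),
                 variant = if (is.null(s$variant)) NA_character_ else as.character(s$variant),
                 sequence = if (is.null(s$sequence)) NA_character_ else as.character(s$sequence),
                 stringsAsFactors = FALSE)))
  } else empty_terminators()

  ord <- order(ex$slot, ex$variant, ex$start, na.last = FALSE)
  ex <- ex[ord, , drop = FALSE]
  rownames(ex) <- NULL
  gene_model(cfg$name, sl, ex, cn, tm,
             genome = genome, genome_ref = cfg$genome_ref)
}
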