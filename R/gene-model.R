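## Gene-model container: ordered exon slots, exon/variant records, splice
## constraints and terminators. This is the combinatorial object behind all
## isoform counts.

#' Construct a gene model
#'
#' A gene model describes a single locus as an ordered list of exon *slots*.
#' A slot is `constitutive` (always present), `optional` (included or
#' skipped), a `cluster` (two or more mutually exclusive variants, exactly one
#' of which is retained per transcript), or a `placeholder` (a slot known to
#' exist but whose sequence was never identified; it participates in slot
#' numbering but not in exon-record counts). Splice constraints couple choices
#' across slots ("if exon 43 is included it is always followed by variant
#' 44.1"), and terminators describe how translation can end: a retained intron
#' that carries its own stop codon and polyadenylation signal (yielding a
#' secreted, tail-less product), or a terminal exon variant containing the
#' stop codon.
#'
#' @param name gene name.
#' @param slots data.frame with columns `slot` (integer, strictly increasing),
#'   `kind` (`constitutive`, `optional`, `cluster`, `placeholder`) and
#'   `region` (`extracellular` or `tail`).
#' @param exons data.frame with columns `id` (`"slot"` for single-exon slots,
#'   `"slot.variant"` for cluster members), `slot`, `variant` (integer or NA),
#'   `start`, `end` (1-based, closed, GFF3 convention), `strand` (`+`/`-`),
#'   `frame_offset` (0..2, reading-frame offset relative to the slot frame;
#'   non-zero only for overlapping terminal variants) and `sequence`
#'   (nucleotide string, or NA when unknown). An optional `peptide` column may
#'   carry the translated exon product.
#' @param constraints data.frame with columns `kind` (`implies`/`forbids`),
#'   `antecedent`, `consequent` (exon ids or slot numbers as strings). May be
#'   empty.
#' @param terminators data.frame with columns `kind`
#'   (`retained_intron`/`stop_variant`), `after_slot` (integer, retained
#'   introns), `variant` (exon id, stop variants) and optionally `sequence`
#'   (the retained-intron sequence appended to a tail-less CDS).
#' @param genome optional genome sequence (character or
#'   [Biostrings::DNAString]) the exon coordinates refer to.
#' @param genome_ref name of the genomic sequence (seqid used in GFF3 output).
#'
#' @return an object of class `gene_model`.
#' @seealso [validate_model()], [exon_census()], [count_isoforms()],
#'   [pmdscam_model()]
#' @export
gene_model <- function(name, slots, exons,
                       constraints = empty_constraints(),
                       terminators = empty_terminators(),
                       genome = NULL, genome_ref = "genome") {
  slots <- as.data.frame(slots, stringsAsFactors = FALSE)
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  if (!"peptide" %in% names(exons))
    exons$peptide <- rep(NA_character_, nrow(exons))
  constraints <- as.data.frame(constraints, stringsAsFactors = FALSE)
  terminators <- as.data.frame(terminators, stringsAsFactors = FALSE)
  if (!"sequence" %in% names(terminators))
    terminators$sequence <- rep(NA_character_, nrow(terminators))
  if (!is.null(genome)) genome <- as.character(genome)
  model <- structure(
    list(name = name, genome = genome, genome_ref = genome_ref,
         slots = slots, exons = exons,
         constraints = constraints, terminators = terminators),
    class = "gene_model")
  model
}

#' @export
empty_constraints <- function() {
  data.frame(kind = character(), antecedent = character(),
             consequent = character(), stringsAsFactors = FALSE)
}

#' @export
empty_terminators <- function() {
  data.frame(kind = character(), after_slot = integer(),
             variant = character(), sequence = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.gene_model <- function(x, ...) {
  cen <- exon_census(x, check = FALSE)
  cat("<gene_model> ", x$name, "\n", sep = "")
  cat("  slots: ", cen$n_slots,
      " (constitutive ", cen$n_constitutive,
      ", optional ", cen$n_optional,
      ", cluster ", cen$n_cluster_slots, ")\n", sep = "")
  cat("  exon records: ", cen$n_exon_records,
      " (", cen$n_variant_records, " cluster variants)\n", sep = "")
  cat("  constraints: ", nrow(x$constraints),
      "; terminators: ", nrow(x$terminators), "\n", sep = "")
  if (!is.null(x$genome))
    cat("  genome: ", x$genome_ref, " (", nchar(x$genome), " bp)\n", sep = "")
  invisible(x)
}

slot_kinds <- c("constitutive", "optional", "cluster", "placeholder")

## exon records of one slot, in model order
slot_exons <- function(model, slot) {
  model$exons[model$exons$slot == slot, , drop = FALSE]
}

## map exon id or slot-number string -> slot integer (NA when unknown)
id_to_slot <- function(model, id) {
  hit <- match(id, model$exons$id)
  out <- model$exons$slot[hit]
  miss <- is.na(hit) & grepl("^[0-9]+$", id)
  out[miss] <- ifelse(as.integer(id[miss]) %in% model$slots$slot,
                      as.integer(id[miss]), NA_integer_)
  out
}

#' Validate a gene model
#'
#' Checks every structural invariant of the container and returns the
#' violations as data, one message per broken rule. An empty character vector
#' means the model is valid. Violations name the offending slot, exon,
#' constraint or terminator.
#'
#' @param model a [gene_model()].
#' @return character vector of violation messages (empty when valid).
#' @export
validate_model <- function(model) {
  v <- character()
  say <- function(...) v[[length(v) + 1L]] <<- paste0(...)

  sl <- model$slots
  ex <- model$exons

  if (anyDuplicated(sl$slot)) say("duplicate slot numbers")
  if (is.unsorted(sl$slot, strictly = TRUE)) say("slots not strictly ordered")
  bad_kind <- setdiff(unique(sl$kind), slot_kinds)
  for (k in bad_kind) say("unknown slot kind '", k, "'")
  bad_region <- setdiff(unique(sl$region), c("extracellular", "tail"))
  for (r in bad_region) say("unknown region tag '", r, "'")

  if (anyDuplicated(ex$id)) {
    for (d in unique(ex$id[duplicated(ex$id)])) say("duplicate exon id '", d, "'")
  }
  orphan <- setdiff(ex$slot, sl$slot)
  for (s in orphan) say("exon record for undeclared slot ", s)

  for (i in seq_len(nrow(sl))) {
    s <- sl$slot[i]; kind <- sl$kind[i]
    n <- sum(ex$slot == s)
    if (kind == "cluster" && n < 2L) say("slot ", s, ": cluster arity<2")
    if (kind %in% c("constitutive", "optional") && n != 1L)
      say("slot ", s, ": ", kind, " slot must have exactly one exon record (has ", n, ")")
    if (kind == "placeholder" && n > 1L)
      say("slot ", s, ": placeholder slot must have at most one record")
  }

  for (i in seq_len(nrow(ex))) {
    id <- ex$id[i]
    if (!is.na(ex$start[i]) && !is.na(ex$end[i]) && ex$start[i] > ex$end[i])
      say("exon ", id, ": start > end")
    if (!ex$strand[i] %in% c("+", "-")) say("exon ", id, ": bad strand")
    if (is.na(ex$frame_offset[i]) || !ex$frame_offset[i] %in% 0:2)
      say("exon ", id, ": frame_offset outside 0..2")
    if (!is.na(ex$sequence[i]) && !is.na(ex$start[i]) && !is.na(ex$end[i]) &&
        nchar(ex$sequence[i]) != ex$end[i] - ex$start[i] + 1L)
      say("exon ", id, ": sequence length != end-start+1")
    if (!is.null(model$genome) && !is.na(ex$end[i]) &&
        (ex$start[i] < 1L || ex$end[i] > nchar(model$genome)))
      say("exon ", id, ": coordinates outside genome")
  }

  ## overlap between genomic intervals is legal only within one cluster slot
  known <- ex[!is.na(ex$start) & !is.na(ex$end), , drop = FALSE]
  if (nrow(known) > 1L) {
    ord <- order(known$start, known$end)
    known <- known[ord, , drop = FALSE]
    for (i in seq_len(nrow(known) - 1L)) {
      for (j in seq(i + 1L, nrow(known))) {
        if (known$start[j] > known$end[i]) break
        if (known$slot[i] != known$slot[j])
          say("exons ", known$id[i], " and ", known$id[j],
              " overlap across slots")
      }
    }
  }

  cn <- model$constraints
  for (i in seq_len(nrow(cn))) {
    if (!cn$kind[i] %in% c("implies", "forbids"))
      say("constraint ", i, ": unknown kind '", cn$kind[i], "'")
    for (fld in c("antecedent", "consequent")) {
      id <- cn[[fld]][i]
      if (is.na(id_to_slot(model, id)))
        say("constraint ", i, ": unknown id '", id, "'")
    }
  }

  tm <- model$terminators
  for (i in seq_len(nrow(tm))) {
    if (tm$kind[i] == "retained_intron") {
      if (is.na(tm$after_slot[i]) || !tm$after_slot[i] %in% sl$slot)
        say("terminator ", i, ": retained intron after unknown slot")
    } else if (tm$kind[i] == "stop_variant") {
      if (is.na(tm$variant[i]) || !tm$variant[i] %in% ex$id)
        say("terminator ", i, ": unknown id '", tm$variant[i], "'")
    } else {
      say("terminator ", i, ": unknown kind '", tm$kind[i], "'")
    }
  }

  v
}

stop_if_invalid <- function(model) {
  v <- validate_model(model)
  if (length(v))
    stop("invalid gene model: ", paste(v, collapse = "; "), call. = FALSE)
  invisible(model)
}

#' Tally the structural census of a gene model
#'
#' Counts slots and exon records by kind. Placeholder slots count towards
#' `n_slots` only; every other exon record contributes to `n_exon_records`,
#' which therefore equals `n_constitutive + n_optional + n_variant_records`.
#'
#' @param model a [gene_model()].
#' @param check validate the model first (default TRUE).
#' @return named list: `n_slots`, `n_constitutive`, `n_optional`,
#'   `n_cluster_slots`, `n_variant_records`, `n_exon_records`.
#' @export
exon_census <- function(model, check = TRUE) {
  if (check) stop_if_invalid(model)
  sl <- model$slots
  cluster_slots <- sl$slot[sl$kind == "cluster"]
  n_var <- sum(model$exons$slot %in% cluster_slots)
  n_con <- sum(sl$kind == "constitutive")
  n_opt <- sum(sl$kind == "optional")
  list(n_slots = nrow(sl),
       n_constitutive = n_con,
       n_optional = n_opt,
       n_cluster_slots = length(cluster_slots),
       n_variant_records = n_var,
       n_exon_records = n_con + n_opt + n_var)
}

#' Restrict a gene model to a subset of slots
#'
#' Keeps the named slots with their exon records; constraints and terminators
#' are retained only when all slots they reference remain in the subset.
#' Useful for working with one region of a gene (e.g. the cytoplasmic tail)
#' in isolation.
#'
#' @param model a [gene_model()].
#' @param slots integer vector of slot numbers to keep.
#' @export
subset_model <- function(model, slots) {
  keep_sl <- model$slots$slot %in% slots
  keep_ex <- model$exons$slot %in% slots
  m <- model
  m$slots <- model$slots[keep_sl, , drop = FALSE]
  m$exons <- model$exons[keep_ex, , drop = FALSE]
  cn <- model$constraints
  if (nrow(cn)) {
    ok <- id_to_slot(model, cn$antecedent) %in% slots &
      id_to_slot(model, cn$consequent) %in% slots
    m$constraints <- cn[ok, , drop = FALSE]
  }
  tm <- model$terminators
  if (nrow(tm)) {
    ok <- ifelse(tm$kind == "retained_intron",
                 tm$after_slot %in% slots,
                 tm$variant %in% m$exons$id)
    m$terminators <- tm[ok, , drop = FALSE]
  }
  m$name <- paste0(model$name, "[", min(slots), "-", max(slots), "]")
  rownames(m$slots) <- rownames(m$exons) <- NULL
  m
}
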