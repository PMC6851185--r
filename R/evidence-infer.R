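## Inference of exon types and implication constraints from observed
## transcript exon chains (e.g. cDNA contigs covering the cytoplasmic tail).
##
## A chain only votes on slots inside its span, so partial contigs never
## misclassify exons they do not cover.

#' Map exon ids to slots
#'
#' @param model a [gene_model()].
#' @return named integer vector: exon id -> slot.
#' @export
slot_map <- function(model) {
  stats::setNames(model$exons$slot, model$exons$id)
}

## normalize chains input: named list of character vectors
as_chain_list <- function(chains) {
  if (is.data.frame(chains)) {
    stopifnot(all(c("transcript_id", "exon_ids") %in% names(chains)))
    out <- lapply(strsplit(chains$exon_ids, ","), trimws)
    names(out) <- chains$transcript_id
    return(out)
  }
  stopifnot(is.list(chains))
  if (is.null(names(chains))) names(chains) <- paste0("chain", seq_along(chains))
  chains
}

#' Classify exon slots from transcript evidence
#'
#' For each slot covered by at least one chain: a slot is called
#' `constitutive` when a single exon id is present in every spanning chain;
#' `optional` when a single id is present in some and absent from other
#' spanning chains; `cluster` when two or more distinct ids are observed,
#' never more than one per chain, and exactly one appears in every spanning
#' chain. Slots never covered are `unobserved`; observation patterns
#' satisfying none of the rules (e.g. two variants co-occurring in one chain)
#' are `unclassified`. Chains whose exon order contradicts the slot order are
#' rejected with a diagnostic and do not vote.
#'
#' @param chains named list of character vectors of exon ids (or a data.frame
#'   with `transcript_id` and comma-separated `exon_ids`; see
#'   [read_chains()]).
#' @param slots named integer vector mapping exon id to slot ([slot_map()]).
#'   Ids absent from the map are labelled novel and excluded from voting.
#' @return `exon_classification`: data.frame with `slot`, `call`, `members`
#'   (comma-joined observed ids), `n_spanning`, `n_present`; rejected chains
#'   and novel ids are attached as attributes.
#' @export
classify_exons <- function(chains, slots) {
  chains <- as_chain_list(chains)
  novel <- setdiff(unique(unlist(chains)), names(slots))
  rejected <- character()
  spans <- list()
  for (nm in names(chains)) {
    ids <- setdiff(chains[[nm]], novel)
    ss <- unname(slots[ids])
    if (is.unsorted(ss, strictly = FALSE)) {
      rejected <- c(rejected, paste0(nm, ": exon order violates slot order (",
                                     paste(ss, collapse = ","), ")"))
      next
    }
    spans[[nm]] <- list(ids = ids, slots = ss,
                        first = min(ss), last = max(ss))
  }
  if (!length(spans)) stop("no usable chains")

  all_slots <- sort(unique(unname(slots)))
  rows <- lapply(all_slots, function(s) {
    spanning <- Filter(function(ch) ch$first <= s && s <= ch$last, spans)
    if (!length(spanning)) {
      return(data.frame(slot = s, call = "unobserved", members = "",
                        n_spanning = 0L, n_present = 0L,
                        stringsAsFactors = FALSE))
    }
    per_chain <- lapply(spanning, function(ch) ch$ids[ch$slots == s])
    counts <- lengths(per_chain)
    members <- sort(unique(unlist(per_chain)))
    n_present <- sum(counts > 0L)
    call <-
      if (any(counts > 1L)) "unclassified"
      else if (length(members) <= 1L) {
        if (n_present == length(spanning) && length(members) == 1L) "constitutive"
        else if (n_present >= 1L) "optional"
        else "skipped"
      } else {
        if (n_present == length(spanning)) "cluster" else "unclassified"
      }
    data.frame(slot = s, call = call,
               members = paste(members, collapse = ","),
               n_spanning = length(spanning), n_present = n_present,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("exon_classification", class(out))
  attr(out, "rejected") <- rejected
  attr(out, "novel_ids") <- novel
  out
}

#' Infer implication constraints from transcript evidence
#'
#' Emits `A implies B` when every evidence chain containing exon id A (and
#' spanning B's slot) also contains B, provided at least `min_support` such
#' chains exist. Pairs where B is present in every chain spanning its slot
#' are skipped: such "implications" are vacuously true of constitutive exons
#' and carry no information.
#'
#' @inheritParams classify_exons
#' @param min_support minimum number of supporting chains (default 3; chosen
#'   for small evidence sets of tens of contigs, where pairs observed once or
#'   twice are too weak to call).
#' @return data.frame with `kind`, `antecedent`, `consequent`, `support`.
#' @export
infer_implications <- function(chains, slots, min_support = 3L) {
  chains <- as_chain_list(chains)
  novel <- setdiff(unique(unlist(chains)), names(slots))
  chains <- lapply(chains, setdiff, y = novel)
  chains <- Filter(function(ids) length(ids) > 0L &&
                     !is.unsorted(unname(slots[ids])), chains)
  ids_seen <- sort(unique(unlist(chains)))
  span_of <- lapply(chains, function(ids) range(unname(slots[ids])))

  ## which chains span slot s / contain id x
  spans_slot <- function(s) vapply(span_of, function(r) r[1] <= s && s <= r[2], TRUE)
  has_id <- function(x) vapply(chains, function(ids) x %in% ids, TRUE)

  presence <- vapply(ids_seen, has_id, logical(length(chains)))
  if (is.null(dim(presence)))
    presence <- matrix(presence, nrow = length(chains),
                       dimnames = list(NULL, ids_seen))
  out <- list()
  for (a in ids_seen) {
    in_a <- presence[, a]
    if (sum(in_a) < 1L) next
    for (b in setdiff(ids_seen, a)) {
      sb <- unname(slots[b])
      if (sb == unname(slots[a])) next
      span_b <- spans_slot(sb)
      ## skip constitutive-like consequents (no information)
      if (all(presence[span_b, b])) next
      voters <- in_a & span_b
      support <- sum(voters)
      if (support < min_support) next
      if (all(presence[voters, b])) {
        out[[length(out) + 1L]] <- data.frame(
          kind = "implies", antecedent = a, consequent = b,
          support = support, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(kind = character(), antecedent = character(),
                      consequent = character(), support = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read / write transcript chains as TSV
#'
#' Two-column tab-separated format: `transcript_id`, comma-separated
#' `exon_ids`.
#' @param path file path.
#' @export
read_chains <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("transcript_id", "exon_ids") %in% names(df)))
    stop("chain TSV must have columns transcript_id, exon_ids: ", path)
  as_chain_list(df)
}

#' @rdname read_chains
#' @param chains named list of exon-id vectors.
#' @export
write_chains <- function(chains, path) {
  chains <- as_chain_list(chains)
  df <- data.frame(transcript_id = names(chains),
                   exon_ids = vapply(chains, paste, "", collapse = ","),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
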