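## Assignment of amplicon clone sequences to exon variants and per-tissue
## detection matrices.
##
## Amplicons are primer-bounded, so a clone is expected to contain each
## cluster's chosen variant essentially end to end: a variant must be covered
## along at least `min_coverage` of its length for the clone to vote on that
## cluster, and identity is computed over the full variant length.

#' Assign one clone sequence to cluster variants
#'
#' For every cluster slot the clone covers, the best variant is chosen by
#' alignment identity (matches divided by variant length, from a local
#' alignment with unit scores). A unique best hit at or above `threshold` is
#' `assigned`; a tie is `ambiguous`; a best hit below threshold is
#' `unassigned`; a cluster whose variants are not covered is `uncovered` and
#' does not vote.
#'
#' @param clone_seq nucleotide string.
#' @param model a [gene_model()] providing cluster variant sequences.
#' @param threshold minimum identity for assignment (default 0.95).
#' @param min_coverage minimum fraction of the variant length that must be
#'   aligned (default 0.9).
#' @param clusters cluster slots to consider (default: all in the model).
#' @return data.frame with one row per considered cluster: `cluster_slot`,
#'   `variant`, `identity`, `status`.
#' @export
assign_clone <- function(clone_seq, model, threshold = 0.95,
                         min_coverage = 0.9, clusters = NULL) {
  stopifnot(is.character(clone_seq), length(clone_seq) == 1L)
  if (!nzchar(clone_seq)) stop("empty clone sequence")
  sl <- model$slots
  clusters <- clusters %||% sl$slot[sl$kind == "cluster"]
  subject <- Biostrings::DNAString(clone_seq)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)

  rows <- lapply(clusters, function(s) {
    ex <- slot_exons(model, s)
    if (any(is.na(ex$sequence)))
      stop("cluster ", s, " has variants with unknown sequence")
    alns <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(ex$sequence), subject, type = "local",
      substitutionMatrix = mat, gapOpening = 0, gapExtension = 1)
    vlen <- nchar(ex$sequence)
    nm <- Biostrings::nmatch(alns)
    cov <- IRanges::width(Biostrings::pattern(alns)) / vlen
    identity <- nm / vlen
    covered <- cov >= min_coverage
    if (!any(covered)) {
      return(data.frame(cluster_slot = s, variant = NA_character_,
                        identity = NA_real_, status = "uncovered",
                        stringsAsFactors = FALSE))
    }
    identity[!covered] <- -Inf
    best <- max(identity)
    ties <- which(identity >= best - 1e-9)
    if (length(ties) > 1L) {
      data.frame(cluster_slot = s, variant = NA_character_,
                 identity = best, status = "ambiguous",
                 stringsAsFactors = FALSE)
    } else if (best < threshold) {
      data.frame(cluster_slot = s, variant = NA_character_,
                 identity = best, status = "unassigned",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(cluster_slot = s, variant = ex$id[ties],
                 identity = best, status = "assigned",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assign a set of clones
#'
#' Vectorized driver over a clone table, one [assign_clone()] call per clone.
#'
#' @param clones data.frame with columns `clone_id`, `tissue`, `sequence`
#'   (a named character vector is accepted, in which case all clones get
#'   tissue `"sample"`).
#' @inheritParams assign_clone
#' @return data.frame: `clone_id`, `tissue`, `cluster_slot`, `variant`,
#'   `identity`, `status`.
#' @export
assign_clones <- function(clones, model, threshold = 0.95,
                          min_coverage = 0.9, clusters = NULL) {
  if (is.character(clones)) {
    clones <- data.frame(clone_id = names(clones) %||% paste0("clone", seq_along(clones)),
                         tissue = "sample", sequence = unname(clones),
                         stringsAsFactors = FALSE)
  }
  stopifnot(all(c("clone_id", "tissue", "sequence") %in% names(clones)))
  rows <- lapply(seq_len(nrow(clones)), function(i) {
    a <- assign_clone(clones$sequence[i], model, threshold = threshold,
                      min_coverage = min_coverage, clusters = clusters)
    cbind(data.frame(clone_id = clones$clone_id[i], tissue = clones$tissue[i],
                     stringsAsFactors = FALSE),
          a)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tally assignments into a detection matrix
#'
#' Builds, per cluster, a variant-by-tissue matrix of assigned-clone counts,
#' plus the derived lists of variants undetected in each tissue and in all
#' tissues. Ambiguous, unassigned and uncovered clones never contribute to
#' counts; they are reported separately.
#'
#' @param assignments output of [assign_clones()].
#' @param model the [gene_model()] (supplies the full variant lists so that
#'   never-detected variants appear as zero rows).
#' @return `detection_matrix`: list with `counts` (named list of matrices,
#'   one per cluster slot), `undetected` (per cluster: per-tissue and
#'   `overall` variant id lists) and `excluded` (non-assigned rows).
#' @export
tally_matrix <- function(assignments, model) {
  stopifnot(nrow(assignments) >= 1L)
  tissues <- sort(unique(assignments$tissue))
  slots <- sort(unique(assignments$cluster_slot))
  counts <- list(); undetected <- list()
  for (s in slots) {
    variants <- slot_exons(model, s)$id
    m <- matrix(0L, nrow = length(variants), ncol = length(tissues),
                dimnames = list(variants, tissues))
    ok <- assignments[assignments$cluster_slot == s &
                        assignments$status == "assigned", , drop = FALSE]
    if (nrow(ok)) {
      tab <- table(factor(ok$variant, levels = variants),
                   factor(ok$tissue, levels = tissues))
      m[] <- as.integer(tab)
    }
    per_tissue <- lapply(tissues, function(t) variants[m[, t] == 0L])
    names(per_tissue) <- tissues
    undet <- list(per_tissue = per_tissue,
                  overall = variants[rowSums(m) == 0L])
    counts[[as.character(s)]] <- m
    undetected[[as.character(s)]] <- undet
  }
  excluded <- assignments[assignments$status != "assigned", , drop = FALSE]
  structure(list(counts = counts, undetected = undetected,
                 excluded = excluded),
            class = "detection_matrix")
}

#' @export
print.detection_matrix <- function(x, ...) {
  cat("<detection_matrix>\n")
  for (s in names(x$counts)) {
    m <- x$counts[[s]]
    cat("  cluster ", s, ": ", nrow(m), " variants x ",
        ncol(m), " tissues; assigned clones ", sum(m), "\n", sep = "")
    ov <- x$undetected[[s]]$overall
    if (length(ov))
      cat("    undetected overall: ", paste(ov, collapse = ", "), "\n", sep = "")
  }
  if (nrow(x$excluded))
    cat("  excluded (ambiguous/unassigned/uncovered): ",
        nrow(x$excluded), " rows\n", sep = "")
  invisible(x)
}

#' Long-format detection table
#'
#' Heat-map-ready long form of a [tally_matrix()] result.
#' @param x a `detection_matrix`.
#' @return data.frame: `cluster_slot`, `variant`, `tissue`, `count`,
#'   `detected`.
#' @export
detection_long <- function(x) {
  stopifnot(inherits(x, "detection_matrix"))
  rows <- lapply(names(x$counts), function(s) {
    m <- x$counts[[s]]
    data.frame(cluster_slot = as.integer(s),
               variant = rep(rownames(m), ncol(m)),
               tissue = rep(colnames(m), each = nrow(m)),
               count = as.integer(m),
               detected = as.integer(m) > 0L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
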