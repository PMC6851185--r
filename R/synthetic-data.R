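## Seeded synthetic instances: genes with planted exon arrays, transcript
## chains sampled from a model, and amplicon clone surveys. Every output is
## fully determined by the seed and traceable through the returned truth
## records.

#' Simulation configuration
#'
#' Defaults emulate a hypervariable-receptor study design: three mutually
#' exclusive clusters, variants mutated from a cluster ancestor to a target
#' peptide identity, and a two-tissue clone survey of ten individuals with
#' twenty clones each.
#'
#' @param seed integer seed; fully determines every simulated output.
#' @param cluster_sizes variants per extracellular cluster.
#' @param variant_aa_len range of ancestor peptide lengths (residues).
#' @param identity target peptide identity of each variant to its cluster
#'   ancestor; the two residues at each end of a variant stay ancestral
#'   (splice-proximal exon ends are conserved), mutations are placed in the
#'   interior, and the mutation count is `round((1 - identity) * length)`.
#' @param n_optional number of optional (include-or-skip) tail exons.
#' @param terminal_cluster add a 2-variant terminal cluster carrying the stop
#'   codon, and (when `link_last_optional`) the constraint that including the
#'   last optional exon forces the first terminal variant.
#' @param link_last_optional see above.
#' @param tailless add a retained-intron terminator (with in-frame stop and
#'   polyadenylation signal) after the last extracellular slot.
#' @param intron_len intron length range (nt). Intron interiors avoid G so
#'   that the only canonical AG/GT splice boundaries in a simulated genome
#'   are the planted ones.
#' @param anchor_len length (nt) of the conserved flanks recorded as anchors.
#' @param n_individuals,clones_per_sample,tissues clone survey design.
#' @param usage_weights optional per-tissue variant usage weights: a list
#'   `tissue -> slot -> numeric weights` (unnormalized; zero excludes a
#'   variant). Default: uniform.
#' @param clone_error_rate per-base substitution rate applied to clones.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       cluster_sizes = c(26L, 81L, 26L),
                       variant_aa_len = c(28L, 36L),
                       identity = 0.85,
                       n_optional = 0L,
                       terminal_cluster = FALSE,
                       link_last_optional = FALSE,
                       tailless = FALSE,
                       intron_len = c(120L, 200L),
                       anchor_len = 15L,
                       n_individuals = 10L,
                       clones_per_sample = 20L,
                       tissues = c("hemocyte", "nerve"),
                       usage_weights = NULL,
                       clone_error_rate = 0.002) {
  cfg <- list(seed = as.integer(seed), cluster_sizes = as.integer(cluster_sizes),
              variant_aa_len = as.integer(variant_aa_len), identity = identity,
              n_optional = as.integer(n_optional),
              terminal_cluster = isTRUE(terminal_cluster),
              link_last_optional = isTRUE(link_last_optional),
              tailless = isTRUE(tailless),
              intron_len = as.integer(intron_len),
              anchor_len = as.integer(anchor_len),
              n_individuals = as.integer(n_individuals),
              clones_per_sample = as.integer(clones_per_sample),
              tissues = tissues, usage_weights = usage_weights,
              clone_error_rate = clone_error_rate)
  if (cfg$identity < 0 || cfg$identity > 1) stop("identity must be in [0, 1]")
  if (cfg$clone_error_rate < 0 || cfg$clone_error_rate > 1)
    stop("clone_error_rate must be in [0, 1]")
  if (any(cfg$cluster_sizes < 2L)) stop("cluster sizes must be >= 2")
  if (diff(cfg$variant_aa_len) < 0 || cfg$variant_aa_len[1L] < 8L)
    stop("variant_aa_len must be an increasing range with min >= 8")
  min_len <- 3L * cfg$variant_aa_len[1L]
  if (cfg$intron_len[1L] < ceiling(0.4 * min_len) + 10L)
    stop("introns too short for the given variant lengths ",
         "(spacing must exceed the candidate length band)")
  structure(cfg, class = "sim_config")
}

## fixed codon per residue; codons avoid a trailing A so that exon/intron
## junctions cannot create spurious AG acceptors
PREFERRED_CODON <- c(
  A = "GCT", C = "TGC", D = "GAT", E = "GAG", F = "TTC", G = "GGT",
  H = "CAT", I = "ATT", K = "AAG", L = "CTG", M = "ATG", N = "AAC",
  P = "CCT", Q = "CAG", R = "CGT", S = "TCT", T = "ACT", V = "GTT",
  W = "TGG", Y = "TAC", `*` = "TAG")

#' Reverse-translate a peptide with a fixed codon choice
#'
#' Deterministic: each residue always maps to the same codon, so identical
#' peptides give identical nucleotide stand-ins.
#'
#' @param peptide residue string (may include `*` for a stop).
#' @return nucleotide string of length `3 * nchar(peptide)`.
#' @export
reverse_translate <- function(peptide) {
  aa <- strsplit(toupper(peptide), "")[[1L]]
  bad <- setdiff(aa, names(PREFERRED_CODON))
  if (length(bad)) stop("cannot reverse-translate residue(s): ",
                        paste(unique(bad), collapse = ", "))
  paste(PREFERRED_CODON[aa], collapse = "")
}

random_peptide <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

## mutate exactly round((1-identity)*len) interior residues to a different one
mutate_peptide <- function(peptide, identity) {
  aa <- strsplit(peptide, "")[[1L]]
  n <- length(aa)
  k <- round((1 - identity) * n)
  if (k == 0L) return(peptide)
  interior <- 3:(n - 2L)
  if (k > length(interior)) k <- length(interior)
  pos <- sample(interior, k)
  for (p in pos) aa[p] <- sample(setdiff(AA20, aa[p]), 1L)
  paste(aa, collapse = "")
}

## intron: GT + G-free interior + AG
random_intron <- function(len) {
  stopifnot(len >= 6L)
  paste0("GT", paste(sample(c("A", "C", "T"), len - 4L, replace = TRUE),
                     collapse = ""), "AG")
}

#' Simulate a gene with planted exon arrays
#'
#' Builds a genome and matching gene model: alternating constitutive exons
#' and mutually exclusive clusters (each cluster a tandem array of variants
#' mutated from a common ancestor), optionally followed by tail slots
#' (optional exons and a 2-variant terminal cluster) and a retained-intron
#' terminator. All exons are bounded by canonical GT-AG introns. The truth
#' record holds every planted coordinate, the cluster ancestors, and the
#' conserved flanking anchors, so downstream recovery can be scored exactly.
#'
#' @param config a [sim_config()].
#' @return list with `model` (a [gene_model()] carrying the genome) and
#'   `truth` (`exons` table with per-variant identity, `ancestors`,
#'   `anchors` as [anchor()] lists per cluster, `config`).
#' @export
simulate_gene <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_gene_impl(config))
}

simulate_gene_impl <- function(cfg) {
  rlen <- function(r) if (r[1L] == r[2L]) r[1L] else sample(r[1L]:r[2L], 1L)

  slots <- list(); exons <- list(); ancestors <- list(); anchors <- list()
  pieces <- character(); pos <- 0L
  emit <- function(x) { pieces[[length(pieces) + 1L]] <<- x; pos <<- pos + nchar(x) }
  add_exon <- function(id, slot, variant, seqnt, peptide = NA_character_,
                       frame_offset = 0L) {
    exons[[length(exons) + 1L]] <<- data.frame(
      id = id, slot = slot, variant = variant,
      start = pos + 1L, end = pos + nchar(seqnt), strand = "+",
      frame_offset = frame_offset, sequence = seqnt, peptide = peptide,
      stringsAsFactors = FALSE)
    emit(seqnt)
  }
  add_slot <- function(slot, kind, region) {
    slots[[length(slots) + 1L]] <<- data.frame(
      slot = slot, kind = kind, region = region, stringsAsFactors = FALSE)
  }

  emit(paste(sample(c("A", "C", "T"), 50L, replace = TRUE), collapse = ""))
  slot_no <- 0L
  const_pep_len <- 30L
  intron <- function() emit(random_intron(rlen(cfg$intron_len)))

  last_const_seq <- NULL
  for (k in seq_along(cfg$cluster_sizes)) {
    ## constitutive spacer before the cluster (its tail is the upstream anchor)
    slot_no <- slot_no + 1L
    pep <- random_peptide(const_pep_len)
    nt <- reverse_translate(pep)
    add_slot(slot_no, "constitutive", "extracellular")
    if (slot_no > 1L) intron()
    add_exon(as.character(slot_no), slot_no, NA_integer_, nt, pep)
    up_anchor <- anchor(paste0("up", k), substr(nt, nchar(nt) - cfg$anchor_len + 1L, nchar(nt)),
                        side = "upstream")

    slot_no <- slot_no + 1L
    add_slot(slot_no, "cluster", "extracellular")
    anc <- random_peptide(rlen(cfg$variant_aa_len))
    ancestors[[as.character(slot_no)]] <- anc
    for (v in seq_len(cfg$cluster_sizes[k])) {
      intron()
      vp <- mutate_peptide(anc, cfg$identity)
      add_exon(paste0(slot_no, ".", v), slot_no, v, reverse_translate(vp), vp)
    }
    anchors[[as.character(slot_no)]] <- list(up = up_anchor)
  }
  ## trailing constitutive exon closes the last cluster (downstream anchors
  ## are attached after it is generated)
  slot_no <- slot_no + 1L
  pep <- random_peptide(const_pep_len)
  nt <- reverse_translate(pep)
  add_slot(slot_no, "constitutive", "extracellular")
  intron()
  add_exon(as.character(slot_no), slot_no, NA_integer_, nt, pep)
  last_extracellular <- slot_no
  ## downstream anchor of cluster k = head of the constitutive exon after it
  ex_df_tmp <- do.call(rbind, exons)
  for (cs in names(anchors)) {
    nxt <- min(ex_df_tmp$slot[ex_df_tmp$slot > as.integer(cs) &
                                is.na(ex_df_tmp$variant)])
    head_nt <- ex_df_tmp$sequence[ex_df_tmp$slot == nxt][1L]
    anchors[[cs]]$down <- anchor(paste0("down", cs),
                                 substr(head_nt, 1L, cfg$anchor_len),
                                 side = "downstream")
  }

  terminators <- empty_terminators()
  if (cfg$tailless) {
    ri_seq <- paste0("TAG", paste(sample(c("A", "C", "T"), 27L, replace = TRUE),
                                  collapse = ""), "AATAAA")
    terminators <- rbind(terminators, data.frame(
      kind = "retained_intron", after_slot = last_extracellular,
      variant = NA_character_, sequence = ri_seq, stringsAsFactors = FALSE))
  }

  constraints <- empty_constraints()
  opt_slots <- integer()
  for (o in seq_len(cfg$n_optional)) {
    slot_no <- slot_no + 1L
    add_slot(slot_no, "optional", "tail")
    pep <- random_peptide(12L)
    intron()
    add_exon(as.character(slot_no), slot_no, NA_integer_,
             reverse_translate(pep), pep)
    opt_slots <- c(opt_slots, slot_no)
  }
  if (cfg$terminal_cluster) {
    slot_no <- slot_no + 1L
    add_slot(slot_no, "cluster", "tail")
    for (v in 1:2) {
      pep <- paste0(random_peptide(10L), "*")
      intron()
      add_exon(paste0(slot_no, ".", v), slot_no, v,
               reverse_translate(pep), sub("\\*$", "", pep))
      terminators <- rbind(terminators, data.frame(
        kind = "stop_variant", after_slot = NA_integer_,
        variant = paste0(slot_no, ".", v), sequence = NA_character_,
        stringsAsFactors = FALSE))
    }
    if (cfg$link_last_optional && length(opt_slots)) {
      constraints <- rbind(constraints, data.frame(
        kind = "implies", antecedent = as.character(max(opt_slots)),
        consequent = paste0(slot_no, ".1"), stringsAsFactors = FALSE))
    }
  }

  genome <- paste(pieces, collapse = "")
  ex_df <- do.call(rbind, exons)
  sl_df <- do.call(rbind, slots)
  model <- gene_model(paste0("sim", cfg$seed), sl_df, ex_df,
                      constraints, terminators,
                      genome = genome,
                      genome_ref = paste0("sim", cfg$seed, "_genome"))
  stop_if_invalid(model)
  truth <- list(exons = ex_df, ancestors = ancestors, anchors = anchors,
                config = cfg)
  list(model = model, truth = truth)
}

#' Sample transcript chains from a gene model
#'
#' Draws `n` valid membrane-bound isoforms (cluster choices by
#' `usage_weights`, optional exons with probability 1/2, constraints enforced
#' by rejection) and returns their exon chains plus the sampled specs as
#' truth.
#'
#' @param model a [gene_model()].
#' @param n number of chains.
#' @param usage_weights optional list `slot -> numeric weights` over that
#'   cluster's variants.
#' @param seed integer seed.
#' @return list with `chains` (named list of exon-id vectors) and `truth`
#'   (list of `isoform_spec`s).
#' @export
simulate_transcripts <- function(model, n, usage_weights = NULL, seed = 1L) {
  stop_if_invalid(model)
  if (n == 0L) return(list(chains = stats::setNames(list(), character()),
                           truth = list()))
  sl <- model$slots
  with_seed(seed, {
    specs <- vector("list", n)
    for (i in seq_len(n)) {
      repeat {
        cc <- character(); oi <- integer()
        for (j in seq_len(nrow(sl))) {
          s <- sl$slot[j]
          if (sl$kind[j] == "cluster") {
            ids <- slot_exons(model, s)$id
            w <- usage_weights[[as.character(s)]] %||% rep(1, length(ids))
            cc[as.character(s)] <- sample(ids, 1L, prob = w)
          } else if (sl$kind[j] == "optional" && stats::runif(1) < 0.5) {
            oi <- c(oi, s)
          }
        }
        spec <- new_isoform_spec(cc, oi, NULL, FALSE)
        cn <- model$constraints
        ok <- !nrow(cn) || all(vapply(seq_len(nrow(cn)), function(ci) {
          sel <- c(as.list(cc),
                   stats::setNames(as.list(rep("1", length(oi))), as.character(oi)))
          constraint_holds(model, cn[ci, , drop = FALSE], sel, sl$slot)
        }, TRUE))
        if (ok) { specs[[i]] <- spec; break }
      }
    }
    chains <- lapply(specs, function(sp) names(splice_parts_ids(model, sp)))
    names(chains) <- sprintf("contig%03d", seq_len(n))
    list(chains = chains, truth = specs)
  })
}

## exon ids contributing to an isoform, in slot order (placeholders excluded)
splice_parts_ids <- function(model, spec) {
  sl <- model$slots
  out <- character()
  for (j in seq_len(nrow(sl))) {
    s <- sl$slot[j]
    id <- switch(sl$kind[j],
                 placeholder = NULL,
                 constitutive = as.character(s),
                 optional = if (s %in% spec$optional_included) as.character(s),
                 cluster = spec$cluster_choices[[as.character(s)]])
    if (!is.null(id)) out[[length(out) + 1L]] <- id
  }
  stats::setNames(rep(NA_character_, length(out)), out)
}

#' Simulate an amplicon clone survey
#'
#' Emulates a per-tissue cloning experiment: for each individual, tissue and
#' clone, one variant is drawn per cluster (by the tissue's usage weights)
#' and the amplicon spanning the clusters (chosen variants plus intervening
#' constitutive exons) is copied with per-base substitution errors.
#'
#' @param model a [gene_model()] with at least one cluster.
#' @param config a [sim_config()]; uses `n_individuals`, `clones_per_sample`,
#'   `tissues`, `usage_weights` (`tissue -> slot -> weights`) and
#'   `clone_error_rate`, seeded by `config$seed`.
#' @return list with `clones` (data.frame `clone_id`, `individual`, `tissue`,
#'   `sequence`) and `truth` (data.frame `clone_id`, `tissue`, `cluster_slot`,
#'   `variant`, `n_errors`).
#' @export
simulate_clone_survey <- function(model, config) {
  stop_if_invalid(model)
  stopifnot(inherits(config, "sim_config"))
  sl <- model$slots
  cl_slots <- sl$slot[sl$kind == "cluster"]
  if (!length(cl_slots)) stop("model has no cluster slot")
  span <- sl$slot[sl$slot >= min(cl_slots) & sl$slot <= max(cl_slots)]

  with_seed(config$seed + 1L, {
    clones <- list(); truth <- list()
    for (ind in seq_len(config$n_individuals)) {
      for (tis in config$tissues) {
        for (cl in seq_len(config$clones_per_sample)) {
          id <- sprintf("ind%02d_%s_c%02d", ind, tis, cl)
          parts <- character(); chosen <- list()
          for (s in span) {
            kind <- sl$kind[sl$slot == s]
            if (kind == "constitutive") {
              parts <- c(parts, model$exons$sequence[model$exons$id == as.character(s)])
            } else if (kind == "cluster") {
              ex <- slot_exons(model, s)
              w <- config$usage_weights[[tis]][[as.character(s)]] %||%
                rep(1, nrow(ex))
              pick <- sample(seq_len(nrow(ex)), 1L, prob = w)
              parts <- c(parts, ex$sequence[pick])
              chosen[[as.character(s)]] <- ex$id[pick]
            }
          }
          seqnt <- strsplit(paste(parts, collapse = ""), "")[[1L]]
          err <- which(stats::runif(length(seqnt)) < config$clone_error_rate)
          for (p in err)
            seqnt[p] <- sample(setdiff(c("A", "C", "G", "T"), seqnt[p]), 1L)
          clones[[id]] <- data.frame(
            clone_id = id, individual = ind, tissue = tis,
            sequence = paste(seqnt, collapse = ""), stringsAsFactors = FALSE)
          truth[[id]] <- data.frame(
            clone_id = id, tissue = tis,
            cluster_slot = as.integer(names(chosen)),
            variant = unlist(chosen, use.names = FALSE),
            n_errors = length(err), stringsAsFactors = FALSE)
        }
      }
    }
    clones <- do.call(rbind, clones); rownames(clones) <- NULL
    truth <- do.call(rbind, truth); rownames(truth) <- NULL
    list(clones = clones, truth = truth)
  })
}

## ---- dual-frame construction ----------------------------------------------

#' Encode two peptides in overlapping reading frames
#'
#' Searches, by deterministic backtracking over synonymous codons, for a
#' nucleotide sequence whose frame-0 translation is `outer` (plus stop) and
#' which contains, starting at a frame-shifted offset, a region translating
#' to `inner` (plus stop). Positions downstream of the outer stop codon
#' (untranslated exon tail of length `utr`) are unconstrained, mirroring
#' terminal exons whose genomic span extends past the stop codon. Offsets are
#' tried in order of decreasing overlap with the outer coding region under a
#' per-offset node budget, so the result is reproducible.
#'
#' @param outer,inner peptide strings (no stop character).
#' @param utr untranslated tail length in nt (default 45).
#' @return list with `sequence`, `offset` (0-based; `offset %% 3` is the
#'   inner frame), `overlap` (nt shared with the outer coding region), or
#'   NULL when no placement is found.
#' @export
encode_dual_frame <- function(outer, inner, utr = 45L) {
  outer_aa <- c(strsplit(outer, "")[[1L]], "*")
  inner_aa <- c(strsplit(inner, "")[[1L]], "*")
  gc_codons <- lapply(stats::setNames(nm = unique(c(outer_aa, inner_aa))),
                      function(a) names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == a])
  Lo <- 3L * length(outer_aa); Li <- 3L * length(inner_aa)
  ds <- seq(1L, Lo + utr - Li)
  ds <- ds[ds %% 3L != 0L]
  for (d in ds) {
    res <- dual_frame_place(outer_aa, inner_aa, d, Lo, utr, gc_codons)
    if (!is.null(res))
      return(list(sequence = res, offset = d, overlap = max(0L, Lo - d)))
  }
  NULL
}

dual_frame_place <- function(outer_aa, inner_aa, d, Lo, utr,
                             gc_codons, budget = 4000L) {
  gc <- Biostrings::GENETIC_CODE
  n <- length(outer_aa)
  seqv <- character(Lo + utr)
  nodes <- 0L
  rec <- function(i) {
    nodes <<- nodes + 1L
    if (nodes > budget) return(NA)
    if (i > n) {
      for (j in seq_along(inner_aa)) {
        s <- d + (j - 1L) * 3L + 1L; e <- s + 2L
        if (e <= Lo) next
        fixed_idx <- which(s:e <= Lo)
        hit <- FALSE
        for (cd in gc_codons[[inner_aa[j]]]) {
          cs <- strsplit(cd, "")[[1L]]
          if (!length(fixed_idx) ||
              all(cs[fixed_idx] == seqv[(s:e)[fixed_idx]])) {
            seqv[s:e] <<- cs; hit <- TRUE; break
          }
        }
        if (!hit) return(FALSE)
      }
      seqv[seqv == ""] <<- "T"
      return(TRUE)
    }
    for (cd in gc_codons[[outer_aa[i]]]) {
      pos <- (i - 1L) * 3L
      seqv[pos + 1:3] <<- strsplit(cd, "")[[1L]]
      ok <- TRUE
      for (j in seq_along(inner_aa)) {
        s <- d + (j - 1L) * 3L + 1L; e <- s + 2L
        if (e > pos + 3L || e > Lo) break
        if (e > pos) {
          cdn <- paste(seqv[s:e], collapse = "")
          if (gc[[cdn]] != inner_aa[j]) { ok <- FALSE; break }
        }
      }
      if (ok) { r <- rec(i + 1L); if (!identical(r, FALSE)) return(r) }
    }
    FALSE
  }
  r <- rec(1L)
  if (isTRUE(r)) paste(seqv, collapse = "") else NULL
}
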