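## Exact counting and enumeration of valid isoforms under splice constraints.
##
## Counting strategy: slots are partitioned into constraint-connected groups.
## A group without constraints contributes a closed-form factor (cluster ->
## arity, optional -> 2, constitutive -> 1); a constrained group contributes
## the count of its exhaustively enumerated valid combinations. The total is
## the product over groups. Counts are exact integers held in doubles (exact
## up to 2^53, far beyond any tandem-array gene).

## ---- choice spaces ---------------------------------------------------------

## per-slot choice vectors, in model order. cluster: variant ids; optional:
## "0"/"1" (excluded enumerated before included); others: single dummy "1".
slot_choices <- function(model, slots) {
  out <- lapply(slots, function(s) {
    kind <- model$slots$kind[model$slots$slot == s]
    if (kind == "cluster") {
      slot_exons(model, s)$id
    } else if (kind == "optional") {
      c("0", "1")
    } else "1"
  })
  names(out) <- as.character(slots)
  out
}

## does a selection (named list slot -> choice) contain exon/slot id?
## `present_slots`: integer vector of slots that exist in the isoform at all.
selection_contains <- function(model, sel, id, present_slots) {
  s <- id_to_slot(model, id)
  if (is.na(s)) stop("unknown id '", id, "' in constraint")
  if (!s %in% present_slots) return(FALSE)
  kind <- model$slots$kind[model$slots$slot == s]
  ch <- sel[[as.character(s)]]
  if (is.null(ch)) {
    ## slot present but outside the selection under evaluation: constitutive
    ## slots are always there, anything else is undetermined -> treat absent
    return(kind %in% c("constitutive", "placeholder"))
  }
  switch(kind,
         cluster = identical(ch, id),
         optional = identical(ch, "1"),
         constitutive = TRUE,
         placeholder = TRUE)
}

## evaluate one constraint row on a selection
constraint_holds <- function(model, cn_row, sel, present_slots) {
  a <- selection_contains(model, sel, cn_row$antecedent, present_slots)
  if (cn_row$kind == "implies") {
    !a || selection_contains(model, sel, cn_row$consequent, present_slots)
  } else { # forbids
    !(a && selection_contains(model, sel, cn_row$consequent, present_slots))
  }
}

## constraints applicable when counting over `slots` (the isoform's present
## slots). A constraint whose antecedent slot is absent is vacuous; one whose
## consequent slot is absent but antecedent present forbids the antecedent
## (the consequent physically cannot be spliced in).
applicable_constraints <- function(model, slots) {
  cn <- model$constraints
  if (!nrow(cn)) return(cn)
  a_in <- id_to_slot(model, cn$antecedent) %in% slots
  c_in <- id_to_slot(model, cn$consequent) %in% slots
  cn[a_in | c_in, , drop = FALSE]
}

## ---- counting --------------------------------------------------------------

## exact count of valid selections over a slot subset
count_space <- function(model, slots) {
  if (!length(slots)) return(1)
  cn <- applicable_constraints(model, slots)
  choices <- slot_choices(model, slots)

  if (!nrow(cn)) {
    return(prod(vapply(choices, length, 1L)))
  }

  ## union-find grouping of slots linked by constraints
  parent <- seq_along(slots)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(nrow(cn))) {
    ia <- match(id_to_slot(model, cn$antecedent[i]), slots)
    ic <- match(id_to_slot(model, cn$consequent[i]), slots)
    if (!is.na(ia) && !is.na(ic)) parent[find(ia)] <- find(ic)
  }
  roots <- vapply(seq_along(slots), find, 1L)
  constrained_idx <- stats::na.omit(unlist(lapply(seq_len(nrow(cn)), function(i) {
    match(c(id_to_slot(model, cn$antecedent[i]),
            id_to_slot(model, cn$consequent[i])), slots)
  })))
  con_roots <- unique(roots[constrained_idx])

  total <- 1
  groups_zero <- character()
  for (r in unique(roots)) {
    members <- slots[roots == r]
    if (!r %in% con_roots) {
      total <- total * prod(vapply(choices[as.character(members)], length, 1L))
    } else {
      n <- count_group_brute(model, members, choices[as.character(members)], cn, slots)
      if (n == 0) groups_zero <- c(groups_zero, paste(members, collapse = ","))
      total <- total * n
    }
  }
  if (length(groups_zero))
    attr(total, "diagnostic") <- paste0(
      "unsatisfiable constraints over slot group(s): ",
      paste(groups_zero, collapse = "; "))
  total
}

count_group_brute <- function(model, members, choices, cn, present_slots) {
  n <- 0
  enumerate_product(choices, function(sel) {
    ok <- all(vapply(seq_len(nrow(cn)), function(i)
      constraint_holds(model, cn[i, , drop = FALSE], sel, present_slots), TRUE))
    if (ok) n <<- n + 1
    TRUE
  })
  n
}

## iterate the Cartesian product of named choice vectors in slot-major order,
## calling fn(selection); stop when fn returns FALSE
enumerate_product <- function(choices, fn) {
  k <- length(choices)
  if (!k) { fn(stats::setNames(list(), character())); return(invisible()) }
  lens <- vapply(choices, length, 1L)
  idx <- rep(1L, k)
  repeat {
    sel <- stats::setNames(
      lapply(seq_len(k), function(j) choices[[j]][idx[j]]), names(choices))
    if (!isTRUE(fn(sel))) return(invisible())
    j <- k
    repeat {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= lens[j]) break
      idx[j] <- 1L
      j <- j - 1L
      if (j == 0L) return(invisible())
    }
  }
}

#' Count the valid isoforms of a gene model
#'
#' Exact combinatorial counts under all splice constraints, split by
#' terminator class. `n_membrane_bound` is the joint count over every slot
#' (for constraint-free models this equals `n_extracellular * n_tail`);
#' `n_tail_less` counts isoforms ending at a retained-intron terminator, which
#' freezes every slot after the retained intron out of the transcript;
#' `n_total` is their sum.
#'
#' @param model a [gene_model()].
#' @return an `isoform_count`: list with `n_extracellular`, `n_tail`,
#'   `n_membrane_bound`, `n_tail_less`, `n_total`. If some constraint group
#'   admits no valid combination the affected counts are 0 and a
#'   `diagnostic` attribute names the slots involved.
#' @examples
#' count_isoforms(pmdscam_model())
#' @export
count_isoforms <- function(model) {
  stop_if_invalid(model)
  sl <- model$slots
  extra <- sl$slot[sl$region == "extracellular"]
  tail_slots <- sl$slot[sl$region == "tail"]

  n_extra <- count_space(model, extra)
  n_tail <- count_space(model, tail_slots)
  n_mb <- count_space(model, sl$slot)

  tm <- model$terminators
  ri <- tm[tm$kind == "retained_intron", , drop = FALSE]
  n_tl <- 0
  for (i in seq_len(nrow(ri))) {
    n_tl <- n_tl + as.numeric(count_space(model, sl$slot[sl$slot <= ri$after_slot[i]]))
  }

  diag <- c(attr(n_extra, "diagnostic"), attr(n_tail, "diagnostic"),
            attr(n_mb, "diagnostic"))
  out <- list(n_extracellular = as.numeric(n_extra),
              n_tail = as.numeric(n_tail),
              n_membrane_bound = as.numeric(n_mb),
              n_tail_less = n_tl,
              n_total = as.numeric(n_mb) + n_tl)
  if (length(diag)) attr(out, "diagnostic") <- unique(diag)
  structure(out, class = "isoform_count")
}

#' @export
print.isoform_count <- function(x, ...) {
  fmt <- function(n) format(n, big.mark = ",", scientific = FALSE)
  cat("isoform count\n")
  cat("  extracellular combinations: ", fmt(x$n_extracellular), "\n", sep = "")
  cat("  tail combinations:          ", fmt(x$n_tail), "\n", sep = "")
  cat("  membrane-bound isoforms:    ", fmt(x$n_membrane_bound), "\n", sep = "")
  cat("  tail-less isoforms:         ", fmt(x$n_tail_less), "\n", sep = "")
  cat("  total:                      ", fmt(x$n_total), "\n", sep = "")
  if (!is.null(attr(x, "diagnostic")))
    cat("  ! ", paste(attr(x, "diagnostic"), collapse = "\n  ! "), "\n", sep = "")
  invisible(x)
}

## ---- enumeration -----------------------------------------------------------

new_isoform_spec <- function(cluster_choices, optional_included, terminator,
                             tail_less) {
  structure(list(cluster_choices = cluster_choices,
                 optional_included = optional_included,
                 terminator = terminator,
                 tail_less = tail_less),
            class = "isoform_spec")
}

#' @export
print.isoform_spec <- function(x, ...) {
  cc <- paste(names(x$cluster_choices), x$cluster_choices,
              sep = "->", collapse = " ")
  cat("<isoform_spec> ",
      if (x$tail_less) "tail-less" else "membrane-bound",
      if (nzchar(cc)) paste0(" | clusters: ", cc) else "",
      " | optional in: {", paste(x$optional_included, collapse = ","), "}\n",
      sep = "")
  invisible(x)
}

## selections (named list) -> isoform_spec for slot subset
sel_to_spec <- function(model, sel, slots, tail_less, terminator) {
  kinds <- model$slots$kind[match(slots, model$slots$slot)]
  cl <- slots[kinds == "cluster"]
  op <- slots[kinds == "optional"]
  cc <- stats::setNames(vapply(as.character(cl), function(s) sel[[s]], ""),
                        as.character(cl))
  oi <- op[vapply(as.character(op), function(s) identical(sel[[s]], "1"), TRUE)]
  new_isoform_spec(cc, as.integer(oi), terminator, tail_less)
}

#' Enumerate valid isoforms
#'
#' Yields every valid isoform exactly once, in a deterministic slot-major
#' order (cluster variants in model order; optional exons excluded before
#' included). Membrane-bound isoforms come first, then tail-less isoforms for
#' each retained-intron terminator in model order. The enumeration length
#' equals [count_isoforms()]'s `n_total` when `limit` is not hit.
#'
#' @param model a [gene_model()].
#' @param limit maximum number of isoforms to yield; when exceeded the result
#'   carries attribute `truncated = TRUE` (never silent).
#' @return list of `isoform_spec` objects.
#' @export
enumerate_isoforms <- function(model, limit = Inf) {
  stop_if_invalid(model)
  sl <- model$slots
  out <- vector("list", min(limit, 65536L))
  n <- 0L
  truncated <- FALSE

  emit_space <- function(slots, tail_less, terminator) {
    cn <- applicable_constraints(model, slots)
    choices <- slot_choices(model, slots)
    enumerate_product(choices, function(sel) {
      ok <- !nrow(cn) || all(vapply(seq_len(nrow(cn)), function(i)
        constraint_holds(model, cn[i, , drop = FALSE], sel, slots), TRUE))
      if (ok) {
        if (n >= limit) { truncated <<- TRUE; return(FALSE) }
        n <<- n + 1L
        out[[n]] <<- sel_to_spec(model, sel, slots, tail_less, terminator)
      }
      TRUE
    })
    !truncated
  }

  tm <- model$terminators
  if (emit_space(sl$slot, tail_less = FALSE, terminator = NULL)) {
    ri <- tm[tm$kind == "retained_intron", , drop = FALSE]
    for (i in seq_len(nrow(ri))) {
      if (!emit_space(sl$slot[sl$slot <= ri$after_slot[i]], tail_less = TRUE,
                      terminator = list(kind = "retained_intron",
                                        after_slot = ri$after_slot[i])))
        break
    }
  }
  out <- out[seq_len(n)]
  ## attach the stop-variant terminator implied by the terminal cluster choice
  sv <- tm[tm$kind == "stop_variant", , drop = FALSE]
  if (nrow(sv)) {
    for (i in seq_along(out)) {
      if (out[[i]]$tail_less) next
      hit <- intersect(sv$variant, out[[i]]$cluster_choices)
      if (length(hit))
        out[[i]]$terminator <- list(kind = "stop_variant", variant = hit[[1L]])
    }
  }
  if (truncated) attr(out, "truncated") <- TRUE
  out
}

#' Classify an isoform as membrane-bound or tail-less
#'
#' An isoform is tail-less iff it terminates at a retained-intron terminator
#' (the retained intron carries its own stop codon and polyadenylation
#' signal, so no transmembrane or cytoplasmic exons are translated).
#'
#' @param spec an `isoform_spec` from [enumerate_isoforms()].
#' @return `"tail_less"` or `"membrane_bound"`.
#' @export
classify_isoform <- function(spec) {
  stopifnot(inherits(spec, "isoform_spec"))
  if (isTRUE(spec$tail_less) ||
      identical(spec$terminator$kind, "retained_intron")) "tail_less"
  else "membrane_bound"
}
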