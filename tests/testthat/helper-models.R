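## Shared fixtures and independent oracles. Oracles are deliberately naive
## re-implementations (exhaustive filters, textbook DP) kept free of any
## package internals beyond the public model accessors.

## a minimal hand-built model: constitutive "1", cluster 2 {2.1, 2.2},
## optional "3", with sequences
tiny_model <- function(constraints = empty_constraints(),
                       terminators = empty_terminators()) {
  slots <- data.frame(slot = 1:3,
                      kind = c("constitutive", "cluster", "optional"),
                      region = c("extracellular", "extracellular", "tail"))
  exons <- data.frame(
    id = c("1", "2.1", "2.2", "3"),
    slot = c(1L, 2L, 2L, 3L),
    variant = c(NA, 1L, 2L, NA),
    start = c(1L, 10L, 20L, 30L),
    end = c(6L, 15L, 25L, 35L),
    strand = "+",
    frame_offset = 0L,
    sequence = c("ATGGCA", "GAATCA", "GAGTGC", "CATTGC"),
    stringsAsFactors = FALSE)
  gene_model("tiny", slots, exons, constraints, terminators)
}

## random small model for property tests: clusters (arity 2-3), optionals,
## constitutives; 0-2 random constraints; sometimes a retained intron
random_model <- function(seed) {
  set.seed(seed)
  n_slots <- sample(2:6, 1)
  kinds <- sample(c("constitutive", "optional", "cluster"), n_slots,
                  replace = TRUE, prob = c(0.3, 0.35, 0.35))
  region <- sort(sample(c("extracellular", "tail"), n_slots, replace = TRUE))
  slots <- data.frame(slot = seq_len(n_slots), kind = kinds, region = region)
  exons <- do.call(rbind, lapply(seq_len(n_slots), function(s) {
    if (kinds[s] == "cluster") {
      arity <- sample(2:3, 1)
      data.frame(id = paste0(s, ".", seq_len(arity)), slot = s,
                 variant = seq_len(arity), start = NA_integer_,
                 end = NA_integer_, strand = "+", frame_offset = 0L,
                 sequence = NA_character_, stringsAsFactors = FALSE)
    } else {
      data.frame(id = as.character(s), slot = s, variant = NA_integer_,
                 start = NA_integer_, end = NA_integer_, strand = "+",
                 frame_offset = 0L, sequence = NA_character_,
                 stringsAsFactors = FALSE)
    }
  }))
  ids <- exons$id[exons$slot %in% slots$slot[slots$kind != "constitutive"]]
  constraints <- empty_constraints()
  n_cn <- sample(0:2, 1)
  if (length(ids) >= 2 && n_cn > 0) {
    for (i in seq_len(n_cn)) {
      pair <- sample(ids, 2)
      constraints <- rbind(constraints, data.frame(
        kind = sample(c("implies", "forbids"), 1),
        antecedent = pair[1], consequent = pair[2],
        stringsAsFactors = FALSE))
    }
  }
  terminators <- empty_terminators()
  if (stats::runif(1) < 0.4) {
    terminators <- rbind(terminators, data.frame(
      kind = "retained_intron",
      after_slot = sample(slots$slot, 1),
      variant = NA_character_, sequence = NA_character_,
      stringsAsFactors = FALSE))
  }
  gene_model(paste0("rand", seed), slots, exons, constraints, terminators)
}

## ---- independent isoform-space oracle --------------------------------------

## all raw selections over the given slots as a list of named lists
## slot -> choice ("0"/"1" for optional, variant id for cluster)
oracle_selections <- function(model, slots) {
  opts <- lapply(slots, function(s) {
    kind <- model$slots$kind[model$slots$slot == s]
    if (kind == "cluster") model$exons$id[model$exons$slot == s]
    else if (kind == "optional") c("0", "1")
    else "1"
  })
  names(opts) <- as.character(slots)
  if (!length(opts)) return(list(stats::setNames(list(), character())))
  grid <- expand.grid(opts, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) as.list(grid[i, , drop = FALSE]))
}

## does a raw selection contain an exon/slot id (independent of the package)
oracle_contains <- function(model, sel, id, slots) {
  row <- model$exons[model$exons$id == id, ]
  s <- if (nrow(row)) row$slot[1] else as.integer(id)
  if (!s %in% slots) return(FALSE)
  kind <- model$slots$kind[model$slots$slot == s]
  if (kind == "constitutive" || kind == "placeholder") return(TRUE)
  ch <- sel[[as.character(s)]]
  if (kind == "optional") return(identical(ch, "1"))
  identical(ch, id)
}

oracle_valid <- function(model, sel, slots) {
  cn <- model$constraints
  for (i in seq_len(nrow(cn))) {
    a <- oracle_contains(model, sel, cn$antecedent[i], slots)
    b <- oracle_contains(model, sel, cn$consequent[i], slots)
    if (cn$kind[i] == "implies" && a && !b) return(FALSE)
    if (cn$kind[i] == "forbids" && a && b) return(FALSE)
  }
  TRUE
}

## exhaustive Cartesian-product-plus-filter count, split like isoform_count
oracle_count <- function(model) {
  all_slots <- model$slots$slot
  mem <- sum(vapply(oracle_selections(model, all_slots), oracle_valid,
                    TRUE, model = model, slots = all_slots))
  ri <- model$terminators[model$terminators$kind == "retained_intron", ,
                          drop = FALSE]
  tl <- 0
  for (i in seq_len(nrow(ri))) {
    sub <- all_slots[all_slots <= ri$after_slot[i]]
    tl <- tl + sum(vapply(oracle_selections(model, sub), oracle_valid,
                          TRUE, model = model, slots = sub))
  }
  list(membrane = mem, tail_less = tl, total = mem + tl)
}

## ---- independent Smith-Waterman oracle -------------------------------------

## textbook O(nm) local alignment score, match +1 / mismatch -1 / gap -1
sw_score_oracle <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  prev <- numeric(m + 1)
  best <- 0
  for (i in seq_len(n)) {
    cur <- numeric(m + 1)
    for (j in seq_len(m)) {
      sub <- prev[j] + if (av[i] == bv[j]) 1 else -1
      cur[j + 1] <- max(0, sub, prev[j + 1] - 1, cur[j] - 1)
      if (cur[j + 1] > best) best <- cur[j + 1]
    }
    prev <- cur
  }
  best
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## random peptide for oracle tests
rand_pep <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

## exon-id chains of every membrane-bound isoform of a model (public API)
membrane_chains <- function(model) {
  specs <- Filter(function(s) !s$tail_less, enumerate_isoforms(model))
  chains <- lapply(specs, function(sp) names(splice_isoform(model, sp)))
  names(chains) <- paste0("iso", seq_along(chains))
  chains
}
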