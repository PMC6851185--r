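test_that("counting handles the textbook cases", {
  ## one constitutive exon -> a single isoform
  m1 <- gene_model(
    "one",
    data.frame(slot = 1L, kind = "constitutive", region = "extracellular"),
    data.frame(id = "1", slot = 1L, variant = NA_integer_, start = NA_integer_,
               end = NA_integer_, strand = "+", frame_offset = 0L,
               sequence = NA_character_))
  expect_equal(count_isoforms(m1)$n_total, 1)

  ## clusters [2,3] + optional O with "O implies B.2": 2*3 = 6 with O out,
  ## 2*1 = 2 with O in -> 8 of the 12 raw combinations
  slots <- data.frame(slot = 1:3, kind = c("cluster", "cluster", "optional"),
                      region = "extracellular")
  exons <- data.frame(
    id = c("1.1", "1.2", "2.1", "2.2", "2.3", "3"),
    slot = c(1L, 1L, 2L, 2L, 2L, 3L),
    variant = c(1L, 2L, 1L, 2L, 3L, NA),
    start = NA_integer_, end = NA_integer_, strand = "+",
    frame_offset = 0L, sequence = NA_character_)
  m2 <- gene_model("combo", slots, exons, constraints = data.frame(
    kind = "implies", antecedent = "3", consequent = "2.2"))
  expect_equal(count_isoforms(m2)$n_total, 8)
  expect_equal(oracle_count(m2)$total, 8)

  ## unsatisfiable constraints -> 0 with a diagnostic
  m3 <- gene_model("unsat", slots, exons, constraints = data.frame(
    kind = c("implies", "forbids"),
    antecedent = c("3", "3"), consequent = c("2.2", "2.2")))
  cnt <- count_isoforms(m3)
  expect_gt(cnt$n_total, 0)          # only O-in combos die; O-out survive
  m4 <- gene_model("unsat2", slots, exons, constraints = data.frame(
    kind = "forbids", antecedent = "1.1", consequent = "1.1"))
  ## forbidding a variant against itself kills every isoform using it;
  ## a fully unsatisfiable group must carry a diagnostic
  m5 <- gene_model(
    "unsat3", slots[1:2, ], exons[1:5, ],
    constraints = data.frame(kind = c("forbids", "forbids", "forbids"),
                             antecedent = c("1.1", "1.2", "1.1"),
                             consequent = c("1.1", "1.2", "1.2")))
  cnt5 <- count_isoforms(m5)
  expect_equal(cnt5$n_total, 0)
  expect_match(attr(cnt5, "diagnostic"), "unsatisfiable")
})

test_that("enumeration agrees with counting and the exhaustive oracle", {
  for (seed in 1:60) {
    m <- random_model(seed)
    cnt <- count_isoforms(m)
    specs <- enumerate_isoforms(m)
    orc <- oracle_count(m)
    expect_equal(length(specs), cnt$n_total,
                 info = paste("seed", seed))
    expect_equal(cnt$n_membrane_bound, orc$membrane,
                 info = paste("seed", seed))
    expect_equal(cnt$n_tail_less, orc$tail_less,
                 info = paste("seed", seed))
    ## no duplicate specs
    keys <- vapply(specs, function(s)
      paste(s$tail_less,
            paste(names(s$cluster_choices), s$cluster_choices, collapse = ";"),
            paste(s$optional_included, collapse = ","), sep = "|"), "")
    expect_equal(anyDuplicated(keys), 0L, info = paste("seed", seed))
  }
})

test_that("enumeration order is deterministic and truncation is flagged", {
  m <- pmdscam_model("tail")
  a <- enumerate_isoforms(m)
  b <- enumerate_isoforms(m)
  expect_identical(a, b)
  expect_null(attr(a, "truncated"))
  tr <- enumerate_isoforms(m, limit = 10)
  expect_length(tr, 10)
  expect_true(attr(tr, "truncated"))
})

test_that("counts are multiplicative over independent slot groups", {
  for (seed in c(2, 5, 11)) {
    a <- random_model(seed)
    b <- random_model(seed + 100)
    ## concatenate b's slots after a's (shift numbering), drop terminators
    shift <- max(a$slots$slot)
    b2 <- b
    b2$slots$slot <- b2$slots$slot + shift
    b2$exons$slot <- b2$exons$slot + shift
    renumber <- function(id) {
      ifelse(grepl("\\.", id),
             paste0(as.integer(sub("\\..*", "", id)) + shift, ".",
                    sub(".*\\.", "", id)),
             as.character(as.integer(id) + shift))
    }
    b2$exons$id <- renumber(b2$exons$id)
    b2$constraints$antecedent <- renumber(b2$constraints$antecedent)
    b2$constraints$consequent <- renumber(b2$constraints$consequent)
    ab <- gene_model("prod", rbind(a$slots, b2$slots),
                     rbind(a$exons, b2$exons),
                     rbind(a$constraints, b2$constraints))
    na <- count_isoforms(gene_model("a", a$slots, a$exons, a$constraints))
    nb <- count_isoforms(gene_model("b", b2$slots, b2$exons, b2$constraints))
    expect_equal(count_isoforms(ab)$n_membrane_bound,
                 na$n_membrane_bound * nb$n_membrane_bound)
  }
})

test_that("removing a constraint never decreases the count", {
  for (seed in 1:30) {
    m <- random_model(seed)
    if (!nrow(m$constraints)) next
    full <- count_isoforms(m)$n_total
    relaxed <- m
    relaxed$constraints <- m$constraints[-1, , drop = FALSE]
    expect_gte(count_isoforms(relaxed)$n_total, full)
  }
})

test_that("isoforms classify by their terminator", {
  tail <- pmdscam_model("tail")
  specs <- enumerate_isoforms(tail)
  cls <- vapply(specs, classify_isoform, "")
  expect_equal(sum(cls == "membrane_bound"), 384)
  expect_equal(sum(cls == "tail_less"), 1)   # slot 31 alone upstream of the intron
  tl <- specs[[which(cls == "tail_less")[1]]]
  expect_true(tl$tail_less)
  expect_equal(tl$terminator$kind, "retained_intron")
  sv <- specs[[which(cls == "membrane_bound")[1]]]
  expect_equal(sv$terminator$kind, "stop_variant")
})
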