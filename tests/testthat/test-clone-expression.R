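## small survey model shared across the clone tests
survey_model <- function() {
  cfg <- sim_config(seed = 21, cluster_sizes = c(4L, 3L),
                    variant_aa_len = c(30L, 34L))
  simulate_gene(cfg)$model
}

test_that("clone assignment follows identity and tie rules", {
  m <- survey_model()
  ex <- m$exons[m$exons$slot == 2L, ]
  ## a clone equal to a variant sequence assigns at identity 1
  a <- assign_clone(ex$sequence[2], m, clusters = 2L)
  expect_equal(a$status, "assigned")
  expect_equal(a$variant, ex$id[2])
  expect_equal(a$identity, 1)

  ## two substitutions in a ~100-nt variant: identity 1 - 2/L, assigned
  seqv <- strsplit(ex$sequence[3], "")[[1]]
  seqv[10] <- setdiff(c("A", "C", "G", "T"), seqv[10])[1]
  seqv[50] <- setdiff(c("A", "C", "G", "T"), seqv[50])[1]
  mutated <- paste(seqv, collapse = "")
  a2 <- assign_clone(mutated, m, clusters = 2L)
  expect_equal(a2$status, "assigned")
  expect_equal(a2$variant, ex$id[3])
  expect_equal(a2$identity, 1 - 2 / nchar(ex$sequence[3]))

  ## a clone equidistant to two variants is ambiguous: build variants that
  ## differ at exactly two sites and a clone matching one site of each
  base <- strsplit(strrep("ACGT", 25), "")[[1]]
  v1 <- v2 <- cl <- base
  v1[10] <- "A"; v2[10] <- "C"; cl[10] <- "A"
  v1[60] <- "G"; v2[60] <- "T"; cl[60] <- "T"
  tie_model <- gene_model(
    "tie",
    data.frame(slot = 1L, kind = "cluster", region = "extracellular"),
    data.frame(id = c("1.1", "1.2"), slot = 1L, variant = 1:2,
               start = NA_integer_, end = NA_integer_, strand = "+",
               frame_offset = 0L,
               sequence = c(paste(v1, collapse = ""),
                            paste(v2, collapse = "")),
               stringsAsFactors = FALSE))
  a3 <- assign_clone(paste(cl, collapse = ""), tie_model)
  expect_equal(a3$status, "ambiguous")
  expect_equal(a3$identity, 0.99)

  expect_error(assign_clone("", m), "empty")
})

test_that("every clone lands in exactly one status per covered cluster", {
  m <- survey_model()
  cfg <- sim_config(seed = 21, cluster_sizes = c(4L, 3L),
                    n_individuals = 2L, clones_per_sample = 5L,
                    clone_error_rate = 0.01)
  surv <- simulate_clone_survey(m, cfg)
  asg <- assign_clones(surv$clones, m)
  expect_equal(nrow(asg), nrow(surv$clones) * 2L)   # two clusters
  expect_true(all(asg$status %in%
                    c("assigned", "ambiguous", "unassigned", "uncovered")))
  tm <- tally_matrix(asg, m)
  total_cells <- sum(vapply(tm$counts, sum, 0))
  expect_equal(total_cells + nrow(tm$excluded), nrow(asg))
})

test_that("assignments recover the generating variants", {
  m <- survey_model()
  cfg <- sim_config(seed = 33, cluster_sizes = c(4L, 3L),
                    n_individuals = 2L, clones_per_sample = 10L,
                    clone_error_rate = 0)
  surv <- simulate_clone_survey(m, cfg)
  asg <- assign_clones(surv$clones, m)
  expect_true(all(asg$status == "assigned"))
  expect_true(all(asg$identity == 1))
  merged <- merge(asg, surv$truth,
                  by = c("clone_id", "tissue", "cluster_slot"))
  expect_equal(merged$variant.x, merged$variant.y)
})

test_that("zero-weighted variants are reported undetected in both tissues", {
  m <- survey_model()
  w <- list(hemocyte = list("2" = c(0, 1, 1, 0)),
            nerve = list("2" = c(0, 1, 1, 0)))
  cfg <- sim_config(seed = 5, cluster_sizes = c(4L, 3L), n_individuals = 3L,
                    clones_per_sample = 8L, usage_weights = w,
                    clone_error_rate = 0)
  surv <- simulate_clone_survey(m, cfg)
  tm <- tally_matrix(assign_clones(surv$clones, m), m)
  expect_equal(tm$undetected[["2"]]$overall, c("2.1", "2.4"))
  expect_equal(tm$undetected[["2"]]$per_tissue$hemocyte, c("2.1", "2.4"))
  ## the unrestricted cluster is fully sampled at this depth
  expect_length(tm$undetected[["4"]]$overall, 0)
})

test_that("detection grows monotonically with sampling depth", {
  m <- survey_model()
  cfg <- sim_config(seed = 13, cluster_sizes = c(4L, 3L), n_individuals = 2L,
                    clones_per_sample = 10L, clone_error_rate = 0)
  surv <- simulate_clone_survey(m, cfg)
  asg <- assign_clones(surv$clones, m)
  detected <- function(a) {
    tm <- tally_matrix(a, m)
    unlist(lapply(names(tm$counts), function(s)
      paste(s, rownames(tm$counts[[s]])[rowSums(tm$counts[[s]]) > 0])))
  }
  shallow <- detected(asg[asg$clone_id %in% unique(asg$clone_id)[1:10], ])
  deep <- detected(asg)
  expect_true(all(shallow %in% deep))
})

test_that("the long-format table mirrors the matrices", {
  m <- survey_model()
  cfg <- sim_config(seed = 13, cluster_sizes = c(4L, 3L), n_individuals = 1L,
                    clones_per_sample = 5L, clone_error_rate = 0)
  surv <- simulate_clone_survey(m, cfg)
  tm <- tally_matrix(assign_clones(surv$clones, m), m)
  long <- detection_long(tm)
  expect_equal(sum(long$count), sum(vapply(tm$counts, sum, 0)))
  expect_setequal(unique(long$cluster_slot), as.integer(names(tm$counts)))
})
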