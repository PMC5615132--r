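test_that("prevalence threshold is the ceiling of one third of the cohort", {
  expect_identical(prevalenceThreshold(19), 7L)
  expect_identical(prevalenceThreshold(3), 1L)
  expect_identical(prevalenceThreshold(20), 7L)
  expect_identical(prevalenceThreshold(1), 1L)
  expect_error(prevalenceThreshold(0), "positive integer")
  expect_error(prevalenceThreshold(2.5), "positive integer")
})

test_that("step recovery has OR semantics over isofunctional accessions", {
  expect_true(stepRecovered(c("K00001", "K09999"), "K00001"))
  expect_true(stepRecovered("K00002", c("K00001", "K00002")))
  expect_false(stepRecovered(character(0), c("K00001", "K00002")))
})

test_that("tri-state scoring follows the signature / prevalence rule", {
  pw <- list(pathway_id = "p", name = "p",
             steps = list(s1 = "A", s2 = "B", s3 = "C", s4 = "D"),
             signature = "s4")
  # fully recovered, signature present
  r <- scorePathway(c("A", "B", "C", "D"), pw, prevalence = 10, n_genomes = 19)
  expect_identical(r$state, "fraction")
  expect_identical(r$completeness, 1)
  # signature absent but prevalent in >= 7 of 19: rescued fraction
  r <- scorePathway(c("A", "B"), pw, prevalence = 7, n_genomes = 19)
  expect_identical(r$state, "fraction")
  expect_identical(r$completeness, 0.5)
  # signature absent, prevalence below threshold: likely absent
  r <- scorePathway(c("A", "B"), pw, prevalence = 5, n_genomes = 19)
  expect_identical(r$state, "likely_absent")
  expect_true(is.na(r$completeness))
  # nothing recovered at all
  r <- scorePathway(character(0), pw, prevalence = 10, n_genomes = 19)
  expect_identical(r$state, "zero")
  expect_identical(r$recovered_steps, 0L)
})

test_that("pathways without a signature report fractions, never (0)", {
  pw <- list(pathway_id = "nosig", name = "nosig",
             steps = list(s1 = "A", s2 = "B"), signature = character(0))
  expect_warning(r <- scorePathway("A", pw, prevalence = 0, n_genomes = 19),
                 "no signature")
  expect_identical(r$state, "fraction")
  expect_identical(r$completeness, 0.5)
  expect_true(r$no_signature)
  r <- scorePathway(character(0), pw, prevalence = 0, n_genomes = 19)
  expect_identical(r$state, "zero")
})

test_that("scoring agrees with exhaustive enumeration of presence patterns", {
  # all 2^5 per-genome presence patterns x every possible prevalence in a
  # 6-genome cohort, against an independent restatement of the rule
  accs <- c("A", "B", "C", "D", "E")
  pw <- list(pathway_id = "p", name = "p",
             steps = as.list(stats::setNames(accs, paste0("s", 1:5))),
             signature = c("s2", "s5"))
  sig_idx <- c(2L, 5L)
  for (mask in 0:31) {
    present <- as.logical(bitwAnd(mask, 2^(0:4)))
    genome <- accs[present]
    for (prev in 0:6) {
      got <- scorePathway(genome, pw, prevalence = prev, n_genomes = 6)
      want <- bruteScore(present, sig_idx, prev, 6)
      expect_identical(got$state, want)
      if (want == "fraction")
        expect_equal(got$completeness, sum(present) / 5)
    }
  }
})

test_that("cohort scoring matches brute-force recomputation on random cohorts", {
  accs <- c("A", "B", "C")
  pw <- PathwaySet(list(list(
    pathway_id = "p", name = "p",
    steps = list(s1 = "A", s2 = "B", s3 = "C"), signature = "s3")))
  set.seed(99)
  for (rep in 1:40) {
    patterns <- matrix(stats::runif(6 * 3) < 0.5, nrow = 6)
    ids <- sprintf("G%d", 1:6)
    rows <- do.call(rbind, lapply(1:6, function(i) {
      acc <- accs[patterns[i, ]]
      if (!length(acc)) return(NULL)
      data.frame(genome_id = ids[i], contig_id = "c1",
                 locus_tag = paste0(ids[i], "_", acc),
                 start = seq_along(acc) * 1000L,
                 end = seq_along(acc) * 1000L + 899L, strand = "+",
                 annotations = acc, localization = "unknown",
                 tm_strand_count = NA_integer_)
    }))
    if (is.null(rows)) next
    f <- tempfile(fileext = ".tsv")
    utils::write.table(rows, f, sep = "\t", quote = FALSE, row.names = FALSE)
    genes <- readGeneTable(f); unlink(f)
    cm <- cohortCompleteness(genes, pw, genome_ids = ids)
    prev <- sum(patterns[, 3])
    for (i in 1:6) {
      want <- bruteScore(patterns[i, ], 3L, prev, 6)
      got <- cm@calls[cm@calls$genome_id == ids[i], ]
      expect_identical(got$state, want)
      expect_identical(got$prevalence_support, as.integer(prev))
    }
  }
})

test_that("completeness is monotone and prevalence shrinks with the cohort", {
  pw <- list(pathway_id = "p", name = "p",
             steps = list(s1 = "A", s2 = "B", s3 = "C", s4 = "D"),
             signature = "s1")
  set.seed(4)
  frac <- function(r) if (r$state == "fraction") r$completeness else 0
  for (rep in 1:25) {
    genome <- sample(c("A", "B", "C", "D"), sample(0:4, 1))
    extra <- union(genome, sample(c("A", "B", "C", "D"), sample(0:4, 1)))
    a <- scorePathway(genome, pw, prevalence = 7, n_genomes = 19)
    b <- scorePathway(extra, pw, prevalence = 7, n_genomes = 19)
    expect_gte(frac(b), frac(a))
  }
  # dropping a genome can only keep or reduce prevalence support
  fx <- triStateFixture(7)
  cm_full <- cohortCompleteness(fx$genes, fx$pathways)
  keep <- fx$ids[-1]
  cm_small <- cohortCompleteness(
    fx$genes[S4Vectors::mcols(fx$genes)$genome_id %in% keep],
    fx$pathways, genome_ids = keep)
  expect_lte(max(cm_small@calls$prevalence_support),
             max(cm_full@calls$prevalence_support))
})

test_that("the serialized matrix uses the 1 / 0 / (0) / fraction convention", {
  fx <- triStateFixture(7)
  cm <- cohortCompleteness(fx$genes, fx$pathways)
  cells <- completenessCells(cm)
  expect_identical(unname(cells[fx$ids[1], "toy4"]), "1")
  expect_identical(unname(cells[fx$ids[19], "toy4"]), "0.50")
  fx6 <- triStateFixture(6)
  cells6 <- completenessCells(cohortCompleteness(fx6$genes, fx6$pathways))
  expect_identical(unname(cells6[fx6$ids[19], "toy4"]), "(0)")
  expect_error(cohortCompleteness(fx$genes, fx$pathways,
                                  genome_ids = c("G01", "G01")),
               "duplicate")
})

test_that("a complete synthetic cohort reproduces its planted pathway truth", {
  co <- generateCohort(compactConfig(dropout = FALSE), seed = 5)
  cm <- suppressWarnings(cohortCompleteness(cohortGenes(co),
                                            cohortPathways(co)))
  cells <- completenessCells(cm)
  truth <- cohortTruth(co)$pathway_presence
  expect_identical(unname(cells == "1"),
                   unname(truth[rownames(cells), colnames(cells)]))
  expect_true(all(cells %in% c("0", "1")))
})
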