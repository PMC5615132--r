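test_that("CxxCH motif counting scans all overlapping windows", {
  r <- countHemeMotifs("MCAACHAA")
  expect_identical(r$count, 1L)
  expect_identical(r$positions, 2L)
  expect_identical(countHemeMotifs("CGGCHCGGCH")$count, 2L)
  expect_identical(countHemeMotifs("MAAAA")$count, 0L)
  expect_identical(countHemeMotifs("")$count, 0L)
  # X is tolerated in the sequence but never matches the C/H anchors
  expect_identical(countHemeMotifs("XAAXH")$count, 0L)
  expect_identical(countHemeMotifs("CXXCH")$count, 1L)
  expect_error(countHemeMotifs("CA-CH"), "non-amino-acid")
  # overlapping motifs are all counted
  r <- countHemeMotifs("CCAACHACH")
  expect_identical(r$positions, bruteCxxch("CCAACHACH")$positions)
})

test_that("motif counting equals a brute-force window scan on random proteins", {
  set.seed(123)
  aas <- c("A", "C", "D", "E", "G", "H", "K", "L", "S", "T")
  for (rep in 1:200) {
    s <- paste(sample(aas, sample(5:80, 1), replace = TRUE), collapse = "")
    got <- countHemeMotifs(s)
    want <- bruteCxxch(s)
    expect_identical(got$count, want$count)
    expect_identical(got$positions, want$positions)
  }
})

pccFixture <- function(tm = 24L, gap_genes = 0L, hemes = 9L) {
  n_fill <- gap_genes
  tags <- c("porin", paste0("fill", seq_len(n_fill))[seq_len(n_fill)], "mhc")
  loc <- c("outer_membrane", rep("cytoplasmic", n_fill), "periplasmic")
  tmv <- c(tm, rep(NA_integer_, n_fill), NA_integer_)
  genes <- toyGeneTable(tags, localization = loc, tm_strand_count = tmv)
  prot <- Biostrings::AAStringSet(c(
    mhc = paste(rep("CAACHAA", hemes), collapse = ""),
    porin = "MKLV"))
  list(genes = genes, prot = prot)
}

test_that("PCC detection needs a 20+ strand porin adjacent to an 8-heme MHC", {
  fx <- pccFixture()
  calls <- detectPCC(fx$genes, fx$prot)
  expect_identical(nrow(calls), 1L)
  expect_match(calls$evidence, "porin=porin")
  expect_match(calls$evidence, "periplasmic_MHC=mhc")

  # fewer than 20 predicted transmembrane strands: not a porin
  fx <- pccFixture(tm = 12L)
  expect_identical(nrow(detectPCC(fx$genes, fx$prot)), 0L)
  # five intervening genes exceed the default adjacency window
  fx <- pccFixture(gap_genes = 5L)
  expect_identical(nrow(detectPCC(fx$genes, fx$prot)), 0L)
  # two intervening genes are still adjacent
  fx <- pccFixture(gap_genes = 2L)
  expect_identical(nrow(detectPCC(fx$genes, fx$prot)), 1L)
  # fewer than 8 heme-binding sites: not an MHC
  fx <- pccFixture(hemes = 7L)
  expect_identical(nrow(detectPCC(fx$genes, fx$prot)), 0L)
  # candidate without a protein sequence is skipped with a warning
  fx <- pccFixture()
  expect_warning(calls <- detectPCC(fx$genes, fx$prot["porin"]),
                 "missing protein")
  expect_identical(nrow(calls), 0L)
})

test_that("an extracellular MHC in the cluster is optional evidence", {
  genes <- toyGeneTable(c("porin", "mhc", "xmhc"),
                        localization = c("outer_membrane", "periplasmic",
                                         "extracellular"),
                        tm_strand_count = c(24L, NA, NA))
  mhc_seq <- paste(rep("CAACHAA", 9), collapse = "")
  prot <- Biostrings::AAStringSet(c(porin = "MKLV", mhc = mhc_seq,
                                    xmhc = mhc_seq))
  calls <- detectPCC(genes, prot)
  expect_identical(nrow(calls), 1L)
  expect_match(calls$evidence, "extracellular_MHC=xmhc")
})

test_that("CUT detection needs TBDR + inner transporter + GH in one window", {
  genes <- toyGeneTable(c("tbdr", "trans", "gh1", "gh2"),
                        annotations = c("COG1629", "COG0477", "GH29", "GH78"),
                        localization = c("outer_membrane", "inner_membrane",
                                         "extracellular", "cytoplasmic"))
  calls <- detectCUT(genes)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$members[[1]], c("tbdr", "trans", "gh1", "gh2"))
  expect_equal(calls$gh_surface_fraction, 0.5)
  expect_match(calls$evidence, "TBDR=tbdr")
  expect_match(calls$evidence, "inner_transporter=trans")

  # TBDR alone is not a locus
  solo <- toyGeneTable("tbdr", annotations = "COG1629")
  expect_identical(nrow(detectCUT(solo)), 0L)
})

test_that("disjoint qualifying windows give separate calls, matching the
           brute-force window enumeration", {
  n <- 40L
  ann <- rep("", n)
  ann[c(2, 3, 4)] <- c("COG1629", "COG0477", "GH29")
  ann[c(30, 32, 34)] <- c("GH2", "COG1629", "COG0477")
  genes <- toyGeneTable(sprintf("g%02d", 1:n), annotations = ann)
  calls <- detectCUT(genes)
  expect_identical(nrow(calls), 2L)
  expect_lt(calls$last_index[1], calls$first_index[2])
  want <- bruteWindowCalls(list(tbdr = c(2, 32), trans = c(3, 34),
                                gh = c(4, 30)), 15L, n)
  expect_identical(cbind(calls$first_index, calls$last_index),
                   matrix(as.integer(want), ncol = 2))
})

test_that("BMC detection pairs shell proteins with fucose/rhamnose genes", {
  genes <- toyGeneTable(c("shell", "fucA"),
                        annotations = c("pfam00936", "K01628"))
  calls <- detectBMC(genes)
  expect_identical(nrow(calls), 1L)
  expect_match(calls$evidence, "shell_protein=shell")
  expect_match(calls$evidence, "fucose_gene=fucA")
  expect_identical(nrow(detectBMC(toyGeneTable("shell",
                                               annotations = "pfam00936"))),
                   0L)
  expect_identical(nrow(detectBMC(toyGeneTable("fucA",
                                               annotations = "K01628"))),
                   0L)
  # rhamnose genes are tagged with their own role
  genes <- toyGeneTable(c("shell", "rhaD"),
                        annotations = c("pfam03319", "K01629"))
  expect_match(detectBMC(genes)$evidence, "rhamnose_gene=rhaD")
})

test_that("locus calls are invariant under reversing the contig gene order", {
  co <- generateCohort(compactConfig(dropout = FALSE), seed = 61)
  genes <- cohortGenes(co)
  calls <- detectLoci(genes, cohortProteins(co))

  # rebuild the gene table with each contig's gene order (and coordinates)
  # reversed; the detectors must find the same loci
  df <- data.frame(genome_id = S4Vectors::mcols(genes)$genome_id,
                   contig_id = as.character(GenomicRanges::seqnames(genes)),
                   locus_tag = S4Vectors::mcols(genes)$locus_tag,
                   start = GenomicRanges::start(genes),
                   end = GenomicRanges::end(genes),
                   strand = as.character(GenomicRanges::strand(genes)),
                   annotations = vapply(S4Vectors::mcols(genes)$annotations,
                                        paste, character(1), collapse = ","),
                   localization = S4Vectors::mcols(genes)$localization,
                   tm_strand_count = S4Vectors::mcols(genes)$tm_strand_count,
                   stringsAsFactors = FALSE)
  key <- paste(df$genome_id, df$contig_id)
  for (k in unique(key)) {
    i <- which(key == k)
    span <- max(df$end[i]) + 1L
    new_start <- span - df$end[i]
    df$end[i] <- span - df$start[i]
    df$start[i] <- new_start
  }
  f <- tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  rev_genes <- readGeneTable(f); unlink(f)
  rev_calls <- detectLoci(rev_genes, cohortProteins(co))
  key_of <- function(x) sort(paste(x$locus_type, x$genome_id, x$contig_id,
                                   vapply(x$members, function(m)
                                     paste(sort(m), collapse = ","),
                                     character(1))))
  expect_identical(key_of(rev_calls), key_of(calls))
})

test_that("planted loci are recovered perfectly without dropout", {
  for (seed in c(7, 19)) {
    co <- generateCohort(compactConfig(dropout = FALSE), seed = seed)
    calls <- detectLoci(cohortGenes(co), cohortProteins(co))
    truth <- cohortTruth(co)$loci
    planted <- unlist(lapply(names(truth), function(g)
      vapply(truth[[g]], function(l)
        paste(l$type, g, l$contig), character(1))))
    got <- paste(calls$locus_type, calls$genome_id, calls$contig_id)
    expect_setequal(got, planted)          # precision = recall = 1
    # every call covers its planted members
    for (g in names(truth)) for (l in truth[[g]]) {
      hit <- which(calls$locus_type == l$type & calls$genome_id == g)
      expect_true(all(l$members %in% unlist(calls$members[hit])))
    }
  }
})
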