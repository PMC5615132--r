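test_that("family census counts per family and dedups chimeric genes", {
  genes <- toyGeneTable(c("g1", "g2", "g3", "g4"),
                        annotations = c("GH2", "GH2", "GH29", "K00001"))
  prof <- countFamilies(genes, "GH")
  expect_identical(familyCounts(prof)["G1", ],
                   c(GH2 = 2L, GH29 = 1L))
  expect_identical(unname(familyRichness(prof)), 2L)
  expect_identical(unname(geneTotals(prof)), 3L)

  # one gene with two GH families: once per family, once toward the total
  genes2 <- toyGeneTable("g1", annotations = "GH2,GH29")
  prof2 <- countFamilies(genes2, "GH")
  expect_identical(familyCounts(prof2)["G1", ], c(GH2 = 1L, GH29 = 1L))
  expect_identical(unname(geneTotals(prof2)), 1L)

  # no matching genes: empty profile, richness 0
  prof3 <- countFamilies(toyGeneTable("g1", annotations = "K00001"), "GH")
  expect_identical(ncol(familyCounts(prof3)), 0L)
  expect_identical(unname(familyRichness(prof3)), 0L)

  expect_error(familyClassSpec("lipase"), "arg")
})

test_that("coding density is the percentage of genes in the class", {
  expect_identical(codingDensity(40, 1000), 4)
  expect_identical(codingDensity(0, 123), 0)
  expect_identical(codingDensity(119, 2975), 4)
  expect_error(codingDensity(1, 0), "gene_count")
})

test_that("planted family counts are recovered exactly without dropout", {
  co <- generateCohort(compactConfig(dropout = FALSE), seed = 21)
  prof <- countFamilies(cohortGenes(co), "GH")
  truth <- cohortTruth(co)$gh_family_counts
  for (g in names(truth)) {
    got <- familyCounts(prof)[g, ]
    got <- got[got > 0]
    expect_identical(got[order(names(got))],
                     truth[[g]][order(names(truth[[g]]))])
  }
})

test_that("GH hit filtering applies the two E-value / coverage rules", {
  hits <- data.frame(
    query_locus = c("q1", "q2", "q3", "q4"),
    subject_id = "ACD03864",
    evalue = c(1e-8, 1e-5, 1e-8, 1e-9),
    query_coverage_pct = c(80, 80, 40, 90))
  expect_identical(filterGHHits(hits, "gh109"), c("q4", "q1"))
  # the default HMM rule ignores coverage but is stricter on E-value
  expect_identical(sort(filterGHHits(hits, "hmm_default")),
                   c("q1", "q3", "q4"))
  # one acceptance per query locus even with multiple passing hits
  hits2 <- rbind(hits, data.frame(query_locus = "q1", subject_id = "ACD04752",
                                  evalue = 1e-10, query_coverage_pct = 95))
  expect_identical(sum(filterGHHits(hits2, "gh109") == "q1"), 1L)
})

test_that("correlation matches the covariance/variance definition", {
  r <- profileCorrelation(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$r, 1)
  r <- profileCorrelation(c(1, 2, 3), c(3, 2, 1))
  expect_equal(r$r, -1)
  r <- profileCorrelation(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$r, 0.8)
  set.seed(8)
  for (rep in 1:20) {
    x <- stats::rnorm(sample(5:30, 1)); y <- stats::rnorm(length(x))
    got <- profileCorrelation(x, y)
    want <- brutePearson(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
  expect_error(profileCorrelation(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(profileCorrelation(1:2, 1:2), "at least 3")
  # Spearman is exposed for rank-based checks
  expect_equal(profileCorrelation(1:5, c(2, 1, 4, 3, 5),
                                  method = "spearman")$r, 0.8)
})

test_that("profile clustering is deterministic and matches naive agglomeration", {
  m <- rbind(A = c(5, 1, 0, 2), B = c(5, 1, 0, 2), C = c(0, 4, 4, 0))
  hc <- clusterProfiles(m, distance = "bray_curtis", linkage = "average")
  expect_equal(min(hc$height), 0)  # identical profiles merge at height 0

  set.seed(12)
  for (rep in 1:25) {
    m <- matrix(stats::rpois(12, 4), nrow = 3,
                dimnames = list(c("A", "B", "C"), NULL))
    if (any(apply(m, 1, stats::sd) == 0)) next
    for (linkage in c("average", "complete")) {
      hc <- clusterProfiles(m, "correlation", linkage)
      d <- stats::as.dist(1 - stats::cor(t(m)))
      want <- bruteAgglomerate(d, linkage)
      expect_equal(sort(hc$height), sort(want$heights), tolerance = 1e-12)
      # the first merged pair must be the closest pair
      pair <- which(as.matrix(d) == min(d), arr.ind = TRUE)[1, ]
      expect_setequal(-hc$merge[1, ], pair)
    }
  }
  expect_error(clusterProfiles(rbind(A = c(0, 0), B = c(1, 2)),
                               "correlation"), "bray_curtis")
})

test_that("planted group contrasts drive the top-level cluster bipartition", {
  co <- generateCohort(compactConfig(group_sizes = c(ME = 3L, TE = 0L, TH = 3L),
                                     n_samples = c(ME = 6L, TE = 1L, TH = 6L),
                                     bmc_per_group = c(ME = 0L, TE = 0L, TH = 0L),
                                     cut_per_group = c(ME = 0L, TE = 0L, TH = 0L),
                                     pcc_per_group = c(ME = 0L, TE = 0L, TH = 0L)),
                       seed = 31)
  prof <- countFamilies(cohortGenes(co), "GH")
  hc <- clusterProfiles(prof)
  groups <- stats::cutree(hc, k = 2)
  lake <- substr(names(groups), 1, 2)
  expect_identical(length(unique(groups[lake == "ME"])), 1L)
  expect_identical(length(unique(groups[lake == "TH"])), 1L)
})

test_that("coding density is stable under uniform gene subsampling", {
  co <- generateCohort(compactConfig(dropout = FALSE), seed = 17)
  genes <- cohortGenes(co)
  g <- cohortGenomes(co)$genome_id[5]  # a TH genome with ~4% GH density
  sub <- genes[S4Vectors::mcols(genes)$genome_id == g]
  prof <- countFamilies(sub, "GH")
  p_full <- geneTotals(prof)[[g]] / length(sub)
  set.seed(77)
  dens <- replicate(100, {
    keep <- sample(length(sub), length(sub) %/% 2)
    s <- sub[keep]
    codingDensity(geneTotals(countFamilies(s, "GH", genome_ids = g))[[g]],
                  length(s))
  })
  # half-sampling without replacement: binomial-style s.e. of the density
  n_half <- length(sub) %/% 2
  se <- 100 * sqrt(p_full * (1 - p_full) / n_half)
  expect_lt(abs(mean(dens) - 100 * p_full), 3 * se / sqrt(100) + 1e-9)
  expect_lt(max(abs(dens - 100 * p_full)), 5 * se)
})
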