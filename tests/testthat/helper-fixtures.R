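# Build a gene-table GRanges through the TSV reader, so fixtures exercise
# the same parsing path as real inputs.
toyGeneTable <- function(locus_tag, annotations = "", genome_id = "G1",
                         contig_id = "c1", localization = "unknown",
                         tm_strand_count = NA_integer_, strand = "+",
                         start = NULL, end = NULL) {
  n <- length(locus_tag)
  if (is.null(start)) start <- (seq_len(n) - 1L) * 1000L + 1L
  if (is.null(end)) end <- start + 899L
  df <- data.frame(genome_id = rep_len(genome_id, n),
                   contig_id = rep_len(contig_id, n),
                   locus_tag = locus_tag, start = start, end = end,
                   strand = rep_len(strand, n),
                   annotations = rep_len(annotations, n),
                   localization = rep_len(localization, n),
                   tm_strand_count = rep_len(tm_strand_count, n),
                   stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  on.exit(unlink(f))
  readGeneTable(f)
}

# Compact generator configuration used by the multi-seed recovery loops;
# keeps the group contrasts of the default conditions at a smaller cohort.
compactConfig <- function(...) {
  syntheticCohortConfig(
    group_sizes = c(ME = 2L, TE = 1L, TH = 2L),
    n_samples = c(ME = 24L, TE = 20L, TH = 20L),
    gene_count_range = c(800L, 1200L),
    pcc_per_group = c(ME = 0L, TE = 0L, TH = 1L),
    cut_per_group = c(ME = 0L, TE = 1L, TH = 0L),
    bmc_per_group = c(ME = 1L, TE = 0L, TH = 1L),
    ...)
}

# A 19-genome cohort for the tri-state scoring checks: `carriers` genomes
# carry the full 4-step pathway (signature included); everyone else carries
# only the two shared steps.
triStateFixture <- function(n_carriers) {
  ids <- sprintf("G%02d", 1:19)
  rows <- lapply(seq_along(ids), function(i) {
    acc <- if (i <= n_carriers) c("K11111", "K22222", "K33333", "K44444")
           else c("K11111", "K22222")
    data.frame(genome_id = ids[i], contig_id = paste0(ids[i], "_c1"),
               locus_tag = paste0(ids[i], "_g", seq_along(acc)),
               start = (seq_along(acc) - 1L) * 1000L + 1L,
               end = (seq_along(acc) - 1L) * 1000L + 900L,
               strand = "+", annotations = acc, localization = "unknown",
               tm_strand_count = NA_integer_, stringsAsFactors = FALSE)
  })
  f <- tempfile(fileext = ".tsv")
  utils::write.table(do.call(rbind, rows), f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  on.exit(unlink(f))
  genes <- readGeneTable(f)
  pw <- PathwaySet(list(list(
    pathway_id = "toy4", name = "four-step toy pathway",
    steps = list(s1 = "K11111", s2 = "K22222", s3 = "K33333",
                 s4 = "K44444"),
    signature = "s4")))
  list(genes = genes, pathways = pw, ids = ids)
}
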