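#' @include AllClasses.R io_tables.R
NULL

.scaleCoverage <- function(cov) {
  # library-size scaling: multiply each sample's depths by
  # (reference depth / sample total mapped bases), reference = median total
  tot <- colData(cov)$total_mapped_bases
  keep <- which(tot > 0)
  if (length(keep) < ncol(cov))
    warning("excluding sample(s) with zero total mapped bases: ",
            paste(colnames(cov)[tot <= 0], collapse = ", "))
  m <- assay(cov, "coverage")[, keep, drop = FALSE]
  tot <- tot[keep]
  ref <- stats::median(tot)
  sweep(m, 2L, ref / tot, "*")
}

#' Normalize a coverage matrix into per-genome abundance series
#'
#' Two documented steps: (1) scale each sample's contig depths by
#' (reference depth / sample total mapped bases), where the reference is the
#' median sample total, removing library-size differences; (2) aggregate
#' each genome's contigs into one value per sample as the contig-length-
#' weighted mean of the scaled depths. Step 2 makes the genome value
#' invariant under splitting a contig in two. When `group_samples = TRUE`
#' each genome's series is restricted to the samples of its own lake group
#' (its metagenome series); genomes whose group has no samples fall back to
#' all samples.
#'
#' @param cov A [CoverageExperiment-class].
#' @param group_samples Restrict each genome to its own lake-group samples
#'   (default TRUE).
#' @return Named list of [AbundanceSeries-class], one per genome.
#' @export
normalizeCoverage <- function(cov, group_samples = TRUE) {
  scaled <- .scaleCoverage(cov)
  cd <- colData(cov)[colnames(scaled), , drop = FALSE]
  rd <- rowData(cov)
  genomes <- unique(rd$genome_id)
  out <- lapply(genomes, function(g) {
    rows <- which(rd$genome_id == g)
    grp <- sub("^(ME|TE|TH).*$", "\\1", g)
    cols <- seq_len(ncol(scaled))
    if (group_samples && grp %in% cd$lake_group)
      cols <- which(cd$lake_group == grp)
    w <- rd$length_bp[rows]
    vals <- apply(scaled[rows, cols, drop = FALSE], 2L,
                  stats::weighted.mean, w = w)
    new("AbundanceSeries", genome_id = g,
        sample_ids = colnames(scaled)[cols],
        dates = as.Date(cd$date[cols]), values = as.numeric(vals))
  })
  names(out) <- genomes
  out
}

#' Median / mean / CV summary of an abundance series
#'
#' The coefficient of variation (sample standard deviation over mean, in
#' percent) summarizes variation among sampling points; together with the
#' median it distinguishes persistent populations from bloom-and-bust ones
#' (low median + large CV). The CV is undefined (`NA`) for an all-zero
#' series.
#'
#' @param x An [AbundanceSeries-class], a plain numeric series, or a list of
#'   `AbundanceSeries`.
#' @param ... Unused.
#' @return Named numeric vector `c(median, mean, cv_pct)`; for a list, a
#'   data.frame with one row per genome.
#' @export
setMethod("seriesStats", "numeric", function(x, ...) {
  if (length(x) < 2L) stop("need at least 2 samples")
  if (any(x < 0)) stop("negative coverage values")
  mu <- mean(x)
  cv <- if (mu > 0) 100 * stats::sd(x) / mu else NA_real_
  c(median = stats::median(x), mean = mu, cv_pct = cv)
})

#' @rdname seriesStats-numeric-method
#' @export
setMethod("seriesStats", "AbundanceSeries", function(x, ...)
  callGeneric(x@values))

#' @rdname seriesStats-numeric-method
#' @export
setMethod("seriesStats", "list", function(x, ...) {
  rows <- t(vapply(x, function(s) seriesStats(s), numeric(3)))
  data.frame(genome_id = names(x), rows, row.names = NULL,
             stringsAsFactors = FALSE)
})

#' Classify population temporal dynamics
#'
#' `bloom_and_bust` populations spike once to a few times per season and
#' stay near zero otherwise: large CV and low median. `persistent`
#' populations keep a steady abundance: CV at or below the threshold. Cases
#' with a high CV but a median at or above the floor, or with an undefined
#' CV, are `indeterminate`.
#'
#' @param stats Named vector from [seriesStats()] or a data.frame of them.
#' @param cv_threshold_pct CV cutoff in percent (default 150).
#' @param median_floor Median normalized coverage floor (default 1.0).
#' @return Character scalar (or vector for a data.frame input):
#'   `"persistent"`, `"bloom_and_bust"` or `"indeterminate"`.
#' @examples
#' classifyPersistence(c(median = 0.0, mean = 0.8, cv_pct = 583))  # bloom
#' classifyPersistence(c(median = 6.1, mean = 6.3, cv_pct = 61))   # persistent
#' @export
classifyPersistence <- function(stats, cv_threshold_pct = 150,
                                median_floor = 1.0) {
  if (is.data.frame(stats)) {
    return(vapply(seq_len(nrow(stats)), function(i)
      classifyPersistence(c(median = stats$median[i], mean = stats$mean[i],
                            cv_pct = stats$cv_pct[i]),
                          cv_threshold_pct, median_floor), character(1)))
  }
  cv <- stats[["cv_pct"]]; med <- stats[["median"]]
  if (is.na(cv)) return("indeterminate")
  if (cv > cv_threshold_pct && med < median_floor) return("bloom_and_bust")
  if (cv <= cv_threshold_pct) return("persistent")
  "indeterminate"
}

#' Temporal-correlation curation of a genome's contigs
#'
#' Flags contigs whose temporal coverage pattern does not track the genome's
#' consensus, the standard bin-curation step for time-series binning. The
#' reference series is the per-sample median over the genome's contigs
#' (library-size-scaled depths); each contig's Pearson correlation with the
#' reference is computed and contigs with `r < r_min` are flagged. The
#' reference is then recomputed once without the flagged contigs and all
#' contigs are re-evaluated against it (single pass, no iteration, so the
#' procedure is deterministic and auditable). Contigs with a constant
#' (zero-variance) series have undefined `r` and are flagged with reason
#' `"zero-variance"`.
#'
#' @param cov A [CoverageExperiment-class].
#' @param genome_id Genome whose contigs to curate; needs >= 3 contigs and
#'   >= 4 samples.
#' @param r_min Pearson correlation threshold (default 0.6).
#' @param group_samples Restrict to the genome's own lake-group samples.
#' @return data.frame: `contig_id`, `r` (against the final reference),
#'   `flagged`, `reason` (`"low-correlation"`, `"zero-variance"` or `""`).
#' @export
curateContigs <- function(cov, genome_id, r_min = 0.6,
                          group_samples = TRUE) {
  rd <- rowData(cov)
  rows <- which(rd$genome_id == genome_id)
  if (length(rows) < 3L) stop("need >= 3 contigs for curation")
  scaled <- .scaleCoverage(cov)
  cd <- colData(cov)[colnames(scaled), , drop = FALSE]
  grp <- sub("^(ME|TE|TH).*$", "\\1", genome_id)
  cols <- seq_len(ncol(scaled))
  if (group_samples && grp %in% cd$lake_group)
    cols <- which(cd$lake_group == grp)
  if (length(cols) < 4L) stop("need >= 4 samples for curation")
  m <- scaled[rows, cols, drop = FALSE]
  contigs <- rownames(m)
  safeCor <- function(x, ref) {
    if (stats::sd(x) == 0 || stats::sd(ref) == 0) return(NA_real_)
    stats::cor(x, ref)
  }
  ref1 <- apply(m, 2L, stats::median)
  r1 <- apply(m, 1L, safeCor, ref = ref1)
  flag1 <- is.na(r1) | r1 < r_min
  keep <- !flag1
  ref2 <- if (any(keep)) apply(m[keep, , drop = FALSE], 2L, stats::median)
          else ref1
  r2 <- apply(m, 1L, safeCor, ref = ref2)
  flagged <- flag1 | is.na(r2) | r2 < r_min
  reason <- ifelse(is.na(r2) | is.na(r1), "zero-variance",
                   ifelse(flagged, "low-correlation", ""))
  data.frame(contig_id = contigs, r = as.numeric(r2), flagged = flagged,
             reason = reason, stringsAsFactors = FALSE)
}

#' Write per-genome abundance summaries as TSV
#'
#' One row per genome with the date-ordered series summary (median, mean,
#' CV percent) and the persistence class.
#'
#' @param series Named list of [AbundanceSeries-class]
#'   (from [normalizeCoverage()]).
#' @param path Output path.
#' @param ... Passed to [classifyPersistence()].
#' @return `path`, invisibly.
#' @export
writeAbundanceSummary <- function(series, path, ...) {
  st <- seriesStats(series)
  st$dynamics <- classifyPersistence(st, ...)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# limnoMAG abundance summary (normalized coverage depth)", con)
  utils::write.table(st, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
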