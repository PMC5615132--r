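#' @include AllClasses.R io_tables.R
NULL

#' Default accession list for the PSCyt domain class
#'
#' The planctomycete-specific cytochrome c (PSCyt1-PSCyt3) and associated
#' protein domains (PSD1-PSD5) are named without database accessions in the
#' literature, so the class is defined by a configurable label list; this is
#' the package default. Supply your own list to [countFamilies()] to override.
#'
#' @return Character vector of domain labels.
#' @export
pscytAccessions <- function() {
  c(paste0("PSCyt", 1:3), paste0("PSD", 1:5))
}

#' Family class specification for a census
#'
#' @param class `"GH"` (CAZy glycoside hydrolase families, accessions
#'   `GH<digits>`), `"sulfatase"` (the pfam00884 sulfatase family) or
#'   `"PSCyt"` (a configurable domain label list, see [pscytAccessions()]).
#' @param accessions Optional explicit accession list overriding the default
#'   for the class (required semantics for `"PSCyt"`-like custom classes).
#' @return List with `class_label` and either `pattern` (regular expression
#'   on accessions) or `accessions`.
#' @export
familyClassSpec <- function(class = c("GH", "sulfatase", "PSCyt"),
                            accessions = NULL) {
  class <- match.arg(class)
  if (!is.null(accessions))
    return(list(class_label = class, accessions = accessions))
  switch(class,
         GH = list(class_label = "GH", pattern = "^GH[0-9]+$"),
         sulfatase = list(class_label = "sulfatase",
                          accessions = "pfam00884"),
         PSCyt = list(class_label = "PSCyt", accessions = pscytAccessions()))
}

#' Census of functional-family gene counts per genome
#'
#' Counts, per genome, the genes annotated to each family of a class (e.g.
#' CAZy GH families). A gene with two annotations of the same family counts
#' once in that family; a gene with annotations in two different families
#' counts once in each family but once toward the per-genome class total
#' ([geneTotals()]), so chimeric hits do not inflate the total.
#'
#' @param genes `GRanges` gene table (see [readGeneTable()]).
#' @param class_spec A specification from [familyClassSpec()], or a class
#'   name accepted by it.
#' @param genome_ids Optional cohort definition; genomes without matching
#'   genes get all-zero rows.
#' @return A [FamilyProfile-class].
#' @examples
#' # a genome with genes annotated GH2, GH2, GH29 profiles as
#' # counts {GH2: 2, GH29: 1}, richness 2
#' @export
countFamilies <- function(genes, class_spec = "GH", genome_ids = NULL) {
  if (is.character(class_spec)) class_spec <- familyClassSpec(class_spec)
  if (is.null(class_spec$class_label))
    stop("unknown family class specification")
  gid <- mcols(genes)$genome_id
  tag <- mcols(genes)$locus_tag
  ann <- mcols(genes)$annotations
  long <- data.frame(genome_id = rep(gid, lengths(ann)),
                     locus_tag = rep(tag, lengths(ann)),
                     accession = unlist(ann, use.names = FALSE),
                     stringsAsFactors = FALSE)
  keep <- if (!is.null(class_spec$pattern))
    grepl(class_spec$pattern, long$accession)
  else long$accession %in% class_spec$accessions
  long <- long[keep, , drop = FALSE]
  long <- unique(long)  # one count per (gene, family)
  if (is.null(genome_ids)) genome_ids <- sort(unique(gid))
  fams <- sort(unique(long$accession))
  counts <- matrix(0L, nrow = length(genome_ids), ncol = length(fams),
                   dimnames = list(genome_ids, fams))
  if (nrow(long)) {
    tab <- table(factor(long$genome_id, levels = genome_ids),
                 factor(long$accession, levels = fams))
    counts[] <- as.integer(tab)
  }
  totals <- vapply(genome_ids, function(g)
    length(unique(long$locus_tag[long$genome_id == g])), integer(1))
  names(totals) <- genome_ids
  new("FamilyProfile", counts = counts, gene_totals = totals,
      class_label = class_spec$class_label)
}

#' Coding density of a family class
#'
#' Percentage of a genome's genes annotated to the class:
#' `100 * profile_total / gene_count`. Normalizing by the total gene count
#' compensates for different genome sizes and completeness levels, under the
#' assumption that class members are randomly distributed between the
#' recovered and missing parts of a draft genome.
#'
#' @param x Numeric vector of class gene counts, or a
#'   [FamilyProfile-class] (then `gene_count` must be a named vector covering
#'   its genomes).
#' @param gene_count Total genes per genome (positive).
#' @param ... Unused.
#' @return Numeric vector of percentages in `[0, 100]`.
#' @examples
#' codingDensity(40, 1000)   # 4
#' @export
setMethod("codingDensity", "numeric", function(x, gene_count, ...) {
  if (any(gene_count <= 0)) stop("gene_count must be > 0")
  100 * x / gene_count
})

#' @rdname codingDensity-numeric-method
#' @export
setMethod("codingDensity", "FamilyProfile", function(x, gene_count, ...) {
  g <- rownames(x@counts)
  if (is.null(names(gene_count)))
    stop("gene_count must be named by genome_id")
  miss <- setdiff(g, names(gene_count))
  if (length(miss)) stop("gene_count missing genome(s): ",
                         paste(miss, collapse = ", "))
  callGeneric(as.numeric(x@gene_totals), gene_count[g])
})

#' Filter homology hits for glycoside hydrolase assignment
#'
#' Two filtering rules are used when assigning GH families from homology
#' searches: the HMM-based default keeps hits with E-value <= 1e-7; the
#' GH109 BLASTP rule (the dbCAN HMM for GH109 is the unspecific pfam01408
#' N-terminal domain, so GH109 is assigned by BLASTP against reference
#' GH109 proteins instead) keeps hits with E-value <= 1e-6 and query
#' coverage >= 50%. One acceptance per query locus (its best-E-value
#' passing hit).
#'
#' @param hits data.frame with columns `query_locus`, `subject_id`,
#'   `evalue`, `query_coverage_pct`.
#' @param rule `"hmm_default"` or `"gh109"`.
#' @return Character vector of accepted query loci (unique, best hit each).
#' @export
filterGHHits <- function(hits, rule = c("hmm_default", "gh109")) {
  rule <- match.arg(rule)
  req <- c("query_locus", "subject_id", "evalue", "query_coverage_pct")
  miss <- setdiff(req, colnames(hits))
  if (length(miss)) stop("hits: missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(!is.finite(hits$evalue)) || any(hits$evalue < 0))
    stop("hits: E-values must be finite and >= 0")
  pass <- switch(rule,
    hmm_default = hits$evalue <= 1e-7,
    gh109 = hits$evalue <= 1e-6 & hits$query_coverage_pct >= 50)
  hits <- hits[pass, , drop = FALSE]
  if (nrow(hits) == 0L) return(character(0))
  hits <- hits[order(hits$evalue), , drop = FALSE]
  unique(hits$query_locus)
}

#' Correlation diagnostic between two per-genome quantities
#'
#' Pearson (default) or Spearman correlation with a two-sided p-value; for
#' Pearson the p-value comes from the t distribution with n - 2 degrees of
#' freedom. Used e.g. to check that genome completeness is not correlated
#' with recovered GH gene counts, and for the GH-density versus
#' PSCyt-density contrast.
#'
#' @param x,y Numeric vectors of equal length >= 3, finite values.
#' @param method `"pearson"` or `"spearman"`.
#' @return List with `r` and `p`.
#' @export
profileCorrelation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         alternative = "two.sided"))
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Hierarchical clustering of family abundance profiles
#'
#' Clusters genomes by their family count profiles, the standard diagnostic
#' for lake-of-origin grouping in GH profiles. Deterministic: genomes are
#' pre-sorted lexically so tie merges are reproducible.
#'
#' @param profile A [FamilyProfile-class] or a numeric matrix
#'   (genomes x families).
#' @param distance `"correlation"` (1 - Pearson correlation between profile
#'   vectors) or `"bray_curtis"` (via [vegan::vegdist()]).
#' @param linkage `"average"` or `"complete"`.
#' @return An [stats::hclust] object; `$labels` in input (lexical) order,
#'   `order` giving the leaf order, `merge`/`height` the merge tree.
#' @export
clusterProfiles <- function(profile,
                            distance = c("correlation", "bray_curtis"),
                            linkage = c("average", "complete")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  m <- if (is(profile, "FamilyProfile")) familyCounts(profile) else profile
  if (nrow(m) < 2L) stop("need at least 2 genomes to cluster")
  m <- m[order(rownames(m)), , drop = FALSE]
  if (distance == "correlation") {
    sds <- apply(m, 1L, stats::sd)
    if (any(sds == 0))
      stop("all-zero/constant profile(s) under correlation distance (",
           paste(rownames(m)[sds == 0], collapse = ", "),
           "); consider distance = 'bray_curtis'")
    d <- stats::as.dist(1 - stats::cor(t(m)))
  } else {
    d <- vegan::vegdist(m, method = "bray")
  }
  stats::hclust(d, method = linkage)
}

#' Top-family count table for reporting
#'
#' The grayscale count panel convention: counts for the `n_top` most
#' abundant families (cohort-wide), plus the per-genome class total and
#' family richness.
#'
#' @param profile A [FamilyProfile-class].
#' @param n_top Number of families to report (default 10).
#' @return data.frame: genome_id, one column per top family, `total_genes`,
#'   `n_families`.
#' @export
topFamilyTable <- function(profile, n_top = 10L) {
  counts <- familyCounts(profile)
  top <- names(sort(colSums(counts), decreasing = TRUE))
  top <- utils::head(top, n_top)
  data.frame(genome_id = rownames(counts),
             counts[, top, drop = FALSE],
             total_genes = as.integer(geneTotals(profile)),
             n_families = as.integer(familyRichness(profile)),
             check.names = FALSE, stringsAsFactors = FALSE)
}
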