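#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start end strand
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' Curated pathway definitions
#'
#' A `PathwaySet` holds one or more pathway definitions. Each pathway is an
#' ordered list of reaction steps; a step is an OR-group of isofunctional
#' annotation accessions (any one accession satisfies the step). A subset of
#' steps may be flagged as signature steps: enzymes specific enough to the
#' pathway that their presence indicates the pathway itself rather than a
#' shared reaction.
#'
#' @slot pathways Named list; each element is a list with components
#'   `pathway_id`, `name`, `steps` (named list of character vectors, one
#'   OR-group per step) and `signature` (character vector of step ids,
#'   possibly empty).
#'
#' @seealso [readPathwayDefs()], [scorePathway()], [cohortCompleteness()]
#' @export
setClass("PathwaySet", representation(pathways = "list"))

setValidity("PathwaySet", function(object) {
  msgs <- character()
  for (pw in object@pathways) {
    need <- c("pathway_id", "name", "steps", "signature")
    if (!all(need %in% names(pw))) {
      msgs <- c(msgs, "each pathway needs pathway_id, name, steps, signature")
      next
    }
    if (length(pw$steps) < 1L)
      msgs <- c(msgs, sprintf("pathway '%s' has zero steps", pw$pathway_id))
    if (!all(pw$signature %in% names(pw$steps)))
      msgs <- c(msgs, sprintf("pathway '%s': signature steps must be a subset of steps",
                              pw$pathway_id))
    if (any(!nzchar(unlist(pw$steps))))
      msgs <- c(msgs, sprintf("pathway '%s': empty accession", pw$pathway_id))
  }
  if (length(msgs)) msgs else TRUE
})

#' Tri-state pathway completeness calls for a MAG cohort
#'
#' Genome-by-pathway completeness calls following the tri-state convention
#' used for incomplete draft genomes: a numeric fraction when the pathway's
#' signature evidence supports presence, `"0"` when no step was recovered at
#' all, and `"(0)"` ("likely absent") when some shared genes are present but
#' the signature gene is missing both in the genome and in more than
#' two-thirds of the cohort.
#'
#' @slot calls A [S4Vectors::DataFrame] with one row per genome x pathway:
#'   `genome_id`, `pathway_id`, `state` (`fraction`/`zero`/`likely_absent`),
#'   `completeness`, `recovered_steps`, `n_steps`, `prevalence_support`,
#'   `no_signature`.
#' @slot n_genomes Integer cohort size used for the prevalence threshold.
#'
#' @seealso [cohortCompleteness()], [completenessCells()]
#' @export
setClass("CompletenessMatrix",
         representation(calls = "DataFrame", n_genomes = "integer"))

#' Per-genome functional family census
#'
#' Gene counts per annotation family (e.g. CAZy glycoside hydrolase families)
#' for every genome in a cohort, with the per-genome total number of distinct
#' genes carrying any family of the class. A gene annotated with two families
#' of the class counts once in each family but only once toward the class
#' total, so chimeric hits are not double counted.
#'
#' @slot counts Integer matrix, genomes x families.
#' @slot gene_totals Named integer vector: distinct genes per genome with at
#'   least one family annotation of the class.
#' @slot class_label Character scalar, e.g. `"GH"`.
#' @export
setClass("FamilyProfile",
         representation(counts = "matrix", gene_totals = "integer",
                        class_label = "character"))

setValidity("FamilyProfile", function(object) {
  if (any(object@counts < 0)) return("negative family counts")
  if (!identical(rownames(object@counts), names(object@gene_totals)))
    return("counts rownames and gene_totals names must agree")
  TRUE
})

#' Contig x sample coverage-depth container
#'
#' Thin [SummarizedExperiment::SummarizedExperiment] subclass carrying one
#' `"coverage"` assay (contigs as rows, samples as columns), contig metadata
#' (`genome_id`, `length_bp`) in `rowData`, and sample metadata (`lake_group`,
#' `date`, `total_mapped_bases`) in `colData`. Coverage values are raw,
#' reads-derived depths; see [normalizeCoverage()] for the normalization
#' contract.
#'
#' @export
setClass("CoverageExperiment", contains = "SummarizedExperiment")

setValidity("CoverageExperiment", function(object) {
  msgs <- character()
  a <- assay(object)
  if (any(is.na(a))) msgs <- c(msgs, "NA coverage entries (coerce at read time)")
  else if (any(a < 0)) msgs <- c(msgs, "negative coverage entries")
  if (!all(c("genome_id", "length_bp") %in% colnames(rowData(object))))
    msgs <- c(msgs, "rowData needs genome_id and length_bp")
  if (!all(c("lake_group", "date", "total_mapped_bases") %in%
           colnames(colData(object))))
    msgs <- c(msgs, "colData needs lake_group, date, total_mapped_bases")
  if (length(msgs)) msgs else TRUE
})

#' Normalized per-genome abundance series
#'
#' Date-ordered normalized coverage of one genome across the samples of its
#' metagenome series, produced by [normalizeCoverage()].
#'
#' @slot genome_id Character scalar.
#' @slot sample_ids Character vector, date-ordered.
#' @slot dates Date vector parallel to `sample_ids`.
#' @slot values Non-negative numeric vector of normalized coverage depths.
#' @seealso [seriesStats()], [classifyPersistence()]
#' @export
setClass("AbundanceSeries",
         representation(genome_id = "character", sample_ids = "character",
                        dates = "Date", values = "numeric"))

setValidity("AbundanceSeries", function(object) {
  if (length(object@values) != length(object@sample_ids))
    return("values and sample_ids lengths differ")
  if (any(object@values < 0)) return("negative normalized coverage")
  if (is.unsorted(object@dates)) return("samples must be date-ordered")
  TRUE
})

#' Synthetic MAG cohort with planted ground truth
#'
#' Container returned by [generateCohort()]: a complete, internally consistent
#' set of inputs for the whole pipeline (gene table, genome table, protein
#' sequences, pathway definitions, coverage matrix) together with the planted
#' truth used by recovery tests.
#'
#' @slot genes [GenomicRanges::GRanges] gene table (see [readGeneTable()]).
#' @slot genomes data.frame genome table (see [readGenomeTable()]).
#' @slot proteins [Biostrings::AAStringSet] named by locus tag.
#' @slot pathways [PathwaySet-class].
#' @slot coverage [CoverageExperiment-class].
#' @slot truth List of planted parameters (pathway presence map, locus
#'   positions, family counts, dynamics classes, retention probabilities).
#' @export
setClass("SyntheticCohort",
         representation(genes = "GRanges", genomes = "data.frame",
                        proteins = "AAStringSet", pathways = "PathwaySet",
                        coverage = "CoverageExperiment", truth = "list"))
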