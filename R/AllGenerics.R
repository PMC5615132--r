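#' @include AllClasses.R
NULL

#' @export
setGeneric("pathwayIds", function(x) standardGeneric("pathwayIds"))

#' @export
setGeneric("nSteps", function(x) standardGeneric("nSteps"))

#' @export
setGeneric("completenessCells", function(x, digits = 2L)
  standardGeneric("completenessCells"))

#' @export
setGeneric("familyCounts", function(x) standardGeneric("familyCounts"))

#' @export
setGeneric("familyRichness", function(x) standardGeneric("familyRichness"))

#' @export
setGeneric("geneTotals", function(x) standardGeneric("geneTotals"))

#' @export
setGeneric("codingDensity", function(x, gene_count, ...)
  standardGeneric("codingDensity"))

#' @export
setGeneric("seriesStats", function(x, ...) standardGeneric("seriesStats"))

#' Number of pathways / accessors for PathwaySet
#'
#' @param x A `PathwaySet`.
#' @return `pathwayIds()` the pathway identifiers; `nSteps()` a named integer
#'   vector of step counts per pathway; `length()` the number of pathways;
#'   `[[` one pathway definition list.
#' @aliases pathwayIds nSteps
#' @rdname PathwaySet-accessors
#' @export
setMethod("pathwayIds", "PathwaySet", function(x)
  vapply(x@pathways, `[[`, character(1), "pathway_id"))

#' @rdname PathwaySet-accessors
#' @export
setMethod("nSteps", "PathwaySet", function(x) {
  out <- vapply(x@pathways, function(p) length(p$steps), integer(1))
  names(out) <- pathwayIds(x)
  out
})

#' @rdname PathwaySet-accessors
#' @export
setMethod("length", "PathwaySet", function(x) length(x@pathways))

#' @rdname PathwaySet-accessors
#' @param i Pathway index or id.
#' @export
setMethod("[[", "PathwaySet", function(x, i) {
  if (is.character(i)) i <- match(i, pathwayIds(x))
  x@pathways[[i]]
})

setMethod("show", "PathwaySet", function(object) {
  cat("PathwaySet with", length(object), "pathway(s)\n")
  ns <- nSteps(object)
  nsig <- vapply(object@pathways, function(p) length(p$signature), integer(1))
  for (i in seq_along(ns))
    cat(sprintf("  %s: %d step(s), %d signature\n", names(ns)[i], ns[i], nsig[i]))
})

setMethod("show", "CompletenessMatrix", function(object) {
  cat("CompletenessMatrix:", length(unique(object@calls$genome_id)),
      "genome(s) x", length(unique(object@calls$pathway_id)),
      "pathway(s), cohort size", object@n_genomes, "\n")
  m <- completenessCells(object)
  print(utils::head(m, 10L))
  if (nrow(m) > 10L) cat("  ...\n")
})

#' @describeIn FamilyProfile-class genomes x families integer count matrix.
#' @param x A `FamilyProfile`.
#' @export
setMethod("familyCounts", "FamilyProfile", function(x) x@counts)

#' @describeIn FamilyProfile-class number of distinct families per genome.
#' @export
setMethod("familyRichness", "FamilyProfile", function(x) {
  out <- as.integer(rowSums(x@counts > 0L))
  names(out) <- rownames(x@counts)
  out
})

#' @describeIn FamilyProfile-class distinct genes per genome carrying the class.
#' @export
setMethod("geneTotals", "FamilyProfile", function(x) x@gene_totals)

setMethod("show", "FamilyProfile", function(object) {
  cat(sprintf("FamilyProfile [%s]: %d genome(s) x %d family(ies)\n",
              object@class_label, nrow(object@counts), ncol(object@counts)))
  cat("  gene totals:", paste(utils::head(object@gene_totals, 6L),
                              collapse = " "), "...\n")
})

setMethod("show", "AbundanceSeries", function(object) {
  s <- seriesStats(object)
  cat(sprintf("AbundanceSeries %s: %d samples; median %.2f, mean %.2f, CV %s%%\n",
              object@genome_id, length(object@values),
              s[["median"]], s[["mean"]],
              if (is.na(s[["cv_pct"]])) "NA" else sprintf("%.0f", s[["cv_pct"]])))
})

setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort:", nrow(object@genomes), "genome(s),",
      length(object@genes), "gene(s),", length(object@proteins),
      "protein(s),", length(object@pathways), "pathway(s)\n")
  cat("  groups:", paste(names(table(object@genomes$lake_group)),
                         table(object@genomes$lake_group),
                         sep = "=", collapse = " "), "\n")
})

#' Accessors for SyntheticCohort slots
#'
#' @param x A `SyntheticCohort`.
#' @return The corresponding component.
#' @name SyntheticCohort-accessors
NULL

#' @rdname SyntheticCohort-accessors
#' @export
cohortGenes <- function(x) x@genes

#' @rdname SyntheticCohort-accessors
#' @export
cohortGenomes <- function(x) x@genomes

#' @rdname SyntheticCohort-accessors
#' @export
cohortProteins <- function(x) x@proteins

#' @rdname SyntheticCohort-accessors
#' @export
cohortPathways <- function(x) x@pathways

#' @rdname SyntheticCohort-accessors
#' @export
cohortCoverage <- function(x) x@coverage

#' @rdname SyntheticCohort-accessors
#' @export
cohortTruth <- function(x) x@truth
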