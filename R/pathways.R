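#' @include AllClasses.R io_tables.R
NULL

#' Signature-gene prevalence threshold for a cohort
#'
#' A pathway whose signature gene is missing from a draft genome can still be
#' reported as present (with a completeness fraction) when the signature is
#' found in at least one third of all genomes in the cohort, since in an
#' incomplete genome the signature itself may simply not have been recovered.
#' The threshold is the smallest integer >= `n_genomes / 3`, so a cohort of
#' 19 genomes gives 7.
#'
#' @param n_genomes Positive integer cohort size.
#' @return The prevalence threshold as an integer.
#' @examples
#' prevalenceThreshold(19)  # 7
#' prevalenceThreshold(3)   # 1
#' @export
prevalenceThreshold <- function(n_genomes) {
  if (length(n_genomes) != 1L || is.na(n_genomes) || n_genomes < 1 ||
      n_genomes != floor(n_genomes))
    stop("n_genomes must be a positive integer")
  as.integer(ceiling(n_genomes / 3))
}

#' Annotation accession sets per genome
#'
#' Collects, per genome, the set of annotation accessions carried by its
#' genes. Used by the pathway-scoring and census routines.
#'
#' @param genes `GRanges` gene table (see [readGeneTable()]).
#' @return Named list of character vectors (one set per genome).
#' @export
genomeAccessions <- function(genes) {
  gid <- mcols(genes)$genome_id
  ann <- mcols(genes)$annotations
  lapply(split(unlist(ann, use.names = FALSE),
               rep(gid, lengths(ann))), unique)
}

#' Is one pathway step recovered in a genome?
#'
#' A step is an OR-group of isofunctional accessions; it counts as recovered
#' when any one of its accessions occurs among the genome's gene annotations.
#'
#' @param accessions Character vector: all annotation accessions of a genome.
#' @param or_group Character vector: the step's alternative accessions.
#' @return Logical scalar.
#' @export
stepRecovered <- function(accessions, or_group) {
  any(or_group %in% accessions)
}

#' Cohort-wide signature prevalence of each pathway
#'
#' Counts, for each pathway, the genomes in which at least one signature step
#' is recovered (any-semantics over multiple signature steps). Pathways with
#' no declared signature get prevalence 0.
#'
#' @param accession_sets Named list as from [genomeAccessions()]; names are
#'   genome ids and define the cohort.
#' @param pathways A [PathwaySet-class].
#' @return Named integer vector, one entry per pathway.
#' @export
signaturePrevalence <- function(accession_sets, pathways) {
  out <- vapply(pathways@pathways, function(pw) {
    if (length(pw$signature) == 0L) return(0L)
    sig_groups <- pw$steps[pw$signature]
    sum(vapply(accession_sets, function(acc)
      any(vapply(sig_groups, stepRecovered, logical(1),
                 accessions = acc)), logical(1)))
  }, integer(1))
  names(out) <- pathwayIds(pathways)
  out
}

#' Score one pathway in one genome (tri-state)
#'
#' Implements the tri-state completeness rule for incomplete draft genomes.
#' Pathway completeness is the fraction of recovered steps. The state is:
#' \describe{
#'   \item{`fraction`}{the signature gene is present in this genome, or it is
#'     absent here but present in at least [prevalenceThreshold()] genomes of
#'     the cohort (the genome-incompleteness rescue); the completeness
#'     fraction is reported.}
#'   \item{`zero`}{no step of the pathway was recovered at all ("0").}
#'   \item{`likely_absent`}{some shared steps are present but the signature
#'     is missing here and in more than two thirds of the cohort ("(0)").}
#' }
#' A pathway with no declared signature can never be `likely_absent`: it
#' reports a fraction whenever at least one step is recovered (flagged
#' `no_signature`, with a warning) and `zero` otherwise.
#'
#' @param accessions Character vector of the genome's annotation accessions.
#' @param pathway One pathway definition (list; see [PathwaySet()]).
#' @param prevalence Integer: cohort genomes with the signature recovered
#'   (see [signaturePrevalence()]).
#' @param n_genomes Integer cohort size.
#' @return List with `state`, `completeness` (`NA` unless `state ==
#'   "fraction"`), `recovered_steps`, `n_steps`, `prevalence_support`,
#'   `no_signature`.
#' @export
scorePathway <- function(accessions, pathway, prevalence, n_genomes) {
  if (n_genomes < 1) stop("n_genomes must be >= 1")
  rec <- vapply(pathway$steps, stepRecovered, logical(1),
                accessions = accessions)
  n_rec <- sum(rec)
  n_steps <- length(rec)
  no_sig <- length(pathway$signature) == 0L
  if (n_rec == 0L) {
    state <- "zero"
    completeness <- NA_real_
  } else if (no_sig) {
    warning("pathway '", pathway$pathway_id,
            "' has no signature step; reporting fraction (no-signature call)")
    state <- "fraction"
    completeness <- n_rec / n_steps
  } else {
    sig_here <- any(rec[names(pathway$steps) %in% pathway$signature])
    if (sig_here || prevalence >= prevalenceThreshold(n_genomes)) {
      state <- "fraction"
      completeness <- n_rec / n_steps
    } else {
      state <- "likely_absent"
      completeness <- NA_real_
    }
  }
  list(state = state, completeness = completeness,
       recovered_steps = as.integer(n_rec), n_steps = as.integer(n_steps),
       prevalence_support = as.integer(prevalence), no_signature = no_sig)
}

#' Genome x pathway tri-state completeness matrix for a cohort
#'
#' Computes signature prevalence once per pathway over the whole cohort, then
#' scores every genome x pathway cell with [scorePathway()].
#'
#' @param genes `GRanges` gene table for the cohort ([readGeneTable()]).
#' @param pathways A [PathwaySet-class].
#' @param genome_ids Optional character vector fixing the cohort (defaults to
#'   the genomes present in `genes`; genomes without genes score zero
#'   everywhere). Duplicates are an error.
#' @return A [CompletenessMatrix-class].
#' @export
cohortCompleteness <- function(genes, pathways, genome_ids = NULL) {
  acc_sets <- genomeAccessions(genes)
  if (is.null(genome_ids)) genome_ids <- sort(names(acc_sets))
  if (anyDuplicated(genome_ids))
    stop("duplicate genome_id in cohort")
  empty <- setdiff(genome_ids, names(acc_sets))
  for (g in empty) acc_sets[[g]] <- character(0)
  acc_sets <- acc_sets[genome_ids]
  n <- length(genome_ids)
  prev <- signaturePrevalence(acc_sets, pathways)
  rows <- list()
  no_sig_warned <- character(0)
  for (pid in pathwayIds(pathways)) {
    pw <- pathways[[pid]]
    for (g in genome_ids) {
      res <- withCallingHandlers(
        scorePathway(acc_sets[[g]], pw, prev[[pid]], n),
        warning = function(w) {
          if (pid %in% no_sig_warned) invokeRestart("muffleWarning")
        })
      no_sig_warned <- union(no_sig_warned, if (res$no_signature) pid)
      rows[[length(rows) + 1L]] <- DataFrame(
        genome_id = g, pathway_id = pid, state = res$state,
        completeness = res$completeness,
        recovered_steps = res$recovered_steps, n_steps = res$n_steps,
        prevalence_support = res$prevalence_support,
        no_signature = res$no_signature)
    }
  }
  new("CompletenessMatrix", calls = do.call(rbind, rows),
      n_genomes = as.integer(n))
}

#' Serialize completeness calls to the tri-state cell convention
#'
#' Cells are `"1"` (complete), `"0"` (no step recovered), `"(0)"` (likely
#' absent) or a decimal fraction (exact fractions, formatted to `digits`
#' decimals at serialization only).
#'
#' @param x A [CompletenessMatrix-class].
#' @param digits Decimals for fractional cells (default 2).
#' @return Character matrix, genomes x pathways.
#' @export
setMethod("completenessCells", "CompletenessMatrix",
          function(x, digits = 2L) {
  calls <- x@calls
  genomes <- unique(calls$genome_id)
  pws <- unique(calls$pathway_id)
  m <- matrix("0", nrow = length(genomes), ncol = length(pws),
              dimnames = list(genomes, pws))
  cell <- ifelse(calls$state == "zero", "0",
          ifelse(calls$state == "likely_absent", "(0)",
          ifelse(calls$completeness == 1, "1",
                 formatC(calls$completeness, digits = digits,
                         format = "f"))))
  m[cbind(match(calls$genome_id, genomes),
          match(calls$pathway_id, pws))] <- cell
  m
})

#' Write a completeness matrix as TSV
#'
#' @param x A [CompletenessMatrix-class].
#' @param path Output path.
#' @param digits Decimals for fractional cells.
#' @return `path`, invisibly.
#' @export
writeCompletenessMatrix <- function(x, path, digits = 2L) {
  m <- completenessCells(x, digits = digits)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# limnoMAG pathway completeness matrix (cohort n = ",
                    x@n_genomes, "); cells: 1 / 0 / (0) / fraction"), con)
  utils::write.table(data.frame(genome_id = rownames(m), m,
                                check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
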