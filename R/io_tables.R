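#' @include AllClasses.R
NULL

LOCALIZATIONS <- c("cytoplasmic", "periplasmic", "inner_membrane",
                   "outer_membrane", "extracellular", "unknown")

GENE_COLS <- c("genome_id", "contig_id", "locus_tag", "start", "end",
               "strand", "annotations", "localization", "tm_strand_count")

#' Infer the annotation scheme of an accession from its prefix
#'
#' Accessions are carried verbatim; the scheme (KO, COG, pfam, TIGRfam, CAZy)
#' is inferred from the conventional prefix. Unrecognized prefixes map to
#' `"other"`. An explicit `schemes` column in the gene table overrides this.
#'
#' @param accession Character vector of annotation accessions
#'   (e.g. `"K01443"`, `"COG1629"`, `"pfam00884"`, `"TIGR01391"`, `"GH29"`).
#' @return Character vector of scheme labels.
#' @examples
#' annotationScheme(c("K01443", "pfam00884", "GH29", "TIGR01391", "COG1629"))
#' @export
annotationScheme <- function(accession) {
  out <- rep("other", length(accession))
  out[grepl("^K[0-9]{5}$", accession)] <- "KO"
  out[grepl("^COG[0-9]+$", accession)] <- "COG"
  out[grepl("^(pfam|PF)[0-9]+$", accession)] <- "pfam"
  out[grepl("^TIGR[0-9]+$", accession)] <- "TIGRfam"
  out[grepl("^(GH|GT|PL|CE|CBM|AA)[0-9]+$", accession)] <- "CAZy"
  out
}

.splitList <- function(x) {
  x[is.na(x)] <- ""
  lapply(strsplit(x, "[,;] *"), function(v) v[nzchar(v)])
}

.assignGeneIndex <- function(df) {
  ord <- order(df$genome_id, df$contig_id, df$start)
  df <- df[ord, , drop = FALSE]
  key <- paste(df$genome_id, df$contig_id, sep = "\r")
  df$gene_index <- stats::ave(seq_len(nrow(df)), key, FUN = seq_along)
  rownames(df) <- NULL
  df
}

.validateGeneFrame <- function(df) {
  if (any(df$start < 1L)) stop("gene table: start must be >= 1")
  if (any(df$end < df$start))
    stop("gene table: end < start for locus ",
         paste(df$locus_tag[df$end < df$start], collapse = ", "))
  if (!all(df$strand %in% c("+", "-")))
    stop("gene table: strand must be '+' or '-'")
  dup <- duplicated(paste(df$genome_id, df$locus_tag))
  if (any(dup))
    stop("gene table: duplicate locus_tag within genome: ",
         paste(unique(df$locus_tag[dup]), collapse = ", "))
  if (any(!nzchar(df$locus_tag))) stop("gene table: empty locus_tag")
  bad <- !(df$localization %in% LOCALIZATIONS)
  if (any(bad))
    stop("gene table: unknown localization value(s): ",
         paste(unique(df$localization[bad]), collapse = ", "))
  invisible(df)
}

.geneFrameToGRanges <- function(df) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$contig_id,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand)
  mcols(gr) <- DataFrame(
    genome_id = df$genome_id,
    locus_tag = df$locus_tag,
    gene_index = as.integer(df$gene_index),
    check.names = FALSE)
  mcols(gr)$annotations <- IRanges::CharacterList(df$annotations_list)
  mcols(gr)$schemes <- IRanges::CharacterList(df$schemes_list)
  mcols(gr)$localization <- df$localization
  mcols(gr)$tm_strand_count <- df$tm_strand_count
  names(gr) <- df$locus_tag
  gr
}

#' Read an annotated gene table
#'
#' Reads one row per predicted gene from a tab-separated table or a GFF3 file
#' into a [GenomicRanges::GRanges] (1-based, inclusive coordinates). Records
#' are sorted by (genome, contig, start) and `gene_index` (ordinal position
#' along the contig) is assigned. Missing localizations default to
#' `"unknown"`; missing transmembrane-strand counts stay `NA` (never imputed).
#'
#' The TSV dialect requires columns `genome_id`, `contig_id`, `locus_tag`,
#' `start`, `end`, `strand`, `annotations` (comma- or semicolon-separated
#' accessions), and optionally `localization`, `tm_strand_count` and a
#' `schemes` override (parallel to `annotations`). Lines starting with `#`
#' are comments. GFF3 input (requires \pkg{rtracklayer}) carries the same
#' fields as attributes; `ID` is used as the locus tag when `locus_tag` is
#' absent.
#'
#' @param path Path to the file.
#' @param format `"tsv"` (default) or `"gff3"`.
#' @return A `GRanges` with metadata columns `genome_id`, `locus_tag`,
#'   `gene_index`, `annotations` (`CharacterList`), `schemes`
#'   (`CharacterList`), `localization`, `tm_strand_count`.
#' @seealso [writeGeneTable()] for the inverse.
#' @export
readGeneTable <- function(path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("gene table not found: ", path)
  if (format == "gff3") return(.readGeneGFF3(path))
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  req <- c("genome_id", "contig_id", "locus_tag", "start", "end", "strand",
           "annotations")
  miss <- setdiff(req, colnames(df))
  if (length(miss))
    stop("gene table: missing required column(s): ", paste(miss, collapse = ", "))
  if (!"localization" %in% colnames(df)) df$localization <- "unknown"
  if (!"tm_strand_count" %in% colnames(df)) df$tm_strand_count <- NA_integer_
  df$localization[is.na(df$localization) | !nzchar(df$localization)] <- "unknown"
  df$tm_strand_count <- suppressWarnings(as.integer(df$tm_strand_count))
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df$annotations_list <- .splitList(as.character(df$annotations))
  if ("schemes" %in% colnames(df)) {
    df$schemes_list <- .splitList(as.character(df$schemes))
    bad <- lengths(df$schemes_list) != lengths(df$annotations_list) &
      lengths(df$schemes_list) > 0L
    if (any(bad)) stop("gene table: schemes column length mismatch")
    empty <- lengths(df$schemes_list) == 0L
    df$schemes_list[empty] <- lapply(df$annotations_list[empty], annotationScheme)
  } else {
    df$schemes_list <- lapply(df$annotations_list, annotationScheme)
  }
  df <- .assignGeneIndex(df)
  .validateGeneFrame(df)
  .geneFrameToGRanges(df)
}

.readGeneGFF3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("GFF3 input needs the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gff3")
  m <- mcols(gr)
  lt <- if ("locus_tag" %in% colnames(m)) m$locus_tag else m$ID
  if (is.null(lt)) stop("gene table (gff3): missing locus_tag/ID attribute")
  if (!"genome_id" %in% colnames(m))
    stop("gene table (gff3): missing genome_id attribute")
  ann <- if ("annotations" %in% colnames(m)) {
    if (is(m$annotations, "List"))
      vapply(as.list(m$annotations), paste, character(1), collapse = ",")
    else as.character(m$annotations)
  } else ""
  df <- data.frame(
    genome_id = as.character(m$genome_id),
    contig_id = as.character(seqnames(gr)),
    locus_tag = as.character(lt),
    start = start(gr), end = end(gr),
    strand = as.character(strand(gr)),
    localization = if ("localization" %in% colnames(m))
      as.character(m$localization) else "unknown",
    tm_strand_count = if ("tm_strand_count" %in% colnames(m))
      suppressWarnings(as.integer(m$tm_strand_count)) else NA_integer_,
    stringsAsFactors = FALSE)
  df$strand[!df$strand %in% c("+", "-")] <- "+"
  df$localization[is.na(df$localization) | !nzchar(df$localization)] <- "unknown"
  df$annotations_list <- .splitList(ann)
  df$schemes_list <- lapply(df$annotations_list, annotationScheme)
  df <- .assignGeneIndex(df)
  .validateGeneFrame(df)
  .geneFrameToGRanges(df)
}

#' Write a gene table as TSV
#'
#' Inverse of [readGeneTable()]; `readGeneTable(writeGeneTable(x, f))`
#' reproduces `x` exactly. Output is UTF-8, tab-delimited, with a commented
#' header line.
#'
#' @param genes `GRanges` as returned by [readGeneTable()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGeneTable <- function(genes, path) {
  df <- data.frame(
    genome_id = mcols(genes)$genome_id,
    contig_id = as.character(seqnames(genes)),
    locus_tag = mcols(genes)$locus_tag,
    start = start(genes), end = end(genes),
    strand = as.character(strand(genes)),
    annotations = vapply(mcols(genes)$annotations, paste, character(1),
                         collapse = ","),
    schemes = vapply(mcols(genes)$schemes, paste, character(1), collapse = ","),
    localization = mcols(genes)$localization,
    tm_strand_count = mcols(genes)$tm_strand_count,
    stringsAsFactors = FALSE)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# limnoMAG gene table (coordinates 1-based, inclusive)", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genome summary table
#'
#' Reads a per-MAG metadata table (one row per genome: completeness,
#' contamination, GC, gene count, coverage summary). The lake/layer group
#' (`ME`/`TE`/`TH`) is taken from a `lake_group` column when present and
#' otherwise inferred from the `genome_id` prefix.
#'
#' @param path Path to a TSV with a header; `#` lines are comments. Required
#'   columns: `genome_id`, `completeness_pct`.
#' @return A data.frame with one row per genome.
#' @examples
#' tab <- readGenomeTable(system.file("extdata", "verrucomicrobia_mags.tsv",
#'                                    package = "limnoMAG"))
#' nrow(tab)                     # 19
#' table(tab$lake_group)         # 8 ME / 3 TE / 8 TH
#' max(tab$completeness_pct)     # 95
#' @export
readGenomeTable <- function(path) {
  if (!file.exists(path)) stop("genome table not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (nrow(df) == 0L) {
    warning("genome table is empty: ", path)
    return(df)
  }
  req <- c("genome_id", "completeness_pct")
  miss <- setdiff(req, colnames(df))
  if (length(miss))
    stop("genome table: missing required column(s): ",
         paste(miss, collapse = ", "))
  if (!"lake_group" %in% colnames(df)) {
    df$lake_group <- sub("^(ME|TE|TH).*$", "\\1", df$genome_id)
    df$lake_group[!df$lake_group %in% c("ME", "TE", "TH")] <- NA_character_
  }
  if (any(df$completeness_pct < 0 | df$completeness_pct > 100))
    stop("genome table: completeness_pct outside [0, 100]")
  if ("contamination_pct" %in% colnames(df) && any(df$contamination_pct < 0))
    stop("genome table: negative contamination_pct")
  if ("gene_count" %in% colnames(df) && any(df$gene_count < 0))
    stop("genome table: negative gene_count")
  dup <- duplicated(df$genome_id)
  if (any(dup))
    stop("genome table: duplicate genome_id: ",
         paste(df$genome_id[dup], collapse = ", "))
  df
}

#' Write a genome summary table as TSV
#'
#' @param genomes data.frame as returned by [readGenomeTable()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGenomeTable <- function(genomes, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# limnoMAG genome table", con)
  utils::write.table(genomes, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a PathwaySet
#'
#' @param pathways List of pathway definitions; each element a list with
#'   `pathway_id`, `name`, `steps` (named list of character OR-groups) and
#'   `signature` (character vector of step ids, possibly empty).
#' @return A [PathwaySet-class].
#' @examples
#' ps <- PathwaySet(list(list(
#'   pathway_id = "toy", name = "toy pathway",
#'   steps = list(s1 = "K00001", s2 = c("K00002", "K00003"), s3 = "K00004"),
#'   signature = "s3")))
#' nSteps(ps)
#' @export
PathwaySet <- function(pathways) {
  names(pathways) <- vapply(pathways, `[[`, character(1), "pathway_id")
  new("PathwaySet", pathways = pathways)
}

#' Read curated pathway definitions
#'
#' One row per (pathway, step); the `accessions` column holds the OR-group of
#' isofunctional alternatives for that step (comma- or semicolon-separated)
#' and `signature` flags signature steps. Duplicate (pathway, step) rows are
#' merged into one OR-group with a warning.
#'
#' @param path TSV with columns `pathway_id`, `step_id`, `accessions`,
#'   `signature` and optionally `name`; `#` lines are comments.
#' @return A [PathwaySet-class].
#' @export
readPathwayDefs <- function(path) {
  if (!file.exists(path)) stop("pathway definitions not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  req <- c("pathway_id", "step_id", "accessions", "signature")
  miss <- setdiff(req, colnames(df))
  if (length(miss))
    stop("pathway definitions: missing required column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop("pathway definitions: no rows (pathway with zero steps)")
  sig_raw <- df$signature
  df$signature <- !is.na(as.logical(sig_raw)) & as.logical(sig_raw) |
    as.character(sig_raw) %in% c("1", "yes")
  if (!"name" %in% colnames(df)) df$name <- df$pathway_id
  acc <- .splitList(as.character(df$accessions))
  if (any(lengths(acc) == 0L))
    stop("pathway definitions: step with no accessions")
  key <- paste(df$pathway_id, df$step_id, sep = "\r")
  if (anyDuplicated(key))
    warning("pathway definitions: duplicate (pathway, step) rows merged")
  pws <- lapply(split(seq_len(nrow(df)), df$pathway_id)[unique(df$pathway_id)],
                function(idx) {
    sub <- df[idx, , drop = FALSE]
    steps <- lapply(split(unlist(acc[idx], use.names = FALSE),
                          rep(sub$step_id, lengths(acc[idx]))),
                    unique)
    steps <- steps[unique(sub$step_id)]
    sig <- unique(sub$step_id[sub$signature])
    list(pathway_id = sub$pathway_id[1L], name = sub$name[1L],
         steps = steps, signature = sig)
  })
  PathwaySet(unname(pws))
}

#' Write pathway definitions as TSV
#'
#' @param pathways A [PathwaySet-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePathwayDefs <- function(pathways, path) {
  rows <- do.call(rbind, lapply(pathways@pathways, function(p)
    data.frame(pathway_id = p$pathway_id, name = p$name,
               step_id = names(p$steps),
               accessions = vapply(p$steps, paste, character(1), collapse = ","),
               signature = names(p$steps) %in% p$signature,
               stringsAsFactors = FALSE)))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# limnoMAG pathway definitions (one row per step)", con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a CoverageExperiment
#'
#' @param coverage Numeric matrix, contigs x samples (raw depths, >= 0).
#' @param contigs data.frame with `contig_id`, `genome_id`, `length_bp`.
#' @param samples data.frame with `sample_id`, `lake_group`, `date`,
#'   `total_mapped_bases`. Samples are ordered by date within lake group.
#' @return A [CoverageExperiment-class].
#' @export
CoverageExperiment <- function(coverage, contigs, samples) {
  stopifnot(nrow(coverage) == nrow(contigs), ncol(coverage) == ncol(samples) ||
              ncol(coverage) == nrow(samples))
  samples$date <- as.Date(samples$date)
  ord <- order(samples$lake_group, samples$date, samples$sample_id)
  samples <- samples[ord, , drop = FALSE]
  coverage <- coverage[, samples$sample_id, drop = FALSE]
  se <- SummarizedExperiment(
    assays = list(coverage = coverage),
    rowData = DataFrame(genome_id = contigs$genome_id,
                        length_bp = as.numeric(contigs$length_bp),
                        row.names = contigs$contig_id),
    colData = DataFrame(lake_group = samples$lake_group,
                        date = samples$date,
                        total_mapped_bases = as.numeric(samples$total_mapped_bases),
                        row.names = samples$sample_id))
  new("CoverageExperiment", se)
}

#' Read a contig x sample coverage matrix plus sample metadata
#'
#' The matrix is a wide TSV with columns `contig_id`, `genome_id`,
#' `length_bp` followed by one column per sample; the metadata TSV has
#' columns `sample_id`, `lake_group`, `date`, `total_mapped_bases`. Samples
#' are reordered by date within lake group. `NA` coverage cells are treated
#' as 0 (absence of mapped reads) with a warning; negative cells are an
#' error, as is any matrix sample absent from the metadata.
#'
#' @param path Matrix TSV path.
#' @param meta_path Sample metadata TSV path.
#' @return A [CoverageExperiment-class].
#' @export
readCoverageMatrix <- function(path, meta_path) {
  if (!file.exists(path)) stop("coverage matrix not found: ", path)
  if (!file.exists(meta_path)) stop("sample metadata not found: ", meta_path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  meta <- utils::read.delim(meta_path, comment.char = "#",
                            stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("contig_id", "genome_id", "length_bp")
  miss <- setdiff(req, colnames(df))
  if (length(miss))
    stop("coverage matrix: missing required column(s): ",
         paste(miss, collapse = ", "))
  mreq <- c("sample_id", "lake_group", "date", "total_mapped_bases")
  mmiss <- setdiff(mreq, colnames(meta))
  if (length(mmiss))
    stop("sample metadata: missing required column(s): ",
         paste(mmiss, collapse = ", "))
  sample_cols <- setdiff(colnames(df), req)
  unknown <- setdiff(sample_cols, meta$sample_id)
  if (length(unknown))
    stop("coverage matrix: sample(s) absent from metadata: ",
         paste(unknown, collapse = ", "))
  m <- as.matrix(df[, sample_cols, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) {
    warning("coverage matrix: NA cells treated as 0 (no mapped reads)")
    m[is.na(m)] <- 0
  }
  if (any(m < 0)) stop("coverage matrix: negative coverage entries")
  rownames(m) <- df$contig_id
  meta <- meta[meta$sample_id %in% sample_cols, , drop = FALSE]
  CoverageExperiment(m, df[, req], meta)
}

#' Write a CoverageExperiment as matrix + metadata TSVs
#'
#' @param cov A [CoverageExperiment-class].
#' @param path Matrix TSV output path.
#' @param meta_path Metadata TSV output path.
#' @return `path`, invisibly.
#' @export
writeCoverageMatrix <- function(cov, path, meta_path) {
  m <- assay(cov, "coverage")
  df <- data.frame(contig_id = rownames(m),
                   genome_id = rowData(cov)$genome_id,
                   length_bp = rowData(cov)$length_bp,
                   m, check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, open = "wt", encoding = "UTF-8")
  writeLines("# limnoMAG coverage matrix (raw depths)", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  meta <- data.frame(sample_id = colnames(m),
                     lake_group = colData(cov)$lake_group,
                     date = as.character(colData(cov)$date),
                     total_mapped_bases = colData(cov)$total_mapped_bases,
                     stringsAsFactors = FALSE)
  con <- file(meta_path, open = "wt", encoding = "UTF-8")
  writeLines("# limnoMAG sample metadata", con)
  utils::write.table(meta, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}
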