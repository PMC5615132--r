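#' @include AllClasses.R io_tables.R
NULL

AA_ALPHABET20X <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                    "R","S","T","V","W","Y","X")

#' Count c-type heme-binding motifs (CxxCH) in a protein sequence
#'
#' Scans all (possibly overlapping) length-5 windows for the canonical
#' c-type cytochrome heme-binding site Cys-X-X-Cys-His. Multiheme
#' cytochromes c (MHCs) of porin-MHC electron-transfer conduits carry eight
#' or more such sites. `X` is tolerated in the sequence but never matches
#' the fixed Cys/His positions.
#'
#' @param sequence Character scalar or [Biostrings::AAString]; 20-letter
#'   amino-acid alphabet plus `X`. An empty sequence gives count 0.
#' @param motif Regular expression for one window (default `"C..CH"`);
#'   configurable for non-canonical binding sites.
#' @return List with `count` and `positions` (1-based residue index of each
#'   window start, strictly increasing).
#' @examples
#' countHemeMotifs("MCAACHAA")   # count 1, position 2
#' @export
countHemeMotifs <- function(sequence, motif = "C..CH") {
  s <- toupper(as.character(sequence))
  if (length(s) != 1L) stop("one sequence at a time; see scanHemeMotifs()")
  if (nchar(s) == 0L) return(list(count = 0L, positions = integer(0)))
  chars <- strsplit(s, "")[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET20X)
  if (length(bad))
    stop("non-amino-acid character(s) in sequence: ",
         paste(bad, collapse = ", "))
  m <- gregexpr(paste0("(?=", motif, ")"), s, perl = TRUE)[[1]]
  pos <- if (m[1] == -1L) integer(0) else as.integer(m)
  list(count = length(pos), positions = pos)
}

#' Heme-motif scan over a protein set
#'
#' @param proteins Named [Biostrings::AAStringSet] (names are locus tags) or
#'   named character vector.
#' @param motif Window pattern, see [countHemeMotifs()].
#' @return [S4Vectors::DataFrame]: `locus_tag`, `heme_motif_count`,
#'   `positions` (IntegerList).
#' @export
scanHemeMotifs <- function(proteins, motif = "C..CH") {
  s <- as.character(proteins)
  scans <- lapply(s, countHemeMotifs, motif = motif)
  DataFrame(locus_tag = names(s),
            heme_motif_count = vapply(scans, `[[`, integer(1), "count"),
            positions = IRanges::IntegerList(lapply(scans, `[[`, "positions")))
}

#' Default parameters and role accession lists for locus detection
#'
#' Role assignment for the gene-neighborhood detectors is driven by
#' configurable accession lists; these defaults cover the commonly used
#' annotation accessions for each role and are meant to be replaced or
#' extended for a given annotation source (a YAML file with the same keys
#' can be loaded with [yaml::read_yaml()] and passed through).
#'
#' Window parameters: porin-MHC (PCC) adjacency allows at most
#' `pcc_max_intervening` genes between the porin and the periplasmic MHC
#' (default 2); CUT and BMC loci must fit in a window of at most
#' `cut_window_genes` / `bmc_window_genes` consecutive genes (default 15).
#' `min_tm` (default 20) is the minimum predicted transmembrane beta-strand
#' count for a PCC porin; `min_hemes` (default 8) the minimum CxxCH count
#' for an MHC, with `hemes_exact = TRUE` switching to exactly `min_hemes`.
#'
#' @param ... Named overrides of any default element.
#' @return Named list of parameters and role accession lists.
#' @export
lociConfig <- function(...) {
  cfg <- list(
    min_tm = 20L,
    min_hemes = 8L,
    hemes_exact = FALSE,
    heme_motif = "C..CH",
    pcc_max_intervening = 2L,
    cut_window_genes = 15L,
    bmc_window_genes = 15L,
    roles = list(
      tbdr = c("COG1629", "pfam00593", "pfam13715", "TIGR01352"),
      inner_transporter = c("COG0477", "pfam00083", "pfam07690", "K02429",
                            "K02025", "K02026"),
      gh_pattern = "^GH[0-9]+$",
      shell_protein = c("pfam00936", "pfam03319"),
      fucose = c("K01818", "K00879", "K01628"),
      rhamnose = c("K01813", "K00848", "K01629")))
  over <- list(...)
  for (k in names(over)) cfg[[k]] <- over[[k]]
  cfg
}

.geneHasAccession <- function(genes, accessions = NULL, pattern = NULL) {
  ann <- mcols(genes)$annotations
  if (!is.null(pattern)) {
    hit <- grepl(pattern, unlist(ann, use.names = FALSE))
  } else {
    hit <- unlist(ann, use.names = FALSE) %in% accessions
  }
  grp <- rep(seq_along(ann), lengths(ann))
  out <- logical(length(ann))
  if (length(hit)) out[unique(grp[hit])] <- TRUE
  out
}

.emptyLocusCalls <- function() {
  DataFrame(locus_type = character(0), genome_id = character(0),
            contig_id = character(0), first_index = integer(0),
            last_index = integer(0), n_genes = integer(0),
            span_bp = integer(0), members = IRanges::CharacterList(),
            evidence = character(0), gh_surface_fraction = numeric(0))
}

.mergeIndexWindows <- function(wins) {
  # wins: IRanges on gene-index coordinates; merge overlapping/adjacent-
  # overlapping qualifying windows into maximal calls
  IRanges::reduce(wins)
}

.makeLocusCall <- function(type, sub, first, last, evidence,
                           gh_surface_fraction = NA_real_) {
  memb <- sub[mcols(sub)$gene_index >= first & mcols(sub)$gene_index <= last]
  memb <- memb[order(mcols(memb)$gene_index)]
  DataFrame(locus_type = type,
            genome_id = mcols(memb)$genome_id[1L],
            contig_id = as.character(seqnames(memb))[1L],
            first_index = as.integer(first), last_index = as.integer(last),
            n_genes = length(memb),
            span_bp = max(end(memb)) - min(start(memb)) + 1L,
            members = IRanges::CharacterList(list(mcols(memb)$locus_tag)),
            evidence = paste(names(evidence), unlist(evidence), sep = "=",
                             collapse = ";"),
            gh_surface_fraction = gh_surface_fraction)
}

.perContig <- function(genes, fun) {
  key <- paste(mcols(genes)$genome_id, as.character(seqnames(genes)),
               sep = "\r")
  parts <- split(seq_along(genes), key)
  calls <- lapply(parts, function(idx) fun(genes[idx]))
  calls <- calls[!vapply(calls, is.null, logical(1))]
  if (!length(calls)) return(.emptyLocusCalls())
  do.call(rbind, unname(calls))
}

#' Detect porin-multiheme-cytochrome (PCC) loci
#'
#' A putative porin-MHC extracellular-electron-transfer locus is called when
#' a porin-like gene (predicted outer-membrane protein with at least
#' `min_tm` transmembrane beta strands, default 20) lies adjacent (at most
#' `pcc_max_intervening` intervening genes, default 2) to a gene encoding a
#' predicted periplasmic protein with at least `min_hemes` CxxCH
#' heme-binding sites (default 8). An extracellular MHC in the same window
#' is recorded as optional supporting evidence. Overlapping candidate pairs
#' on one contig are merged into one maximal call. Candidates whose protein
#' sequence is missing are skipped with a warning.
#'
#' @param genes `GRanges` gene table ([readGeneTable()]); requires
#'   `localization` and `tm_strand_count`.
#' @param proteins Named [Biostrings::AAStringSet] (locus tags).
#' @param config [lociConfig()] list.
#' @return [S4Vectors::DataFrame] of locus calls (possibly empty): type,
#'   genome, contig, member tags, evidence roles, span.
#' @export
detectPCC <- function(genes, proteins, config = lociConfig()) {
  prot_names <- names(proteins)
  heme_cache <- new.env(parent = emptyenv())
  hemeCount <- function(tag) {
    if (!is.null(heme_cache[[tag]])) return(heme_cache[[tag]])
    n <- countHemeMotifs(as.character(proteins[[match(tag, prot_names)]]),
                         motif = config$heme_motif)$count
    heme_cache[[tag]] <- n
    n
  }
  hemeOK <- function(n) if (config$hemes_exact) n == config$min_hemes
                        else n >= config$min_hemes
  .perContig(genes, function(sub) {
    m <- mcols(sub)
    tm <- m$tm_strand_count
    porin <- !is.na(tm) & tm >= config$min_tm & m$localization == "outer_membrane"
    cand_mhc <- m$localization %in% c("periplasmic", "extracellular")
    if (!any(porin) || !any(cand_mhc)) return(NULL)
    missing_seq <- cand_mhc & !(m$locus_tag %in% prot_names)
    if (any(missing_seq)) {
      warning("PCC scan: missing protein sequence(s) for candidate(s) ",
              paste(m$locus_tag[missing_seq], collapse = ", "),
              "; skipped")
      cand_mhc <- cand_mhc & !missing_seq
    }
    hemes <- rep(NA_integer_, length(sub))
    hemes[cand_mhc] <- vapply(m$locus_tag[cand_mhc], hemeCount, integer(1))
    peri_mhc <- cand_mhc & m$localization == "periplasmic" &
      vapply(hemes, function(n) !is.na(n) && hemeOK(n), logical(1))
    extra_mhc <- cand_mhc & m$localization == "extracellular" &
      vapply(hemes, function(n) !is.na(n) && hemeOK(n), logical(1))
    if (!any(peri_mhc)) return(NULL)
    gidx <- m$gene_index
    maxgap <- config$pcc_max_intervening + 1L
    wins <- list()
    for (i in which(porin)) for (j in which(peri_mhc)) {
      if (i != j && abs(gidx[i] - gidx[j]) <= maxgap)
        wins[[length(wins) + 1L]] <- c(min(gidx[i], gidx[j]),
                                       max(gidx[i], gidx[j]))
    }
    if (!length(wins)) return(NULL)
    ir <- .mergeIndexWindows(IRanges::IRanges(
      start = vapply(wins, `[`, numeric(1), 1L),
      end = vapply(wins, `[`, numeric(1), 2L)))
    calls <- lapply(seq_along(ir), function(k) {
      first <- IRanges::start(ir)[k]; last <- IRanges::end(ir)[k]
      inwin <- gidx >= first & gidx <= last
      near <- gidx >= first - maxgap & gidx <= last + maxgap
      ev <- list(porin = m$locus_tag[porin & inwin][1L],
                 periplasmic_MHC = m$locus_tag[peri_mhc & inwin][1L])
      if (any(extra_mhc & near)) {
        ev$extracellular_MHC <- m$locus_tag[extra_mhc & near][1L]
        # the cluster-resident extracellular MHC belongs to the call
        xi <- gidx[match(ev$extracellular_MHC, m$locus_tag)]
        first <- min(first, xi); last <- max(last, xi)
      }
      .makeLocusCall("PCC", sub, first, last, ev)
    })
    do.call(rbind, calls)
  })
}

.windowCalls <- function(sub, role_flags, window, type, extra_roles = NULL,
                         gh_flag = NULL) {
  # role_flags: named list of logical vectors; a window qualifies when every
  # role occurs at least once within `window` consecutive gene indices
  m <- mcols(sub)
  gidx <- m$gene_index
  n <- length(sub)
  idx_of <- lapply(role_flags, function(f) sort(gidx[f]))
  if (any(lengths(idx_of) == 0L)) return(NULL)
  lo <- min(gidx); hi <- max(gidx)
  wins <- list()
  for (s in lo:hi) {
    e <- min(s + window - 1L, hi)
    ok <- all(vapply(idx_of, function(v) any(v >= s & v <= e), logical(1)))
    if (ok) {
      # tighten to the span of role-carrying genes inside the window
      occ <- unlist(lapply(idx_of, function(v) v[v >= s & v <= e]))
      wins[[length(wins) + 1L]] <- range(occ)
    }
  }
  if (!length(wins)) return(NULL)
  ir <- .mergeIndexWindows(IRanges::IRanges(
    start = vapply(wins, min, numeric(1)),
    end = vapply(wins, max, numeric(1))))
  calls <- lapply(seq_along(ir), function(k) {
    first <- IRanges::start(ir)[k]; last <- IRanges::end(ir)[k]
    inwin <- gidx >= first & gidx <= last
    ev <- lapply(role_flags, function(f) m$locus_tag[f & inwin][1L])
    ev <- ev[!vapply(ev, is.na, logical(1))]
    ghf <- NA_real_
    if (!is.null(gh_flag) && any(gh_flag & inwin)) {
      surf <- m$localization[gh_flag & inwin] %in%
        c("extracellular", "outer_membrane")
      ghf <- mean(surf)
    }
    .makeLocusCall(type, sub, first, last, ev, gh_surface_fraction = ghf)
  })
  do.call(rbind, calls)
}

#' Detect carbohydrate utilization (CUT) loci
#'
#' A CUT locus couples extracellular hydrolysis to uptake: a TonB-dependent
#' receptor (TBDR) gene clustering with inner-membrane sugar transporter
#' genes and glycoside hydrolase genes. A call is made for a maximal run of
#' genes in which a window of at most `cut_window_genes` consecutive genes
#' (default 15) contains at least one TBDR, one inner-membrane transporter
#' and one GH. The fraction of member GHs predicted extracellular or
#' outer-membrane is reported (`gh_surface_fraction`), since surface-exposed
#' hydrolases are the hallmark of functional CUT loci.
#'
#' @inheritParams detectPCC
#' @return [S4Vectors::DataFrame] of calls.
#' @export
detectCUT <- function(genes, config = lociConfig()) {
  .perContig(genes, function(sub) {
    gh <- .geneHasAccession(sub, pattern = config$roles$gh_pattern)
    flags <- list(
      TBDR = .geneHasAccession(sub, config$roles$tbdr),
      inner_transporter = .geneHasAccession(sub, config$roles$inner_transporter),
      GH = gh)
    .windowCalls(sub, flags, config$cut_window_genes, "CUT", gh_flag = gh)
  })
}

#' Detect bacterial microcompartment (BMC) loci
#'
#' BMC loci for fucose/rhamnose degradation: at least one shell-protein gene
#' co-occurring with at least one L-fucose- or L-rhamnose-degradation gene
#' within a window of at most `bmc_window_genes` consecutive genes (default
#' 15). Sugar roles are tagged `fucose_gene` / `rhamnose_gene` in the
#' evidence.
#'
#' @inheritParams detectPCC
#' @return [S4Vectors::DataFrame] of calls.
#' @export
detectBMC <- function(genes, config = lociConfig()) {
  .perContig(genes, function(sub) {
    shell <- .geneHasAccession(sub, config$roles$shell_protein)
    fuc <- .geneHasAccession(sub, config$roles$fucose)
    rha <- .geneHasAccession(sub, config$roles$rhamnose)
    sugar <- fuc | rha
    calls <- .windowCalls(sub,
                          list(shell_protein = shell, sugar = sugar),
                          config$bmc_window_genes, "BMC")
    if (is.null(calls)) return(NULL)
    # re-tag the generic sugar role as fucose_gene / rhamnose_gene
    m <- mcols(sub)
    calls$evidence <- vapply(seq_len(nrow(calls)), function(k) {
      inwin <- m$gene_index >= calls$first_index[k] &
        m$gene_index <= calls$last_index[k]
      ev <- list(shell_protein = m$locus_tag[shell & inwin][1L])
      if (any(fuc & inwin)) ev$fucose_gene <- m$locus_tag[fuc & inwin][1L]
      if (any(rha & inwin)) ev$rhamnose_gene <- m$locus_tag[rha & inwin][1L]
      paste(names(ev), unlist(ev), sep = "=", collapse = ";")
    }, character(1))
    calls
  })
}

#' Scan a cohort for all three locus classes
#'
#' @inheritParams detectPCC
#' @return [S4Vectors::DataFrame] with PCC, CUT and BMC calls stacked.
#' @export
detectLoci <- function(genes, proteins, config = lociConfig()) {
  rbind(detectPCC(genes, proteins, config),
        detectCUT(genes, config),
        detectBMC(genes, config))
}

#' Write locus calls as TSV
#'
#' @param calls DataFrame from [detectLoci()] and friends.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeLocusCalls <- function(calls, path) {
  df <- as.data.frame(calls[, setdiff(colnames(calls), "members")])
  df$members <- vapply(calls$members, paste, character(1), collapse = ",")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# limnoMAG locus calls (evidence: role=locus_tag;...)", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
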