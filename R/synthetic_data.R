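#' @include AllClasses.R io_tables.R loci.R
NULL

#' Default configuration for the synthetic MAG cohort generator
#'
#' The defaults emulate the cohort structure the analysis is designed for:
#' 19 genomes in three lake/layer groups (8 ME / 3 TE / 8 TH), completeness
#' drawn from 51--95% acting as an independent per-gene retention
#' probability, GH coding densities contrasted by group (ME ~1%, TE ~3%,
#' TH ~4%) with group-specific overrepresented families, planted PCC loci
#' restricted to TH genomes, CUT loci in one TE and one TH genome, BMC loci
#' in seven genomes across groups, bloom-and-bust coverage dynamics for ME
#' populations versus persistent dynamics for TE/TH, and weekly sampling
#' dates with the 94 / 45 / 45 ME/TE/TH series sizes of the cohort the
#' generator emulates.
#'
#' @param ... Named overrides of any default element.
#' @return Named configuration list for [generateCohort()].
#' @export
syntheticCohortConfig <- function(...) {
  cfg <- list(
    group_sizes = c(ME = 8L, TE = 3L, TH = 8L),
    n_samples = c(ME = 94L, TE = 45L, TH = 45L),
    gene_count_range = c(1200L, 5600L),
    completeness_range = c(51, 95),
    dropout = TRUE,
    n_contigs = 6L,
    gh_density = c(ME = 0.010, TE = 0.030, TH = 0.040),
    sulfatase_density = c(ME = 0.008, TE = 0.010, TH = 0.012),
    pscyt_density = c(ME = 0.020, TE = 0.015, TH = 0.004),
    pathway_presence_prob = 0.7,
    pcc_per_group = c(ME = 0L, TE = 0L, TH = 4L),
    cut_per_group = c(ME = 0L, TE = 1L, TH = 1L),
    bmc_per_group = c(ME = 2L, TE = 1L, TH = 4L),
    dynamics_by_group = c(ME = "bloom", TE = "persistent", TH = "persistent"),
    persistent_baseline = 5, persistent_noise_sd = 0.3,
    bloom_baseline = 0.05, bloom_amplitude = 8, bloom_width_days = 10,
    bloom_noise_sd = 0.3,
    contig_noise_sd = 0.05, sample_noise_sd = 0.05,
    total_bases_meanlog = log(1e9), total_bases_sdlog = 0.3,
    protein_length_range = c(150L, 400L),
    contaminant_genomes = character(0))
  over <- list(...)
  for (k in names(over)) cfg[[k]] <- over[[k]]
  bad_sizes <- any(cfg$group_sizes < 0) || any(cfg$n_samples < 1)
  if (bad_sizes) stop("invalid config: negative group sizes / empty sampling")
  if (any(cfg$gh_density < 0 | cfg$gh_density > 1) ||
      cfg$pathway_presence_prob <= 0 || cfg$pathway_presence_prob > 1)
    stop("invalid config: probabilities must lie in (0, 1]")
  cfg
}

#' Curated toy pathway definitions used by the synthetic cohort
#'
#' A small set of sugar-degradation, central-carbon and nitrogen pathways
#' with real KO accessions and designated signature steps, so synthetic
#' fixtures exercise the same accession vocabulary as curated inputs.
#'
#' @return A [PathwaySet-class].
#' @export
defaultPathways <- function() {
  PathwaySet(list(
    list(pathway_id = "emp", name = "Embden-Meyerhof glycolysis",
         steps = list(glk = c("K00844", "K00845"), pgi = "K01810",
                      pfk = "K00850", fba = c("K01623", "K01624"),
                      tpi = "K01803", gap = "K00134", pgk = "K00927",
                      eno = "K01689", pyk = "K00873"),
         signature = "pfk"),
    list(pathway_id = "tca", name = "TCA cycle",
         steps = list(glt = "K01647", acn = "K01681", idh = "K00031",
                      ogdh = c("K00164", "K00658"), suc = "K01902",
                      sdh = "K00239", fum = "K01679", mdh = "K00024"),
         signature = "glt"),
    list(pathway_id = "fucose_deg", name = "L-fucose degradation",
         steps = list(fucI = "K01818", fucK = "K00879", fucA = "K01628"),
         signature = "fucA"),
    list(pathway_id = "rhamnose_deg", name = "L-rhamnose degradation",
         steps = list(rhaA = "K01813", rhaB = "K00848", rhaD = "K01629"),
         signature = "rhaD"),
    list(pathway_id = "xylose_deg", name = "D-xylose degradation",
         steps = list(xylA = "K01805", xylB = "K00854"),
         signature = "xylA"),
    list(pathway_id = "galactose_leloir", name = "galactose (Leloir)",
         steps = list(galK = "K00849", galT = "K00965", galE = "K01784"),
         signature = "galT"),
    list(pathway_id = "urease", name = "urea hydrolysis",
         steps = list(ureC = "K01428", ureB = "K01429", ureA = "K01430"),
         signature = "ureC"),
    list(pathway_id = "nitrogen_fixation", name = "nitrogen fixation",
         steps = list(nifH = "K02588", nifD = "K02586", nifK = "K02591"),
         signature = "nifH")))
}

GH_FAMILY_POOL <- list(
  trout = c("GH2", "GH29", "GH78", "GH95", "GH106"),
  mendota = c("GH13", "GH20", "GH33", "GH57", "GH77"),
  shared = c("GH1", "GH3", "GH5", "GH10", "GH16", "GH31", "GH36", "GH43",
             "GH51", "GH65"))

.ghFamilyWeights <- function(group) {
  pool <- c(GH_FAMILY_POOL$trout, GH_FAMILY_POOL$mendota, GH_FAMILY_POOL$shared)
  w <- if (group == "ME")
    c(rep(0.02, 5), rep(0.12, 5), rep(0.03, 10))
  else
    c(rep(0.12, 5), rep(0.02, 5), rep(0.03, 10))
  names(w) <- pool
  w / sum(w)
}

.randomProtein <- function(len) {
  paste(sample(setdiff(AA_ALPHABET20X, "X"), len, replace = TRUE),
        collapse = "")
}

.mhcProtein <- function(len, n_hemes) {
  # random backbone with n_hemes planted CAACH heme-binding sites
  seg <- max(5L, (len - 5L * n_hemes) %/% (n_hemes + 1L))
  parts <- character(2L * n_hemes + 1L)
  for (i in seq_len(n_hemes)) {
    parts[2L * i - 1L] <- .randomProtein(seg)
    parts[2L * i] <- "CAACH"
  }
  parts[2L * n_hemes + 1L] <- .randomProtein(seg)
  paste(parts, collapse = "")
}

#' Apply completeness dropout to a gene set
#'
#' Models genome incompleteness as independent per-gene retention: each gene
#' is kept with probability `retention_p`, matching the modelling assumption
#' that functional genes are randomly distributed between the recovered and
#' missing parts of a draft genome.
#'
#' @param genes `GRanges` gene table, or any vector-like object.
#' @param retention_p Retention probability in (0, 1].
#' @return The retained subset (same class as the input).
#' @export
applyDropout <- function(genes, retention_p) {
  if (length(retention_p) != 1L || retention_p <= 0 || retention_p > 1)
    stop("retention_p must lie in (0, 1]")
  genes[stats::runif(length(genes)) < retention_p]
}

#' Simulate one coverage-dynamics series
#'
#' `persistent` series fluctuate lognormally around a baseline;
#' `bloom` series sit at a low baseline with one Gaussian-shaped peak during
#' the season plus noise (median near the baseline, mean pulled up by the
#' peak, hence a large coefficient of variation). Output is non-negative.
#'
#' @param dynamics `"persistent"` or `"bloom"`.
#' @param dates Date vector of sampling dates.
#' @param baseline Baseline normalized coverage (> 0 for persistent; the
#'   between-bloom level for bloom dynamics).
#' @param amplitude Peak height above baseline (bloom only).
#' @param peak_date Date of the bloom peak (default: random within range).
#' @param width_days Gaussian s.d. of the bloom in days.
#' @param noise_sd Lognormal noise s.d. (log scale).
#' @return Numeric series parallel to `dates`.
#' @export
simulateCoverage <- function(dynamics = c("persistent", "bloom"), dates,
                             baseline = 5, amplitude = 8, peak_date = NULL,
                             width_days = 10, noise_sd = 0.3) {
  dynamics <- match.arg(dynamics)
  if (baseline <= 0 || amplitude <= 0 || width_days <= 0 || noise_sd < 0)
    stop("dynamics parameters must be positive")
  n <- length(dates)
  noise <- exp(stats::rnorm(n, 0, noise_sd))
  if (dynamics == "persistent") return(baseline * noise)
  t <- as.numeric(dates)
  if (is.null(peak_date))
    peak_date <- dates[1L] + stats::runif(1L, 0.2, 0.8) * (max(t) - min(t))
  peak <- amplitude * exp(-0.5 * ((t - as.numeric(peak_date)) / width_days)^2)
  (baseline + peak) * noise
}

.genomeSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
}

#' Generate a synthetic MAG cohort with planted truth
#'
#' Builds a complete cohort: per-genome gene tables with planted GH /
#' sulfatase / PSCyt content at group-contrasted densities, pathway gene
#' complements for a per-genome presence map, planted PCC / CUT / BMC loci
#' on a dedicated contig, protein sequences with planted CxxCH motifs for
#' MHC genes, completeness-dependent gene dropout, and a contig x sample
#' coverage matrix with group-specific temporal dynamics. Fully
#' deterministic given `seed` (per-genome substreams are derived from it).
#'
#' @param config List from [syntheticCohortConfig()].
#' @param seed Integer seed governing all randomness.
#' @return A [SyntheticCohort-class]; `cohortTruth()` exposes the planted
#'   parameters for recovery tests.
#' @export
generateCohort <- function(config = syntheticCohortConfig(), seed = 7L) {
  if (is.null(names(config$group_sizes)))
    stop("invalid config: group_sizes must be named")
  pathways <- defaultPathways()
  pids <- pathwayIds(pathways)
  set.seed(seed)
  groups <- rep(names(config$group_sizes), config$group_sizes)
  genome_ids <- unlist(lapply(names(config$group_sizes), function(g)
    paste0(g, "S", sprintf("%02d", seq_len(config$group_sizes[[g]])))),
    use.names = FALSE)
  # which genomes carry planted loci (first k of each group)
  lociPlan <- function(per_group) unlist(lapply(
    names(config$group_sizes), function(g) {
      ids <- genome_ids[groups == g]
      utils::head(ids, per_group[[g]])
    }), use.names = FALSE)
  pcc_in <- lociPlan(config$pcc_per_group)
  cut_in <- lociPlan(config$cut_per_group)
  bmc_in <- lociPlan(config$bmc_per_group)

  gene_rows <- list(); prot_seqs <- character(0)
  truth_genomes <- list(); truth_loci <- list()
  truth_pathways <- matrix(FALSE, nrow = length(genome_ids),
                           ncol = length(pids),
                           dimnames = list(genome_ids, pids))
  truth_fams <- list()
  genome_meta <- list()

  for (gi in seq_along(genome_ids)) {
    gid <- genome_ids[gi]; grp <- groups[gi]
    set.seed(.genomeSeed(seed, gi))
    n_true <- sample(config$gene_count_range[1]:config$gene_count_range[2], 1L)
    completeness <- stats::runif(1L, config$completeness_range[1],
                                 config$completeness_range[2])
    retention <- if (isTRUE(config$dropout)) completeness / 100 else 1
    n_body <- config$n_contigs - 1L
    contig_of <- c(rep(seq_len(n_body), length.out = n_true))
    contig_of <- sort(contig_of)
    contig_ids <- paste0(gid, "_c", contig_of)
    pos_on <- stats::ave(seq_len(n_true), contig_of, FUN = seq_along)
    df <- data.frame(
      genome_id = gid, contig_id = contig_ids,
      locus_tag = paste0(gid, "_g", sprintf("%05d", seq_len(n_true))),
      start = (pos_on - 1L) * 1200L + 1L,
      end = (pos_on - 1L) * 1200L + 900L,
      strand = sample(c("+", "-"), n_true, replace = TRUE),
      annotation = "", localization = "cytoplasmic",
      tm_strand_count = NA_integer_, stringsAsFactors = FALSE)
    df$localization <- sample(
      c("cytoplasmic", "unknown", "inner_membrane", "periplasmic",
        "outer_membrane", "extracellular"), n_true, replace = TRUE,
      prob = c(0.60, 0.20, 0.10, 0.05, 0.03, 0.02))
    free <- rep(TRUE, n_true)

    claim <- function(n) {
      idx <- sample(which(free), n)
      free[idx] <<- FALSE
      idx
    }
    # family content
    n_gh <- round(config$gh_density[[grp]] * n_true)
    gh_idx <- claim(n_gh)
    w <- .ghFamilyWeights(grp)
    df$annotation[gh_idx] <- sample(names(w), n_gh, replace = TRUE, prob = w)
    n_sulf <- round(config$sulfatase_density[[grp]] * n_true)
    df$annotation[claim(n_sulf)] <- "pfam00884"
    n_ps <- round(config$pscyt_density[[grp]] * n_true)
    df$annotation[claim(n_ps)] <- sample(pscytAccessions(), n_ps,
                                         replace = TRUE)
    # pathway content: core carbon pathways in every genome, others random;
    # BMC genomes always carry the fucose/rhamnose pathways their planted
    # microcompartment genes belong to
    present <- pids %in% c("emp", "tca") |
      stats::runif(length(pids)) < config$pathway_presence_prob
    names(present) <- pids
    if (gid %in% bmc_in)
      present[c("fucose_deg", "rhamnose_deg")] <- TRUE
    truth_pathways[gid, ] <- present
    for (pid in pids[present]) {
      pw <- pathways[[pid]]
      for (stp in pw$steps) {
        acc <- if (length(stp) == 1L) stp else sample(stp, 1L)
        df$annotation[claim(1L)] <- acc
      }
    }
    # planted loci on a dedicated trailing contig
    locus_rows <- list()
    locus_contig <- paste0(gid, "_cL")
    addLocusGene <- function(k, annotation, localization, tm = NA_integer_) {
      data.frame(genome_id = gid, contig_id = locus_contig,
                 locus_tag = paste0(gid, "_L", sprintf("%03d", k)),
                 start = (k - 1L) * 1200L + 1L, end = (k - 1L) * 1200L + 900L,
                 strand = "+", annotation = annotation,
                 localization = localization, tm_strand_count = tm,
                 stringsAsFactors = FALSE)
    }
    k <- 0L
    planted <- list()
    if (gid %in% pcc_in) {
      rows <- list(addLocusGene(k + 1L, "", "outer_membrane", tm = 24L),
                   addLocusGene(k + 2L, "", "periplasmic"),
                   addLocusGene(k + 3L, "", "extracellular"))
      tags <- vapply(rows, `[[`, character(1), "locus_tag")
      prot_seqs[tags[1L]] <- .randomProtein(
        sample(config$protein_length_range[1]:config$protein_length_range[2], 1L))
      prot_seqs[tags[2L]] <- .mhcProtein(350L, 9L)
      prot_seqs[tags[3L]] <- .mhcProtein(350L, 8L)
      locus_rows <- c(locus_rows, rows)
      planted[[length(planted) + 1L]] <-
        list(type = "PCC", contig = locus_contig, members = tags)
      k <- k + 4L  # one spacer gene position left empty
    }
    if (gid %in% cut_in) {
      rows <- list(addLocusGene(k + 1L, "COG1629", "outer_membrane"),
                   addLocusGene(k + 2L, "COG0477", "inner_membrane"),
                   addLocusGene(k + 3L, "GH29", "extracellular"),
                   addLocusGene(k + 4L, "GH78", "outer_membrane"))
      tags <- vapply(rows, `[[`, character(1), "locus_tag")
      locus_rows <- c(locus_rows, rows)
      planted[[length(planted) + 1L]] <-
        list(type = "CUT", contig = locus_contig, members = tags)
      k <- k + 5L
    }
    if (gid %in% bmc_in) {
      rows <- list(addLocusGene(k + 1L, "pfam00936", "cytoplasmic"),
                   addLocusGene(k + 2L, "pfam03319", "cytoplasmic"),
                   addLocusGene(k + 3L, "K01628", "cytoplasmic"),
                   addLocusGene(k + 4L, "K01629", "cytoplasmic"))
      tags <- vapply(rows, `[[`, character(1), "locus_tag")
      locus_rows <- c(locus_rows, rows)
      planted[[length(planted) + 1L]] <-
        list(type = "BMC", contig = locus_contig, members = tags)
      k <- k + 5L
    }
    if (length(locus_rows)) df <- rbind(df, do.call(rbind, locus_rows))
    truth_loci[[gid]] <- planted
    # true (pre-dropout) GH family counts, locus-contig GH genes included
    gh_ann <- df$annotation[grepl("^GH[0-9]+$", df$annotation)]
    fam_tab <- table(gh_ann)
    truth_fams[[gid]] <- stats::setNames(as.integer(fam_tab), names(fam_tab))

    # proteins for membrane/secreted genes (heme scans need them)
    need_prot <- df$localization %in% c("periplasmic", "outer_membrane",
                                        "extracellular") &
      !(df$locus_tag %in% names(prot_seqs))
    for (tag in df$locus_tag[need_prot])
      prot_seqs[tag] <- .randomProtein(
        sample(config$protein_length_range[1]:config$protein_length_range[2], 1L))

    # completeness dropout (planted loci genes included)
    kept <- stats::runif(nrow(df)) < retention
    df <- df[kept, , drop = FALSE]

    gene_rows[[gid]] <- df
    genome_meta[[gid]] <- data.frame(
      genome_id = gid, lake_group = grp,
      subdivision = as.character(sample(1:4, 1L)),
      size_bp = sum(df$end - df$start + 1L) + 300L * nrow(df),
      completeness_pct = round(completeness),
      contamination_pct = round(stats::runif(1L, 0, 8)),
      gc_pct = round(stats::runif(1L, 42, 68)),
      coding_pct = round(stats::runif(1L, 86, 95), 1L),
      gene_count = nrow(df), stringsAsFactors = FALSE)
    truth_genomes[[gid]] <- list(
      lake_group = grp, retention = retention,
      dynamics = config$dynamics_by_group[[grp]], n_true_genes = n_true)
  }

  all_df <- do.call(rbind, gene_rows)
  all_df$annotations_list <- .splitList(all_df$annotation)
  all_df$schemes_list <- lapply(all_df$annotations_list, annotationScheme)
  all_df <- .assignGeneIndex(all_df)
  .validateGeneFrame(all_df)
  genes <- .geneFrameToGRanges(all_df)
  genomes <- do.call(rbind, unname(genome_meta))
  rownames(genomes) <- NULL
  proteins <- Biostrings::AAStringSet(prot_seqs)

  cov <- .simulateCohortCoverage(genome_ids, groups, gene_rows, config,
                                 seed, truth_genomes)
  truth <- list(seed = seed, config = config,
                genomes = truth_genomes, pathway_presence = truth_pathways,
                loci = truth_loci, gh_family_counts = truth_fams,
                dynamics = cov$dynamics, contaminants = cov$contaminants)
  new("SyntheticCohort", genes = genes, genomes = genomes,
      proteins = proteins, pathways = pathways, coverage = cov$coverage,
      truth = truth)
}

.simulateCohortCoverage <- function(genome_ids, groups, gene_rows, config,
                                    seed, truth_genomes) {
  set.seed(.genomeSeed(seed, 999983L))
  grp_names <- names(config$group_sizes)
  samples <- do.call(rbind, lapply(grp_names, function(g) {
    n <- config$n_samples[[g]]
    data.frame(sample_id = paste0(g, "_s", sprintf("%02d", seq_len(n))),
               lake_group = g,
               date = as.Date("2009-05-01") + seq(0L, by = 7L,
                                                  length.out = n),
               stringsAsFactors = FALSE)
  }))
  samples$total_mapped_bases <- stats::rlnorm(
    nrow(samples), config$total_bases_meanlog, config$total_bases_sdlog)
  ref <- stats::median(samples$total_mapped_bases)
  contigs <- list(); rows <- list(); dyn <- list(); contam <- character(0)
  for (gi in seq_along(genome_ids)) {
    gid <- genome_ids[gi]; grp <- groups[gi]
    set.seed(.genomeSeed(seed, 10000L + gi))
    df <- gene_rows[[gid]]
    ctab <- tapply(df$end, df$contig_id, max)
    cids <- names(ctab)
    lens <- as.numeric(ctab) + 300
    dynamics <- config$dynamics_by_group[[grp]]
    in_grp <- samples$lake_group == grp
    dates <- samples$date[in_grp]
    series <- if (dynamics == "bloom")
      simulateCoverage("bloom", dates, baseline = config$bloom_baseline,
                       amplitude = config$bloom_amplitude,
                       width_days = config$bloom_width_days,
                       noise_sd = config$bloom_noise_sd)
    else
      simulateCoverage("persistent", dates,
                       baseline = config$persistent_baseline,
                       noise_sd = config$persistent_noise_sd)
    dyn[[gid]] <- list(class = dynamics, series = series,
                       sample_ids = samples$sample_id[in_grp])
    m <- matrix(0, nrow = length(cids), ncol = nrow(samples),
                dimnames = list(cids, samples$sample_id))
    cnoise <- exp(stats::rnorm(length(cids), 0, config$contig_noise_sd))
    libfac <- samples$total_mapped_bases[in_grp] / ref
    for (ci in seq_along(cids)) {
      snoise <- exp(stats::rnorm(length(dates), 0, config$sample_noise_sd))
      m[ci, in_grp] <- series * cnoise[ci] * snoise * libfac
    }
    if (gid %in% config$contaminant_genomes) {
      # one extra contig with independent temporal dynamics
      bad_id <- paste0(gid, "_contam")
      bad <- matrix(0, nrow = 1L, ncol = nrow(samples),
                    dimnames = list(bad_id, samples$sample_id))
      bad[1L, in_grp] <- simulateCoverage(
        "bloom", dates, baseline = config$bloom_baseline,
        amplitude = config$bloom_amplitude,
        width_days = config$bloom_width_days,
        noise_sd = config$bloom_noise_sd) * libfac
      m <- rbind(m, bad)
      cids <- c(cids, bad_id)
      lens <- c(lens, stats::median(lens))
      contam <- c(contam, bad_id)
    }
    contigs[[gid]] <- data.frame(contig_id = cids, genome_id = gid,
                                 length_bp = lens, stringsAsFactors = FALSE)
    rows[[gid]] <- m
  }
  contig_df <- do.call(rbind, unname(contigs))
  mat <- do.call(rbind, unname(rows))
  cov <- CoverageExperiment(mat, contig_df, samples)
  list(coverage = cov, dynamics = dyn, contaminants = contam)
}

#' Write a synthetic cohort to fixture files
#'
#' Emits exactly the formats the readers consume: gene table TSV, genome
#' table TSV, pathway definitions TSV, protein FASTA, coverage matrix +
#' sample metadata TSVs, and a truth summary TSV of planted locus members.
#'
#' @param cohort A [SyntheticCohort-class].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genes = file.path(dir, "genes.tsv"),
    genomes = file.path(dir, "genomes.tsv"),
    pathways = file.path(dir, "pathways.tsv"),
    proteins = file.path(dir, "proteins.faa"),
    coverage = file.path(dir, "coverage.tsv"),
    coverage_meta = file.path(dir, "samples.tsv"),
    truth_loci = file.path(dir, "truth_loci.tsv"))
  writeGeneTable(cohortGenes(cohort), paths[["genes"]])
  writeGenomeTable(cohortGenomes(cohort), paths[["genomes"]])
  writePathwayDefs(cohortPathways(cohort), paths[["pathways"]])
  Biostrings::writeXStringSet(cohortProteins(cohort), paths[["proteins"]])
  writeCoverageMatrix(cohortCoverage(cohort), paths[["coverage"]],
                      paths[["coverage_meta"]])
  tl <- cohortTruth(cohort)$loci
  rows <- do.call(rbind, unlist(lapply(names(tl), function(g)
    lapply(tl[[g]], function(l)
      data.frame(genome_id = g, locus_type = l$type, contig_id = l$contig,
                 members = paste(l$members, collapse = ","),
                 stringsAsFactors = FALSE))), recursive = FALSE))
  if (is.null(rows))
    rows <- data.frame(genome_id = character(0), locus_type = character(0),
                       contig_id = character(0), members = character(0))
  con <- file(paths[["truth_loci"]], open = "wt", encoding = "UTF-8")
  writeLines("# limnoMAG synthetic planted loci (truth)", con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(paths)
}
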