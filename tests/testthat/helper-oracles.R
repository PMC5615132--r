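# Independent brute-force oracles used by the equivalence tests. These are
# deliberately naive re-derivations, kept free of the package's code paths.

# character-by-character window scan for the CxxCH heme motif
bruteCxxch <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  pos <- integer(0)
  if (n >= 5L) for (i in 1:(n - 4L)) {
    if (chars[i] == "C" && chars[i + 3L] == "C" && chars[i + 4L] == "H")
      pos <- c(pos, i)
  }
  list(count = length(pos), positions = pos)
}

# Pearson r from the covariance/variance definition, p from the t transform
brutePearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# independent restatement of the tri-state scoring rule
bruteScore <- function(step_present, sig_idx, sig_prevalence, n_genomes) {
  thr <- ceiling(n_genomes / 3)
  if (!any(step_present)) return("zero")
  if (any(step_present[sig_idx]) || sig_prevalence >= thr) return("fraction")
  "likely_absent"
}

# naive agglomeration for small distance matrices: repeatedly merge the
# closest pair under the given linkage, recording merge heights
bruteAgglomerate <- function(d, linkage = "average") {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1L) {
    k <- length(clusters)
    best <- c(NA, NA); bestd <- Inf
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      dij <- d[clusters[[i]], clusters[[j]], drop = FALSE]
      val <- if (linkage == "average") mean(dij) else max(dij)
      if (val < bestd) { bestd <- val; best <- c(i, j) }
    }
    heights <- c(heights, bestd)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    partitions <- c(partitions, list(lapply(clusters, sort)))
  }
  list(heights = heights, partitions = partitions)
}

# naive overlapping 4-mer census of one window
bruteKmerFreq <- function(seq) {
  n <- nchar(seq)
  counts <- integer(0)
  if (n >= 4L) {
    kmers <- substring(seq, 1:(n - 3L), 4:n)
    kmers <- kmers[!grepl("N", kmers)]
    counts <- table(kmers)
  }
  tot <- sum(counts)
  if (tot == 0) return(numeric(0))
  out <- as.numeric(counts) / tot
  names(out) <- names(counts)
  out
}

# enumerate qualifying fixed-size windows and merge overlaps: CUT oracle
bruteWindowCalls <- function(role_positions, window, n_genes) {
  spans <- list()
  for (s in 1:n_genes) {
    e <- min(s + window - 1L, n_genes)
    if (all(vapply(role_positions, function(v) any(v >= s & v <= e),
                   logical(1)))) {
      occ <- unlist(lapply(role_positions, function(v) v[v >= s & v <= e]))
      spans[[length(spans) + 1L]] <- range(occ)
    }
  }
  if (!length(spans)) return(matrix(numeric(0), ncol = 2))
  m <- do.call(rbind, spans)
  m <- m[order(m[, 1]), , drop = FALSE]
  merged <- m[1, , drop = FALSE]
  if (nrow(m) > 1) for (i in 2:nrow(m)) {
    last <- nrow(merged)
    if (m[i, 1] <= merged[last, 2]) {
      merged[last, 2] <- max(merged[last, 2], m[i, 2])
    } else merged <- rbind(merged, m[i, ])
  }
  merged
}
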