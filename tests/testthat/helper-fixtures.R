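library(data.table)

# -- small builders ----------------------------------------------------------

toy_sites <- function(contig, pos, m, total = 20L) {
  # equal strand split; meth counts chosen to give fraction m exactly
  half <- total %/% 2L
  site_table(data.table(
    contig = contig, pos = as.integer(pos),
    meth_plus = as.integer(round(m * half)), total_plus = half,
    meth_minus = as.integer(round(m * half)), total_minus = half))
}

toy_annotation <- function(features, contig_lengths = c(chr1 = 10000L)) {
  def <- data.table(feature_id = character(), contig = character(),
                    start = integer(), end = integer(), strand = character(),
                    class = character(), parent = character())
  ft <- rbind(def, as.data.table(features), fill = TRUE)
  ft[is.na(strand), strand := "+"]
  ft[is.na(contig), contig := names(contig_lengths)[1L]]
  genome_annotation(ft, contig_lengths)
}

feat <- function(id, start, end, class, strand = "+", parent = NA_character_,
                 contig = "chr1") {
  data.table(feature_id = id, contig = contig, start = as.integer(start),
             end = as.integer(end), strand = strand, class = class,
             parent = parent)
}

# -- independent oracles -----------------------------------------------------

# O(n^2) double-loop pair enumeration for correlation-by-distance
bf_correlation <- function(sites, features, dmin = 3L, dmax = 500L,
                           min_pairs = 20L) {
  ft <- if (inherits(features, "genome_annotation")) features$features else
    as.data.table(features)
  pairs <- list()
  for (i in seq_len(nrow(ft))) {
    sel <- sites[contig == ft$contig[i] & pos >= ft$start[i] & pos < ft$end[i]]
    if (nrow(sel) < 2L) next
    for (a in seq_len(nrow(sel) - 1L)) for (b in (a + 1L):nrow(sel)) {
      d <- sel$pos[b] - sel$pos[a]
      if (d >= dmin && d <= dmax)
        pairs[[length(pairs) + 1L]] <- c(d, sel$m[a], sel$m[b])
    }
  }
  pm <- do.call(rbind, pairs)
  r <- rep(NA_real_, dmax - dmin + 1L)
  n <- integer(dmax - dmin + 1L)
  for (d in dmin:dmax) {
    rows <- pm[pm[, 1L] == d, , drop = FALSE]
    n[d - dmin + 1L] <- nrow(rows)
    if (nrow(rows) >= min_pairs &&
        stats::sd(rows[, 2L]) > 0 && stats::sd(rows[, 3L]) > 0)
      r[d - dmin + 1L] <- stats::cor(rows[, 2L], rows[, 3L])
  }
  data.table(d = dmin:dmax, r = r, n_pairs = n)
}

# naive DFT sum at component k of a zero-padded series
naive_dft_amplitude <- function(series, pad, k) {
  N <- length(series) + pad
  t <- seq_along(series) - 1L
  Mod(sum(series * exp(-2i * pi * k * t / N)))
}

# GLS ancestral estimate at an internal node from pairwise path lengths:
# re-rooted covariance V[i,j] = (d(v,i) + d(v,j) - d(i,j)) / 2
gls_node_oracle <- function(tree, tip_values, node) {
  D <- ape::dist.nodes(tree)
  ntip <- length(tree$tip.label)
  x <- unname(tip_values[tree$tip.label])
  V <- matrix(0, ntip, ntip)
  for (i in seq_len(ntip)) for (j in seq_len(ntip))
    V[i, j] <- (D[node, i] + D[node, j] - D[i, j]) / 2
  diag(V) <- D[node, seq_len(ntip)]
  one <- rep(1, ntip)
  Vi <- solve(V)
  sum(Vi %*% x) / sum(Vi)
}

# periodicity-test genome: many genes with long exons, phased methylome
phased_sim <- function(seed, L = 160L, A = 0.2, n_genes = 520L,
                       exon_len = 600L, coverage = 50, n_exons = 1L,
                       intron_len = 450L) {
  probs <- rep(0, 8L); probs[n_exons] <- 1
  cfg <- sim_config(
    "strigamia-like", seed = seed,
    n_contigs = 4L,
    contig_length = as.integer(ceiling(n_genes / 4 *
      (exon_len * n_exons + intron_len * (n_exons - 1L) + 500L)) + 4000L),
    n_genes = n_genes, n_tes = 0L,
    exon_count_probs = probs, exon_length = exon_len,
    intron_length = intron_len,
    min_feature_gap = 200L, cpg_density = 0.05,
    nucleosome_repeat_length = L, periodic_amplitude = A,
    meth_gene_fraction = 1, promoter_silencing = FALSE,
    class_means = c(exon = 0.5, exon_unmeth = 0.05, intron = 0.5,
                    upstream = 0.1, TE = 0.5, rRNA = 0.05, tRNA = 0.05,
                    background = 0.2),
    coverage_mean = coverage, spike_in_sites = 200L)
  genome <- simulate_genome(cfg)
  meth <- simulate_methylome(genome, cfg)
  counts <- simulate_bisulfite_counts(meth, cfg)
  list(cfg = cfg, genome = genome, meth = meth,
       sites = filter_sites(counts$sample, 10L))
}
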