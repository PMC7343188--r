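#' Normalise CTSS tag counts to tags per million
#'
#' `tpm = 1e6 * count / sum(count)` over the whole table.
#'
#' @param ctss a `ctss_table` (`contig`, `pos`, `strand`, `count`).
#' @return the table with a `tpm` column added.
#' @export
tpm_normalize <- function(ctss) {
  if (nrow(ctss) == 0L) stopf("empty CTSS table")
  tot <- sum(ctss$count)
  if (tot <= 0) stopf("total tag count is zero")
  out <- copy(ctss)
  out[, tpm := 1e6 * count / tot]
  out
}

#' Distance-based clustering of CTSSs into tag clusters
#'
#' Greedy scan per contig and strand: consecutive CTSSs join one cluster
#' while the gap to the previous CTSS is at most `max_gap` bp (boundary
#' inclusive). Clusters never span contigs or strands; the output partitions
#' the input.
#'
#' @param ctss a `ctss_table`, ideally TPM-normalised ([tpm_normalize()]).
#' @param max_gap maximum allowed gap between adjacent members (default 20).
#' @return a `tag_clusters` list: `clusters` (data.table `cluster_id`,
#'   `contig`, `strand`, `start`, `end`, `n_ctss`, `total_count`,
#'   `total_tpm`, `peak_pos`) and `members` (input rows + `cluster_id`).
#' @export
cluster_ctss <- function(ctss, max_gap = 20L) {
  mem <- copy(as.data.table(ctss))
  setorder(mem, contig, strand, pos)
  mem[, grp := cumsum(c(1L, as.integer(diff(pos) > max_gap))), by = .(contig, strand)]
  mem[, cluster_id := .GRP, by = .(contig, strand, grp)]
  mem[, grp := NULL]
  if (!("tpm" %in% names(mem))) mem[, tpm := NA_real_]
  cl <- mem[, .(contig = contig[1L], strand = strand[1L], start = min(pos),
                end = max(pos), n_ctss = .N, total_count = sum(count),
                total_tpm = sum(tpm), peak_pos = pos[which.max(count)]),
            by = cluster_id]
  structure(list(clusters = cl, members = mem), class = "tag_clusters")
}

.GRP <- NULL  # data.table special, silence R CMD check

#' Interquantile width of a tag cluster
#'
#' Positions are scanned in order; the cumulative expression fraction is a
#' step function and the quantile position is the first position at which
#' the fraction reaches the quantile. Width = pos(q_high) - pos(q_low).
#' Invariant under uniform rescaling of the weights.
#'
#' @param positions member CTSS positions (sorted or not).
#' @param weights expression weights (TPM or raw tags).
#' @param q_low,q_high cumulative fractions (defaults 0.1, 0.9).
#' @return width in bp.
#' @export
interquantile_width <- function(positions, weights, q_low = 0.1, q_high = 0.9) {
  stopifnot(length(positions) == length(weights), length(positions) > 0L)
  o <- order(positions)
  cum <- cumsum(weights[o]) / sum(weights)
  pl <- positions[o][which(cum >= q_low - 1e-12)[1L]]
  ph <- positions[o][which(cum >= q_high - 1e-12)[1L]]
  ph - pl
}

#' Interquantile widths for every cluster
#' @param tc a [cluster_ctss()] result.
#' @param q_low,q_high cumulative fractions.
#' @return data.table `cluster_id`, `width`.
#' @export
cluster_widths <- function(tc, q_low = 0.1, q_high = 0.9) {
  w <- tc$members[, {
    wt <- if (all(is.na(tpm))) count else tpm
    .(width = interquantile_width(pos, wt, q_low, q_high))
  }, by = cluster_id]
  w[]
}

#' Contrast promoter widths between methylation groups
#'
#' Clusters are assigned to the nearest annotated TSS (by cluster peak
#' position, same strand, within `window` bp); each gene's width is that of
#' its widest assigned cluster. Group medians are contrasted with a
#' Mann-Whitney test.
#'
#' @param tc a [cluster_ctss()] result.
#' @param tss data.table `gene_id`, `contig`, `pos`, `strand` (see
#'   [gene_tss()]).
#' @param meth_groups list with `high` / `low` gene-id vectors.
#' @param window assignment window around the TSS in bp (default 500).
#' @param q_low,q_high width quantiles.
#' @return list with `median_high`, `median_low`, `p`, `widths` (per-gene
#'   data.table), `n_high`, `n_low`.
#' @export
width_contrast <- function(tc, tss, meth_groups, window = 500L,
                           q_low = 0.1, q_high = 0.9) {
  wd <- cluster_widths(tc, q_low, q_high)
  cl <- tc$clusters[wd, on = "cluster_id"]
  tssdt <- as.data.table(tss)
  # nearest same-strand TSS within the window, by cluster peak
  cand <- cl[tssdt, on = .(contig, strand), allow.cartesian = TRUE, nomatch = NULL]
  cand[, dist := abs(peak_pos - pos)]
  cand <- cand[dist <= window]
  if (nrow(cand) == 0L) stopf("no clusters assignable to a TSS")
  setorder(cand, cluster_id, dist, gene_id)
  cand <- cand[!duplicated(cluster_id)]
  per_gene <- cand[, .(width = max(width)), by = gene_id]
  hi <- per_gene[gene_id %in% meth_groups$high, width]
  lo <- per_gene[gene_id %in% meth_groups$low, width]
  if (!length(hi) || !length(lo)) {
    warnf("a methylation group has no assigned clusters; contrast undefined")
    return(list(median_high = if (length(hi)) median(hi) else NA_real_,
                median_low = if (length(lo)) median(lo) else NA_real_,
                p = NA_real_, widths = per_gene[], n_high = length(hi),
                n_low = length(lo)))
  }
  wt <- suppressWarnings(wilcox.test(hi, lo))
  list(median_high = median(hi), median_low = median(lo), p = wt$p.value,
       widths = per_gene[], n_high = length(hi), n_low = length(lo))
}

#' Nucleosome occupancy metagene around TSSs with a resampled loess band
#'
#' Average occupancy in `window`-bp windows spanning `flank` bp either side
#' of each TSS (windows flipped for minus-strand genes), averaged over
#' genes. The confidence band repeats the per-window mean on `resamples`
#' random subsets containing `keep` of the genes, loess-smooths each
#' resampled curve, and keeps the lowest and highest smoothed value per
#' window. Deterministic given `seed`.
#'
#' @param track an `occupancy_track` (`contig`, `start`, `end`, `value`).
#' @param tss data.table `gene_id`, `contig`, `pos`, `strand`.
#' @param window window width in bp (default 200).
#' @param flank half-span in bp (default 2000).
#' @param resamples number of resamples (default 100).
#' @param keep fraction of genes per resample (default 0.9).
#' @param seed optional seed.
#' @param span loess span (default 0.3).
#' @return data.table `window` (1-based index), `center` (bp relative to
#'   TSS), `mean`, `fit` (loess of the full-data means), `lo`, `hi`,
#'   `n_genes`.
#' @export
occupancy_metagene <- function(track, tss, window = 200L, flank = 2000L,
                               resamples = 100L, keep = 0.9, seed = NULL,
                               span = 0.3) {
  if (!is.null(seed)) set.seed(seed)
  tssdt <- as.data.table(tss)
  nw <- as.integer(2L * flank / window)
  offs <- seq.int(-flank, flank - window, by = window)
  wins <- tssdt[rep(seq_len(.N), each = nw)]
  wins[, wi := rep(seq_len(nw), times = nrow(tssdt))]
  wins[, ws := ifelse(strand == "-", pos - (offs[wi] + window - 1L), pos + offs[wi])]
  wins[, we := ws + window]
  tr <- data.table(contig = track$contig, s = track$start, e = track$end - 1L,
                   value = track$value)
  setkey(tr, contig, s, e)
  qq <- data.table(contig = wins$contig, s = wins$ws, e = wins$we - 1L,
                   gene_id = wins$gene_id, wi = wins$wi)
  hits <- foverlaps(qq, tr, type = "any", nomatch = NULL)
  if (nrow(hits) == 0L) stopf("track does not cover any TSS window")
  hits[, w := pmin(e, i.e) - pmax(s, i.s) + 1L]
  gw <- hits[, .(v = sum(value * w) / sum(w)), by = .(gene_id, wi)]
  genes <- unique(gw$gene_id)
  full <- gw[, .(mean = mean(v), n_genes = .N), by = wi]
  setorder(full, wi)
  centers <- offs + window / 2
  lfit <- function(y) predict(loess(y ~ centers, span = span), centers)
  fit <- lfit(full$mean)
  lo <- rep(Inf, nw); hi <- rep(-Inf, nw)
  nkeep <- max(1L, floor(keep * length(genes)))
  for (b in seq_len(resamples)) {
    sub <- sample(genes, nkeep)
    mb <- gw[gene_id %in% sub, .(mean = mean(v)), by = wi]
    setorder(mb, wi)
    yy <- rep(NA_real_, nw); yy[mb$wi] <- mb$mean
    fb <- lfit(yy)
    lo <- pmin(lo, fb, na.rm = TRUE); hi <- pmax(hi, fb, na.rm = TRUE)
  }
  data.table(window = full$wi, center = centers[full$wi], mean = full$mean,
             fit = fit[full$wi], lo = lo[full$wi], hi = hi[full$wi],
             n_genes = full$n_genes)
}
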