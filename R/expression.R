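#' Fragments per kilobase per million mapped reads
#'
#' `fpkm = count / ((length/1000) * (total_mapped/1e6))`, per sample.
#'
#' @param counts numeric matrix of read counts (genes x samples).
#' @param feature_lengths named numeric vector of feature lengths in bp.
#' @param total_mapped mapped reads per sample; defaults to column sums.
#' @return numeric matrix of FPKM values, same shape as `counts`.
#' @export
fpkm <- function(counts, feature_lengths, total_mapped = colSums(counts)) {
  counts <- as.matrix(counts)
  len <- feature_lengths[rownames(counts)]
  if (anyNA(len)) stopf("missing feature length(s)")
  if (any(len <= 0)) stopf("feature lengths must be > 0")
  if (any(total_mapped <= 0)) stopf("total_mapped must be > 0")
  sweep(counts / (len / 1000), 2L, total_mapped / 1e6, `/`)
}

# top/bottom q split that partitions the genes at q = 0.5, stable id order
split_groups <- function(values, q = 0.2) {
  ids <- names(values)
  if (is.null(ids)) stopf("values must be named by gene id")
  n <- length(values)
  if (n < 5L) stopf("need >= 5 genes")
  if (diff(range(values)) == 0) warnf("all values identical; groups set by id order")
  ord <- order(-values, ids)
  h <- ceiling(q * n)
  l <- min(floor(q * n), n - h)
  if (l == 0L) l <- min(1L, n - h)
  list(high = ids[ord[seq_len(h)]], low = ids[rev(ord)[seq_len(l)]])
}

#' Split genes into high / low expression groups
#'
#' Top and bottom `q` fraction by mean expression across samples; ties are
#' broken by stable gene-id order, and `q = 0.5` partitions all genes.
#'
#' @param expr an [expression_table()] or a named per-gene numeric vector.
#' @param q group fraction (default 0.2).
#' @return list with `high` and `low` gene-id vectors.
#' @export
expression_groups <- function(expr, q = 0.2) {
  v <- if (inherits(expr, "expression_table")) rowMeans(expr$abund) else expr
  split_groups(v, q)
}

#' Expression across bins of upstream (promoter) methylation
#'
#' Genes are binned by quantiles of upstream-region methylation (bin 1 =
#' highest methylation); per-bin median expression is reported together with
#' a Kruskal-Wallis test across bins.
#'
#' @param upstream_meth named per-gene upstream methylation fractions.
#' @param expr named per-gene expression (or an [expression_table()], whose
#'   row means are used).
#' @param n_bins number of quantile bins (default 10).
#' @return list with `table` (data.table `bin`, `n`, `median_expr`,
#'   `meth_lo`, `meth_hi`), `statistic`, `p`.
#' @export
upstream_meth_expression <- function(upstream_meth, expr, n_bins = 10L) {
  ev <- if (inherits(expr, "expression_table")) rowMeans(expr$abund) else expr
  genes <- intersect(names(upstream_meth), names(ev))
  if (length(genes) < 2L) stopf("need >= 2 genes with both values")
  mv <- upstream_meth[genes]; ev <- ev[genes]
  br <- unique(quantile(mv, probs = seq(0, 1, length.out = n_bins + 1L)))
  if (length(br) < 3L) stopf("fewer than 2 populated methylation bins")
  binned <- cut(mv, breaks = br, include.lowest = TRUE, labels = FALSE)
  # bin 1 = highest methylation
  bin <- max(binned) - binned + 1L
  if (length(unique(bin)) < 2L) stopf("fewer than 2 populated methylation bins")
  kw <- kruskal.test(ev, factor(bin))
  tab <- data.table(bin = bin, expr = ev, meth = mv)[
    , .(n = .N, median_expr = median(expr), meth_lo = min(meth),
        meth_hi = max(meth)), by = bin]
  setorder(tab, bin)
  list(table = tab[], statistic = unname(kw$statistic), p = kw$p.value)
}

#' Per-gene coefficient of variation of expression across tissues
#'
#' `CV = sd/mean` (sample sd, n-1) across the tissue samples; genes with
#' zero mean are undefined (`NA`).
#'
#' @param expr an [expression_table()] with >= 2 samples.
#' @return named numeric vector of CVs.
#' @export
tissue_cv <- function(expr) {
  stopifnot(inherits(expr, "expression_table"))
  if (ncol(expr$abund) < 2L) stopf("need >= 2 tissue samples")
  mu <- rowMeans(expr$abund)
  s <- apply(expr$abund, 1L, sd)
  ifelse(mu > 0, s / mu, NA_real_)
}

#' Contrast tissue-CV between methylation groups
#'
#' @param cv named per-gene CV vector (see [tissue_cv()]).
#' @param meth_groups list with `high` and `low` gene-id vectors (genes
#'   grouped by methylation).
#' @return list with `median_high`, `median_low`, `p` (Mann-Whitney),
#'   `n_high`, `n_low`.
#' @export
cv_contrast <- function(cv, meth_groups) {
  hi <- cv[intersect(meth_groups$high, names(cv))]
  lo <- cv[intersect(meth_groups$low, names(cv))]
  hi <- hi[!is.na(hi)]; lo <- lo[!is.na(lo)]
  if (!length(hi) || !length(lo)) stopf("empty methylation group after matching")
  wt <- wilcox.test(hi, lo)
  list(median_high = median(hi), median_low = median(lo), p = wt$p.value,
       n_high = length(hi), n_low = length(lo))
}

#' Within-species Z-scores of methylation and expression
#'
#' Standardises methylation and expression within each species
#' (`z = (x - species mean)/species sd`) so genes pool across species on a
#' common scale.
#'
#' @param meth data.table/data.frame with `species`, `gene_id`, `meth`.
#' @param expr data.table/data.frame with `species`, `gene_id`, `expr`.
#' @param conserved optional character vector of gene ids flagged as
#'   belonging to conserved orthogroups.
#' @return data.table `species`, `gene_id`, `z_meth`, `z_expr`, `conserved`.
#' @export
zscore_coupling <- function(meth, expr, conserved = NULL) {
  m <- as.data.table(meth); e <- as.data.table(expr)
  dt <- m[e, on = c("species", "gene_id"), nomatch = NULL]
  if (nrow(dt) == 0L) stopf("no genes shared between meth and expr")
  bad <- dt[, .(n = .N, s1 = sd(meth), s2 = sd(expr)), by = species][
    n < 2L | s1 == 0 | s2 == 0]
  if (nrow(bad)) stopf("species with < 2 genes or zero variance: %s",
                       paste(bad$species, collapse = ", "))
  dt[, `:=`(z_meth = (meth - mean(meth)) / sd(meth),
            z_expr = (expr - mean(expr)) / sd(expr)), by = species]
  dt[, conserved := if (is.null(conserved)) NA else gene_id %in% conserved]
  dt[, .(species, gene_id, z_meth, z_expr, conserved)]
}

#' Housekeeping-gene enrichment in methylation groups
#'
#' 2x2 contingency of housekeeping membership in the top-20% vs bottom-20%
#' methylation groups, with Fisher's exact test (hypergeometric p,
#' conditional-ML odds ratio).
#'
#' @param meth named per-gene methylation vector.
#' @param housekeeping_set character vector of housekeeping gene ids (an
#'   external reference list, never inferred).
#' @param q group fraction (default 0.2).
#' @return list with `table` (2x2 matrix), `odds_ratio`, `p`, `groups`.
#' @export
housekeeping_enrichment <- function(meth, housekeeping_set, q = 0.2) {
  grp <- split_groups(meth, q)
  tab <- rbind(top = c(hk = sum(grp$high %in% housekeeping_set),
                       non = sum(!grp$high %in% housekeeping_set)),
               bottom = c(hk = sum(grp$low %in% housekeeping_set),
                          non = sum(!grp$low %in% housekeeping_set)))
  if (any(rowSums(tab) == 0L)) stopf("empty margin in contingency table")
  ft <- fisher.test(tab)
  list(table = tab, odds_ratio = unname(ft$estimate), p = ft$p.value, groups = grp)
}

#' Orthogroup-level methylation scores across species
#'
#' Methylation is z-scored within each species (across all genes supplied),
#' paralogs are averaged within species per orthogroup, and the orthogroup
#' score is the mean across species. With `conserved_only` (default) only
#' orthogroups present in every species are scored. Scores are ranked
#' descending and top/bottom `q` sets emitted.
#'
#' @param meth data.table/data.frame `species`, `gene_id`, `meth`.
#' @param orthomap data.table/data.frame `orthogroup`, `species`, `gene_id`.
#' @param conserved_only require presence in all species (default TRUE).
#' @param q fraction for the top/bottom sets (default 0.2).
#' @return list with `scores` (data.table `orthogroup`, `score`, `rank`,
#'   `n_species`), `top`, `bottom`.
#' @export
orthogroup_methylation <- function(meth, orthomap, conserved_only = TRUE, q = 0.2) {
  m <- as.data.table(meth); om <- as.data.table(orthomap)
  if (anyDuplicated(om, by = c("species", "gene_id")))
    stopf("a gene belongs to more than one orthogroup")
  m[, z := (meth - mean(meth)) / sd(meth), by = species]
  dt <- om[m, on = c("species", "gene_id"), nomatch = NULL]
  nsp <- length(unique(m$species))
  sc <- dt[, .(z = mean(z)), by = .(orthogroup, species)][
    , .(score = mean(z), n_species = .N), by = orthogroup]
  if (conserved_only) sc <- sc[n_species == nsp]
  if (nrow(sc) == 0L) stopf("no conserved orthogroups with methylation data")
  setorder(sc, -score, orthogroup)
  sc[, rank := seq_len(.N)]
  v <- setNames(sc$score, sc$orthogroup)
  grp <- if (nrow(sc) >= 5L) split_groups(v, q) else list(high = character(), low = character())
  list(scores = sc[], top = grp$high, bottom = grp$low)
}

#' Methylation of single-exon vs multi-exon genes
#'
#' Splits genes by exon count (1 vs >= 2) and contrasts their gene-body
#' methylation with a Mann-Whitney test.
#'
#' @param gene_meth named per-gene methylation vector.
#' @param annotation a [genome_annotation()] with exons.
#' @return list with `mean_single`, `mean_multi`, `n_single`, `n_multi`, `p`
#'   (`NA` with a warning when a group is empty).
#' @export
exon_count_contrast <- function(gene_meth, annotation) {
  nex <- features_of(annotation, "exon")[!is.na(parent), .N, by = parent]
  single <- gene_meth[intersect(names(gene_meth), nex[N == 1L, parent])]
  multi <- gene_meth[intersect(names(gene_meth), nex[N >= 2L, parent])]
  single <- single[!is.na(single)]; multi <- multi[!is.na(multi)]
  if (!length(single) || !length(multi)) {
    warnf("a gene group is empty; contrast undefined")
    return(list(mean_single = if (length(single)) mean(single) else NA_real_,
                mean_multi = if (length(multi)) mean(multi) else NA_real_,
                n_single = length(single), n_multi = length(multi), p = NA_real_))
  }
  wt <- wilcox.test(single, multi)
  list(mean_single = mean(single), mean_multi = mean(multi),
       n_single = length(single), n_multi = length(multi), p = wt$p.value)
}
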