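#' Mean methylation per feature
#'
#' Assigns coverage-filtered CpG sites to features by position and averages
#' the pooled-strand site fractions. Features with fewer than `min_cpgs`
#' covered sites get `NA` (they are excluded from class summaries).
#'
#' @param features a [genome_annotation()] or a features data.table.
#' @param sites a coverage-filtered [site_table()].
#' @param min_cpgs minimum covered CpGs per feature (default 3).
#' @return data.table `feature_id`, `class`, `contig`, `parent`, `n_cpgs`,
#'   `mean_meth` (`NA` when `n_cpgs < min_cpgs`).
#' @export
feature_mean_methylation <- function(features, sites, min_cpgs = 3L) {
  ft <- if (inherits(features, "genome_annotation")) features$features else
    as.data.table(features)
  out <- ft[, .(feature_id, class, contig, start, end, parent)]
  if (nrow(out) == 0L)
    return(out[, .(feature_id, class, contig, parent,
                   n_cpgs = integer(0L), mean_meth = numeric(0L))])
  ss <- data.table(contig = sites$contig, s = sites$pos, e = sites$pos, m = sites$m)
  ff <- data.table(contig = out$contig, s = out$start, e = out$end - 1L,
                   idx = seq_len(nrow(out)))
  setkey(ff, contig, s, e)
  hits <- foverlaps(ss, ff, type = "within", nomatch = NULL)
  agg <- hits[, .(n_cpgs = .N, mean_meth = mean(m)), by = idx]
  out[, `:=`(n_cpgs = 0L, mean_meth = NA_real_)]
  out[agg$idx, `:=`(n_cpgs = agg$n_cpgs, mean_meth = agg$mean_meth)]
  out[n_cpgs < min_cpgs, mean_meth := NA_real_]
  out[, .(feature_id, class, contig, parent, n_cpgs, mean_meth)]
}

#' Per-class methylation summary with bootstrap confidence intervals
#'
#' Point estimate is the mean over defined features of a class; the CI is the
#' 2.5/97.5 percentile of `n_boot` feature-resampled means (features drawn
#' with replacement). The genome background is the plain mean over background
#' CpG site fractions, with no feature resampling.
#'
#' @param feature_meths output of [feature_mean_methylation()].
#' @param background_sites optional [site_table()] restricted to background
#'   regions (see [background_mask()]).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed optional seed for the bootstrap.
#' @return data.table `class`, `n`, `mean`, `ci_lo`, `ci_hi`.
#' @export
class_summary <- function(feature_meths, background_sites = NULL,
                          n_boot = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  def <- feature_meths[!is.na(mean_meth)]
  if (nrow(def) == 0L && is.null(background_sites)) stopf("no defined features")
  out <- def[, {
    v <- mean_meth
    bm <- vapply(seq_len(n_boot),
                 function(i) mean(v[sample.int(length(v), replace = TRUE)]),
                 numeric(1L))
    .(n = .N, mean = mean(v),
      ci_lo = unname(quantile(bm, 0.025)), ci_hi = unname(quantile(bm, 0.975)))
  }, by = class]
  if (!is.null(background_sites) && nrow(background_sites))
    out <- rbind(out, data.table(class = "background", n = nrow(background_sites),
                                 mean = mean(background_sites$m),
                                 ci_lo = NA_real_, ci_hi = NA_real_))
  out[]
}

#' Cluster features into highly- and lowly-methylated groups
#'
#' Two-component univariate clustering on logit-transformed methylation
#' values (clamped to \[1e-3, 1 - 1e-3\]). Deterministic: k-means is
#' initialised at the 10th/90th percentiles of the transformed values. The
#' component with the larger centre is "high". A two-component Gaussian
#' mixture (EM) is available via `method = "gmm"`.
#'
#' @param values numeric methylation fractions (NAs dropped).
#' @param method `"kmeans"` (default) or `"gmm"`.
#' @return list with `labels` (factor `high`/`low` aligned to the non-NA
#'   input values), `proportion_high`, `centers` (original scale), `method`.
#' @export
cluster_high_low <- function(values, method = c("kmeans", "gmm")) {
  method <- match.arg(method)
  v <- values[!is.na(values)]
  if (length(v) < 2L) stopf("need >= 2 defined values")
  x <- logit(clamp(v, 1e-3, 1 - 1e-3))
  init <- unname(quantile(x, c(0.1, 0.9)))
  if (diff(range(x)) < 1e-12 || diff(init) < 1e-12) {
    warnf("values form a single cluster; proportion_high set to 0")
    return(list(labels = factor(rep("low", length(v)), levels = c("low", "high")),
                proportion_high = 0, centers = rep(mean(v), 2L), method = method))
  }
  if (method == "kmeans") {
    km <- kmeans(x, centers = matrix(init, ncol = 1L))
    hi <- which.max(km$centers)
    lab <- ifelse(km$cluster == hi, "high", "low")
    centers <- 1 / (1 + exp(-sort(km$centers[, 1L])))
  } else {
    fit <- gmm1d_em(x, init)
    lab <- ifelse(fit$post_high > 0.5, "high", "low")
    centers <- 1 / (1 + exp(-sort(fit$mu)))
  }
  list(labels = factor(lab, levels = c("low", "high")),
       proportion_high = mean(lab == "high"), centers = centers, method = method)
}

# 1-D two-component Gaussian mixture via EM, deterministic init
gmm1d_em <- function(x, init, max_iter = 300L, tol = 1e-8) {
  mu <- init; s <- rep(max(sd(x), 1e-3), 2L); pi1 <- 0.5
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- pi1 * stats::dnorm(x, mu[1L], s[1L])
    d2 <- (1 - pi1) * stats::dnorm(x, mu[2L], s[2L])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g2 <- d2 / tot
    pi1 <- mean(1 - g2)
    mu[1L] <- sum((1 - g2) * x) / max(sum(1 - g2), 1e-12)
    mu[2L] <- sum(g2 * x) / max(sum(g2), 1e-12)
    s[1L] <- sqrt(sum((1 - g2) * (x - mu[1L])^2) / max(sum(1 - g2), 1e-12))
    s[2L] <- sqrt(sum(g2 * (x - mu[2L])^2) / max(sum(g2), 1e-12))
    s <- pmax(s, 1e-4)
    ll <- sum(log(tot))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  if (mu[2L] >= mu[1L]) list(mu = mu, post_high = g2)
  else list(mu = rev(mu), post_high = 1 - g2)
}

#' Metagene methylation profile
#'
#' Each feature body is scaled to `body_bins` bins (a site at offset `o` in a
#' feature of length `len` falls in bin `floor(body_bins * o / len)`; minus
#' strand features are read 5' to 3'). Flanks of `flank_bp` are split into
#' `flank_bins` fixed-width bins and clipped at contig ends. Sites are pooled
#' across features per bin.
#'
#' @param features features data.table (one class) or [genome_annotation()].
#' @param sites a [site_table()].
#' @param body_bins number of body bins (default 20).
#' @param flank_bp flank width in bp (default 1000).
#' @param flank_bins number of bins per flank (default 20).
#' @return a `metagene_profile` data.table: `bin` (0-based overall index),
#'   `zone` (`upstream`/`body`/`downstream`), `rel` (bin midpoint, flanks in
#'   bp, body in fraction), `mean_meth`, `n_sites`.
#' @export
metagene <- function(features, sites, body_bins = 20L, flank_bp = 1000L,
                     flank_bins = 20L) {
  ft <- if (inherits(features, "genome_annotation")) features$features else
    as.data.table(features)
  fb_w <- flank_bp / flank_bins
  nb <- flank_bins + body_bins + flank_bins
  ss <- data.table(contig = sites$contig, s = sites$pos, e = sites$pos, m = sites$m)
  ff <- data.table(contig = ft$contig, s = ft$start - flank_bp,
                   e = ft$end + flank_bp - 1L,
                   fstart = ft$start, fend = ft$end, strand = ft$strand,
                   idx = seq_len(nrow(ft)))
  setkey(ff, contig, s, e)
  hits <- foverlaps(ss, ff, type = "within", nomatch = NULL)
  if (nrow(hits)) {
    hits[, len := fend - fstart]
    hits[, off := ifelse(strand == "-", fend - 1L - i.s, i.s - fstart)]
    hits[, bin := ifelse(off < 0, flank_bins + floor(off / fb_w),
                  ifelse(off < len, flank_bins + floor(body_bins * off / len),
                         flank_bins + body_bins + floor((off - len) / fb_w)))]
    hits <- hits[bin >= 0L & bin < nb]
    agg <- hits[, .(mean_meth = mean(m), n_sites = .N), by = bin]
  } else {
    agg <- data.table(bin = integer(0L), mean_meth = numeric(0L), n_sites = integer(0L))
  }
  prof <- data.table(bin = seq_len(nb) - 1L)
  prof[, zone := ifelse(bin < flank_bins, "upstream",
                 ifelse(bin < flank_bins + body_bins, "body", "downstream"))]
  prof[, rel := ifelse(zone == "upstream", (bin - flank_bins + 0.5) * fb_w,
               ifelse(zone == "body", (bin - flank_bins + 0.5) / body_bins,
                      (bin - flank_bins - body_bins + 0.5) * fb_w))]
  prof <- agg[prof, on = "bin"]
  prof[is.na(n_sites), n_sites := 0L]
  setcolorder(prof, c("bin", "zone", "rel", "mean_meth", "n_sites"))
  setattr(prof, "class", c("metagene_profile", class(prof)))
  prof[]
}

setcolorder <- data.table::setcolorder

#' Mean methylation by exon rank
#'
#' Exons are ranked 1..k from the 5' end in transcript orientation; ranks at
#' or above `max_rank` are pooled. Site fractions are pooled per rank.
#'
#' @param annotation a [genome_annotation()] with exons.
#' @param sites a [site_table()].
#' @param max_rank pooling rank (default 6).
#' @return data.table `rank`, `mean_meth`, `n_sites`, `n_exons`.
#' @export
exon_rank_profile <- function(annotation, sites, max_rank = 6L) {
  ex <- features_of(annotation, "exon")
  if (nrow(ex) == 0L) stopf("no exons in annotation")
  ex <- copy(ex)
  setorder(ex, parent, start)
  ex[, rank := if (strand[1L] == "-") rev(seq_len(.N)) else seq_len(.N), by = parent]
  ex[, rank := pmin(rank, max_rank)]
  ss <- data.table(contig = sites$contig, s = sites$pos, e = sites$pos, m = sites$m)
  ff <- data.table(contig = ex$contig, s = ex$start, e = ex$end - 1L, rank = ex$rank)
  setkey(ff, contig, s, e)
  hits <- foverlaps(ss, ff, type = "within", nomatch = NULL)
  agg <- hits[, .(mean_meth = mean(m), n_sites = .N), by = rank]
  nex <- ex[, .(n_exons = .N), by = rank]
  out <- agg[nex, on = "rank"]
  setorder(out, rank)
  out[]
}

#' Paired exon vs intron methylation test per gene
#'
#' For every gene with at least one defined exon mean and one defined intron
#' mean, the per-gene difference (mean over exons minus mean over introns)
#' enters a paired t-test.
#'
#' @param feature_meths output of [feature_mean_methylation()] containing
#'   exon and intron rows.
#' @return list with `diff` (mean exon - intron), `t`, `df`, `p`, `n` and the
#'   per-gene table.
#' @export
exon_intron_paired_test <- function(feature_meths) {
  per <- feature_meths[class %in% c("exon", "intron") & !is.na(mean_meth) &
                         !is.na(parent),
                       .(v = mean(mean_meth)), by = .(parent, class)]
  wide <- data.table::dcast(per, parent ~ class, value.var = "v")
  if (!all(c("exon", "intron") %in% names(wide)))
    stopf("need genes with both exon and intron means")
  wide <- wide[!is.na(exon) & !is.na(intron)]
  if (nrow(wide) < 2L) stopf("fewer than 2 genes with paired exon/intron means")
  d <- wide$exon - wide$intron
  if (sd(d) == 0) {
    # degenerate paired test: all differences identical
    return(list(diff = mean(d), t = if (mean(d) == 0) 0 else Inf,
                df = nrow(wide) - 1L, p = if (mean(d) == 0) 1 else 0,
                n = nrow(wide), genes = wide))
  }
  tt <- t.test(wide$exon, wide$intron, paired = TRUE)
  list(diff = unname(tt$estimate), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value, n = nrow(wide), genes = wide)
}
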