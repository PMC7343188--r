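#' Per-CpG-dyad site table
#'
#' A `site_table` stores one record per CpG dyad, keyed by the 0-based
#' position of the + strand cytosine, with methylated/total read counts per
#' strand. The derived per-site fraction `m` pools both strands:
#' `m = (meth_plus + meth_minus) / (total_plus + total_minus)`.
#'
#' @param x data.frame with columns `contig`, `pos`, `meth_plus`,
#'   `total_plus`, `meth_minus`, `total_minus`.
#' @return a `site_table` (a keyed `data.table` with derived columns
#'   `total`, `meth`, `m`).
#' @export
site_table <- function(x) {
  st <- as.data.table(x)
  need <- c("contig", "pos", "meth_plus", "total_plus", "meth_minus", "total_minus")
  miss <- setdiff(need, names(st))
  if (length(miss)) stopf("site table missing columns: %s", paste(miss, collapse = ", "))
  st <- st[, need, with = FALSE]
  if (nrow(st)) {
    if (any(st$meth_plus > st$total_plus) || any(st$meth_minus > st$total_minus))
      stopf("methylated count exceeds total count")
    if (any(st$meth_plus < 0L) || any(st$meth_minus < 0L))
      stopf("negative counts")
  }
  setorder(st, contig, pos)
  if (nrow(st) && anyDuplicated(st, by = c("contig", "pos")))
    stopf("duplicate dyad positions")
  st[, total := total_plus + total_minus]
  st[, meth := meth_plus + meth_minus]
  st[, m := ifelse(total > 0L, meth / total, NA_real_)]
  setattr(st, "class", c("site_table", class(st)))
  st
}

setattr <- data.table::setattr

#' Write a site table as a Bismark-style cytosine report
#'
#' Two rows per dyad: the + strand cytosine at 1-based position `pos + 1` and
#' the - strand cytosine at `pos + 2`, with columns chrom, position, strand,
#' count_methylated, count_unmethylated, context, trinucleotide.
#'
#' @param sites a [site_table()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(sites, path) {
  plus <- data.table(chrom = sites$contig, position = sites$pos + 1L,
                     strand = "+", count_meth = sites$meth_plus,
                     count_unmeth = sites$total_plus - sites$meth_plus)
  minus <- data.table(chrom = sites$contig, position = sites$pos + 2L,
                      strand = "-", count_meth = sites$meth_minus,
                      count_unmeth = sites$total_minus - sites$meth_minus)
  out <- rbind(plus, minus)
  setorder(out, chrom, position)
  out[, `:=`(context = "CpG", tricontext = "CGN")]
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read per-cytosine methylation calls and merge CpG dyads
#'
#' Reads a Bismark cytosine-report-style TSV (chrom, 1-based position,
#' strand, count_methylated, count_unmethylated, context and optionally a
#' trinucleotide column)
#' and merges the two strand rows of each dyad (+ at p, - at p+1) into one
#' record keyed at the + strand cytosine. A dyad observed on one strand only
#' keeps zero counts on the missing strand. Output is sorted.
#'
#' @param path TSV path (may be headerless).
#' @param dialect `"cytosine_report"` (per-cytosine rows, merged here) or
#'   `"methylextract_like"` (already dyad-level: contig, 1-based + strand
#'   position, meth_plus, total_plus, meth_minus, total_minus).
#' @return a [site_table()].
#' @export
read_site_table <- function(path, dialect = c("cytosine_report", "methylextract_like")) {
  dialect <- match.arg(dialect)
  raw <- if (file.size(path) > 0L) fread(path, header = FALSE, sep = "\t") else
    data.table()
  if (nrow(raw) == 0L)
    return(site_table(data.table(contig = character(), pos = integer(),
                                 meth_plus = integer(), total_plus = integer(),
                                 meth_minus = integer(), total_minus = integer())))
  if (dialect == "methylextract_like") {
    setnames(raw, seq_len(6L),
             c("contig", "pos1", "meth_plus", "total_plus", "meth_minus", "total_minus"))
    raw[, pos := as.integer(pos1) - 1L]
    return(site_table(raw[, .(contig, pos, meth_plus, total_plus,
                              meth_minus, total_minus)]))
  }
  setnames(raw, seq_len(5L), c("contig", "pos1", "strand", "meth", "unmeth"))
  if (ncol(raw) >= 6L) {
    ctx <- unique(as.character(raw[[6L]]))
    if (!all(ctx %in% c("CpG", "CG")))
      warnf("inconsistent context labels: %s", paste(setdiff(ctx, c("CpG", "CG")), collapse = ", "))
  }
  if (!all(raw$strand %in% c("+", "-"))) stopf("strand column must be + or -")
  raw[, dyad := ifelse(strand == "+", pos1 - 1L, pos1 - 2L)]  # 0-based + strand C
  merged <- raw[, .(
    meth_plus = sum(meth[strand == "+"]), total_plus = sum((meth + unmeth)[strand == "+"]),
    meth_minus = sum(meth[strand == "-"]), total_minus = sum((meth + unmeth)[strand == "-"])
  ), by = .(contig, pos = dyad)]
  site_table(merged)
}

setnames <- data.table::setnames

#' Coverage-filter CpG sites
#'
#' Keeps sites covered by at least `min_per_strand` reads on each strand
#' (the per-strand rule; a site rich on one strand but thin on the other is
#' excluded).
#'
#' @param sites a [site_table()].
#' @param min_per_strand minimum reads per strand (default 10).
#' @return filtered [site_table()]. Idempotent.
#' @export
filter_sites <- function(sites, min_per_strand = 10L) {
  stopifnot(min_per_strand >= 0L)
  site_table(sites[total_plus >= min_per_strand & total_minus >= min_per_strand,
                   .(contig, pos, meth_plus, total_plus, meth_minus, total_minus)])
}

#' Estimate bisulfite non-conversion from an unmethylated spike-in
#'
#' Pools methylated/total counts over all spike-in sites; the rate is the
#' error floor of methylation calls. The 95% CI is Clopper-Pearson.
#'
#' @param spike a [site_table()] of spike-in sites.
#' @param conf confidence level (default 0.95).
#' @return list with `rate`, `ci` (length 2), `meth`, `total`.
#' @export
estimate_nonconversion <- function(spike, conf = 0.95) {
  if (nrow(spike) == 0L) stopf("empty spike-in table")
  x <- sum(spike$meth); n <- sum(spike$total)
  if (n == 0L) stopf("spike-in has zero total reads")
  a <- (1 - conf) / 2
  lo <- if (x == 0L) 0 else qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else qbeta(1 - a, x + 1, n - x)
  list(rate = x / n, ci = c(lo, hi), meth = x, total = n)
}

#' Genome-wide methylation level
#'
#' Two callers for the percentage of CpG sites methylated genome-wide:
#' `mean_fraction` reports `100 * mean(m_i)`; `binomial_vs_spike` tests each
#' site one-sided against the non-conversion rate
#' (Binomial(total, rate), Benjamini-Hochberg at `q`) and reports
#' `100 * called / tested`.
#'
#' @param sites a coverage-filtered [site_table()].
#' @param caller `"binomial_vs_spike"` (default) or `"mean_fraction"`.
#' @param nonconversion non-conversion rate (required for the binomial caller).
#' @param q BH false-discovery threshold (default 0.05).
#' @return list with `percent`, `caller`, `n_sites`, and for the binomial
#'   caller a logical `called` vector aligned with `sites`.
#' @export
genomewide_methylation <- function(sites,
                                   caller = c("binomial_vs_spike", "mean_fraction"),
                                   nonconversion = NULL, q = 0.05) {
  caller <- match.arg(caller)
  if (nrow(sites) == 0L) stopf("empty site table")
  if (caller == "mean_fraction")
    return(list(percent = 100 * mean(sites$m), caller = caller, n_sites = nrow(sites)))
  if (is.null(nonconversion)) stopf("binomial_vs_spike requires a nonconversion rate")
  # one-sided P(X >= meth) under Binomial(total, rate)
  pv <- pbinom(sites$meth - 1L, sites$total, nonconversion, lower.tail = FALSE)
  called <- p.adjust(pv, "BH") <= q
  list(percent = 100 * mean(called), caller = caller, n_sites = nrow(sites),
       called = called, p = pv)
}

#' Compare sample methylation with the unmethylated spike-in
#'
#' Two-proportion z-test on pooled methylated/total counts of the sample
#' against the spike-in (two-sided). A non-significant result indicates
#' methylation indistinguishable from bisulfite non-conversion error.
#'
#' @param sites sample [site_table()].
#' @param spike spike-in [site_table()].
#' @return list with `diff` (sample minus spike proportion), `z`, `p`.
#' @export
compare_to_spikein <- function(sites, spike) {
  if (nrow(sites) == 0L || nrow(spike) == 0L) stopf("empty table")
  x1 <- sum(sites$meth); n1 <- sum(sites$total)
  x2 <- sum(spike$meth); n2 <- sum(spike$total)
  if (n1 == 0L || n2 == 0L) stopf("zero total reads")
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(diff = p1 - p2, z = z, p = 2 * pnorm(-abs(z)))
}

#' Write per-site methylation fractions as bedGraph
#' @param sites a [site_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites_bedgraph <- function(sites, path) {
  out <- data.table(chrom = sites$contig, start = sites$pos,
                    end = sites$pos + 2L, value = round(sites$m, 6L))
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
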