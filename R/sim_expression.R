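#' Expression abundance container
#'
#' Genes x samples abundance matrix (FPKM-scale) with a tissue label per
#' sample.
#'
#' @param abund numeric matrix, rownames = gene ids, colnames = sample ids.
#' @param tissue character vector of tissue labels, one per column.
#' @return an `expression_table`.
#' @export
expression_table <- function(abund, tissue) {
  stopifnot(is.matrix(abund), length(tissue) == ncol(abund))
  if (any(abund < 0)) stopf("abundances must be >= 0")
  if (is.null(rownames(abund)) || is.null(colnames(abund)))
    stopf("abundance matrix needs row and column names")
  structure(list(abund = abund, tissue = setNames(as.character(tissue), colnames(abund))),
            class = "expression_table")
}

#' Simulate tissue-structured gene expression
#'
#' Per-gene baseline abundance is log-normal; per-tissue values multiply the
#' baseline by a log-normal tissue effect whose spread sets the cross-tissue
#' coefficient of variation. With `config$expression_coupling`, methylated
#' genes behave like housekeeping genes: their baselines avoid the low tail
#' (they are drawn above the 30th percentile of the baseline distribution)
#' and their tissue effect uses `cv_low`; other genes use `cv_high`. With
#' `config$promoter_silencing`, promoter-silenced genes have their baseline
#' multiplied by `silencing_factor`.
#'
#' @param genome a [simulate_genome()] result.
#' @param config the same [sim_config()].
#' @param methylome optional [simulate_methylome()] result supplying the
#'   methylated / silenced gene flags; without it flags are drawn afresh.
#' @return an [expression_table()] with attribute `genes` (data.table
#'   `gene_id`, `methylated`, `housekeeping_like`, `silenced`, `base`).
#' @export
simulate_expression <- function(genome, config = genome$config, methylome = NULL) {
  stopifnot(inherits(genome, "sim_genome"))
  set.seed(derive_seed(config$seed, 3L))
  g <- features_of(genome$annotation, "gene")
  if (nrow(g) == 0L) stopf("genome has no genes")
  genes <- sim_gene_flags(g$feature_id, config, methylome)
  mu <- log(30); sdl <- 1.2
  n <- nrow(genes)
  u <- runif(n)
  # methylated/housekeeping-like genes never fall in the bottom 30%
  u[genes$housekeeping_like] <- 0.3 + 0.7 * u[genes$housekeeping_like]
  base <- exp(mu + sdl * qnorm(u))
  base[genes$silenced] <- base[genes$silenced] * config$silencing_factor
  genes[, base := base]
  tiss <- sprintf("tissue%d", seq_len(config$n_tissues))
  s <- ifelse(genes$housekeeping_like, config$cv_low, config$cv_high)
  ab <- vapply(seq_len(config$n_tissues),
               function(t) base * exp(rnorm(n, 0, s)), numeric(n))
  dimnames(ab) <- list(genes$gene_id, tiss)
  out <- expression_table(ab, tiss)
  attr(out, "genes") <- genes
  out
}

sim_gene_flags <- function(gene_ids, config, methylome = NULL) {
  if (!is.null(methylome)) {
    genes <- copy(methylome$genes)[match(gene_ids, gene_id)]
  } else {
    genes <- data.table(gene_id = gene_ids,
                        methylated = runif(length(gene_ids)) < config$meth_gene_fraction,
                        silenced = FALSE, upstream_level = NA_real_)
    genes[, silenced := config$promoter_silencing & runif(.N) < config$silenced_fraction]
  }
  genes[, housekeeping_like := if (config$expression_coupling) methylated
        else runif(.N) < 0.3]
  genes
}

#' Simulate CAGE CTSS tags around gene TSSs
#'
#' Housekeeping-like genes get broad tag clusters (tags spread over
#' `ctss_broad_span` bp downstream of the TSS, near-uniform weights); other
#' genes get narrow clusters (`ctss_narrow_span` bp, steeply decaying
#' weights). Tag totals per gene are Poisson(`ctss_tags_per_gene`).
#'
#' @inheritParams simulate_expression
#' @return a `ctss_table` data.table (`contig`, `pos`, `strand`, `count`)
#'   with attribute `genes`.
#' @export
simulate_ctss <- function(genome, config = genome$config, methylome = NULL) {
  stopifnot(inherits(genome, "sim_genome"))
  set.seed(derive_seed(config$seed, 4L))
  tss <- gene_tss(genome$annotation)
  if (nrow(tss) == 0L) stopf("genome has no genes with TSS")
  genes <- sim_gene_flags(tss$gene_id, config, methylome)
  rows <- vector("list", nrow(tss))
  for (i in seq_len(nrow(tss))) {
    broad <- genes$housekeeping_like[i]
    span <- if (broad) config$ctss_broad_span else config$ctss_narrow_span
    span <- max(1L, as.integer(span))
    ntags <- rpois(1L, config$ctss_tags_per_gene)
    if (ntags == 0L) next
    w <- if (broad) runif(span, 0.5, 1) else 0.5^(seq_len(span) - 1L)
    cnt <- as.vector(rmultinom(1L, ntags, w))
    dirn <- if (tss$strand[i] == "-") -1L else 1L
    pos <- tss$pos[i] + dirn * (seq_len(span) - 1L)
    ok <- cnt > 0L & pos >= 0L
    rows[[i]] <- data.table(contig = tss$contig[i], pos = pos[ok],
                            strand = tss$strand[i], count = cnt[ok])
  }
  out <- rbindlist(rows)
  setorder(out, contig, strand, pos)
  setattr(out, "class", c("ctss_table", class(out)))
  attr(out, "genes") <- genes
  out
}

#' Simulate a nucleosome occupancy track
#'
#' A binned track (bin width `occupancy_bin`) across every contig. Genes of
#' the broad-TSS (housekeeping-like) class get a phased cosine of period
#' `nucleosome_repeat_length` over 2 kb downstream of the TSS, peaking at the
#' +1 nucleosome; elsewhere the track is flat noise around 1.
#'
#' @inheritParams simulate_expression
#' @return an `occupancy_track` data.table (`contig`, `start`, `end`,
#'   `value`), 0-based half-open bins.
#' @export
simulate_occupancy <- function(genome, config = genome$config, methylome = NULL) {
  stopifnot(inherits(genome, "sim_genome"))
  set.seed(derive_seed(config$seed, 5L))
  bw <- as.integer(config$occupancy_bin)
  L <- config$nucleosome_repeat_length
  tss <- gene_tss(genome$annotation)
  genes <- if (nrow(tss)) sim_gene_flags(tss$gene_id, config, methylome) else NULL
  tracks <- lapply(names(genome$annotation$contigs), function(ctg) {
    clen <- genome$annotation$contigs[[ctg]]
    starts <- seq.int(0L, clen - 1L, by = bw)
    val <- 1 + rnorm(length(starts), 0, config$occupancy_noise_sd)
    if (!is.null(genes)) {
      here <- which(tss$contig == ctg & genes$housekeeping_like)
      for (i in here) {
        mid <- starts + bw / 2
        d <- if (tss$strand[i] == "-") tss$pos[i] - mid else mid - tss$pos[i]
        inwin <- d >= 0 & d < 2000
        # phased array with net occupancy gain, so the signal survives
        # window-level averaging as it does in MNase profiles
        val[inwin] <- val[inwin] + config$occupancy_amplitude *
          (0.4 + cos(2 * pi * (d[inwin] - L / 2) / L))
      }
    }
    data.table(contig = ctg, start = starts,
               end = pmin(starts + bw, as.integer(clen)), value = val)
  })
  out <- rbindlist(tracks)
  setattr(out, "class", c("occupancy_track", class(out)))
  out
}

#' Write an expression table as TSV
#' @param expr an [expression_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  dt <- data.table(gene_id = rownames(expr$abund))
  for (j in colnames(expr$abund)) dt[[j]] <- expr$abund[, j]
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read an expression TSV (gene_id column + one column per sample)
#' @param path TSV path.
#' @param tissue tissue label per sample column; defaults to column names.
#' @return an [expression_table()].
#' @export
read_expression_tsv <- function(path, tissue = NULL) {
  dt <- fread(path)
  ab <- as.matrix(dt[, -1L])
  rownames(ab) <- dt[[1L]]
  expression_table(ab, tissue %||% colnames(ab))
}

#' Write CTSS tags as 6-column BED (score = tag count)
#' @param ctss a `ctss_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ctss_bed <- function(ctss, path) {
  out <- data.table(chrom = ctss$contig, start = ctss$pos, end = ctss$pos + 1L,
                    name = sprintf("ctss_%d", seq_len(nrow(ctss))),
                    score = ctss$count, strand = ctss$strand)
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read CTSS tags from 6-column BED (score = tag count)
#' @param path BED path.
#' @return a `ctss_table`.
#' @export
read_ctss_bed <- function(path) {
  raw <- fread(path, header = FALSE)
  out <- data.table(contig = as.character(raw[[1L]]), pos = as.integer(raw[[2L]]),
                    strand = as.character(raw[[6L]]), count = as.numeric(raw[[5L]]))
  setorder(out, contig, strand, pos)
  setattr(out, "class", c("ctss_table", class(out)))
  out
}

#' Write / read an occupancy track as bedGraph
#' @param track an `occupancy_track`.
#' @param path file path.
#' @return `path` (writer) or an `occupancy_track` (reader).
#' @export
write_bedgraph_track <- function(track, path) {
  fwrite(track[, .(contig, start, end, value = round(value, 6L))], path,
         sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_bedgraph_track
#' @export
read_bedgraph_track <- function(path) {
  raw <- fread(path, header = FALSE)
  out <- data.table(contig = as.character(raw[[1L]]), start = as.integer(raw[[2L]]),
                    end = as.integer(raw[[3L]]), value = as.numeric(raw[[4L]]))
  setattr(out, "class", c("occupancy_track", class(out)))
  out
}
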