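#' Simulate an annotated multi-contig genome with CpG sites
#'
#' Places non-overlapping genes (with exon/intron structure), TEs and
#' optional rRNA/tRNA features on `n_contigs` contigs, then scatters CpG
#' dyads at `cpg_density` sites per bp with a minimum spacing of 2 bp.
#' Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a `sim_genome`: list with `annotation` (a [genome_annotation()]
#'   holding genes, exons, TEs, rRNA, tRNA), `cpg` (data.table `contig`,
#'   `pos`, 0-based dyad positions) and `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 0L))
  n_exons <- if (config$n_genes > 0L)
    sample.int(8L, config$n_genes, replace = TRUE, prob = config$exon_count_probs)
  else integer(0L)
  specs <- list()
  for (i in seq_len(config$n_genes)) {
    ex <- draw_len(config$exon_length, n_exons[i])
    intr <- if (n_exons[i] > 1L) draw_len(config$intron_length, n_exons[i] - 1L) else integer(0L)
    specs[[length(specs) + 1L]] <- list(
      kind = "gene", id = sprintf("gene_%03d", i), exons = ex, introns = intr,
      span = sum(ex) + sum(intr), strand = sample(c("+", "-"), 1L))
  }
  for (i in seq_len(config$n_tes))
    specs[[length(specs) + 1L]] <- list(
      kind = "TE", id = sprintf("te_%03d", i),
      span = draw_len(config$te_length, 1L), strand = sample(c("+", "-"), 1L))
  for (i in seq_len(config$n_rrna))
    specs[[length(specs) + 1L]] <- list(kind = "rRNA", id = sprintf("rrna_%02d", i),
                                        span = 120L, strand = "+")
  for (i in seq_len(config$n_trna))
    specs[[length(specs) + 1L]] <- list(kind = "tRNA", id = sprintf("trna_%02d", i),
                                        span = 80L, strand = "+")
  contig_names <- sprintf("contig_%02d", seq_len(config$n_contigs))
  contig_lengths <- setNames(rep(as.numeric(config$contig_length), config$n_contigs),
                             contig_names)
  # round-robin assignment of shuffled features to contigs, then sequential
  # packing with a minimum gap and random allocation of the slack
  assign_ctg <- rep(seq_len(config$n_contigs), length.out = length(specs))
  if (length(specs)) {
    specs <- specs[sample.int(length(specs))]
    feats <- list()
    for (ci in seq_len(config$n_contigs)) {
      idx <- which(assign_ctg == ci)
      if (!length(idx)) next
      spans <- vapply(specs[idx], function(s) as.numeric(s$span), numeric(1L))
      k <- length(idx)
      slack <- config$contig_length - sum(spans) - (k + 1L) * config$min_feature_gap
      if (slack < 0)
        stopf("infeasible packing: contig %s needs %.0f bp for %d feature(s), has %d",
              contig_names[ci], sum(spans) + (k + 1L) * config$min_feature_gap,
              k, config$contig_length)
      cuts <- sort(runif(k, 0, slack))
      extra <- diff(c(0, cuts))
      pos <- config$min_feature_gap
      for (j in seq_len(k)) {
        s <- specs[[idx[j]]]
        start <- as.integer(round(pos + extra[j]))
        feats[[length(feats) + 1L]] <- place_feature(s, contig_names[ci], start)
        pos <- start + s$span + config$min_feature_gap
      }
    }
    ft <- rbindlist(feats)
  } else {
    ft <- data.table(feature_id = character(), contig = character(),
                     start = integer(), end = integer(), strand = character(),
                     class = character(), parent = character())
  }
  ann <- genome_annotation(ft, contig_lengths)
  # CpG dyads: candidate even positions thinned to the target density
  cpg <- rbindlist(lapply(contig_names, function(ctg) {
    cand <- seq.int(0L, config$contig_length - 2L, by = 2L)
    keep <- runif(length(cand)) < config$cpg_density * 2
    data.table(contig = ctg, pos = cand[keep])
  }))
  structure(list(annotation = ann, cpg = cpg, config = config),
            class = "sim_genome")
}

place_feature <- function(s, contig, start) {
  if (s$kind != "gene") {
    return(data.table(feature_id = s$id, contig = contig, start = start,
                      end = start + as.integer(s$span), strand = s$strand,
                      class = s$kind, parent = NA_character_))
  }
  k <- length(s$exons)
  ex_start <- integer(k); ex_end <- integer(k)
  pos <- start
  for (j in seq_len(k)) {
    ex_start[j] <- pos
    ex_end[j] <- pos + s$exons[j]
    pos <- ex_end[j] + if (j < k) s$introns[j] else 0L
  }
  rbind(
    data.table(feature_id = s$id, contig = contig, start = start,
               end = start + as.integer(s$span), strand = s$strand,
               class = "gene", parent = NA_character_),
    data.table(feature_id = sprintf("%s_exon_%d", s$id, seq_len(k)),
               contig = contig, start = ex_start, end = ex_end,
               strand = s$strand, class = "exon", parent = s$id))
}

#' Transcription start sites of simulated (or annotated) genes
#' @param annotation a [genome_annotation()].
#' @return data.table `gene_id`, `contig`, `pos` (0-based TSS), `strand`.
#' @export
gene_tss <- function(annotation) {
  g <- features_of(annotation, "gene")
  g[, .(gene_id = feature_id, contig,
        pos = ifelse(strand == "-", end - 1L, start), strand)]
}
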