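#' Simulate a true methylome over the CpG sites of a synthetic genome
#'
#' Each CpG dyad gets a latent methylation probability `p` from its feature
#' class. A configured fraction of genes forms the "methylated" class (their
#' exons at `class_means["exon"]`), the rest sit near zero
#' (`class_means["exon_unmeth"]`), reproducing the bimodal gene-body
#' methylation distribution. Inside exons of methylated genes (and TE bodies
#' when `config$phase_te`), a nucleosome-phased cosine is added:
#' `p = clamp(mean + A * cos(2*pi*(x - phi_c)/L), 0, 1)` with per-contig
#' random phase `phi_c`, `L = nucleosome_repeat_length` and
#' `A = periodic_amplitude`. Background and intron sites carry their class
#' mean with no periodic term. Upstream (promoter) levels are drawn per gene;
#' under `promoter_silencing` a `silenced_fraction` of genes gets a highly
#' methylated promoter and is flagged for transcriptional silencing.
#'
#' @param genome a [simulate_genome()] result.
#' @param config the same [sim_config()].
#' @return a `true_methylome`: list with `sites` (data.table `contig`, `pos`,
#'   `p`, `class`, `gene_id`) and `genes` (data.table `gene_id`,
#'   `methylated`, `upstream_level`, `silenced`).
#' @export
simulate_methylome <- function(genome, config = genome$config) {
  stopifnot(inherits(genome, "sim_genome"))
  cm <- config$class_means
  needed <- c("exon", "exon_unmeth", "intron", "upstream", "TE", "background")
  if (!all(needed %in% names(cm)))
    stopf("unknown architecture preset: class_means must define %s",
          paste(needed, collapse = ", "))
  set.seed(derive_seed(config$seed, 1L))
  ann <- derive_upstream(derive_introns(genome$annotation), 1000L)
  sites <- copy(genome$cpg)

  g <- features_of(ann, "gene")
  genes <- data.table(gene_id = g$feature_id)
  genes[, methylated := runif(.N) < config$meth_gene_fraction]
  genes[, silenced := config$promoter_silencing & runif(.N) < config$silenced_fraction]
  genes[, upstream_level := clamp(
    ifelse(silenced, runif(.N, 0.7, 0.9),
           runif(.N, pmax(0, cm[["upstream"]] - 0.05), cm[["upstream"]] + 0.1)),
    0, 1)]

  # site classification, priority exon > rRNA > tRNA > TE > intron > upstream
  sites[, `:=`(class = "background", gene_id = NA_character_)]
  assign_class <- function(cls) {
    fset <- features_of(ann, cls)
    if (!nrow(fset)) return(invisible())
    ss <- data.table(contig = sites$contig, s = sites$pos, e = sites$pos)
    ff <- data.table(contig = fset$contig, s = fset$start, e = fset$end - 1L,
                     gid = if (cls %in% c("exon", "intron", "upstream"))
                       fset$parent else NA_character_)
    setkey(ff, contig, s, e)
    hits <- foverlaps(ss, ff, type = "within", nomatch = NULL, which = TRUE)
    if (!nrow(hits)) return(invisible())
    hits <- hits[!duplicated(xid)]
    sites[hits$xid, `:=`(class = cls, gene_id = ff$gid[hits$yid])]
    invisible()
  }
  for (cls in c("upstream", "intron", "TE", "tRNA", "rRNA", "exon")) assign_class(cls)

  sites[genes, on = .(gene_id), `:=`(g_meth = i.methylated, g_up = i.upstream_level)]
  base <- cm[["background"]]
  sites[, mean_p := base]
  sites[class == "TE", mean_p := cm[["TE"]]]
  sites[class == "rRNA", mean_p := cm[["rRNA"]]]
  sites[class == "tRNA", mean_p := cm[["tRNA"]]]
  sites[class == "exon", mean_p := ifelse(g_meth, cm[["exon"]], cm[["exon_unmeth"]])]
  sites[class == "intron", mean_p := ifelse(g_meth, cm[["intron"]], cm[["exon_unmeth"]])]
  sites[class == "upstream", mean_p := g_up]

  L <- config$nucleosome_repeat_length
  A <- config$periodic_amplitude
  phases <- setNames(runif(length(genome$annotation$contigs), 0, L),
                     names(genome$annotation$contigs))
  sites[, phased := (class == "exon" & g_meth %in% TRUE) |
          (config$phase_te & class == "TE")]
  sites[, p := mean_p]
  if (A > 0)
    sites[phased == TRUE,
          p := clamp(mean_p + A * cos(2 * pi * (pos - phases[contig]) / L), 0, 1)]
  out <- sites[, .(contig, pos, p, class, gene_id)]
  structure(list(sites = out, genes = genes, config = config),
            class = "true_methylome")
}

#' Simulate bisulfite read counts from a true methylome
#'
#' Per strand, total reads are Poisson(`coverage_mean`) and methylated reads
#' Binomial(total, q) with
#' `q = p * (1 - failed_methylated_conversion) + (1 - p) * nonconversion_rate`.
#' An unmethylated spike-in (p = 0) is emitted as a separate table on the
#' reserved contig `"spike"`.
#'
#' @param methylome a [simulate_methylome()] result.
#' @param config the same [sim_config()].
#' @return list with `sample` and `spike`, both [site_table()]s.
#' @export
simulate_bisulfite_counts <- function(methylome, config = methylome$config) {
  stopifnot(inherits(methylome, "true_methylome"))
  if (config$nonconversion_rate < 0 || config$nonconversion_rate >= 1)
    stopf("nonconversion_rate must be in [0, 1)")
  set.seed(derive_seed(config$seed, 2L))
  draw <- function(p) {
    n <- length(p)
    q <- p * (1 - config$failed_methylated_conversion) +
      (1 - p) * config$nonconversion_rate
    tp <- rpois(n, config$coverage_mean)
    tm <- rpois(n, config$coverage_mean)
    data.table(meth_plus = rbinom(n, tp, q), total_plus = tp,
               meth_minus = rbinom(n, tm, q), total_minus = tm)
  }
  s <- methylome$sites
  sample_tab <- site_table(cbind(s[, .(contig, pos)], draw(s$p)))
  nspike <- config$spike_in_sites
  spike_tab <- site_table(cbind(
    data.table(contig = rep("spike", nspike), pos = seq.int(0L, by = 2L, length.out = nspike)),
    draw(rep(0, nspike))))
  list(sample = sample_tab, spike = spike_tab)
}
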