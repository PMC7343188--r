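#' Default end-to-end run configuration
#'
#' A plain-list (JSON-serialisable) configuration for [run_pipeline()]:
#' stage toggles, per-stage parameter blocks mirroring each module's
#' defaults, a global seed propagated to every stochastic stage as
#' `seed + stage offset`, and the output directory. The demo tree is a small
#' time-scaled 8-species phylogeny used by the comparative stage.
#'
#' @param seed global integer seed.
#' @param out_dir output directory.
#' @param preset synthetic architecture preset (see [sim_config()]).
#' @return a nested list, the `RunConfig`.
#' @export
default_run_config <- function(seed = 1L, out_dir = "arthromethyl_run",
                               preset = "strigamia-like") {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = list(simulate = TRUE, annotate = TRUE, sites = TRUE,
                  features = TRUE, periodicity = TRUE, phylo = TRUE,
                  expression = TRUE, tss = TRUE),
    simulate = list(preset = preset, n_contigs = 4L, contig_length = 60000L,
                    n_genes = 48L, n_tes = 32L, coverage_mean = 30,
                    spike_in_sites = 2000L),
    annotate = list(upstream_length = 1000L, upstream_against = "prescreen",
                    background_min_distance = 0L),
    sites = list(min_per_strand = 10L, bh_q = 0.05),
    features = list(min_cpgs = 3L, n_boot = 1000L, body_bins = 20L,
                    flank_bp = 1000L, flank_bins = 20L),
    periodicity = list(d_min = 3L, d_max = 500L, min_pairs = 20L,
                       pad_zeros = 50000L, band = c(140, 200),
                       n_shuffles = 199L),
    phylo = list(
      tree = paste0("((((spA:50,spB:50):100,(spC:80,spD:80):70):150,",
                    "(spE:120,spF:120):180):200,(spG:250,spH:250):250);"),
      root_value = 20, sigma2 = 0.5),
    expression = list(q = 0.2, n_bins = 8L),
    tss = list(max_gap = 20L, q_low = 0.1, q_high = 0.9, window = 200L,
               flank = 2000L, resamples = 50L, keep = 0.9, assign_window = 500L)
  )
}

#' Read a run configuration from JSON
#'
#' Values in the file override the defaults of [default_run_config()];
#' unknown keys are an error. Referenced input paths are checked before any
#' stage runs.
#'
#' @param path JSON file path.
#' @return a validated `RunConfig` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_run_config()
  merge_into <- function(base, over, prefix = "") {
    for (k in names(over)) {
      if (!k %in% names(base))
        stopf("unknown config key: %s%s", prefix, k)
      if (is.list(base[[k]]) && is.list(over[[k]]))
        base[[k]] <- merge_into(base[[k]], over[[k]], paste0(prefix, k, "."))
      else base[[k]] <- over[[k]]
    }
    base
  }
  merge_into(cfg, user)
}

#' Run the full pipeline: simulate, annotate, summarise, detect, reconstruct
#'
#' Executes the enabled stages in dependency order against a synthetic
#' genome, writing standard-format intermediates (GFF3, cytosine report,
#' Newick, TSV/BED/bedGraph) and per-stage summary JSON to
#' `config$out_dir`. Every stage output is a pure function of (inputs,
#' parameters, seed); the returned manifest records parameters and MD5
#' checksums of every file, so identical configs yield identical manifests.
#'
#' @param config a `RunConfig` (see [default_run_config()]).
#' @return the manifest list, invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config = default_run_config()) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0L)
  emit <- function(name) file.path(out, name)
  note <- function(p) { paths[length(paths) + 1L] <<- p; p }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  summaries <- list()
  st <- config$stages

  sim <- stage("simulate", {
    sc <- do.call(sim_config, c(list(architecture = config$simulate$preset,
                                     seed = config$seed),
                                config$simulate[setdiff(names(config$simulate), "preset")]))
    genome <- simulate_genome(sc)
    methylome <- simulate_methylome(genome, sc)
    counts <- simulate_bisulfite_counts(methylome, sc)
    expr <- simulate_expression(genome, sc, methylome)
    ctss <- simulate_ctss(genome, sc, methylome)
    occ <- simulate_occupancy(genome, sc, methylome)
    if (isTRUE(st$simulate)) {
      note(write_annotation(genome$annotation, emit("genome.gff3")))
      note(write_cytosine_report(counts$sample, emit("sites.cov.tsv")))
      note(write_cytosine_report(counts$spike, emit("spike.cov.tsv")))
      note(write_expression_tsv(expr, emit("expression.tsv")))
      note(write_ctss_bed(ctss, emit("ctss.bed")))
      note(write_bedgraph_track(occ, emit("occupancy.bedGraph")))
      fwrite(methylome$genes, emit("truth_genes.tsv"), sep = "\t")
      note(emit("truth_genes.tsv"))
    }
    list(sc = sc, genome = genome, methylome = methylome, counts = counts,
         expr = expr, ctss = ctss, occ = occ)
  })

  ann <- stage("annotate", {
    a <- read_annotation(emit("genome.gff3"), "gff3")
    a <- derive_introns(a)
    a <- derive_upstream(a, config$annotate$upstream_length)
    a <- screen_overlaps(a, config$annotate$upstream_against)
    note(write_annotation(a, emit("annotation.derived.gff3")))
    a
  })
  bg <- background_mask(ann, config$annotate$background_min_distance)

  sites <- stage("sites", {
    raw <- read_site_table(emit("sites.cov.tsv"))
    spike <- read_site_table(emit("spike.cov.tsv"))
    filt <- filter_sites(raw, config$sites$min_per_strand)
    nc <- estimate_nonconversion(filter_sites(spike, config$sites$min_per_strand))
    gw_mean <- genomewide_methylation(filt, "mean_fraction")
    gw_bin <- genomewide_methylation(filt, "binomial_vs_spike",
                                     nonconversion = nc$rate, q = config$sites$bh_q)
    cmp <- compare_to_spikein(filt, spike)
    summaries$sites <- list(
      n_raw = nrow(raw), n_filtered = nrow(filt),
      nonconversion = nc$rate, nonconversion_ci = nc$ci,
      percent_mean_fraction = gw_mean$percent,
      percent_binomial = gw_bin$percent, spike_z = cmp$z, spike_p = cmp$p)
    list(filtered = filt, spike = spike, nonconversion = nc)
  })

  featm <- stage("features", {
    fm <- feature_mean_methylation(ann, sites$filtered, config$features$min_cpgs)
    bgsites <- sites$filtered[overlaps_any(
      data.table(contig = sites$filtered$contig, start = sites$filtered$pos,
                 end = sites$filtered$pos + 2L), bg)]
    cs <- class_summary(fm, bgsites, config$features$n_boot,
                        seed = derive_seed(config$seed, 10L))
    gm <- fm[class == "gene" & !is.na(mean_meth)]
    cl <- cluster_high_low(setNames(gm$mean_meth, gm$feature_id))
    mg <- metagene(features_of(ann, "TE"), sites$filtered,
                   config$features$body_bins, config$features$flank_bp,
                   config$features$flank_bins)
    fwrite(fm, emit("feature_methylation.tsv"), sep = "\t"); note(emit("feature_methylation.tsv"))
    fwrite(cs, emit("class_summary.tsv"), sep = "\t"); note(emit("class_summary.tsv"))
    fwrite(mg, emit("metagene_te.tsv"), sep = "\t"); note(emit("metagene_te.tsv"))
    summaries$features <- list(proportion_high_genes = cl$proportion_high,
                                classes = cs$class, class_means = cs$mean)
    list(fm = fm, cluster = cl, metagene = mg)
  })

  stage("periodicity", {
    prof <- correlation_by_distance(sites$filtered, features_of(ann, "exon"),
                                    c(config$periodicity$d_min, config$periodicity$d_max),
                                    config$periodicity$min_pairs)
    res <- detrend_profile(prof)
    spec <- meth_spectrum(res, config$periodicity$pad_zeros)
    bs <- band_score(spec, config$periodicity$band)
    dp <- dominant_period(spec, config$periodicity$band)
    pn <- periodicity_null(prof, config$periodicity$n_shuffles,
                           seed = derive_seed(config$seed, 11L),
                           period_band = config$periodicity$band,
                           pad_zeros = config$periodicity$pad_zeros)
    fwrite(prof, emit("correlation_profile.tsv"), sep = "\t"); note(emit("correlation_profile.tsv"))
    summaries$periodicity <- list(band_intensity = bs, dominant_period = dp,
                                   p = pn$p, n_defined = attr(res, "n_defined"))
    NULL
  })

  stage("phylo", {
    tf <- emit("species_tree.nwk")
    writeLines(config$phylo$tree, tf)
    tree <- read_newick(tf); note(tf)
    tips <- simulate_tree_tips(tree, config$phylo$root_value, config$phylo$sigma2,
                               seed = derive_seed(config$seed, 12L))
    asr <- asr_bm(tree, tips$tips)
    td <- data.frame(meth = unname(tips$tips),
                     alkb2 = rep(c(1, 0), length.out = length(tips$tips)),
                     row.names = names(tips$tips))
    reg <- pgls(meth ~ alkb2, td, tree)
    fwrite(asr$estimates, emit("asr_nodes.tsv"), sep = "\t"); note(emit("asr_nodes.tsv"))
    summaries$phylo <- list(sigma2 = asr$sigma2, root = asr$root,
                             pgls_p_alkb2 = reg$coefficients[term == "alkb2"]$p)
    NULL
  })

  stage("expression", {
    expr <- sim$expr
    fm <- featm$fm
    upm <- fm[class == "upstream" & !is.na(mean_meth)]
    upv <- setNames(upm$mean_meth, upm$parent)
    kw <- tryCatch(upstream_meth_expression(upv, expr, config$expression$n_bins),
                   error = function(e) NULL)
    gm <- fm[class == "gene" & !is.na(mean_meth)]
    groups <- split_groups(setNames(gm$mean_meth, gm$feature_id), config$expression$q)
    cv <- tissue_cv(expr)
    cvc <- cv_contrast(cv, groups)
    hk <- attr(expr, "genes")[housekeeping_like == TRUE, gene_id]
    hke <- tryCatch(housekeeping_enrichment(setNames(gm$mean_meth, gm$feature_id), hk,
                                            config$expression$q),
                    error = function(e) NULL)
    ecc <- exon_count_contrast(setNames(gm$mean_meth, gm$feature_id), ann)
    summaries$expression <- list(
      kw_p = if (!is.null(kw)) kw$p else NA,
      top_bin_median = if (!is.null(kw)) kw$table$median_expr[1L] else NA,
      cv_median_high = cvc$median_high, cv_median_low = cvc$median_low,
      cv_p = cvc$p, hk_odds_ratio = if (!is.null(hke)) hke$odds_ratio else NA,
      hk_p = if (!is.null(hke)) hke$p else NA,
      single_multi_p = ecc$p)
    NULL
  })

  stage("tss", {
    ctss <- tpm_normalize(read_ctss_bed(emit("ctss.bed")))
    tc <- cluster_ctss(ctss, config$tss$max_gap)
    wd <- cluster_widths(tc, config$tss$q_low, config$tss$q_high)
    fwrite(tc$clusters[wd, on = "cluster_id"], emit("tag_clusters.tsv"), sep = "\t")
    note(emit("tag_clusters.tsv"))
    gm <- featm$fm[class == "gene" & !is.na(mean_meth)]
    groups <- split_groups(setNames(gm$mean_meth, gm$feature_id), config$expression$q)
    tssdt <- gene_tss(sim$genome$annotation)
    wc <- tryCatch(width_contrast(tc, tssdt, groups, config$tss$assign_window,
                                  config$tss$q_low, config$tss$q_high),
                   error = function(e) NULL)
    occ <- read_bedgraph_track(emit("occupancy.bedGraph"))
    om <- occupancy_metagene(occ, tssdt, config$tss$window, config$tss$flank,
                             config$tss$resamples, config$tss$keep,
                             seed = derive_seed(config$seed, 13L))
    fwrite(om, emit("occupancy_metagene.tsv"), sep = "\t"); note(emit("occupancy_metagene.tsv"))
    summaries$tss <- list(n_clusters = nrow(tc$clusters),
                           median_width_high = if (!is.null(wc)) wc$median_high else NA,
                           median_width_low = if (!is.null(wc)) wc$median_low else NA,
                           width_p = if (!is.null(wc)) wc$p else NA)
    NULL
  })

  summary_path <- emit("summaries.json")
  jsonlite::write_json(summaries, summary_path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  note(summary_path)
  par_path <- emit("params.json")
  jsonlite::write_json(config, par_path, auto_unbox = TRUE, pretty = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("arthromethyl")),
    seed = config$seed,
    params_md5 = unname(tools::md5sum(par_path)),
    outputs = lapply(setNames(paths, basename(paths)),
                     function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, emit("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
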