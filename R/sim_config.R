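#' Simulation configuration and architecture presets
#'
#' Builds a validated configuration for the synthetic-data generators. An
#' `architecture` preset fixes the class-specific true methylation means and
#' the couplings the downstream analyses look for:
#'
#' * `"strigamia-like"` - myriapod/chelicerate-style architecture: substantial
#'   background methylation, TE bodies strongly enriched over background,
#'   bimodal gene-body methylation, nucleosome-phased exonic methylation,
#'   promoter-silencing coupling (top upstream-methylation decile forces low
#'   expression) and housekeeping-style low tissue-CV for methylated genes.
#' * `"holometabolan"` - holometabolous-insect-style architecture: sparse
#'   methylation targeted at the bodies of a minority of genes, TEs at or
#'   below background, no promoter silencing.
#' * `"crustacean-null"` - essentially unmethylated genome; every class sits
#'   at the non-conversion floor.
#'
#' Lengths given as a 2-vector are drawn uniformly; a scalar is fixed.
#'
#' @param architecture preset name.
#' @param seed integer seed; all generators derive their streams from it.
#' @param ... overrides for any default field (see Details in the vignette).
#' @return a `sim_config` list.
#' @export
sim_config <- function(architecture = c("strigamia-like", "holometabolan",
                                        "crustacean-null"),
                       seed = 1L, ...) {
  architecture <- match.arg(architecture)
  cfg <- list(
    seed = as.integer(seed),
    architecture = architecture,
    n_contigs = 5L,
    contig_length = 100000L,
    n_genes = 100L,
    exon_count_probs = c(0.25, 0.2, 0.2, 0.15, 0.1, 0.05, 0.03, 0.02),
    exon_length = c(200L, 400L),
    intron_length = c(100L, 500L),
    n_tes = 50L,
    te_length = c(500L, 1500L),
    n_rrna = 0L,
    n_trna = 0L,
    min_feature_gap = 1500L,
    cpg_density = 0.04,
    nucleosome_repeat_length = 160L,
    periodic_amplitude = 0.15,
    phase_te = FALSE,
    meth_gene_fraction = 0.5,
    silenced_fraction = 0.1,
    class_means = c(exon = 0.75, exon_unmeth = 0.05, intron = 0.15,
                    upstream = 0.1, TE = 0.75, rRNA = 0.05, tRNA = 0.05,
                    background = 0.25),
    promoter_silencing = TRUE,
    expression_coupling = TRUE,
    coverage_mean = 30,
    nonconversion_rate = 0.005,
    failed_methylated_conversion = 0,
    spike_in_sites = 2000L,
    n_tissues = 4L,
    cv_low = 0.1,
    cv_high = 1.0,
    silencing_factor = 0.02,
    ctss_broad_span = 40L,
    ctss_narrow_span = 5L,
    ctss_tags_per_gene = 200,
    occupancy_amplitude = 0.5,
    occupancy_noise_sd = 0.05,
    occupancy_bin = 10L)
  if (architecture == "holometabolan") {
    cfg$class_means <- c(exon = 0.65, exon_unmeth = 0.02, intron = 0.05,
                         upstream = 0.04, TE = 0.02, rRNA = 0.02, tRNA = 0.02,
                         background = 0.03)
    cfg$periodic_amplitude <- 0.1
    cfg$meth_gene_fraction <- 0.3
    cfg$promoter_silencing <- FALSE
  } else if (architecture == "crustacean-null") {
    cfg$class_means <- c(exon = 0.005, exon_unmeth = 0.005, intron = 0.005,
                         upstream = 0.005, TE = 0.005, rRNA = 0.005,
                         tRNA = 0.005, background = 0.005)
    cfg$periodic_amplitude <- 0
    cfg$meth_gene_fraction <- 0
    cfg$promoter_silencing <- FALSE
    cfg$expression_coupling <- FALSE
  }
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stopf("unknown sim_config field(s): %s",
                             paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  frac <- c(cfg$cpg_density, cfg$periodic_amplitude, cfg$meth_gene_fraction,
            cfg$nonconversion_rate, cfg$failed_methylated_conversion,
            cfg$silenced_fraction, cfg$class_means)
  if (any(frac < 0) || any(frac > 1)) stopf("fractions must lie in [0, 1]")
  if (cfg$nonconversion_rate >= 1) stopf("nonconversion_rate must be < 1")
  if (max(cfg$class_means) + cfg$periodic_amplitude > 1)
    stopf("class means + periodic amplitude must not exceed 1")
  if (cfg$periodic_amplitude > 0.5) stopf("periodic_amplitude must be <= 0.5")
  if (cfg$n_contigs < 1L || cfg$contig_length < 1L) stopf("need >= 1 contig with positive length")
  if (abs(sum(cfg$exon_count_probs) - 1) > 1e-8)
    stopf("exon_count_probs must sum to 1")
  if (cfg$nucleosome_repeat_length <= 0) stopf("nucleosome_repeat_length must be positive")
  invisible(cfg)
}

# draw n lengths from a scalar (fixed) or 2-vector (uniform integer) spec
draw_len <- function(spec, n) {
  if (length(spec) == 1L) rep(as.integer(spec), n)
  else as.integer(round(runif(n, spec[1L], spec[2L])))
}
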