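# the synthetic-data generators: genome, methylome, counts, tree traits,
# expression / CTSS / occupancy

test_that("genome structure honours the configuration", {
  one <- sim_config("strigamia-like", seed = 5, n_contigs = 1L,
                    contig_length = 20000L, n_genes = 1L, n_tes = 0L,
                    exon_count_probs = c(1, rep(0, 7L)))
  g <- simulate_genome(one)
  ann <- derive_introns(g$annotation)
  expect_equal(nrow(features_of(ann, "gene")), 1L)
  expect_equal(nrow(features_of(ann, "exon")), 1L)
  expect_equal(nrow(features_of(ann, "intron")), 0L)

  none <- sim_config("strigamia-like", seed = 5, n_genes = 0L, n_tes = 0L,
                     n_contigs = 2L, contig_length = 10000L)
  g0 <- simulate_genome(none)
  expect_equal(nrow(g0$annotation$features), 0L)
  expect_gt(nrow(g0$cpg), 0L)
})

test_that("features never overlap and CpG dyads are spaced >= 2 bp", {
  cfg <- sim_config("strigamia-like", seed = 11, n_genes = 40L, n_tes = 30L,
                    n_contigs = 3L, contig_length = 120000L)
  g <- simulate_genome(cfg)
  top <- g$annotation$features[class %in% c("gene", "TE")]
  setorder(top, contig, start)
  expect_true(all(top[, start[-1L] >= head(end, -1L), by = contig]$V1))
  expect_true(all(g$cpg[, diff(pos) >= 2L, by = contig]$V1))
  dens <- nrow(g$cpg) / (3 * 120000)
  expect_gt(dens, 0.03); expect_lt(dens, 0.05)
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- sim_config("strigamia-like", seed = 23, n_genes = 20L, n_tes = 10L,
                    n_contigs = 2L, contig_length = 60000L,
                    spike_in_sites = 100L)
  run <- function() {
    g <- simulate_genome(cfg)
    m <- simulate_methylome(g, cfg)
    ct <- simulate_bisulfite_counts(m, cfg)
    e <- simulate_expression(g, cfg, m)
    cts <- simulate_ctss(g, cfg, m)
    oc <- simulate_occupancy(g, cfg, m)
    f1 <- tempfile(); write_annotation(g$annotation, f1)
    f2 <- tempfile(); write_cytosine_report(ct$sample, f2)
    list(gff = readLines(f1), rep = readLines(f2), p = m$sites$p,
         expr = e$abund, ctss = as.data.frame(cts), occ = oc$value)
  }
  a <- run(); b <- run()
  expect_identical(a, b)
})

test_that("infeasible packing is an explicit error", {
  cfg <- sim_config("strigamia-like", seed = 1, n_contigs = 1L,
                    contig_length = 5000L, n_genes = 30L, n_tes = 0L)
  expect_error(simulate_genome(cfg), "infeasible packing")
})

test_that("zero amplitude puts every methylated exonic site at the class mean", {
  cfg <- sim_config("strigamia-like", seed = 3, n_genes = 25L, n_tes = 0L,
                    n_contigs = 2L, contig_length = 80000L,
                    periodic_amplitude = 0, meth_gene_fraction = 1,
                    class_means = c(exon = 0.8, exon_unmeth = 0.02,
                                    intron = 0.1, upstream = 0.1, TE = 0.5,
                                    rRNA = 0.05, tRNA = 0.05, background = 0.1))
  m <- simulate_methylome(simulate_genome(cfg), cfg)
  expect_true(all(m$sites[class == "exon", p] == 0.8))
})

test_that("phased methylome oscillates with the configured repeat length", {
  sim <- phased_sim(seed = 101, L = 160L, A = 0.2)
  exonic <- sim$meth$sites[class == "exon"]
  expect_true(all(exonic$p >= 0.3 - 1e-12 & exonic$p <= 0.7 + 1e-12))
  # independent oracle: brute-force autocorrelation of the true p series
  # within exons; the phased signal is positive at lag ~L, negative at ~L/2
  ex <- features_of(sim$genome$annotation, "exon")
  pr <- bf_correlation(sim$meth$sites[, .(contig, pos, m = p)], ex,
                       dmin = 3L, dmax = 340L, min_pairs = 30L)
  at <- function(center, half = 6L) mean(pr[abs(d - center) <= half, r], na.rm = TRUE)
  expect_gt(at(160), 0.5)
  expect_lt(at(80), -0.3)
  expect_gt(at(320), at(240))
})

test_that("holometabolan preset keeps TE methylation at or below background", {
  cfg <- sim_config("holometabolan", seed = 17, n_genes = 30L, n_tes = 40L,
                    n_contigs = 3L, contig_length = 100000L)
  m <- simulate_methylome(simulate_genome(cfg), cfg)
  expect_lt(mean(m$sites[class == "TE", p]),
            mean(m$sites[class == "background", p]) + 0.01)
})

test_that("strigamia-like preset: realized TE methylation exceeds background by half the gap", {
  cfg <- sim_config("strigamia-like", seed = 29, n_genes = 0L, n_tes = 500L,
                    n_contigs = 10L, contig_length = 150000L,
                    te_length = c(400L, 900L), min_feature_gap = 300L,
                    spike_in_sites = 100L)
  g <- simulate_genome(cfg)
  m <- simulate_methylome(g, cfg)
  ct <- simulate_bisulfite_counts(m, cfg)
  st <- filter_sites(ct$sample)
  cls <- m$sites[, .(contig, pos, class)][st, on = c("contig", "pos")]
  realized <- cbind(cls[, .(class)], m = st$m)
  gap <- cfg$class_means[["TE"]] - cfg$class_means[["background"]]
  expect_gte(nrow(features_of(g$annotation, "TE")), 500L)
  expect_gt(realized[class == "TE", mean(m)],
            realized[class == "background", mean(m)] + gap / 2)
})

test_that("bisulfite counts respect conservation, saturation and the error floor", {
  cfg <- sim_config("strigamia-like", seed = 31, n_genes = 10L, n_tes = 5L,
                    n_contigs = 2L, contig_length = 50000L,
                    nonconversion_rate = 0, periodic_amplitude = 0,
                    meth_gene_fraction = 1,
                    class_means = c(exon = 1, exon_unmeth = 1, intron = 1,
                                    upstream = 1, TE = 1, rRNA = 1, tRNA = 1,
                                    background = 1))
  m <- simulate_methylome(simulate_genome(cfg), cfg)
  expect_true(all(m$sites[class != "upstream", p] == 1))
  ct <- simulate_bisulfite_counts(m, cfg)
  # p = 1 with perfect conversion: methylated count equals total on each strand
  truth_pos <- m$sites[p == 1, .(contig, pos)]
  full <- ct$sample[truth_pos, on = c("contig", "pos")]
  expect_equal(full$meth_plus, full$total_plus)
  expect_equal(full$meth_minus, full$total_minus)
  expect_true(all(ct$spike$meth <= ct$spike$total))

  # spike-in fraction ~ nonconversion within 3 binomial SE, >= 1e5 reads
  cfg2 <- sim_config("crustacean-null", seed = 33, n_genes = 0L, n_tes = 0L,
                     n_contigs = 1L, contig_length = 5000L,
                     nonconversion_rate = 0.005, spike_in_sites = 2000L,
                     coverage_mean = 30)
  m2 <- simulate_methylome(simulate_genome(cfg2), cfg2)
  ct2 <- simulate_bisulfite_counts(m2, cfg2)
  n_reads <- sum(ct2$spike$total)
  expect_gte(n_reads, 1e5)
  se <- sqrt(0.005 * 0.995 / n_reads)
  expect_lt(abs(sum(ct2$spike$meth) / n_reads - 0.005), 3 * se)

  # CLT bound at p = 0.5 over >= 1000 sites
  cfg3 <- sim_config("strigamia-like", seed = 35, n_genes = 0L, n_tes = 0L,
                     n_contigs = 1L, contig_length = 60000L,
                     cpg_density = 0.05, nonconversion_rate = 0,
                     class_means = c(exon = 0.5, exon_unmeth = 0.5, intron = 0.5,
                                     upstream = 0.5, TE = 0.5, rRNA = 0.5,
                                     tRNA = 0.5, background = 0.5))
  m3 <- simulate_methylome(simulate_genome(cfg3), cfg3)
  ct3 <- simulate_bisulfite_counts(m3, cfg3)
  n <- nrow(ct3$sample)
  expect_gte(n, 1000L)
  se3 <- sqrt(0.25 / (2 * cfg3$coverage_mean) / n)  # between+within site noise bound
  expect_lt(abs(mean(ct3$sample$m) - 0.5), 3 * se3 + 0.002)
})

test_that("Brownian tip simulation has the BM variance structure", {
  two <- ape::read.tree(text = "(A:1,B:1);")
  z <- simulate_tree_tips(two, root_value = 5, sigma2 = 0, seed = 1)
  expect_equal(unname(z$tips), c(5, 5))

  d <- replicate(1e4, {
    t <- simulate_tree_tips(two, 0, 1)
    t$tips[["A"]] - t$tips[["B"]]
  })
  expect_equal(var(d), 2, tolerance = 0.08)

  # tip covariance equals sigma2 * shared path length on an ultrametric tree
  set.seed(7)
  tr <- ape::rcoal(6)
  tips <- replicate(4000, simulate_tree_tips(tr, 0, 1)$tips)
  emp <- cov(t(tips))
  expect_lt(max(abs(emp - ape::vcv(tr)[rownames(emp), colnames(emp)])),
            4 * max(ape::vcv(tr)) / sqrt(2000))
  expect_error(simulate_tree_tips(structure(list(), class = "phylo"), 0, 1),
               "branch length")
})

test_that("expression generator orders tissue CV by class and CTSS spans collapse", {
  cfg <- sim_config("strigamia-like", seed = 41, n_genes = 80L, n_tes = 0L,
                    n_contigs = 4L, contig_length = 80000L,
                    cv_low = 0.1, cv_high = 1.0, ctss_narrow_span = 1L)
  g <- simulate_genome(cfg)
  m <- simulate_methylome(g, cfg)
  e <- simulate_expression(g, cfg, m)
  info <- attr(e, "genes")
  cv <- tissue_cv(e)
  expect_lt(median(cv[info$housekeeping_like], na.rm = TRUE),
            median(cv[!info$housekeeping_like], na.rm = TRUE))

  cts <- simulate_ctss(g, cfg, m)
  narrow <- info[housekeeping_like == FALSE, gene_id]
  tssdt <- gene_tss(g$annotation)
  for (gid in head(narrow, 5L)) {
    row <- tssdt[gene_id == gid]
    tags <- cts[contig == row$contig & strand == row$strand &
                  abs(pos - row$pos) < 50L]
    expect_equal(unique(tags$pos), row$pos)  # span 1: all tags at the TSS
  }
})

test_that("zero occupancy amplitude gives a flat metagene", {
  cfg <- sim_config("strigamia-like", seed = 43, n_genes = 30L, n_tes = 0L,
                    n_contigs = 2L, contig_length = 60000L,
                    occupancy_amplitude = 0, occupancy_noise_sd = 0.01)
  g <- simulate_genome(cfg)
  occ <- simulate_occupancy(g, cfg)
  om <- occupancy_metagene(occ, gene_tss(g$annotation), resamples = 10L, seed = 1)
  expect_lt(diff(range(om$mean)), 0.05)
  expect_equal(mean(om$mean), 1, tolerance = 0.01)
})
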