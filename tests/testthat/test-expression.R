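test_that("fpkm arithmetic, scaling and linearity", {
  cts <- matrix(c(0, 100, 100, 200), nrow = 2L,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
  len <- c(g1 = 1000, g2 = 2000)
  fk <- fpkm(cts, len, total_mapped = c(1e7, 1e7))
  expect_equal(fk["g1", "s1"], 0)
  expect_equal(fk["g2", "s1"], 5)     # 100 / (2 kb * 10 M/1e6)
  fk2 <- fpkm(cts, len, total_mapped = c(2e7, 2e7))
  expect_equal(fk2, fk / 2)
  expect_equal(fpkm(3 * cts, len, total_mapped = c(1e7, 1e7)), 3 * fk)
  expect_error(fpkm(cts, c(g1 = 0, g2 = 2000), c(1e7, 1e7)), "> 0")
})

test_that("expression groups cut at the quantile with stable ties", {
  v <- setNames(c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1), paste0("g", 1:10))
  gr <- expression_groups(v, 0.2)
  expect_equal(sort(gr$high), c("g1", "g2"))
  expect_equal(sort(gr$low), c("g10", "g9"))
  v11 <- setNames(11:1, paste0("g", 1:11))
  gh <- expression_groups(v11, 0.5)
  expect_equal(sort(unique(c(gh$high, gh$low))), sort(names(v11)))  # partition
  expect_warning(expression_groups(setNames(rep(1, 6L), paste0("g", 1:6))),
                 "identical")
})

test_that("promoter-methylation bins order expression and calibrate under the null", {
  set.seed(3)
  meth <- setNames(runif(200L), paste0("g", 1:200))
  expr <- setNames(rlnorm(200L, 3, 1), paste0("g", 1:200))
  # implant silencing in the top decile of promoter methylation
  top <- names(sort(meth, decreasing = TRUE))[1:20]
  expr[top] <- expr[top] * 0.02
  r <- upstream_meth_expression(meth, expr, n_bins = 10L)
  expect_equal(r$table[which.min(median_expr), bin], 1L)  # bin 1 = most methylated
  expect_lt(r$p, 1e-6)
  expect_error(upstream_meth_expression(setNames(rep(0.5, 50L), paste0("g", 1:50)),
                                        expr[1:50], 10L), "populated")

  set.seed(11)
  rej <- vapply(1:200, function(i) {
    mm <- setNames(runif(60L), paste0("g", 1:60))
    ee <- setNames(rlnorm(60L), paste0("g", 1:60))
    upstream_meth_expression(mm, ee, 5L)$p <= 0.05
  }, logical(1L))
  expect_gte(mean(rej), 0.02); expect_lte(mean(rej), 0.09)
})

test_that("tissue CV arithmetic and contrast", {
  ab <- rbind(g1 = c(2, 2, 2), g2 = c(1, 3, 2), g3 = c(0, 0, 0))
  colnames(ab) <- paste0("t", 1:3)
  et <- expression_table(ab, colnames(ab))
  cv <- tissue_cv(et)
  expect_equal(unname(cv["g1"]), 0)
  expect_true(is.na(cv["g3"]))
  et2 <- expression_table(ab[, 1:2][1:2, , drop = FALSE], c("t1", "t2"))
  cv2 <- tissue_cv(et2)
  expect_equal(unname(cv2["g2"]), sd(c(1, 3)) / 2, tolerance = 1e-12)
  expect_equal(unname(cv2["g2"]), 0.7071, tolerance = 1e-4)

  set.seed(5)
  cvs <- setNames(c(rnorm(50, 0.2, 0.02), rnorm(50, 1, 0.1)), paste0("g", 1:100))
  ct <- cv_contrast(cvs, list(high = paste0("g", 1:50), low = paste0("g", 51:100)))
  expect_lt(ct$median_high, ct$median_low)
  expect_lt(ct$p, 1e-10)
})

test_that("z-scores standardise within species and pool cleanly", {
  set.seed(7)
  meth <- data.table(species = rep(c("sp1", "sp2"), each = 100L),
                     gene_id = rep(paste0("g", 1:100), 2L),
                     meth = c(runif(100L), runif(100L, 0, 0.2)))
  expr <- data.table(species = meth$species, gene_id = meth$gene_id,
                     expr = rlnorm(200L))
  z <- zscore_coupling(meth, expr)
  bysp <- z[, .(m1 = mean(z_meth), s1 = sd(z_meth),
                m2 = mean(z_expr), s2 = sd(z_expr)), by = species]
  expect_equal(bysp$m1, c(0, 0), tolerance = 1e-12)
  expect_equal(bysp$s1, c(1, 1), tolerance = 1e-12)
  expect_equal(bysp$s2, c(1, 1), tolerance = 1e-12)
  # pooling preserves the per-species standardisation
  expect_equal(z[species == "sp1", z_meth],
               zscore_coupling(meth[species == "sp1"],
                               expr[species == "sp1"])$z_meth)
})

test_that("generator coupling keeps methylated genes out of the silent low tail", {
  cfg <- sim_config("strigamia-like", seed = 47, n_genes = 200L, n_tes = 0L,
                    n_contigs = 8L, contig_length = 90000L, cpg_density = 0.005,
                    min_feature_gap = 500L,
                    meth_gene_fraction = 0.3, promoter_silencing = FALSE)
  z_all <- rbindlist(lapply(c(47L, 48L), function(sd) {
    cfg$seed <- sd
    g <- simulate_genome(cfg)
    m <- simulate_methylome(g, cfg)
    e <- simulate_expression(g, cfg, m)
    gm <- m$sites[class == "exon", .(meth = mean(p)), by = gene_id]
    data.table(species = paste0("sp", sd), gene_id = gm$gene_id, meth = gm$meth,
               expr = rowMeans(e$abund)[gm$gene_id])
  }))
  z <- zscore_coupling(z_all[, .(species, gene_id, meth)],
                       z_all[, .(species, gene_id, expr)])
  expect_lt(mean(z$z_meth > 1 & z$z_expr < -1), 0.01)
})

test_that("housekeeping enrichment equals the hypergeometric oracle", {
  # 2x2 table [[10,10],[3,17]]
  meth <- setNames(c(seq(0.9, 0.8, length.out = 20L),
                     rep(0.5, 60L),
                     seq(0.2, 0.1, length.out = 20L)), paste0("g", 1:100))
  hk <- c(paste0("g", 1:10), paste0("g", 81:83))
  r <- housekeeping_enrichment(meth, hk, q = 0.2)
  expect_equal(unname(r$table["top", ]), c(10L, 10L))
  expect_equal(unname(r$table["bottom", ]), c(3L, 17L))
  # two-sided Fisher p by direct enumeration over the fixed margins
  pobs <- dhyper(10, 13, 27, 20)
  p_oracle <- sum(dhyper(0:13, 13, 27, 20)[dhyper(0:13, 13, 27, 20) <= pobs + 1e-12])
  expect_equal(r$p, p_oracle, tolerance = 1e-12)

  flat <- setNames(seq(0, 1, length.out = 40L), paste0("g", 1:40))
  hk2 <- paste0("g", c(1:4, 33:36))  # 4 hk in each tail of 8
  r2 <- housekeeping_enrichment(flat, hk2, q = 0.2)
  expect_equal(unname(r2$odds_ratio), 1, tolerance = 1e-9)
})

test_that("orthogroup scores average z across species, order-invariantly", {
  meth <- data.table(
    species = rep(c("a", "b"), each = 10L),
    gene_id = c(paste0("ga", 1:10), paste0("gb", 1:10)),
    meth = c(seq(0.1, 1, 0.1), seq(0.05, 0.5, 0.05)))
  om <- data.table(orthogroup = rep(paste0("og", 1:10), 2L),
                   species = rep(c("a", "b"), each = 10L),
                   gene_id = c(paste0("ga", 1:10), paste0("gb", 1:10)))
  r <- r2 <- orthogroup_methylation(meth, om)
  expect_equal(nrow(r$scores), 10L)
  # one gene per species, matched ranks: score equals the shared z
  za <- scale(seq(0.1, 1, 0.1))[, 1L]
  expect_equal(r$scores[order(orthogroup)]$score,
               za[order(paste0("og", 1:10))], tolerance = 1e-12)
  r2 <- orthogroup_methylation(meth[order(-seq_len(20L))], om)
  expect_equal(r2$scores[order(orthogroup)], r$scores[order(orthogroup)])
  # implanted methylated orthogroups land in the top set
  expect_true(all(c("og10", "og9") %in% r$top))
})

test_that("single- vs multi-exon contrast handles edges and implanted effects", {
  ann1 <- toy_annotation(rbind(
    feat("g1", 0, 100, "gene"), feat("g1.e1", 0, 100, "exon", parent = "g1"),
    feat("g2", 200, 300, "gene"), feat("g2.e1", 200, 300, "exon", parent = "g2")))
  expect_warning(r0 <- exon_count_contrast(c(g1 = 0.5, g2 = 0.2), ann1), "empty")
  expect_true(is.na(r0$p))

  nsingle <- 60L; nmulti <- 60L
  ft <- list(); meth <- numeric(0L)
  for (i in seq_len(nsingle + nmulti)) {
    gid <- paste0("g", i); s <- (i - 1L) * 400L
    if (i <= nsingle) {
      ft[[length(ft) + 1L]] <- rbind(feat(gid, s, s + 200L, "gene"),
                                     feat(paste0(gid, ".e1"), s, s + 200L, "exon", parent = gid))
    } else {
      ft[[length(ft) + 1L]] <- rbind(feat(gid, s, s + 300L, "gene"),
        feat(paste0(gid, ".e1"), s, s + 100L, "exon", parent = gid),
        feat(paste0(gid, ".e2"), s + 200L, s + 300L, "exon", parent = gid))
    }
  }
  set.seed(9)
  meth <- setNames(c(runif(nsingle, 0, 0.3), runif(nmulti, 0.3, 0.6)),
                   paste0("g", seq_len(nsingle + nmulti)))
  ann <- toy_annotation(rbindlist(ft), contig_lengths = c(chr1 = 60000L))
  r <- exon_count_contrast(meth, ann)
  expect_lt(r$mean_single, r$mean_multi)
  expect_lt(r$p, 1e-6)
})
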