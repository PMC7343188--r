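test_that("GFF3 coordinates convert to 0-based half-open and round-trip", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "##sequence-region chr1 1 10000",
    "chr1\tsrc\tgene\t101\t300\t.\t+\t.\tID=g1",
    "chr1\tsrc\texon\t101\t200\t.\t+\t.\tID=g1.e1;Parent=g1",
    "chr1\tsrc\texon\t251\t300\t.\t+\t.\tID=g1.e2;Parent=g1"), gff)
  ann <- read_annotation(gff, "gff3")
  ex <- features_of(ann, "exon")
  expect_equal(ex[feature_id == "g1.e1", start], 100L)
  expect_equal(ex[feature_id == "g1.e1", end], 200L)
  expect_equal(ex[feature_id == "g1.e1", end - start], 100L)
  expect_equal(unname(ann$contigs["chr1"]), 10000)
  # write -> read identity on intervals
  out <- tempfile(fileext = ".gff3")
  write_annotation(ann, out)
  ann2 <- read_annotation(out, "gff3")
  expect_equal(ann2$features[order(feature_id)],
               ann$features[order(feature_id)])
  expect_equal(ann2$contigs, ann$contigs)
})

test_that("genes split across multiple contigs are dropped with a warning", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "##sequence-region chr1 1 10000",
    "##sequence-region chr2 1 10000",
    "chr1\tsrc\tgene\t101\t300\t.\t+\t.\tID=gsplit",
    "chr1\tsrc\texon\t101\t200\t.\t+\t.\tID=e1;Parent=gsplit",
    "chr2\tsrc\texon\t501\t600\t.\t+\t.\tID=e2;Parent=gsplit",
    "chr2\tsrc\tgene\t1001\t1300\t.\t+\t.\tID=gok",
    "chr2\tsrc\texon\t1001\t1300\t.\t+\t.\tID=e3;Parent=gok"), gff)
  expect_warning(ann <- read_annotation(gff, "gff3"), "split across")
  expect_equal(features_of(ann, "gene")$feature_id, "gok")
  expect_equal(features_of(ann, "exon")$feature_id, "e3")
})

test_that("empty annotation file parses to an empty annotation", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "##sequence-region chr1 1 5000"), gff)
  ann <- read_annotation(gff, "gff3")
  expect_equal(nrow(ann$features), 0L)
  expect_equal(unname(ann$contigs["chr1"]), 5000)
})

test_that("derive_introns builds inter-exon gaps", {
  ann <- toy_annotation(rbind(
    feat("g1", 0, 300, "gene"),
    feat("g1.e1", 0, 100, "exon", parent = "g1"),
    feat("g1.e2", 200, 300, "exon", parent = "g1"),
    feat("g2", 500, 600, "gene"),
    feat("g2.e1", 500, 600, "exon", parent = "g2"),
    feat("g3", 1000, 1600, "gene"),
    feat("g3.e1", 1000, 1100, "exon", parent = "g3"),
    feat("g3.e2", 1200, 1350, "exon", parent = "g3"),
    feat("g3.e3", 1500, 1600, "exon", parent = "g3")))
  ann2 <- derive_introns(ann)
  intr <- features_of(ann2, "intron")
  expect_equal(intr[parent == "g1", .(start, end)], data.table(start = 100L, end = 200L))
  expect_equal(nrow(intr[parent == "g2"]), 0L)
  # 3 exons -> 2 introns; intron length = gene span - exon lengths
  g3i <- intr[parent == "g3"]
  expect_equal(nrow(g3i), 2L)
  expect_equal(sum(g3i$end - g3i$start), 600L - (100L + 150L + 100L))
})

test_that("derive_introns rejects overlapping exons, naming the gene", {
  ann <- toy_annotation(rbind(
    feat("gbad", 0, 300, "gene"),
    feat("e1", 0, 150, "exon", parent = "gbad"),
    feat("e2", 100, 300, "exon", parent = "gbad")))
  expect_error(derive_introns(ann), "gbad")
})

test_that("derive_upstream is strand-aware and excludes windows off-contig", {
  ann <- toy_annotation(rbind(
    feat("gfwd", 5000, 8000, "gene", strand = "+"),
    feat("grev", 5000, 8000, "gene", strand = "-"),
    feat("gshort", 500, 900, "gene", strand = "+")),
    contig_lengths = c(chr1 = 8500L))
  up <- features_of(derive_upstream(ann, 1000L), "upstream")
  expect_equal(up[parent == "gfwd", .(start, end)],
               data.table(start = 4000L, end = 5000L))
  # minus-strand window would end at 9000 > 8500; plus gene window < 0
  expect_false("grev" %in% up$parent)
  expect_false("gshort" %in% up$parent)
})

test_that("screen_overlaps removes conflicted TEs and upstream regions", {
  ann <- toy_annotation(rbind(
    feat("g1", 150, 160, "gene"),
    feat("e1", 150, 160, "exon", parent = "g1"),
    feat("te_hit", 100, 200, "TE"),
    feat("te_abut", 160, 260, "TE"),
    feat("trna1", 999, 1070, "tRNA"),
    feat("up1", 0, 1000, "upstream", parent = "gX"),
    feat("gX", 2000, 2100, "gene"),
    feat("eX", 2000, 2100, "exon", parent = "gX")))
  scr <- screen_overlaps(ann)
  expect_false("te_hit" %in% scr$features$feature_id)     # overlaps exon
  expect_true("te_abut" %in% scr$features$feature_id)     # half-open abutment
  expect_false("up1" %in% scr$features$feature_id)        # 1 bp tRNA overlap
  # idempotence
  scr2 <- screen_overlaps(scr)
  expect_equal(scr2$features[order(feature_id)], scr$features[order(feature_id)])
})

test_that("upstream screening against pre- vs post-screen TEs differs", {
  # TE overlaps an exon (so it is removed) and also the upstream region
  ann <- toy_annotation(rbind(
    feat("g1", 3000, 3500, "gene"),
    feat("e1", 3000, 3500, "exon", parent = "g1"),
    feat("te1", 3400, 4200, "TE"),
    feat("g2", 5000, 5600, "gene"),
    feat("e2", 5000, 5600, "exon", parent = "g2"),
    feat("up2", 4000, 5000, "upstream", parent = "g2")))
  pre <- screen_overlaps(ann, "prescreen")
  post <- screen_overlaps(ann, "postscreen")
  expect_false("up2" %in% pre$features$feature_id)
  expect_true("up2" %in% post$features$feature_id)
})

test_that("background_mask complements and erodes correctly", {
  ann0 <- toy_annotation(feat("g", 1, 2, "gene")[0], contig_lengths = c(chr1 = 1000L))
  expect_equal(background_mask(ann0),
               data.table(contig = "chr1", start = 0L, end = 1000L))
  ann <- toy_annotation(rbind(feat("te1", 100, 200, "TE")),
                        contig_lengths = c(chr1 = 1000L))
  expect_equal(background_mask(ann, 0L),
               data.table(contig = "chr1", start = c(0L, 200L), end = c(100L, 1000L)))
  expect_equal(background_mask(ann, 50L),
               data.table(contig = "chr1", start = c(0L, 250L), end = c(50L, 1000L)))
})

test_that("background + eroded features tile the contig", {
  set.seed(42)
  starts <- sort(sample.int(9000L, 12L))
  ft <- rbindlist(lapply(seq_along(starts), function(i)
    feat(paste0("te", i), starts[i], starts[i] + sample(50:400, 1L), "TE")))
  ft[, end := pmin(end, 10000L)]
  ann <- toy_annotation(ft, contig_lengths = c(chr1 = 10000L))
  md <- 100L
  bg <- background_mask(ann, md)
  # no overlap between background and any feature padded by md
  pad <- copy(ann$features)[, `:=`(start = pmax(0L, start - md),
                                   end = pmin(10000L, end + md))]
  expect_false(any(overlaps_any <- sapply(seq_len(nrow(bg)), function(i)
    any(pad$start < bg$end[i] & pad$end > bg$start[i]))))
  # union covers the contig: background + merged padded features
  cov <- sum(bg$end - bg$start)
  m <- pad[order(start)]
  merged <- 0L; cur_s <- -1L; cur_e <- -1L
  for (i in seq_len(nrow(m))) {
    if (m$start[i] > cur_e) { merged <- merged + max(0L, cur_e - cur_s); cur_s <- m$start[i]; cur_e <- m$end[i] }
    else cur_e <- max(cur_e, m$end[i])
  }
  merged <- merged + max(0L, cur_e - cur_s)
  expect_equal(cov + merged, 10000L)
})
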