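#' Genome annotation container
#'
#' A `genome_annotation` holds typed, strand-aware feature intervals on a set
#' of contigs. Coordinates are 0-based half-open internally; GFF3 (1-based
#' closed) is converted at the I/O boundary. Recognised feature classes are
#' `gene`, `exon`, `intron`, `UTR`, `upstream`, `TE`, `rRNA` and `tRNA`.
#'
#' @param features data.frame with columns `feature_id`, `contig`, `start`,
#'   `end`, `strand` (`+`, `-` or `.`), `class`, `parent` (gene id or `NA`).
#' @param contig_lengths named numeric vector of contig lengths in bp.
#' @return An object of class `genome_annotation`: a list with elements
#'   `contigs` (named lengths) and `features` (a `data.table`).
#' @export
genome_annotation <- function(features, contig_lengths) {
  ft <- as.data.table(features)
  need <- c("feature_id", "contig", "start", "end", "strand", "class", "parent")
  miss <- setdiff(need, names(ft))
  if (length(miss)) stopf("features missing columns: %s", paste(miss, collapse = ", "))
  ft <- ft[, need, with = FALSE]
  if (is.null(names(contig_lengths)) || anyNA(names(contig_lengths)))
    stopf("contig_lengths must be a named vector")
  known <- c("gene", "exon", "intron", "UTR", "upstream", "TE", "rRNA", "tRNA")
  bad <- setdiff(unique(ft$class), known)
  if (length(bad)) stopf("unknown feature class(es): %s", paste(bad, collapse = ", "))
  if (nrow(ft)) {
    unk <- setdiff(unique(ft$contig), names(contig_lengths))
    if (length(unk)) stopf("features on unknown contig(s): %s", paste(unk, collapse = ", "))
    if (any(ft$start < 0L) || any(ft$start >= ft$end))
      stopf("invalid interval: need 0 <= start < end")
    if (any(ft$end > contig_lengths[ft$contig]))
      stopf("interval end exceeds contig length")
    orphan <- ft[class == "exon" & !(parent %in% ft[class == "gene", feature_id])]
    if (nrow(orphan)) stopf("exon(s) without parent gene: %s",
                            paste(head(orphan$feature_id, 3L), collapse = ", "))
  }
  setorder(ft, class, contig, start, end, feature_id)
  structure(list(contigs = contig_lengths, features = ft),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d contig(s), %.0f bp total\n",
              length(x$contigs), sum(x$contigs)))
  if (nrow(x$features)) print(x$features[, .N, by = class]) else cat("  (no features)\n")
  invisible(x)
}

#' Subset features of an annotation by class
#' @param annotation a `genome_annotation`.
#' @param classes character vector of feature classes.
#' @return `data.table` of matching features.
#' @export
features_of <- function(annotation, classes) {
  annotation$features[class %in% classes]
}

# map GFF3 `type` values onto internal classes
.gff_class_map <- c(
  gene = "gene", mRNA = NA, exon = "exon", intron = "intron",
  five_prime_UTR = "UTR", three_prime_UTR = "UTR", UTR = "UTR",
  upstream = "upstream", promoter = "upstream",
  transposable_element = "TE", TE = "TE", repeat_region = "TE",
  rRNA = "rRNA", tRNA = "tRNA")

#' Read a genome annotation from GFF3 or BED
#'
#' GFF3 1-based closed coordinates are converted to the internal 0-based
#' half-open convention. Genes whose own record or whose exons are split
#' across multiple contigs are dropped with a warning, and their child
#' features with them. Contig lengths are taken from `##sequence-region`
#' pragmas unless supplied.
#'
#' @param path file path.
#' @param format `"gff3"` or `"bed"`.
#' @param contig_lengths optional named vector overriding/supplying lengths.
#' @param feature_class class assigned to BED records (BED carries no type).
#' @return a [genome_annotation()].
#' @export
read_annotation <- function(path, format = c("gff3", "bed"),
                            contig_lengths = NULL, feature_class = "TE") {
  format <- match.arg(format)
  gr <- rtracklayer::import(path, format = if (format == "gff3") "gff3" else "bed")
  if (format == "bed") {
    ft <- data.table(
      feature_id = if (!is.null(gr$name)) as.character(gr$name) else
        sprintf("%s_%d", feature_class, seq_along(gr)),
      contig = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
      class = feature_class, parent = NA_character_)
    if (is.null(contig_lengths)) stopf("BED input requires contig_lengths")
    return(genome_annotation(ft, contig_lengths))
  }
  if (is.null(contig_lengths)) {
    prag <- grep("^##sequence-region", readLines(path, warn = FALSE), value = TRUE)
    if (!length(prag))
      stopf("no ##sequence-region pragmas in %s; pass contig_lengths", path)
    parts <- strsplit(trimws(prag), "\\s+")
    contig_lengths <- setNames(
      vapply(parts, function(p) as.numeric(p[4L]), numeric(1L)),
      vapply(parts, `[`, character(1L), 2L))
  }
  type <- as.character(gr$type)
  cls <- .gff_class_map[type]
  keep <- !is.na(cls) & type %in% names(.gff_class_map)
  gr <- gr[keep]
  cls <- cls[keep]
  par <- rep(NA_character_, length(gr))
  if (!is.null(gr$Parent)) {
    pl <- gr$Parent
    has <- lengths(pl) > 0L
    par[has] <- vapply(as.list(pl[has]), `[`, character(1L), 1L)
  }
  id <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
  noid <- is.na(id)
  id[noid] <- sprintf("%s_%d", cls[noid], seq_len(sum(noid)))
  ft <- data.table(
    feature_id = id,
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
    class = unname(cls), parent = par)
  # genes split across contigs: gene id seen on >1 contig, directly or via exons
  gcontig <- rbind(ft[class == "gene", .(gid = feature_id, contig)],
                   ft[class == "exon" & !is.na(parent), .(gid = parent, contig)])
  split_genes <- gcontig[, uniqueN(contig), by = gid][V1 > 1L, gid]
  if (length(split_genes)) {
    warnf("dropping %d gene(s) split across multiple contigs: %s",
          length(split_genes), paste(head(split_genes, 5L), collapse = ", "))
    ft <- ft[!(feature_id %in% split_genes) & !(parent %in% split_genes)]
  }
  genome_annotation(ft, contig_lengths)
}

# rtracklayer loads GenomeInfoDb; avoid a hard Imports entry for one accessor
GenomeInfoDb_seqlengths <- function(gr) {
  getExportedValue("GenomeInfoDb", "seqlengths")(gr)
}
uniqueN <- data.table::uniqueN

#' Write a genome annotation to GFF3
#'
#' Emits `##sequence-region` pragmas for every contig; internal 0-based
#' half-open coordinates are converted back to GFF3 1-based closed. Output is
#' byte-deterministic for a given annotation.
#'
#' @param annotation a [genome_annotation()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  ft <- copy(annotation$features)
  # stable emission order: contig, start, genes before children
  ord <- c(gene = 1L, exon = 2L, UTR = 3L, intron = 4L, upstream = 5L,
           TE = 6L, rRNA = 7L, tRNA = 8L)
  ft[, rank := ord[class]]
  setorder(ft, contig, start, rank, feature_id)
  type <- c(gene = "gene", exon = "exon", intron = "intron", UTR = "UTR",
            upstream = "upstream", TE = "transposable_element",
            rRNA = "rRNA", tRNA = "tRNA")[ft$class]
  attrs <- paste0("ID=", ft$feature_id,
                  ifelse(is.na(ft$parent), "", paste0(";Parent=", ft$parent)))
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %.0f",
                     names(annotation$contigs), annotation$contigs),
             if (nrow(ft)) sprintf("%s\tarthromethyl\t%s\t%d\t%d\t.\t%s\t.\t%s",
                                   ft$contig, type, ft$start + 1L, ft$end,
                                   ft$strand, attrs))
  writeLines(lines, path)
  invisible(path)
}

#' Derive introns from exon positions
#'
#' For each gene with k >= 2 exons, the k-1 inter-exon gaps become introns;
#' single-exon genes yield none. Pre-existing introns are replaced.
#'
#' @param annotation a [genome_annotation()].
#' @return a new `genome_annotation` including derived introns.
#' @export
derive_introns <- function(annotation) {
  ex <- features_of(annotation, "exon")
  ft <- annotation$features[class != "intron"]
  if (nrow(ex) == 0L) return(genome_annotation(ft, annotation$contigs))
  setorder(ex, parent, start)
  ov <- ex[, any(start[-1L] < head(end, -1L)), by = parent][V1 == TRUE]
  if (nrow(ov)) stopf("overlapping exons within gene(s): %s",
                      paste(head(ov$parent, 3L), collapse = ", "))
  intr <- ex[, if (.N >= 2L) .(contig = contig[1L],
                               start = head(end, -1L), end = start[-1L],
                               strand = strand[1L]), by = parent]
  if (nrow(intr)) intr <- intr[end > start]  # abutting exons leave no intron
  if (nrow(intr)) {
    intr[, feature_id := sprintf("%s_intron_%d", parent, seq_len(.N)), by = parent]
    intr[, class := "intron"]
    ft <- rbind(ft, intr[, .(feature_id, contig, start, end, strand, class, parent)])
  }
  genome_annotation(ft, annotation$contigs)
}

#' Derive upstream (putative promoter) regions
#'
#' Takes `length` bases immediately 5' of each gene start, strand-aware.
#' Genes whose window would run past the contig start or end are excluded.
#'
#' @param annotation a [genome_annotation()].
#' @param length window size in bp (default 1000).
#' @return a new `genome_annotation` with `upstream` features replacing any
#'   existing ones.
#' @export
derive_upstream <- function(annotation, length = 1000L) {
  g <- features_of(annotation, "gene")
  ft <- annotation$features[class != "upstream"]
  if (nrow(g)) {
    up <- copy(g)
    up[, `:=`(ustart = ifelse(strand == "-", end, start - length),
              uend   = ifelse(strand == "-", end + length, start))]
    up <- up[ustart >= 0 & uend <= annotation$contigs[contig]]
    if (nrow(up)) {
      up <- up[, .(feature_id = paste0(feature_id, "_upstream"), contig,
                   start = as.integer(ustart), end = as.integer(uend),
                   strand, class = "upstream", parent = feature_id)]
      ft <- rbind(ft, up)
    }
  }
  genome_annotation(ft, annotation$contigs)
}

#' Screen out ambiguous overlapping annotations
#'
#' TEs overlapping any rRNA, tRNA or exon are removed; upstream regions
#' overlapping any TE, rRNA, tRNA or exon are removed. Overlap is >= 1 shared
#' bp, strand-blind. By default upstream regions are screened against the
#' pre-screen TE set (the conservative reading); set
#' `upstream_against = "postscreen"` to screen against surviving TEs only.
#'
#' @param annotation a [genome_annotation()].
#' @param upstream_against `"prescreen"` (default) or `"postscreen"`.
#' @return a screened `genome_annotation`. Idempotent.
#' @export
screen_overlaps <- function(annotation, upstream_against = c("prescreen", "postscreen")) {
  upstream_against <- match.arg(upstream_against)
  ft <- annotation$features
  te <- ft[class == "TE"]
  blockers_te <- ft[class %in% c("rRNA", "tRNA", "exon")]
  te_bad <- if (nrow(te)) overlaps_any(te, blockers_te) else logical(0L)
  te_kept <- te[!te_bad]
  up <- ft[class == "upstream"]
  te_ref <- if (upstream_against == "prescreen") te else te_kept
  blockers_up <- rbind(ft[class %in% c("rRNA", "tRNA", "exon")], te_ref)
  up_bad <- if (nrow(up)) overlaps_any(up, blockers_up) else logical(0L)
  out <- rbind(ft[!(class %in% c("TE", "upstream"))], te_kept, up[!up_bad])
  genome_annotation(out, annotation$contigs)
}

#' Background (unannotated) regions of the genome
#'
#' Complement of the union of all annotated features on each contig,
#' optionally eroded by `min_distance` bp on each side: `min_distance = 0`
#' gives the "outside annotated features" background, `min_distance = 1000`
#' the strict "more than 1 kb from any annotation" background.
#'
#' @param annotation a [genome_annotation()].
#' @param min_distance erosion in bp (default 0).
#' @return `data.table` with `contig`, `start`, `end` (0-based half-open).
#' @export
background_mask <- function(annotation, min_distance = 0L) {
  stopifnot(min_distance >= 0L)
  out <- vector("list", length(annotation$contigs))
  for (i in seq_along(annotation$contigs)) {
    ctg <- names(annotation$contigs)[i]
    L <- annotation$contigs[[i]]
    iv <- annotation$features[contig == ctg, .(start, end)]
    if (nrow(iv)) {
      iv[, `:=`(start = pmax(0, start - min_distance),
                end = pmin(L, end + min_distance))]
      setorder(iv, start, end)
      # merge the padded union
      m <- iv[, {
        grp <- cumsum(c(1L, as.integer(start[-1L] > cummax(head(end, -1L)))))
        .(start = start, end = end, grp = grp)
      }][, .(start = min(start), end = max(end)), by = grp]
      gs <- c(0, m$end); ge <- c(m$start, L)
    } else {
      gs <- 0; ge <- L
    }
    keep <- ge > gs
    out[[i]] <- data.table(contig = ctg, start = as.integer(gs[keep]),
                           end = as.integer(ge[keep]))
  }
  rbindlist(out)
}
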