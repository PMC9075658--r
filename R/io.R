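# Readers/writers for the standard formats the pipeline touches.
# Internal coordinates are 0-based half-open; the CpG position refers to the
# C of the CpG on the + strand with both strands assumed collapsed into one
# record. Bismark coverage files are 1-based inclusive; writers restore the
# dialect they are asked for.

#' Gene models container
#'
#' @param genes Data frame with gene_id, chrom, strand, start, end (0-based
#'   half-open span), n_exons and optionally true_meth_class.
#' @param exons Data frame with gene_id, rank (transcription order; rank 1 is
#'   the 5' exon), start, end.
#' @return Object of class `gene_models`.
#' @export
gene_models <- function(genes, exons) {
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in% names(genes)),
            all(c("gene_id", "rank", "start", "end") %in% names(exons)))
  if (!"n_exons" %in% names(genes)) {
    genes$n_exons <- as.integer(table(exons$gene_id)[genes$gene_id])
  }
  # validate: exons inside span, non-overlapping, >=1 per gene
  for (gid in genes$gene_id) {
    ex <- exons[exons$gene_id == gid, ]
    if (nrow(ex) < 1L) stop(sprintf("gene %s has no exons", gid), call. = FALSE)
    g <- genes[genes$gene_id == gid, ]
    if (any(ex$start < g$start | ex$end > g$end)) {
      stop(sprintf("gene %s: exon outside gene span", gid), call. = FALSE)
    }
    o <- order(ex$start)
    if (any(ex$start[o][-1] < ex$end[o][-nrow(ex)])) {
      stop(sprintf("gene %s: overlapping exon blocks", gid), call. = FALSE)
    }
  }
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("Gene models: %d genes, %d exons on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$exons), length(unique(x$genes$chrom))))
  invisible(x)
}

#' Read per-CpG methylation counts
#'
#' Auto-detects the dialect by column count: 6 columns is Bismark coverage
#' (chrom, 1-based start, end, methylation percentage, count methylated,
#' count unmethylated; total reads = methylated + unmethylated); 5 columns is
#' a bedGraph-style table (chrom, 0-based start, end, count methylated, count
#' total).
#'
#' @param path File path (tab- or space-delimited, no header).
#' @param sample_id Sample identifier attached to the result.
#' @return A `cpg_counts` data frame (chrom, pos 0-based, k, n) sorted by
#'   (chrom, position).
#' @export
read_methylation_counts <- function(path, sample_id = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning(sprintf("%s: empty methylation count file", path))
    out <- data.frame(chrom = character(), pos = integer(),
                      k = integer(), n = integer(), stringsAsFactors = FALSE)
    return(structure(out, class = c("cpg_counts", "data.frame"),
                     sample_id = sample_id))
  }
  fields <- strsplit(lines, "[ \t]+")
  ncols <- lengths(fields)
  if (length(unique(ncols)) != 1L || !(ncols[1] %in% c(5L, 6L))) {
    bad <- which(ncols != ncols[1])[1] %||% 1L
    stop(sprintf("%s: line %d: expected 5 or 6 columns, found %d",
                 path, bad, ncols[bad]), call. = FALSE)
  }
  mat <- do.call(rbind, fields)
  chrom <- mat[, 1]
  if (ncols[1] == 6L) {           # Bismark coverage, 1-based
    pos <- suppressWarnings(as.integer(mat[, 2])) - 1L
    k <- suppressWarnings(as.integer(mat[, 5]))
    u <- suppressWarnings(as.integer(mat[, 6]))
    n <- k + u
    bad <- which(is.na(pos) | is.na(k) | is.na(u) | k < 0 | u < 0)[1]
  } else {                        # bedGraph dialect, 0-based
    pos <- suppressWarnings(as.integer(mat[, 2]))
    k <- suppressWarnings(as.integer(mat[, 4]))
    n <- suppressWarnings(as.integer(mat[, 5]))
    bad <- which(is.na(pos) | is.na(k) | is.na(n) | k < 0 | n < 0 | k > n)[1]
  }
  if (!is.na(bad)) {
    stop(sprintf("%s: line %d: malformed or negative counts", path, bad),
         call. = FALSE)
  }
  if (any(k > n)) {
    stop(sprintf("%s: line %d: methylated count exceeds total", path,
                 which(k > n)[1]), call. = FALSE)
  }
  out <- data.frame(chrom = chrom, pos = pos, k = k, n = n,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  structure(out, class = c("cpg_counts", "data.frame"), sample_id = sample_id)
}

#' Write per-CpG methylation counts
#'
#' @param x A `cpg_counts` data frame (needs chrom, pos, k, n).
#' @param path Output path.
#' @param dialect `"bismark"` (6-column coverage, 1-based, with methylation
#'   percentage) or `"bedgraph"` (5-column, 0-based).
#' @export
write_methylation_counts <- function(x, path, dialect = c("bismark", "bedgraph")) {
  dialect <- match.arg(dialect)
  if (dialect == "bismark") {
    pct <- ifelse(x$n > 0, 100 * x$k / x$n, 0)
    df <- data.frame(x$chrom, x$pos + 1L, x$pos + 1L,
                     formatC(pct, format = "fg", digits = 6), x$k, x$n - x$k)
  } else {
    df <- data.frame(x$chrom, x$pos, x$pos + 1L, x$k, x$n)
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

strip_gr_models <- function(gr_genes) gr_genes

#' Read gene models from BED12 or GFF3
#'
#' BED12 blocks become exons; GFF3 gene/mRNA/exon features are assembled per
#' gene (for multi-transcript genes the transcript with the most exons is
#' used, ties broken by transcript id). Minus-strand genes are reversed so
#' exon rank 1 is the 5' exon. Genes without any transcript/exon are skipped
#' with a warning.
#'
#' @param path Path to a `.bed` (12-column) or `.gff`/`.gff3` file; format is
#'   chosen by extension, falling back to sniffing the first line.
#' @return A `gene_models` object (0-based half-open internal coordinates).
#' @export
read_gene_models <- function(path) {
  ext <- tolower(tools::file_ext(path))
  fmt <- if (ext %in% c("gff", "gff3")) "gff3"
         else if (ext %in% c("bed", "bed12")) "bed"
         else if (grepl("^##gff", readLines(path, n = 1L))) "gff3" else "bed"
  if (fmt == "bed") read_gene_models_bed12(path) else read_gene_models_gff3(path)
}

read_gene_models_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (is.null(gr$blocks)) stop("BED file has no block (exon) columns", call. = FALSE)
  genes <- data.frame(gene_id = as.character(gr$name),
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      strand = as.character(GenomicRanges::strand(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      stringsAsFactors = FALSE)
  if (any(genes$strand == "*")) stop("BED12 gene without strand", call. = FALSE)
  ex_list <- vector("list", length(gr))
  for (i in seq_along(gr)) {
    bl <- gr$blocks[[i]]                    # block ranges relative to chrom
    st <- GenomicRanges::start(gr)[i] - 1L + IRanges::start(bl) - 1L
    en <- GenomicRanges::start(gr)[i] - 1L + IRanges::end(bl)
    if (any(en > genes$end[i])) {
      stop(sprintf("gene %s: block extends past record end", genes$gene_id[i]),
           call. = FALSE)
    }
    o <- order(st)
    st <- st[o]; en <- en[o]
    if (any(st[-1] < en[-length(en)])) {
      stop(sprintf("gene %s: overlapping blocks", genes$gene_id[i]),
           call. = FALSE)
    }
    rk <- if (genes$strand[i] == "+") seq_along(st) else rev(seq_along(st))
    ex_list[[i]] <- data.frame(gene_id = genes$gene_id[i], rank = rk,
                               start = st, end = en, stringsAsFactors = FALSE)
  }
  genes$n_exons <- vapply(ex_list, nrow, integer(1))
  gene_models(genes, do.call(rbind, ex_list))
}

read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- tolower(as.character(gr$type))
  g <- gr[typ == "gene"]
  tx <- gr[typ %in% c("mrna", "transcript")]
  ex <- gr[typ == "exon"]
  first_chr <- function(x) vapply(x, function(v) as.character(v)[1] %||% NA_character_, character(1))
  tx_parent <- first_chr(tx$Parent)
  ex_parent <- first_chr(ex$Parent)
  genes_rows <- list(); exon_rows <- list()
  for (i in seq_along(g)) {
    gid <- as.character(g$ID[i])
    gname <- gid
    tix <- which(tx_parent == gid)
    if (length(tix) == 0L) {
      warning(sprintf("gene %s has no transcript; skipped", gname))
      next
    }
    # pick the transcript with the most exons (tie -> smaller id)
    tids <- as.character(tx$ID[tix])
    nex <- vapply(tids, function(t) sum(ex_parent == t), integer(1))
    tid <- tids[order(-nex, tids)][1]
    eix <- which(ex_parent == tid)
    if (length(eix) == 0L) {
      warning(sprintf("gene %s has no exons; skipped", gname))
      next
    }
    e <- ex[eix]
    st <- GenomicRanges::start(e) - 1L
    en <- GenomicRanges::end(e)
    o <- order(st); st <- st[o]; en <- en[o]
    if (any(st[-1] < en[-length(en)])) {
      stop(sprintf("gene %s: overlapping exons", gname), call. = FALSE)
    }
    strand <- as.character(GenomicRanges::strand(g))[i]
    rk <- if (strand == "+") seq_along(st) else rev(seq_along(st))
    genes_rows[[length(genes_rows) + 1L]] <- data.frame(
      gene_id = gname, chrom = as.character(GenomicRanges::seqnames(g))[i],
      strand = strand, start = GenomicRanges::start(g)[i] - 1L,
      end = GenomicRanges::end(g)[i], n_exons = length(st),
      stringsAsFactors = FALSE)
    exon_rows[[length(exon_rows) + 1L]] <- data.frame(
      gene_id = gname, rank = rk, start = st, end = en,
      stringsAsFactors = FALSE)
  }
  if (length(genes_rows) == 0L) stop("no usable genes in GFF3", call. = FALSE)
  gene_models(do.call(rbind, genes_rows), do.call(rbind, exon_rows))
}

#' Write gene models as BED12
#'
#' @param genes A `gene_models` object.
#' @param path Output path.
#' @export
write_gene_models_bed12 <- function(genes, path) {
  gdf <- genes$genes
  lines <- character(nrow(gdf))
  for (i in seq_len(nrow(gdf))) {
    ex <- genes$exons[genes$exons$gene_id == gdf$gene_id[i], ]
    ex <- ex[order(ex$start), ]
    sizes <- ex$end - ex$start
    starts <- ex$start - gdf$start[i]
    lines[i] <- paste(gdf$chrom[i], gdf$start[i], gdf$end[i], gdf$gene_id[i],
                      0, gdf$strand[i], gdf$start[i], gdf$end[i], "0,0,0",
                      nrow(ex),
                      paste0(paste(sizes, collapse = ","), ","),
                      paste0(paste(starts, collapse = ","), ","),
                      sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Assign CpGs to genes and intragenic features
#'
#' Labels each CpG with the gene whose span contains it and the exon/intron
#' rank of the containing feature (transcription order). A CpG inside two
#' overlapping genes goes to the gene whose span start is nearest upstream of
#' the site (largest start <= position), ties broken by the lexicographically
#' smaller gene id; `strict = TRUE` drops ambiguous sites instead.
#'
#' @param counts A `cpg_counts` data frame (chrom, pos, ...).
#' @param genes A `gene_models` object.
#' @param strict Drop ambiguously overlapped CpGs instead of resolving them.
#' @return The input with gene_id, feature ("exon"/"intron"/"intergenic") and
#'   rank columns replaced by the assignment.
#' @export
assign_cpgs_to_genes <- function(counts, genes, strict = FALSE) {
  gdf <- genes$genes
  n_in <- nrow(counts)
  counts$gene_id <- NA_character_
  counts$feature <- "intergenic"
  counts$rank <- NA_integer_
  if (n_in == 0L || nrow(gdf) == 0L) return(counts)
  site_gr <- GenomicRanges::GRanges(counts$chrom,
                                    IRanges::IRanges(counts$pos + 1L, counts$pos + 1L))
  gene_gr <- GenomicRanges::GRanges(gdf$chrom,
                                    IRanges::IRanges(gdf$start + 1L, gdf$end))
  hits <- GenomicRanges::findOverlaps(site_gr, gene_gr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  if (length(qh)) {
    # nearest-upstream-start rule with lexicographic tie-break
    ord <- order(qh, -gdf$start[sh], gdf$gene_id[sh])
    qh <- qh[ord]; sh <- sh[ord]
    dup <- duplicated(qh)
    if (strict) {
      ambiguous <- unique(qh[dup])
      keep <- !(qh %in% ambiguous)
      qh <- qh[keep]; sh <- sh[keep]
    } else {
      qh <- qh[!dup]; sh <- sh[!dup]
    }
    counts$gene_id[qh] <- gdf$gene_id[sh]
    # feature + rank within the assigned gene
    ex <- genes$exons
    for (g in unique(gdf$gene_id[sh])) {
      gi <- which(gdf$gene_id == g)
      rows <- qh[gdf$gene_id[sh] == g]
      exg <- ex[ex$gene_id == g, ]
      exg <- exg[order(exg$start), ]
      pos <- counts$pos[rows]
      # exon containment
      eidx <- findInterval(pos, exg$start)
      in_exon <- eidx >= 1L & pos < exg$end[pmax(eidx, 1L)]
      counts$feature[rows] <- ifelse(in_exon, "exon", "intron")
      erank <- ifelse(in_exon, exg$rank[pmax(eidx, 1L)], NA_integer_)
      # intron j (genomic) follows genomic exon j; transcription rank depends
      # on strand
      strand <- gdf$strand[gi]
      irank_genomic <- pmax(eidx, 1L)
      irank <- if (strand == "+") irank_genomic else nrow(exg) - irank_genomic
      counts$rank[rows] <- ifelse(in_exon, erank, irank)
    }
  }
  if (nrow(counts) != n_in) stop("internal: assignment changed row count")
  counts
}

#' Read a sample sheet
#'
#' TSV with header; columns sample_id, assay (wgbs/rnaseq), condition
#' (control/knockdown), stage (rnaseq only), replicate, nonconversion (wgbs
#' only), path. Warns when a wgbs non-conversion rate exceeds 0.01 (typical
#' bisulfite libraries sit near 0.005) and errors above 0.05.
#'
#' @param path TSV path.
#' @param stages Ordered stage labels used to validate rnaseq rows.
#' @return Data frame of class `sample_sheet`.
#' @export
read_sample_sheet <- function(path, stages = DEFAULT_STAGES) {
  ss <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  required <- c("sample_id", "assay", "condition", "replicate")
  miss <- setdiff(required, names(ss))
  if (length(miss)) {
    stop(sprintf("sample sheet missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (!all(ss$assay %in% c("wgbs", "rnaseq"))) {
    stop("assay must be 'wgbs' or 'rnaseq'", call. = FALSE)
  }
  if (!all(ss$condition %in% c("control", "knockdown"))) {
    stop("condition must be 'control' or 'knockdown'", call. = FALSE)
  }
  if (!"stage" %in% names(ss)) ss$stage <- NA_character_
  rna <- ss$assay == "rnaseq"
  if (any(rna & !(ss$stage %in% stages))) {
    stop("rnaseq rows must carry a known stage label", call. = FALSE)
  }
  key <- paste(ss$assay, ss$condition, ifelse(is.na(ss$stage), "", ss$stage),
               ss$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate (assay, condition, stage, replicate) in sample sheet",
         call. = FALSE)
  }
  if (any(ss$assay == "wgbs")) {
    if (!"nonconversion" %in% names(ss) ||
        anyNA(ss$nonconversion[ss$assay == "wgbs"])) {
      stop("wgbs rows must carry a nonconversion rate", call. = FALSE)
    }
    e <- ss$nonconversion[ss$assay == "wgbs"]
    if (any(e < 0 | e > 0.05)) {
      stop("wgbs nonconversion rate outside [0, 0.05]", call. = FALSE)
    }
    if (any(e > 0.01)) {
      warning("wgbs nonconversion rate above 0.01; check library conversion")
    }
  }
  class(ss) <- c("sample_sheet", "data.frame")
  ss
}

#' Write an expression matrix as TSV
#'
#' @param expr An `expr_set` or an integer matrix.
#' @param path Output path; gene ids go in the first column.
#' @export
write_expression_tsv <- function(expr, path) {
  counts <- if (inherits(expr, "expr_set")) expr$counts else expr
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix TSV
#'
#' @param path TSV written by [write_expression_tsv()] (gene_id column plus
#'   one integer column per sample named `SAMPLE__STAGE__CONDITION__REP`).
#' @return An `expr_set` (sample metadata parsed from the column names).
#' @export
read_expression_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$gene_id
  storage.mode(counts) <- "integer"
  parts <- strsplit(colnames(counts), "__", fixed = TRUE)
  if (any(lengths(parts) != 4L)) {
    stop("expression column names must be SAMPLE__STAGE__CONDITION__REP",
         call. = FALSE)
  }
  samples <- data.frame(
    sample_id = vapply(parts, `[`, "", 1L),
    stage = vapply(parts, `[`, "", 2L),
    condition = vapply(parts, `[`, "", 3L),
    replicate = as.integer(vapply(parts, `[`, "", 4L)),
    stringsAsFactors = FALSE)
  structure(list(counts = counts, samples = samples, gene_truth = NULL),
            class = "expr_set")
}

#' Write the simulation ground-truth sidecar
#'
#' @param sim A `gbm_sim` from [simulate_dataset()].
#' @param path Output TSV (per-gene truth: class, base level, depletion,
#'   trajectory, condition effect).
#' @export
write_truth_sidecar <- function(sim, path) {
  gt <- merge(sim$truth$gene_truth,
              sim$expr$gene_truth[c("gene_id", "trajectory", "baseline",
                                    "cond_lfc", "indirect_up")],
              by = "gene_id")
  write.table(gt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
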