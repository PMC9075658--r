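# Per-CpG binomial methylation calling against the bisulfite non-conversion
# rate, gene-body fractional methylation, methylated-gene classification and
# metagene profiles.

#' Upper-tail binomial test for methylation
#'
#' Returns `P(X >= k)` for `X ~ Binomial(n, e)`, the probability of observing
#' at least `k` methylated reads at an unmethylated site whose apparent
#' methylation is entirely bisulfite non-conversion at rate `e`. The tail is
#' inclusive. Vectorized; sites with `n = 0` yield `NA` (no call), never a
#' p-value.
#'
#' @param k Methylated read counts.
#' @param n Total read counts.
#' @param e Non-conversion rate, in (0, 1).
#' @return Raw upper-tail p-values.
#' @export
binomial_call <- function(k, n, e) {
  if (length(e) != 1L || is.na(e) || e <= 0 || e >= 1) {
    stop("nonconversion rate e must be a single value in (0, 1)", call. = FALSE)
  }
  if (any(k < 0 | k > n, na.rm = TRUE)) stop("need 0 <= k <= n", call. = FALSE)
  p <- pbinom(k - 1, n, e, lower.tail = FALSE)
  p[n == 0L] <- NA_real_
  p
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' stable under permutation of the input order.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
adjust_bh <- function(p) {
  if (anyNA(p)) stop("NA p-values not allowed in BH adjustment", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Call methylated CpGs in one sample
#'
#' Tests every covered CpG against the sample's non-conversion rate, adjusts
#' across all covered sites of the sample (BH) and labels sites with adjusted
#' p below `alpha` as methylated CpGs (mCGs). Fractional methylation
#' `f = k/n` is computed for covered sites; uncovered sites are kept with
#' `NA` statistics and are never mCGs.
#'
#' @param counts A `cpg_counts` data frame.
#' @param e Non-conversion rate of the sample (taken from the sample sheet).
#' @param alpha mCG significance threshold on the adjusted p-value.
#' @return A `meth_calls` data frame: counts columns plus f, p_raw, q, is_mcg.
#' @export
call_sample <- function(counts, e, alpha = 0.05) {
  if (missing(e) || is.null(e) || is.na(e)) {
    stop("nonconversion rate e is required (see the sample sheet)", call. = FALSE)
  }
  if (anyDuplicated(counts[c("chrom", "pos")])) {
    stop("duplicate CpG rows in sample counts", call. = FALSE)
  }
  out <- as.data.frame(counts)
  covered <- out$n > 0L
  out$f <- ifelse(covered, out$k / out$n, NA_real_)
  out$p_raw <- NA_real_
  out$p_raw[covered] <- binomial_call(out$k[covered], out$n[covered], e)
  out$q <- NA_real_
  if (any(covered)) out$q[covered] <- adjust_bh(out$p_raw[covered])
  out$is_mcg <- !is.na(out$q) & out$q < alpha
  structure(out, class = c("meth_calls", "data.frame"),
            sample_id = attr(counts, "sample_id"),
            condition = attr(counts, "condition"),
            nonconversion = e, alpha = alpha)
}

#' @export
print.meth_calls <- function(x, ...) {
  cov <- sum(x$n > 0L)
  cat(sprintf("Methylation calls for %s: %d sites (%d covered), %d mCGs (alpha %.3g)\n",
              attr(x, "sample_id") %||% "<sample>", nrow(x), cov,
              sum(x$is_mcg), attr(x, "alpha")))
  invisible(x)
}

#' Union of mCG coordinates across replicates
#'
#' @param call_sets List of `meth_calls` (typically the control replicates).
#' @return Data frame of unique (chrom, pos) called methylated in at least one
#'   replicate; per-replicate mCG counts and the union size in attributes.
#' @export
union_mcgs <- function(call_sets) {
  if (!is.list(call_sets) || length(call_sets) == 0L ||
      inherits(call_sets, "data.frame")) {
    stop("need a non-empty list of call sets", call. = FALSE)
  }
  per_rep <- vapply(call_sets, function(cs) sum(cs$is_mcg), integer(1))
  coords <- do.call(rbind, lapply(call_sets, function(cs) {
    cs[cs$is_mcg, c("chrom", "pos")]
  }))
  u <- unique(coords)
  u <- u[order(u$chrom, u$pos), ]
  rownames(u) <- NULL
  structure(u, per_replicate = per_rep, union_size = nrow(u))
}

# average per-CpG fractional methylation across replicates; sites covered in
# no replicate get NA. weight = "none" is the unweighted mean over replicates
# with coverage; "coverage" pools reads (sum k / sum n).
pool_f <- function(call_sets, weight = c("none", "coverage")) {
  weight <- match.arg(weight)
  if (inherits(call_sets, "data.frame")) call_sets <- list(call_sets)
  ref <- call_sets[[1]]
  for (cs in call_sets[-1]) {
    if (nrow(cs) != nrow(ref) || any(cs$pos != ref$pos) ||
        any(cs$chrom != ref$chrom)) {
      stop("call sets must share an identical site grid", call. = FALSE)
    }
  }
  K <- sapply(call_sets, function(cs) cs$k)
  N <- sapply(call_sets, function(cs) cs$n)
  if (is.null(dim(K))) { K <- matrix(K, ncol = length(call_sets))
                         N <- matrix(N, ncol = length(call_sets)) }
  if (weight == "coverage") {
    tk <- rowSums(K); tn <- rowSums(N)
    f <- ifelse(tn > 0, tk / tn, NA_real_)
  } else {
    F <- ifelse(N > 0, K / N, NA)
    ncov <- rowSums(N > 0)
    f <- ifelse(ncov > 0, rowSums(F, na.rm = TRUE) / ncov, NA_real_)
  }
  f
}

#' Gene-body methylation table
#'
#' Computes per gene the mean gene-body fractional methylation `F` — the
#' unweighted mean of per-CpG fractional methylation over all covered CpGs in
#' the gene body (exons and introns) — together with both methylated-gene
#' classifications used in this analysis tradition: at least one mCG, and
#' `F >= threshold` (threshold 0.02, inclusive, exploiting the bimodal
#' distribution of gene-level methylation). With several replicates the
#' per-CpG fraction is first averaged, unweighted, over replicates with
#' coverage (`weight = "coverage"` pools reads instead). Genes with zero
#' covered CpGs are flagged `no_data` and excluded from classification.
#'
#' @param call_sets One `meth_calls` or a list of them (same site grid, with
#'   gene assignment columns from [assign_cpgs_to_genes()] or the simulator).
#' @param genes A `gene_models` object.
#' @param threshold Gene-body fractional methylation classification cutoff.
#' @param weight Replicate averaging: `"none"` (unweighted) or `"coverage"`.
#' @return A `gene_meth` data frame: gene_id, n_cpgs, n_covered, F, n_mcgs,
#'   methylated_by_mcg, methylated_by_threshold, no_data.
#' @export
gene_body_methylation <- function(call_sets, genes, threshold = 0.02,
                                  weight = c("none", "coverage")) {
  weight <- match.arg(weight)
  if (inherits(call_sets, "data.frame")) call_sets <- list(call_sets)
  ref <- call_sets[[1]]
  if (!"gene_id" %in% names(ref)) {
    stop("call set lacks gene assignment; run assign_cpgs_to_genes() first",
         call. = FALSE)
  }
  f <- pool_f(call_sets, weight)
  any_mcg <- Reduce(`|`, lapply(call_sets, function(cs) cs$is_mcg))
  gdf <- genes$genes
  genic <- !is.na(ref$gene_id)
  gid <- factor(ref$gene_id[genic], levels = gdf$gene_id)
  fg <- f[genic]
  covered <- !is.na(fg)
  n_cpgs <- as.integer(table(gid))
  n_covered <- as.integer(tapply(covered, gid, sum, default = 0L))
  Fm <- as.numeric(tapply(fg[covered], gid[covered], mean, default = NA_real_))
  n_mcgs <- as.integer(tapply(any_mcg[genic], gid, sum, default = 0L))
  no_data <- n_covered == 0L
  out <- data.frame(gene_id = gdf$gene_id, n_cpgs = n_cpgs,
                    n_covered = n_covered, F = Fm, n_mcgs = n_mcgs,
                    methylated_by_mcg = ifelse(no_data, NA, n_mcgs >= 1L),
                    methylated_by_threshold = ifelse(no_data, NA,
                                                     Fm >= threshold),
                    no_data = no_data, stringsAsFactors = FALSE)
  structure(out, class = c("gene_meth", "data.frame"), threshold = threshold)
}

#' @export
print.gene_meth <- function(x, ...) {
  cl <- !x$no_data
  cat(sprintf("Gene-body methylation: %d genes (%d with data); %d methylated by F >= %.3g, %d by >= 1 mCG\n",
              nrow(x), sum(cl), sum(x$methylated_by_threshold[cl]),
              attr(x, "threshold"), sum(x$methylated_by_mcg[cl])))
  invisible(x)
}

#' Metagene methylation profile
#'
#' Mean fractional methylation across the first four and last four exons and
#' introns (transcription order) of methylated genes, each feature divided
#' into equal-width positional bins. The per-bin value is the mean CpG
#' fraction within the bin averaged over genes contributing at least one CpG
#' there. Genes with fewer than eight exons contribute the same feature to
#' both the "first" and "last" slots when ranks coincide.
#'
#' @param call_sets One `meth_calls` or a list (replicate fractions averaged
#'   unweighted, as in [gene_body_methylation()]).
#' @param genes A `gene_models` object.
#' @param n_bins Positional bins per feature (>= 1).
#' @param gene_table Optional precomputed [gene_body_methylation()] result
#'   used to restrict to methylated genes (threshold rule); computed
#'   internally when omitted.
#' @param threshold Classification threshold when `gene_table` is computed.
#' @return A `metagene_profile` data frame: feature (exon/intron), slot
#'   (first/last), rank (1-4), bin, mean_f, n_genes.
#' @export
metagene_profile <- function(call_sets, genes, n_bins = 5L, gene_table = NULL,
                             threshold = 0.02) {
  if (n_bins < 1L) stop("n_bins must be >= 1", call. = FALSE)
  if (inherits(call_sets, "data.frame")) call_sets <- list(call_sets)
  ref <- call_sets[[1]]
  if (is.null(gene_table)) {
    gene_table <- gene_body_methylation(call_sets, genes, threshold = threshold)
  }
  meth_genes <- gene_table$gene_id[!gene_table$no_data &
                                     gene_table$methylated_by_threshold]
  f <- pool_f(call_sets)
  gdf <- genes$genes
  ex <- genes$exons
  keep <- !is.na(ref$gene_id) & ref$gene_id %in% meth_genes & !is.na(f)
  sites <- data.frame(gene_id = ref$gene_id[keep], pos = ref$pos[keep],
                      feature = ref$feature[keep], rank = ref$rank[keep],
                      f = f[keep], stringsAsFactors = FALSE)
  n_exons <- setNames(gdf$n_exons, gdf$gene_id)
  strand <- setNames(gdf$strand, gdf$gene_id)
  ne <- n_exons[sites$gene_id]
  n_feat <- ifelse(sites$feature == "exon", ne, ne - 1L)
  rank_from_end <- n_feat - sites$rank + 1L

  # positional fraction along the feature, in transcription orientation
  feat_bounds <- function(gid, feature, rank) {
    exg <- ex[ex$gene_id == gid, ]
    exg <- exg[order(exg$start), ]
    nex <- nrow(exg)
    plus <- strand[[gid]] == "+"
    if (feature == "exon") {
      j <- if (plus) rank else nex - rank + 1L
      c(exg$start[j], exg$end[j])
    } else {
      j <- if (plus) rank else nex - rank   # genomic intron index
      c(exg$end[j], exg$start[j + 1L])
    }
  }
  rows <- list()
  for (slot in c("first", "last")) {
    rk <- if (slot == "first") sites$rank else rank_from_end
    sel <- which(!is.na(rk) & rk >= 1L & rk <= 4L)
    if (!length(sel)) next
    sub <- sites[sel, ]
    sub$slot_rank <- rk[sel]
    key <- paste(sub$gene_id, sub$feature, sub$rank)
    bounds <- lapply(unique(key), function(kk) {
      r <- sub[match(kk, key), ]
      feat_bounds(r$gene_id, r$feature, r$rank)
    })
    names(bounds) <- unique(key)
    b <- do.call(rbind, bounds[key])
    rel <- (sub$pos - b[, 1] + 0.5) / (b[, 2] - b[, 1])
    if (any(strand[sub$gene_id] == "-")) {
      neg <- strand[sub$gene_id] == "-"
      rel[neg] <- 1 - rel[neg]
    }
    sub$bin <- pmin(n_bins, pmax(1L, ceiling(rel * n_bins)))
    # per-gene mean within (feature, slot_rank, bin), then across genes
    agg_gene <- stats::aggregate(
      f ~ gene_id + feature + slot_rank + bin, data = sub, FUN = mean)
    agg <- stats::aggregate(f ~ feature + slot_rank + bin, data = agg_gene,
                            FUN = mean)
    cnt <- stats::aggregate(f ~ feature + slot_rank + bin, data = agg_gene,
                            FUN = length)
    agg$n_genes <- cnt$f
    agg$slot <- slot
    rows[[slot]] <- agg
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(feature = character(), slot_rank = integer(),
                      bin = integer(), f = numeric(), n_genes = integer(),
                      slot = character(), stringsAsFactors = FALSE)
  }
  names(out)[names(out) == "slot_rank"] <- "rank"
  names(out)[names(out) == "f"] <- "mean_f"
  out <- out[c("feature", "slot", "rank", "bin", "mean_f", "n_genes")]
  out <- out[order(out$slot, out$feature, out$rank, out$bin), ]
  rownames(out) <- NULL
  structure(out, class = c("metagene_profile", "data.frame"), n_bins = n_bins)
}
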