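# Integration of methylome and transcriptome results: DEG x methylation
# contingency tables with exact tests, the relative-GBM-change vs log2FC
# rank correlation, Welch comparisons of group distributions, and z-scored
# hierarchical clustering of DEG trajectories.

#' Classify DEGs by methylation status
#'
#' Labels each differentially expressed gene methylated/unmethylated by the
#' gene-body threshold classifier; DEGs without usable gene-body data go to
#' an unclassifiable bucket. Also emits the union of DEGs across stages
#' (differential expression in at least one stage).
#'
#' @param de_list Named list of `de_result` (one per stage) or a single
#'   `de_result`.
#' @param gene_meth A `gene_meth` table from [gene_body_methylation()].
#' @return A `deg_classes` list: `per_stage` (data frame per stage: gene_id,
#'   direction, meth_class), `union` (gene_id, meth_class, directions seen)
#'   and counts (`n_mdeg`, `n_udeg`, `n_unclassifiable`).
#' @export
classify_degs <- function(de_list, gene_meth) {
  if (inherits(de_list, "de_result")) {
    de_list <- setNames(list(de_list), attr(de_list, "stage"))
  }
  lookup <- setNames(
    ifelse(gene_meth$no_data, NA,
           ifelse(gene_meth$methylated_by_threshold, "methylated",
                  "unmethylated")),
    gene_meth$gene_id)
  per_stage <- lapply(de_list, function(de) {
    degs <- de[de$is_deg, c("gene_id", "direction", "log2FC")]
    cls <- lookup[degs$gene_id]
    cls[!(degs$gene_id %in% names(lookup))] <- NA
    degs$meth_class <- ifelse(is.na(cls), "unclassifiable", cls)
    rownames(degs) <- NULL
    degs
  })
  all_degs <- do.call(rbind, lapply(names(per_stage), function(s) {
    if (nrow(per_stage[[s]]) == 0L) return(NULL)
    cbind(per_stage[[s]], stage = s, stringsAsFactors = FALSE)
  }))
  if (is.null(all_degs)) {
    union_df <- data.frame(gene_id = character(), meth_class = character(),
                           stringsAsFactors = FALSE)
  } else {
    union_df <- unique(all_degs[c("gene_id", "meth_class")])
    union_df <- union_df[order(union_df$gene_id), ]
    rownames(union_df) <- NULL
  }
  structure(list(per_stage = per_stage, union = union_df,
                 n_mdeg = sum(union_df$meth_class == "methylated"),
                 n_udeg = sum(union_df$meth_class == "unmethylated"),
                 n_unclassifiable = sum(union_df$meth_class == "unclassifiable")),
            class = "deg_classes")
}

#' @export
print.deg_classes <- function(x, ...) {
  cat(sprintf("DEG classification: %d union DEGs (%d methylated, %d unmethylated, %d unclassifiable)\n",
              nrow(x$union), x$n_mdeg, x$n_udeg, x$n_unclassifiable))
  invisible(x)
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value by summation of hypergeometric probabilities not
#' exceeding the observed table's probability (the standard probability-mass
#' rule). The odds ratio is the sample cross-product ratio `ad/bc`; a
#' continuity-corrected ratio (0.5 added to every cell) is reported
#' separately when any cell is zero.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return List of class `fisher2x2`: `p`, `odds_ratio`,
#'   `odds_ratio_continuity` (NA unless a zero cell), `table`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2L)) stop("need a 2x2 table", call. = FALSE)
  if (any(tab < 0) || any(tab != floor(tab))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(tab) == 0) stop("table total is zero", call. = FALSE)
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  p <- min(1, fisher_p2(a, b, c, d))
  or <- (a * d) / (b * c)
  or_cc <- if (any(tab == 0)) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
           else NA_real_
  structure(list(p = p, odds_ratio = or, odds_ratio_continuity = or_cc,
                 table = tab), class = "fisher2x2")
}

#' @export
print.fisher2x2 <- function(x, ...) {
  cat(sprintf("Fisher exact 2x2: p = %.4g, odds ratio = %.4g\n",
              x$p, x$odds_ratio))
  invisible(x)
}

#' Build DEG-direction x methylation contingency tables for a stage
#'
#' @param deg_classes A `deg_classes` object.
#' @param stage Stage label.
#' @param background Optional `gene_meth` table supplying the genome
#'   background (all classified genes) as an extra margin.
#' @return List with the down/up 2x2 tables (each direction vs the background
#'   of classified genes), their Fisher results, and the raw direction x
#'   class table.
#' @export
deg_meth_tables <- function(deg_classes, stage, background = NULL) {
  df <- deg_classes$per_stage[[stage]]
  if (is.null(df)) stop(sprintf("no DE results for stage '%s'", stage),
                        call. = FALSE)
  cls <- df$meth_class[df$meth_class != "unclassifiable"]
  dir <- df$direction[df$meth_class != "unclassifiable"]
  ct <- table(factor(dir, c("down", "up")),
              factor(cls, c("methylated", "unmethylated")))
  res <- list(direction_by_class = ct)
  # direction-vs-class association: down/up x methylated/unmethylated; a
  # stage without classified DEGs has no table to test
  res$fisher_direction <- if (sum(ct) > 0) {
    fisher_exact_2x2(matrix(as.integer(ct), 2L))
  } else {
    structure(list(p = NA_real_, odds_ratio = NA_real_,
                   odds_ratio_continuity = NA_real_, table = ct),
              class = "fisher2x2")
  }
  if (!is.null(background)) {
    bk <- background[!background$no_data, ]
    bg <- c(methylated = sum(bk$methylated_by_threshold),
            unmethylated = sum(!bk$methylated_by_threshold))
    res$background <- bg
    res$fisher_down_vs_background <- fisher_exact_2x2(
      rbind(ct["down", ], bg - ct["down", ]))
    res$fisher_up_vs_background <- fisher_exact_2x2(
      rbind(ct["up", ], bg - ct["up", ]))
  }
  res
}

#' Rank correlation of relative GBM change with expression change
#'
#' Spearman correlation (average-rank ties) between per-gene relative
#' gene-body methylation change and the stage's log2 fold change, over
#' methylated genes with both quantities defined. P-value by the
#' t-approximation, exact for n <= 10 (no ties).
#'
#' @param rg Output of [gene_relative_gbm_change()].
#' @param de A `de_result` for the stage of interest.
#' @param gene_meth `gene_meth` table used to restrict to methylated genes
#'   (threshold rule).
#' @return List: `rho`, `p`, `n`; `rho`/`p` are NA (flagged) when n < 3.
#' @export
gbm_expression_correlation <- function(rg, de, gene_meth) {
  meth <- gene_meth$gene_id[!gene_meth$no_data &
                              gene_meth$methylated_by_threshold]
  m <- merge(rg[rg$gene_id %in% meth & !is.na(rg$rel_gbm_change),
                c("gene_id", "rel_gbm_change")],
             de[, c("gene_id", "log2FC")], by = "gene_id")
  n <- nrow(m)
  if (n < 3L) {
    return(list(rho = NA_real_, p = NA_real_, n = n, flagged = TRUE))
  }
  ct <- suppressWarnings(cor.test(m$rel_gbm_change, m$log2FC,
                                  method = "spearman", exact = n <= 10L))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n, flagged = FALSE)
}

#' Welch's t-test (unequal variances)
#'
#' Two-tailed t-test assuming unequal variance, accepting raw values or
#' (mean, sd, n) summaries. Degrees of freedom by Welch-Satterthwaite. Groups
#' of fewer than two observations are an error; two groups with zero variance
#' and equal means return t = 0, p = 1 by convention.
#'
#' @param a,b Numeric vectors, or lists/named vectors with `mean`, `sd`, `n`.
#' @return List of class `welch_t`: `t`, `df`, `p`, group summaries.
#' @export
welch_t <- function(a, b) {
  summarize <- function(x, nm) {
    if (all(c("mean", "sd", "n") %in% names(x))) {
      list(mean = unname(x[["mean"]]), sd = unname(x[["sd"]]),
           n = unname(x[["n"]]))
    } else if (is.numeric(x)) {
      list(mean = mean(x), sd = if (length(x) > 1L) sd(x) else NA_real_,
           n = length(x))
    } else {
      stop(sprintf("group %s: need >= 2 raw values or mean/sd/n summaries", nm),
           call. = FALSE)
    }
  }
  ga <- summarize(a, "A"); gb <- summarize(b, "B")
  if (ga$n < 2L || gb$n < 2L) stop("each group needs n >= 2", call. = FALSE)
  va <- ga$sd^2 / ga$n; vb <- gb$sd^2 / gb$n
  if (va + vb == 0) {
    t <- if (ga$mean == gb$mean) 0 else sign(ga$mean - gb$mean) * Inf
    df <- ga$n + gb$n - 2
    p <- if (t == 0) 1 else 0
  } else {
    t <- (ga$mean - gb$mean) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (ga$n - 1) + vb^2 / (gb$n - 1))
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(t = t, df = df, p = p, group_a = ga, group_b = gb),
            class = "welch_t")
}

#' @export
print.welch_t <- function(x, ...) {
  cat(sprintf("Welch t = %.4g, df = %.3g, two-sided p = %.4g\n",
              x$t, x$df, x$p))
  invisible(x)
}

#' Z-score and hierarchically cluster expression trajectories
#'
#' Each gene's vector of per-(stage x condition) mean normalized expression
#' is z-scored across its own entries (constant vectors become zero vectors),
#' then clustered by agglomerative hierarchical clustering on Euclidean
#' distance with average linkage. Rows are pre-sorted by gene id so the leaf
#' order is deterministic; the tree is cut at `k` clusters.
#'
#' @param traj Numeric matrix, genes x (stage x condition) columns, rownames
#'   = gene ids.
#' @param k Number of clusters.
#' @return List of class `traj_clusters`: `clusters` (named integer vector),
#'   `order` (leaf order), `zmat` (z-scored matrix), `hclust`.
#' @export
zscore_cluster <- function(traj, k = 3L) {
  if (nrow(traj) < k) stop("fewer genes than clusters requested", call. = FALSE)
  traj <- traj[order(rownames(traj)), , drop = FALSE]
  mu <- rowMeans(traj)
  s <- apply(traj, 1L, sd)
  z <- (traj - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  hc <- hclust(dist(z), method = "average")
  cl <- cutree(hc, k = k)
  structure(list(clusters = cl, order = hc$order, zmat = z, hclust = hc),
            class = "traj_clusters")
}

#' Per-gene stage x condition trajectory matrix
#'
#' @param expr An `expr_set`.
#' @param sf Size factors (computed when omitted).
#' @param gene_ids Restrict to these genes (default all).
#' @return Matrix genes x (stage_condition) of mean normalized counts.
#' @export
trajectory_matrix <- function(expr, sf = NULL, gene_ids = NULL) {
  if (is.null(sf)) sf <- size_factors(expr$counts)
  q <- norm_counts(expr$counts, sf)
  samp <- expr$samples
  cols <- unique(samp[c("stage", "condition")])
  M <- sapply(seq_len(nrow(cols)), function(i) {
    sel <- samp$stage == cols$stage[i] & samp$condition == cols$condition[i]
    rowMeans(q[, sel, drop = FALSE])
  })
  colnames(M) <- paste(cols$stage, cols$condition, sep = "_")
  if (!is.null(gene_ids)) M <- M[rownames(M) %in% gene_ids, , drop = FALSE]
  M
}

#' Assemble the full integration report
#'
#' Runs the headline integration statistics for every stage: DEG-direction x
#' methylation contingency tables with exact tests (plus the classified-gene
#' background), the Spearman correlation of relative GBM change with log2
#' fold change over methylated genes, Welch comparisons of mDEG/uDEG
#' expression between conditions, DEG counts, and z-score trajectory
#' clustering of the mDEGs.
#'
#' @param de_list Named list of per-stage `de_result`.
#' @param gene_meth A `gene_meth` table.
#' @param rg Output of [gene_relative_gbm_change()].
#' @param expr The `expr_set` the DE results came from.
#' @param sf Size factors used for normalization.
#' @param cluster_k Clusters for the trajectory heatmap.
#' @return An `integration_report` list.
#' @export
integration_report <- function(de_list, gene_meth, rg, expr, sf = NULL,
                               cluster_k = 3L) {
  if (is.null(sf)) sf <- size_factors(expr$counts)
  dc <- classify_degs(de_list, gene_meth)
  q <- norm_counts(expr$counts, sf)
  samp <- expr$samples
  per_stage <- lapply(names(de_list), function(s) {
    tabs <- deg_meth_tables(dc, s, background = gene_meth)
    corr <- gbm_expression_correlation(rg, de_list[[s]], gene_meth)
    # Welch comparison of mDEG expression (log2 normalized + 1) between
    # conditions at this stage
    stage_sel <- samp$stage == s
    welch_of <- function(ids) {
      ids <- intersect(ids, rownames(q))
      if (length(ids) < 2L) return(NULL)
      m <- log2(q[ids, stage_sel, drop = FALSE] + 1)
      ctrl <- rowMeans(m[, samp$condition[stage_sel] == "control", drop = FALSE])
      kd <- rowMeans(m[, samp$condition[stage_sel] == "knockdown", drop = FALSE])
      welch_t(ctrl, kd)
    }
    st_degs <- dc$per_stage[[s]]
    list(stage = s, tables = tabs, correlation = corr,
         n_degs = nrow(st_degs),
         welch_mdeg = welch_of(st_degs$gene_id[st_degs$meth_class == "methylated"]),
         welch_udeg = welch_of(st_degs$gene_id[st_degs$meth_class == "unmethylated"]))
  })
  names(per_stage) <- names(de_list)
  mdeg_ids <- dc$union$gene_id[dc$union$meth_class == "methylated"]
  clusters <- NULL
  if (length(mdeg_ids) >= cluster_k) {
    clusters <- zscore_cluster(trajectory_matrix(expr, sf, mdeg_ids),
                               k = cluster_k)
  }
  structure(list(per_stage = per_stage, deg_classes = dc, clusters = clusters,
                 n_mdeg = dc$n_mdeg, n_udeg = dc$n_udeg,
                 n_union_degs = nrow(dc$union)),
            class = "integration_report")
}

#' @export
print.integration_report <- function(x, ...) {
  cat("Methylome-transcriptome integration report\n")
  cat(sprintf("  union DEGs: %d (%d methylated / %d unmethylated)\n",
              x$n_union_degs, x$n_mdeg, x$n_udeg))
  for (s in names(x$per_stage)) {
    ps <- x$per_stage[[s]]
    corr <- ps$correlation
    cat(sprintf("  %s: %d DEGs; direction x methylation Fisher p = %.3g; rho(GBM change, log2FC) = %.3f (p = %.3g, n = %d)\n",
                s, ps$n_degs, ps$tables$fisher_direction$p,
                corr$rho %||% NA, corr$p %||% NA, corr$n))
  }
  invisible(x)
}
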