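# Simplified negative-binomial differential expression: low-expression
# filter, median-of-ratios size factors, a per-stage two-group NB Wald test
# with trend-shrunk method-of-moments dispersions, and the 2-fold
# stage-transition analysis. This is a deliberately lean engine following
# the standard RNA-seq conventions (count filter at max 10, FDR 0.1) without
# the full Cox-Reid / empirical-Bayes machinery of the large packages.

#' Filter lowly expressed genes
#'
#' Removes genes whose maximum count across all samples is at or below the
#' threshold (a gene whose maximum read value is 10 is removed; 11 is kept).
#'
#' @param counts Integer matrix (genes x samples) or `expr_set`.
#' @param threshold Maximum-count cutoff (genes with `max <= threshold` drop).
#' @return Same type as the input, with the filtered matrix; the number of
#'   removed genes is reported in attribute `n_removed` (and a message).
#' @export
filter_low_expression <- function(counts, threshold = 10) {
  es <- NULL
  if (inherits(counts, "expr_set")) { es <- counts; counts <- es$counts }
  if (any(counts != floor(counts)) || any(counts < 0)) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  keep <- apply(counts, 1L, max) > threshold
  n_removed <- sum(!keep)
  if (all(!keep)) warning("all genes removed by the low-expression filter")
  message(sprintf("filter_low_expression: removed %d of %d genes (max count <= %g)",
                  n_removed, length(keep), threshold))
  out <- counts[keep, , drop = FALSE]
  if (!is.null(es)) {
    es$counts <- out
    if (!is.null(es$gene_truth)) {
      es$gene_truth <- es$gene_truth[keep, , drop = FALSE]
    }
    return(structure(es, n_removed = n_removed))
  }
  structure(out, n_removed = n_removed)
}

#' Median-of-ratios size factors
#'
#' Per gene, the geometric mean of its counts across samples (genes with any
#' zero excluded); per sample, the median over genes of count / geometric
#' mean; factors then rescaled to geometric mean 1.
#'
#' @param counts Integer matrix (genes x samples) or `expr_set`.
#' @return Named numeric vector of positive size factors (class
#'   `size_factors`).
#' @export
size_factors <- function(counts) {
  if (inherits(counts, "expr_set")) counts <- counts$counts
  if (ncol(counts) < 2L) stop("need >= 2 samples", call. = FALSE)
  all_pos <- rowSums(counts == 0) == 0L
  if (!any(all_pos)) {
    stop("no gene has nonzero counts in every sample; consider a pseudo-reference",
         call. = FALSE)
  }
  lc <- log(counts[all_pos, , drop = FALSE])
  geo <- rowMeans(lc)
  sf <- apply(lc, 2L, function(x) exp(median(x - geo)))
  sf <- sf / exp(mean(log(sf)))
  structure(sf, class = "size_factors")
}

norm_counts <- function(counts, sf) sweep(counts, 2L, sf, "/")

#' Per-stage two-group NB Wald differential expression test
#'
#' For the chosen stage, normalized counts are modelled as negative binomial.
#' Gene-wise dispersions come from a method-of-moments estimate on normalized
#' counts (floored at 1e-8), shrunk half-way toward a fitted mean-dispersion
#' trend `a0 + a1/mean`; the condition effect is a Wald test on the log ratio
#' of condition means with the NB delta-method variance. BH across tested
#' genes; `is_deg` at adjusted p < `fdr`.
#'
#' @param expr An `expr_set` (typically already filtered with
#'   [filter_low_expression()]).
#' @param stage Stage label to test.
#' @param sf Size factors for all samples of the matrix (computed on the full
#'   matrix when omitted).
#' @param fdr DEG threshold on the adjusted p-value.
#' @param shrink_weight Weight of the trend in the dispersion blend.
#' @return A `de_result` data frame: gene_id, baseMean, log2FC (knockdown vs
#'   control), lfcSE, stat, p, q, is_deg, direction.
#' @export
de_test <- function(expr, stage, sf = NULL, fdr = 0.1, shrink_weight = 0.5) {
  stopifnot(inherits(expr, "expr_set"))
  samp <- expr$samples
  if (!stage %in% samp$stage) stop(sprintf("unknown stage '%s'", stage),
                                   call. = FALSE)
  if (is.null(sf)) sf <- size_factors(expr$counts)
  sel <- samp$stage == stage
  cond <- samp$condition[sel]
  if (length(unique(cond)) < 2L) {
    stop(sprintf("stage '%s' lacks one of the conditions", stage), call. = FALSE)
  }
  if (min(table(cond)) < 2L) {
    stop(sprintf("stage '%s' needs >= 2 replicates per condition", stage),
         call. = FALSE)
  }
  cnt <- expr$counts[, sel, drop = FALSE]
  sfs <- sf[sel]
  q <- norm_counts(cnt, sfs)
  is_c <- cond == "control"; is_r <- !is_c
  m_c <- sum(is_c); m_r <- sum(is_r)
  mu_c <- rowMeans(q[, is_c, drop = FALSE])
  mu_r <- rowMeans(q[, is_r, drop = FALSE])
  baseMean <- rowMeans(q)

  # method-of-moments dispersion on normalized counts, pooled within condition
  vc <- apply(q[, is_c, drop = FALSE], 1L, var)
  vr <- apply(q[, is_r, drop = FALSE], 1L, var)
  pooled_var <- ((m_c - 1) * vc + (m_r - 1) * vr) / (m_c + m_r - 2)
  # Var(K/s) = mu/s + alpha mu^2; use the stage-mean of 1/s as the scale term
  inv_s <- mean(1 / sfs)
  mu_bar <- (m_c * mu_c + m_r * mu_r) / (m_c + m_r)
  alpha_raw <- pmax(1e-8, (pooled_var - mu_bar * inv_s) / mu_bar^2)
  # parametric trend alpha = a0 + a1/mu fitted by least squares on genes with
  # informative raw estimates, coefficients clamped non-negative
  use <- is.finite(alpha_raw) & mu_bar > 0 & alpha_raw > 1e-8
  if (sum(use) >= 10L) {
    fit <- stats::lm.fit(cbind(1, 1 / mu_bar[use]), alpha_raw[use])
    a <- pmax(fit$coefficients, 0)
  } else {
    a <- c(mean(alpha_raw[mu_bar > 0]), 0)
  }
  alpha_trend <- pmax(1e-8, a[1] + a[2] / pmax(mu_bar, 1e-8))
  alpha <- shrink_weight * alpha_trend + (1 - shrink_weight) * alpha_raw

  # Wald on beta = log(mu_r / mu_c); zero condition means are floored at half
  # a normalized read so the statistic stays finite
  floor_c <- 0.5 * inv_s / m_c
  mu_c_s <- pmax(mu_c, floor_c)
  mu_r_s <- pmax(mu_r, floor_c)
  beta <- log(mu_r_s) - log(mu_c_s)
  var_logmean <- function(mu, idx, m) {
    # Var(mean of K_j/s_j) = (1/m^2) sum(mu/s_j + alpha mu^2)
    v <- outer(mu, rep(1, m))
    sterm <- matrix(1 / sfs[idx], nrow = length(mu), ncol = m, byrow = TRUE)
    rowSums(v * sterm + alpha * v^2) / m^2 / mu^2
  }
  vl <- var_logmean(mu_c_s, which(is_c), m_c) +
    var_logmean(mu_r_s, which(is_r), m_r)
  se <- sqrt(vl)
  z <- beta / se
  both_zero <- mu_c == 0 & mu_r == 0
  z[both_zero] <- 0
  pval <- 2 * pnorm(-abs(z))
  qval <- adjust_bh(pval)
  is_deg <- qval < fdr
  out <- data.frame(gene_id = rownames(cnt), baseMean = baseMean,
                    log2FC = beta / log(2), lfcSE = se / log(2), stat = z,
                    p = pval, q = qval, is_deg = is_deg,
                    direction = ifelse(is_deg, ifelse(beta > 0, "up", "down"),
                                       NA_character_),
                    stringsAsFactors = FALSE)
  structure(out, class = c("de_result", "data.frame"), stage = stage,
            fdr = fdr)
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("Differential expression at stage '%s': %d genes tested, %d DEGs at FDR %.2g (%d up / %d down)\n",
              attr(x, "stage"), nrow(x), sum(x$is_deg), attr(x, "fdr"),
              sum(x$is_deg & x$direction == "up", na.rm = TRUE),
              sum(x$is_deg & x$direction == "down", na.rm = TRUE)))
  invisible(x)
}

#' Run the DE test at every stage
#'
#' @param expr An `expr_set`.
#' @param sf Size factors (full matrix; computed when omitted).
#' @param fdr DEG threshold.
#' @return Named list of `de_result`, one per stage in trajectory order.
#' @export
de_all_stages <- function(expr, sf = NULL, fdr = 0.1) {
  if (is.null(sf)) sf <- size_factors(expr$counts)
  stages <- unique(expr$samples$stage)
  setNames(lapply(stages, function(s) de_test(expr, s, sf = sf, fdr = fdr)),
           stages)
}

#' Two-fold transition analysis
#'
#' For each consecutive stage pair, labels genes whose (normalized mean +
#' pseudocount) ratio is at least `fold` as up and at most `1/fold` as down
#' (a ratio of exactly 2 counts as 2-fold). Computed per condition, with the
#' cross-condition comparison sets (changed in knockdown only, control only,
#' or both).
#'
#' @param expr An `expr_set`.
#' @param sf Size factors (computed when omitted).
#' @param fold Fold-change cutoff.
#' @param pseudocount Added to normalized stage means before the ratio.
#' @return A `transition_sets` list: per transition and direction, the gene
#'   sets per condition plus both/knockdown-only/control-only.
#' @export
transition_fold_changes <- function(expr, sf = NULL, fold = 2, pseudocount = 1) {
  stopifnot(inherits(expr, "expr_set"))
  samp <- expr$samples
  stages <- unique(samp$stage)
  if (length(stages) < 2L) stop("need >= 2 ordered stages", call. = FALSE)
  if (is.null(sf)) sf <- size_factors(expr$counts)
  q <- norm_counts(expr$counts, sf)
  conds <- unique(samp$condition)
  stage_means <- lapply(setNames(conds, conds), function(cd) {
    sapply(setNames(stages, stages), function(st) {
      rowMeans(q[, samp$stage == st & samp$condition == cd, drop = FALSE])
    })
  })
  out <- list()
  for (t in seq_len(length(stages) - 1L)) {
    trans <- sprintf("%s_to_%s", stages[t], stages[t + 1L])
    per_cond <- lapply(stage_means, function(M) {
      ratio <- (M[, t + 1L] + pseudocount) / (M[, t] + pseudocount)
      list(up = rownames(q)[ratio >= fold],
           down = rownames(q)[ratio <= 1 / fold])
    })
    cmp <- lapply(c(up = "up", down = "down"), function(dir) {
      kd <- per_cond$knockdown[[dir]] %||% character()
      ct <- per_cond$control[[dir]] %||% character()
      list(both = intersect(kd, ct),
           knockdown_only = setdiff(kd, ct),
           control_only = setdiff(ct, kd))
    })
    out[[trans]] <- list(per_condition = per_cond, comparison = cmp)
  }
  structure(out, class = "transition_sets", fold = fold)
}

#' @export
print.transition_sets <- function(x, ...) {
  cat(sprintf("%g-fold stage-transition sets:\n", attr(x, "fold")))
  for (tr in names(x)) {
    pc <- x[[tr]]$per_condition
    cat(sprintf("  %s:", tr))
    for (cd in names(pc)) {
      cat(sprintf(" %s up %d / down %d;", cd, length(pc[[cd]]$up),
                  length(pc[[cd]]$down)))
    }
    cat("\n")
  }
  invisible(x)
}
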