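# Two-group per-CpG differential methylation testing, per-mCG depletion
# statistics and per-gene relative gene-body methylation change.
#
# Only CpG sites methylated in at least one control sample are retained. Per
# site the test is a beta-binomial Wald on the difference of (empirical)
# logit-proportions, with a common method-of-moments dispersion; degenerate
# sites (a single covered replicate on either side, or zero estimated
# dispersion) fall back to a two-sided Fisher exact test on pooled counts.

#' Retain sites methylated in at least one control sample
#'
#' @param control_calls List of `meth_calls` for the control replicates.
#' @param counts_list Named list of `cpg_counts` for all samples (both
#'   conditions) on the same site grid.
#' @param conditions Condition label per element of `counts_list`; defaults to
#'   the `condition` attribute of each table.
#' @return A `retained_sites` list: `sites` (coordinates plus gene
#'   assignment), count matrices `K`/`N` (sites x samples) and the condition
#'   vector. Zero-coverage entries are kept (n = 0 means missing).
#' @export
retain_sites <- function(control_calls, counts_list, conditions = NULL) {
  u <- union_mcgs(control_calls)
  if (nrow(u) == 0L) {
    stop("no methylated CpGs in any control sample; inputs look null",
         call. = FALSE)
  }
  if (is.null(conditions)) {
    conditions <- vapply(counts_list, function(x) attr(x, "condition") %||%
                           NA_character_, character(1))
  }
  if (anyNA(conditions) || !all(conditions %in% c("control", "knockdown"))) {
    stop("each counts table needs a condition of control/knockdown",
         call. = FALSE)
  }
  ref <- counts_list[[1]]
  key_ref <- paste(ref$chrom, ref$pos)
  idx <- match(paste(u$chrom, u$pos), key_ref)
  if (anyNA(idx)) stop("retained coordinates missing from count tables",
                       call. = FALSE)
  K <- sapply(counts_list, function(x) x$k[idx])
  N <- sapply(counts_list, function(x) x$n[idx])
  if (is.null(dim(K))) { K <- matrix(K, ncol = length(counts_list))
                         N <- matrix(N, ncol = length(counts_list)) }
  colnames(K) <- colnames(N) <- names(counts_list)
  sites <- ref[idx, intersect(c("chrom", "pos", "gene_id", "feature", "rank"),
                              names(ref))]
  rownames(sites) <- NULL
  structure(list(sites = sites, K = K, N = N, conditions = conditions),
            class = "retained_sites")
}

#' Two-sided Fisher exact p for a 2x2 count table (internal vectorized core)
#' @noRd
fisher_p2 <- function(a, b, c, d) {
  # table rows (a, b) / (c, d); conditional on margins, a ~ hypergeometric
  m <- a + b; n2 <- c + d; kk <- a + c
  lo <- max(0L, kk - n2); hi <- min(kk, m)
  supp <- lo:hi
  pr <- dhyper(supp, m, n2, kk)
  p_obs <- dhyper(a, m, n2, kk)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

#' Per-CpG differential methylation test
#'
#' @param retained A `retained_sites` object from [retain_sites()].
#' @param fdr FDR threshold for the DM call (adjusted p < `fdr`).
#' @return A `dm_result` data frame, one row per retained site: pooled
#'   condition fractions `f_control`/`f_knockdown` (coverage-weighted within
#'   condition), `delta`, relative change `rel_change` (control denominator),
#'   `stat`, `p`, `q`, `is_dm`, `direction`, `method` (wald/fisher) and
#'   `testable`. Sites covered in only one condition are untestable and are
#'   excluded from the BH universe.
#' @export
dm_test <- function(retained, fdr = 0.1) {
  stopifnot(inherits(retained, "retained_sites"))
  K <- retained$K; N <- retained$N
  is_c <- retained$conditions == "control"
  is_r <- !is_c
  ns <- nrow(K)
  Kc <- K[, is_c, drop = FALSE]; Nc <- N[, is_c, drop = FALSE]
  Kr <- K[, is_r, drop = FALSE]; Nr <- N[, is_r, drop = FALSE]
  mc <- rowSums(Nc > 0L); mr <- rowSums(Nr > 0L)
  sKc <- rowSums(Kc); sNc <- rowSums(Nc)
  sKr <- rowSums(Kr); sNr <- rowSums(Nr)
  f_c <- ifelse(sNc > 0, sKc / sNc, NA_real_)
  f_r <- ifelse(sNr > 0, sKr / sNr, NA_real_)
  testable <- mc >= 1L & mr >= 1L

  p <- rep(NA_real_, ns); stat <- rep(NA_real_, ns)
  method <- rep(NA_character_, ns)

  # method-of-moments common dispersion across covered replicates
  phi <- rep(0, ns)
  both_multi <- testable & mc >= 2L & mr >= 2L
  if (any(both_multi)) {
    i <- which(both_multi)
    resid2 <- function(Ki, Ni, pi) {
      e <- Ni * pi
      v <- Ni * pi * (1 - pi)
      r <- (Ki - e)^2 / v
      r[Ni == 0 | v == 0] <- 0
      rowSums(r, na.rm = TRUE)
    }
    X2 <- resid2(Kc[i, , drop = FALSE], Nc[i, , drop = FALSE], f_c[i]) +
      resid2(Kr[i, , drop = FALSE], Nr[i, , drop = FALSE], f_r[i])
    df <- (mc[i] - 1L) + (mr[i] - 1L)
    nbar <- (rowSums(Nc[i, , drop = FALSE]) + rowSums(Nr[i, , drop = FALSE])) /
      (mc[i] + mr[i])
    phi[i] <- pmax(0, (X2 / df - 1) / pmax(nbar - 1, 1e-8))
  }

  wald <- which(both_multi & phi > 0)
  if (length(wald)) {
    i <- wald
    # empirical logits with 0.5-count smoothing keep 0/1 proportions finite
    pc <- (sKc[i] + 0.5) / (sNc[i] + 1)
    pr <- (sKr[i] + 0.5) / (sNr[i] + 1)
    nbar_c <- sNc[i] / mc[i]; nbar_r <- sNr[i] / mr[i]
    vc <- pc * (1 - pc) * (1 + (nbar_c - 1) * phi[i]) / sNc[i]
    vr <- pr * (1 - pr) * (1 + (nbar_r - 1) * phi[i]) / sNr[i]
    vlc <- vc / (pc * (1 - pc))^2
    vlr <- vr / (pr * (1 - pr))^2
    z <- (log(pr / (1 - pr)) - log(pc / (1 - pc))) / sqrt(vlc + vlr)
    stat[i] <- z
    p[i] <- 2 * pnorm(-abs(z))
    method[i] <- "wald"
  }
  fish <- which(testable & !(seq_len(ns) %in% wald))
  for (i in fish) {
    p[i] <- min(1, fisher_p2(sKc[i], sNc[i] - sKc[i], sKr[i], sNr[i] - sKr[i]))
    stat[i] <- f_r[i] - f_c[i]
    method[i] <- "fisher"
  }

  q <- rep(NA_real_, ns)
  if (any(testable)) q[testable] <- adjust_bh(p[testable])
  is_dm <- !is.na(q) & q < fdr
  direction <- ifelse(is_dm, ifelse(f_r < f_c, "loss", "gain"), NA_character_)
  out <- cbind(retained$sites,
               data.frame(f_control = f_c, f_knockdown = f_r,
                          delta = f_r - f_c,
                          rel_change = ifelse(!is.na(f_c) & f_c > 0,
                                              (f_r - f_c) / f_c, NA_real_),
                          stat = stat, p = p, q = q, is_dm = is_dm,
                          direction = direction, method = method,
                          testable = testable, stringsAsFactors = FALSE))
  structure(out, class = c("dm_result", "data.frame"), fdr = fdr,
            n_retained = ns, n_testable = sum(testable),
            n_untestable = sum(!testable))
}

#' @export
print.dm_result <- function(x, ...) {
  cat(sprintf("Differential methylation: %d retained sites (%d testable), %d DM at FDR %.2g (%d loss / %d gain)\n",
              attr(x, "n_retained"), attr(x, "n_testable"), sum(x$is_dm),
              attr(x, "fdr"), sum(x$is_dm & x$direction == "loss", na.rm = TRUE),
              sum(x$is_dm & x$direction == "gain", na.rm = TRUE)))
  invisible(x)
}

#' Per-mCG depletion summary
#'
#' @param dm A `dm_result`.
#' @return List of class `depletion_summary`: `mean_depletion_pct` (mean over
#'   retained sites with nonzero control fraction of
#'   `100 (f_control - f_knockdown) / f_control`), `pct_significant_loss`
#'   (percentage of retained sites that are DM with direction loss),
#'   `pct_any_loss` (percentage showing any nominal reduction) and the site
#'   counts behind each.
#' @export
depletion_summary <- function(dm) {
  stopifnot(inherits(dm, "dm_result"))
  ok <- !is.na(dm$f_control) & dm$f_control > 0 & !is.na(dm$f_knockdown)
  dep <- (dm$f_control[ok] - dm$f_knockdown[ok]) / dm$f_control[ok]
  n_ret <- attr(dm, "n_retained")
  structure(list(
    mean_depletion_pct = 100 * mean(dep),
    pct_significant_loss = 100 * sum(dm$is_dm & dm$direction == "loss",
                                     na.rm = TRUE) / n_ret,
    pct_any_loss = 100 * sum(dm$delta[ok] < 0) / n_ret,
    n_retained = n_ret,
    n_depletion_sites = sum(ok)), class = "depletion_summary")
}

#' @export
print.depletion_summary <- function(x, ...) {
  cat(sprintf("Mean per-mCG depletion: %.1f%% (over %d sites); %.1f%% of retained sites significantly reduced, %.1f%% nominally reduced\n",
              x$mean_depletion_pct, x$n_depletion_sites,
              x$pct_significant_loss, x$pct_any_loss))
  invisible(x)
}

#' Per-gene relative gene-body methylation change
#'
#' `r_g = (F_knockdown - F_control) / F_control`, where each `F` is the mean
#' over the gene's retained sites of the condition-pooled per-CpG fraction.
#' Genes with no retained sites or `F_control = 0` are undefined (`NA`) and
#' excluded from downstream correlation.
#'
#' @param dm A `dm_result` whose sites carry gene assignment.
#' @param genes A `gene_models` object.
#' @return Data frame gene_id, n_sites, F_control, F_knockdown, rel_gbm_change.
#' @export
gene_relative_gbm_change <- function(dm, genes) {
  stopifnot(inherits(dm, "dm_result"))
  if (!"gene_id" %in% names(dm)) {
    stop("dm result lacks gene assignment", call. = FALSE)
  }
  gdf <- genes$genes
  genic <- !is.na(dm$gene_id) & !is.na(dm$f_control) & !is.na(dm$f_knockdown)
  gid <- factor(dm$gene_id[genic], levels = gdf$gene_id)
  Fc <- as.numeric(tapply(dm$f_control[genic], gid, mean, default = NA_real_))
  Fr <- as.numeric(tapply(dm$f_knockdown[genic], gid, mean, default = NA_real_))
  n_sites <- as.integer(table(gid))
  r <- ifelse(!is.na(Fc) & Fc > 0, (Fr - Fc) / Fc, NA_real_)
  data.frame(gene_id = gdf$gene_id, n_sites = n_sites, F_control = Fc,
             F_knockdown = Fr, rel_gbm_change = r, stringsAsFactors = FALSE)
}
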