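# DEG classification, exact contingency tests, GBM-expression correlation,
# Welch comparisons and trajectory clustering.

test_that("Fisher exact 2x2 matches enumeration and the reference implementation", {
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2))$p, 1)

  # full-enumeration oracle over all tables with the observed margins
  enum_fisher <- function(tab) {
    r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
    lo <- max(0, c1 - r2); hi <- min(c1, r1)
    probs <- vapply(lo:hi, function(a) {
      b <- r1 - a; c <- c1 - a; d <- r2 - c
      exp(lchoose(r1, a) + lchoose(r2, c) - lchoose(r1 + r2, c1))
    }, numeric(1))
    obs <- probs[tab[1, 1] - lo + 1]
    sum(probs[probs <= obs * (1 + 1e-7)])
  }
  set.seed(61)
  for (i in 1:40) {
    tab <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    got <- fisher_exact_2x2(tab)
    expect_equal(got$p, enum_fisher(tab), tolerance = 1e-12)
    expect_equal(got$p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }

  # cellularization-style table: 24/24 vs 1/24 successes
  cel <- fisher_exact_2x2(matrix(c(24, 1, 0, 23), 2))
  expect_lt(cel$p, 1e-4)
  expect_true(is.infinite(cel$odds_ratio))
  expect_false(is.na(cel$odds_ratio_continuity))
  expect_error(fisher_exact_2x2(matrix(0, 2, 2)), "zero")
})

test_that("Welch t-test matches the textbook formula and the reference implementation", {
  x <- c(1.2, 1.4, 1.1, 1.3)
  expect_equal(welch_t(x, x)$t, 0)
  expect_equal(welch_t(x, x)$p, 1)

  # summary-level comparison of two timing distributions
  w <- welch_t(c(mean = 193, sd = 13.12, n = 5), c(mean = 171, sd = 5.98, n = 5))
  va <- 13.12^2 / 5; vb <- 5.98^2 / 5
  t_or <- (193 - 171) / sqrt(va + vb)
  df_or <- (va + vb)^2 / (va^2 / 4 + vb^2 / 4)
  expect_equal(w$t, t_or, tolerance = 1e-10)
  expect_equal(w$df, df_or, tolerance = 1e-10)
  expect_equal(w$p, 2 * pt(-abs(t_or), df_or), tolerance = 1e-10)
  expect_lt(w$p, 0.05)

  set.seed(67)
  a <- rnorm(8); b <- rnorm(6, 1)
  w2 <- welch_t(a, b)
  tt <- t.test(a, b)
  expect_equal(w2$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(w2$p, tt$p.value, tolerance = 1e-12)
  expect_error(welch_t(1, b), "n >= 2")
})

test_that("Spearman correlation: monotone extremes and tie handling", {
  rg <- data.frame(gene_id = sprintf("g%d", 1:8),
                   rel_gbm_change = seq(-0.9, -0.2, 0.1),
                   stringsAsFactors = FALSE)
  de_up <- structure(data.frame(gene_id = rg$gene_id,
                                log2FC = seq(-2, 1.5, 0.5),
                                stringsAsFactors = FALSE),
                     class = c("de_result", "data.frame"))
  gm <- data.frame(gene_id = rg$gene_id, no_data = FALSE,
                   methylated_by_threshold = TRUE, stringsAsFactors = FALSE)
  expect_equal(gbm_expression_correlation(rg, de_up, gm)$rho, 1)
  de_dn <- de_up; de_dn$log2FC <- rev(de_dn$log2FC)
  expect_equal(gbm_expression_correlation(rg, de_dn, gm)$rho, -1)
  small <- gbm_expression_correlation(rg[1:2, ], de_up, gm)
  expect_true(small$flagged)
  expect_true(is.na(small$rho))
})

test_that("DEG classification buckets and contingency conservation", {
  gm <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                   no_data = c(FALSE, FALSE, TRUE, FALSE),
                   methylated_by_threshold = c(TRUE, FALSE, NA, TRUE),
                   stringsAsFactors = FALSE)
  de <- structure(data.frame(gene_id = c("g1", "g2", "g3", "g9"),
                             is_deg = TRUE,
                             direction = c("down", "up", "down", "up"),
                             log2FC = c(-1, 1, -2, 2),
                             stringsAsFactors = FALSE),
                  class = c("de_result", "data.frame"))
  attr(de, "stage") <- "middle"
  dc <- classify_degs(de, gm)
  st <- dc$per_stage$middle
  expect_equal(st$meth_class[st$gene_id == "g1"], "methylated")
  expect_equal(st$meth_class[st$gene_id == "g2"], "unmethylated")
  expect_equal(st$meth_class[st$gene_id == "g3"], "unclassifiable")
  expect_equal(st$meth_class[st$gene_id == "g9"], "unclassifiable")
  # conservation: classified + unclassifiable = total DEGs
  tabs <- deg_meth_tables(dc, "middle")
  expect_equal(sum(tabs$direction_by_class) +
                 sum(st$meth_class == "unclassifiable"), nrow(st))

  empty <- classify_degs(structure(
    data.frame(gene_id = character(), is_deg = logical(),
               direction = character(), log2FC = numeric()),
    class = c("de_result", "data.frame"), stage = "egg"), gm)
  expect_equal(nrow(empty$union), 0L)
})

test_that("z-scored trajectories cluster deterministically and recover planted archetypes", {
  arch <- rbind(c(2, 1, 0, -1, -2, -2, -2, -2),
                c(-2, -2, -1, 2, 2, 1, 2, 2),
                c(0, 0, 0, 0, 0.5, 0, -0.5, 0))
  set.seed(71)
  lab <- rep(1:3, each = 10)
  traj <- arch[lab, ] + matrix(rnorm(240, 0, 0.15), 30)
  rownames(traj) <- sprintf("g%02d", 1:30)
  cl <- zscore_cluster(traj, k = 3)
  expect_gte(adjusted_rand(cl$clusters, lab), 0.9)

  # duplicate trajectories land in the same cluster; constants z-score to zero
  traj2 <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(9, 9, 9, 9),
                 d = c(4, 3, 2, 1))
  cl2 <- zscore_cluster(traj2, k = 2)
  expect_equal(cl2$clusters[["a"]], cl2$clusters[["b"]])
  expect_true(all(cl2$zmat["c", ] == 0))
  expect_error(zscore_cluster(traj2, k = 10), "fewer genes")
})

test_that("coupled simulation reproduces the direction-methylation bias and positive correlation", {
  sim <- default_sim()
  ctrl_ids <- sim$wgbs_samples$sample_id[sim$wgbs_samples$condition == "control"]
  ctrl <- lapply(ctrl_ids, function(s) {
    call_sample(sim$wgbs[[s]], e = sim$wgbs_samples$nonconversion[
      match(s, sim$wgbs_samples$sample_id)])
  })
  gm <- gene_body_methylation(ctrl, sim$genes)
  dm <- dm_test(retain_sites(ctrl, sim$wgbs))
  rg <- gene_relative_gbm_change(dm, sim$genes)
  expr <- suppressMessages(filter_low_expression(sim$expr))
  sf <- size_factors(expr$counts)
  de_list <- de_all_stages(expr, sf = sf)
  rep <- integration_report(de_list, gm, rg, expr, sf = sf)

  # mDEG/uDEG split agrees with the simulation truth for classified DEGs
  truth <- setNames(sim$truth$gene_truth$true_meth_class,
                    sim$truth$gene_truth$gene_id)
  u <- rep$deg_classes$union
  u <- u[u$meth_class != "unclassifiable", ]
  expect_gte(mean(u$meth_class == truth[u$gene_id]), 0.99)

  ps <- rep$per_stage$middle
  ct <- ps$tables$direction_by_class
  # down-regulated DEGs predominantly methylated, up-regulated predominantly
  # unmethylated, both strongly non-random
  expect_gt(ct["down", "methylated"], ct["down", "unmethylated"])
  expect_gt(ct["up", "unmethylated"], ct["up", "methylated"])
  expect_lt(ps$tables$fisher_direction$p, 0.01)
  expect_gt(ps$correlation$rho, 0)
  expect_lt(ps$correlation$p, 0.01)
})
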