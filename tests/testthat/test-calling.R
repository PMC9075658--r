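# Binomial methylation caller, BH adjustment, gene-body methylation and
# metagene profiles.

# independent oracle: direct pmf summation of the inclusive upper tail
pmf_sum_tail <- function(k, n, e) sum(dbinom(k:n, n, e))

test_that("binomial upper tail matches closed forms and the pmf-sum oracle", {
  expect_equal(binomial_call(0, 14, 0.005), 1)
  expect_equal(binomial_call(14, 14, 0.005), 0.005^14)
  p <- binomial_call(2, 14, 0.0052)
  expect_equal(p, pmf_sum_tail(2, 14, 0.0052), tolerance = 1e-12)

  set.seed(42)
  n <- sample(1:60, 200, replace = TRUE)
  k <- vapply(n, function(ni) sample(0:ni, 1), integer(1))
  p_vec <- binomial_call(k, n, 0.0052)
  p_or <- mapply(pmf_sum_tail, k, n, 0.0052)
  expect_equal(p_vec, p_or, tolerance = 1e-12)

  expect_true(is.na(binomial_call(0, 0, 0.005)))
  expect_error(binomial_call(3, 2, 0.005), "k <= n")
  expect_error(binomial_call(1, 2, 0), "e must be")
})

test_that("BH adjustment equals the brute-force step-up and is order-stable", {
  bh_oracle <- function(p) {
    m <- length(p); o <- order(p); q <- numeric(m)
    sorted <- p[o] * m / seq_len(m)
    q[o] <- rev(cummin(rev(sorted)))
    pmin(q, 1)
  }
  expect_equal(adjust_bh(rep(0.01, 10)), rep(0.01, 10))
  p <- c(0.01, 0.02, 0.03, 1.0)
  expect_equal(adjust_bh(p), bh_oracle(p))
  expect_equal(adjust_bh(0.37), 0.37)
  set.seed(8)
  p2 <- runif(50)
  perm <- sample(50)
  expect_equal(adjust_bh(p2)[perm], adjust_bh(p2[perm]))
  expect_error(adjust_bh(c(0.1, NaN)), "NA")
})

test_that("call_sample labels mCGs over covered sites only", {
  cc <- make_counts(k = rep(0L, 20L), n = rep(15L, 20L))
  calls <- call_sample(cc, e = 0.005)
  expect_equal(sum(calls$is_mcg), 0L)

  # a fully methylated locus at ~15x: every covered site is called; the
  # smallest called k must sit at or above the per-site oracle threshold
  set.seed(21)
  n <- rpois(300, 15)
  k <- n
  cc2 <- make_counts(k = k, n = n)
  calls2 <- call_sample(cc2, e = 0.0052)
  covered <- calls2$n > 0
  expect_true(all(calls2$is_mcg[covered]))
  expect_true(all(!calls2$is_mcg[!covered]))
  expect_true(all(is.na(calls2$f[!covered])))
  # BH never lowers a p-value
  expect_true(all(calls2$q[covered] >= calls2$p_raw[covered]))

  cc3 <- make_counts(k = c(0L, 0L), n = c(5L, 5L))
  cc3$pos <- c(10L, 10L)
  expect_error(call_sample(cc3, e = 0.005), "duplicate")
  expect_error(call_sample(cc, e = NA), "nonconversion")
})

test_that("caller power is monotone in coverage at fixed true methylation", {
  set.seed(99)
  e <- 0.0052; m_true <- 0.12; n_sites <- 4000L
  frac_called <- vapply(c(5L, 15L, 50L), function(nn) {
    k <- rbinom(n_sites, nn, m_true + (1 - m_true) * e)
    calls <- call_sample(make_counts(k, rep(nn, n_sites)), e = e)
    mean(calls$is_mcg)
  }, numeric(1))
  expect_true(all(diff(frac_called) > 0))
})

test_that("union of replicate mCG sets obeys set arithmetic", {
  mk <- function(pos, called) {
    df <- make_counts(rep(5L, length(pos)), rep(10L, length(pos)))
    df$pos <- pos
    df$is_mcg <- called
    df
  }
  a <- mk(1:5 * 10L, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  b <- mk(1:5 * 10L, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(nrow(union_mcgs(list(a, b))), 3L)
  b2 <- mk(1:5 * 10L, c(FALSE, FALSE, FALSE, TRUE, TRUE))
  c2 <- mk(6:7 * 10L, c(TRUE, TRUE))
  expect_equal(nrow(union_mcgs(list(a, b2, c2))), 7L)
  expect_error(union_mcgs(list()), "non-empty")

  sim <- default_sim()
  calls <- lapply(names(sim$wgbs)[1:3], function(sid) {
    call_sample(sim$wgbs[[sid]], e = sim$wgbs_samples$nonconversion[
      match(sid, sim$wgbs_samples$sample_id)])
  })
  u <- union_mcgs(calls)
  per_rep <- attr(u, "per_replicate")
  expect_gte(nrow(u), max(per_rep))
})

test_that("gene-body methylation matches a flat brute-force oracle and the inclusive threshold", {
  # boundary: mean of (0, 0.04) is exactly 0.02 -> methylated ("at least")
  gdf <- data.frame(gene_id = c("ga", "gb"), chrom = "chr1", strand = "+",
                    start = c(0L, 1000L), end = c(500L, 1500L), n_exons = 1L,
                    stringsAsFactors = FALSE)
  gm <- gene_models(gdf, data.frame(gene_id = c("ga", "gb"), rank = 1L,
                                    start = gdf$start, end = gdf$end,
                                    stringsAsFactors = FALSE))
  cc <- make_counts(k = c(0L, 4L, 0L, 0L), n = c(100L, 100L, 50L, 50L),
                    gene_id = c("ga", "ga", "gb", "gb"))
  cc$pos <- c(10L, 20L, 1010L, 1020L)
  cc$feature <- "exon"; cc$rank <- 1L
  calls <- call_sample(cc, e = 0.005)
  gt <- gene_body_methylation(calls, gm)
  expect_equal(gt$F, c(0.02, 0))
  expect_true(gt$methylated_by_threshold[1])
  expect_false(gt$methylated_by_threshold[2])
  expect_false(gt$methylated_by_mcg[2])

  # 50-gene simulated fixture against a double-loop oracle
  sim <- simulate_dataset(sim_config(seed = 17L, n_genes = 50L))
  calls3 <- lapply(names(sim$wgbs)[1:3], function(sid) {
    call_sample(sim$wgbs[[sid]], e = sim$wgbs_samples$nonconversion[
      match(sid, sim$wgbs_samples$sample_id)])
  })
  gt3 <- gene_body_methylation(calls3, sim$genes)
  for (g in sample(sim$genes$genes$gene_id, 10)) {
    fs <- c()
    for (i in which(!is.na(calls3[[1]]$gene_id) & calls3[[1]]$gene_id == g)) {
      vals <- c(); nn <- 0
      for (cs in calls3) {
        if (cs$n[i] > 0) { vals <- c(vals, cs$k[i] / cs$n[i]); nn <- nn + 1 }
      }
      if (nn > 0) fs <- c(fs, mean(vals))
    }
    expected <- if (length(fs)) mean(fs) else NA_real_
    expect_equal(gt3$F[gt3$gene_id == g], expected)
  }
  # genes with zero covered CpGs are no-data and unclassified
  expect_true(all(is.na(gt3$methylated_by_threshold[gt3$no_data])))
})

test_that("threshold classifier recovers simulated gene classes at 15x", {
  sim <- default_sim()
  calls <- lapply(names(sim$wgbs)[1:3], function(sid) {
    call_sample(sim$wgbs[[sid]], e = sim$wgbs_samples$nonconversion[
      match(sid, sim$wgbs_samples$sample_id)])
  })
  gt <- gene_body_methylation(calls, sim$genes)
  truth <- sim$truth$gene_truth
  m <- merge(gt[!gt$no_data, ], truth, by = "gene_id")
  acc <- mean((m$methylated_by_threshold & m$true_meth_class == "methylated") |
                (!m$methylated_by_threshold & m$true_meth_class == "unmethylated"))
  expect_gte(acc, 0.99)
})

test_that("metagene profile: constant field, 5' decay, knockdown scaling", {
  sim <- default_sim()
  ctrl_ids <- sim$wgbs_samples$sample_id[sim$wgbs_samples$condition == "control"]
  kd_ids <- sim$wgbs_samples$sample_id[sim$wgbs_samples$condition == "knockdown"]
  e_of <- function(sid) sim$wgbs_samples$nonconversion[
    match(sid, sim$wgbs_samples$sample_id)]
  ctrl <- lapply(ctrl_ids, function(s) call_sample(sim$wgbs[[s]], e_of(s)))
  kd <- lapply(kd_ids, function(s) call_sample(sim$wgbs[[s]], e_of(s)))
  gt <- gene_body_methylation(ctrl, sim$genes)
  prof_c <- metagene_profile(ctrl, sim$genes, gene_table = gt)
  prof_k <- metagene_profile(kd, sim$genes, gene_table = gt)

  ex1 <- prof_c$mean_f[prof_c$feature == "exon" & prof_c$slot == "first" &
                         prof_c$rank == 1]
  ex4 <- prof_c$mean_f[prof_c$feature == "exon" & prof_c$slot == "first" &
                         prof_c$rank == 4]
  expect_gt(mean(ex1), mean(ex4))

  # knockdown preserves shape, scales the level by about 1 - d in every bin
  m <- merge(prof_c, prof_k, by = c("feature", "slot", "rank", "bin"))
  ratio <- m$mean_f.y / m$mean_f.x
  expect_true(all(abs(ratio - (1 - 0.815)) < 0.08))

  # constant field: uniform f gives a flat profile
  gdf <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                    start = 0L, end = 900L, n_exons = 2L,
                    stringsAsFactors = FALSE)
  gmod <- gene_models(gdf, data.frame(gene_id = "g1", rank = 1:2,
                                      start = c(0L, 500L), end = c(300L, 900L),
                                      stringsAsFactors = FALSE))
  cc <- make_counts(k = rep(5L, 6L), n = rep(10L, 6L), gene_id = "g1")
  cc$pos <- c(10L, 150L, 290L, 350L, 510L, 700L)
  cc$feature <- c("exon", "exon", "exon", "intron", "exon", "exon")
  cc$rank <- c(1L, 1L, 1L, 1L, 2L, 2L)
  calls <- call_sample(cc, e = 0.005)
  prof <- metagene_profile(calls, gmod, n_bins = 3,
                           gene_table = data.frame(
                             gene_id = "g1", no_data = FALSE,
                             methylated_by_threshold = TRUE))
  expect_true(all(prof$mean_f == 0.5))
  expect_error(metagene_profile(calls, gmod, n_bins = 0), "n_bins")
})
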