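# Low-expression filter, median-of-ratios size factors, NB Wald DE engine
# and the 2-fold transition analysis.

test_that("low-expression filter removes max <= 10 and keeps max 11", {
  m <- rbind(g1 = c(0L, 10L, 3L), g2 = c(11L, 0L, 0L), g3 = c(2L, 2L, 2L))
  suppressMessages(f <- filter_low_expression(m))
  expect_equal(rownames(f), "g2")
  expect_equal(attr(f, "n_removed"), 2L)
  z <- matrix(0L, 3, 3)
  suppressMessages(expect_warning(filter_low_expression(z), "all genes"))
  expect_error(suppressMessages(filter_low_expression(matrix(0.5, 2, 2))),
               "integer")
})

test_that("size factors: closed forms, hand-enumerated fixture, and an independent cross-check", {
  A <- c(10L, 20L, 40L, 100L, 7L)
  m <- cbind(a = A, b = 2L * A)
  sf <- size_factors(m)
  expect_equal(as.numeric(sf), c(1 / sqrt(2), sqrt(2)))
  expect_equal(as.numeric(size_factors(cbind(A, A, A))), c(1, 1, 1))

  # 5-gene, 3-sample fixture vs a per-gene ratio table computed by hand
  m2 <- rbind(c(12L, 30L, 21L), c(100L, 190L, 95L), c(7L, 16L, 10L),
              c(55L, 110L, 62L), c(9L, 27L, 12L))
  geo <- apply(m2, 1, function(x) exp(mean(log(x))))
  raw <- apply(m2, 2, function(col) median(col / geo))
  expect_equal(as.numeric(size_factors(m2)),
               as.numeric(raw / exp(mean(log(raw)))))

  # independent implementation agrees (after the geometric-mean-1 rescale)
  ds <- DESeq2::estimateSizeFactorsForMatrix(m2)
  expect_equal(as.numeric(size_factors(m2)),
               as.numeric(ds / exp(mean(log(ds)))), tolerance = 1e-12)

  expect_error(size_factors(cbind(c(0L, 1L), c(1L, 0L))), "pseudo-reference")
})

test_that("DE engine: null calibration, trivial gene, BH universe", {
  cfg <- sim_config(seed = 41L, n_genes = 400L, coupling_gamma = 0,
                    coupling_noise_sd = 0, indirect_up_fraction = 0,
                    depletion = 0)
  sim <- simulate_dataset(cfg)
  expr <- suppressMessages(filter_low_expression(sim$expr))
  sf <- size_factors(expr$counts)
  de <- de_test(expr, "middle", sf = sf)
  expect_lte(mean(de$is_deg), 0.1)
  expect_equal(nrow(de), nrow(expr$counts))  # BH universe = filtered genes

  # a gene with identical counts in every sample is exactly null
  m <- expr$counts
  m[1, expr$samples$stage == "middle"] <- 500L
  expr2 <- expr; expr2$counts <- m
  de2 <- de_test(expr2, "middle", sf = setNames(rep(1, ncol(m)), colnames(m)))
  expect_equal(de2$log2FC[1], 0)
  expect_gt(de2$p[1], 0.99)

  expect_error(de_test(expr, "pupa"), "unknown stage")
})

test_that("DE power: a 2-fold effect at n = 3 vs 3, mean 500, dispersion 0.05", {
  set.seed(43)
  n_sim <- 500L
  mu <- 500
  counts <- cbind(
    matrix(rnbinom(3 * n_sim, size = 20, mu = mu), n_sim),
    matrix(rnbinom(3 * n_sim, size = 20, mu = mu / 2), n_sim))
  rownames(counts) <- sprintf("g%03d", seq_len(n_sim))
  colnames(counts) <- sprintf("s%d__one__%s__%d", 1:6,
                              rep(c("control", "knockdown"), each = 3), 1:3)
  expr <- structure(list(
    counts = counts,
    samples = data.frame(sample_id = sprintf("s%d", 1:6), stage = "one",
                         condition = rep(c("control", "knockdown"), each = 3),
                         replicate = rep(1:3, 2), stringsAsFactors = FALSE),
    gene_truth = NULL), class = "expr_set")
  de <- de_test(expr, "one", sf = setNames(rep(1, 6), colnames(counts)))
  expect_gte(mean(de$p < 0.05), 0.8)
  expect_lt(median(de$log2FC), -0.8)
})

test_that("log2FC is invariant to rescaling one sample's library", {
  sim <- simulate_dataset(sim_config(seed = 47L, n_genes = 200L))
  expr <- suppressMessages(filter_low_expression(sim$expr))
  de1 <- de_test(expr, "middle", sf = size_factors(expr$counts))
  expr2 <- expr
  j <- which(expr$samples$stage == "middle")[1]
  expr2$counts[, j] <- expr2$counts[, j] * 3L
  de2 <- de_test(expr2, "middle", sf = size_factors(expr2$counts))
  expect_equal(de1$log2FC, de2$log2FC, tolerance = 1e-8)
  expect_equal(de1$p, de2$p, tolerance = 1e-2)  # variance terms see 1/s_j
})

test_that("transition sets match a brute-force ratio scan, boundary at exactly 2-fold", {
  # controlled matrix: gene u doubles (exactly 2-fold with pseudocount),
  # gene f is flat
  stages <- c("egg", "early", "middle", "late")
  samples <- expand.grid(replicate = 1:2, condition = c("control", "knockdown"),
                         stage = stages, stringsAsFactors = FALSE)
  samples <- samples[c("stage", "condition", "replicate")]
  samples$sample_id <- sprintf("s%02d", seq_len(nrow(samples)))
  base <- c(u = 99L, f = 50L, d = 400L)
  counts <- matrix(0L, 3, nrow(samples),
                   dimnames = list(names(base),
                                   sprintf("%s__%s__%s__%d", samples$sample_id,
                                           samples$stage, samples$condition,
                                           samples$replicate)))
  mult <- c(egg = 1, early = 2, middle = 2, late = 2)  # u: up at egg->early
  for (j in seq_len(nrow(samples))) {
    counts["u", j] <- as.integer(base["u"] * mult[samples$stage[j]] +
                                   (samples$stage[j] != "egg"))
    counts["f", j] <- base["f"]
    counts["d", j] <- if (samples$stage[j] == "egg") 400L else 199L
  }
  expr <- structure(list(counts = counts, samples = samples, gene_truth = NULL),
                    class = "expr_set")
  sfs <- setNames(rep(1, ncol(counts)), colnames(counts))
  tr <- transition_fold_changes(expr, sf = sfs)
  # (99+1) -> (199+1): ratio exactly 2 counts as 2-fold
  expect_true("u" %in% tr$egg_to_early$per_condition$control$up)
  expect_false("f" %in% unlist(tr$egg_to_early$per_condition$control))
  expect_true("d" %in% tr$egg_to_early$per_condition$control$down)
  expect_equal(length(tr$early_to_middle$per_condition$control$up), 0L)

  # 20-gene random fixture against an independent scan
  sim <- simulate_dataset(sim_config(seed = 53L, n_genes = 20L))
  sf2 <- size_factors(sim$expr$counts)
  tr2 <- transition_fold_changes(sim$expr, sf = sf2)
  q <- sweep(sim$expr$counts, 2, sf2, "/")
  samp <- sim$expr$samples
  for (cond in c("control", "knockdown")) {
    m_egg <- rowMeans(q[, samp$stage == "egg" & samp$condition == cond])
    m_early <- rowMeans(q[, samp$stage == "early" & samp$condition == cond])
    ratio <- (m_early + 1) / (m_egg + 1)
    expect_setequal(tr2$egg_to_early$per_condition[[cond]]$up,
                    rownames(q)[ratio >= 2])
    expect_setequal(tr2$egg_to_early$per_condition[[cond]]$down,
                    rownames(q)[ratio <= 0.5])
  }
  # cross-condition bookkeeping
  cmp <- tr2$egg_to_early$comparison$down
  expect_setequal(c(cmp$both, cmp$knockdown_only),
                  tr2$egg_to_early$per_condition$knockdown$down)
})
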