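# Shared fixtures, built in code. The default simulated dataset is cached so
# several test files can reuse it within one run.

.sim_cache <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    .sim_cache$sim <- simulate_dataset(sim_config(seed = 7L))
  }
  .sim_cache$sim
}

# hand-built true methylome on a flat site grid, for count-model tests
flat_truth <- function(n_sites, m, chrom = "chr1") {
  sites <- data.frame(chrom = chrom, pos = seq_len(n_sites) * 10L,
                      gene_id = NA_character_, feature = "intergenic",
                      rank = NA_integer_, m_control = m, m_knockdown = m,
                      stringsAsFactors = FALSE)
  structure(list(sites = sites,
                 gene_truth = data.frame(gene_id = character(),
                                         true_meth_class = character(),
                                         base_m = numeric(),
                                         depletion = numeric())),
            class = "true_methylome")
}

# minimal count table on a flat grid
make_counts <- function(k, n, chrom = "chr1", sample_id = "s",
                        condition = "control", gene_id = NA_character_) {
  structure(data.frame(chrom = chrom, pos = seq_along(k) * 10L,
                       gene_id = gene_id, feature = "intergenic",
                       rank = NA_integer_, k = k, n = n,
                       stringsAsFactors = FALSE),
            class = c("cpg_counts", "data.frame"),
            sample_id = sample_id, condition = condition)
}

# retained_sites object built directly from per-replicate (k, n) matrices
make_retained <- function(K, N, conditions, gene_id = NULL) {
  ns <- nrow(K)
  sites <- data.frame(chrom = "chr1", pos = seq_len(ns) * 10L,
                      gene_id = gene_id %||% rep(NA_character_, ns),
                      feature = "exon", rank = 1L, stringsAsFactors = FALSE)
  structure(list(sites = sites, K = K, N = N, conditions = conditions),
            class = "retained_sites")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# adjusted Rand index for planted-cluster recovery checks
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_i * sum_j / comb2(n)
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}
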