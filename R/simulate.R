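# Synthetic-data generator: genome layout, true methylome, bisulfite read
# counts and a stage-structured expression matrix with knockdown effects
# coupled to methylation loss. Everything is deterministic given the config
# seed; each generator seeds the RNG at config$seed plus a fixed offset so
# stages can be re-run independently yet reproducibly.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a gene annotation and CpG site map
#'
#' Lays `n_genes` multi-exon genes along a small set of chromosomes and
#' scatters CpG sites over exons, introns and intergenic gaps. Gene bodies run
#' from transcription start to transcription end; exon rank 1 is always the
#' 5' exon regardless of strand. A configurable fraction of CpGs (default 7%)
#' falls outside gene bodies so that the gene-assignment plumbing is
#' exercised, mirroring the observation that the vast majority of methylated
#' CpGs in this system are intragenic.
#'
#' @param config A [sim_config()] object.
#' @return A list with `genes` (a `gene_models` object: `$genes` table and
#'   `$exons` table with transcription-order ranks) and `cpgs` (data frame of
#'   0-based site coordinates with gene/feature assignment and the simulation
#'   truth class).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_genes
    if (n == 0L) {
      genes <- gene_models(
        data.frame(gene_id = character(), chrom = character(),
                   strand = character(), start = integer(), end = integer(),
                   n_exons = integer(), true_meth_class = character(),
                   stringsAsFactors = FALSE),
        data.frame(gene_id = character(), rank = integer(),
                   start = integer(), end = integer(), stringsAsFactors = FALSE))
      return(list(genes = genes,
                  cpgs = data.frame(chrom = character(), pos = integer(),
                                    gene_id = character(), feature = character(),
                                    rank = integer(), stringsAsFactors = FALSE)))
    }
    meth_class <- ifelse(
      runif(n) < config$frac_methylated_genes, "methylated", "unmethylated")
    n_exons <- 1L + rpois(n, max(0, config$exons_per_gene_mean - 1))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    chrom_of <- sprintf("chr%d", ((seq_len(n) - 1L) %% config$n_chroms) + 1L)
    gene_id <- sprintf("g%05d", seq_len(n))

    exon_rows <- vector("list", n)
    gene_start <- integer(n); gene_end <- integer(n)
    cursor <- setNames(rep(config$intergenic_gap, config$n_chroms),
                       sprintf("chr%d", seq_len(config$n_chroms)))
    gaps <- list()
    for (i in seq_len(n)) {
      ch <- chrom_of[i]
      ne <- n_exons[i]
      s0 <- cursor[[ch]]
      starts <- s0 + (seq_len(ne) - 1L) * (config$exon_length + config$intron_length)
      ends <- starts + config$exon_length
      gene_start[i] <- starts[1L]
      gene_end[i] <- ends[ne]
      rank <- if (strand[i] == "+") seq_len(ne) else rev(seq_len(ne))
      exon_rows[[i]] <- data.frame(gene_id = gene_id[i], rank = rank,
                                   start = starts, end = ends,
                                   stringsAsFactors = FALSE)
      gaps[[length(gaps) + 1L]] <- data.frame(
        chrom = ch, start = gene_end[i], end = gene_end[i] + config$intergenic_gap)
      cursor[[ch]] <- gene_end[i] + config$intergenic_gap
    }
    exons <- do.call(rbind, exon_rows)
    genes_df <- data.frame(gene_id = gene_id, chrom = chrom_of, strand = strand,
                           start = gene_start, end = gene_end,
                           n_exons = n_exons, true_meth_class = meth_class,
                           stringsAsFactors = FALSE)

    # CpGs per feature: sample positions without replacement within each
    # exon/intron so sites are unique.
    cpg_rows <- vector("list", n)
    for (i in seq_len(n)) {
      ne <- n_exons[i]
      ex <- exon_rows[[i]][order(exon_rows[[i]]$start), ]
      per_exon <- rpois(ne, config$cpgs_per_exon_mean)
      rows <- list()
      for (j in seq_len(ne)) {
        if (per_exon[j] > 0) {
          pos <- sort(sample.int(config$exon_length, per_exon[j])) - 1L + ex$start[j]
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = chrom_of[i], pos = pos, gene_id = gene_id[i],
            feature = "exon", rank = ex$rank[j], stringsAsFactors = FALSE)
        }
      }
      if (ne > 1L) {
        per_intron <- rpois(ne - 1L, config$cpgs_per_intron_mean)
        for (j in seq_len(ne - 1L)) {
          if (per_intron[j] > 0) {
            # intron j (genomic) lies between genomic exons j and j+1; its
            # transcription rank follows the 5' exon on that strand
            irank <- if (strand[i] == "+") j else n_exons[i] - j
            pos <- sort(sample.int(config$intron_length, per_intron[j])) - 1L +
              ex$end[j]
            rows[[length(rows) + 1L]] <- data.frame(
              chrom = chrom_of[i], pos = pos, gene_id = gene_id[i],
              feature = "intron", rank = irank, stringsAsFactors = FALSE)
          }
        }
      }
      cpg_rows[[i]] <- if (length(rows)) do.call(rbind, rows) else NULL
    }
    cpgs <- do.call(rbind, cpg_rows)
    n_genic <- if (is.null(cpgs)) 0L else nrow(cpgs)

    icf <- config$intergenic_cpg_frac
    n_inter <- if (icf > 0) round(icf / (1 - icf) * n_genic) else 0L
    if (n_inter > 0) {
      gapdf <- do.call(rbind, gaps)
      pick <- sample.int(nrow(gapdf), n_inter, replace = TRUE)
      width <- gapdf$end[pick] - gapdf$start[pick]
      ipos <- gapdf$start[pick] + floor(runif(n_inter) * width)
      inter <- data.frame(chrom = gapdf$chrom[pick], pos = as.integer(ipos),
                          gene_id = NA_character_, feature = "intergenic",
                          rank = NA_integer_, stringsAsFactors = FALSE)
      inter <- inter[!duplicated(inter[c("chrom", "pos")]), ]
      cpgs <- rbind(cpgs, inter)
    }
    if (is.null(cpgs)) {
      cpgs <- data.frame(chrom = character(), pos = integer(),
                         gene_id = character(), feature = character(),
                         rank = integer(), stringsAsFactors = FALSE)
    }
    cpgs <- cpgs[order(cpgs$chrom, cpgs$pos), ]
    rownames(cpgs) <- NULL
    list(genes = gene_models(genes_df, exons), cpgs = cpgs)
  })
}

#' Simulate the true methylome
#'
#' Assigns every CpG a true methylation probability per condition. CpGs of
#' methylated-class genes draw a gene-level base level from a Beta
#' distribution (bimodal genome-wide: the other mode sits at the background),
#' decayed multiplicatively by exon rank (5' > 3') and reduced in introns
#' relative to their upstream exon. Under knockdown every site of a gene is
#' multiplied by `1 - d_g`, where `d_g` is the gene's depletion drawn around
#' the configured mean `depletion` (exactly `depletion` for every gene when
#' `depletion_concentration = Inf` or `depletion` is 0 or 1).
#'
#' @param genes,cpgs Output of [simulate_genome()].
#' @param config The same [sim_config()].
#' @return A `true_methylome`: list with `sites` (CpG table plus `m_control`,
#'   `m_knockdown`) and `gene_truth` (per-gene class, base level, depletion).
#' @export
simulate_true_methylome <- function(genes, cpgs, config) {
  stopifnot(inherits(config, "sim_config"), inherits(genes, "gene_models"))
  with_seed(config$seed + 1L, {
    gdf <- genes$genes
    base_m <- ifelse(gdf$true_meth_class == "methylated",
                     rbeta(nrow(gdf), config$meth_beta_shape1,
                           config$meth_beta_shape2),
                     config$background_m)
    d <- config$depletion
    kappa <- config$depletion_concentration
    if (d %in% c(0, 1) || is.infinite(kappa)) {
      dep <- rep(d, nrow(gdf))
    } else {
      dep <- rbeta(nrow(gdf), d * kappa, (1 - d) * kappa)
    }
    gene_truth <- data.frame(gene_id = gdf$gene_id,
                             true_meth_class = gdf$true_meth_class,
                             base_m = base_m, depletion = dep,
                             stringsAsFactors = FALSE)
    idx <- match(cpgs$gene_id, gdf$gene_id)
    m <- rep(config$background_m, nrow(cpgs))
    genic <- !is.na(idx)
    gm <- base_m[idx[genic]]
    cls <- gdf$true_meth_class[idx[genic]]
    decay <- config$five_prime_decay ^ (cpgs$rank[genic] - 1L)
    fac <- ifelse(cpgs$feature[genic] == "intron", config$intron_m_factor, 1)
    m[genic] <- ifelse(cls == "methylated", pmin(1, gm * decay * fac),
                       config$background_m)
    dep_site <- rep(d, nrow(cpgs))
    dep_site[genic] <- dep[idx[genic]]
    sites <- cpgs
    sites$m_control <- m
    sites$m_knockdown <- m * (1 - dep_site)
    structure(list(sites = sites, gene_truth = gene_truth),
              class = "true_methylome")
  })
}

#' Default WGBS sample sheet for a simulation
#'
#' @param config A [sim_config()].
#' @return Data frame with sample_id, condition, replicate and per-sample
#'   non-conversion rate (recycled from the configured vectors).
#' @export
sim_wgbs_samples <- function(config) {
  nr <- config$n_replicates
  e_c <- rep_len(config$nonconversion_control, nr)
  e_k <- rep_len(config$nonconversion_knockdown, nr)
  data.frame(
    sample_id = c(sprintf("control_%d", seq_len(nr)),
                  sprintf("knockdown_%d", seq_len(nr))),
    condition = rep(c("control", "knockdown"), each = nr),
    replicate = rep(seq_len(nr), 2L),
    nonconversion = c(e_c, e_k),
    stringsAsFactors = FALSE)
}

#' Simulate bisulfite read counts
#'
#' Per sample and site, total reads `n` are drawn from the coverage
#' distribution (Poisson by default, negative binomial optionally) and
#' methylated reads `k ~ Binomial(n, m(1 - over_conversion) + (1 - m) e)`,
#' where `e` is the sample's non-conversion rate — the generative mirror of
#' the caller's binomial null. Sites with `n = 0` are emitted with `k = 0`;
#' no site is ever dropped.
#'
#' @param truth A `true_methylome`.
#' @param samples Sample sheet as from [sim_wgbs_samples()]; must carry
#'   `sample_id`, `condition` and `nonconversion` columns.
#' @param config The [sim_config()].
#' @return Named list of per-sample `cpg_counts` data frames (chrom, pos,
#'   gene_id, feature, rank, k, n) with sample metadata in attributes.
#' @export
simulate_wgbs_counts <- function(truth, samples = NULL, config) {
  stopifnot(inherits(truth, "true_methylome"), inherits(config, "sim_config"))
  if (is.null(samples)) samples <- sim_wgbs_samples(config)
  if (any(samples$nonconversion < 0 | samples$nonconversion >= 1)) {
    stop("nonconversion rate must lie in [0, 1)", call. = FALSE)
  }
  with_seed(config$seed + 2L, {
    sites <- truth$sites
    ns <- nrow(sites)
    out <- vector("list", nrow(samples))
    names(out) <- samples$sample_id
    for (i in seq_len(nrow(samples))) {
      m <- if (samples$condition[i] == "knockdown") sites$m_knockdown else sites$m_control
      n <- if (config$coverage_model == "poisson") {
        rpois(ns, config$coverage_mean)
      } else {
        rnbinom(ns, size = config$coverage_nb_size, mu = config$coverage_mean)
      }
      p_obs <- m * (1 - config$over_conversion) +
        (1 - m) * samples$nonconversion[i]
      k <- rbinom(ns, n, p_obs)
      tab <- sites[c("chrom", "pos", "gene_id", "feature", "rank")]
      tab$k <- k
      tab$n <- n
      out[[i]] <- structure(tab, class = c("cpg_counts", "data.frame"),
                            sample_id = samples$sample_id[i],
                            condition = samples$condition[i],
                            nonconversion = samples$nonconversion[i])
    }
    out
  })
}

sim_stage_offsets <- function(traj, stages, config) {
  S <- length(stages)
  t <- seq_len(S)
  switch(traj,
    maternal = config$maternal_lfc_step * (t - 1),
    zygotic = {
      mid <- ceiling(S / 2)
      off <- -2 + 0.5 * (t - 1)
      off[t > mid] <- off[mid] + config$zga_lfc + 0.5 * (t[t > mid] - mid - 1)
      off
    },
    flat = rep(0, S))
}

#' Simulate a stage-structured expression matrix
#'
#' Counts are negative-binomial with mean
#' `depth_factor x stage baseline x 2^(condition effect)`. Genes follow one of
#' three stage trajectories (maternal decay, zygotic activation at the
#' mid-blastoderm stage, flat). The egg-stage condition effect is always 0
#' (the maternal transcript pool is deposited before the knockdown can act on
#' zygotic transcription); in later stages the effect of a methylated gene is
#' `coupling_gamma x (relative GBM change) + noise` — negative effects
#' dominate because methylation is lost — while a configured fraction of
#' unmethylated genes is indirectly upregulated by `indirect_up_lfc`.
#'
#' @param genes A `gene_models` object from [simulate_genome()].
#' @param truth The `true_methylome` (supplies per-gene depletion).
#' @param config The [sim_config()].
#' @return An `expr_set`: list with integer `counts` (genes x samples, column
#'   names `SAMPLE__STAGE__CONDITION__REP`), `samples` metadata (including
#'   depth factors) and `gene_truth` (trajectory, true condition log2 effect).
#' @export
simulate_expression <- function(genes, truth, config) {
  stopifnot(inherits(genes, "gene_models"), inherits(truth, "true_methylome"),
            inherits(config, "sim_config"))
  with_seed(config$seed + 3L, {
    gdf <- genes$genes
    ng <- nrow(gdf)
    stages <- config$stages
    nr <- config$n_replicates
    gt <- truth$gene_truth[match(gdf$gene_id, truth$gene_truth$gene_id), ]

    baseline <- rlnorm(ng, config$expr_meanlog, config$expr_sdlog)
    traj <- sample(c("maternal", "zygotic", "flat"), ng, replace = TRUE,
                   prob = c(config$maternal_frac, config$zygotic_frac,
                            1 - config$maternal_frac - config$zygotic_frac))
    offsets <- vapply(traj, sim_stage_offsets, numeric(length(stages)),
                      stages = stages, config = config)   # stages x genes

    is_meth <- gt$true_meth_class == "methylated"
    rel_gbm_change <- ifelse(is_meth, -gt$depletion, 0)
    cond_lfc <- numeric(ng)
    cond_lfc[is_meth] <- config$coupling_gamma * rel_gbm_change[is_meth] +
      rnorm(sum(is_meth), 0, config$coupling_noise_sd)
    unmeth_idx <- which(!is_meth)
    n_ind <- round(config$indirect_up_fraction * length(unmeth_idx))
    indirect <- rep(FALSE, ng)
    if (n_ind > 0) {
      ind_idx <- sample(unmeth_idx, n_ind)
      indirect[ind_idx] <- TRUE
      cond_lfc[ind_idx] <- config$indirect_up_lfc
    }

    samples <- expand.grid(replicate = seq_len(nr),
                           condition = c("control", "knockdown"),
                           stage = stages, stringsAsFactors = FALSE)
    samples <- samples[c("stage", "condition", "replicate")]
    samples$sample_id <- sprintf("s%02d", seq_len(nrow(samples)))
    samples$depth_factor <- rlnorm(nrow(samples), 0, config$depth_factor_sdlog)
    colnm <- sprintf("%s__%s__%s__%d", samples$sample_id, samples$stage,
                     samples$condition, samples$replicate)

    counts <- matrix(0L, ng, nrow(samples), dimnames = list(gdf$gene_id, colnm))
    for (j in seq_len(nrow(samples))) {
      st <- match(samples$stage[j], stages)
      eff <- if (st == 1L) 0 else cond_lfc * (samples$condition[j] == "knockdown")
      mu <- samples$depth_factor[j] * baseline * 2 ^ (offsets[st, ] + eff)
      counts[, j] <- rnbinom(ng, size = 1 / config$nb_dispersion, mu = mu)
    }
    storage.mode(counts) <- "integer"
    gene_truth <- data.frame(gene_id = gdf$gene_id,
                             true_meth_class = gt$true_meth_class,
                             depletion = gt$depletion,
                             trajectory = traj,
                             baseline = baseline,
                             cond_lfc = cond_lfc,
                             indirect_up = indirect,
                             stringsAsFactors = FALSE)
    structure(list(counts = counts, samples = samples, gene_truth = gene_truth),
              class = "expr_set")
  })
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("Expression set: %d genes x %d samples (%s; conditions %s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$samples$stage), collapse = "/"),
              paste(unique(x$samples$condition), collapse = "/")))
  invisible(x)
}

#' Run the whole generator
#'
#' Convenience wrapper producing gene models, CpG map, true methylome,
#' per-sample bisulfite count tables and the expression set in one call.
#'
#' @param config A [sim_config()].
#' @return List of class `gbm_sim` with elements `genes`, `cpgs`, `truth`,
#'   `wgbs_samples`, `wgbs`, `expr`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  gen <- simulate_genome(config)
  truth <- simulate_true_methylome(gen$genes, gen$cpgs, config)
  wsamp <- sim_wgbs_samples(config)
  wgbs <- simulate_wgbs_counts(truth, wsamp, config)
  expr <- simulate_expression(gen$genes, truth, config)
  structure(list(genes = gen$genes, cpgs = gen$cpgs, truth = truth,
                 wgbs_samples = wsamp, wgbs = wgbs, expr = expr,
                 config = config),
            class = "gbm_sim")
}

#' @export
print.gbm_sim <- function(x, ...) {
  cat(sprintf("Simulated GBM dataset: %d genes, %d CpGs, %d WGBS samples, %d RNA samples\n",
              nrow(x$genes$genes), nrow(x$cpgs), length(x$wgbs),
              ncol(x$expr$counts)))
  invisible(x)
}
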