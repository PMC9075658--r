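#' Simulation configuration
#'
#' Builds and validates the configuration of the synthetic-data generator.
#' The defaults describe a wasp-embryo knockdown experiment at the scale the
#' pipeline is demonstrated on: ~2,000 genes of which about a third carry
#' gene body methylation, ~15x Poisson CpG coverage, bisulfite non-conversion
#' rates near 0.005, a strongly bimodal methylated/unmethylated split, 5'-
#' biased exon-enriched intragenic methylation, an average 81.5% loss of true
#' methylation under knockdown, and a four-stage (egg to late blastoderm)
#' expression time course in which the knockdown effect of methylated genes
#' is coupled to their relative methylation loss.
#'
#' @param seed Integer seed; identical seed + config reproduces byte-identical
#'   simulated data in every generator.
#' @param n_genes Number of genes to simulate.
#' @param frac_methylated_genes Proportion of genes drawn into the methylated
#'   class.
#' @param exons_per_gene_mean Mean exon count per gene (1 + Poisson).
#' @param cpgs_per_exon_mean,cpgs_per_intron_mean Mean CpG count per exon /
#'   intron (Poisson).
#' @param exon_length,intron_length,intergenic_gap Feature sizes in bp used to
#'   lay genes along the simulated chromosomes.
#' @param n_chroms Number of chromosomes genes are distributed over.
#' @param intergenic_cpg_frac Fraction of all CpGs placed outside gene bodies.
#' @param coverage_mean Mean reads per CpG (lambda of the coverage
#'   distribution).
#' @param coverage_model `"poisson"` (default) or `"nb"`; `coverage_nb_size`
#'   is the negative-binomial size when `"nb"` is chosen.
#' @param coverage_nb_size Size parameter of the NB coverage option.
#' @param nonconversion_control,nonconversion_knockdown Per-replicate bisulfite
#'   non-conversion rates (probability an unmethylated C reads as methylated);
#'   recycled to `n_replicates`.
#' @param over_conversion Probability a truly methylated C reads as
#'   unmethylated (0 by default; the caller ignores this failure mode, the
#'   knob exists to stress it).
#' @param meth_beta_shape1,meth_beta_shape2 Beta parameters of the gene-level
#'   methylation of the methylated class (defaults give mean 0.8).
#' @param background_m True methylation of unmethylated-class and intergenic
#'   CpGs.
#' @param five_prime_decay Multiplicative decay of methylation per exon rank
#'   (rank 1 is 5'); 1 means flat.
#' @param intron_m_factor Multiplier applied to introns relative to the
#'   upstream exon, enforcing exon > intron methylation in expectation.
#' @param depletion Mean proportion by which true methylation is multiplied
#'   down under knockdown (d; 0.815 by default).
#' @param depletion_concentration Concentration of the per-gene Beta
#'   distribution of depletion around `depletion`; `Inf` makes the depletion
#'   exactly `depletion` for every gene.
#' @param n_replicates Replicates per condition (both assays).
#' @param stages Ordered stage labels of the expression time course.
#' @param expr_meanlog,expr_sdlog Log-scale mean/sd of baseline expression.
#' @param nb_dispersion Per-gene NB overdispersion of expression counts.
#' @param coupling_gamma Slope linking a methylated gene's relative GBM change
#'   to its knockdown log2 fold change in post-egg stages.
#' @param coupling_noise_sd Gene-level noise (log2) around the coupled effect.
#' @param indirect_up_fraction Fraction of unmethylated genes indirectly
#'   upregulated under knockdown.
#' @param indirect_up_lfc Their log2 effect size.
#' @param maternal_frac,zygotic_frac Fractions of genes with maternal-decay and
#'   zygotic-activation trajectories (the remainder is flat).
#' @param maternal_lfc_step Per-transition log2 step of maternal decay.
#' @param zga_lfc Log2 jump of zygotic genes at the middle-blastoderm stage.
#' @param depth_factor_sdlog Log-sd of per-sample library-size multipliers.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       frac_methylated_genes = 0.32,
                       exons_per_gene_mean = 4,
                       cpgs_per_exon_mean = 3.5,
                       cpgs_per_intron_mean = 1.5,
                       exon_length = 300L,
                       intron_length = 400L,
                       intergenic_gap = 1000L,
                       n_chroms = 5L,
                       intergenic_cpg_frac = 0.07,
                       coverage_mean = 15,
                       coverage_model = c("poisson", "nb"),
                       coverage_nb_size = 10,
                       nonconversion_control = c(0.0052, 0.0051, 0.0055),
                       nonconversion_knockdown = c(0.0052, 0.0051, 0.0053),
                       over_conversion = 0,
                       meth_beta_shape1 = 8,
                       meth_beta_shape2 = 2,
                       background_m = 0,
                       five_prime_decay = 0.9,
                       intron_m_factor = 0.6,
                       depletion = 0.815,
                       depletion_concentration = 20,
                       n_replicates = 3L,
                       stages = DEFAULT_STAGES,
                       expr_meanlog = log(250),
                       expr_sdlog = 1.2,
                       nb_dispersion = 0.05,
                       coupling_gamma = 1,
                       coupling_noise_sd = 0.25,
                       indirect_up_fraction = 0.1,
                       indirect_up_lfc = 1,
                       maternal_frac = 0.3,
                       zygotic_frac = 0.4,
                       maternal_lfc_step = -1.5,
                       zga_lfc = 2.5,
                       depth_factor_sdlog = 0.08) {
  coverage_model <- match.arg(coverage_model)
  cfg <- list(
    seed = check_count(seed, "seed", allow_zero = TRUE),
    n_genes = check_count(n_genes, "n_genes", allow_zero = TRUE),
    frac_methylated_genes = check_prop(frac_methylated_genes,
                                       "frac_methylated_genes",
                                       open0 = TRUE, open1 = TRUE),
    exons_per_gene_mean = exons_per_gene_mean,
    cpgs_per_exon_mean = cpgs_per_exon_mean,
    cpgs_per_intron_mean = cpgs_per_intron_mean,
    exon_length = check_count(exon_length, "exon_length"),
    intron_length = check_count(intron_length, "intron_length"),
    intergenic_gap = check_count(intergenic_gap, "intergenic_gap"),
    n_chroms = check_count(n_chroms, "n_chroms"),
    intergenic_cpg_frac = check_prop(intergenic_cpg_frac,
                                     "intergenic_cpg_frac", open1 = TRUE),
    coverage_mean = coverage_mean,
    coverage_model = coverage_model,
    coverage_nb_size = coverage_nb_size,
    nonconversion_control = check_prop(nonconversion_control,
                                       "nonconversion_control", open1 = TRUE),
    nonconversion_knockdown = check_prop(nonconversion_knockdown,
                                         "nonconversion_knockdown",
                                         open1 = TRUE),
    over_conversion = check_prop(over_conversion, "over_conversion",
                                 open1 = TRUE),
    meth_beta_shape1 = meth_beta_shape1,
    meth_beta_shape2 = meth_beta_shape2,
    background_m = check_prop(background_m, "background_m", open1 = TRUE),
    five_prime_decay = check_prop(five_prime_decay, "five_prime_decay",
                                  open0 = TRUE),
    intron_m_factor = check_prop(intron_m_factor, "intron_m_factor",
                                 open0 = TRUE),
    depletion = check_prop(depletion, "depletion"),
    depletion_concentration = depletion_concentration,
    n_replicates = check_count(n_replicates, "n_replicates"),
    stages = stages,
    expr_meanlog = expr_meanlog,
    expr_sdlog = expr_sdlog,
    nb_dispersion = nb_dispersion,
    coupling_gamma = coupling_gamma,
    coupling_noise_sd = coupling_noise_sd,
    indirect_up_fraction = check_prop(indirect_up_fraction,
                                      "indirect_up_fraction"),
    indirect_up_lfc = indirect_up_lfc,
    maternal_frac = check_prop(maternal_frac, "maternal_frac"),
    zygotic_frac = check_prop(zygotic_frac, "zygotic_frac"),
    maternal_lfc_step = maternal_lfc_step,
    zga_lfc = zga_lfc,
    depth_factor_sdlog = depth_factor_sdlog
  )
  if (cfg$exons_per_gene_mean < 1) {
    stop_config("exons_per_gene_mean", "must be >= 1")
  }
  if (cfg$cpgs_per_exon_mean < 0) stop_config("cpgs_per_exon_mean", "must be >= 0")
  if (cfg$cpgs_per_intron_mean < 0) stop_config("cpgs_per_intron_mean", "must be >= 0")
  if (cfg$coverage_mean <= 0) stop_config("coverage_mean", "must be > 0")
  if (cfg$coverage_nb_size <= 0) stop_config("coverage_nb_size", "must be > 0")
  if (cfg$meth_beta_shape1 <= 0 || cfg$meth_beta_shape2 <= 0) {
    stop_config("meth_beta_shape", "Beta shapes must be > 0")
  }
  if (!is.infinite(cfg$depletion_concentration) &&
      cfg$depletion_concentration <= 0) {
    stop_config("depletion_concentration", "must be > 0 (or Inf)")
  }
  if (cfg$nb_dispersion <= 0) stop_config("nb_dispersion", "must be > 0")
  if (cfg$expr_sdlog < 0) stop_config("expr_sdlog", "must be >= 0")
  if (cfg$coupling_noise_sd < 0) stop_config("coupling_noise_sd", "must be >= 0")
  if (cfg$depth_factor_sdlog < 0) stop_config("depth_factor_sdlog", "must be >= 0")
  if (anyDuplicated(cfg$stages)) stop_config("stages", "labels must be unique")
  if (length(cfg$stages) < 2) stop_config("stages", "need >= 2 ordered stages")
  if (cfg$maternal_frac + cfg$zygotic_frac > 1) {
    stop_config("maternal_frac", "maternal_frac + zygotic_frac must be <= 1")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic WGBS/RNA-seq simulation configuration\n")
  cat(sprintf("  seed %d; %d genes (%.0f%% methylated class), %d chroms\n",
              x$seed, x$n_genes, 100 * x$frac_methylated_genes, x$n_chroms))
  cat(sprintf("  coverage %s(mean %.1f); non-conversion %s / %s\n",
              x$coverage_model, x$coverage_mean,
              paste(x$nonconversion_control, collapse = ","),
              paste(x$nonconversion_knockdown, collapse = ",")))
  cat(sprintf("  knockdown depletion d = %.3f; coupling gamma = %.2f\n",
              x$depletion, x$coupling_gamma))
  cat(sprintf("  stages: %s; %d replicates per condition\n",
              paste(x$stages, collapse = " -> "), x$n_replicates))
  invisible(x)
}
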