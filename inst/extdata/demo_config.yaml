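# Demo pipeline configuration: a synthetic knockdown experiment at the
# scale the pipeline is demonstrated on (~2,000 genes, ~40,000 CpGs, four
# stages x two conditions x three replicates). All analysis thresholds
# default to the standard values of this analysis tradition.
seed: 1
out_dir: gbm_demo_run
n_genes: 2000
alpha: 0.05
gene_threshold: 0.02
dm_fdr: 0.1
de_fdr: 0.1
transition_fold: 2
min_max_count: 10
cluster_k: 3
log_level: info
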