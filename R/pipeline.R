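# End-to-end pipeline driver: simulate -> callmeth -> diffmeth -> diffexpr
# -> integrate, with a flat YAML config, per-stage output files, a JSON run
# manifest with input/output checksums, and checksum-based stage resumption.

default_pipeline_config <- function() {
  list(seed = 1L, out_dir = "gbm_run", n_genes = 2000L,
       alpha = 0.05, gene_threshold = 0.02, dm_fdr = 0.1, de_fdr = 0.1,
       transition_fold = 2, min_max_count = 10, cluster_k = 3L,
       log_level = "info")
}

read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- utils::modifyList(default_pipeline_config(), cfg)
  out
}

pipe_log <- function(level, cfg, fmt, ...) {
  levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)
  if (levels[[level]] >= levels[[cfg$log_level %||% "info"]]) {
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  }
}

checksum_files <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

#' Validate pipeline inputs
#'
#' Checks the sample sheet and referenced files: format dialects parse,
#' methylated counts never exceed totals, every (stage, condition) cell of
#' the expression design has at least two replicates, and every wgbs sample
#' carries a non-conversion rate. Problems are reported, not thrown.
#'
#' @param sample_sheet A `sample_sheet` data frame (or path to one).
#' @param base_dir Directory file paths in the sheet are relative to.
#' @param stages Ordered stage labels.
#' @return Data frame of class `validation_report` with columns level
#'   ("error"/"warning") and message; zero rows means a clean run.
#' @export
validate_inputs <- function(sample_sheet, base_dir = ".",
                            stages = DEFAULT_STAGES) {
  if (is.character(sample_sheet)) {
    sample_sheet <- tryCatch(read_sample_sheet(sample_sheet, stages),
                             error = function(e) e)
    if (inherits(sample_sheet, "error")) {
      out <- data.frame(level = "error",
                        message = conditionMessage(sample_sheet),
                        stringsAsFactors = FALSE)
      class(out) <- c("validation_report", "data.frame")
      return(out)
    }
  }
  issues <- list()
  add <- function(level, msg) {
    issues[[length(issues) + 1L]] <<- data.frame(level = level, message = msg,
                                                 stringsAsFactors = FALSE)
  }
  wgbs <- sample_sheet[sample_sheet$assay == "wgbs", ]
  for (i in seq_len(nrow(wgbs))) {
    if (is.null(wgbs$nonconversion) || is.na(wgbs$nonconversion[i])) {
      add("error", sprintf("wgbs sample %s: missing nonconversion rate",
                           wgbs$sample_id[i]))
    }
    if (!is.null(wgbs$path)) {
      fp <- file.path(base_dir, wgbs$path[i])
      if (!file.exists(fp)) {
        add("error", sprintf("wgbs sample %s: file not found: %s",
                             wgbs$sample_id[i], wgbs$path[i]))
      } else {
        cc <- tryCatch(read_methylation_counts(fp, wgbs$sample_id[i]),
                       error = function(e) e)
        if (inherits(cc, "error")) {
          add("error", sprintf("wgbs sample %s: %s", wgbs$sample_id[i],
                               conditionMessage(cc)))
        } else if (any(cc$k > cc$n)) {
          add("error", sprintf("wgbs sample %s: k > n", wgbs$sample_id[i]))
        }
      }
    }
  }
  rna <- sample_sheet[sample_sheet$assay == "rnaseq", ]
  if (nrow(rna)) {
    cells <- table(rna$stage, rna$condition)
    for (st in rownames(cells)) for (cd in colnames(cells)) {
      if (cells[st, cd] > 0L && cells[st, cd] < 2L) {
        add("error", sprintf(
          "stage %s / %s has %d replicate(s); differential expression needs >= 2",
          st, cd, cells[st, cd]))
      }
    }
  }
  out <- if (length(issues)) do.call(rbind, issues) else
    data.frame(level = character(), message = character(),
               stringsAsFactors = FALSE)
  class(out) <- c("validation_report", "data.frame")
  out
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0L) cat("Input validation: no issues\n")
  else {
    cat(sprintf("Input validation: %d error(s), %d warning(s)\n",
                sum(x$level == "error"), sum(x$level == "warning")))
    for (i in seq_len(nrow(x))) cat(sprintf("  [%s] %s\n", x$level[i],
                                            x$message[i]))
  }
  invisible(x)
}

#' Run the whole pipeline
#'
#' Executes simulate, methylation calling, differential methylation,
#' differential expression and integration in order, writing each stage's
#' outputs (TSV/JSON) under `out_dir` and a run manifest recording the seed,
#' package version, config hash and per-stage file checksums. On re-runs,
#' stages whose recorded input checksums still match are skipped and their
#' outputs reused.
#'
#' @param config Path to a flat YAML config, or a named list; recognised keys
#'   (all optional) are seed, out_dir, n_genes, alpha, gene_threshold,
#'   dm_fdr, de_fdr, transition_fold, min_max_count, cluster_k, log_level,
#'   plus any [sim_config()] argument.
#' @param out_dir Output directory (overrides the config value).
#' @return The `run_manifest` (invisibly the full result list is attached as
#'   attribute `results`).
#' @export
run_all <- function(config = list(), out_dir = NULL) {
  cfg_hash <- NA_character_
  if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("config not found: %s", config),
                                   call. = FALSE)
    cfg_hash <- unname(tools::md5sum(config))
    config <- read_pipeline_config(config)
  } else {
    config <- utils::modifyList(default_pipeline_config(), config)
  }
  if (!is.null(out_dir)) config$out_dir <- out_dir
  od <- config$out_dir
  dir.create(od, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(od, "manifest.json")
  prev <- if (file.exists(manifest_path)) {
    tryCatch(jsonlite::read_json(manifest_path), error = function(e) NULL)
  } else NULL

  sim_args <- intersect(names(config), names(formals(sim_config)))
  scfg <- do.call(sim_config, config[sim_args])
  stages_run <- list()

  # --- simulate ---------------------------------------------------------
  sim_files <- file.path(od, c("genes.bed", "expression.tsv", "truth.tsv",
                               "wgbs_samples.tsv"))
  sim_key <- list(seed = scfg$seed, n_genes = scfg$n_genes)
  reuse_sim <- !is.null(prev$stages$simulate) &&
    identical(prev$stages$simulate$key, sim_key) &&
    all(file.exists(sim_files))
  sim <- simulate_dataset(scfg)   # in-memory objects always rebuilt (seeded)
  if (!reuse_sim) {
    pipe_log("info", config, "simulate: writing synthetic dataset to %s", od)
    write_gene_models_bed12(sim$genes, sim_files[1])
    write_expression_tsv(sim$expr, sim_files[2])
    write_truth_sidecar(sim, sim_files[3])
    write.table(sim$wgbs_samples, sim_files[4], sep = "\t", quote = FALSE,
                row.names = FALSE)
    for (sid in names(sim$wgbs)) {
      write_methylation_counts(sim$wgbs[[sid]],
                               file.path(od, sprintf("%s.cov", sid)))
    }
  } else {
    pipe_log("info", config, "simulate: outputs up to date, skipped rewrite")
  }
  stages_run$simulate <- list(key = sim_key, outputs = checksum_files(sim_files))

  # --- callmeth ---------------------------------------------------------
  pipe_log("info", config, "callmeth: binomial calling at alpha %.3g",
           config$alpha)
  calls <- lapply(names(sim$wgbs), function(sid) {
    i <- match(sid, sim$wgbs_samples$sample_id)
    call_sample(sim$wgbs[[sid]], e = sim$wgbs_samples$nonconversion[i],
                alpha = config$alpha)
  })
  names(calls) <- names(sim$wgbs)
  ctrl <- calls[sim$wgbs_samples$condition == "control"]
  gm <- gene_body_methylation(ctrl, sim$genes,
                              threshold = config$gene_threshold)
  prof <- metagene_profile(ctrl, sim$genes, gene_table = gm)
  gm_path <- file.path(od, "gene_methylation.tsv")
  write.table(as.data.frame(gm), gm_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(as.data.frame(prof), file.path(od, "metagene_profile.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (sid in names(calls)) {
    write.table(as.data.frame(calls[[sid]]),
                file.path(od, sprintf("calls_%s.tsv", sid)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  stages_run$callmeth <- list(
    outputs = checksum_files(c(gm_path, file.path(od, "metagene_profile.tsv"))))

  # --- diffmeth ---------------------------------------------------------
  pipe_log("info", config, "diffmeth: per-CpG two-group test at FDR %.2g",
           config$dm_fdr)
  ret <- retain_sites(ctrl, sim$wgbs)
  dm <- dm_test(ret, fdr = config$dm_fdr)
  dep <- depletion_summary(dm)
  rg <- gene_relative_gbm_change(dm, sim$genes)
  write.table(as.data.frame(dm), file.path(od, "dm_sites.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(rg, file.path(od, "gene_gbm_change.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(dep), file.path(od, "depletion_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  stages_run$diffmeth <- list(outputs = checksum_files(
    file.path(od, c("dm_sites.tsv", "gene_gbm_change.tsv",
                    "depletion_summary.json"))))

  # --- diffexpr ---------------------------------------------------------
  pipe_log("info", config, "diffexpr: NB Wald per stage at FDR %.2g",
           config$de_fdr)
  expr_f <- suppressMessages(
    filter_low_expression(sim$expr, threshold = config$min_max_count))
  sf <- size_factors(expr_f$counts)
  de_list <- de_all_stages(expr_f, sf = sf, fdr = config$de_fdr)
  for (s in names(de_list)) {
    write.table(as.data.frame(de_list[[s]]),
                file.path(od, sprintf("de_%s.tsv", s)), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  write.table(data.frame(sample = names(sf), size_factor = as.numeric(sf)),
              file.path(od, "size_factors.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  trans <- transition_fold_changes(expr_f, sf = sf,
                                   fold = config$transition_fold)
  stages_run$diffexpr <- list(outputs = checksum_files(
    file.path(od, c(sprintf("de_%s.tsv", names(de_list)), "size_factors.tsv"))))

  # --- integrate --------------------------------------------------------
  pipe_log("info", config, "integrate: contingency, correlation, clustering")
  report <- integration_report(de_list, gm, rg, expr_f, sf = sf,
                               cluster_k = config$cluster_k)
  report_json <- list(
    n_union_degs = report$n_union_degs, n_mdeg = report$n_mdeg,
    n_udeg = report$n_udeg,
    per_stage = lapply(report$per_stage, function(ps) list(
      n_degs = ps$n_degs,
      fisher_direction_p = ps$tables$fisher_direction$p,
      odds_ratio = ps$tables$fisher_direction$odds_ratio,
      rho = ps$correlation$rho, rho_p = ps$correlation$p,
      rho_n = ps$correlation$n)),
    depletion = unclass(dep))
  jsonlite::write_json(report_json, file.path(od, "integration_report.json"),
                       auto_unbox = TRUE, digits = NA)
  stages_run$integrate <- list(outputs = checksum_files(
    file.path(od, "integration_report.json")))

  manifest <- list(config_hash = cfg_hash, seed = scfg$seed,
                   version = as.character(utils::packageVersion("gbmkit")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   stages = stages_run)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  res <- list(sim = sim, calls = calls, gene_meth = gm, profile = prof,
              dm = dm, depletion = dep, rg = rg, de = de_list,
              size_factors = sf, transitions = trans, report = report)
  structure(manifest, class = "run_manifest", results = res)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("Pipeline run manifest (seed %s, version %s)\n", x$seed,
              x$version))
  cat(sprintf("  stages: %s\n", paste(names(x$stages), collapse = " -> ")))
  invisible(x)
}
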