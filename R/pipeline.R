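#' Preset configurations for a full simulation experiment
#'
#' `desk_config()` is sized so a full run completes in minutes on one core:
#' n = 400 individuals per population, 20 genes of 150 sites, k = 10, three
#' sharing levels, 3 replicates, 10-fold external CV. `paper_config()`
#' mirrors the full-scale design (n = 1000, 98 genes, k in {1, 10, 20, 40},
#' 11 sharing levels, 100 replicates, LOOCV external CV) and is intended for
#' cluster-scale runs; validate it with `run_experiment(..., dry_run =
#' TRUE)`.
#'
#' @param master_seed Master seed from which all stage seeds derive.
#' @return A `run_config` list.
#' @export
desk_config <- function(master_seed = 1) {
  structure(list(
    master_seed = master_seed,
    scale = "desk",
    n = 400, n_genes = 20, sites_per_gene = 150,
    n_haplotypes = 200, n_founders = 12, mutation_prob = 0.002,
    switch_prob_scale = 0.02, drift_rounds = 40,
    admix_alpha = 0.8,
    k_list = 10, p_list = c(0, 0.5, 1), h2 = 0.15,
    n_replicates = 3,
    external_scheme = "kfold", external_k = 10, internal_folds = 10,
    mixing = 0.5, lambda_choice = "min",
    twas_h2_pheno = 0.205, twas_sigma2 = 0.01, twas_replicates = 50,
    alpha_level = 0.05, n_genes_for_bonferroni = 98,
    sweep_alphas = NULL
  ), class = "run_config")
}

#' @rdname desk_config
#' @export
paper_config <- function(master_seed = 1) {
  cfg <- desk_config(master_seed)
  cfg$scale <- "paper"
  cfg$n <- 1000
  cfg$n_genes <- 98
  cfg$sites_per_gene <- 205
  cfg$k_list <- c(1, 10, 20, 40)
  cfg$p_list <- seq(0, 1, by = 0.1)
  cfg$n_replicates <- 100
  cfg$external_scheme <- "loocv"
  cfg$internal_folds <- 10
  cfg$twas_replicates <- 100
  cfg$sweep_alphas <- seq(0, 1, by = 0.1)
  cfg
}

#' Validate a run configuration
#'
#' @param config A `run_config` list.
#' @return `TRUE` invisibly; otherwise an error naming the offending fields.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  need <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  need(is.numeric(config$master_seed) && length(config$master_seed) == 1,
       "master_seed: single integer required")
  need(config$n >= 2, "n: at least 2 individuals")
  need(config$n_genes >= 1, "n_genes: at least 1")
  need(config$sites_per_gene >= 2, "sites_per_gene: at least 2")
  need(all(config$k_list >= 1), "k_list: k >= 1")
  need(all(config$p_list >= 0 & config$p_list <= 1), "p_list: p in [0, 1]")
  need(config$h2 > 0 && config$h2 < 1, "h2: in (0, 1)")
  need(config$n_replicates >= 1, "n_replicates: at least 1")
  need(config$external_scheme %in% c("kfold", "loocv"),
       "external_scheme: 'kfold' or 'loocv'")
  need(all(config$sites_per_gene >= 2 * config$k_list),
       "sites_per_gene: needs at least 2k sites per gene")
  need(config$twas_sigma2 > 0, "twas_sigma2: positive")
  need(is.null(config$sweep_alphas) ||
         all(config$sweep_alphas >= 0 & config$sweep_alphas <= 1),
       "sweep_alphas: in [0, 1]")
  if (length(problems)) {
    stop("invalid config:\n  ", paste(problems, collapse = "\n  "))
  }
  invisible(TRUE)
}

#' Run the full simulation experiment
#'
#' Executes population simulation, architecture and expression simulation,
#' model training, cross-population evaluation, and TWAS power estimation
#' for every scenario in the configuration grid, writing all tables and a
#' structured log to `output_dir`. The run is idempotent given the master
#' seed: rerunning with the same config reproduces byte-identical tables.
#' Completed stage outputs are reused when `resume = TRUE`.
#'
#' @param config A `run_config` from [desk_config()] or [paper_config()].
#' @param output_dir Output directory (created if absent).
#' @param dry_run Validate the config and report the planned grid without
#'   executing.
#' @param resume Skip stages whose output files already exist.
#' @return `output_dir`, invisibly. Writes `config.json`, `fst.tsv`,
#'   `scores.tsv`, `summaries.tsv`, `sharing_curve.tsv`, `power.tsv`,
#'   optionally `admixture_sweep.tsv`, and `log.txt`.
#' @export
run_experiment <- function(config, output_dir, dry_run = FALSE, resume = FALSE) {
  validate_config(config)
  pairs <- expand.grid(train = c("A", "B", "admixed"),
                       test = c("A", "B", "admixed"),
                       stringsAsFactors = FALSE)
  if (dry_run) {
    message(sprintf(
      "dry run: %d genes x %d sites, n = %d, k in {%s}, p in {%s}, %d replicates, %d train-test pairs",
      config$n_genes, config$sites_per_gene, config$n,
      paste(config$k_list, collapse = ","),
      paste(config$p_list, collapse = ","),
      config$n_replicates, nrow(pairs)))
    return(invisible(output_dir))
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(output_dir, "log.txt")
  log_line <- function(...) {
    msg <- sprintf(...)
    cat(format(Sys.time(), "%H:%M:%S"), msg, "\n", file = log_path,
        append = TRUE)
    message(msg)
  }
  jsonlite::write_json(unclass(config), file.path(output_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  seeds <- split_seeds(config$master_seed, 7,
                       c("panel", "drift_A", "drift_B", "expand_A", "expand_B",
                         "admix", "grid"))
  regions <- make_gene_regions(config$n_genes, config$sites_per_gene)
  S <- config$n_genes * config$sites_per_gene

  log_line("simulating panels (%d sites, %d haplotypes)", S, config$n_haplotypes)
  anc <- generate_ancestral_panel(S, config$n_haplotypes, config$n_founders,
                                  config$mutation_prob,
                                  config$switch_prob_scale, seed = seeds["panel"])
  pan_A <- derive_population_panel(anc, config$drift_rounds, seed = seeds["drift_A"],
                                   pop_label = "A")
  pan_B <- derive_population_panel(anc, config$drift_rounds, seed = seeds["drift_B"],
                                   pop_label = "B")
  fst <- estimate_fst(pan_A, pan_B)
  write_table_tsv(data.frame(comparison = "A_vs_B", mean_fst = fst$mean_fst,
                             estimator = fst$estimator),
                  file.path(output_dir, "fst.tsv"))
  log_line("mean Hudson F_ST between derived panels: %.4f", fst$mean_fst)

  samples <- list(
    A = expand_population(pan_A, config$n, seed = seeds["expand_A"],
                          pop_label = "A", role = "A"),
    B = expand_population(pan_B, config$n, seed = seeds["expand_B"],
                          pop_label = "B", role = "B"),
    admixed = sample_admixed(pan_A, pan_B, config$n, config$admix_alpha,
                             regions, seed = seeds["admix"],
                             pop_label = "admixed"))

  scores_path <- file.path(output_dir, "scores.tsv")
  power_path <- file.path(output_dir, "power.tsv")
  if (resume && file.exists(scores_path) && file.exists(power_path)) {
    log_line("resume: scores.tsv and power.tsv present, skipping grid")
    scores <- as.data.frame(data.table::fread(scores_path))
  } else {
    grid <- expand.grid(k = config$k_list, p = config$p_list,
                        replicate = seq_len(config$n_replicates))
    gseeds <- split_seeds(seeds["grid"], nrow(grid) * 3)
    all_scores <- list()
    all_power <- list()
    maf_A <- compute_maf(samples$A)
    maf_B <- compute_maf(samples$B)
    for (i in seq_len(nrow(grid))) {
      k <- grid$k[i]; p <- grid$p[i]; rep_i <- grid$replicate[i]
      s_arch <- gseeds[3 * i - 2]; s_expr <- gseeds[3 * i - 1]; s_train <- gseeds[3 * i]
      arch <- sample_architecture(regions, maf_A, maf_B, k = k, p = p, seed = s_arch)
      exprs <- lapply(samples, function(smp)
        simulate_expression(smp, arch, h2 = config$h2, seed = s_expr + smp$n))
      wts <- lapply(names(samples), function(nm)
        train_population(samples[[nm]], exprs[[nm]], regions,
                         external_scheme = config$external_scheme,
                         external_k = config$external_k,
                         internal_folds = config$internal_folds,
                         mixing = config$mixing,
                         lambda_choice = config$lambda_choice,
                         seed = s_train + match(nm, names(samples))))
      names(wts) <- names(samples)
      preds <- list()
      for (j in seq_len(nrow(pairs))) {
        tr <- pairs$train[j]; te <- pairs$test[j]
        pred <- if (tr == te) oos_predictions(wts[[tr]])
                else predict_expression(wts[[tr]], samples[[te]])
        keep <- apply_model_filters(wts[[tr]], pred)$keep
        scen <- list(train = tr, test = te, k = k, p = p, replicate = rep_i)
        if (length(keep)) {
          all_scores[[length(all_scores) + 1L]] <-
            score_predictions(pred, exprs[[te]], scenario = scen, genes = keep)
        }
        pred$values <- pred$values[keep, , drop = FALSE]
        preds[[paste0(tr, "->", te)]] <- pred
      }
      if (rep_i == 1L && k == max(config$k_list)) {
        for (j in seq_len(nrow(pairs))) {
          tr <- pairs$train[j]; te <- pairs$test[j]
          nm <- paste0(tr, "->", te)
          pe <- estimate_power(exprs[[te]], preds[nm],
                               h2_pheno = config$twas_h2_pheno,
                               sigma2 = config$twas_sigma2,
                               n_replicates = config$twas_replicates,
                               alpha_level = config$alpha_level,
                               n_genes_for_bonferroni = config$n_genes_for_bonferroni,
                               seed = s_train + 101L + j)
          tab <- pe$table
          tab$train <- tr; tab$test <- te; tab$k <- k; tab$p <- p
          all_power[[length(all_power) + 1L]] <- tab
        }
      }
      log_line("grid cell k=%d p=%.2f replicate %d done", k, p, rep_i)
    }
    scores <- do.call(rbind, all_scores)
    write_table_tsv(scores, scores_path)
    write_table_tsv(do.call(rbind, all_power), power_path)
  }

  summaries <- rbind(summarize_scenarios(scores, "all"),
                     summarize_scenarios(scores, "positive_only"))
  write_table_tsv(summaries, file.path(output_dir, "summaries.tsv"))
  sc <- sharing_curve(scores)
  write_table_tsv(sc$curve, file.path(output_dir, "sharing_curve.tsv"))

  if (!is.null(config$sweep_alphas)) {
    log_line("admixture sweep over %d alpha levels", length(config$sweep_alphas))
    sweep <- admixture_sweep(pan_A, pan_B, regions,
                             alphas = config$sweep_alphas, p = 0.5,
                             k = max(config$k_list), h2 = config$h2,
                             h2_pheno = config$twas_h2_pheno,
                             sigma2 = config$twas_sigma2, n = config$n,
                             n_replicates = config$twas_replicates,
                             external_scheme = config$external_scheme,
                             external_k = config$external_k,
                             internal_folds = config$internal_folds,
                             alpha_level = config$alpha_level,
                             n_genes_for_bonferroni = config$n_genes_for_bonferroni,
                             seed = config$master_seed + 17L)
    write_table_tsv(sweep, file.path(output_dir, "admixture_sweep.tsv"))
  }
  log_line("experiment complete")
  invisible(output_dir)
}

#' Assemble figure-shaped report tables from a completed run
#'
#' Reads the tables written by [run_experiment()] and reshapes them into the
#' three figure-shaped summaries of the study: mean correlation versus
#' shared-eQTL proportion per train-test pair, power per train-test scenario
#' at the configured heritability, and (when the sweep ran) power versus
#' admixture proportion. Missing stages raise an explicit error.
#'
#' @param output_dir Directory written by [run_experiment()].
#' @return A list with `correlation_vs_sharing`, `power_by_scenario`, and
#'   (optionally) `power_vs_admixture` data.frames; also writes
#'   `report.md` into `output_dir`.
#' @export
report_tables <- function(output_dir) {
  need <- function(f) {
    path <- file.path(output_dir, f)
    if (!file.exists(path)) stop("missing stage output: ", f)
    as.data.frame(data.table::fread(path))
  }
  curve <- need("sharing_curve.tsv")
  power <- need("power.tsv")
  out <- list(correlation_vs_sharing = curve,
              power_by_scenario = power[, c("train", "test", "k", "p",
                                            "level", "level_type", "power",
                                            "ci_lower", "ci_upper",
                                            "mean_h2_pheno")])
  sweep_path <- file.path(output_dir, "admixture_sweep.tsv")
  if (file.exists(sweep_path)) {
    out$power_vs_admixture <- as.data.frame(data.table::fread(sweep_path))
  }
  md <- c("# Simulation report", "",
          "## Mean Spearman correlation vs shared-eQTL proportion", "",
          utils::capture.output(print(curve, row.names = FALSE)), "",
          "## TWAS power by train-test scenario", "",
          utils::capture.output(print(out$power_by_scenario, row.names = FALSE)))
  if (!is.null(out$power_vs_admixture)) {
    md <- c(md, "", "## TWAS power vs admixture proportion", "",
            utils::capture.output(print(out$power_vs_admixture, row.names = FALSE)))
  }
  writeLines(md, file.path(output_dir, "report.md"))
  out
}
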