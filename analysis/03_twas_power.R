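#!/usr/bin/env Rscript
# Stage 3: TWAS power across train-test scenarios and sharing levels.
#
# Simulates n = 1000 populations (power depends directly on the
# test-population size and the 0.05/98 Bonferroni threshold, so this stage
# keeps the full-scale population size), trains prediction models in each
# population for sharing levels p = 0, 0.5, 1, and estimates the power to
# detect the causal gene for all nine train-test scenarios at phenotype
# heritabilities 0.06, 0.205, and 0.58. Writes the power table under
# results/power/.

suppressMessages(library(twasim))

out_dir <- "results/power"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

n <- 1000
n_genes <- 15
h2_pheno <- c(0.06, 0.205, 0.58)
p_grid <- c(0, 0.5, 1)
n_reps <- 100

seeds <- split_seeds(20210503, 6)
regions <- make_gene_regions(n_genes, 150)
anc <- generate_ancestral_panel(n_genes * 150, 200, seed = seeds[1])
pan_A <- derive_population_panel(anc, seed = seeds[2], pop_label = "CEU")
pan_B <- derive_population_panel(anc, seed = seeds[3], pop_label = "YRI")
samp <- list(
  CEU = expand_population(pan_A, n, seed = seeds[4], pop_label = "CEU",
                          role = "A"),
  YRI = expand_population(pan_B, n, seed = seeds[5], pop_label = "YRI",
                          role = "B"),
  AA = sample_admixed(pan_A, pan_B, n, 0.8, regions, seed = seeds[6],
                      pop_label = "AA"))
maf_A <- compute_maf(samp$CEU)
maf_B <- compute_maf(samp$YRI)

rows <- list()
for (p in p_grid) {
  ps <- split_seeds(20210504 + round(100 * p), 8)
  arch <- sample_architecture(regions, maf_A, maf_B, k = 10, p = p,
                              seed = ps[1])
  exprs <- lapply(seq_along(samp), function(j)
    simulate_expression(samp[[j]], arch, h2 = 0.15, seed = ps[1 + j]))
  names(exprs) <- names(samp)
  wts <- lapply(seq_along(samp), function(j)
    train_population(samp[[j]], exprs[[j]], regions, seed = ps[4 + j]))
  names(wts) <- names(samp)
  for (tr in names(samp)) {
    for (te in names(samp)) {
      pred <- if (tr == te) oos_predictions(wts[[tr]])
              else predict_expression(wts[[tr]], samp[[te]])
      keep <- apply_model_filters(wts[[tr]], pred)$keep
      pred$values <- pred$values[keep, , drop = FALSE]
      pe <- estimate_power(exprs[[te]], stats::setNames(list(pred),
                                                        paste0(tr, "->", te)),
                           h2_pheno = h2_pheno, n_replicates = n_reps,
                           seed = ps[8])
      tab <- pe$table
      tab$train <- tr; tab$test <- te; tab$p <- p; tab$k <- 10
      rows[[length(rows) + 1L]] <- tab
    }
    message(sprintf("p = %.1f, trained %s: power estimated for all targets",
                    p, tr))
  }
}
power <- do.call(rbind, rows)
write_table_tsv(power, file.path(out_dir, "power.tsv"))

mid <- power[power$level == 0.205, ]
message("power at phenotype heritability 0.205:")
for (p in p_grid) {
  sub <- mid[mid$p == p, ]
  within <- sub$power[sub$train == sub$test]
  cross <- sub$power[sub$train != sub$test]
  message(sprintf("  p = %.1f: within-population %.2f-%.2f, cross-population %.2f-%.2f",
                  p, min(within), max(within), min(cross), max(cross)))
}
message("wrote power table to ", out_dir)
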