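#!/usr/bin/env Rscript
# Stage 2: prediction quality versus shared-eQTL proportion.
#
# For each sharing level p, samples a k = 10 eQTL architecture, simulates
# expression at cis-h2 = 0.15 in CEU-like, YRI-like, and admixed samples,
# trains nested-CV elastic-net models in each population, and scores all
# nine train-test pairs (out-of-sample within population, model transfer
# across populations). Writes the long score table and the correlation
# versus sharing curve under results/sharing/.

suppressMessages(library(twasim))

out_dir <- "results/sharing"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- desk_config(master_seed = 20210502)
p_grid <- c(0, 0.25, 0.5, 0.75, 1)
n_reps <- 2

seeds <- split_seeds(cfg$master_seed, 6)
regions <- make_gene_regions(cfg$n_genes, cfg$sites_per_gene)
anc <- generate_ancestral_panel(cfg$n_genes * cfg$sites_per_gene,
                                cfg$n_haplotypes, cfg$n_founders,
                                seed = seeds[1])
pan_A <- derive_population_panel(anc, seed = seeds[2], pop_label = "CEU")
pan_B <- derive_population_panel(anc, seed = seeds[3], pop_label = "YRI")
samp <- list(
  CEU = expand_population(pan_A, cfg$n, seed = seeds[4], pop_label = "CEU",
                          role = "A"),
  YRI = expand_population(pan_B, cfg$n, seed = seeds[5], pop_label = "YRI",
                          role = "B"),
  AA = sample_admixed(pan_A, pan_B, cfg$n, cfg$admix_alpha, regions,
                      seed = seeds[6], pop_label = "AA"))
maf_A <- compute_maf(samp$CEU)
maf_B <- compute_maf(samp$YRI)

grid <- expand.grid(p = p_grid, replicate = seq_len(n_reps))
gseeds <- split_seeds(cfg$master_seed + 1, nrow(grid))
scores <- list()
for (i in seq_len(nrow(grid))) {
  p <- grid$p[i]
  rs <- split_seeds(gseeds[i], 7)
  arch <- sample_architecture(regions, maf_A, maf_B, k = 10, p = p,
                              seed = rs[1])
  exprs <- lapply(seq_along(samp), function(j)
    simulate_expression(samp[[j]], arch, h2 = cfg$h2, seed = rs[1 + j]))
  names(exprs) <- names(samp)
  wts <- lapply(seq_along(samp), function(j)
    train_population(samp[[j]], exprs[[j]], regions, seed = rs[4 + j]))
  names(wts) <- names(samp)
  for (tr in names(samp)) {
    for (te in names(samp)) {
      pred <- if (tr == te) oos_predictions(wts[[tr]])
              else predict_expression(wts[[tr]], samp[[te]])
      keep <- apply_model_filters(wts[[tr]], pred)$keep
      if (!length(keep)) next
      scores[[length(scores) + 1L]] <- score_predictions(
        pred, exprs[[te]],
        scenario = list(train = tr, test = te, k = 10, p = p,
                        replicate = grid$replicate[i]),
        genes = keep)
    }
  }
  message(sprintf("p = %.2f replicate %d scored", p, grid$replicate[i]))
}
scores <- do.call(rbind, scores)
write_table_tsv(scores, file.path(out_dir, "scores.tsv"))

sc <- sharing_curve(scores)
write_table_tsv(sc$curve, file.path(out_dir, "sharing_curve.tsv"))
write_table_tsv(sc$trend, file.path(out_dir, "sharing_trend.tsv"))

within <- sc$curve[sc$curve$train == sc$curve$test, ]
cross <- sc$curve[sc$curve$train != sc$curve$test, ]
message(sprintf("within-population mean rho: %.3f (ceiling sqrt(h2) = %.3f)",
                mean(within$mean_rho), sqrt(cfg$h2)))
message(sprintf("cross-population mean rho at p = 0: %.3f; at p = 1: %.3f",
                mean(cross$mean_rho[cross$p == 0]),
                mean(cross$mean_rho[cross$p == 1])))
trend_cross <- sc$trend[sc$trend$train != sc$trend$test, ]
message(sprintf("cross-population sharing trend statistic: min %.2f over %d pairs",
                min(trend_cross$trend_statistic), nrow(trend_cross)))
message("wrote scores and curves to ", out_dir)
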