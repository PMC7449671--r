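#!/usr/bin/env Rscript
# Stage 1: simulate the three study populations.
#
# Builds one ancestral founder-mosaic haplotype panel, derives two diverged
# population panels (CEU-like and YRI-like) by drift rounds calibrated to
# continental-scale F_ST, expands each to diploid samples, and samples an
# 80/20 admixed population with gene-level local ancestry. Writes the panels
# and a divergence report under results/populations/.

suppressMessages(library(twasim))

out_dir <- "results/populations"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- desk_config(master_seed = 20210501)
seeds <- split_seeds(cfg$master_seed, 6,
                     c("panel", "drift_A", "drift_B", "exp_A", "exp_B", "admix"))
regions <- make_gene_regions(cfg$n_genes, cfg$sites_per_gene)
S <- cfg$n_genes * cfg$sites_per_gene

message(sprintf("ancestral panel: %d sites, %d haplotypes, %d founders",
                S, cfg$n_haplotypes, cfg$n_founders))
anc <- generate_ancestral_panel(S, cfg$n_haplotypes, cfg$n_founders,
                                cfg$mutation_prob, cfg$switch_prob_scale,
                                seed = seeds["panel"])
pan_A <- derive_population_panel(anc, cfg$drift_rounds, seed = seeds["drift_A"],
                                 pop_label = "CEU")
pan_B <- derive_population_panel(anc, cfg$drift_rounds, seed = seeds["drift_B"],
                                 pop_label = "YRI")

fst <- estimate_fst(pan_A, pan_B)
message(sprintf("mean Hudson F_ST between derived panels: %.3f (%d informative sites)",
                fst$mean_fst, sum(is.finite(fst$per_site_fst))))

samp_A <- expand_population(pan_A, cfg$n, seed = seeds["exp_A"],
                            pop_label = "CEU", role = "A")
samp_B <- expand_population(pan_B, cfg$n, seed = seeds["exp_B"],
                            pop_label = "YRI", role = "B")
samp_AA <- sample_admixed(pan_A, pan_B, cfg$n, cfg$admix_alpha, regions,
                          seed = seeds["admix"], pop_label = "AA")
message(sprintf("samples: n = %d per population; AA gene-haplotype YRI fraction %.3f",
                cfg$n, mean(samp_AA$ancestry == "B")))

write_panel(pan_A, file.path(out_dir, "CEU"))
write_panel(pan_B, file.path(out_dir, "YRI"))
write_dosages(samp_A, file.path(out_dir, "CEU.dosages.tsv"))
write_dosages(samp_B, file.path(out_dir, "YRI.dosages.tsv"))
write_dosages(samp_AA, file.path(out_dir, "AA.dosages.tsv"))
write_table_tsv(data.frame(comparison = "CEU_vs_YRI", mean_fst = fst$mean_fst,
                           estimator = fst$estimator,
                           informative_sites = sum(is.finite(fst$per_site_fst))),
                file.path(out_dir, "fst.tsv"))
write_table_tsv(regions, file.path(out_dir, "regions.tsv"))
message("wrote panels, dosages, regions, and divergence report to ", out_dir)
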