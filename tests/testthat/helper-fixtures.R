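# Small shared fixtures, built once per test run. Sizes are kept minimal:
# two diverged panels over 2 gene regions of 150 sites, expanded to n = 200.
tiny <- local({
  regions <- make_gene_regions(2, 150)
  anc <- generate_ancestral_panel(300, 120, n_founders = 10, seed = 101)
  pan_A <- derive_population_panel(anc, 40, seed = 102, pop_label = "A")
  pan_B <- derive_population_panel(anc, 40, seed = 103, pop_label = "B")
  samp_A <- expand_population(pan_A, 200, seed = 104, role = "A")
  samp_B <- expand_population(pan_B, 200, seed = 105, role = "B")
  list(regions = regions, anc = anc, pan_A = pan_A, pan_B = pan_B,
       samp_A = samp_A, samp_B = samp_B,
       maf_A = compute_maf(samp_A), maf_B = compute_maf(samp_B))
})

# minimal hand-built weight_set over named sites, for predict/filter tests
manual_weight_set <- function(gene_weights, intercepts = NULL, train_pop = "A") {
  genes <- names(gene_weights)
  if (is.null(intercepts)) intercepts <- stats::setNames(rep(0, length(genes)), genes)
  models <- lapply(genes, function(g) {
    w <- gene_weights[[g]]
    list(weights = w, intercept = intercepts[[g]], oos = NULL, n_folds = 1L,
         n_folds_contributing = stats::setNames(rep(1L, length(w)), names(w)),
         flag = "ok")
  })
  names(models) <- genes
  structure(list(models = models,
                 oos = matrix(0, length(genes), 1, dimnames = list(genes, NULL)),
                 train_pop = train_pop, external_scheme = "kfold",
                 external_k = 1, internal_folds = 1, mixing = 0.5,
                 lambda_choice = "min", seed = 0L),
            class = "weight_set")
}

# minimal expression container for scoring/power tests
manual_expression <- function(values, pop_label = "test") {
  structure(list(values = values, genetic_values = values,
                 target_h2 = NA_real_,
                 realized_h2 = rep(NA_real_, nrow(values)),
                 degenerate = rep(FALSE, nrow(values)), pop_label = pop_label),
            class = "expression_matrix")
}

# minimal prediction container
manual_predictions <- function(values, train_pop = "A", target_pop = "B") {
  structure(list(values = values,
                 nonmissing_fraction = stats::setNames(rep(1, nrow(values)),
                                                       rownames(values)),
                 train_pop = train_pop, target_pop = target_pop),
            class = "prediction_matrix")
}
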