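# one moderately informative gene, reused across several blocks
trained_gene <- local({
  set.seed(201)
  arch <- sample_architecture(tiny$regions, tiny$maf_A, tiny$maf_B,
                              k = 5, p = 1, seed = 202)
  expr <- simulate_expression(tiny$samp_A, arch, h2 = 0.4, seed = 203)
  idx <- tiny$regions$start[1]:tiny$regions$end[1]
  X <- tiny$samp_A$dosages[, idx]
  y <- expr$values[1, ]
  list(X = X, y = y, arch = arch, expr = expr,
       fit = fit_gene_model(X, y, seed = 204))
})

test_that("averaged weights equal the sum of fold weights over all folds", {
  fit <- trained_gene$fit
  expect_equal(fit$flag, "ok")
  sums <- colSums(fit$fold_weights)
  expect_equal(unname(fit$weights * fit$n_folds),
               unname(sums[names(fit$weights)]), tolerance = 1e-12)
  # sites absent from the weight map had zero weight in every fold
  dropped <- setdiff(colnames(fit$fold_weights), names(fit$weights))
  expect_true(all(fit$fold_weights[, dropped] == 0))
  expect_equal(fit$intercept, mean(fit$fold_intercepts), tolerance = 1e-12)
})

test_that("seed determinism: identical config reproduces identical weights", {
  again <- fit_gene_model(trained_gene$X, trained_gene$y, seed = 204)
  expect_identical(trained_gene$fit$weights, again$weights)
  expect_identical(trained_gene$fit$oos, again$oos)
})

test_that("with a vanishing penalty fold weights match the OLS solution", {
  set.seed(210)
  X <- matrix(rbinom(200 * 3, 2, 0.4), 200, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- X %*% c(0.5, -0.3, 0.2) + rnorm(200, sd = 0.3)
  fit <- fit_gene_model(X, y, external_k = 2,
                        lambda_grid = c(1e-6, 1e-7, 1e-8), seed = 211,
                        thresh = 1e-14)
  for (f in 1:2) {
    tr <- fit$fold_id != f
    Z <- cbind(1, X[tr, ])
    beta_ols <- solve(t(Z) %*% Z, t(Z) %*% y[tr])
    expect_lt(max(abs(fit$fold_weights[f, ] - beta_ols[-1])), 1e-4)
    expect_lt(abs(fit$fold_intercepts[f] - beta_ols[1]), 1e-4)
  }
})

test_that("pure-noise genes carry no predictive signal", {
  # under the sparser 1se rule the averaged model is empty almost always,
  # so the gene is removed by the no-eQTL filter
  res <- sapply(1:40, function(s) {
    set.seed(s)
    X <- matrix(rbinom(100 * 50, 2, 0.3), 100, 50)
    y <- rnorm(100)
    fit <- fit_gene_model(X, y, lambda_choice = "1se", seed = 1000 + s)
    length(fit$weights) == 0
  })
  expect_gte(mean(res), 0.9)

  # under lambda.min small noise weights survive, but the out-of-sample
  # predictions remain uninformative
  cors <- sapply(1:10, function(s) {
    set.seed(s)
    X <- matrix(rbinom(100 * 50, 2, 0.3), 100, 50)
    y <- rnorm(100)
    fit <- fit_gene_model(X, y, seed = 2000 + s)
    if (var(fit$oos) == 0) 0 else cor(fit$oos, y)
  })
  expect_lt(abs(mean(cors)), 0.15)
})

test_that("a single strong causal site is recovered up to LD", {
  hits <- sapply(1:20, function(s) {
    pan <- generate_ancestral_panel(150, 150, n_founders = 10, seed = 300 + s)
    smp <- expand_population(pan, 500, seed = 400 + s, role = "A")
    maf <- compute_maf(smp)
    regions <- make_gene_regions(1, 150)
    arch <- sample_architecture(regions, maf, maf, k = 1, p = 1, seed = 500 + s)
    expr <- simulate_expression(smp, arch, h2 = 0.5, seed = 600 + s)
    fit <- fit_gene_model(smp$dosages, expr$values[1, ], seed = 700 + s)
    if (!length(fit$weights)) return(FALSE)
    top <- names(which.max(abs(fit$weights)))
    causal <- arch$genes[[1]]$eqtls_A$site
    top_idx <- match(top, colnames(smp$dosages))
    if (top_idx == causal) return(TRUE)
    cor(smp$dosages[, top_idx], smp$dosages[, causal])^2 > 0.8
  })
  expect_gte(mean(hits), 0.9)
})

test_that("constant y and constant predictors are handled", {
  X <- trained_gene$X
  fit <- fit_gene_model(X, rep(1, nrow(X)), seed = 1)
  expect_equal(fit$flag, "constant_y")
  expect_length(fit$weights, 0)

  Xc <- matrix(1L, 50, 4, dimnames = list(NULL, letters[1:4]))
  fit2 <- fit_gene_model(Xc, rnorm(50), seed = 2)
  expect_equal(fit2$flag, "no_variable_sites")
})

test_that("out-of-sample predictions do not outperform in-sample fits", {
  fit <- trained_gene$fit
  keep <- names(fit$weights)
  pred_in <- fit$intercept +
    as.numeric(trained_gene$X[, keep, drop = FALSE] %*% fit$weights)
  r2_in <- cor(pred_in, trained_gene$y)^2
  r2_out <- cor(fit$oos, trained_gene$y)^2
  expect_gte(r2_in, r2_out - 0.02)
})

test_that("prediction is a linear site-weight contraction of dosages", {
  dos <- matrix(c(0L, 1L, 2L, 1L,
                  2L, 0L, 1L, 1L), 4, 2,
                dimnames = list(NULL, c("s1", "s2")))
  target <- population_sample(dos, "B", role = "B")
  ws <- manual_weight_set(list(gA = c(s1 = 1), gB = c(s1 = 2, s2 = -1)),
                          intercepts = list(gA = 0, gB = 0.5))
  pred <- predict_expression(ws, target)
  expect_equal(unname(pred$values["gA", ]), as.numeric(dos[, "s1"]))
  expect_equal(unname(pred$values["gB", ]),
               0.5 + 2 * dos[, "s1"] - 1 * dos[, "s2"],
               ignore_attr = TRUE)
  # doubling the weights doubles (prediction - intercept) exactly
  ws2 <- manual_weight_set(list(gA = c(s1 = 2), gB = c(s1 = 4, s2 = -2)),
                           intercepts = list(gA = 0, gB = 0.5))
  pred2 <- predict_expression(ws2, target)
  expect_equal(pred2$values["gB", ] - 0.5, 2 * (pred$values["gB", ] - 0.5),
               tolerance = 1e-12)
})

test_that("weight sites absent from the target are skipped and tracked", {
  dos <- matrix(c(0L, 1L, 2L), 3, 1, dimnames = list(NULL, "s1"))
  target <- population_sample(dos, "B", role = "B")
  ws <- manual_weight_set(list(gA = c(s1 = 1, s_absent = 5)))
  pred <- predict_expression(ws, target)
  expect_equal(unname(pred$values["gA", ]), c(0, 1, 2))

  # NA dosages mark individuals nonmissing
  dos_na <- matrix(c(0, NA, 2, 1, 1, 0), 3, 2,
                   dimnames = list(NULL, c("s1", "s2")))
  target_na <- structure(list(dosages = dos_na, n = 3, pop_label = "B",
                              role = "B", ancestry = NULL, haplotypes = NULL,
                              seed_record = NA), class = "population_sample")
  pred_na <- predict_expression(ws, target_na)
  expect_true(is.na(pred_na$values["gA", 2]))
  expect_equal(unname(pred_na$nonmissing_fraction["gA"]), 2 / 3)
})

test_that("model filters drop no-eQTL and high-missingness genes with reasons", {
  ws <- manual_weight_set(list(g1 = stats::setNames(numeric(0), character(0)),
                               g2 = c(s1 = 0.5), g3 = c(s1 = 1)))
  pred <- manual_predictions(matrix(0, 3, 4, dimnames = list(c("g1", "g2", "g3"), NULL)))
  pred$nonmissing_fraction <- c(g1 = 1, g2 = 0.4, g3 = 1)
  flt <- apply_model_filters(ws, pred)
  expect_identical(flt$keep, "g3")
  expect_identical(flt$log$reason[flt$log$gene_id == "g1"], "no_eqtls")
  expect_identical(flt$log$reason[flt$log$gene_id == "g2"], "missingness")
})
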