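#' Simulate a phenotype driven by one causal gene's expression
#'
#' `y_i = G_i * beta + e_i` with i.i.d. Normal(0, `sigma2`) environmental
#' noise, where `G` is the *true* simulated expression of the causal gene in
#' the test population (predicted expression enters only at the association
#' step). The realized phenotype heritability
#' `Var(G * beta) / Var(y)` is recorded from sample variances.
#'
#' @param expression_of_G True expression vector of the causal gene.
#' @param beta Causal effect size.
#' @param sigma2 Environmental noise variance (> 0; default 0.01).
#' @param seed Optional integer seed.
#' @return A list with `y`, `realized_h2_pheno`, `beta`, and `sigma2`.
#' @export
simulate_phenotype <- function(expression_of_G, beta, sigma2 = 0.01, seed = NULL) {
  stopifnot(all(is.finite(expression_of_G)), sigma2 > 0,
            stats::var(expression_of_G) > 0)
  if (!is.null(seed)) set.seed(seed)
  g <- expression_of_G * beta
  y <- g + stats::rnorm(length(g), 0, sqrt(sigma2))
  list(y = y,
       realized_h2_pheno = stats::var(g) / stats::var(y),
       beta = beta, sigma2 = sigma2)
}

#' Solve for the effect size reaching a target phenotype heritability
#'
#' Because the variance scale of simulated expression depends on the eQTL
#' architecture, power experiments are keyed on the phenotype heritability
#' `h2 = beta^2 Var(G) / (beta^2 Var(G) + sigma2)` rather than on raw
#' `beta`. This inverts that relation:
#' `beta = sqrt(h2 / (1 - h2) * sigma2 / Var(G))`.
#'
#' @param expression_of_G Expression vector of the causal gene (or a single
#'   number interpreted as its variance).
#' @param h2_target Target phenotype heritability in `(0, 1)`.
#' @param sigma2 Environmental noise variance (default 0.01).
#' @return The calibrated effect size.
#' @export
calibrate_beta <- function(expression_of_G, h2_target, sigma2 = 0.01) {
  stopifnot(h2_target > 0, h2_target < 1, sigma2 > 0)
  v <- if (length(expression_of_G) == 1L) expression_of_G else stats::var(expression_of_G)
  stopifnot(v > 0)
  sqrt(h2_target / (1 - h2_target) * sigma2 / v)
}

#' Transcriptome-wide association test of a phenotype on predicted expression
#'
#' Regresses the phenotype on each gene's predicted expression (simple linear
#' regression, two-sided t test) and flags genes significant at the
#' Bonferroni-corrected threshold `alpha_level / n_genes_for_bonferroni`.
#' The default denominator of 98 genes is the transcriptome-wide family size
#' of the full-scale design and is kept even in scaled-down runs so power
#' refers to the same multiple-testing burden. Constant prediction columns
#' are assigned `p = 1`.
#'
#' @param y Phenotype vector.
#' @param predictions A [predict_expression()] result (or any object with a
#'   `values` matrix of genes x individuals).
#' @param alpha_level Family-wise significance level (default 0.05).
#' @param n_genes_for_bonferroni Bonferroni denominator (default 98).
#' @return A data.frame with per-gene `slope`, `t`, `p`, `significant`;
#'   the threshold is stored in attribute `"threshold"`.
#' @export
run_twas <- function(y, predictions, alpha_level = 0.05,
                     n_genes_for_bonferroni = 98) {
  stopifnot(all(is.finite(y)), n_genes_for_bonferroni >= 1)
  vals <- predictions$values
  threshold <- alpha_level / n_genes_for_bonferroni
  genes <- rownames(vals)
  out <- data.frame(gene_id = genes, slope = NA_real_, t = NA_real_,
                    p = NA_real_, stringsAsFactors = FALSE)
  for (g in seq_along(genes)) {
    x <- vals[g, ]
    ok <- is.finite(x)
    xn <- x[ok]; yn <- y[ok]
    if (length(xn) < 3L || stats::var(xn) == 0) {
      out$slope[g] <- 0; out$t[g] <- 0; out$p[g] <- 1
      next
    }
    r <- stats::cor(xn, yn)
    df <- length(xn) - 2L
    tt <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
    out$slope[g] <- r * stats::sd(yn) / stats::sd(xn)
    out$t[g] <- tt
    out$p[g] <- 2 * stats::pt(-abs(tt), df)
  }
  out$significant <- out$p < threshold
  attr(out, "threshold") <- threshold
  out
}

# Wilson score interval for a binomial proportion
wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  phat <- x / n
  centre <- (phat + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  # the interval always contains the point estimate, including at 0 and 1
  c(lower = if (x == 0) 0 else max(0, centre - half),
    upper = if (x == n) 1 else min(1, centre + half))
}

#' Estimate TWAS power across effect sizes and train-test scenarios
#'
#' For each effect size (or target phenotype heritability) and each
#' replicate, a causal gene is drawn uniformly at random, a phenotype is
#' simulated from its true expression in the test population, and the TWAS
#' is run against every supplied prediction set; power is the fraction of
#' replicates in which the causal gene is Bonferroni-significant, with a
#' Wilson 95% confidence interval. When the effect-size grid has at least
#' two levels, a binomial-logistic curve of the significance indicator on
#' `log10(beta)` is fitted per scenario (degenerate all-0/all-1 outcomes are
#' flagged and summarized as a step function).
#'
#' Within a replicate the causal gene, effect size, and environmental noise
#' are shared across all scenarios, and rejections at non-causal genes are
#' tallied as a family-wise error diagnostic.
#'
#' @param expression_test True expression of the *test* population (an
#'   [simulate_expression()] result).
#' @param predictions_list Named list of prediction matrices for the test
#'   population (one per train-test scenario), already filtered by
#'   [apply_model_filters()].
#' @param beta Numeric vector of effect sizes, or `NULL` to calibrate.
#' @param h2_pheno Numeric vector of target phenotype heritabilities used
#'   when `beta` is `NULL`.
#' @param beta_calibration How to reach a target heritability:
#'   `"mean_h2"` (default) solves for one fixed effect size per level such
#'   that the *mean* realized heritability over candidate causal genes hits
#'   the target, mirroring the fixed-effect-size design in which realized
#'   heritability varies with the causal gene's expression variance;
#'   `"per_gene"` re-calibrates the effect size to each replicate's causal
#'   gene so every replicate sits exactly at the target.
#' @param sigma2 Environmental noise variance (default 0.01).
#' @param n_replicates Replicates per effect-size level (>= 10).
#' @param alpha_level,n_genes_for_bonferroni Passed to [run_twas()].
#' @param genes Candidate causal genes (default: all genes in
#'   `expression_test` with positive expression variance).
#' @param seed Integer seed.
#' @return An object of class `power_estimate`: a `table` data.frame with
#'   one row per scenario x effect-size level (`power`, `ci_lower`,
#'   `ci_upper`, `mean_h2_pheno`, `mean_beta`, `fwer_noncausal`,
#'   `n_replicates`) and a `curves` list of per-scenario logistic fits.
#' @export
estimate_power <- function(expression_test, predictions_list, beta = NULL,
                           h2_pheno = NULL, sigma2 = 0.01, n_replicates = 100,
                           alpha_level = 0.05, n_genes_for_bonferroni = 98,
                           genes = NULL,
                           beta_calibration = c("mean_h2", "per_gene"),
                           seed = 1) {
  stopifnot(n_replicates >= 10)
  beta_calibration <- match.arg(beta_calibration)
  if (is.null(beta) && is.null(h2_pheno)) {
    stop("supply either beta or h2_pheno")
  }
  if (is.null(names(predictions_list))) {
    names(predictions_list) <- vapply(
      predictions_list,
      function(p) paste0(p$train_pop, "->", p$target_pop), character(1))
  }
  if (is.null(genes)) {
    vg <- apply(expression_test$values, 1L, stats::var)
    genes <- rownames(expression_test$values)[vg > 0]
  }
  levels_grid <- if (!is.null(beta)) beta else h2_pheno
  by_h2 <- is.null(beta)
  scen <- names(predictions_list)
  seeds <- split_seeds(seed, length(levels_grid))
  var_g_all <- apply(expression_test$values[genes, , drop = FALSE], 1L,
                     stats::var)
  # one fixed effect size per level such that the mean realized phenotype
  # heritability over candidate causal genes equals the target
  solve_mean_beta <- function(target) {
    f <- function(lb) mean((10^(2 * lb) * var_g_all) /
                             (10^(2 * lb) * var_g_all + sigma2)) - target
    10^stats::uniroot(f, c(-8, 4), tol = 1e-12)$root
  }
  rows <- list()
  records <- list()  # per-replicate yes/no for logistic fits
  for (li in seq_along(levels_grid)) {
    set.seed(seeds[li])
    b_fixed <- if (by_h2 && beta_calibration == "mean_h2") {
      solve_mean_beta(levels_grid[li])
    } else NULL
    sig <- matrix(FALSE, n_replicates, length(scen), dimnames = list(NULL, scen))
    fwer <- matrix(0, n_replicates, length(scen), dimnames = list(NULL, scen))
    h2_rec <- numeric(n_replicates)
    beta_rec <- numeric(n_replicates)
    for (r in seq_len(n_replicates)) {
      causal <- sample(genes, 1L)
      expr_g <- expression_test$values[causal, ]
      b <- if (!by_h2) levels_grid[li]
           else if (!is.null(b_fixed)) b_fixed
           else calibrate_beta(expr_g, levels_grid[li], sigma2)
      ph <- simulate_phenotype(expr_g, b, sigma2)
      h2_rec[r] <- ph$realized_h2_pheno
      beta_rec[r] <- b
      for (s in scen) {
        tw <- run_twas(ph$y, predictions_list[[s]], alpha_level,
                       n_genes_for_bonferroni)
        hit <- tw$significant[tw$gene_id == causal]
        sig[r, s] <- length(hit) == 1L && hit
        others <- tw$significant[tw$gene_id != causal]
        fwer[r, s] <- if (length(others)) mean(others) else 0
      }
    }
    for (s in scen) {
      ci <- wilson_ci(sum(sig[, s]), n_replicates)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = s, level = levels_grid[li],
        level_type = if (by_h2) "h2_pheno" else "beta",
        power = mean(sig[, s]), ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
        mean_h2_pheno = mean(h2_rec), mean_beta = mean(beta_rec),
        fwer_noncausal = mean(fwer[, s]), n_replicates = n_replicates,
        stringsAsFactors = FALSE)
      records[[length(records) + 1L]] <- data.frame(
        scenario = s, beta = beta_rec, sig = sig[, s])
    }
  }
  table <- do.call(rbind, rows)
  rec <- do.call(rbind, records)
  curves <- NULL
  if (length(levels_grid) >= 2L) {
    curves <- lapply(split(rec, rec$scenario), function(sub) {
      if (all(sub$sig) || !any(sub$sig)) {
        list(degenerate = TRUE, step = mean(sub$sig),
             note = "all replicates identical; step-function summary")
      } else {
        fit <- suppressWarnings(
          stats::glm(sig ~ log10(beta), family = stats::binomial(), data = sub))
        list(degenerate = FALSE, coef = stats::coef(fit),
             slope = unname(stats::coef(fit)[2L]))
      }
    })
  }
  structure(list(table = table, curves = curves,
                 alpha_level = alpha_level,
                 n_genes_for_bonferroni = n_genes_for_bonferroni),
            class = "power_estimate")
}

#' @exportS3Method base::print
print.power_estimate <- function(x, ...) {
  cat(sprintf("power_estimate (threshold %.3g = %.2g / %d):\n",
              x$alpha_level / x$n_genes_for_bonferroni, x$alpha_level,
              x$n_genes_for_bonferroni))
  print(x$table[, c("scenario", "level", "level_type", "power",
                    "ci_lower", "ci_upper", "mean_h2_pheno")], digits = 3)
  invisible(x)
}

#' Sweep TWAS power across admixture proportions
#'
#' Reproduces the two-way admixture experiment: for each admixture
#' proportion `alpha`, an admixed population is sampled from the two
#' ancestral panels (at `alpha = 0` it is an independent reshuffle of the A
#' panel, at `alpha = 1` of the B panel), expression is simulated under the
#' union eQTL model, prediction models are trained in the admixed
#' population, and TWAS power is estimated for the four cross-population
#' scenarios (AD to/from each ancestral population) at each requested
#' phenotype heritability.
#'
#' The ancestral samples, their eQTL architecture (shared fraction `p`,
#' model size `k`), expression, and trained models are held fixed across the
#' sweep so that `alpha` is the only moving part.
#'
#' @param panel_A,panel_B Ancestral [haplotype_panel()]s on one site grid.
#' @param regions Gene regions from [make_gene_regions()].
#' @param alphas Admixture proportions to sweep (default `seq(0, 1, 0.1)`).
#' @param p Shared-eQTL proportion (default 0.5).
#' @param k Causal eQTLs per ancestral population (default 10).
#' @param h2 Expression cis-heritability (default 0.15).
#' @param h2_pheno Target phenotype heritabilities (default
#'   `c(0.06, 0.20, 0.58)`).
#' @param sigma2 Environmental noise variance (default 0.01).
#' @param n Individuals per population.
#' @param n_replicates Phenotype replicates per power cell.
#' @param scenarios Subset of `c("AD->A", "AD->B", "A->AD", "B->AD")`.
#' @param external_scheme,external_k,internal_folds,lambda_choice Passed to
#'   [train_population()].
#' @param alpha_level,n_genes_for_bonferroni Passed to [run_twas()].
#' @param seed Integer master seed.
#' @return A data.frame with one row per (scenario, alpha, heritability
#'   level): power, Wilson 95% CI, realized heritability, and scenario keys.
#' @export
admixture_sweep <- function(panel_A, panel_B, regions,
                            alphas = seq(0, 1, by = 0.1), p = 0.5, k = 10,
                            h2 = 0.15, h2_pheno = c(0.06, 0.20, 0.58),
                            sigma2 = 0.01, n = 1000, n_replicates = 100,
                            scenarios = c("AD->A", "AD->B", "A->AD", "B->AD"),
                            external_scheme = "kfold", external_k = 10,
                            internal_folds = 10, lambda_choice = "min",
                            alpha_level = 0.05, n_genes_for_bonferroni = 98,
                            seed = 1) {
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  sd0 <- split_seeds(seed, 8 + 3 * length(alphas))
  samp_A <- expand_population(panel_A, n, seed = sd0[1], role = "A")
  samp_B <- expand_population(panel_B, n, seed = sd0[2], role = "B")
  arch <- sample_architecture(regions, compute_maf(samp_A), compute_maf(samp_B),
                              k = k, p = p, seed = sd0[3])
  expr_A <- simulate_expression(samp_A, arch, h2 = h2, seed = sd0[4])
  expr_B <- simulate_expression(samp_B, arch, h2 = h2, seed = sd0[5])
  need_anc <- any(c("A->AD", "B->AD") %in% scenarios)
  w_A <- if (need_anc) train_population(samp_A, expr_A, regions,
                                        external_scheme = external_scheme,
                                        external_k = external_k,
                                        internal_folds = internal_folds,
                                        lambda_choice = lambda_choice,
                                        seed = sd0[6])
  w_B <- if (need_anc) train_population(samp_B, expr_B, regions,
                                        external_scheme = external_scheme,
                                        external_k = external_k,
                                        internal_folds = internal_folds,
                                        lambda_choice = lambda_choice,
                                        seed = sd0[7])
  out <- list()
  for (ai in seq_along(alphas)) {
    a <- alphas[ai]
    s_ad <- sd0[8 + 3 * (ai - 1) + 1]
    s_ex <- sd0[8 + 3 * (ai - 1) + 2]
    s_tr <- sd0[8 + 3 * (ai - 1) + 3]
    samp_AD <- sample_admixed(panel_A, panel_B, n, alpha = a, regions,
                              seed = s_ad, pop_label = "AD")
    expr_AD <- simulate_expression(samp_AD, arch, h2 = h2, seed = s_ex)
    w_AD <- train_population(samp_AD, expr_AD, regions,
                             external_scheme = external_scheme,
                             external_k = external_k,
                             internal_folds = internal_folds,
                             lambda_choice = lambda_choice, seed = s_tr)
    run_one <- function(wts, test_samp, test_expr, scen_name) {
      preds <- predict_expression(wts, test_samp)
      keep <- apply_model_filters(wts, preds)$keep
      preds$values <- preds$values[keep, , drop = FALSE]
      pe <- estimate_power(test_expr, stats::setNames(list(preds), scen_name),
                           h2_pheno = h2_pheno, sigma2 = sigma2,
                           n_replicates = n_replicates,
                           alpha_level = alpha_level,
                           n_genes_for_bonferroni = n_genes_for_bonferroni,
                           seed = seed + ai)
      pe$table
    }
    for (scen in scenarios) {
      tab <- switch(scen,
        "AD->A" = run_one(w_AD, samp_A, expr_A, "AD->A"),
        "AD->B" = run_one(w_AD, samp_B, expr_B, "AD->B"),
        "A->AD" = run_one(w_A, samp_AD, expr_AD, "A->AD"),
        "B->AD" = run_one(w_B, samp_AD, expr_AD, "B->AD"))
      tab$alpha_admix <- a
      tab$p <- p
      tab$k <- k
      out[[length(out) + 1L]] <- tab
    }
  }
  do.call(rbind, out)
}
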