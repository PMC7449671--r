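#' Fit one gene's prediction model by nested cross-validation elastic net
#'
#' The external loop (leave-one-out or K-fold) holds out individuals; on each
#' external training portion an elastic net (mixing parameter 0.5) is fitted
#' with the penalty strength chosen by internal cross-validation minimizing
#' mean squared prediction error over a log-spaced lambda grid (the
#' `lambda.min` convention; `lambda_choice = "1se"` selects the sparser
#' one-standard-error rule instead). Held-out predictions are recorded for
#' out-of-sample within-population evaluation. The final weights are the
#' per-site average of fold weights over *all* external folds, counting a
#' site as zero in folds where it was not selected; only sites with at least
#' one nonzero fold weight are kept. Predictors are standardized internally
#' by glmnet and weights are reported on the dosage scale.
#'
#' @param X Dosage matrix `[n x m]` with named columns.
#' @param y Expression vector of length `n`.
#' @param external_scheme `"kfold"` or `"loocv"` external cross-validation.
#' @param external_k Number of external folds when `external_scheme =
#'   "kfold"` (default 10).
#' @param internal_folds Number of internal CV folds (default 10; set to the
#'   training-fold size for internal LOOCV).
#' @param mixing Elastic-net mixing parameter in `[0, 1]` (default 0.5).
#' @param lambda_grid Optional decreasing penalty grid; by default glmnet
#'   auto-scales a log-spaced grid from the data.
#' @param nlambda Grid size when `lambda_grid` is `NULL` (default 30; the
#'   internal-CV error is flat beyond that on these problem sizes).
#' @param lambda_min_ratio Smallest grid lambda as a fraction of the largest
#'   (default 0.01).
#' @param lambda_choice `"min"` (internal-CV MSE minimizer) or `"1se"`.
#' @param seed Integer seed controlling fold assignment.
#' @param ... Further arguments passed to [glmnet::cv.glmnet()] (e.g.
#'   `thresh` for a tighter convergence tolerance).
#' @return A list with `weights` (named vector over retained sites),
#'   `intercept`, `oos` (out-of-sample predictions, length `n`),
#'   `n_folds`, `n_folds_contributing` (per retained site),
#'   `fold_weights`/`fold_intercepts` and `fold_id` (per external fold, for
#'   audit), `flag` (`"ok"`, `"constant_y"`, or `"no_variable_sites"`), and
#'   scheme metadata.
#' @export
fit_gene_model <- function(X, y, external_scheme = c("kfold", "loocv"),
                           external_k = 10, internal_folds = 10, mixing = 0.5,
                           lambda_grid = NULL, nlambda = 30,
                           lambda_min_ratio = 0.01,
                           lambda_choice = c("min", "1se"), seed = 1, ...) {
  external_scheme <- match.arg(external_scheme)
  lambda_choice <- match.arg(lambda_choice)
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n, all(is.finite(y)))
  if (is.null(colnames(X))) colnames(X) <- sprintf("s%05d", seq_len(ncol(X)))
  meta <- list(external_scheme = external_scheme,
               external_k = if (external_scheme == "loocv") n else external_k,
               internal_folds = internal_folds, mixing = mixing,
               lambda_choice = lambda_choice, seed = seed)

  # constant predictors are dropped before fitting
  keep <- apply(X, 2L, function(col) stats::var(col) > 0)
  zero_model <- function(flag) {
    c(list(weights = stats::setNames(numeric(0), character(0)), intercept = mean(y),
           oos = rep(mean(y), n), n_folds = meta$external_k,
           n_folds_contributing = integer(0), fold_weights = NULL,
           fold_intercepts = NULL, flag = flag), meta)
  }
  if (stats::var(y) == 0) return(zero_model("constant_y"))
  if (!any(keep)) return(zero_model("no_variable_sites"))
  Xk <- X[, keep, drop = FALSE]
  m <- ncol(Xk)

  set.seed(seed)
  n_ext <- if (external_scheme == "loocv") n else min(external_k, n)
  fold_id <- if (external_scheme == "loocv") {
    seq_len(n)
  } else {
    sample(rep_len(seq_len(n_ext), n))
  }

  fold_w <- matrix(0, n_ext, m, dimnames = list(NULL, colnames(Xk)))
  fold_b <- numeric(n_ext)
  oos <- numeric(n)
  pad <- m == 1L  # glmnet needs >= 2 columns; pad with a zero column
  for (f in seq_len(n_ext)) {
    tr <- fold_id != f
    Xtr <- Xk[tr, , drop = FALSE]
    if (pad) Xtr <- cbind(Xtr, .pad = 0)
    nf <- min(internal_folds, sum(tr))
    set.seed(seed + 7919L * f)
    cv <- if (is.null(lambda_grid)) {
      glmnet::cv.glmnet(Xtr, y[tr], alpha = mixing, nfolds = nf,
                        nlambda = nlambda, lambda.min.ratio = lambda_min_ratio,
                        grouped = nf > 3, standardize = TRUE, ...)
    } else {
      glmnet::cv.glmnet(Xtr, y[tr], alpha = mixing, nfolds = nf,
                        lambda = lambda_grid, grouped = nf > 3,
                        standardize = TRUE, ...)
    }
    s <- if (lambda_choice == "min") "lambda.min" else "lambda.1se"
    co <- as.numeric(stats::coef(cv, s = s))
    fold_b[f] <- co[1L]
    fold_w[f, ] <- co[seq_len(m) + 1L]
    Xte <- Xk[!tr, , drop = FALSE]
    if (pad) Xte <- cbind(Xte, .pad = 0)
    oos[!tr] <- as.numeric(stats::predict(cv, Xte, s = s))
  }
  avg_w <- colSums(fold_w) / n_ext
  contributing <- colSums(fold_w != 0)
  retained <- contributing > 0
  c(list(weights = avg_w[retained],
         intercept = sum(fold_b) / n_ext,
         oos = oos, n_folds = n_ext,
         n_folds_contributing = contributing[retained],
         fold_weights = fold_w, fold_intercepts = fold_b, fold_id = fold_id,
         flag = "ok"), meta)
}

#' Train prediction models for every gene in a population
#'
#' Runs [fit_gene_model()] per gene on the dosages of that gene's region and
#' the simulated (or supplied) expression, collecting the averaged weights
#' and out-of-sample predictions.
#'
#' @param sample A [population_sample()] providing training dosages.
#' @param expression An [simulate_expression()] result (or compatible list
#'   with a `values` matrix) for the same individuals.
#' @param regions Gene regions from [make_gene_regions()].
#' @param seed Integer seed; per-gene fold seeds are split from it.
#' @inheritParams fit_gene_model
#' @return An object of class `weight_set`: per-gene model entries, an `oos`
#'   matrix of held-out predictions (`genes x individuals`), and scheme
#'   metadata.
#' @export
train_population <- function(sample, expression, regions,
                             external_scheme = c("kfold", "loocv"),
                             external_k = 10, internal_folds = 10,
                             mixing = 0.5, lambda_grid = NULL, nlambda = 30,
                             lambda_min_ratio = 0.01,
                             lambda_choice = c("min", "1se"), seed = 1, ...) {
  external_scheme <- match.arg(external_scheme)
  lambda_choice <- match.arg(lambda_choice)
  stopifnot(inherits(sample, "population_sample"))
  genes <- regions$gene_id
  seeds <- split_seeds(seed, length(genes), genes)
  models <- vector("list", length(genes))
  names(models) <- genes
  oos <- matrix(NA_real_, length(genes), sample$n, dimnames = list(genes, NULL))
  for (g in seq_along(genes)) {
    idx <- regions$start[g]:regions$end[g]
    X <- sample$dosages[, idx, drop = FALSE]
    y <- expression$values[genes[g], ]
    models[[g]] <- fit_gene_model(X, y, external_scheme = external_scheme,
                                  external_k = external_k,
                                  internal_folds = internal_folds,
                                  mixing = mixing, lambda_grid = lambda_grid,
                                  nlambda = nlambda,
                                  lambda_min_ratio = lambda_min_ratio,
                                  lambda_choice = lambda_choice,
                                  seed = seeds[g])
    oos[g, ] <- models[[g]]$oos
  }
  structure(
    list(models = models, oos = oos, train_pop = sample$pop_label,
         external_scheme = external_scheme,
         external_k = if (external_scheme == "loocv") sample$n else external_k,
         internal_folds = internal_folds, mixing = mixing,
         lambda_choice = lambda_choice, seed = seed),
    class = "weight_set"
  )
}

#' @exportS3Method base::print
print.weight_set <- function(x, ...) {
  nz <- vapply(x$models, function(m) length(m$weights), integer(1))
  cat(sprintf("weight_set trained in '%s' (%s external CV, %d genes)\n",
              x$train_pop, x$external_scheme, length(x$models)))
  cat(sprintf("  nonzero sites per gene: median %g, %d genes with none\n",
              stats::median(nz), sum(nz == 0)))
  invisible(x)
}

#' Predict expression in a target population from a trained weight set
#'
#' Computes `intercept + sum(weight * dosage)` per gene over the weight
#' sites present in the target sample. Sites absent from the target are
#' skipped; individuals with missing (NA) dosages at any used site are
#' flagged nonmissing, and the per-gene nonmissing fraction is recorded.
#'
#' @param weights A [train_population()] result.
#' @param target A [population_sample()] to predict into.
#' @return An object of class `prediction_matrix` with `values`
#'   (`genes x individuals`), `nonmissing_fraction` per gene, `train_pop`,
#'   and `target_pop`.
#' @export
predict_expression <- function(weights, target) {
  stopifnot(inherits(weights, "weight_set"),
            inherits(target, "population_sample"))
  genes <- names(weights$models)
  n <- target$n
  vals <- matrix(NA_real_, length(genes), n, dimnames = list(genes, NULL))
  nonmiss <- stats::setNames(numeric(length(genes)), genes)
  site_ids <- colnames(target$dosages)
  for (g in seq_along(genes)) {
    m <- weights$models[[g]]
    present <- names(m$weights)[names(m$weights) %in% site_ids]
    if (length(present) == 0L) {
      vals[g, ] <- m$intercept
      nonmiss[g] <- 1
      next
    }
    D <- target$dosages[, present, drop = FALSE]
    pred <- m$intercept + as.numeric(D %*% m$weights[present])
    ok <- !apply(is.na(D), 1L, any)
    pred[!ok] <- NA_real_
    vals[g, ] <- pred
    nonmiss[g] <- mean(ok)
  }
  structure(
    list(values = vals, nonmissing_fraction = nonmiss,
         train_pop = weights$train_pop, target_pop = target$pop_label),
    class = "prediction_matrix"
  )
}

#' @exportS3Method base::print
print.prediction_matrix <- function(x, ...) {
  cat(sprintf("prediction_matrix: %s -> %s, %d genes x %d individuals\n",
              x$train_pop, x$target_pop, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Apply the two gene-model filters
#'
#' Drops genes whose predictive model contains no eQTLs (no site with a
#' nonzero averaged weight) and genes for which fewer than half of the
#' target individuals have nonmissing predictions. Both filters mirror
#' standard transcriptome-imputation practice; the filter log records the
#' reason each gene was dropped.
#'
#' @param weights A [train_population()] result.
#' @param predictions A [predict_expression()] result from those weights.
#' @param min_nonmissing Minimum nonmissing fraction (default 0.5).
#' @return A list with `keep` (character vector of retained gene ids) and
#'   `log` (data.frame of dropped genes and reasons).
#' @export
apply_model_filters <- function(weights, predictions, min_nonmissing = 0.5) {
  stopifnot(inherits(weights, "weight_set"),
            inherits(predictions, "prediction_matrix"))
  genes <- names(weights$models)
  no_eqtl <- vapply(weights$models, function(m) length(m$weights) == 0L, logical(1))
  low_nm <- predictions$nonmissing_fraction[genes] < min_nonmissing
  reason <- ifelse(no_eqtl, "no_eqtls", ifelse(low_nm, "missingness", NA))
  list(keep = genes[is.na(reason)],
       log = data.frame(gene_id = genes[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        row.names = NULL, stringsAsFactors = FALSE))
}
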