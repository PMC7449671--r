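#' Score one gene's predictions against measurements
#'
#' `r2` is the squared Pearson correlation between prediction and
#' measurement — identical to the R-squared of the simple linear regression
#' of measurement on prediction. `rho` is the Spearman rank correlation with
#' average-rank tie handling. A constant prediction has no defined rank
#' correlation; such genes are scored non-positive with `r2 = 0` and flagged
#' rather than dropped silently.
#'
#' @param pred Numeric prediction vector.
#' @param measured Numeric measurement vector of the same length.
#' @return A one-row data.frame with `r2`, `rho`, `positive_correlation`
#'   (`rho > 0` strictly), and `flag`.
#' @export
score_gene <- function(pred, measured) {
  ok <- is.finite(pred) & is.finite(measured)
  if (sum(ok) < 3L) stop("need at least 3 paired finite values")
  pred <- pred[ok]; measured <- measured[ok]
  if (stats::var(measured) == 0) stop("measured values are constant")
  if (stats::var(pred) == 0) {
    return(data.frame(r2 = 0, rho = NA_real_, positive_correlation = FALSE,
                      flag = "constant_prediction", stringsAsFactors = FALSE))
  }
  r <- stats::cor(pred, measured)
  rho <- stats::cor(pred, measured, method = "spearman")
  data.frame(r2 = r^2, rho = rho, positive_correlation = rho > 0,
             flag = "ok", stringsAsFactors = FALSE)
}

#' Score a prediction matrix against an expression matrix
#'
#' @param predictions A [predict_expression()] result, or a `weight_set`'s
#'   `oos` matrix wrapped by [oos_predictions()] for within-population
#'   scoring.
#' @param expression An [simulate_expression()] result for the same
#'   individuals.
#' @param scenario Named list or one-row data.frame of scenario keys
#'   (e.g. `train`, `test`, `k`, `p`, `alpha`, `replicate`) replicated onto
#'   every row.
#' @param genes Genes to score (default: all genes in `predictions`).
#' @return A data.frame with one row per gene: scenario keys, `gene_id`,
#'   `r2`, `rho`, `positive_correlation`, `flag`.
#' @export
score_predictions <- function(predictions, expression, scenario = NULL,
                              genes = NULL) {
  vals <- predictions$values
  if (is.null(genes)) genes <- rownames(vals)
  rows <- lapply(genes, function(g) {
    cbind(data.frame(gene_id = g, stringsAsFactors = FALSE),
          score_gene(vals[g, ], expression$values[g, ]))
  })
  out <- do.call(rbind, rows)
  if (!is.null(scenario)) out <- cbind(as.data.frame(scenario), out, row.names = NULL)
  out
}

#' Wrap a weight set's out-of-sample predictions for scoring
#'
#' Within-population evaluation must use only held-out fold predictions;
#' this wraps the `oos` matrix of a [train_population()] result as a
#' `prediction_matrix` so it can be scored like any cross-population
#' prediction.
#'
#' @param weights A [train_population()] result.
#' @return A `prediction_matrix` whose values are the held-out predictions.
#' @export
oos_predictions <- function(weights) {
  stopifnot(inherits(weights, "weight_set"))
  structure(
    list(values = weights$oos,
         nonmissing_fraction = stats::setNames(
           rep(1, nrow(weights$oos)), rownames(weights$oos)),
         train_pop = weights$train_pop, target_pop = weights$train_pop),
    class = "prediction_matrix"
  )
}

#' Summarize gene scores per scenario
#'
#' @param scores Long-format score table from [score_predictions()] with a
#'   `scenario` column (or columns named in `by`).
#' @param partition `"all"` (every scored gene), `"positive_only"` (genes
#'   with strictly positive Spearman correlation), or `"common_genes"`
#'   (genes positively correlated in *every* scenario of the grid).
#' @param by Character vector of scenario key columns (default: all columns
#'   before `gene_id`).
#' @return A data.frame with one row per scenario: `n_genes_total`,
#'   `n_genes_used`, `mean_r2`, `mean_rho`, `sd_r2`, `sd_rho`.
#' @export
summarize_scenarios <- function(scores,
                                partition = c("all", "positive_only", "common_genes"),
                                by = NULL) {
  partition <- match.arg(partition)
  if (is.null(by)) {
    gi <- match("gene_id", names(scores))
    by <- names(scores)[seq_len(gi - 1L)]
  }
  key <- interaction(scores[by], drop = TRUE, lex.order = TRUE)
  used <- switch(partition,
    all = rep(TRUE, nrow(scores)),
    positive_only = scores$positive_correlation,
    common_genes = {
      pos_everywhere <- tapply(scores$positive_correlation, scores$gene_id, all)
      scores$gene_id %in% names(pos_everywhere)[pos_everywhere]
    })
  rows <- lapply(levels(key), function(lv) {
    sel <- key == lv
    sub <- scores[sel & used, , drop = FALSE]
    head_row <- scores[which(sel)[1L], by, drop = FALSE]
    cbind(head_row,
          data.frame(partition = partition,
                     n_genes_total = sum(sel),
                     n_genes_used = nrow(sub),
                     mean_r2 = if (nrow(sub)) mean(sub$r2) else NA_real_,
                     mean_rho = if (nrow(sub)) mean(sub$rho, na.rm = TRUE) else NA_real_,
                     sd_r2 = if (nrow(sub) > 1) stats::sd(sub$r2) else NA_real_,
                     sd_rho = if (nrow(sub) > 1) stats::sd(sub$rho, na.rm = TRUE) else NA_real_),
          row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Mean correlation versus shared-eQTL proportion per train-test pair
#'
#' Aggregates a grid of gene scores over the sharing proportion `p` into the
#' trend of mean Spearman correlation per train-test pair, with a
#' monotone-trend statistic (Spearman correlation of the pair's mean rho
#' against `p`; `NA` when the grid has a single sharing level).
#'
#' @param scores Score table with columns `train`, `test`, `p`, `rho`.
#' @return A list with `curve` (one row per train, test, p: `mean_rho`,
#'   `se_rho`, `n`) and `trend` (one row per train-test pair with the trend
#'   statistic).
#' @export
sharing_curve <- function(scores) {
  stopifnot(all(c("train", "test", "p", "rho") %in% names(scores)))
  key <- interaction(scores$train, scores$test, scores$p, drop = TRUE)
  curve <- do.call(rbind, lapply(levels(key), function(lv) {
    sub <- scores[key == lv, , drop = FALSE]
    rho <- sub$rho[is.finite(sub$rho)]
    data.frame(train = sub$train[1], test = sub$test[1], p = sub$p[1],
               mean_rho = mean(rho), se_rho = stats::sd(rho) / sqrt(length(rho)),
               n = length(rho), stringsAsFactors = FALSE)
  }))
  curve <- curve[order(curve$train, curve$test, curve$p), , drop = FALSE]
  pair <- interaction(curve$train, curve$test, drop = TRUE)
  trend <- do.call(rbind, lapply(levels(pair), function(lv) {
    sub <- curve[pair == lv, , drop = FALSE]
    stat <- if (nrow(sub) >= 2L) {
      suppressWarnings(stats::cor(sub$mean_rho, sub$p, method = "spearman"))
    } else NA_real_
    data.frame(train = sub$train[1], test = sub$test[1],
               trend_statistic = stat, n_levels = nrow(sub),
               stringsAsFactors = FALSE)
  }))
  list(curve = curve, trend = trend)
}
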