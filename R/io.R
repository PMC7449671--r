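#' Write and read haplotype panels as TSV
#'
#' A panel is stored as two plain-text files: `<stem>.haps.tsv` (one row per
#' haplotype, header of site IDs) and `<stem>.sites.tsv` (columns `id`,
#' `position`, `switch_prob`; the switch probability on a row refers to the
#' interval *following* that site, `NA` on the last row).
#'
#' @param panel A [haplotype_panel()].
#' @param stem Path stem for the two files.
#' @return `write_panel` returns `stem` invisibly; `read_panel` returns a
#'   [haplotype_panel()].
#' @export
write_panel <- function(panel, stem) {
  stopifnot(inherits(panel, "haplotype_panel"))
  haps <- data.table::as.data.table(panel$alleles)
  data.table::fwrite(haps, paste0(stem, ".haps.tsv"), sep = "\t")
  S <- ncol(panel$alleles)
  sites <- data.table::data.table(
    id = colnames(panel$alleles), position = panel$positions,
    switch_prob = c(panel$switch_prob, NA_real_)[seq_len(S)],
    pop_label = panel$pop_label)
  data.table::fwrite(sites, paste0(stem, ".sites.tsv"), sep = "\t")
  invisible(stem)
}

#' @rdname write_panel
#' @export
read_panel <- function(stem) {
  haps <- as.matrix(data.table::fread(paste0(stem, ".haps.tsv")))
  sites <- data.table::fread(paste0(stem, ".sites.tsv"))
  colnames(haps) <- sites$id
  haplotype_panel(haps, positions = sites$position,
                  switch_prob = sites$switch_prob[-nrow(sites)],
                  pop_label = sites$pop_label[1])
}

#' Read a phased haplotype panel from a VCF file
#'
#' A convenience ingestion path for real phased haplotypes; requires the
#' `vcfR` package and phased `GT` fields. Biallelic sites only; per-interval
#' switch probabilities are set to a uniform `switch_prob`.
#'
#' @param path Path to a VCF file with phased genotypes.
#' @param switch_prob Uniform per-interval template-switch probability used
#'   for mosaic copying from the ingested panel.
#' @param pop_label Label for the panel.
#' @return A [haplotype_panel()].
#' @export
read_panel_vcf <- function(path, switch_prob = 0.02, pop_label = "vcf") {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_panel_vcf requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  if (any(!grepl("|", gt, fixed = TRUE))) stop("VCF genotypes must be phased ('|')")
  h1 <- apply(gt, 2L, function(g) as.integer(substr(g, 1L, 1L)))
  h2 <- apply(gt, 2L, function(g) as.integer(substr(g, 3L, 3L)))
  haps <- t(cbind(h1, h2))
  pos <- as.integer(vcfR::getPOS(v))
  o <- order(pos)
  haps <- haps[, o, drop = FALSE]
  colnames(haps) <- vcfR::getID(v)[o]
  haplotype_panel(haps, positions = pos[o],
                  switch_prob = rep(switch_prob, ncol(haps) - 1L),
                  pop_label = pop_label)
}

#' Read a phased panel from IMPUTE-style .hap/.legend files
#'
#' @param hap_path Whitespace-separated 0/1 matrix, one row per site, one
#'   column per haplotype.
#' @param legend_path Legend with a header and columns `id`, `position` (the
#'   first two columns are used).
#' @param switch_prob Uniform per-interval switch probability.
#' @param pop_label Label for the panel.
#' @return A [haplotype_panel()].
#' @export
read_panel_hap_legend <- function(hap_path, legend_path, switch_prob = 0.02,
                                  pop_label = "impute") {
  hap <- as.matrix(data.table::fread(hap_path, header = FALSE))
  leg <- data.table::fread(legend_path, header = TRUE)
  haps <- t(hap)
  colnames(haps) <- as.character(leg[[1L]])
  haplotype_panel(haps, positions = as.integer(leg[[2L]]),
                  switch_prob = rep(switch_prob, ncol(haps) - 1L),
                  pop_label = pop_label)
}

#' Export a dosage matrix as TSV
#'
#' @param sample A [population_sample()].
#' @param path Output path.
#' @export
write_dosages <- function(sample, path) {
  stopifnot(inherits(sample, "population_sample"))
  dt <- data.table::as.data.table(sample$dosages)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Export averaged prediction weights in PredictDB-flavored TSV
#'
#' Writes one row per (gene, site) with a nonzero averaged weight, columns
#' `gene`, `site_id`, `weight`, `ref_allele`, `eff_allele`, plus a JSON
#' sidecar (`<path>.json`) recording the training scheme.
#'
#' @param weights A [train_population()] result.
#' @param path Output TSV path.
#' @export
write_weights <- function(weights, path) {
  stopifnot(inherits(weights, "weight_set"))
  rows <- lapply(names(weights$models), function(g) {
    m <- weights$models[[g]]
    if (!length(m$weights)) return(NULL)
    data.table::data.table(gene = g, site_id = names(m$weights),
                           weight = as.numeric(m$weights),
                           ref_allele = "0", eff_allele = "1",
                           n_folds_contributing = as.integer(m$n_folds_contributing))
  })
  dt <- data.table::rbindlist(rows)
  data.table::fwrite(dt, path, sep = "\t")
  meta <- list(train_pop = weights$train_pop,
               external_scheme = weights$external_scheme,
               external_k = weights$external_k,
               internal_folds = weights$internal_folds,
               mixing = weights$mixing, lambda_choice = weights$lambda_choice,
               seed = weights$seed,
               intercepts = lapply(weights$models, `[[`, "intercept"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a table as TSV with stable formatting
#'
#' @param x A data.frame.
#' @param path Output path.
#' @export
write_table_tsv <- function(x, path) {
  data.table::fwrite(data.table::as.data.table(x), path, sep = "\t")
  invisible(path)
}
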