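#' Sample per-gene eQTL architectures with a controllable shared fraction
#'
#' For each gene, `round(p * k)` shared causal sites are drawn uniformly from
#' sites with minor-allele frequency >= `maf_floor` in *both* ancestral
#' populations and assigned one common effect; each population then receives
#' `k - round(p * k)` population-specific causal sites (MAF-eligible in its
#' own population only), disjoint from every other chosen site, each with its
#' own effect. The admixed population inherits the union of the two
#' population lists, so it carries `2k - round(p * k)` causal eQTLs.
#' Effects are i.i.d. Normal(0, `effect_sd`^2); the scale is immaterial
#' because expression noise is later matched to the realized genetic
#' variance.
#'
#' @param regions Gene regions from [make_gene_regions()].
#' @param maf_A,maf_B Per-site minor-allele frequencies over the full site
#'   grid in populations A and B (see [compute_maf()]).
#' @param k Causal eQTLs per ancestral population.
#' @param p Shared eQTL proportion, conventionally on the grid
#'   `0, 0.1, ..., 1`.
#' @param effect_sd Effect-size standard deviation (> 0).
#' @param seed Integer seed.
#' @param maf_floor MAF eligibility floor (default 0.05).
#' @return An object of class `eqtl_architecture`: a list with one entry per
#'   gene, each holding `eqtls_A`, `eqtls_B`, `eqtls_admixed` (data.frames of
#'   `site`, `site_id`, `effect`, `origin`) and `shared_sites`.
#' @export
sample_architecture <- function(regions, maf_A, maf_B, k, p, effect_sd = 1,
                                seed = 1, maf_floor = 0.05) {
  stopifnot(k >= 1, p >= 0, p <= 1, effect_sd > 0)
  set.seed(seed)
  n_shared <- round(p * k)
  site_ids <- names(maf_A)
  arch <- lapply(seq_len(nrow(regions)), function(g) {
    idx <- regions$start[g]:regions$end[g]
    elig_A <- idx[maf_A[idx] >= maf_floor]
    elig_B <- idx[maf_B[idx] >= maf_floor]
    elig_both <- intersect(elig_A, elig_B)
    if (length(elig_both) < n_shared ||
        length(elig_A) < k + (k - n_shared) ||
        length(elig_B) < k + (k - n_shared)) {
      stop(sprintf("gene %s: not enough sites with MAF >= %g to place %d eQTLs",
                   regions$gene_id[g], maf_floor, k))
    }
    draw <- function(pool, size) sort(pool[sample.int(length(pool), size)])
    shared <- draw(elig_both, n_shared)
    pool_A <- setdiff(elig_A, shared)
    spec_A <- draw(pool_A, k - n_shared)
    pool_B <- setdiff(elig_B, c(shared, spec_A))
    if (length(pool_B) < k - n_shared) {
      stop(sprintf("gene %s: not enough B-eligible sites disjoint from A's eQTLs",
                   regions$gene_id[g]))
    }
    spec_B <- draw(pool_B, k - n_shared)
    eff_shared <- stats::rnorm(n_shared, 0, effect_sd)
    eff_A <- stats::rnorm(k - n_shared, 0, effect_sd)
    eff_B <- stats::rnorm(k - n_shared, 0, effect_sd)
    mk <- function(site, effect, origin) {
      data.frame(site = site, site_id = site_ids[site], effect = effect,
                 origin = rep(origin, length(site)), stringsAsFactors = FALSE)
    }
    eqtls_A <- rbind(mk(shared, eff_shared, "shared"), mk(spec_A, eff_A, "A"))
    eqtls_B <- rbind(mk(shared, eff_shared, "shared"), mk(spec_B, eff_B, "B"))
    eqtls_admixed <- rbind(mk(shared, eff_shared, "shared"),
                           mk(spec_A, eff_A, "A"), mk(spec_B, eff_B, "B"))
    list(gene_id = regions$gene_id[g], k = k, shared_fraction = p,
         eqtls_A = eqtls_A, eqtls_B = eqtls_B, eqtls_admixed = eqtls_admixed,
         shared_sites = shared)
  })
  names(arch) <- regions$gene_id
  structure(list(genes = arch, k = k, p = p, regions = regions, seed = seed),
            class = "eqtl_architecture")
}

#' @exportS3Method base::print
print.eqtl_architecture <- function(x, ...) {
  cat(sprintf("eqtl_architecture: %d genes, k = %d, shared fraction p = %g\n",
              length(x$genes), x$k, x$p))
  cat(sprintf("  eQTLs per gene: %d in each ancestral population, %d in the admixed union\n",
              x$k, nrow(x$genes[[1]]$eqtls_admixed)))
  invisible(x)
}

# eQTL list applying to a sample role
arch_eqtls <- function(gene_arch, role) {
  switch(role,
         A = gene_arch$eqtls_A,
         B = gene_arch$eqtls_B,
         admixed = gene_arch$eqtls_admixed,
         stop("role must be 'A', 'B', or 'admixed'"))
}

#' Simulate gene expression at a fixed cis-heritability
#'
#' For each gene, the genetic value of individual `i` is
#' `g_i = sum_j dosage_ij * effect_j` over the eQTL list matching the
#' sample's role (A, B, or the admixed union applied to dosages regardless of
#' haplotype ancestry). Environmental noise is drawn i.i.d.
#' Normal(0, `Var(g) * (1 - h2) / h2`), so the realized cis-heritability
#' `Var(g) / Var(g + noise)` is on target in every simulated population.
#'
#' With `ancestry_aware = TRUE` (admixed samples only), population-specific
#' effects contribute only through haplotypes whose local ancestry matches
#' the effect's population of origin; shared effects always apply. This
#' variant is exposed for sensitivity analyses and is not used by the default
#' pipeline.
#'
#' @param sample A [population_sample()].
#' @param arch An [sample_architecture()] result.
#' @param h2 Target cis-heritability in `(0, 1)` (default 0.15).
#' @param seed Integer seed.
#' @param ancestry_aware Apply population-specific effects only on
#'   matching-ancestry haplotypes (admixed samples with stored haplotypes
#'   and ancestry only).
#' @return An object of class `expression_matrix` with `values` and
#'   `genetic_values` (`genes x individuals`), `target_h2`, per-gene
#'   `realized_h2`, a `degenerate` flag per gene, and `pop_label`.
#' @export
simulate_expression <- function(sample, arch, h2 = 0.15, seed = 1,
                                ancestry_aware = FALSE) {
  stopifnot(inherits(sample, "population_sample"),
            inherits(arch, "eqtl_architecture"), h2 > 0, h2 < 1)
  set.seed(seed)
  genes <- names(arch$genes)
  n <- sample$n
  g_mat <- matrix(NA_real_, length(genes), n, dimnames = list(genes, NULL))
  for (gi in seq_along(genes)) {
    ga <- arch$genes[[gi]]
    eq <- arch_eqtls(ga, sample$role)
    if (ancestry_aware) {
      if (is.null(sample$haplotypes) || is.null(sample$ancestry)) {
        stop("ancestry_aware expression needs haplotypes and ancestry labels")
      }
      h1 <- sample$haplotypes[seq(1L, 2L * n, by = 2L), eq$site, drop = FALSE]
      h2m <- sample$haplotypes[seq(2L, 2L * n, by = 2L), eq$site, drop = FALSE]
      anc1 <- sample$ancestry[, 1L, gi]
      anc2 <- sample$ancestry[, 2L, gi]
      g <- numeric(n)
      for (j in seq_len(nrow(eq))) {
        use1 <- eq$origin[j] == "shared" | anc1 == eq$origin[j]
        use2 <- eq$origin[j] == "shared" | anc2 == eq$origin[j]
        g <- g + eq$effect[j] * (h1[, j] * use1 + h2m[, j] * use2)
      }
    } else {
      g <- as.numeric(sample$dosages[, eq$site, drop = FALSE] %*% eq$effect)
    }
    g_mat[gi, ] <- g
  }
  var_g <- apply(g_mat, 1L, stats::var)
  degenerate <- var_g == 0
  noise_sd <- sqrt(ifelse(degenerate, 0, var_g * (1 - h2) / h2))
  noise <- matrix(stats::rnorm(length(g_mat)), nrow(g_mat), n) * noise_sd
  values <- g_mat + noise
  var_e <- apply(values, 1L, stats::var)
  realized_h2 <- ifelse(var_e > 0, var_g / var_e, NA_real_)
  structure(
    list(values = values, genetic_values = g_mat, target_h2 = h2,
         realized_h2 = realized_h2, degenerate = degenerate,
         pop_label = sample$pop_label),
    class = "expression_matrix"
  )
}

#' @exportS3Method base::print
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix '%s': %d genes x %d individuals (target h2 %.3g, mean realized %.3g)\n",
              x$pop_label, nrow(x$values), ncol(x$values), x$target_h2,
              mean(x$realized_h2, na.rm = TRUE)))
  invisible(x)
}
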