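#' Construct a phased haplotype panel
#'
#' A haplotype panel holds `H` phased binary haplotypes over `S` biallelic
#' sites, together with base-pair positions and a per-interval probability of
#' switching copying template. Panels are the unit of population divergence
#' and of mosaic copying: new haplotypes are always generated as
#' Li-Stephens-style mosaics of an existing panel.
#'
#' @param alleles Integer matrix `[H x S]` with entries in `{0, 1}`.
#' @param positions Strictly increasing integer base-pair positions, length `S`.
#' @param switch_prob Per-adjacent-interval template-switch probabilities in
#'   `[0, 1)`, length `S - 1`.
#' @param pop_label Population label string.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(alleles, positions = seq_len(ncol(alleles)),
                            switch_prob = rep(0.02, max(ncol(alleles) - 1L, 0L)),
                            pop_label = "pop") {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (nrow(alleles) < 4L) stop("a haplotype panel needs at least 4 haplotypes")
  if (ncol(alleles) < 1L) stop("a haplotype panel needs at least 1 site")
  if (!all(alleles %in% c(0L, 1L))) stop("alleles must be 0/1")
  if (length(positions) != ncol(alleles)) stop("positions length != number of sites")
  if (ncol(alleles) > 1L && any(diff(positions) <= 0)) {
    stop("positions must be strictly increasing")
  }
  if (length(switch_prob) != max(ncol(alleles) - 1L, 0L)) {
    stop("switch_prob must have length S - 1")
  }
  if (length(switch_prob) && (any(switch_prob < 0) || any(switch_prob >= 1))) {
    stop("switch_prob entries must lie in [0, 1)")
  }
  if (is.null(colnames(alleles))) {
    colnames(alleles) <- sprintf("s%05d", seq_len(ncol(alleles)))
  }
  structure(
    list(alleles = alleles, positions = as.integer(positions),
         switch_prob = as.numeric(switch_prob), pop_label = pop_label),
    class = "haplotype_panel"
  )
}

#' @exportS3Method base::print
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel '%s': %d haplotypes x %d sites\n",
              x$pop_label, nrow(x$alleles), ncol(x$alleles)))
  f <- colMeans(x$alleles)
  cat(sprintf("  allele freq: median %.3f, %d monomorphic sites\n",
              stats::median(f), sum(f == 0 | f == 1)))
  invisible(x)
}

#' @exportS3Method base::dim
dim.haplotype_panel <- function(x) dim(x$alleles)

# Draw n_out mosaic haplotypes from a panel of template haplotypes.
# At each adjacent-site interval the copying template is switched with that
# interval's probability; copied alleles are flipped with prob mutation_prob.
# Assumes the RNG is already seeded by the caller.
mosaic_haplotypes <- function(alleles, switch_prob, n_out, mutation_prob = 0) {
  H <- nrow(alleles)
  S <- ncol(alleles)
  out <- matrix(0L, n_out, S)
  for (i in seq_len(n_out)) {
    if (S > 1L) {
      sw <- stats::runif(S - 1L) < switch_prob
      seg <- c(0L, cumsum(sw)) + 1L
      tmpl <- sample.int(H, seg[S], replace = TRUE)
      hap <- alleles[cbind(tmpl[seg], seq_len(S))]
    } else {
      hap <- alleles[sample.int(H, 1L), , drop = TRUE]
    }
    if (mutation_prob > 0) {
      flip <- stats::runif(S) < mutation_prob
      hap[flip] <- 1L - hap[flip]
    }
    out[i, ] <- hap
  }
  colnames(out) <- colnames(alleles)
  out
}

#' Generate an ancestral haplotype panel with linkage disequilibrium
#'
#' Draws `n_founders` founder haplotypes with independent per-site allele
#' frequencies from a distribution concentrated on intermediate frequencies
#' (density proportional to 1/x truncated to `[0.02, 0.98]`), then emits
#' `n_haplotypes` Li-Stephens-style mosaics of the founders. A small founder
#' count induces realistic LD; per-interval switch probabilities are
#' exponentially distributed around `switch_prob_scale`, mimicking
#' recombination-rate heterogeneity.
#'
#' @param n_sites Number of biallelic sites (>= 1).
#' @param n_haplotypes Number of output haplotypes (>= 4).
#' @param n_founders Number of founder haplotypes (>= 2).
#' @param mutation_prob Per-site copying error probability in `[0, 0.05]`.
#' @param switch_prob_scale Mean per-interval template-switch probability.
#' @param seed Integer seed.
#' @param pop_label Label for the returned panel.
#' @return A [haplotype_panel()].
#' @examples
#' p <- generate_ancestral_panel(50, 40, n_founders = 6, seed = 1)
#' dim(p)
#' @export
generate_ancestral_panel <- function(n_sites, n_haplotypes, n_founders = 12,
                                     mutation_prob = 0.002,
                                     switch_prob_scale = 0.02, seed = 1,
                                     pop_label = "ancestral") {
  if (n_founders < 2) stop("n_founders must be >= 2")
  if (n_sites < 1) stop("n_sites must be >= 1")
  if (n_haplotypes < 4) stop("n_haplotypes must be >= 4")
  if (mutation_prob < 0 || mutation_prob > 0.05) {
    stop("mutation_prob must lie in [0, 0.05]")
  }
  set.seed(seed)
  # inverse-CDF draw from density proportional to 1/x on [0.02, 0.98]
  freqs <- 0.02 * (0.98 / 0.02)^stats::runif(n_sites)
  founders <- matrix(stats::rbinom(n_founders * n_sites, 1L, rep(freqs, each = n_founders)),
                     n_founders, n_sites)
  switch_prob <- if (n_sites > 1L) {
    pmin(0.45, switch_prob_scale * stats::rexp(n_sites - 1L))
  } else numeric(0)
  alleles <- mosaic_haplotypes(founders, switch_prob, n_haplotypes, mutation_prob)
  haplotype_panel(alleles, positions = seq_len(n_sites) * 1000L,
                  switch_prob = switch_prob, pop_label = pop_label)
}

#' Derive a diverged population panel by repeated mosaic resampling
#'
#' Applies `drift_rounds` rounds of resampling in which the panel is replaced
#' by fresh mosaics of itself (same copying rule, no founder reset). Each
#' round drifts allele frequencies by roughly `1/H`, so divergence between
#' independently derived panels accumulates approximately linearly in the
#' number of rounds. The default of 40 rounds was calibrated once so that two
#' independent derivations reach a mean Hudson F_ST near 0.14
#' (continental-scale divergence).
#'
#' @param ancestral A [haplotype_panel()].
#' @param drift_rounds Number of resampling rounds (>= 0).
#' @param seed Integer seed.
#' @param mutation_prob Per-site copying error during drift (default 0).
#' @param pop_label Label for the derived panel.
#' @return A [haplotype_panel()] with the same site grid as `ancestral`.
#' @export
derive_population_panel <- function(ancestral, drift_rounds = 40, seed = 1,
                                    mutation_prob = 0,
                                    pop_label = ancestral$pop_label) {
  stopifnot(inherits(ancestral, "haplotype_panel"), drift_rounds >= 0)
  alleles <- ancestral$alleles
  if (drift_rounds > 0) {
    set.seed(seed)
    H <- nrow(alleles)
    for (r in seq_len(drift_rounds)) {
      alleles <- mosaic_haplotypes(alleles, ancestral$switch_prob, H, mutation_prob)
    }
  }
  haplotype_panel(alleles, ancestral$positions, ancestral$switch_prob, pop_label)
}

#' Construct a diploid population sample
#'
#' @param dosages Integer matrix `[n x S]` with entries in `{0, 1, 2}`.
#' @param pop_label Population label.
#' @param role Which eQTL list applies when simulating expression:
#'   `"A"`, `"B"`, or `"admixed"`.
#' @param ancestry Optional `[n x 2 x G]` array of per-gene per-haplotype
#'   ancestry labels (`"A"`/`"B"`), admixed samples only.
#' @param haplotypes Optional `[2n x S]` phased haplotype matrix.
#' @param seed_record Seed(s) used to draw the sample.
#' @return An object of class `population_sample`.
#' @export
population_sample <- function(dosages, pop_label, role = pop_label,
                              ancestry = NULL, haplotypes = NULL,
                              seed_record = NA_integer_) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (!all(dosages %in% 0:2)) stop("dosages must be 0/1/2")
  if (!is.null(ancestry) && dim(ancestry)[1] != nrow(dosages)) {
    stop("ancestry first dimension must match sample size")
  }
  structure(
    list(dosages = dosages, n = nrow(dosages), pop_label = pop_label,
         role = role, ancestry = ancestry, haplotypes = haplotypes,
         seed_record = seed_record),
    class = "population_sample"
  )
}

#' @exportS3Method base::print
print.population_sample <- function(x, ...) {
  cat(sprintf("population_sample '%s' (role %s): %d individuals x %d sites%s\n",
              x$pop_label, x$role, x$n, ncol(x$dosages),
              if (!is.null(x$ancestry)) ", with gene-level ancestry" else ""))
  invisible(x)
}

#' Expand a haplotype panel into a diploid population sample
#'
#' Draws `2n` mosaic haplotypes from the panel (same copying rule as panel
#' generation) and pairs consecutive haplotypes into `n` diploid individuals.
#'
#' @param panel A [haplotype_panel()].
#' @param n Number of diploid individuals (>= 2).
#' @param seed Integer seed.
#' @param mutation_prob Per-site copying error (default 0).
#' @param pop_label Label for the sample.
#' @param role Expression role of the sample (`"A"` or `"B"`); see
#'   [simulate_expression()].
#' @return A [population_sample()].
#' @export
expand_population <- function(panel, n, seed = 1, mutation_prob = 0,
                              pop_label = panel$pop_label, role = pop_label) {
  stopifnot(inherits(panel, "haplotype_panel"), n >= 2)
  set.seed(seed)
  haps <- mosaic_haplotypes(panel$alleles, panel$switch_prob, 2L * n, mutation_prob)
  dos <- haps[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    haps[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  population_sample(dos, pop_label, role = role, seed_record = seed)
}

#' Sample a two-way admixed population with gene-level local ancestry
#'
#' For each individual, each of the two haplotypes, and each gene region
#' independently, ancestry is drawn as `B` with probability `alpha` (else
#' `A`), and the haplotype segment over the region is a fresh mosaic of the
#' chosen panel restricted to the region's sites. Local ancestry is therefore
#' constant within a gene for each haplotype, and recorded per gene and
#' haplotype.
#'
#' @param panel_A,panel_B Two [haplotype_panel()]s sharing the same site grid.
#' @param n Number of diploid individuals.
#' @param alpha Admixture proportion of B ancestry in `[0, 1]`.
#' @param regions Gene regions from [make_gene_regions()].
#' @param seed Integer seed.
#' @param pop_label Label for the sample.
#' @return A [population_sample()] with `role = "admixed"`, ancestry labels,
#'   and phased haplotypes retained (needed for ancestry-aware expression).
#' @export
sample_admixed <- function(panel_A, panel_B, n, alpha, regions, seed = 1,
                           pop_label = "admixed") {
  stopifnot(inherits(panel_A, "haplotype_panel"),
            inherits(panel_B, "haplotype_panel"),
            alpha >= 0, alpha <= 1, n >= 2)
  if (!identical(panel_A$positions, panel_B$positions)) {
    stop("panel_A and panel_B must share the same site grid")
  }
  set.seed(seed)
  S <- ncol(panel_A$alleles)
  G <- nrow(regions)
  haps <- matrix(0L, 2L * n, S)
  colnames(haps) <- colnames(panel_A$alleles)
  ancestry <- array("A", dim = c(n, 2L, G),
                    dimnames = list(NULL, NULL, regions$gene_id))
  for (g in seq_len(G)) {
    idx <- regions$start[g]:regions$end[g]
    sw <- panel_A$switch_prob[idx[-length(idx)]]
    from_B <- stats::runif(2L * n) < alpha
    nB <- sum(from_B)
    if (nB < 2L * n) {
      haps[!from_B, idx] <- mosaic_haplotypes(
        panel_A$alleles[, idx, drop = FALSE], sw, 2L * n - nB)
    }
    if (nB > 0L) {
      haps[from_B, idx] <- mosaic_haplotypes(
        panel_B$alleles[, idx, drop = FALSE], sw, nB)
    }
    anc <- matrix(c("A", "B")[from_B + 1L], n, 2L, byrow = TRUE)
    ancestry[, , g] <- anc
  }
  dos <- haps[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    haps[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  population_sample(dos, pop_label, role = "admixed", ancestry = ancestry,
                    haplotypes = haps, seed_record = seed)
}

#' Hudson-style F_ST between two haplotype panels
#'
#' Per-site Hudson estimator from the two panels' allele frequencies and
#' haplotype counts; the mean is taken over sites that are polymorphic in at
#' least one panel or carry a fixed difference (sites monomorphic for the
#' same allele in both panels are undefined and excluded).
#'
#' @param panel_A,panel_B Two [haplotype_panel()]s on the same site grid.
#' @return A list of class `divergence_report` with `per_site_fst`,
#'   `mean_fst`, and `estimator`.
#' @export
estimate_fst <- function(panel_A, panel_B) {
  stopifnot(inherits(panel_A, "haplotype_panel"),
            inherits(panel_B, "haplotype_panel"))
  if (!identical(panel_A$positions, panel_B$positions)) {
    stop("panels must share the same site grid")
  }
  p1 <- colMeans(panel_A$alleles)
  p2 <- colMeans(panel_B$alleles)
  n1 <- nrow(panel_A$alleles)
  n2 <- nrow(panel_B$alleles)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  fst <- ifelse(den > 0, num / den, NA_real_)
  structure(
    list(per_site_fst = fst,
         mean_fst = if (all(is.na(fst))) NA_real_ else mean(fst, na.rm = TRUE),
         estimator = "hudson"),
    class = "divergence_report"
  )
}

#' @exportS3Method base::print
print.divergence_report <- function(x, ...) {
  cat(sprintf("divergence_report (%s): mean F_ST %.4f over %d informative sites\n",
              x$estimator, x$mean_fst, sum(!is.na(x$per_site_fst))))
  invisible(x)
}

#' Minor-allele frequencies of a panel or sample
#'
#' @param x A [haplotype_panel()] or [population_sample()].
#' @param region Optional one-row region (or site index vector) restricting
#'   the computation.
#' @return Named numeric vector of per-site `min(f, 1 - f)`.
#' @export
compute_maf <- function(x, region = NULL) {
  f <- if (inherits(x, "haplotype_panel")) {
    colMeans(x$alleles)
  } else if (inherits(x, "population_sample")) {
    colMeans(x$dosages) / 2
  } else stop("x must be a haplotype_panel or population_sample")
  if (!is.null(region)) {
    idx <- if (is.data.frame(region)) region$start[1]:region$end[1] else region
    f <- f[idx]
  }
  pmin(f, 1 - f)
}

#' Lay out disjoint gene regions on a site grid
#'
#' Genes are modelled as disjoint consecutive windows of sites, the per-gene
#' analysis unit of the whole pipeline.
#'
#' @param n_genes Number of genes.
#' @param sites_per_gene Number of sites in each gene window.
#' @return A data.frame with columns `gene_id`, `start`, `end` (1-based,
#'   inclusive site indices).
#' @examples
#' make_gene_regions(3, 10)
#' @export
make_gene_regions <- function(n_genes, sites_per_gene) {
  stopifnot(n_genes >= 1, sites_per_gene >= 1)
  start <- (seq_len(n_genes) - 1L) * sites_per_gene + 1L
  data.frame(gene_id = sprintf("g%03d", seq_len(n_genes)),
             start = start, end = start + sites_per_gene - 1L,
             stringsAsFactors = FALSE)
}

#' Subset a population sample to the first `idx` individuals
#'
#' @param sample A [population_sample()].
#' @param idx Integer vector of individual indices to keep.
#' @return A [population_sample()] restricted to those individuals.
#' @export
subset_individuals <- function(sample, idx) {
  stopifnot(inherits(sample, "population_sample"))
  hap_idx <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  population_sample(
    sample$dosages[idx, , drop = FALSE], sample$pop_label, role = sample$role,
    ancestry = if (!is.null(sample$ancestry)) sample$ancestry[idx, , , drop = FALSE],
    haplotypes = if (!is.null(sample$haplotypes)) sample$haplotypes[hap_idx, , drop = FALSE],
    seed_record = sample$seed_record)
}
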