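test_that("eQTL count bookkeeping holds across the (k, p) grid", {
  for (k in c(1, 4, 10)) {
    for (p in c(0, 0.3, 0.5, 1)) {
      arch <- sample_architecture(tiny$regions, tiny$maf_A, tiny$maf_B,
                                  k = k, p = p, seed = 400 + 10 * k + p * 10)
      n_shared <- round(p * k)
      for (ga in arch$genes) {
        expect_equal(nrow(ga$eqtls_A), k)
        expect_equal(nrow(ga$eqtls_B), k)
        expect_equal(length(ga$shared_sites), n_shared)
        expect_equal(nrow(ga$eqtls_admixed), 2 * k - n_shared)
      }
    }
  }
})

test_that("shared eQTLs carry one common effect and specifics are disjoint", {
  arch <- sample_architecture(tiny$regions, tiny$maf_A, tiny$maf_B,
                              k = 10, p = 0.5, seed = 41)
  for (ga in arch$genes) {
    sh_A <- ga$eqtls_A[ga$eqtls_A$origin == "shared", ]
    sh_B <- ga$eqtls_B[ga$eqtls_B$origin == "shared", ]
    expect_identical(sh_A$site, sh_B$site)
    expect_identical(sh_A$effect, sh_B$effect)
    spec_A <- ga$eqtls_A$site[ga$eqtls_A$origin == "A"]
    spec_B <- ga$eqtls_B$site[ga$eqtls_B$origin == "B"]
    expect_length(intersect(spec_A, spec_B), 0)
    expect_length(intersect(spec_A, ga$shared_sites), 0)
    # MAF floor in the relevant population(s)
    expect_true(all(tiny$maf_A[ga$eqtls_A$site] >= 0.05))
    expect_true(all(tiny$maf_B[ga$eqtls_B$site] >= 0.05))
    expect_true(all(tiny$maf_B[ga$shared_sites] >= 0.05))
  }
})

test_that("p = 1 makes all three eQTL lists identical", {
  arch <- sample_architecture(tiny$regions, tiny$maf_A, tiny$maf_B,
                              k = 10, p = 1, seed = 42)
  for (ga in arch$genes) {
    expect_identical(ga$eqtls_A, ga$eqtls_B)
    expect_identical(ga$eqtls_A$site, ga$eqtls_admixed$site)
    expect_identical(ga$eqtls_A$effect, ga$eqtls_admixed$effect)
  }
})

test_that("insufficient eligible sites raise an error naming the gene", {
  regions <- make_gene_regions(1, 10)
  maf <- stats::setNames(rep(0.3, 10), sprintf("s%05d", 1:10))
  expect_error(sample_architecture(regions, maf, maf, k = 8, p = 0, seed = 1),
               "g001")
})

test_that("realized cis-heritability is on target", {
  regions <- make_gene_regions(20, 50)
  pan <- generate_ancestral_panel(1000, 150, seed = 51)
  smp <- expand_population(pan, 400, seed = 52, role = "A")
  maf <- compute_maf(smp)
  arch <- sample_architecture(regions, maf, maf, k = 5, p = 1, seed = 53)
  expr <- simulate_expression(smp, arch, h2 = 0.15, seed = 54)
  expect_equal(mean(expr$realized_h2), 0.15, tolerance = 0.02 / 0.15)
  expect_lt(max(abs(expr$realized_h2 - 0.15)), 0.08)
  # regressing expression on the genetic value recovers h2
  r2 <- sapply(rownames(expr$values), function(g)
    cor(expr$values[g, ], expr$genetic_values[g, ])^2)
  expect_equal(mean(r2), 0.15, tolerance = 0.03 / 0.15)
})

test_that("vanishing noise makes expression track the genetic value", {
  arch <- sample_architecture(tiny$regions, tiny$maf_A, tiny$maf_B,
                              k = 3, p = 1, seed = 61)
  expr <- simulate_expression(tiny$samp_A, arch, h2 = 0.999, seed = 62)
  for (g in rownames(expr$values)) {
    expect_gt(cor(expr$values[g, ], expr$genetic_values[g, ]), 0.99)
  }
})

test_that("single-eQTL genetic variance matches the HWE closed form", {
  pan <- generate_ancestral_panel(40, 150, seed = 71)
  smp <- expand_population(pan, 1000, seed = 72, role = "A")
  maf <- compute_maf(smp)
  regions <- make_gene_regions(1, 40)
  arch <- sample_architecture(regions, maf, maf, k = 1, p = 1, seed = 73)
  expr <- simulate_expression(smp, arch, h2 = 0.5, seed = 74)
  site <- arch$genes[[1]]$eqtls_A$site
  w <- arch$genes[[1]]$eqtls_A$effect
  q <- mean(smp$dosages[, site]) / 2
  v_emp <- var(expr$genetic_values[1, ])
  v_hwe <- w^2 * 2 * q * (1 - q)
  # 3 SEs of the sample variance of the dosage-driven genetic value
  centred <- (expr$genetic_values[1, ] - mean(expr$genetic_values[1, ]))^2
  se <- sd(centred) / sqrt(1000)
  expect_lt(abs(v_emp - v_hwe), 3 * se + 1e-12)
})

test_that("degenerate genes (monomorphic causal sites) are flagged", {
  dos <- cbind(matrix(rbinom(50 * 4, 2, 0.4), 50, 4), rep(1L, 50))
  colnames(dos) <- sprintf("s%05d", 1:5)
  smp <- population_sample(dos, "A", role = "A")
  regions <- make_gene_regions(1, 5)
  arch <- structure(list(genes = list(g001 = list(
    gene_id = "g001", k = 1, shared_fraction = 1,
    eqtls_A = data.frame(site = 5L, site_id = "s00005", effect = 1,
                         origin = "shared"),
    eqtls_B = data.frame(site = 5L, site_id = "s00005", effect = 1,
                         origin = "shared"),
    eqtls_admixed = data.frame(site = 5L, site_id = "s00005", effect = 1,
                               origin = "shared"),
    shared_sites = 5L)), k = 1, p = 1, regions = regions, seed = 0),
    class = "eqtl_architecture")
  expr <- simulate_expression(smp, arch, h2 = 0.15, seed = 81)
  expect_true(expr$degenerate[1])
  expect_true(all(expr$values[1, ] == expr$genetic_values[1, ]))
})

test_that("ancestry-aware expression equals the union model when all eQTLs are shared", {
  regions <- make_gene_regions(2, 150)
  smp <- sample_admixed(tiny$pan_A, tiny$pan_B, 100, alpha = 0.5, regions,
                        seed = 91)
  arch1 <- sample_architecture(regions, tiny$maf_A, tiny$maf_B, k = 5, p = 1,
                               seed = 92)
  e_union <- simulate_expression(smp, arch1, h2 = 0.15, seed = 93)
  e_aware <- simulate_expression(smp, arch1, h2 = 0.15, seed = 93,
                                 ancestry_aware = TRUE)
  expect_equal(e_union$genetic_values, e_aware$genetic_values, tolerance = 1e-12)

  # with population-specific eQTLs the two generators must differ
  arch0 <- sample_architecture(regions, tiny$maf_A, tiny$maf_B, k = 5, p = 0,
                               seed = 94)
  g_union <- simulate_expression(smp, arch0, h2 = 0.15, seed = 95)$genetic_values
  g_aware <- simulate_expression(smp, arch0, h2 = 0.15, seed = 95,
                                 ancestry_aware = TRUE)$genetic_values
  expect_gt(max(abs(g_union - g_aware)), 1e-8)
})
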