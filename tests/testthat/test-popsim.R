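test_that("degenerate panel parameters are rejected", {
  expect_error(generate_ancestral_panel(100, 50, n_founders = 1), "n_founders")
  expect_error(generate_ancestral_panel(0, 50), "n_sites")
  expect_error(generate_ancestral_panel(100, 3), "n_haplotypes")
  expect_error(generate_ancestral_panel(100, 50, mutation_prob = 0.2),
               "mutation_prob")
  expect_error(haplotype_panel(matrix(0L, 4, 2), positions = c(5, 3)),
               "strictly increasing")
})

test_that("a single-site panel without mutation only copies founder alleles", {
  p <- generate_ancestral_panel(1, 20, n_founders = 5, mutation_prob = 0,
                                seed = 3)
  expect_true(all(p$alleles %in% c(0L, 1L)))
  # with one site every output allele is a direct founder copy, so the
  # panel cannot contain an allele absent from every founder: frequencies
  # are either 0, 1, or strictly between (both alleles present in founders)
  expect_equal(dim(p), c(20L, 1L))
})

test_that("mosaics with zero switch probability are exact template copies", {
  set.seed(9)
  founders <- matrix(rbinom(6 * 40, 1, 0.5), 6, 40)
  pan <- haplotype_panel(founders, switch_prob = rep(0, 39), pop_label = "f")
  der <- derive_population_panel(pan, drift_rounds = 1, seed = 11)
  founder_keys <- apply(founders, 1, paste, collapse = "")
  out_keys <- apply(der$alleles, 1, paste, collapse = "")
  expect_true(all(out_keys %in% founder_keys))
})

test_that("drift_rounds = 0 returns the input panel unchanged", {
  der <- derive_population_panel(tiny$anc, drift_rounds = 0, seed = 1)
  expect_identical(der$alleles, tiny$anc$alleles)
  expect_identical(der$positions, tiny$anc$positions)
})

test_that("mosaic closure: without mutation every allele traces to a founder", {
  # any site monomorphic in the source panel must stay monomorphic for the
  # same allele in every mosaic derivative
  der <- derive_population_panel(tiny$pan_A, drift_rounds = 3, seed = 42)
  f <- colMeans(tiny$pan_A$alleles)
  mono0 <- f == 0
  mono1 <- f == 1
  expect_true(all(der$alleles[, mono0] == 0L))
  expect_true(all(der$alleles[, mono1] == 1L))
})

test_that("LD decays with inter-site distance", {
  r2_by_class <- sapply(1:20, function(s) {
    pan <- generate_ancestral_panel(500, 200, n_founders = 10,
                                    mutation_prob = 0, seed = 1000 + s)
    A <- pan$alleles
    poly <- which(apply(A, 2, var) > 0)
    adj <- poly[(poly + 1) %in% poly][1:60]
    r2 <- function(i, j) suppressWarnings(cor(A[, i], A[, j]))^2
    near <- mean(mapply(r2, adj, adj + 1), na.rm = TRUE)
    mid <- mean(mapply(r2, adj, pmin(adj + 30, 500)), na.rm = TRUE)
    far <- mean(mapply(r2, adj, pmin(adj + 120, 500)), na.rm = TRUE)
    c(near = near, mid = mid, far = far)
  })
  means <- rowMeans(r2_by_class)
  expect_gt(means["near"], means["mid"])
  expect_gt(means["mid"], means["far"])
})

test_that("divergence accumulates with drift rounds", {
  fst_at <- function(rounds, s) {
    anc <- generate_ancestral_panel(300, 100, n_founders = 10, seed = 2000 + s)
    der <- derive_population_panel(anc, rounds, seed = 3000 + s)
    estimate_fst(anc, der)$mean_fst
  }
  f2 <- sapply(1:20, function(s) fst_at(2, s))
  f8 <- sapply(1:20, function(s) fst_at(8, s))
  expect_gt(mean(f8), mean(f2))
})

test_that("default drift rounds land in the calibrated F_ST window", {
  anc <- generate_ancestral_panel(1200, 200, seed = 77)
  a <- derive_population_panel(anc, seed = 78)
  b <- derive_population_panel(anc, seed = 79)
  fst <- estimate_fst(a, b)$mean_fst
  expect_gte(fst, 0.10)
  expect_lte(fst, 0.20)
})

test_that("diploid expansion respects dosage contracts and panel frequencies", {
  s <- expand_population(tiny$pan_A, 3, seed = 5)
  expect_equal(dim(s$dosages), c(3L, 300L))
  expect_true(all(s$dosages %in% 0:2))

  big <- expand_population(tiny$pan_A, 1000, seed = 6)
  f_pan <- colMeans(tiny$pan_A$alleles)
  f_smp <- colMeans(big$dosages) / 2
  se <- sqrt(pmax(f_pan * (1 - f_pan), 1e-12) / (2 * 1000))
  poly <- f_pan > 0 & f_pan < 1
  within3 <- abs(f_smp - f_pan)[poly] < 3 * se[poly]
  expect_gte(mean(within3), 0.95)
})

test_that("two complementary haplotypes without switching give coherent dosages", {
  h <- rep(c(0L, 1L), length.out = 30)
  pan <- haplotype_panel(rbind(h, 1L - h, h, 1L - h),
                         switch_prob = rep(0, 29), pop_label = "c")
  s <- expand_population(pan, 20, seed = 8)
  legal <- rbind(2L * h, h + (1L - h), 2L * (1L - h))
  keys <- apply(legal, 1, paste, collapse = "")
  expect_true(all(apply(s$dosages, 1, paste, collapse = "") %in% keys))
})

test_that("admixture bookkeeping matches the target proportion", {
  s0 <- sample_admixed(tiny$pan_A, tiny$pan_B, 50, alpha = 0, tiny$regions,
                       seed = 21)
  expect_true(all(s0$ancestry == "A"))

  s <- sample_admixed(tiny$pan_A, tiny$pan_B, 500, alpha = 0.8, tiny$regions,
                      seed = 22)
  frac_B <- mean(s$ancestry == "B")
  n_labels <- length(s$ancestry)
  se <- sqrt(0.8 * 0.2 / n_labels)
  expect_lt(abs(frac_B - 0.8), 3 * se)
})

test_that("local ancestry is constant per haplotype within a gene", {
  # with an all-0 panel A and all-1 panel B, the copied segment reveals the
  # ancestry directly and must match the recorded label at every site
  regions <- make_gene_regions(2, 20)
  pA <- haplotype_panel(matrix(0L, 6, 40), switch_prob = rep(0.3, 39),
                        pop_label = "A")
  pB <- haplotype_panel(matrix(1L, 6, 40), switch_prob = rep(0.3, 39),
                        pop_label = "B")
  s <- sample_admixed(pA, pB, 30, alpha = 0.5, regions, seed = 23)
  for (g in 1:2) {
    idx <- regions$start[g]:regions$end[g]
    for (i in 1:30) {
      h1 <- s$haplotypes[2 * i - 1, idx]
      h2 <- s$haplotypes[2 * i, idx]
      expect_equal(unname(unique(h1)),
                   if (s$ancestry[i, 1, g] == "B") 1L else 0L)
      expect_equal(unname(unique(h2)),
                   if (s$ancestry[i, 2, g] == "B") 1L else 0L)
    }
  }
})

test_that("mismatched site grids are rejected for admixture", {
  pan_short <- haplotype_panel(tiny$pan_B$alleles[, 1:100],
                               positions = tiny$pan_B$positions[1:100],
                               switch_prob = tiny$pan_B$switch_prob[1:99])
  expect_error(sample_admixed(tiny$pan_A, pan_short, 10, 0.5, tiny$regions),
               "site grid")
})

test_that("Hudson F_ST matches an independent transcription on a toy panel", {
  # 5 sites, two panels of 6 haplotypes each, counted by hand
  A <- matrix(c(1, 1, 1, 0, 0, 0,   # p1 = 3/6
                1, 1, 1, 1, 1, 1,   # p1 = 1
                0, 0, 0, 0, 0, 0,   # p1 = 0
                1, 0, 0, 0, 0, 0,   # p1 = 1/6
                1, 1, 0, 0, 0, 0),  # p1 = 2/6
              nrow = 6)
  B <- matrix(c(1, 0, 0, 0, 0, 0,   # p2 = 1/6
                0, 0, 0, 0, 0, 0,   # p2 = 0 (fixed difference vs p1 = 1)
                0, 0, 0, 0, 0, 0,   # p2 = 0 (monomorphic in both)
                1, 1, 1, 1, 0, 0,   # p2 = 4/6
                1, 1, 0, 0, 0, 0),  # p2 = 2/6
              nrow = 6)
  pA <- haplotype_panel(A, switch_prob = rep(0, 4))
  pB <- haplotype_panel(B, switch_prob = rep(0, 4))
  rep_fst <- estimate_fst(pA, pB)
  # independent element-wise transcription of the estimator
  p1 <- colMeans(A); p2 <- colMeans(B)
  expected <- ((p1 - p2)^2 - p1 * (1 - p1) / 5 - p2 * (1 - p2) / 5) /
    (p1 * (1 - p2) + p2 * (1 - p1))
  expect_equal(rep_fst$per_site_fst[2], 1, tolerance = 1e-12,
               ignore_attr = TRUE)       # fixed difference
  expect_true(is.na(rep_fst$per_site_fst[3]))  # monomorphic in both
  expect_equal(unname(rep_fst$per_site_fst[c(1, 2, 4, 5)]),
               expected[c(1, 2, 4, 5)], tolerance = 1e-12)
  expect_equal(rep_fst$mean_fst, mean(expected[c(1, 2, 4, 5)]),
               tolerance = 1e-12)
})

test_that("identical panels give near-zero F_ST and all-monomorphic gives NA", {
  self <- estimate_fst(tiny$pan_A, tiny$pan_A)
  expect_lt(abs(self$mean_fst), 0.01)

  mono <- haplotype_panel(matrix(0L, 6, 3), switch_prob = rep(0, 2))
  expect_true(is.na(estimate_fst(mono, mono)$mean_fst))
})

test_that("minor allele frequencies fold and match a hand count", {
  toy <- haplotype_panel(matrix(c(0, 0, 0, 0,    # freq 0    -> MAF 0
                                  1, 1, 1, 0,    # freq 3/4  -> MAF 1/4
                                  1, 0, 0, 0,    # freq 1/4  -> MAF 1/4
                                  1, 1, 1, 1),   # freq 1    -> MAF 0
                                nrow = 4),
                         switch_prob = rep(0, 3))
  expect_equal(unname(compute_maf(toy)), c(0, 0.25, 0.25, 0))

  f <- rep(0L, 100); f[1:93] <- 1L
  pan <- haplotype_panel(matrix(f, 100, 1), switch_prob = numeric(0))
  expect_equal(unname(compute_maf(pan)), 0.07)
})
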