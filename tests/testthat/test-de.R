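test_that("size factors match the median-of-ratios hand computation", {
  m <- ct(matrix(c(10, 30, 50, 20, 60, 100), nrow = 3))
  sf <- size_factors(m, rescale = FALSE)
  # per-gene geometric means 14.142/42.426/70.711; all column-1 ratios 0.7071
  expect_equal(sf$size_factor, c(1 / sqrt(2), sqrt(2)), tolerance = 1e-6)
  # identical columns give unit factors
  eq <- ct(matrix(c(5, 8, 11, 5, 8, 11, 5, 8, 11), nrow = 3))
  expect_equal(size_factors(eq)$size_factor, c(1, 1, 1))
  # homogeneity: scaling one column by k multiplies the factor ratio by k
  sc <- m
  sc$s2 <- as.integer(sc$s2 * 3)
  sf_sc <- size_factors(sc, rescale = FALSE)
  expect_equal(
    sf_sc$size_factor[2] / sf_sc$size_factor[1],
    3 * sf$size_factor[2] / sf$size_factor[1],
    tolerance = 1e-6
  )
  # rescaled factors have geometric mean 1
  expect_equal(exp(mean(log(size_factors(m)$size_factor))), 1, tolerance = 1e-10)
})

test_that("size factors refuse data with no all-positive gene", {
  m <- ct(matrix(c(0, 5, 3, 0), nrow = 2))
  err <- expect_error(size_factors(m), class = "hilcis_error_no_reference_genes")
  expect_match(conditionMessage(err), "median-of-ratios")
})

test_that("BH adjustment reproduces the hand step-up and the brute-force oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.037), 0.037)
  expect_error(bh_adjust(c(0.5, 1.2)), class = "hilcis_error_bad_pvalues")

  set.seed(71)
  for (n in c(1, 7, 113, 1000)) {
    p <- runif(n)^2
    expect_equal(bh_adjust(p), bh_brute(p), info = paste("n =", n))
    expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"), info = paste("n =", n))
    # permutation equivariance
    perm <- sample(n)
    expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
  }
})

test_that("dispersion estimates recover truth and degenerate cases", {
  set.seed(21)
  mk <- function(n_rep, rfun) {
    m <- t(vapply(seq_len(1500), function(i) rfun(n_rep), numeric(n_rep)))
    ct(m)
  }
  ss <- function(n_rep) {
    tibble::tibble(
      sample_id = sprintf("s%d", seq_len(n_rep)),
      group = "g1", replicate = seq_len(n_rep)
    )
  }
  unit_sf <- function(n_rep) {
    tibble::tibble(sample_id = sprintf("s%d", seq_len(n_rep)), size_factor = 1)
  }

  # Poisson data (true alpha 0): median estimate near zero at n = 6
  pois <- mk(6, function(n) rpois(n, 600))
  d_pois <- estimate_dispersion(pois, unit_sf(6), ss(6))
  expect_lte(median(d_pois$alpha), 0.01)

  # parameter recovery at alpha = 0.5, n = 10, mu = 1000
  nb <- mk(10, function(n) rnbinom(n, mu = 1000, size = 2))
  d_nb <- estimate_dispersion(nb, unit_sf(10), ss(10))
  expect_gt(median(d_nb$alpha), 0.3)
  expect_lt(median(d_nb$alpha), 0.7)

  # a constant toy dataset floors at zero
  const <- ct(matrix(7, nrow = 3, ncol = 4))
  d_const <- estimate_dispersion(const, unit_sf(4), ss(4))
  expect_equal(d_const$alpha, rep(1e-8, 3))

  # single-replicate-everywhere designs are rejected
  one <- ct(matrix(1:4, nrow = 2))
  ss1 <- tibble::tibble(
    sample_id = c("s1", "s2"), group = c("a", "b"), replicate = c(1L, 1L)
  )
  expect_error(
    estimate_dispersion(one, unit_sf(2), ss1),
    class = "hilcis_error_no_replication"
  )
})

test_that("Wald contrasts honour null, direction and symmetry contracts", {
  set.seed(33)
  base <- matrix(rnbinom(200 * 6, mu = 300, size = 20), nrow = 200)
  tab <- ct(base)
  samples <- tibble::tibble(
    sample_id = sprintf("s%d", 1:6),
    group = rep(c("A", "B"), each = 3),
    replicate = rep(1:3, 2)
  )
  sf <- size_factors(tab)
  disp <- estimate_dispersion(tab, sf, samples)

  # identical groups: mirror the first three columns
  same <- tab
  same[, 5:7] <- same[, 2:4]
  sf_same <- size_factors(same)
  disp_same <- estimate_dispersion(same, sf_same, samples)
  res_same <- nb_wald_contrast(same, sf_same, disp_same, samples, "A", "B")
  expect_true(all(abs(res_same$log2fc) < 1e-10))
  expect_true(all(res_same$p > 0.999))

  # direction: higher means in A give positive log2fc
  up <- tab
  up[1, 2:4] <- list(400L, 400L, 380L)
  up[1, 5:7] <- list(100L, 104L, 98L)
  res_up <- nb_wald_contrast(up, size_factors(up),
    estimate_dispersion(up, size_factors(up), samples),
    samples, "A", "B"
  )
  expect_gt(res_up$log2fc[1], 0)

  # relabelling flips the fold change and keeps the p-value
  res_ab <- nb_wald_contrast(tab, sf, disp, samples, "A", "B")
  res_ba <- nb_wald_contrast(tab, sf, disp, samples, "B", "A")
  expect_equal(res_ab$log2fc, -res_ba$log2fc)
  expect_equal(res_ab$p, res_ba$p)

  # an all-zero gene is a definitional null
  zero <- tab
  zero[2, -1] <- as.list(rep(0L, 6))
  res_zero <- nb_wald_contrast(zero, sf, disp, samples, "A", "B")
  expect_equal(res_zero$log2fc[2], 0)
  expect_equal(res_zero$p[2], 1)

  expect_error(
    nb_wald_contrast(tab, sf, disp, samples, "A", "C"),
    class = "hilcis_error_missing_group"
  )
})

test_that("padj is never below p and probabilities stay in range", {
  fx <- fx_recovery()
  tab <- tidy(fx$res$triplets$HIL1)
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  expect_true(all(tab$padj >= tab$p - 1e-12))
  expect_true(all(is.finite(tab$log2fc)))
})

test_that("trans-only and compensatory truth separate the right contrasts", {
  fx <- fx_engine() # d = 2, alpha = 0.05, 5 replicates, clean counts
  truth <- fx$study$truth
  tab <- triplet_wide(fx$triplet, threshold = 0.05)
  arch <- truth$architecture[match(tab$gene_id, truth$gene_id)]
  to <- tab[arch == "trans_only", ]
  expect_gte(mean(to$sig_BvN & !to$sig_HvB), 0.9)
  # compensatory: parents equal, HIL apart from both
  cp <- tab[arch == "compensatory", ]
  expect_gte(mean(!cp$sig_BvN & cp$sig_HvN & cp$sig_HvB), 0.85)
})

test_that("DEG counts grow monotonically with the simulated effect size", {
  n_sig <- vapply(c(0, 1, 2, 3), function(d) {
    cfg <- sim_config(
      n_genes = 1200, effect_size = d, seed = 17, mapping_leak = 1,
      introgressions = list(HIL = list(chrom = "X", start = 1, end = 8e6))
    )
    study <- simulate_hil_study(cfg)
    counts <- filter_detectable(
      restrict_to_orthologs(study$counts_refN, study$orthologs)
    )
    tri <- build_triplet(counts, study$samples, "HIL")
    tab <- tidy(tri)
    sum(tab$padj[tab$contrast == "HvN"] < 0.05)
  }, numeric(1))
  expect_true(all(diff(n_sig) >= 0))
  expect_gt(n_sig[4], n_sig[1])
})

test_that("triplets align gene sets and external tables round-trip", {
  fx <- fx_recovery()
  tri <- fx$res$triplets$HIL1
  tab <- tidy(tri)
  sets <- split(tab$gene_id, tab$contrast)
  expect_true(all(vapply(sets, setequal, logical(1), sets[[1]])))

  dir <- withr::local_tempdir()
  paths <- write_triplet(tri, dir, "HIL1")
  back <- triplet_from_tables(paths["BvN"], paths["HvN"], paths["HvB"], hil = "HIL1")
  wide_a <- triplet_wide(tri)
  wide_b <- triplet_wide(back)
  expect_equal(wide_b$sig_HvN, wide_a$sig_HvN)
  expect_equal(wide_b$log2fc_BvN, wide_a$log2fc_BvN, tolerance = 1e-9)
})

test_that("the engine agrees with an established NB framework on strong signal", {
  skip_if_not_installed("DESeq2")
  cfg <- sim_config(
    n_genes = 300, effect_size = 2, seed = 23, mapping_leak = 1,
    alpha_range = c(0.05, 0.05),
    introgressions = list(HIL = list(chrom = "X", start = 1, end = 8e6))
  )
  study <- simulate_hil_study(cfg)
  counts <- filter_detectable(
    restrict_to_orthologs(study$counts_refN, study$orthologs)
  )
  samples <- study$samples[study$samples$group %in% c("species_B", "species_N"), ]
  sf <- size_factors(counts)
  disp <- estimate_dispersion(counts, sf, samples)
  ours <- nb_wald_contrast(counts, sf, disp, samples, "species_B", "species_N")

  m <- as.matrix(counts[, samples$sample_id])
  rownames(m) <- counts$gene_id
  cd <- data.frame(species = factor(samples$group, levels = c("species_N", "species_B")))
  dds <- DESeq2::DESeqDataSetFromMatrix(m, cd, ~species)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- as.data.frame(DESeq2::results(dds, contrast = c("species", "species_B", "species_N")))
  ref <- ref[ours$gene_id, ]

  expect_gt(cor(ours$log2fc, ref$log2FoldChange), 0.98)
  both_called <- ours$padj < 0.05 & ref$padj < 0.05
  expect_true(all(sign(ours$log2fc[both_called]) == sign(ref$log2FoldChange[both_called])))
  # call agreement on the clear-cut majority
  agree <- mean((ours$padj < 0.05) == (ref$padj < 0.05), na.rm = TRUE)
  expect_gt(agree, 0.9)
})
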