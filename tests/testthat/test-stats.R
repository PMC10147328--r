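test_that("rounding is half-away-from-zero at the reporting precisions", {
  expect_equal(round_half_up(0.35, 1), 0.4)
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(72.5), 73)
  expect_equal(round_half_up(-0.35, 1), -0.4)
  expect_equal(round_half_up(0.5593, 1), 0.6)
})

test_that("jaccard matches definition and edge cases", {
  expect_equal(jaccard(1005, 1253, 1549), 1005 / 1797)
  expect_equal(round_half_up(jaccard(1005, 1253, 1549), 1), 0.6)
  expect_equal(jaccard(30, 30, 30), 1)
  expect_equal(jaccard(0, 10, 20), 0)
  expect_error(jaccard(0, 0, 0), class = "hilcis_error_bad_overlap")
  expect_error(jaccard(11, 10, 20), class = "hilcis_error_bad_overlap")
})

test_that("overlap test equals exact hypergeometric enumeration", {
  # complete overlap of two 5-sets in a 20-universe: p = 1/C(20,5)
  res <- overlap_test(5, 5, 5, 20)
  expect_equal(res$p_overlap, 1 / choose(20, 5), tolerance = 1e-12)
  # zero overlap is certain or near-certain
  expect_equal(overlap_test(0, 5, 5, 20)$p_overlap, 1)

  # brute-force agreement across many margins with universe <= 60
  set.seed(19)
  for (i in 1:60) {
    n_univ <- sample(10:60, 1)
    n_a <- sample(1:n_univ, 1)
    n_b <- sample(1:n_univ, 1)
    ks <- seq(max(0, n_a + n_b - n_univ), min(n_a, n_b))
    k <- ks[sample.int(length(ks), 1)]
    expect_equal(
      overlap_test(k, n_a, n_b, n_univ)$p_overlap,
      hyper_brute(k, n_a, n_b, n_univ),
      tolerance = 1e-9,
      info = sprintf("k=%d a=%d b=%d N=%d", k, n_a, n_b, n_univ)
    )
  }
  expect_error(overlap_test(6, 5, 5, 20), class = "hilcis_error_bad_overlap")
  expect_error(overlap_test(1, 30, 5, 20), class = "hilcis_error_bad_overlap")
})

test_that("chromosome enrichment matches brute-force Fisher enumeration", {
  mk_calls <- function(a, b, cc, d) {
    tibble::tibble(
      gene_id = sprintf("g%04d", seq_len(a + b + cc + d)),
      chrom_class = c(
        rep("autosome", a), rep("X", b), rep("autosome", cc), rep("X", d)
      ),
      direction = factor(
        c(rep("down", a + b), rep("ns", cc + d)),
        levels = c("up", "down", "ns")
      )
    )
  }
  even <- chrom_enrichment(mk_calls(50, 25, 50, 25), "down")
  expect_equal(even$odds_ratio, 1)
  expect_equal(even$p, 1)

  skewed <- chrom_enrichment(mk_calls(90, 10, 50, 50), "down")
  expect_equal(skewed$p, fisher_brute(90, 10, 50, 50), tolerance = 1e-9)
  expect_equal(skewed$odds_ratio, (90 * 50) / (10 * 50))

  zero <- chrom_enrichment(mk_calls(20, 0, 30, 10), "down")
  expect_equal(zero$odds_ratio, (20.5 * 10.5) / (0.5 * 30.5)) # Haldane cells

  lop <- mk_calls(10, 5, 20, 8)
  lop$chrom_class <- "autosome"
  expect_error(chrom_enrichment(lop, "down"), class = "hilcis_error_empty_stratum")
})

test_that("enrichment rejects on truly autosome-biased downregulation", {
  fx <- fx_recovery()
  # construct an autosome-biased down set from a real call table
  calls <- fx$res$calls_shared$HIL1
  biased <- calls
  biased$direction[biased$chrom_class == "X" &
    as.character(biased$direction) == "down"] <- "ns"
  res <- chrom_enrichment(biased, "down")
  expect_lt(res$p, 0.01)
  expect_gt(res$odds_ratio, 1)
})

test_that("concordance diagnoses identity, independence and relabeling", {
  mk <- function(ids, cat, dir = "down") {
    tibble::tibble(
      gene_id = ids,
      regulatory = factor(cat, levels = REGULATORY_LEVELS),
      inheritance = factor("additive", levels = INHERITANCE_LEVELS),
      direction = factor(dir, levels = c("up", "down", "ns"))
    )
  }
  ids <- sprintf("g%05d", 1:300)
  cats <- sample(REGULATORY_LEVELS, 300, replace = TRUE)
  same <- concordance(mk(ids, cats), mk(ids, cats), "regulatory")
  expect_equal(same$diagonal_fraction, 1)
  expect_equal(same$n_shared_deg, 300)

  # independent uniform categories: diagonal tends to 1/6
  set.seed(31)
  n <- 10000
  ids_n <- sprintf("g%05d", seq_len(n))
  a <- mk(ids_n, sample(REGULATORY_LEVELS, n, replace = TRUE))
  b <- mk(ids_n, sample(REGULATORY_LEVELS, n, replace = TRUE))
  indep <- concordance(a, b, "regulatory")
  expect_lt(abs(indep$diagonal_fraction - 1 / 6), 0.02)

  # simultaneous relabeling leaves the diagonal fraction unchanged
  relabel <- setNames(rev(REGULATORY_LEVELS), REGULATORY_LEVELS)
  a2 <- mk(ids_n, relabel[as.character(a$regulatory)])
  b2 <- mk(ids_n, relabel[as.character(b$regulatory)])
  expect_equal(
    concordance(a2, b2, "regulatory")$diagonal_fraction,
    indep$diagonal_fraction
  )

  # no shared DEGs is an error
  expect_error(
    concordance(mk(ids, cats, dir = "ns"), mk(ids, cats, dir = "ns")),
    class = "hilcis_error_empty_deg_set"
  )
})

test_that("category tallies conserve totals and report joint cis+trans shares", {
  calls <- tibble::tibble(
    gene_id = sprintf("g%04d", 1:828),
    regulatory = factor(
      rep(c("compensatory", "cis_trans_combined", "trans_only"), c(321, 277, 230)),
      levels = REGULATORY_LEVELS
    ),
    direction = factor("down", levels = c("up", "down", "ns"))
  )
  tally <- category_tally(calls)
  expect_equal(sum(tally$n), 828)
  expect_equal(tally$n[tally$regulatory == "compensatory"], 321L)
  expect_equal(attr(tally, "pct_cis_and_trans")[["down"]], 72)

  empty <- category_tally(calls[0, ])
  expect_equal(nrow(empty), 0L)

  fx <- fx_recovery()
  real <- category_tally(fx$res$calls_shared$HIL1)
  expect_equal(sum(real$n), nrow(fx$res$calls_shared$HIL1))
})

test_that("the summary report is internally consistent and printable", {
  fx <- fx_recovery()
  rep <- fx$res$report
  for (h in names(rep$per_hil)) {
    p <- rep$per_hil[[h]]
    expect_equal(p$n_deg, p$n_down + p$n_up)
    expect_equal(p$pct_deg, round_half_up(100 * p$n_deg / p$n_expressed))
    expect_equal(sum(unlist(p$regulatory)), p$n_expressed)
  }
  ov <- rep$cross_hil$overlap$down
  expect_equal(
    ov$jaccard,
    jaccard(ov$n_overlap, ov$n_a, ov$n_b)
  )
  cc <- rep$cross_hil$concordance$regulatory
  expect_equal(cc$pct_diagonal, round_half_up(100 * cc$n_diagonal / cc$n_shared_deg))
  txt <- format(rep)
  expect_true(any(grepl("Jaccard", txt)))
})
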