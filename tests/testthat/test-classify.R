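# exhaustive grid over significance flags and fold-change signs
sig_grid <- function() {
  g <- expand.grid(
    bvn = c(TRUE, FALSE), hvn = c(TRUE, FALSE), hvb = c(TRUE, FALSE),
    d_bvn = c(1, -1), d_hvn = c(1, -1), d_hvb = c(1, -1)
  )
  tibble::tibble(
    gene_id = sprintf("g%02d", seq_len(nrow(g))),
    log2fc_BvN = g$d_bvn, padj_BvN = ifelse(g$bvn, 0.01, 0.5), sig_BvN = g$bvn,
    log2fc_HvN = g$d_hvn, padj_HvN = ifelse(g$hvn, 0.01, 0.5), sig_HvN = g$hvn,
    log2fc_HvB = g$d_hvb, padj_HvB = ifelse(g$hvb, 0.01, 0.5), sig_HvB = g$hvb
  )
}

test_that("both decision tables are total over all patterns", {
  grid <- sig_grid()
  inh <- classify_inheritance(grid)
  reg <- classify_regulatory(grid)
  expect_equal(length(inh), nrow(grid))
  expect_false(anyNA(inh))
  expect_false(anyNA(reg))
  expect_true(all(inh %in% INHERITANCE_LEVELS))
  expect_true(all(reg %in% REGULATORY_LEVELS))
  # the strict-transgressive variant is also total
  inh2 <- classify_inheritance(grid, require_parental_difference = TRUE)
  expect_false(anyNA(inh2))
})

test_that("canonical significance patterns map to their categories", {
  # parents differ, HIL differs from N but matches B
  s <- sig_row(bvn = TRUE, hvn = TRUE, hvb = FALSE)
  expect_equal(as.character(classify_inheritance(s)), "cbr_dominant")
  expect_equal(as.character(classify_regulatory(s)), "trans_only")

  # parents differ, HIL matches N
  s <- sig_row(bvn = TRUE, hvn = FALSE, hvb = TRUE)
  expect_equal(as.character(classify_inheritance(s)), "cni_dominant")
  expect_equal(as.character(classify_regulatory(s)), "no_effect")

  # nothing significant
  s <- sig_row()
  expect_equal(as.character(classify_inheritance(s)), "conserved")
  expect_equal(as.character(classify_regulatory(s)), "conserved")

  # HIL above both parents, parents equal
  s <- sig_row(hvn = TRUE, hvb = TRUE, d_hvn = 1, d_hvb = 1)
  expect_equal(as.character(classify_inheritance(s)), "transgressive_high")
  expect_equal(as.character(classify_regulatory(s)), "compensatory")

  # HIL below both parents, parents differ
  s <- sig_row(bvn = TRUE, hvn = TRUE, hvb = TRUE, d_hvn = -1, d_hvb = -1)
  expect_equal(as.character(classify_inheritance(s)), "transgressive_low")
  expect_equal(as.character(classify_regulatory(s)), "cis_trans_combined")

  # all significant, HIL strictly between the parents
  s <- sig_row(bvn = TRUE, hvn = TRUE, hvb = TRUE, d_hvn = 1, d_hvb = -1)
  expect_equal(as.character(classify_inheritance(s)), "additive")
  expect_equal(as.character(classify_regulatory(s)), "cis_trans_combined")

  # an intransitive pattern falls through to ambiguous
  s <- sig_row(bvn = TRUE)
  expect_equal(as.character(classify_inheritance(s)), "ambiguous")
  expect_equal(as.character(classify_regulatory(s)), "ambiguous")

  # a zero fold change alongside a significant flag cannot be oriented
  s <- sig_row(hvn = TRUE, hvb = TRUE, d_hvn = 0, d_hvb = 0)
  expect_equal(as.character(classify_inheritance(s)), "ambiguous")
})

test_that("the two tables are mutually consistent over the exhaustive grid", {
  grid <- sig_grid()
  inh <- as.character(classify_inheritance(grid))
  reg <- as.character(classify_regulatory(grid))
  expect_true(all(reg[inh == "cbr_dominant"] == "trans_only"))
  expect_true(all(reg[inh == "cni_dominant"] == "no_effect"))
  expect_true(all(reg[inh == "additive"] == "cis_trans_combined"))
  expect_true(all((inh == "conserved") == (reg == "conserved")))
  transgressive <- inh %in% c("transgressive_high", "transgressive_low")
  expect_true(all(reg[transgressive & !grid$sig_BvN] == "compensatory"))
  expect_true(all(reg[transgressive & grid$sig_BvN] == "cis_trans_combined"))
})

test_that("direction calls follow the HIL-vs-N contrast", {
  expect_equal(
    as.character(direction_call(sig_row(hvn = TRUE, d_hvn = -2.4))),
    "down"
  )
  expect_equal(
    as.character(direction_call(sig_row(hvn = TRUE, d_hvn = 0.8))),
    "up"
  )
  expect_equal(as.character(direction_call(sig_row(hvn = FALSE))), "ns")
  expect_error(
    direction_call(sig_row(hvn = TRUE, d_hvn = 0)),
    class = "hilcis_error_ambiguous_direction"
  )
})

test_that("calls are invariant to gene order and fold-change scale", {
  fx <- fx_recovery()
  tri <- fx$res$triplets$HIL1
  calls <- classify_all(tri, threshold = 0.05)

  shuffled <- tri[sample(nrow(tri)), ]
  attr(shuffled, "hil") <- "HIL1"
  class(shuffled) <- class(tri)
  calls_shuf <- classify_all(shuffled, threshold = 0.05)
  calls_shuf <- calls_shuf[match(calls$gene_id, calls_shuf$gene_id), ]
  expect_equal(as.character(calls$inheritance), as.character(calls_shuf$inheritance))

  scaled <- tri
  scaled$log2fc <- scaled$log2fc * 3 # signs unchanged
  class(scaled) <- class(tri)
  calls_scaled <- classify_all(scaled, threshold = 0.05)
  expect_equal(as.character(calls$regulatory), as.character(calls_scaled$regulatory))
  expect_equal(as.character(calls$direction), as.character(calls_scaled$direction))
})

test_that("generative architectures are recovered as their matching categories", {
  fx <- fx_recovery()
  truth <- fx$study$truth
  calls <- fx$res$calls_shared$HIL1
  arch <- truth_arch(calls, truth)

  to_hit <- mean(as.character(calls$regulatory[arch == "trans_only"]) == "trans_only")
  expect_gte(to_hit, 0.85)
  cp_hit <- mean(as.character(calls$regulatory[arch == "compensatory"]) == "compensatory")
  expect_gte(cp_hit, 0.85)
  # compensatory genes misexpress outside the parental range
  cp_inh <- as.character(calls$inheritance[arch == "compensatory" &
    as.character(calls$regulatory) == "compensatory"])
  expect_true(all(cp_inh %in% c("transgressive_high", "transgressive_low")))

  # null study: nearly everything conserved
  fx0 <- fx_null()
  calls0 <- fx0$res$calls_shared$HIL1
  expect_gte(mean(as.character(calls0$regulatory) == "conserved"), 0.9)
})

test_that("misaligned triplets are rejected", {
  fx <- fx_recovery()
  tri <- fx$res$triplets$HIL1
  broken <- tri[-1, ] # drops one gene from one contrast
  class(broken) <- class(tri)
  expect_error(triplet_wide(broken), class = "hilcis_error_bad_triplet")
})
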