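# Shared fixtures and independent oracles. Fixtures are built once per test
# run and memoised; all randomness is seeded inside the generator configs.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# strong-signal study (d = 3, fixed dispersion 0.02, 5 replicates) plus its
# full pipeline run: the category-recovery conditions
fx_recovery <- function() {
  memo("recovery", function() {
    cfg <- sim_config(
      n_genes = 4000, effect_size = 3, alpha_range = c(0.02, 0.02),
      n_replicates = 5, seed = 42
    )
    study <- simulate_hil_study(cfg)
    res <- run_hil_pipeline(
      study$counts_refB, study$counts_refN, study$samples,
      study$annotation, study$orthologs,
      verbose = FALSE
    )
    list(cfg = cfg, study = study, res = res)
  })
}

# engine-level fixture: moderate effect (d = 2, alpha = 0.05, 5 replicates)
# with mapping leak disabled so the counts reflect the truth means directly,
# isolating the DE engine from the dual-reference mappability artifact
fx_engine <- function() {
  memo("engine", function() {
    cfg <- sim_config(
      n_genes = 4000, effect_size = 2, alpha_range = c(0.05, 0.05),
      n_replicates = 5, seed = 42, mapping_leak = 1
    )
    study <- simulate_hil_study(cfg)
    counts <- filter_detectable(
      restrict_to_orthologs(study$counts_refN, study$orthologs)
    )
    tri <- build_triplet(counts, study$samples, "HIL1")
    list(cfg = cfg, study = study, triplet = tri)
  })
}

# null study (d = 0) and its pipeline run
fx_null <- function() {
  memo("null", function() {
    cfg <- sim_config(n_genes = 3000, effect_size = 0, seed = 5)
    study <- simulate_hil_study(cfg)
    res <- run_hil_pipeline(
      study$counts_refB, study$counts_refN, study$samples,
      study$annotation, study$orthologs,
      verbose = FALSE
    )
    list(cfg = cfg, study = study, res = res)
  })
}

# truth architecture aligned to a classification table
truth_arch <- function(calls, truth) {
  truth$architecture[match(calls$gene_id, truth$gene_id)]
}

# build a count table from a plain matrix
ct <- function(mat, tag = "refN") {
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("g%03d", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("s%d", seq_len(ncol(mat)))
  out <- tibble::tibble(gene_id = rownames(mat))
  out <- dplyr::bind_cols(out, tibble::as_tibble(mat))
  attr(out, "reference_tag") <- tag
  out
}

# one-row significance-pattern tibble for the decision tables
sig_row <- function(bvn = FALSE, hvn = FALSE, hvb = FALSE,
                    d_bvn = 1, d_hvn = 1, d_hvb = 1) {
  tibble::tibble(
    gene_id = "g",
    log2fc_BvN = d_bvn, padj_BvN = ifelse(bvn, 0.01, 0.5), sig_BvN = bvn,
    log2fc_HvN = d_hvn, padj_HvN = ifelse(hvn, 0.01, 0.5), sig_HvN = hvn,
    log2fc_HvB = d_hvb, padj_HvB = ifelse(hvb, 0.01, 0.5), sig_HvB = hvb
  )
}

# --- independent oracles -------------------------------------------------

# Benjamini-Hochberg by direct definition: for each p_i, the minimum over
# thresholds t >= p_i of t * m / (#{p <= t}), capped at 1
bh_brute <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    cand <- p[p >= pi]
    min(1, min(vapply(cand, function(t) t * m / sum(p <= t), numeric(1))))
  }, numeric(1))
}

# upper-tail hypergeometric by explicit enumeration with choose()
hyper_brute <- function(k, n_a, n_b, n_univ) {
  ks <- k:min(n_a, n_b)
  sum(choose(n_a, ks) * choose(n_univ - n_a, n_b - ks)) / choose(n_univ, n_b)
}

# two-sided Fisher exact p by enumeration over all tables with the margins
fisher_brute <- function(a, b, cc, d) {
  m <- a + b
  n <- cc + d
  k <- a + cc
  support <- max(0, k - n):min(k, m)
  probs <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  p_obs <- choose(m, a) * choose(n, cc) / choose(m + n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
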