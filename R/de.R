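#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median across genes of the ratio of
#' that sample's count to the gene's geometric mean across samples, computed
#' over genes whose geometric mean is positive; factors are then rescaled to
#' geometric mean 1.
#'
#' @param counts Count table.
#' @param rescale Rescale factors to geometric mean 1 (default `TRUE`).
#' @return A tibble with columns `sample_id`, `size_factor`.
#' @examples
#' m <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
#'                     s1 = c(10, 30, 50), s2 = c(20, 60, 100))
#' size_factors(m)
#' @export
size_factors <- function(counts, rescale = TRUE) {
  assert_count_table(counts)
  m <- count_matrix(counts)
  log_gm <- rowMeans(log(m))
  use <- is.finite(log_gm) # genes with all-positive counts
  if (!any(use)) {
    hilcis_abort(
      paste(
        "No gene has positive counts in every sample;",
        "median-of-ratios is undefined. Filter genes or supply size factors."
      ),
      class = "no_reference_genes"
    )
  }
  sf <- apply(m[use, , drop = FALSE], 2, function(col) {
    median(exp(log(col) - log_gm[use]))
  })
  if (rescale) sf <- sf / exp(mean(log(sf)))
  tibble(sample_id = colnames(m), size_factor = unname(sf))
}

# size-factor vector aligned to the table's sample columns
sf_vector <- function(counts, sf) {
  v <- sf$size_factor[match(sample_ids(counts), sf$sample_id)]
  if (anyNA(v)) {
    hilcis_abort("Size factors missing for some samples.", class = "bad_input")
  }
  v
}

#' Per-gene NB dispersion estimates
#'
#' Method-of-moments estimate `alpha = max(0, (s^2 - mean)/mean^2)` on
#' size-factor-normalized counts, pooled across groups (weighted by within-
#' group degrees of freedom), then stabilised by shrinking 50/50 toward a
#' mean-dispersion trend in the standard parametric form
#' `alpha(mu) = a0 + a1/mu` (asymptotic dispersion plus shot noise), fitted
#' by least squares to the positive raw estimates. The shrink applies to
#' every gene - a raw estimate of zero at small replicate numbers is usually
#' truncation noise rather than evidence of Poisson variance - and the blend
#' carries a mild `(df+1)/df` finite-sample correction that fades out as
#' replication grows. When no trend is fittable (fewer than 10 genes with
#' positive raw estimates, as in degenerate toy data), the raw estimates are
#' used as-is, so a constant gene yields zero (the floor of `1e-8`).
#'
#' @param counts Count table.
#' @param sf Size factors from [size_factors()].
#' @param samples Sample sheet mapping `sample_id` to `group`.
#' @return Tibble with `gene_id`, `base_mean`, `alpha_mom` (raw MoM),
#'   `alpha` (final, floored at 1e-8).
#' @export
estimate_dispersion <- function(counts, sf, samples) {
  assert_count_table(counts)
  m <- count_matrix(counts)
  v <- sf_vector(counts, sf)
  keep <- colnames(m) %in% samples$sample_id
  m <- m[, keep, drop = FALSE]
  v <- v[keep]
  norm <- sweep(m, 2, v, "/")
  grp <- samples$group[match(colnames(m), samples$sample_id)]
  reps <- table(grp)
  if (all(reps < 2)) {
    hilcis_abort(
      "Dispersion needs at least one group with >= 2 replicates.",
      class = "no_replication"
    )
  }
  num <- 0
  den <- 0
  for (g in names(reps)[reps >= 2]) {
    sub <- norm[, grp == g, drop = FALSE]
    mg <- rowMeans(sub)
    vg <- apply(sub, 1, var)
    w <- ncol(sub) - 1
    # per-group MoM alpha, weighted by within-group df; guard mean 0
    ag <- ifelse(mg > 0, (vg - mg) / mg^2, 0)
    num <- num + w * ag
    den <- den + w
  }
  alpha_mom <- pmax(0, num / den)
  base_mean <- rowMeans(norm)

  floor_a <- 1e-8
  pos <- alpha_mom > 0 & base_mean > 0
  if (sum(pos) >= 10) {
    # mean-dispersion trend in the standard parametric form
    # alpha(mu) = a0 + a1/mu (asymptotic dispersion plus shot noise),
    # fitted to genes with observable extra-Poisson spread but applied to
    # every gene: zero-MoM estimates at small n are mostly truncation, not
    # evidence of Poisson variance
    fit <- lm(alpha_mom[pos] ~ I(1 / base_mean[pos]))
    a0 <- max(coef(fit)[1], floor_a)
    a1 <- max(coef(fit)[2], 0)
    trend <- pmin(a0 + a1 / pmax(base_mean, 1e-8), 10)
    # mild finite-df correction: the blend underestimates dispersion for
    # genes whose raw estimate truncated low, which inflates Wald type-I
    # error at triplicate designs; (df+1)/df fades out as replication grows
    alpha <- (0.5 * alpha_mom + 0.5 * trend) * (den + 1) / den
  } else {
    alpha <- alpha_mom
  }
  tibble(
    gene_id = rownames(m),
    base_mean = unname(base_mean),
    alpha_mom = unname(alpha_mom),
    alpha = unname(pmax(alpha, floor_a))
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' The classic step-up procedure: with p-values sorted ascending,
#' `q_(i) = min over j >= i of p_(j) * m / j`, capped at 1, returned in the
#' input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed, ignored for
#'   the count `m` and returned as NA).
#' @return Adjusted p-values in input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    hilcis_abort("p-values must lie in [0, 1].", class = "bad_pvalues")
  }
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0) {
    return(q)
  }
  ord <- ok[order(p[ok])]
  stepped <- pmin(1, rev(cummin(rev(p[ord] * m / seq_len(m)))))
  q[ord] <- stepped
  q
}

#' One pairwise negative-binomial Wald contrast
#'
#' Group means are plug-in averages of size-factor-normalized counts. The
#' log2 fold change is `log2((muA + eps) / (muB + eps))` with a half-count
#' guard `eps = 0.5 / median(sf)`; its standard error comes from the NB
#' variance of each group-mean estimate (`Var(k_j/s_j) = mu/s_j + alpha mu^2`)
#' by the delta method, and the Wald statistic is referred to the standard
#' normal. Genes with zero counts in both groups get `log2fc = 0`, `p = 1`.
#' BH adjustment is applied across genes within the contrast.
#'
#' @param counts Count table containing both groups' samples.
#' @param sf Size factors from [size_factors()].
#' @param dispersion Dispersion table from [estimate_dispersion()] (its
#'   `alpha` column is used), aligned by `gene_id`.
#' @param samples Sample sheet.
#' @param group_a,group_b Group labels to contrast; `log2fc > 0` means higher
#'   in `group_a`.
#' @return Tibble with `gene_id`, `group_a`, `group_b`, `base_mean`,
#'   `log2fc`, `se`, `p`, `padj`.
#' @export
nb_wald_contrast <- function(counts, sf, dispersion, samples, group_a, group_b) {
  assert_count_table(counts)
  m <- count_matrix(counts)
  v <- sf_vector(counts, sf)
  grp <- samples$group[match(colnames(m), samples$sample_id)]
  for (g in c(group_a, group_b)) {
    if (sum(grp == g, na.rm = TRUE) < 2) {
      hilcis_abort(
        sprintf("Group '%s' is absent or has < 2 replicates.", g),
        class = "missing_group"
      )
    }
  }
  alpha <- dispersion$alpha[match(rownames(m), dispersion$gene_id)]
  if (anyNA(alpha)) {
    hilcis_abort("Dispersion estimates missing for some genes.", class = "bad_input")
  }

  group_stats <- function(g) {
    idx <- which(grp == g)
    sub <- sweep(m[, idx, drop = FALSE], 2, v[idx], "/")
    mu <- rowMeans(sub)
    # Var(mean of normalized counts) under NB(s_j mu, alpha)
    var_mu <- vapply(
      seq_along(idx),
      function(k) mu / v[idx[k]] + alpha * mu^2,
      numeric(nrow(sub))
    )
    list(mu = mu, var = rowSums(matrix(var_mu, nrow = nrow(sub))) / length(idx)^2)
  }
  a <- group_stats(group_a)
  b <- group_stats(group_b)

  eps <- 0.5 / median(v)
  log2fc <- log2((a$mu + eps) / (b$mu + eps))
  se <- sqrt(
    a$var / (a$mu + eps)^2 + b$var / (b$mu + eps)^2
  ) / log(2)
  se <- pmax(se, 1e-12)
  z <- log2fc / se
  p <- 2 * pnorm(-abs(z))
  both_zero <- a$mu == 0 & b$mu == 0
  log2fc[both_zero] <- 0
  p[both_zero] <- 1
  tibble(
    gene_id = rownames(m),
    group_a = group_a,
    group_b = group_b,
    base_mean = unname(rowMeans(sweep(m, 2, v, "/"))),
    log2fc = unname(log2fc),
    se = unname(se),
    p = unname(p),
    padj = unname(bh_adjust(p))
  )
}

#' Three-way contrast triplet for one HIL
#'
#' Runs the three pairwise contrasts (B vs N, HIL vs N, HIL vs B) on the
#' common gene set, sharing one set of size factors and dispersion estimates
#' across the whole design. BH correction is applied within each contrast
#' separately.
#'
#' @param counts Count table with parental and HIL samples.
#' @param samples Sample sheet.
#' @param hil Label of the HIL group (e.g. `"HIL1"`).
#' @param sf,dispersion Optional precomputed [size_factors()] /
#'   [estimate_dispersion()] results; computed from all samples if omitted.
#' @return A `hilcis_triplet`: a long tibble with a `contrast` column
#'   (`"BvN"`, `"HvN"`, `"HvB"`) over the columns of [nb_wald_contrast()].
#' @export
build_triplet <- function(counts, samples, hil, sf = NULL, dispersion = NULL) {
  keep <- samples$group %in% c("species_B", "species_N", hil)
  samples <- samples[keep, , drop = FALSE]
  missing <- setdiff(c("species_B", "species_N", hil), unique(samples$group))
  if (length(missing) > 0) {
    hilcis_abort(
      sprintf("Missing group(s): %s.", paste(missing, collapse = ", ")),
      class = "missing_group"
    )
  }
  cols <- c("gene_id", samples$sample_id)
  counts <- counts[, intersect(names(counts), cols), drop = FALSE]
  if (is.null(sf)) sf <- size_factors(counts)
  if (is.null(dispersion)) dispersion <- estimate_dispersion(counts, sf, samples)
  contrasts <- list(
    BvN = c("species_B", "species_N"),
    HvN = c(hil, "species_N"),
    HvB = c(hil, "species_B")
  )
  out <- bind_rows(lapply(names(contrasts), function(nm) {
    ab <- contrasts[[nm]]
    res <- nb_wald_contrast(counts, sf, dispersion, samples, ab[1], ab[2])
    mutate(res, contrast = nm, .before = 1)
  }))
  structure(out, class = c("hilcis_triplet", class(out)), hil = hil)
}

#' Read a DESeq2-results-shaped contrast table
#'
#' Adapter for externally produced differential-expression results: a TSV
#' with a gene-ID first column and columns `baseMean`, `log2FoldChange`,
#' `lfcSE`, `pvalue`, `padj`, mapped onto the internal contrast layout so the
#' classification layer can consume results from any DE engine.
#'
#' @param path Path to the TSV.
#' @param group_a,group_b Group labels the contrast compares.
#' @return Tibble shaped like [nb_wald_contrast()] output.
#' @export
read_contrast_table <- function(path, group_a, group_b) {
  if (!file.exists(path)) {
    hilcis_abort(sprintf("Contrast table not found: '%s'.", path), class = "missing_file")
  }
  tab <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  names(tab)[1] <- "gene_id"
  pick <- function(...) {
    nm <- intersect(c(...), names(tab))
    if (length(nm) == 0) {
      hilcis_abort(
        sprintf("Column %s missing from '%s'.", c(...)[1], path),
        class = "bad_contrast_table"
      )
    }
    tab[[nm[1]]]
  }
  tibble(
    gene_id = as.character(tab$gene_id),
    group_a = group_a,
    group_b = group_b,
    base_mean = as.numeric(pick("baseMean", "base_mean")),
    log2fc = as.numeric(pick("log2FoldChange", "log2fc")),
    se = as.numeric(pick("lfcSE", "se")),
    p = as.numeric(pick("pvalue", "p")),
    padj = as.numeric(pick("padj"))
  )
}

#' Assemble a triplet from three external contrast tables
#'
#' @param path_bvn,path_hvn,path_hvb TSV paths for the B-vs-N, HIL-vs-N and
#'   HIL-vs-B contrasts (DESeq2-results-shaped or internal layout).
#' @param hil HIL label.
#' @return A `hilcis_triplet` restricted to genes present in all three tables.
#' @export
triplet_from_tables <- function(path_bvn, path_hvn, path_hvb, hil = "HIL") {
  parts <- list(
    BvN = read_contrast_table(path_bvn, "species_B", "species_N"),
    HvN = read_contrast_table(path_hvn, hil, "species_N"),
    HvB = read_contrast_table(path_hvb, hil, "species_B")
  )
  common <- Reduce(intersect, lapply(parts, function(x) x$gene_id))
  if (length(common) == 0) {
    hilcis_abort("No genes shared by the three contrast tables.", class = "empty_intersection")
  }
  out <- bind_rows(lapply(names(parts), function(nm) {
    res <- filter(parts[[nm]], .data$gene_id %in% common)
    mutate(arrange(res, .data$gene_id), contrast = nm, .before = 1)
  }))
  structure(out, class = c("hilcis_triplet", class(out)), hil = hil)
}
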