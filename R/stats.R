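#' Jaccard index from set sizes
#'
#' @param n_overlap Size of the intersection.
#' @param n_a,n_b Sizes of the two sets.
#' @return `n_overlap / (n_a + n_b - n_overlap)`.
#' @examples
#' jaccard(1005, 1253, 1549) # ~0.559, reported as 0.6 at one decimal
#' @export
jaccard <- function(n_overlap, n_a, n_b) {
  if (n_overlap > min(n_a, n_b)) {
    hilcis_abort("n_overlap cannot exceed the smaller set.", class = "bad_overlap")
  }
  union <- n_a + n_b - n_overlap
  if (union == 0) {
    hilcis_abort("Jaccard undefined for an empty union.", class = "bad_overlap")
  }
  n_overlap / union
}

#' Hypergeometric overlap test of two gene sets
#'
#' Upper-tail probability `P(X >= n_overlap)` for the overlap of a set of
#' size `n_a` and a set of size `n_b` drawn from a universe of size
#' `n_universe` - equivalent to a one-sided Fisher exact test for enrichment
#' on the 2x2 table.
#'
#' @param n_overlap Observed overlap.
#' @param n_a,n_b Set sizes.
#' @param n_universe Universe size.
#' @return A tibble (`hilcis_overlap`) with `n_a`, `n_b`, `n_overlap`,
#'   `n_universe`, `jaccard`, `p_overlap`.
#' @export
overlap_test <- function(n_overlap, n_a, n_b, n_universe) {
  if (n_a > n_universe || n_b > n_universe ||
    n_overlap > min(n_a, n_b) ||
    n_overlap < max(0, n_a + n_b - n_universe)) {
    hilcis_abort("Inconsistent overlap margins.", class = "bad_overlap")
  }
  p <- phyper(n_overlap - 1, n_a, n_universe - n_a, n_b, lower.tail = FALSE)
  structure(
    tibble(
      n_a = n_a, n_b = n_b, n_overlap = n_overlap, n_universe = n_universe,
      jaccard = jaccard(n_overlap, n_a, n_b),
      p_overlap = p
    ),
    class = c("hilcis_overlap", class(tibble()))
  )
}

#' Overlap statistics of two HILs' DEG sets
#'
#' @param calls_a,calls_b `hilcis_classification` tables for the two HILs,
#'   already restricted to the shared (non-introgressed) genome.
#' @param direction `"down"`, `"up"`, or `"any"` (any DEG).
#' @return [overlap_test()] result; the universe is the genes present in
#'   both tables.
#' @export
deg_overlap <- function(calls_a, calls_b, direction = c("down", "up", "any")) {
  direction <- match.arg(direction)
  shared <- intersect(calls_a$gene_id, calls_b$gene_id)
  pick <- function(calls) {
    calls <- calls[calls$gene_id %in% shared, , drop = FALSE]
    if (direction == "any") {
      calls$gene_id[calls$direction != "ns"]
    } else {
      calls$gene_id[calls$direction == direction]
    }
  }
  a <- pick(calls_a)
  b <- pick(calls_b)
  overlap_test(length(intersect(a, b)), length(a), length(b), length(shared))
}

#' Autosome/X enrichment of up- or downregulated genes
#'
#' Two-sided Fisher exact test on the 2x2 table of (in-direction vs not) by
#' (autosome vs X). The odds ratio is the cross-product `(a d)/(b c)`, with
#' the Haldane 0.5 correction applied only when a zero cell occurs. Genes
#' inside introgression segments must be excluded upstream (the shared-genome
#' convention).
#'
#' @param calls A `hilcis_classification` with a `chrom_class` column.
#' @param direction `"down"` or `"up"`.
#' @return Tibble with the table cells, `odds_ratio` and `p`.
#' @export
chrom_enrichment <- function(calls, direction = c("down", "up")) {
  direction <- match.arg(direction)
  if (!"chrom_class" %in% names(calls)) {
    hilcis_abort("chrom_enrichment needs a chrom_class column.", class = "bad_input")
  }
  if (!all(c("autosome", "X") %in% calls$chrom_class)) {
    hilcis_abort("One chromosome stratum is empty.", class = "empty_stratum")
  }
  hit <- calls$direction == direction
  auto <- calls$chrom_class == "autosome"
  a <- sum(hit & auto)
  b <- sum(hit & !auto)
  cc <- sum(!hit & auto)
  d <- sum(!hit & !auto)
  tab <- matrix(c(a, b, cc, d), nrow = 2)
  or <- if (any(tab == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  } else {
    (a * d) / (b * cc)
  }
  tibble(
    direction = direction,
    n_dir_autosome = a, n_dir_x = b,
    n_other_autosome = cc, n_other_x = d,
    odds_ratio = or,
    p = fisher.test(tab)$p.value
  )
}

#' Cross-HIL category concordance
#'
#' For genes differentially expressed (HIL vs N, padj below the
#' classification threshold) in *both* HILs, cross-tabulates the category
#' assigned by each HIL and reports the diagonal fraction - the share of
#' shared DEGs placed in the identical category by both lines.
#'
#' @param calls_a,calls_b `hilcis_classification` tables restricted to the
#'   shared genome.
#' @param which `"inheritance"` or `"regulatory"`.
#' @return A `hilcis_concordance` list: `matrix` (category x category counts,
#'   HIL A rows), `n_shared_deg`, `n_diagonal`, `diagonal_fraction`.
#' @export
concordance <- function(calls_a, calls_b, which = c("inheritance", "regulatory")) {
  which <- match.arg(which)
  de_genes <- function(calls) calls$gene_id[calls$direction != "ns"]
  shared <- intersect(de_genes(calls_a), de_genes(calls_b))
  if (length(shared) == 0) {
    hilcis_abort("No genes are differentially expressed in both HILs.", class = "empty_deg_set")
  }
  cat_a <- calls_a[[which]][match(shared, calls_a$gene_id)]
  cat_b <- calls_b[[which]][match(shared, calls_b$gene_id)]
  lv <- union(levels(factor(cat_a)), levels(factor(cat_b)))
  tab <- table(A = factor(cat_a, levels = lv), B = factor(cat_b, levels = lv))
  structure(
    list(
      which = which,
      matrix = unclass(tab),
      n_shared_deg = length(shared),
      n_diagonal = sum(diag(tab)),
      diagonal_fraction = sum(diag(tab)) / length(shared),
      genes = shared
    ),
    class = "hilcis_concordance"
  )
}

#' @export
print.hilcis_concordance <- function(x, ...) {
  cat(sprintf(
    "Cross-HIL %s concordance: %d of %d shared DEGs on the diagonal (%s%%)\n",
    x$which, x$n_diagonal, x$n_shared_deg,
    format(round_half_up(100 * x$diagonal_fraction))
  ))
  print(x$matrix)
  invisible(x)
}

#' Tally regulatory categories of shared DEGs by direction
#'
#' Counts genes per regulatory category among shared DEGs, split by
#' direction, with percentages (round-half-up to the nearest integer).
#' `pct_cis_and_trans` is the share of genes with evidence of joint cis and
#' trans action (`compensatory` plus `cis_trans_combined`).
#'
#' @param calls A classification table (or concordant subset) with
#'   `regulatory` and `direction` columns.
#' @param direction_filter Optional `"down"` or `"up"` to tally one
#'   direction.
#' @return Tibble of `direction`, `regulatory`, `n`, `pct` plus attribute
#'   `pct_cis_and_trans` per direction.
#' @export
category_tally <- function(calls, direction_filter = NULL) {
  tab <- as_tibble(calls)
  if (!is.null(direction_filter)) {
    tab <- filter(tab, .data$direction == direction_filter)
  }
  if (nrow(tab) == 0) {
    out <- tibble(
      direction = character(), regulatory = character(),
      n = integer(), pct = numeric()
    )
    attr(out, "pct_cis_and_trans") <- numeric()
    return(out)
  }
  out <- tab |>
    group_by(.data$direction, .data$regulatory) |>
    summarise(n = n(), .groups = "drop_last") |>
    mutate(pct = round_half_up(100 * .data$n / sum(.data$n))) |>
    ungroup() |>
    mutate(
      direction = as.character(.data$direction),
      regulatory = as.character(.data$regulatory)
    )
  both <- out |>
    group_by(.data$direction) |>
    summarise(
      pct_cis_and_trans = round_half_up(
        100 * sum(.data$n[.data$regulatory %in%
          c("compensatory", "cis_trans_combined")]) / sum(.data$n)
      ),
      .groups = "drop"
    )
  attr(out, "pct_cis_and_trans") <- setNames(
    both$pct_cis_and_trans, both$direction
  )
  out
}
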