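#' Tidy a contrast triplet
#'
#' @param x A `hilcis_triplet`.
#' @param ... Unused.
#' @return A plain tibble, one row per gene and contrast.
#' @export
tidy.hilcis_triplet <- function(x, ...) {
  as_tibble(unclass(x)[setdiff(names(unclass(x)), NULL)])
}

#' One-row summary of a contrast triplet
#'
#' @param x A `hilcis_triplet`.
#' @param threshold padj threshold used for the significant-gene counts.
#' @param ... Unused.
#' @return Tibble with the HIL label, gene count and per-contrast counts of
#'   genes at `padj < threshold`.
#' @export
glance.hilcis_triplet <- function(x, threshold = 0.05, ...) {
  tab <- as_tibble(x)
  sig <- tab |>
    group_by(.data$contrast) |>
    summarise(n = sum(.data$padj < threshold, na.rm = TRUE), .groups = "drop")
  tibble(
    hil = attr(x, "hil", exact = TRUE) %||% NA_character_,
    n_genes = length(unique(tab$gene_id)),
    n_sig_BvN = sig$n[sig$contrast == "BvN"],
    n_sig_HvN = sig$n[sig$contrast == "HvN"],
    n_sig_HvB = sig$n[sig$contrast == "HvB"]
  )
}

#' Tidy a classification table
#'
#' @param x A `hilcis_classification`.
#' @param ... Unused.
#' @return Long tibble of category counts: `which` (`inheritance` or
#'   `regulatory`), `category`, `n`, `fraction`.
#' @export
tidy.hilcis_classification <- function(x, ...) {
  tab <- as_tibble(x)
  bind_rows(lapply(c("inheritance", "regulatory"), function(w) {
    counts <- table(tab[[w]])
    tibble(
      which = w,
      category = names(counts),
      n = as.integer(counts),
      fraction = as.integer(counts) / nrow(tab)
    )
  }))
}

#' One-row summary of a classification table
#'
#' @param x A `hilcis_classification`.
#' @param ... Unused.
#' @return Tibble with the HIL label, threshold, gene and DEG counts.
#' @export
glance.hilcis_classification <- function(x, ...) {
  tab <- as_tibble(x)
  tibble(
    hil = attr(x, "hil", exact = TRUE) %||% NA_character_,
    threshold = attr(x, "threshold", exact = TRUE) %||% NA_real_,
    n_genes = nrow(tab),
    n_deg = sum(tab$direction != "ns"),
    n_down = sum(tab$direction == "down"),
    n_up = sum(tab$direction == "up"),
    n_conserved = sum(tab$inheritance == "conserved")
  )
}

#' Tidy a concordance matrix
#'
#' @param x A `hilcis_concordance`.
#' @param ... Unused.
#' @return Long tibble of cells: `category_a`, `category_b`, `n`, `diagonal`.
#' @export
tidy.hilcis_concordance <- function(x, ...) {
  df <- as.data.frame(as.table(x$matrix), stringsAsFactors = FALSE)
  names(df) <- c("category_a", "category_b", "n")
  mutate(as_tibble(df), diagonal = .data$category_a == .data$category_b)
}

#' One-row summary of a concordance matrix
#'
#' @param x A `hilcis_concordance`.
#' @param ... Unused.
#' @return Tibble with shared-DEG count, diagonal count and fraction.
#' @export
glance.hilcis_concordance <- function(x, ...) {
  tibble(
    which = x$which,
    n_shared_deg = x$n_shared_deg,
    n_diagonal = x$n_diagonal,
    diagonal_fraction = x$diagonal_fraction
  )
}
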