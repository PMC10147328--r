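#' Round half away from zero
#'
#' Base R's `round()` rounds half to even ("banker's rounding"); report
#' conventions here call for conventional round-half-up (0.35 -> 0.4 at one
#' decimal, 72.5 -> 73 at integer precision).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(0.35, 1) # 0.4, where round(0.35, 1) gives 0.3 or 0.4
#' round_half_up(72.5) # 73
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# typed failure helper: all package errors carry class "hilcis_error" plus a
# specific subclass, so callers can condition on them
hilcis_abort <- function(message, class, ...) {
  abort(message, class = c(paste0("hilcis_error_", class), "hilcis_error"), ...)
}

# stderr stage logging used by the pipeline
hilcis_log <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) {
    message(sprintf("[hilcis] %s", sprintf(...)))
  }
}

#' @noRd
assert_count_table <- function(counts, arg = "counts") {
  if (!is.data.frame(counts) || !"gene_id" %in% names(counts)) {
    hilcis_abort(
      sprintf("`%s` must be a data frame with a `gene_id` column.", arg),
      class = "bad_input"
    )
  }
  if (ncol(counts) < 2L) {
    hilcis_abort(
      sprintf("`%s` has no sample columns.", arg),
      class = "bad_input"
    )
  }
  invisible(counts)
}

# sample columns of a count table (everything except gene_id)
sample_ids <- function(counts) setdiff(names(counts), "gene_id")

# numeric matrix view of a count table, genes as rows
count_matrix <- function(counts) {
  m <- as.matrix(counts[, sample_ids(counts), drop = FALSE])
  rownames(m) <- counts$gene_id
  storage.mode(m) <- "double"
  m
}

# rebuild a count table from a matrix, preserving the reference tag
as_count_table <- function(m, reference_tag = NULL) {
  out <- tibble(gene_id = rownames(m))
  out <- bind_cols(out, as_tibble(m))
  if (!is.null(reference_tag)) {
    attr(out, "reference_tag") <- reference_tag
  }
  out
}

#' Reference-genome tag of a count table
#'
#' @param counts A count table as returned by [read_counts()].
#' @return A string such as `"refN"`, `"refB"` or `"merged"`, or `NULL`.
#' @export
reference_tag <- function(counts) attr(counts, "reference_tag", exact = TRUE)
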