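#' Read a featureCounts-style count table
#'
#' Reads a tab-separated gene-by-sample count table. The first column is taken
#' as the gene ID; featureCounts annotation columns (`Chr`, `Start`, `End`,
#' `Strand`, `Length`) are dropped if present, and header lines starting with
#' `#` are skipped. Counts must be non-negative integers.
#'
#' @param path Path to a TSV file.
#' @param reference_tag Which reference genome the reads were mapped to:
#'   `"refN"` (the *C. nigoni*-like background species) or `"refB"`
#'   (the *C. briggsae*-like donor species).
#' @return A tibble with a `gene_id` column and one integer column per sample,
#'   carrying the reference tag as an attribute (see [reference_tag()]).
#'   Input gene order is preserved.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\ts1\ts2", "g1\t5\t9", "g2\t0\t2"), tsv)
#' read_counts(tsv, "refN")
#' @export
read_counts <- function(path, reference_tag = c("refN", "refB", "merged")) {
  reference_tag <- match.arg(reference_tag)
  if (!file.exists(path)) {
    hilcis_abort(sprintf("Count file not found: '%s'.", path), class = "missing_file")
  }
  tab <- readr::read_tsv(
    path,
    comment = "#", col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  names(tab)[1] <- "gene_id"
  drop <- intersect(c("Chr", "Start", "End", "Strand", "Length"), names(tab))
  tab <- tab[, setdiff(names(tab), drop), drop = FALSE]
  if (anyDuplicated(tab$gene_id)) {
    dup <- tab$gene_id[duplicated(tab$gene_id)][1]
    hilcis_abort(
      sprintf("Duplicated gene ID '%s' in '%s'.", dup, path),
      class = "duplicate_gene"
    )
  }
  for (col in setdiff(names(tab), "gene_id")) {
    x <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(x) | x < 0 | x != floor(x))
    if (length(bad) > 0) {
      hilcis_abort(
        sprintf(
          "Non-integer count '%s' at row %d (gene '%s'), column '%s' of '%s'.",
          tab[[col]][bad[1]], bad[1], tab$gene_id[bad[1]], col, path
        ),
        class = "bad_count"
      )
    }
    tab[[col]] <- as.integer(x)
  }
  out <- as_tibble(tab)
  attr(out, "reference_tag") <- reference_tag
  out
}

#' Write a count table to TSV
#'
#' @param counts Count table (see [read_counts()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  assert_count_table(counts)
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' The sample sheet is a CSV with columns `sample_id`, `group`, `replicate`.
#' `group` is `species_B`, `species_N`, or a HIL label such as `HIL1`.
#'
#' @param path Path to a CSV file.
#' @return A tibble with columns `sample_id`, `group`, `replicate`.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) {
    hilcis_abort(sprintf("Sample sheet not found: '%s'.", path), class = "missing_file")
  }
  ss <- readr::read_csv(path, col_types = "cci", progress = FALSE)
  req <- c("sample_id", "group", "replicate")
  if (!all(req %in% names(ss))) {
    hilcis_abort(
      sprintf(
        "Sample sheet must have columns %s.", paste(req, collapse = ", ")
      ),
      class = "bad_sample_sheet"
    )
  }
  validate_sample_sheet(ss)
}

#' Validate a sample sheet
#'
#' Checks the sample-sheet invariants: unique sample IDs and at least two
#' replicates per group (the study design has three).
#'
#' @param samples A data frame with `sample_id`, `group`, `replicate`.
#' @return `samples` as a tibble, invisibly validated.
#' @export
validate_sample_sheet <- function(samples) {
  if (anyDuplicated(samples$sample_id)) {
    hilcis_abort(
      sprintf(
        "Duplicated sample_id '%s'.",
        samples$sample_id[duplicated(samples$sample_id)][1]
      ),
      class = "bad_sample_sheet"
    )
  }
  n_per <- table(samples$group)
  if (any(n_per < 2)) {
    hilcis_abort(
      sprintf(
        "Group '%s' has fewer than 2 replicates.", names(n_per)[n_per < 2][1]
      ),
      class = "bad_sample_sheet"
    )
  }
  as_tibble(samples)
}

#' HIL group labels in a sample sheet
#'
#' @param samples Sample sheet tibble.
#' @return Character vector of group labels other than the two parent species.
#' @export
hil_labels <- function(samples) {
  sort(setdiff(unique(samples$group), c("species_B", "species_N")))
}

#' Read a 1:1 ortholog map
#'
#' Two-column TSV (with header) pairing gene IDs of the B reference with gene
#' IDs of the N reference, strictly one-to-one.
#'
#' @param path Path to TSV with columns `gene_id_refB`, `gene_id_refN`.
#' @return A tibble with columns `gene_id_refB`, `gene_id_refN`.
#' @export
read_ortholog_map <- function(path) {
  if (!file.exists(path)) {
    hilcis_abort(sprintf("Ortholog map not found: '%s'.", path), class = "missing_file")
  }
  o <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  if (!all(c("gene_id_refB", "gene_id_refN") %in% names(o))) {
    names(o)[1:2] <- c("gene_id_refB", "gene_id_refN")
  }
  validate_ortholog_map(o)
}

#' Validate a 1:1 ortholog map
#'
#' @param orthologs Data frame with columns `gene_id_refB`, `gene_id_refN`.
#' @return The map as a tibble; errors if any gene ID appears twice.
#' @export
validate_ortholog_map <- function(orthologs) {
  for (col in c("gene_id_refB", "gene_id_refN")) {
    if (anyDuplicated(orthologs[[col]])) {
      hilcis_abort(
        sprintf(
          "Ortholog map is not 1:1 - '%s' appears more than once in %s.",
          orthologs[[col]][duplicated(orthologs[[col]])][1], col
        ),
        class = "bad_ortholog_map"
      )
    }
  }
  as_tibble(orthologs)
}

#' Read gene annotation from GFF3 or BED
#'
#' Gene coordinates are held 1-based inclusive internally; BED input
#' (0-based half-open) is converted on read by `rtracklayer`. Chromosomes are
#' classified as X or autosome from their name.
#'
#' @param path Path to a GFF3 (`.gff`, `.gff3`) or BED file.
#' @param x_chroms Chromosome names counted as the X chromosome
#'   (default `"X"`).
#' @param feature_type For GFF3, which feature type to keep (default
#'   `"gene"`); ignored for BED.
#' @return Tibble with columns `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `chrom_class` (`"autosome"` or `"X"`).
#' @export
read_annotation <- function(path, x_chroms = "X", feature_type = "gene") {
  if (!file.exists(path)) {
    hilcis_abort(sprintf("Annotation not found: '%s'.", path), class = "missing_file")
  }
  gr <- rtracklayer::import(path)
  meta <- S4Vectors::mcols(gr)
  if ("type" %in% names(meta)) {
    gr <- gr[as.character(meta$type) == feature_type]
    meta <- S4Vectors::mcols(gr)
  }
  ids <- if ("ID" %in% names(meta)) {
    as.character(meta$ID)
  } else if ("Name" %in% names(meta)) {
    as.character(meta$Name)
  } else if ("name" %in% names(meta)) {
    as.character(meta$name)
  } else {
    hilcis_abort("Annotation has no ID or name field.", class = "bad_annotation")
  }
  ann <- tibble(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  annotate_chrom_class(ann, x_chroms = x_chroms)
}

#' Add the autosome/X classification to an annotation table
#'
#' @param annotation Tibble with at least `chrom`.
#' @param x_chroms Chromosome names counted as X.
#' @return The annotation with a `chrom_class` column.
#' @export
annotate_chrom_class <- function(annotation, x_chroms = "X") {
  bad <- annotation$start > annotation$end
  if (any(bad, na.rm = TRUE)) {
    hilcis_abort(
      sprintf(
        "Gene '%s' has start > end.", annotation$gene_id[which(bad)[1]]
      ),
      class = "bad_annotation"
    )
  }
  mutate(
    as_tibble(annotation),
    chrom_class = if_else(.data$chrom %in% x_chroms, "X", "autosome")
  )
}

#' Write gene annotation as GFF3
#'
#' @param annotation Annotation tibble (see [read_annotation()]).
#' @param path Output `.gff3` path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = annotation$start, end = annotation$end),
    strand = ifelse(annotation$strand %in% c("+", "-"), annotation$strand, "*")
  )
  S4Vectors::mcols(gr)$ID <- annotation$gene_id
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$source <- "hilcis"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Restrict a count table to 1:1 orthologs
#'
#' Keeps exactly the genes present in the ortholog map and re-keys them to the
#' canonical ortholog ID (the refN gene ID, since the HIL background genome is
#' species N). Output rows are sorted by canonical ID so the result does not
#' depend on input row order.
#'
#' @param counts Count table whose [reference_tag()] determines which column
#'   of the map is matched (`"merged"` matches the refN column).
#' @param orthologs Ortholog map tibble (see [read_ortholog_map()]).
#' @return Count table keyed by canonical (refN) gene IDs, sorted by ID.
#' @export
restrict_to_orthologs <- function(counts, orthologs) {
  assert_count_table(counts)
  orthologs <- validate_ortholog_map(orthologs)
  tag <- reference_tag(counts) %||% "refN"
  key <- if (tag == "refB") "gene_id_refB" else "gene_id_refN"
  idx <- match(counts$gene_id, orthologs[[key]])
  keep <- !is.na(idx)
  if (!any(keep)) {
    hilcis_abort(
      "No genes in common between the count table and the ortholog map.",
      class = "empty_intersection"
    )
  }
  out <- counts[keep, , drop = FALSE]
  out$gene_id <- orthologs$gene_id_refN[idx[keep]]
  out <- arrange(out, .data$gene_id)
  attr(out, "reference_tag") <- tag
  out
}

#' Filter genes with detectable expression
#'
#' Retains genes whose mean raw count across all samples is at least
#' `min_mean` and that have at least one nonzero count. The detectability rule
#' is deliberately simple and reproducible; it is configurable because no
#' single convention is standard.
#'
#' @param counts Count table.
#' @param min_mean Minimum mean raw count across samples (default 1).
#' @return Filtered count table; idempotent.
#' @export
filter_detectable <- function(counts, min_mean = 1) {
  assert_count_table(counts)
  stopifnot(min_mean >= 0)
  m <- count_matrix(counts)
  keep <- rowMeans(m) >= min_mean & rowSums(m > 0) >= 1L
  out <- counts[keep, , drop = FALSE]
  attr(out, "reference_tag") <- reference_tag(counts)
  out
}
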