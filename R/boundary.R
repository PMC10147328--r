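#' Per-gene dual-reference mapping deltas
#'
#' For each gene, the difference `log2(mean count on refB + 0.1) -
#' log2(mean count on refN + 0.1)` over the HIL's samples only. Genes derived
#' from B-species DNA (the introgressed fragment) map well only to the B
#' reference, so their delta is strongly positive; parental samples are
#' excluded because species-B samples would flag the whole genome.
#'
#' @param counts_refB,counts_refN Count tables on the two references, both
#'   already restricted to the canonical ortholog gene set
#'   (see [restrict_to_orthologs()]).
#' @param hil_samples Character vector of the HIL's sample IDs.
#' @param annotation Annotation tibble giving each gene's `chrom` and `start`.
#' @param pseudocount Added inside each log (fixed at 0.1 by convention).
#' @return Tibble `gene_id`, `chrom`, `position`, `mean_refB`, `mean_refN`,
#'   `delta`, ordered by chromosome then position.
#' @export
mapping_deltas <- function(counts_refB, counts_refN, hil_samples, annotation,
                           pseudocount = 0.1) {
  assert_count_table(counts_refB, "counts_refB")
  assert_count_table(counts_refN, "counts_refN")
  genes <- counts_refN$gene_id
  if (!setequal(genes, counts_refB$gene_id)) {
    miss <- head(c(
      setdiff(genes, counts_refB$gene_id),
      setdiff(counts_refB$gene_id, genes)
    ), 1)
    hilcis_abort(
      sprintf("Gene '%s' is missing from one of the two matrices.", miss),
      class = "bad_input"
    )
  }
  take <- function(counts) {
    cols <- intersect(hil_samples, sample_ids(counts))
    if (length(cols) == 0) {
      hilcis_abort("None of hil_samples are in the count table.", class = "bad_input")
    }
    m <- count_matrix(counts[, c("gene_id", cols)])
    unname(rowMeans(m)[genes])
  }
  mb <- take(counts_refB)
  mn <- take(counts_refN)
  out <- tibble(
    gene_id = genes,
    mean_refB = mb,
    mean_refN = mn,
    delta = log2(mb + pseudocount) - log2(mn + pseudocount)
  )
  out <- inner_join(
    select(annotation, "gene_id", "chrom", position = "start"),
    out,
    by = "gene_id"
  )
  arrange(out, .data$chrom, .data$position)
}

#' Call introgressed segments from mapping deltas
#'
#' Flags genes with `delta > threshold` and, within each chromosome, reports
#' maximal runs containing at least `min_run` flagged genes while tolerating
#' at most `max_gap` consecutive unflagged genes inside a run. A segment
#' spans the outermost flagged genes; its members are all genes between them
#' (flagged genes plus tolerated gaps).
#'
#' @param deltas Position-sorted output of [mapping_deltas()].
#' @param threshold Delta threshold (default 1, i.e. a two-fold mappability
#'   advantage on refB beyond the pseudocount guard).
#' @param min_run Minimum number of flagged genes in a segment (default 5).
#' @param max_gap Maximum tolerated run of unflagged genes inside a segment
#'   (default 2).
#' @param annotation Optional annotation supplying gene `start`/`end`
#'   coordinates; if omitted, segment bounds use the deltas' `position`.
#' @return Tibble of segments: `chrom`, `left_gene`, `right_gene`, `start`,
#'   `end`, `n_members`, and a list-column `members` of member gene IDs
#'   sorted by position.
#' @export
segment_introgression <- function(deltas, threshold = 1, min_run = 5,
                                  max_gap = 2, annotation = NULL) {
  segs <- list()
  for (chr in unique(deltas$chrom)) {
    d <- deltas[deltas$chrom == chr, , drop = FALSE]
    if (is.unsorted(d$position)) {
      hilcis_abort(
        sprintf("Deltas on chromosome '%s' are not position-sorted.", chr),
        class = "unsorted_input"
      )
    }
    flag <- d$delta > threshold
    hits <- which(flag)
    if (length(hits) == 0) next
    # group flagged genes into runs: a new run starts when more than max_gap
    # unflagged genes separate consecutive flagged genes
    run_id <- cumsum(c(1, diff(hits) > max_gap + 1))
    for (r in unique(run_id)) {
      members_idx <- seq(min(hits[run_id == r]), max(hits[run_id == r]))
      if (sum(flag[members_idx]) < min_run) next
      left <- min(members_idx)
      right <- max(members_idx)
      start <- d$position[left]
      end <- d$position[right]
      if (!is.null(annotation)) {
        idx <- match(c(d$gene_id[left], d$gene_id[right]), annotation$gene_id)
        if (!anyNA(idx)) {
          start <- annotation$start[idx[1]]
          end <- annotation$end[idx[2]]
        }
      }
      segs[[length(segs) + 1]] <- tibble(
        chrom = chr,
        left_gene = d$gene_id[left],
        right_gene = d$gene_id[right],
        start = start,
        end = end,
        n_members = length(members_idx),
        members = list(d$gene_id[members_idx])
      )
    }
  }
  if (length(segs) == 0) {
    return(tibble(
      chrom = character(), left_gene = character(), right_gene = character(),
      start = integer(), end = integer(), n_members = integer(),
      members = list()
    ))
  }
  bind_rows(segs)
}

#' Merge dual-reference counts along introgression segments
#'
#' Genes inside any called segment take their counts from the B-reference
#' matrix (their reads map well only there); all other genes take the
#' N-reference counts. Both matrices must share the canonical gene set.
#'
#' @param counts_refB,counts_refN Ortholog-restricted count tables.
#' @param segments Output of [segment_introgression()].
#' @return A merged count table tagged `"merged"`, in refN gene order.
#' @export
merge_counts_by_region <- function(counts_refB, counts_refN, segments) {
  assert_count_table(counts_refB, "counts_refB")
  assert_count_table(counts_refN, "counts_refN")
  if (nrow(segments) > 0) {
    for (chr in unique(segments$chrom)) {
      s <- segments[segments$chrom == chr, , drop = FALSE]
      if (nrow(s) > 1) {
        s <- s[order(s$start), , drop = FALSE]
        if (any(s$start[-1] <= s$end[-nrow(s)])) {
          hilcis_abort(
            sprintf("Overlapping segments on chromosome '%s'.", chr),
            class = "overlapping_segments"
          )
        }
      }
    }
  }
  inside <- unique(unlist(segments$members))
  out <- counts_refN
  if (length(inside) > 0) {
    idx_n <- match(inside, counts_refN$gene_id)
    idx_b <- match(inside, counts_refB$gene_id)
    if (anyNA(idx_n) || anyNA(idx_b)) {
      hilcis_abort(
        "Segment member genes missing from a count table.",
        class = "bad_input"
      )
    }
    cols <- sample_ids(counts_refN)
    out[idx_n, cols] <- counts_refB[idx_b, cols]
  }
  attr(out, "reference_tag") <- "merged"
  out
}

#' Write segments as BED
#'
#' Coordinates are converted from the internal 1-based inclusive convention
#' to BED's 0-based half-open on write.
#'
#' @param segments Output of [segment_introgression()].
#' @param path Output `.bed` path.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  bed <- tibble(
    chrom = segments$chrom,
    start = as.integer(segments$start) - 1L,
    end = as.integer(segments$end),
    name = paste0(segments$left_gene, "..", segments$right_gene),
    score = segments$n_members,
    strand = "."
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
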