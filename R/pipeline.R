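#' Run the full HIL analysis pipeline
#'
#' Executes every stage on in-memory inputs: ortholog restriction of both
#' reference-specific count matrices, per-HIL dual-reference mapping deltas
#' and introgression segmentation, region-aware merging of the two matrices,
#' detectability filtering, the three-way NB contrasts, inheritance /
#' regulatory classification, and (with two or more HILs) the cross-HIL
#' comparative statistics. Genes inside any HIL's introgression are excluded
#' from the shared-genome call tables used for the comparative statistics.
#'
#' @param counts_refB,counts_refN Count tables mapped to each reference
#'   (see [read_counts()]).
#' @param samples Sample sheet (see [read_sample_sheet()]).
#' @param annotation Annotation tibble (see [read_annotation()]).
#' @param orthologs 1:1 ortholog map (see [read_ortholog_map()]).
#' @param padj Significance threshold on BH-adjusted p (default 0.05).
#' @param delta_threshold,min_run,max_gap Segmentation rule parameters
#'   (see [segment_introgression()]).
#' @param min_mean Detectability filter (see [filter_detectable()]).
#' @param require_parental_difference Passed to [classify_inheritance()].
#' @param outdir Optional directory; when given, per-HIL deltas, segments
#'   (BED), contrast tables, classification tables and the JSON/text report
#'   are written there.
#' @param verbose Log stage-by-stage gene counts to standard error.
#' @return A `hilcis_result` list: `segments`, `deltas`, `triplets`, `calls`
#'   (full per-HIL tables), `calls_shared` (shared-genome tables), `report`,
#'   and `stage_log`.
#' @export
run_hil_pipeline <- function(counts_refB, counts_refN, samples, annotation,
                             orthologs,
                             padj = 0.05, delta_threshold = 1, min_run = 5,
                             max_gap = 2, min_mean = 1,
                             require_parental_difference = FALSE,
                             outdir = NULL, verbose = TRUE) {
  samples <- validate_sample_sheet(samples)
  hils <- hil_labels(samples)
  if (length(hils) == 0) {
    hilcis_abort("Sample sheet contains no HIL group.", class = "bad_sample_sheet")
  }
  stage_log <- list()
  log_stage <- function(stage, n_in, n_out) {
    stage_log[[stage]] <<- list(n_in = n_in, n_out = n_out)
    hilcis_log("%s: %d genes in, %d genes out", stage, n_in, n_out,
      verbose = verbose
    )
  }

  n0 <- nrow(counts_refN)
  rB <- restrict_to_orthologs(counts_refB, orthologs)
  rN <- restrict_to_orthologs(counts_refN, orthologs)
  common <- intersect(rB$gene_id, rN$gene_id)
  rB <- filter(rB, .data$gene_id %in% common)
  rN <- filter(rN, .data$gene_id %in% common)
  attr(rB, "reference_tag") <- "refB"
  attr(rN, "reference_tag") <- "refN"
  log_stage("restrict_to_orthologs", n0, nrow(rN))

  deltas <- list()
  segments <- list()
  for (h in hils) {
    hs <- samples$sample_id[samples$group == h]
    deltas[[h]] <- mapping_deltas(rB, rN, hs, annotation)
    segments[[h]] <- segment_introgression(
      deltas[[h]],
      threshold = delta_threshold, min_run = min_run, max_gap = max_gap,
      annotation = annotation
    )
    hilcis_log(
      "%s: %d introgression segment(s), %d member genes",
      h, nrow(segments[[h]]), length(unlist(segments[[h]]$members)),
      verbose = verbose
    )
  }
  introgressed <- unique(unlist(lapply(segments, function(s) unlist(s$members))))

  triplets <- list()
  calls <- list()
  calls_shared <- list()
  for (h in hils) {
    merged <- merge_counts_by_region(rB, rN, segments[[h]])
    detectable <- filter_detectable(merged, min_mean = min_mean)
    log_stage(paste0("filter_detectable_", h), nrow(merged), nrow(detectable))
    triplets[[h]] <- build_triplet(detectable, samples, h)
    calls[[h]] <- classify_all(
      triplets[[h]],
      threshold = padj, annotation = annotation,
      require_parental_difference = require_parental_difference
    )
    shared <- calls[[h]][!calls[[h]]$gene_id %in% introgressed, , drop = FALSE]
    attr(shared, "hil") <- h
    calls_shared[[h]] <- shared
    log_stage(paste0("shared_genome_", h), nrow(calls[[h]]), nrow(shared))
  }

  report <- summary_report(
    calls_shared,
    segments_by_hil = segments, stage_log = stage_log
  )

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (h in hils) {
      readr::write_tsv(
        deltas[[h]], file.path(outdir, paste0("deltas_", h, ".tsv")),
        progress = FALSE
      )
      if (nrow(segments[[h]]) > 0) {
        write_segments_bed(
          segments[[h]], file.path(outdir, paste0("segments_", h, ".bed"))
        )
      }
      write_triplet(triplets[[h]], outdir, h)
      write_classification(
        calls[[h]], file.path(outdir, paste0("classification_", h, ".tsv"))
      )
    }
    write_report(report, outdir)
  }

  structure(
    list(
      segments = segments, deltas = deltas, triplets = triplets,
      calls = calls, calls_shared = calls_shared,
      report = report, stage_log = stage_log,
      params = list(
        padj = padj, delta_threshold = delta_threshold, min_run = min_run,
        max_gap = max_gap, min_mean = min_mean
      )
    ),
    class = "hilcis_result"
  )
}

#' Write a triplet's three contrast tables as TSV
#'
#' @param triplet A `hilcis_triplet`.
#' @param dir Output directory.
#' @param hil Label used in the file names.
#' @return Named file paths, invisibly.
#' @export
write_triplet <- function(triplet, dir, hil = attr(triplet, "hil")) {
  paths <- c()
  for (nm in c("BvN", "HvN", "HvB")) {
    part <- filter(as_tibble(triplet), .data$contrast == nm)
    path <- file.path(dir, paste0("contrast_", hil, "_", nm, ".tsv"))
    readr::write_tsv(select(part, -"contrast"), path, progress = FALSE)
    paths[nm] <- path
  }
  invisible(paths)
}

#' Classification and comparative statistics from external contrast tables
#'
#' Adapter path that skips the internal DE engine: consumes
#' DESeq2-results-shaped (or internal-layout) contrast TSVs for each HIL and
#' runs only the classification and comparative-statistics stages.
#'
#' @param tables_by_hil Named list (one element per HIL) of character vectors
#'   with members `bvn`, `hvn`, `hvb` giving the three contrast TSV paths.
#' @param annotation Optional annotation tibble.
#' @param padj Significance threshold (default 0.05).
#' @param require_parental_difference Passed to [classify_inheritance()].
#' @param outdir Optional output directory for classification tables and the
#'   report.
#' @return A `hilcis_result` (without `segments`/`deltas`).
#' @export
classify_from_tables <- function(tables_by_hil, annotation = NULL,
                                 padj = 0.05,
                                 require_parental_difference = FALSE,
                                 outdir = NULL) {
  triplets <- list()
  calls <- list()
  for (h in names(tables_by_hil)) {
    paths <- tables_by_hil[[h]]
    triplets[[h]] <- triplet_from_tables(
      paths[["bvn"]], paths[["hvn"]], paths[["hvb"]],
      hil = h
    )
    calls[[h]] <- classify_all(
      triplets[[h]],
      threshold = padj, annotation = annotation,
      require_parental_difference = require_parental_difference
    )
  }
  report <- summary_report(calls)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (h in names(calls)) {
      write_classification(
        calls[[h]], file.path(outdir, paste0("classification_", h, ".tsv"))
      )
    }
    write_report(report, outdir)
  }
  structure(
    list(
      triplets = triplets, calls = calls, calls_shared = calls,
      report = report, params = list(padj = padj)
    ),
    class = "hilcis_result"
  )
}

#' @export
print.hilcis_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}
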