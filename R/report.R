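#' Build the cross-HIL summary report
#'
#' Assembles, from per-HIL classification tables restricted to the shared
#' (non-introgressed) genome, the quantities a HIL comparison reports:
#' expressed/DEG counts and percentages per HIL, up/down counts, autosome/X
#' enrichment tests, cross-HIL overlap statistics with Jaccard indices,
#' inheritance and regulatory concordance diagonals, and regulatory category
#' tallies of concordant shared DEGs by direction. Percentages are rounded
#' half-up to the nearest integer and Jaccard indices to one decimal.
#'
#' @param calls_by_hil Named list of `hilcis_classification` tables (one per
#'   HIL), already restricted to the shared genome.
#' @param segments_by_hil Optional named list of segment tables, echoed into
#'   the report.
#' @param stage_log Optional named list of per-stage gene counts, echoed
#'   into the report.
#' @return A `hilcis_report` list; see [write_report()].
#' @export
summary_report <- function(calls_by_hil, segments_by_hil = NULL,
                           stage_log = NULL) {
  hils <- names(calls_by_hil)
  per_hil <- lapply(hils, function(h) {
    calls <- calls_by_hil[[h]]
    n <- nrow(calls)
    n_deg <- sum(calls$direction != "ns")
    out <- list(
      n_expressed = n,
      n_deg = n_deg,
      pct_deg = round_half_up(100 * n_deg / n),
      n_down = sum(calls$direction == "down"),
      n_up = sum(calls$direction == "up"),
      inheritance = as.list(table(calls$inheritance)),
      regulatory = as.list(table(calls$regulatory))
    )
    # chromosomal enrichment needs annotation; skip when absent
    if ("chrom_class" %in% names(calls) &&
      all(c("autosome", "X") %in% calls$chrom_class)) {
      out$enrichment_down <- as.list(chrom_enrichment(calls, "down"))
      out$enrichment_up <- as.list(chrom_enrichment(calls, "up"))
    }
    out
  })
  names(per_hil) <- hils

  cross <- NULL
  if (length(hils) >= 2) {
    a <- calls_by_hil[[1]]
    b <- calls_by_hil[[2]]
    ov <- lapply(c(down = "down", up = "up", any = "any"), function(d) {
      res <- deg_overlap(a, b, d)
      out <- as.list(res)
      out$jaccard_1dp <- round_half_up(res$jaccard, 1)
      out
    })
    conc <- lapply(
      c(inheritance = "inheritance", regulatory = "regulatory"),
      function(w) {
        cc <- concordance(a, b, w)
        list(
          n_shared_deg = cc$n_shared_deg,
          n_diagonal = cc$n_diagonal,
          diagonal_fraction = cc$diagonal_fraction,
          pct_diagonal = round_half_up(100 * cc$diagonal_fraction),
          matrix = cc$matrix
        )
      }
    )
    # regulatory tallies among concordant shared DEGs, by direction
    cc_reg <- concordance(a, b, "regulatory")
    same <- cc_reg$genes[
      as.character(a$regulatory[match(cc_reg$genes, a$gene_id)]) ==
        as.character(b$regulatory[match(cc_reg$genes, b$gene_id)])
    ]
    conc_calls <- a[a$gene_id %in% same, , drop = FALSE]
    tally <- category_tally(conc_calls)
    cross <- list(
      hils = hils[1:2],
      overlap = ov,
      concordance = conc,
      concordant_tally = list(
        table = tally,
        pct_cis_and_trans = as.list(attr(tally, "pct_cis_and_trans"))
      )
    )
  }

  structure(
    list(
      hils = hils,
      per_hil = per_hil,
      cross_hil = cross,
      segments = segments_by_hil,
      stage_log = stage_log
    ),
    class = "hilcis_report"
  )
}

# drop non-serialisable bits and convert matrices for JSON
report_payload <- function(report) {
  payload <- unclass(report)
  if (!is.null(payload$cross_hil)) {
    for (w in names(payload$cross_hil$concordance)) {
      m <- payload$cross_hil$concordance[[w]]$matrix
      payload$cross_hil$concordance[[w]]$matrix <-
        as.data.frame.matrix(m)
    }
    payload$cross_hil$concordant_tally$table <-
      as.data.frame(payload$cross_hil$concordant_tally$table)
  }
  if (!is.null(payload$segments)) {
    payload$segments <- lapply(payload$segments, function(s) {
      s$members <- NULL
      as.data.frame(s)
    })
  }
  payload
}

#' Write the summary report as JSON and text
#'
#' Writes `report.json` (machine-readable, stable key order, fixed digits so
#' re-runs at the same seed are byte-identical) and `report.txt` (a
#' human-readable summary) into `dir`.
#'
#' @param report A `hilcis_report` from [summary_report()].
#' @param dir Output directory.
#' @return Named paths of the two files, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(dir, "report.json")
  txt_path <- file.path(dir, "report.txt")
  jsonlite::write_json(
    report_payload(report), json_path,
    auto_unbox = TRUE, digits = 10, pretty = TRUE
  )
  writeLines(format(report), txt_path)
  invisible(c(json = json_path, text = txt_path))
}

#' @export
format.hilcis_report <- function(x, ...) {
  lines <- c("HIL expression inheritance / regulatory divergence summary", "")
  for (h in names(x$per_hil)) {
    p <- x$per_hil[[h]]
    lines <- c(
      lines,
      sprintf("%s: %d expressed genes; %d DEGs (%s%%): %d down, %d up",
        h, p$n_expressed, p$n_deg, format(p$pct_deg), p$n_down, p$n_up
      )
    )
    if (!is.null(p$enrichment_down)) {
      lines <- c(lines, sprintf(
        "  down-gene autosome enrichment: OR = %.3g, Fisher p = %.3g",
        p$enrichment_down$odds_ratio, p$enrichment_down$p
      ))
    }
  }
  if (!is.null(x$cross_hil)) {
    ov <- x$cross_hil$overlap
    cc <- x$cross_hil$concordance
    lines <- c(
      lines, "",
      sprintf(
        "Down DEG overlap: %d of %d and %d (Jaccard %.1f, p = %.3g)",
        ov$down$n_overlap, ov$down$n_a, ov$down$n_b,
        ov$down$jaccard_1dp, ov$down$p_overlap
      ),
      sprintf(
        "Up DEG overlap: %d of %d and %d (Jaccard %.1f, p = %.3g)",
        ov$up$n_overlap, ov$up$n_a, ov$up$n_b,
        ov$up$jaccard_1dp, ov$up$p_overlap
      ),
      sprintf(
        "Inheritance concordance: %d of %d shared DEGs (%s%%)",
        cc$inheritance$n_diagonal, cc$inheritance$n_shared_deg,
        format(cc$inheritance$pct_diagonal)
      ),
      sprintf(
        "Regulatory concordance: %d of %d shared DEGs (%s%%)",
        cc$regulatory$n_diagonal, cc$regulatory$n_shared_deg,
        format(cc$regulatory$pct_diagonal)
      )
    )
    pct <- x$cross_hil$concordant_tally$pct_cis_and_trans
    for (d in intersect(c("down", "up"), names(pct))) {
      lines <- c(lines, sprintf(
        "Concordant %s-regulated DEGs with joint cis+trans evidence: %s%%",
        d, format(pct[[d]])
      ))
    }
  }
  lines
}

#' @export
print.hilcis_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}
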