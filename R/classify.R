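#' Category levels
#'
#' @name categories
#' @keywords internal
NULL

#' @rdname categories
#' @export
INHERITANCE_LEVELS <- c(
  "cbr_dominant", "cni_dominant", "additive",
  "transgressive_high", "transgressive_low", "conserved", "ambiguous"
)

#' @rdname categories
#' @export
REGULATORY_LEVELS <- c(
  "trans_only", "compensatory", "cis_trans_combined",
  "no_effect", "conserved", "ambiguous"
)

#' Pivot a contrast triplet to one row per gene
#'
#' @param triplet A `hilcis_triplet` from [build_triplet()] or
#'   [triplet_from_tables()].
#' @param threshold padj significance threshold (default 0.05).
#' @return Tibble with, per contrast `X` in `BvN`, `HvN`, `HvB`: `log2fc_X`,
#'   `padj_X`, `sig_X`; genes must be identical across contrasts.
#' @export
triplet_wide <- function(triplet, threshold = 0.05) {
  parts <- split(triplet, triplet$contrast)
  need <- c("BvN", "HvN", "HvB")
  if (!setequal(names(parts), need)) {
    hilcis_abort("Triplet must contain contrasts BvN, HvN, HvB.", class = "bad_triplet")
  }
  gsets <- lapply(parts, function(x) sort(x$gene_id))
  if (!all(vapply(gsets[-1], identical, logical(1), gsets[[1]]))) {
    hilcis_abort(
      "Triplet is misaligned: gene sets differ across contrasts.",
      class = "bad_triplet"
    )
  }
  wide <- NULL
  for (nm in need) {
    part <- arrange(parts[[nm]], .data$gene_id)
    block <- tibble(
      gene_id = part$gene_id,
      log2fc = part$log2fc,
      padj = part$padj,
      sig = !is.na(part$padj) & part$padj < threshold
    )
    names(block)[-1] <- paste(c("log2fc", "padj", "sig"), nm, sep = "_")
    wide <- if (is.null(wide)) block else left_join(wide, block, by = "gene_id")
  }
  wide
}

#' Classify expression inheritance
#'
#' Assigns each gene one of the five inheritance categories of the three-way
#' parent/HIL comparison, or `conserved`/`ambiguous`. The decision table,
#' evaluated in order on the significance flags and fold-change signs
#' (`HvN`/`HvB` oriented HIL-minus-parent, `BvN` as B-minus-N):
#'
#' 1. nothing significant -> `conserved`;
#' 2. HIL differs from both parents in the same direction ->
#'    `transgressive_high` (above both) or `transgressive_low` (below both),
#'    regardless of the parental contrast;
#' 3. all three significant with the HIL strictly between the parents
#'    (opposite HIL-minus-parent signs) -> `additive`;
#' 4. parents differ, HIL differs from B only -> `cni_dominant`;
#' 5. parents differ, HIL differs from N only -> `cbr_dominant`;
#' 6. anything else -> `ambiguous`.
#'
#' A significant contrast with a log2 fold change of exactly zero cannot be
#' oriented and routes to `ambiguous`.
#'
#' @param sig Tibble from [triplet_wide()] (columns `sig_*`, `log2fc_*`).
#' @param require_parental_difference If `TRUE`, transgressive calls
#'   additionally require the parental contrast to be significant (the
#'   stricter reading; default `FALSE`, under which genes with equal parents
#'   can be transgressive, as compensatory regulatory divergence implies).
#' @return Factor of inheritance calls with levels `INHERITANCE_LEVELS`.
#' @export
classify_inheritance <- function(sig, require_parental_difference = FALSE) {
  dir_hn <- sign(sig$log2fc_HvN)
  dir_hb <- sign(sig$log2fc_HvB)
  trans_ok <- if (require_parental_difference) sig$sig_BvN else TRUE
  call <- case_when(
    !sig$sig_BvN & !sig$sig_HvN & !sig$sig_HvB ~ "conserved",
    sig$sig_HvN & sig$sig_HvB & trans_ok &
      dir_hn > 0 & dir_hb > 0 ~ "transgressive_high",
    sig$sig_HvN & sig$sig_HvB & trans_ok &
      dir_hn < 0 & dir_hb < 0 ~ "transgressive_low",
    sig$sig_BvN & sig$sig_HvN & sig$sig_HvB &
      dir_hn * dir_hb < 0 ~ "additive",
    sig$sig_BvN & sig$sig_HvB & !sig$sig_HvN ~ "cni_dominant",
    sig$sig_BvN & sig$sig_HvN & !sig$sig_HvB ~ "cbr_dominant",
    TRUE ~ "ambiguous"
  )
  factor(call, levels = INHERITANCE_LEVELS)
}

#' Classify cis/trans regulatory divergence
#'
#' Assigns each gene a regulatory-divergence mode from the significance
#' pattern of the three pairwise contrasts. In a homozygous introgression
#' line the introgressed alleles experience the N-species trans environment,
#' so (unlike F1 allele-specific designs) cis-only divergence is undetectable
#' and the observable modes are:
#'
#' * `trans_only`: parents differ and the HIL differs from N but not from B
#'   (the HIL reconstitutes the B expression state through shared trans
#'   factors).
#' * `compensatory`: parents are equal yet the HIL differs from both -
#'   opposing cis and trans changes that cancel within each species but not
#'   in the hybrid.
#' * `cis_trans_combined`: all three contrasts significant.
#' * `no_effect`: parents differ, the HIL matches N and differs from B.
#' * `conserved`: nothing significant.
#' * `ambiguous`: any other pattern.
#'
#' @inheritParams classify_inheritance
#' @return Factor of regulatory calls with levels `REGULATORY_LEVELS`.
#' @export
classify_regulatory <- function(sig) {
  call <- case_when(
    sig$sig_BvN & sig$sig_HvN & !sig$sig_HvB ~ "trans_only",
    !sig$sig_BvN & sig$sig_HvN & sig$sig_HvB ~ "compensatory",
    sig$sig_BvN & sig$sig_HvN & sig$sig_HvB ~ "cis_trans_combined",
    sig$sig_BvN & !sig$sig_HvN & sig$sig_HvB ~ "no_effect",
    !sig$sig_BvN & !sig$sig_HvN & !sig$sig_HvB ~ "conserved",
    TRUE ~ "ambiguous"
  )
  factor(call, levels = REGULATORY_LEVELS)
}

#' Direction of differential expression in the HIL
#'
#' Up/down is defined relative to species N: `up` when the HIL-vs-N contrast
#' is significant with positive log2 fold change, `down` when negative,
#' `ns` otherwise.
#'
#' @inheritParams classify_inheritance
#' @return Factor with levels `up`, `down`, `ns`.
#' @export
direction_call <- function(sig) {
  zero_sig <- sig$sig_HvN & sig$log2fc_HvN == 0
  if (any(zero_sig, na.rm = TRUE)) {
    hilcis_abort(
      "Significant HvN contrast with log2fc exactly 0 cannot be oriented.",
      class = "ambiguous_direction"
    )
  }
  call <- case_when(
    sig$sig_HvN & sig$log2fc_HvN > 0 ~ "up",
    sig$sig_HvN & sig$log2fc_HvN < 0 ~ "down",
    TRUE ~ "ns"
  )
  factor(call, levels = c("up", "down", "ns"))
}

#' Classify every gene of a contrast triplet
#'
#' Applies [classify_inheritance()], [classify_regulatory()] and
#' [direction_call()] to one HIL's triplet. Calls depend only on the
#' significance flags and fold-change signs, so they are invariant to gene
#' order and count scale.
#'
#' @param triplet A `hilcis_triplet`.
#' @param threshold padj threshold shared by both decision tables
#'   (default 0.05).
#' @param annotation Optional annotation; if given, `chrom` and `chrom_class`
#'   are joined onto the result.
#' @param require_parental_difference Passed to [classify_inheritance()].
#' @return A `hilcis_classification` tibble: `gene_id`, `inheritance`,
#'   `regulatory`, `direction`, plus the per-contrast `log2fc_*`/`padj_*`
#'   columns (and annotation columns when supplied).
#' @export
classify_all <- function(triplet, threshold = 0.05, annotation = NULL,
                         require_parental_difference = FALSE) {
  wide <- triplet_wide(triplet, threshold = threshold)
  out <- mutate(
    wide,
    inheritance = classify_inheritance(
      wide,
      require_parental_difference = require_parental_difference
    ),
    regulatory = classify_regulatory(wide),
    direction = direction_call(wide)
  )
  if (!is.null(annotation)) {
    out <- left_join(
      out,
      select(annotation, "gene_id", "chrom", "chrom_class"),
      by = "gene_id"
    )
  }
  out <- select(
    out, "gene_id", dplyr::any_of(c("chrom", "chrom_class")),
    "inheritance", "regulatory", "direction", dplyr::everything()
  )
  structure(
    out,
    class = c("hilcis_classification", class(out)),
    hil = attr(triplet, "hil", exact = TRUE),
    threshold = threshold
  )
}

#' Write a classification table as TSV
#'
#' @param calls A `hilcis_classification`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classification <- function(calls, path) {
  readr::write_tsv(as_tibble(calls), path, progress = FALSE)
  invisible(path)
}
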