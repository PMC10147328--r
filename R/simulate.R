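#' Architectures recognised by the generator
#'
#' The five generative regulatory architectures: `conserved` (no divergence),
#' `no_effect` (cis divergence invisible in the HIL background), `trans_only`,
#' `compensatory` (opposing cis and trans changes; parents equal, HIL not),
#' and `combined` (both cis and trans effects).
#'
#' @export
ARCHITECTURES <- c("conserved", "no_effect", "trans_only", "compensatory", "combined")

#' Simulation configuration
#'
#' Defines the study conditions emulated by the synthetic-data generator:
#' two parent nematode species at high sequence divergence, plus one or more
#' hybrid introgression lines (HILs) carrying a homozygous X-linked fragment
#' of the B species in an N-species background, profiled by bulk RNA-seq in
#' triplicate.
#'
#' @param n_genes Number of 1:1 ortholog genes (default 12000).
#' @param arch_fractions Named fractions per architecture, summing to 1.
#'   Defaults put half the genes in `conserved`, with the remainder spread
#'   over the divergent classes.
#' @param effect_size Regulatory effect size `d` in log2 units (default 2);
#'   divergent means differ from the base mean by a factor `2^d`.
#' @param mu0_range Range of base expression means, drawn log-uniform
#'   (default 20-2000 expected counts).
#' @param alpha_range Range of the per-gene NB dispersion `alpha`
#'   (variance = mu + alpha * mu^2), drawn log-uniform (default 0.01-0.2,
#'   typical of replicated bulk RNA-seq). Set both ends equal for a fixed
#'   dispersion; set to 0 for Poisson counts.
#' @param n_replicates Replicates per group (default 3, the study design).
#' @param libsize_sd Standard deviation of log-normal per-sample library-size
#'   factors (default 0.1).
#' @param x_fraction Fraction of genes on the X chromosome (default 0.17).
#' @param chrom_lengths Named chromosome lengths in bp.
#' @param introgressions Named list (one per HIL) of introgressed intervals,
#'   each `list(chrom, start, end)` in 1-based inclusive bp. Defaults mirror
#'   a two-HIL design with non-overlapping X-linked fragments of ~4.8 and
#'   ~7.4 Mb.
#' @param mapping_leak Fraction `lambda` in `[0, 1]` of reads that still map
#'   to the wrong-species reference (default 0.05; cross-species mapping is
#'   poor but nonzero at ~21% synonymous-site divergence).
#' @param combined_weights Weights of the three `combined` sub-patterns
#'   (HIL intermediate between parents, reinforced beyond the B parent,
#'   shifted opposite to the B parent); default equal thirds.
#' @param seed Integer RNG seed.
#' @return A `hilcis_sim_config` list.
#' @export
sim_config <- function(n_genes = 12000,
                       arch_fractions = c(
                         conserved = 0.50, no_effect = 0.12,
                         trans_only = 0.13, compensatory = 0.13,
                         combined = 0.12
                       ),
                       effect_size = 2,
                       mu0_range = c(20, 2000),
                       alpha_range = c(0.01, 0.2),
                       n_replicates = 3,
                       libsize_sd = 0.1,
                       x_fraction = 0.17,
                       chrom_lengths = c(
                         I = 15.5e6, II = 16.6e6, III = 14.6e6,
                         IV = 17.5e6, V = 19.5e6, X = 21.5e6
                       ),
                       introgressions = list(
                         HIL1 = list(chrom = "X", start = 16392964, end = 21277039),
                         HIL2 = list(chrom = "X", start = 4742872, end = 12165712)
                       ),
                       mapping_leak = 0.05,
                       combined_weights = c(
                         intermediate = 1 / 3,
                         reinforced = 1 / 3,
                         opposing = 1 / 3
                       ),
                       seed = 1L) {
  arch_fractions <- arch_fractions[ARCHITECTURES]
  if (anyNA(arch_fractions)) {
    hilcis_abort(
      sprintf(
        "arch_fractions must be named by %s.",
        paste(ARCHITECTURES, collapse = ", ")
      ),
      class = "bad_config"
    )
  }
  if (abs(sum(arch_fractions) - 1) > 1e-8) {
    hilcis_abort("arch_fractions must sum to 1.", class = "bad_config")
  }
  if (effect_size < 0) {
    hilcis_abort("effect_size must be >= 0.", class = "bad_config")
  }
  if (mapping_leak < 0 || mapping_leak > 1) {
    hilcis_abort("mapping_leak must be in [0, 1].", class = "bad_config")
  }
  structure(
    list(
      n_genes = as.integer(n_genes),
      arch_fractions = arch_fractions,
      effect_size = effect_size,
      mu0_range = mu0_range,
      alpha_range = alpha_range,
      n_replicates = as.integer(n_replicates),
      libsize_sd = libsize_sd,
      x_fraction = x_fraction,
      chrom_lengths = chrom_lengths,
      introgressions = introgressions,
      mapping_leak = mapping_leak,
      combined_weights = combined_weights / sum(combined_weights),
      seed = as.integer(seed)
    ),
    class = "hilcis_sim_config"
  )
}

# largest-remainder apportionment of n among fractions (sums exactly to n)
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate per-gene ground truth
#'
#' Assigns each gene a chromosome, position, regulatory architecture, NB
#' dispersion and expected-count triplet `(mu_B, mu_N, mu_H)` for the two
#' parents and the HIL. With base mean `mu0` and a random sign `s`, the
#' architectures force the patterns:
#' `conserved` (mu0, mu0, mu0); `no_effect` (mu0*2^(s d), mu0, mu0);
#' `trans_only` (mu0*2^(s d), mu0, mu0*2^(s d));
#' `compensatory` (mu0, mu0, mu0*2^(s d)); and `combined`, where the HIL mean
#' is intermediate, reinforced beyond the B parent, or shifted opposite to it.
#' With `effect_size = 0` every architecture collapses to the null triplet.
#'
#' @param cfg A [sim_config()].
#' @return A tibble of ground-truth records: `gene_id` (canonical, refN),
#'   `gene_id_refB`, `chrom`, `position`, `architecture`, `mu_B`, `mu_N`,
#'   `mu_H`, `dispersion`, and one `in_introgression*` logical column per HIL.
#' @export
make_truth <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "hilcis_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes

  # gene placement: x_fraction on X, remainder spread over the autosomes
  autosomes <- setdiff(names(cfg$chrom_lengths), "X")
  n_x <- round(n * cfg$x_fraction)
  chrom <- c(
    sample(autosomes, n - n_x, replace = TRUE),
    rep("X", n_x)
  )
  position <- floor(runif(n, min = 1, max = cfg$chrom_lengths[chrom]))
  ord <- order(match(chrom, names(cfg$chrom_lengths)), position)
  chrom <- chrom[ord]
  position <- position[ord]

  architecture <- sample(rep(ARCHITECTURES, apportion(n, cfg$arch_fractions)))
  mu0 <- exp(runif(n, log(cfg$mu0_range[1]), log(cfg$mu0_range[2])))
  alpha <- if (max(cfg$alpha_range) <= 0) {
    rep(0, n)
  } else {
    exp(runif(n, log(cfg$alpha_range[1]), log(cfg$alpha_range[2])))
  }
  s <- sample(c(1, -1), n, replace = TRUE)
  d <- cfg$effect_size
  sub <- sample(names(cfg$combined_weights), n,
    replace = TRUE, prob = cfg$combined_weights
  )

  fac <- 2^(s * d)
  mu_B <- ifelse(architecture %in% c("no_effect", "trans_only", "combined"),
    mu0 * fac, mu0
  )
  mu_H <- mu0
  mu_H[architecture == "trans_only"] <- (mu0 * fac)[architecture == "trans_only"]
  mu_H[architecture == "compensatory"] <- (mu0 * fac)[architecture == "compensatory"]
  comb <- architecture == "combined"
  h_exp <- s * d / 2 # intermediate between the parents
  h_exp[sub == "reinforced"] <- (s * 1.5 * d)[sub == "reinforced"]
  h_exp[sub == "opposing"] <- (-s * d / 2)[sub == "opposing"]
  mu_H[comb] <- (mu0 * 2^h_exp)[comb]

  truth <- tibble(
    gene_id = sprintf("cnig_g%05d", seq_len(n)),
    gene_id_refB = sprintf("cbri_g%05d", sample(n)),
    chrom = chrom,
    position = as.integer(position),
    architecture = architecture,
    mu_B = mu_B,
    mu_N = mu0,
    mu_H = mu_H,
    dispersion = alpha
  )
  for (hl in names(cfg$introgressions)) {
    iv <- cfg$introgressions[[hl]]
    col <- if (length(cfg$introgressions) == 1L) {
      "in_introgression"
    } else {
      paste0("in_introgression_", hl)
    }
    truth[[col]] <- truth$chrom == iv$chrom &
      truth$position >= iv$start & truth$position <= iv$end
  }
  truth
}

# in_introgression column name for a HIL label
introgression_col <- function(truth, hil) {
  col <- paste0("in_introgression_", hil)
  if (!col %in% names(truth)) col <- "in_introgression"
  col
}

#' Simulate dual-reference count matrices from ground truth
#'
#' Counts for gene `g` in sample `j` are negative binomial with mean
#' `mu * L_j * map` and dispersion `alpha_g`, where `L_j` is the sample's
#' library-size factor and `map` models reference mappability: reads from
#' B-species DNA map fully only to the B reference and at a residual fraction
#' `mapping_leak` to the N reference, and vice versa. In a HIL, genes inside
#' that line's introgression are B-derived (map well to refB only); all other
#' genes are N-derived. `alpha = 0` genes are drawn Poisson.
#'
#' @param truth Ground truth from [make_truth()].
#' @param cfg The same [sim_config()].
#' @return A list with `counts_refN` and `counts_refB` count tables (refB is
#'   keyed and ordered by refB gene IDs), the `samples` sheet, and the
#'   per-sample `lib_factors`.
#' @export
simulate_counts <- function(truth, cfg = sim_config()) {
  stopifnot(inherits(cfg, "hilcis_sim_config"))
  set.seed(cfg$seed + 1L)
  hils <- names(cfg$introgressions)
  groups <- c("species_B", "species_N", hils)
  samples <- tibble(
    sample_id = unlist(lapply(groups, function(g) {
      paste0(sub("species_", "", g), "_", seq_len(cfg$n_replicates))
    })),
    group = rep(groups, each = cfg$n_replicates),
    replicate = rep(seq_len(cfg$n_replicates), times = length(groups))
  )
  n_s <- nrow(samples)
  lib <- exp(rnorm(n_s, mean = 0, sd = cfg$libsize_sd))
  names(lib) <- samples$sample_id

  n_g <- nrow(truth)
  mu <- matrix(0, n_g, n_s, dimnames = list(truth$gene_id, samples$sample_id))
  for (j in seq_len(n_s)) {
    grp <- samples$group[j]
    mu[, j] <- switch(grp,
      species_B = truth$mu_B,
      species_N = truth$mu_N,
      truth$mu_H
    ) * lib[j]
  }

  lam <- cfg$mapping_leak
  # mappability masks: fraction of each gene's reads recovered per reference
  map_n <- matrix(1, n_g, n_s)
  map_b <- matrix(lam, n_g, n_s)
  for (j in seq_len(n_s)) {
    grp <- samples$group[j]
    if (grp == "species_B") {
      map_n[, j] <- lam
      map_b[, j] <- 1
    } else if (grp %in% hils) {
      inside <- truth[[introgression_col(truth, grp)]]
      map_n[inside, j] <- lam
      map_b[inside, j] <- 1
    }
  }

  draw <- function(mean_mat) {
    mv <- as.vector(mean_mat)
    sz <- rep(ifelse(truth$dispersion > 0, 1 / truth$dispersion, Inf), times = n_s)
    out <- numeric(length(mv))
    pois <- is.infinite(sz)
    out[pois] <- rpois(sum(pois), lambda = mv[pois])
    out[!pois] <- rnbinom(sum(!pois), mu = mv[!pois], size = sz[!pois])
    matrix(as.integer(out), n_g, n_s, dimnames = dimnames(mean_mat))
  }
  cn <- draw(mu * map_n)
  cb <- draw(mu * map_b)

  counts_refN <- as_count_table(cn, reference_tag = "refN")
  rownames(cb) <- truth$gene_id_refB
  cb <- cb[order(rownames(cb)), , drop = FALSE]
  counts_refB <- as_count_table(cb, reference_tag = "refB")
  list(
    counts_refN = counts_refN,
    counts_refB = counts_refB,
    samples = samples,
    lib_factors = lib
  )
}

#' Annotation table implied by a truth table
#'
#' Genes are given 1 kb footprints starting at their sampled position.
#'
#' @param truth Truth tibble from [make_truth()].
#' @param x_chroms Chromosomes classified as X.
#' @return Annotation tibble (see [read_annotation()]).
#' @export
truth_annotation <- function(truth, x_chroms = "X") {
  annotate_chrom_class(
    tibble(
      gene_id = truth$gene_id,
      chrom = truth$chrom,
      start = truth$position,
      end = truth$position + 999L,
      strand = "+"
    ),
    x_chroms = x_chroms
  )
}

#' Ortholog map implied by a truth table
#'
#' @param truth Truth tibble from [make_truth()].
#' @return Tibble with `gene_id_refB`, `gene_id_refN`.
#' @export
truth_orthologs <- function(truth) {
  arrange(
    tibble(gene_id_refB = truth$gene_id_refB, gene_id_refN = truth$gene_id),
    .data$gene_id_refB
  )
}

#' Simulate a complete HIL study
#'
#' Runs [make_truth()] and [simulate_counts()] and assembles every input the
#' analysis pipeline consumes.
#'
#' @param cfg A [sim_config()].
#' @return List with `truth`, `counts_refN`, `counts_refB`, `samples`,
#'   `annotation`, `orthologs`, `lib_factors` and `config`.
#' @export
simulate_hil_study <- function(cfg = sim_config()) {
  truth <- make_truth(cfg)
  sim <- simulate_counts(truth, cfg)
  c(
    list(truth = truth),
    sim,
    list(
      annotation = truth_annotation(truth),
      orthologs = truth_orthologs(truth),
      config = cfg
    )
  )
}

#' Write a simulated study to disk as a fixture directory
#'
#' Writes the exact plain-text formats the readers consume: two count TSVs
#' (one per reference), a GFF3 annotation, the ortholog TSV, the sample CSV
#' and the ground-truth TSV. Byte-deterministic given the config seed.
#'
#' @param study Output of [simulate_hil_study()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the six file paths, invisibly.
#' @export
write_fixture <- function(study, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, mode = 2L) != 0L) {
    hilcis_abort(sprintf("Cannot write to '%s'.", dir), class = "unwritable_path")
  }
  paths <- c(
    counts_refN = file.path(dir, "counts_refN.tsv"),
    counts_refB = file.path(dir, "counts_refB.tsv"),
    annotation = file.path(dir, "annotation.gff3"),
    orthologs = file.path(dir, "orthologs.tsv"),
    samples = file.path(dir, "samples.csv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_counts(study$counts_refN, paths[["counts_refN"]])
  write_counts(study$counts_refB, paths[["counts_refB"]])
  write_annotation(study$annotation, paths[["annotation"]])
  readr::write_tsv(study$orthologs, paths[["orthologs"]], progress = FALSE)
  readr::write_csv(study$samples, paths[["samples"]], progress = FALSE)
  readr::write_tsv(study$truth, paths[["truth"]], progress = FALSE)
  invisible(paths)
}
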