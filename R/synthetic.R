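# Synthetic expression-data generator: CommonMind-like gene x subject
# matrices with controlled SCZ/HC ratios, plus matched GWAS p-value tables,
# so the full expression-to-conductance pipeline is testable without any
# restricted-access download.

#' Generator configuration for synthetic expression data
#'
#' Cohort sizes default to the CommonMind regional cohorts (ACC: 230 SCZ /
#' 251 HC; PFC: 263 SCZ / 295 HC). Per-gene target SCZ/HC ratios default to
#' the published regional coefficients ([published_gene_table()]). Counts
#' are gamma-distributed (a continuous gamma-Poisson-like model, since
#' normalized counts are non-integer) with squared coefficient of variation
#' equal to the dispersion; dispersion 0 degenerates to exact group means.
#'
#' @param region `"ACC"` or `"PFC"`; sets default cohort sizes and ratios
#' @param n_scz,n_hc cohort sizes (>= 1)
#' @param genes `data.frame(gene, hc_mean, ratio, min_p)`; defaults to the
#'   seven mapped genes with the published ratios and p-values and an
#'   arbitrary baseline mean
#' @param dispersion gamma dispersion (variance = dispersion * mean^2)
#' @param n_decoys number of unmapped decoy genes (ratio 1, p above the
#'   GWAS threshold)
#' @param seed RNG seed used by [generate_expression()] /
#'   [generate_gwas_table()]
#' @return object of class `generator_config`
#' @export
generator_config <- function(region = c("ACC", "PFC"),
                             n_scz = NULL, n_hc = NULL, genes = NULL,
                             dispersion = 0.2, n_decoys = 5, seed = 1) {
  region <- match.arg(region)
  if (is.null(n_scz)) n_scz <- if (region == "ACC") 230L else 263L
  if (is.null(n_hc)) n_hc <- if (region == "ACC") 251L else 295L
  if (is.null(genes)) {
    t1 <- published_gene_table()
    genes <- data.frame(
      gene = t1$gene, hc_mean = 1000,
      ratio = if (region == "ACC") t1$acc_coefficient else t1$pfc_coefficient,
      min_p = t1$min_p, stringsAsFactors = FALSE)
  }
  stopifnot(n_scz >= 1, n_hc >= 1, all(genes$hc_mean > 0),
            all(genes$ratio > 0), dispersion >= 0)
  structure(list(region = region, n_scz = as.integer(n_scz),
                 n_hc = as.integer(n_hc), genes = genes,
                 dispersion = dispersion, n_decoys = as.integer(n_decoys),
                 seed = seed),
            class = "generator_config")
}

#' Generate a synthetic expression dataset
#'
#' HC subjects draw counts with mean `hc_mean`, SCZ subjects with mean
#' `ratio * hc_mean`, per gene, from a gamma model with the configured
#' dispersion. Decoy genes have ratio 1 and log-uniform baseline means.
#' Fully determined by `cfg$seed`.
#'
#' @param cfg a [generator_config()]
#' @return an [expression_dataset()]
#' @export
generate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  n <- cfg$n_scz + cfg$n_hc
  subj <- sprintf("%s_S%04d", cfg$region, seq_len(n))
  diagnosis <- c(rep("SCZ", cfg$n_scz), rep("HC", cfg$n_hc))
  genes <- cfg$genes
  if (cfg$n_decoys > 0) {
    genes <- rbind(genes, data.frame(
      gene = sprintf("DECOY%02d", seq_len(cfg$n_decoys)),
      hc_mean = 10^runif(cfg$n_decoys, 1, 4), ratio = 1,
      min_p = NA_real_, stringsAsFactors = FALSE))
  }
  draw <- function(mu, k) {
    if (cfg$dispersion == 0) rep(mu, k)
    else rgamma(k, shape = 1 / cfg$dispersion, scale = mu * cfg$dispersion)
  }
  counts <- t(vapply(seq_len(nrow(genes)), function(i) {
    mu <- genes$hc_mean[i]
    c(draw(genes$ratio[i] * mu, cfg$n_scz), draw(mu, cfg$n_hc))
  }, numeric(n)))
  rownames(counts) <- genes$gene
  colnames(counts) <- subj
  expression_dataset(
    counts,
    data.frame(subject_id = subj, diagnosis = diagnosis,
               region = cfg$region, stringsAsFactors = FALSE),
    provenance = sprintf("synthetic (gamma model, dispersion %g, seed %d)",
                         cfg$dispersion, cfg$seed))
}

#' Generate a matching GWAS minimal-p-value table
#'
#' Mapped genes receive their configured (published) p-values, all below
#' the 5e-6 filter threshold; decoys receive uniform p-values well above
#' it.
#'
#' @param genes gene symbols to include (default: all genes of `cfg`,
#'   mapped plus decoys)
#' @param cfg a [generator_config()]
#' @return `data.frame(gene, min_p)`
#' @export
generate_gwas_table <- function(genes = NULL, cfg = generator_config()) {
  set.seed(cfg$seed + 1)
  mapped <- cfg$genes
  if (is.null(genes))
    genes <- c(mapped$gene, if (cfg$n_decoys > 0)
      sprintf("DECOY%02d", seq_len(cfg$n_decoys)))
  p <- vapply(genes, function(g) {
    i <- match(g, mapped$gene)
    if (!is.na(i) && !is.na(mapped$min_p[i])) mapped$min_p[i]
    else runif(1, 0.01, 1)
  }, 0)
  data.frame(gene = genes, min_p = unname(p), stringsAsFactors = FALSE)
}

#' Write a synthetic dataset to the TSV formats the readers consume
#'
#' @param ds an [expression_dataset()]
#' @param gwas a GWAS table from [generate_gwas_table()]
#' @param dir output directory
#' @return invisibly, the three file paths written
#' @export
write_synthetic_dataset <- function(ds, gwas, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mp <- file.path(dir, "expression_matrix.tsv")
  dp <- file.path(dir, "subject_metadata.tsv")
  gp <- file.path(dir, "gwas_min_p.tsv")
  m <- data.frame(gene = rownames(ds$counts), ds$counts, check.names = FALSE)
  write.table(m, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ds$metadata, dp, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(gwas, gp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrix = mp, metadata = dp, gwas = gp))
}
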