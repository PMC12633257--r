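# Mapping bulk gene-expression data onto ion-channel conductance
# coefficients: GWAS-based gene filtering, SCZ/HC group expression ratios,
# and population-averaged or subject-wise coefficient sets.

#' Gene-to-channel map
#'
#' The closed-world map from risk genes to the model conductances they
#' scale: CACNA1C and CACNA1D both target the high-voltage-activated Ca2+
#' channel (`CaHVA`), CACNA1I the low-voltage-activated channel (`CaLVA`),
#' HCN1 the hyperpolarization-activated current (`Ih`), KCNB1 the
#' persistent K+ channel (`KPst`), KCNQ3 the M-type K+ channel (`Im`), and
#' GABBR2 the GABA_B-receptor-mediated synaptic conductance (`GABA_B`).
#' Glutamatergic and GABA_A receptor genes are deliberately excluded
#' (their expression is likely confounded by antipsychotic use).
#'
#' @return `data.frame(gene, channel)`
#' @export
gene_channel_map <- function() {
  data.frame(
    gene = c("CACNA1C", "CACNA1D", "CACNA1I", "HCN1", "KCNB1", "KCNQ3",
             "GABBR2"),
    channel = c("CaHVA", "CaHVA", "CaLVA", "Ih", "KPst", "Im", "GABA_B"),
    stringsAsFactors = FALSE)
}

#' Published per-gene expression coefficients and GWAS p-values
#'
#' The reference table of SCZ/HC expression ratios per region and minimal
#' single-SNP GWAS p-values for the seven mapped genes, as reported for the
#' CommonMind ACC/PFC cohorts. Used as generator targets for synthetic data
#' and as published reference values.
#'
#' @return `data.frame(gene, channel, acc_coefficient, pfc_coefficient,
#'   min_p)`
#' @export
published_gene_table <- function() {
  m <- gene_channel_map()
  data.frame(
    gene = m$gene, channel = m$channel,
    acc_coefficient = c(1.171, 1.158, 1.173, 1.034, 1.123, 1.056, 1.084),
    pfc_coefficient = c(1.139, 1.135, 1.144, 1.117, 1.150, 1.034, 1.095),
    min_p = c(1.279e-21, 3.277e-9, 1.171e-13, 2.873e-14, 2.197e-10,
              2.128e-6, 9.334e-9),
    stringsAsFactors = FALSE)
}

#' Expression dataset container
#'
#' @param counts numeric matrix of normalized expression values, genes as
#'   rows (rownames = gene symbols), subjects as columns (colnames =
#'   subject ids); values must be non-negative
#' @param metadata `data.frame(subject_id, diagnosis, region)` with
#'   `diagnosis` in SCZ/HC and `region` in ACC/PFC
#' @param provenance free-text provenance note
#' @return object of class `expression_dataset`
#' @export
expression_dataset <- function(counts, metadata, provenance = "") {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0), !is.null(rownames(counts)),
            !anyDuplicated(rownames(counts)),
            all(colnames(counts) %in% metadata$subject_id),
            all(metadata$diagnosis %in% c("SCZ", "HC")),
            all(metadata$region %in% c("ACC", "PFC")))
  metadata <- metadata[match(colnames(counts), metadata$subject_id), ]
  structure(list(counts = counts, metadata = metadata,
                 provenance = provenance),
            class = "expression_dataset")
}

#' Read an expression dataset from TSV/CSV files
#'
#' @param matrix_path expression matrix, genes as rows (first column = gene
#'   symbol), subjects as columns; tab- or comma-separated
#' @param metadata_path subject metadata with columns `subject_id`,
#'   `diagnosis`, `region`
#' @return an [expression_dataset()]
#' @export
read_expression_dataset <- function(matrix_path, metadata_path) {
  sep1 <- if (grepl("\\.csv$", matrix_path)) "," else "\t"
  sep2 <- if (grepl("\\.csv$", metadata_path)) "," else "\t"
  m <- read.table(matrix_path, header = TRUE, sep = sep1, row.names = 1,
                  check.names = FALSE)
  md <- read.table(metadata_path, header = TRUE, sep = sep2,
                   stringsAsFactors = FALSE)
  expression_dataset(as.matrix(m), md,
                     provenance = paste("read from", matrix_path))
}

#' GWAS filter for mapped genes
#'
#' Retains genes whose minimal single-SNP p-value is below the threshold
#' and that are present in the gene-to-channel map.
#'
#' @param genes candidate gene symbols
#' @param pvalue_table `data.frame(gene, min_p)`
#' @param threshold p-value threshold (default 5e-6)
#' @param map gene-to-channel map (default [gene_channel_map()])
#' @return character vector of retained genes
#' @export
gwas_filter <- function(genes, pvalue_table, threshold = 5e-6,
                        map = gene_channel_map()) {
  stopifnot(all(pvalue_table$min_p > 0), all(pvalue_table$min_p <= 1))
  p <- pvalue_table$min_p[match(genes, pvalue_table$gene)]
  genes[!is.na(p) & p < threshold & genes %in% map$gene]
}

#' SCZ/HC group mean-expression ratio
#'
#' Ratio of group means (not mean of ratios): `mean(SCZ)/mean(HC)` for one
#' gene within one region.
#'
#' @param ds an [expression_dataset()]
#' @param gene gene symbol
#' @param region `"ACC"` or `"PFC"`
#' @return scalar ratio
#' @export
group_ratio <- function(ds, gene, region) {
  if (!gene %in% rownames(ds$counts)) stop("gene not in dataset: ", gene)
  md <- ds$metadata
  scz <- md$subject_id[md$diagnosis == "SCZ" & md$region == region]
  hc <- md$subject_id[md$diagnosis == "HC" & md$region == region]
  if (length(scz) == 0 || length(hc) == 0)
    stop("both diagnosis groups must be non-empty in region ", region)
  m_hc <- mean(ds$counts[gene, hc])
  if (m_hc == 0) stop("undefined ratio: HC mean expression is zero for ", gene)
  mean(ds$counts[gene, scz]) / m_hc
}

#' Conductance coefficient set
#'
#' @param coefficients named numeric vector, one multiplicative coefficient
#'   per channel key (all > 0)
#' @param scope `"population"` or a subject id
#' @param region region tag
#' @return object of class `coefficient_set`
#' @export
coefficient_set <- function(coefficients, scope = "population",
                            region = NA_character_) {
  stopifnot(all(coefficients > 0), !is.null(names(coefficients)))
  structure(list(coefficients = coefficients, scope = scope,
                 region = region), class = "coefficient_set")
}

#' Population-averaged conductance coefficients from gene ratios
#'
#' One coefficient per channel; the HVA Ca2+ coefficient is the mean of the
#' CACNA1C and CACNA1D ratios, every other gene passes through.
#'
#' @param ratios named numeric vector of per-gene SCZ/HC expression ratios
#'   (all mapped genes present)
#' @param map gene-to-channel map
#' @param region region tag recorded on the result
#' @return a [coefficient_set()]
#' @export
build_population_coefficients <- function(ratios, map = gene_channel_map(),
                                          region = NA_character_) {
  missing <- setdiff(map$gene, names(ratios))
  if (length(missing))
    stop("missing ratios for mapped gene(s): ", paste(missing, collapse = ", "))
  channels <- unique(map$channel)
  co <- vapply(channels, function(ch)
    mean(ratios[map$gene[map$channel == ch]]), 0)
  coefficient_set(setNames(co, channels), scope = "population",
                  region = region)
}

#' Subject-wise conductance coefficients
#'
#' Per gene, the subject's expression divided by the healthy-control mean
#' of the subject's region (computed for HC subjects too), then the HVA
#' averaging rule.
#'
#' @param ds an [expression_dataset()]
#' @param subject subject id present in the dataset
#' @param map gene-to-channel map
#' @return a [coefficient_set()] with `scope = subject`
#' @export
build_subject_coefficients <- function(ds, subject, map = gene_channel_map()) {
  md <- ds$metadata
  if (!subject %in% md$subject_id) stop("unknown subject: ", subject)
  region <- md$region[md$subject_id == subject][1]
  hc <- md$subject_id[md$diagnosis == "HC" & md$region == region]
  ratios <- vapply(map$gene, function(g) {
    if (!g %in% rownames(ds$counts))
      stop("missing gene ", g, " for subject ", subject)
    val <- ds$counts[g, subject]
    if (is.na(val)) stop("missing value for gene ", g, " subject ", subject)
    val / mean(ds$counts[g, hc])
  }, 0)
  cs <- build_population_coefficients(ratios, map, region = region)
  cs$scope <- subject
  cs
}
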