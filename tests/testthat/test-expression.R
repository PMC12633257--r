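# Expression-to-coefficient pipeline: GWAS filtering, group ratios, and
# the HVA averaging rule, checked against explicit-loop oracles on tiny
# matrices.

toy_dataset <- function() {
  genes <- c(gene_channel_map()$gene, "DECOYA")
  counts <- matrix(0, nrow = length(genes), ncol = 6,
                   dimnames = list(genes, paste0("S", 1:6)))
  set.seed(11)
  counts[] <- rgamma(length(counts), shape = 5, scale = 200)
  md <- data.frame(subject_id = paste0("S", 1:6),
                   diagnosis = rep(c("SCZ", "HC"), each = 3),
                   region = "ACC", stringsAsFactors = FALSE)
  expression_dataset(counts, md)
}

test_that("the GWAS filter keeps mapped genes below threshold", {
  tab <- data.frame(gene = c(gene_channel_map()$gene, "FOO", "BAR", "BAZ"),
                    min_p = c(published_gene_table()$min_p, 0.2, 1e-7, 0.9))
  genes <- tab$gene
  # brute-force reference filter
  keep <- character(0)
  for (g in genes) {
    p <- tab$min_p[tab$gene == g]
    if (p < 5e-6 && g %in% gene_channel_map()$gene) keep <- c(keep, g)
  }
  expect_equal(gwas_filter(genes, tab), keep)
  expect_length(gwas_filter(genes, tab), 7)   # all seven mapped genes pass
  # BAR is below threshold but unmapped -> excluded
  expect_false("BAR" %in% gwas_filter(genes, tab))
  # an extreme threshold excludes everything
  expect_length(gwas_filter(genes, tab, threshold = 1e-30), 0)
  expect_error(gwas_filter(genes, data.frame(gene = "A", min_p = 0)),
               "min_p")
})

test_that("group ratios are ratios of group means, matching an explicit loop", {
  ds <- toy_dataset()
  for (g in c("CACNA1C", "HCN1", "DECOYA")) {
    s <- 0; n <- 0
    for (subj in paste0("S", 1:3)) { s <- s + ds$counts[g, subj]; n <- n + 1 }
    m_scz <- s / n
    s <- 0; n <- 0
    for (subj in paste0("S", 4:6)) { s <- s + ds$counts[g, subj]; n <- n + 1 }
    expect_equal(group_ratio(ds, g, "ACC"), m_scz / (s / n))
  }
  # identical group means -> ratio 1
  ds2 <- ds
  ds2$counts["HCN1", ] <- rep(c(7, 8, 9), 2)
  expect_equal(group_ratio(ds2, "HCN1", "ACC"), 1)
  ds2$counts["HCN1", 4:6] <- 0
  expect_error(group_ratio(ds2, "HCN1", "ACC"), "undefined ratio")
  expect_error(group_ratio(ds, "CACNA1C", "PFC"), "non-empty")
})

test_that("population coefficients apply the HVA averaging rule", {
  t1 <- published_gene_table()
  acc <- setNames(t1$acc_coefficient, t1$gene)
  cs <- build_population_coefficients(acc, region = "ACC")
  expect_equal(unname(cs$coefficients["CaHVA"]),
               mean(c(1.171, 1.158)))            # = 1.1645, prints as 1.164
  expect_equal(round(unname(cs$coefficients["CaHVA"]), 3), 1.164,
               tolerance = 5e-4)
  pfc <- setNames(t1$pfc_coefficient, t1$gene)
  expect_equal(round(mean(c(1.139, 1.135)), 3), 1.137)
  expect_equal(unname(build_population_coefficients(pfc)$coefficients["CaHVA"]),
               1.137)
  # every non-HVA gene passes through
  expect_equal(unname(cs$coefficients["CaLVA"]), 1.173)
  expect_equal(unname(cs$coefficients["GABA_B"]), 1.084)
  # identity ratios give an identity set; gene order is irrelevant
  ones <- setNames(rep(1, 7), t1$gene)
  expect_true(all(build_population_coefficients(ones)$coefficients == 1))
  shuf <- acc[sample(names(acc))]
  expect_equal(build_population_coefficients(shuf)$coefficients,
               cs$coefficients)
  expect_error(build_population_coefficients(acc[-1]), "missing ratios")
})

test_that("subject coefficients normalize to the regional HC mean", {
  ds <- toy_dataset()
  hc_mean <- rowMeans(ds$counts[, 4:6])
  cs <- build_subject_coefficients(ds, "S2")
  map <- gene_channel_map()
  for (ch in unique(map$channel)) {
    genes <- map$gene[map$channel == ch]
    expect_equal(unname(cs$coefficients[ch]),
                 mean(ds$counts[genes, "S2"] / hc_mean[genes]))
  }
  expect_equal(cs$scope, "S2")
  # a subject at exactly the HC mean gets the identity set
  counts <- ds$counts
  counts[, "S1"] <- rowMeans(counts[, 4:6])
  ds4 <- expression_dataset(counts, ds$metadata)
  cs4 <- build_subject_coefficients(ds4, "S1")
  expect_true(all(abs(cs4$coefficients - 1) < 1e-12))
  expect_error(build_subject_coefficients(ds, "NOPE"), "unknown subject")
})

test_that("the mean of subject-wise coefficients equals the population average", {
  # shared HC-mean denominators make this an algebraic identity
  cfg <- generator_config(region = "ACC", n_scz = 25, n_hc = 30,
                          dispersion = 0.3, n_decoys = 0, seed = 5)
  ds <- generate_expression(cfg)
  md <- ds$metadata
  scz <- md$subject_id[md$diagnosis == "SCZ"]
  per <- vapply(scz, function(s)
    build_subject_coefficients(ds, s)$coefficients, numeric(6))
  ratios <- vapply(rownames(ds$counts), function(g)
    group_ratio(ds, g, "ACC"), 0)
  popc <- build_population_coefficients(ratios)
  expect_equal(rowMeans(per), popc$coefficients, tolerance = 1e-12)
})

test_that("coefficients are invariant to a global rescaling of counts", {
  ds <- toy_dataset()
  ds2 <- expression_dataset(ds$counts * 37.5, ds$metadata)
  r1 <- vapply(gene_channel_map()$gene, function(g) group_ratio(ds, g, "ACC"), 0)
  r2 <- vapply(gene_channel_map()$gene, function(g) group_ratio(ds2, g, "ACC"), 0)
  expect_equal(r1, r2)
  expect_equal(build_subject_coefficients(ds, "S3")$coefficients,
               build_subject_coefficients(ds2, "S3")$coefficients)
})

test_that("datasets round-trip through the TSV reader", {
  cfg <- generator_config(n_scz = 4, n_hc = 5, n_decoys = 2, seed = 3)
  ds <- generate_expression(cfg)
  gwas <- generate_gwas_table(cfg = cfg)
  dir <- tempfile()
  paths <- write_synthetic_dataset(ds, gwas, dir)
  back <- read_expression_dataset(paths["matrix"], paths["metadata"])
  expect_equal(back$counts, ds$counts, tolerance = 1e-12)
  expect_equal(back$metadata$diagnosis, ds$metadata$diagnosis)
  gb <- read.table(paths["gwas"], header = TRUE, sep = "\t")
  expect_equal(gwas_filter(gb$gene, gb), gene_channel_map()$gene)
})
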