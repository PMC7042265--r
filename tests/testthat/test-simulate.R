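test_that("genotype generator matches Hardy-Weinberg expectation and is deterministic", {
  g <- sim_genotypes(10000, 3, maf_low = 0.5, maf_high = 0.5, seed = 11)
  # at MAF 0.5 the expected heterozygote fraction is 2pq = 0.5
  for (j in 1:3) {
    het <- mean(g$dosage[, j] == 1)
    expect_lt(abs(het - 0.5), 3 * sqrt(0.5 * 0.5 / 10000))
  }
  g2 <- sim_genotypes(10000, 3, maf_low = 0.5, maf_high = 0.5, seed = 11)
  expect_identical(g$dosage, g2$dosage)

  expect_error(sim_genotypes(1, 5), "at least 2")
  expect_error(sim_genotypes(10, 5, maf_low = 0.6), "maf_low")
  expect_error(sim_genotypes(10, 5, maf_low = 0.3, maf_high = 0.2), "maf_low")
})

test_that("expression generator plants exact effects and truth bookkeeping", {
  g <- sim_genotypes(30, 4, seed = 2)
  feats <- data.frame(
    feature_id = c("gA_e1", "gA_e2", "gB_e1", "gB_e2"),
    gene_id = c("gA", "gA", "gB", "gB"), stringsAsFactors = FALSE)
  eff <- data.frame(
    feature_id = c("gA_e1", "gA_e2", "gB_e1"),
    snp_id = c("snp0001", "snp0001", "snp0002"),
    beta = c(1, 1, 1), stringsAsFactors = FALSE)
  out <- sim_expression(g, feats, eff, noise_sd = 0, seed = 5)
  expect_equal(unname(out$expr["gA_e1", ]), unname(g$dosage[, "snp0001"]))
  # shared gene: equal betas on both exons; distinct gene: 1 vs 0
  sharing <- out$truth$gene_sharing
  expect_true(sharing$shared[sharing$gene_id == "gA"])
  expect_false(sharing$shared[sharing$gene_id == "gB"])

  expect_error(sim_expression(g, feats, eff, noise_sd = -1), "non-negative")
  eff$snp_id[1] <- "nope"
  expect_error(sim_expression(g, feats, eff), "absent from genotypes")
})

test_that("null expression gives uniform association p-values", {
  g <- sim_genotypes(80, 1, maf_low = 0.3, maf_high = 0.3, seed = 7)
  feats <- data.frame(feature_id = paste0("f", 1:300), gene_id = NA)
  out <- sim_expression(g, feats, data.frame(feature_id = character(),
                                             snp_id = character(),
                                             beta = numeric()),
                        noise_sd = 1, seed = 8)
  p <- apply(out$expr, 1, function(y) {
    fit_eqtl(g$dosage[, 1], y)$p_value
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("allele count generator matches its stated marginals per class", {
  # null: mean allelic ratio near 0.5
  s_null <- sim_allele_counts(2000, data.frame(snp_id = "s", class = "null",
                                               p_alt = 0.5), seed = 21)
  ratio <- with(s_null$counts, c1 / (c1 + c2))
  expect_lt(abs(mean(ratio) - 0.5), 3 * sd(ratio) / sqrt(length(ratio)))

  # nmd at p_alt = 0.98, fixed depth-ish: essentially all draws mono-allelic
  s_nmd <- sim_allele_counts(500, data.frame(snp_id = "s", class = "nmd",
                                             p_alt = 0.98), seed = 22,
                             depth_meanlog = log(100), depth_sdlog = 0)
  mono <- flag_monoallelic(s_nmd$counts$c1, s_nmd$counts$c2)
  # exact binomial tail: P(>95% of 100 reads on one allele) at p = 0.98
  p_mono <- pbinom(95, 100, 0.98, lower.tail = FALSE) + pbinom(4, 100, 0.98)
  expect_gt(mean(mono), p_mono - 3 * sqrt(p_mono * (1 - p_mono) / 500))

  # imprinted: both directions appear across 20 individuals
  s_imp <- sim_allele_counts(20, data.frame(snp_id = "s", class = "imprinted",
                                            p_alt = 0.9), seed = 23,
                             depth_meanlog = log(100), depth_sdlog = 0)
  dir <- with(s_imp$counts, sign(c1 - c2))
  expect_true(any(dir > 0) && any(dir < 0))

  expect_error(sim_allele_counts(10, data.frame(snp_id = character(),
                                                class = character(),
                                                p_alt = numeric())), "empty")
  expect_error(sim_allele_counts(10, data.frame(snp_id = "s", class = "cis",
                                                p_alt = 1.2)), "strictly in")
  expect_error(sim_allele_counts(10, data.frame(snp_id = "s", class = "nmd",
                                                p_alt = 0.6)), "nmd")
})

test_that("split-read generator produces junctions in exactly the requested samples", {
  genes <- sim_gene_models(2)
  regions <- data.frame(chrom = "chrS", start = genes$end[4] + 2000L,
                        end = genes$end[4] + 2400L, id = "ER1",
                        stringsAsFactors = FALSE)
  links4 <- data.frame(er_id = "ER1", gene_id = "gene001", n_samples = 4L)
  reads <- sim_split_reads(regions, genes, links4, seed = 1)
  expect_equal(length(unique(reads$sample_id)), 4L)
  link <- link_by_split_reads(regions[1, ], reads, genes)
  expect_equal(link$gene_id, "gene001")
  expect_equal(link$n_junction_samples, 4L)

  links3 <- data.frame(er_id = "ER1", gene_id = "gene001", n_samples = 3L)
  reads3 <- sim_split_reads(regions, genes, links3, seed = 1)
  link3 <- link_by_split_reads(regions[1, ], reads3, genes)
  expect_true(is.na(link3$gene_id))
  expect_equal(link3$n_junction_samples, 3L)

  expect_equal(nrow(sim_split_reads(regions, genes, NULL)), 0L)
  genes_other <- genes
  genes_other$chrom <- "chrX"
  expect_error(sim_split_reads(regions, genes_other, links4),
               "different chromosomes")
})

test_that("GWAS generator: planted shift moves -log10 p by its size, none under null", {
  ids <- paste0("rs", 1:4000)
  enr <- ids[1:1000]
  out <- sim_gwas(ids, enriched = enr, shift = 2, seed = 31)
  nl <- -log10(out$gwas$p_value)
  diff <- mean(nl[ids %in% enr]) - mean(nl[!ids %in% enr])
  se <- sqrt(1 / log(10)^2 * (1 / 1000 + 1 / 3000))
  expect_lt(abs(diff - 2), 3 * se)

  out0 <- sim_gwas(ids, enriched = enr, shift = 0, seed = 32)
  nl0 <- -log10(out0$gwas$p_value)
  expect_gt(ks.test(nl0[ids %in% enr], nl0[!ids %in% enr])$p.value, 0.01)
  # background p-values are uniform
  expect_gt(ks.test(out0$gwas$p_value, "punif")$p.value, 0.01)

  expect_error(sim_gwas(ids, enriched = "absent"), "not in snp_ids")
  expect_error(sim_gwas(ids, shift = -1), "non-negative")
})

test_that("every generator is deterministic under a fixed seed", {
  a <- sim_allele_counts(15, data.frame(snp_id = "s", class = "cis",
                                        p_alt = 0.7), seed = 5)
  b <- sim_allele_counts(15, data.frame(snp_id = "s", class = "cis",
                                        p_alt = 0.7), seed = 5)
  expect_identical(a, b)
  g1 <- sim_gwas(paste0("r", 1:50), seed = 5)
  g2 <- sim_gwas(paste0("r", 1:50), seed = 5)
  expect_identical(g1, g2)
})
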