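mk_er <- function(start, end, id = "ER") {
  data.frame(chrom = "chrS", start = start, end = end, id = id,
             stringsAsFactors = FALSE)
}

mk_reads <- function(n_samples, er, exon, per_sample = 1L) {
  blocks <- data.frame(
    left_start = er$start, left_end = er$start + 20L,
    right_start = exon$start, right_end = exon$start + 20L)
  if (blocks$left_start > blocks$right_start) {
    blocks <- data.frame(left_start = blocks$right_start,
                         left_end = blocks$right_end,
                         right_start = blocks$left_start,
                         right_end = blocks$left_end)
  }
  do.call(rbind, lapply(seq_len(n_samples), function(s) {
    data.frame(sample_id = rep(paste0("S", s), per_sample), chrom = "chrS",
               blocks, stringsAsFactors = FALSE)
  }))
}

test_that("split-read linking counts distinct samples, not junctions", {
  genes <- sim_gene_models(1)
  er <- mk_er(genes$end[4] + 3000L, genes$end[4] + 3400L)

  link4 <- link_by_split_reads(er, mk_reads(4, er, genes[1, ]), genes)
  expect_equal(link4$gene_id, "gene001")
  expect_equal(link4$n_junction_samples, 4L)

  link3 <- link_by_split_reads(er, mk_reads(3, er, genes[1, ]), genes)
  expect_true(is.na(link3$gene_id))

  # ten junctions in one sample still count as one sample
  link1 <- link_by_split_reads(er, mk_reads(1, er, genes[1, ], per_sample = 10L),
                               genes)
  expect_equal(link1$n_junction_samples, 1L)
  expect_true(is.na(link1$gene_id))
})

test_that("nearest gene distance and tie-breaks follow the span geometry", {
  genes <- data.frame(gene_id = c("gA", "gB"), exon_id = c("gA_e1", "gB_e1"),
                      chrom = "chrS", start = c(1000L, 9000L),
                      end = c(2000L, 10000L), stringsAsFactors = FALSE)
  # 1 kb downstream of gA's end
  expect_equal(nearest_gene(mk_er(3000L, 3200L), genes),
               list(gene_id = "gA", distance_bp = 1000L))
  # overlapping an exon
  expect_equal(nearest_gene(mk_er(1500L, 1600L), genes)$distance_bp, 0L)
  # exactly equidistant between gA end (2000) and gB start (9000)
  tie <- nearest_gene(mk_er(5300L, 5700L), genes)
  expect_equal(tie$gene_id, "gA")   # lower start coordinate wins
  # no gene on the chromosome
  er_off <- mk_er(100L, 200L)
  er_off$chrom <- "chrZ"
  expect_null(nearest_gene(er_off, genes))
})

test_that("max exon r-squared: perfect correlation either sign, null, degenerate input", {
  set.seed(5)
  x <- rnorm(50)
  expect_equal(max_exon_r2(x, rbind(x)), 1)
  expect_equal(max_exon_r2(x, rbind(-x)), 1)  # anti-correlation has r2 = 1
  expect_error(max_exon_r2(rep(1, 50), rbind(x)), "constant ER")
  expect_error(max_exon_r2(x, rbind(rep(2, 50))), "constant")
  expect_error(max_exon_r2(x[1:2], rbind(x[1:2])), "3 shared samples")

  # independent vectors, n = 1000, 1 exon: r2 < 0.05 nearly always
  set.seed(6)
  hits <- sum(replicate(100, max_exon_r2(rnorm(1000), rbind(rnorm(1000))) < 0.05))
  expect_gte(hits, 95)
})

test_that("tier classification applies strong > moderate > weak precedence", {
  genes <- sim_gene_models(1)
  near <- mk_er(genes$end[4] + 3000L, genes$end[4] + 3400L, "ERnear")
  set.seed(9)
  exon_expr <- matrix(rnorm(4 * 60), 4, 60, dimnames = list(genes$exon_id, NULL))
  corr_expr <- exon_expr[1, ] + rnorm(60, sd = 0.5)   # r2 well above 0.2
  noise_expr <- rnorm(60)

  # junction evidence wins regardless of r2
  strong <- classify_er(near, mk_reads(4, near, genes[1, ]), genes,
                        noise_expr, exon_expr)
  expect_equal(strong$tier, "strong")
  expect_equal(strong$linked_gene, "gene001")

  # co-expression + proximity, junctions in too few samples
  moderate <- classify_er(near, mk_reads(2, near, genes[1, ]), genes,
                          corr_expr, exon_expr)
  expect_equal(moderate$tier, "moderate")
  expect_equal(moderate$n_junction_samples, 2L)

  # high r2 but too far away
  no_reads <- mk_reads(1, near, genes[1, ])[0, ]
  far <- mk_er(genes$end[4] + 6000L, genes$end[4] + 6400L, "ERfar")
  weak <- classify_er(far, no_reads, genes, corr_expr, exon_expr)
  expect_equal(weak$tier, "weak")
})

test_that("tier boundaries are strict and match the rule oracle; no gene means unclassified", {
  genes <- sim_gene_models(1)
  set.seed(10)
  exon_expr <- matrix(rnorm(4 * 40), 4, 40, dimnames = list(genes$exon_id, NULL))
  empty_reads <- data.frame(sample_id = character(), chrom = character(),
                            left_start = integer(), left_end = integer(),
                            right_start = integer(), right_end = integer())
  # distance exactly 5000 is not < 5000: weak even with r2 = 1
  at5k <- mk_er(genes$end[4] + 5000L, genes$end[4] + 5400L)
  res <- classify_er(at5k, empty_reads, genes, exon_expr[1, ], exon_expr)
  expect_equal(res$distance_bp, 5000L)
  expect_equal(res$tier, "weak")
  # 4999 with r2 = 1 is moderate
  res2 <- classify_er(mk_er(genes$end[4] + 4999L, genes$end[4] + 5400L),
                      empty_reads, genes, exon_expr[1, ], exon_expr)
  expect_equal(res2$tier, "moderate")

  off <- mk_er(100L, 300L)
  off$chrom <- "chrZ"
  expect_equal(classify_er(off, empty_reads, genes)$tier, "unclassified")
  # no expression provided: r2 unavailable
  expect_equal(classify_er(at5k, empty_reads, genes)$tier, "unclassified")

  short <- mk_er(100L, 180L)
  expect_warning(classify_ers(short, empty_reads, genes), "100 bp")
})

test_that("re-expression validation applies the 80% rule at its boundary", {
  expect_true(validate_expression(c(rep(0.2, 8), 0, 0)))
  expect_false(validate_expression(c(rep(0.2, 7), 0, 0, 0)))
  expect_false(validate_expression(rep(0, 10)))
  expect_true(validate_expression(rep(0.2, 1)))
  expect_error(validate_expression(numeric()), "at least one")
})

test_that("enhancer overlap statistics: arithmetic, fold identities and invariances", {
  targets <- data.frame(chrom = "chr1", start = c(0L, 20000L),
                        end = c(5000L, 25000L))       # 10 kb total
  enh <- data.frame(chrom = "chr1", start = 3000L, end = 21000L)  # 2+1 kb inside
  ref <- data.frame(chrom = "chr1", start = 50000L, end = 60000L) # 10 kb, no hit
  expect_warning(st <- enhancer_overlap_stats(targets, ref, enh),
                 "fold undefined")
  expect_equal(st$pct_overlap_targets, 30)  # 3 kb of 10 kb
  expect_equal(st$pct_overlap_reference, 0)

  # identical sets give fold 1
  st_id <- enhancer_overlap_stats(targets, targets, enh)
  expect_equal(st_id$fold, 1)

  # splitting an interval into adjacent pieces or reordering changes nothing
  split_targets <- data.frame(chrom = "chr1",
                              start = c(20000L, 2500L, 0L),
                              end = c(25000L, 5000L, 2500L))
  st_split <- enhancer_overlap_stats(split_targets, targets, enh)
  expect_equal(st_split$pct_overlap_targets, 30)
  expect_equal(st_split$fold, 1)
})
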