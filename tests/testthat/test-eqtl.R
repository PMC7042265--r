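test_that("exact HWE test behaves across balanced and extreme genotype tables", {
  # strong deviation: all heterozygotes among 100 with both alleles at 0.5
  expect_lt(hwe_exact_test(100, 0, 0), 1e-4)
  # perfect HWE proportions are not rejected
  expect_gt(hwe_exact_test(50, 25, 25), 0.2)
  # matches a direct conditional enumeration on a small table
  n_het <- 2; n_aa <- 4; n_bb <- 4
  n <- n_het + n_aa + n_bb
  n_rare <- 2 * min(n_aa, n_bb) + n_het
  hs <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), 2)
  probs <- sapply(hs, function(h) {
    naa <- (n_rare - h) / 2; nbb <- n - naa - h
    exp(lfactorial(n) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb) +
          lfactorial(n_rare) + lfactorial(2 * n - n_rare) -
          lfactorial(2 * n) + h * log(2))
  })
  expect_equal(hwe_exact_test(n_het, n_aa, n_bb),
               sum(probs[probs <= probs[hs == n_het] * (1 + 1e-7)]))
})

test_that("genotype QC removes monomorphic, low-MAF, HWE-deviant and het-poor SNPs", {
  n <- 100
  dos <- cbind(
    mono = rep(0, n),
    low_maf = c(rep(1, 8), rep(0, n - 8)),            # MAF 0.04
    one_het = c(1, rep(2, 59), rep(0, n - 60)),       # 1 heterozygote
    hwe_bad = rep(c(0, 2), n / 2),                    # no hets at MAF 0.5
    good = rep(c(0, 1, 1, 2), n / 4)
  )
  g <- aseqtl:::new_genotype_matrix(dos, data.frame(
    snp_id = colnames(dos), chrom = "chrS", pos = 1:5 * 1000L))
  out <- genotype_qc(g)
  expect_equal(out$snps$snp_id, "good")
  expect_error(genotype_qc(g, maf_min = 0.9), "no SNPs pass")
  # fractional dosages: HWE and het filters skipped with a warning
  dos2 <- dos
  dos2[1, "good"] <- 0.5
  g2 <- aseqtl:::new_genotype_matrix(dos2, g$snps)
  expect_warning(out2 <- genotype_qc(g2), "skipped")
  expect_true("hwe_bad" %in% out2$snps$snp_id)
})

test_that("expression filter keeps features above RPKM in enough samples", {
  m <- rbind(keep = c(rep(0.2, 8), 0, 0),      # 80% of samples
             drop = c(rep(0.2, 7), 0, 0, 0),   # 70%
             zero = rep(0, 10))
  out <- filter_features(m)
  expect_equal(rownames(out), "keep")
})

test_that("cis pairing is window-inclusive and matches a brute-force scan", {
  feat <- data.frame(id = "f1", chrom = "chrS", start = 2e6, end = 2.001e6)
  snps <- data.frame(snp_id = c("in_edge", "out_edge", "inside"),
                     chrom = "chrS",
                     pos = c(1e6, 1e6 - 1, 2.0005e6))
  pr <- cis_pairs(snps, feat)
  expect_setequal(pr$snp_id, c("in_edge", "inside"))
  expect_equal(pr$distance_bp[pr$snp_id == "in_edge"], 1e6)
  expect_equal(pr$distance_bp[pr$snp_id == "inside"], 0)

  # oracle equivalence on a random layout
  set.seed(20)
  snps2 <- data.frame(snp_id = paste0("s", 1:500),
                      chrom = sample(c("c1", "c2"), 500, TRUE),
                      pos = sample.int(5e6, 500))
  feats2 <- data.frame(id = paste0("f", 1:50),
                       chrom = sample(c("c1", "c2"), 50, TRUE),
                       start = sample.int(5e6, 50))
  feats2$end <- feats2$start + sample.int(5e4, 50)
  got <- cis_pairs(snps2, feats2, window_bp = 5e5)
  want <- do.call(rbind, lapply(1:50, function(i) {
    d <- pmax(0, feats2$start[i] - snps2$pos,
              snps2$pos - (feats2$end[i] - 1))
    hit <- snps2$chrom == feats2$chrom[i] & d <= 5e5
    if (!any(hit)) return(NULL)
    data.frame(snp_id = snps2$snp_id[hit], feature_id = feats2$id[i],
               distance_bp = d[hit])
  }))
  rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("eQTL fit agrees with the closed-form simple regression to 1e-10", {
  set.seed(30)
  x <- rbinom(80, 2, 0.3)
  y <- 0.7 * x + rnorm(80)
  fit <- fit_eqtl(x, y)
  # closed form
  b <- cov(x, y) / var(x)
  a <- mean(y) - b * mean(x)
  rss <- sum((y - a - b * x)^2)
  se <- sqrt(rss / 78 / (var(x) * 79))
  tt <- b / se
  expect_equal(fit$beta, b, tolerance = 1e-10)
  expect_equal(fit$se, se, tolerance = 1e-10)
  expect_equal(fit$p_value, 2 * pt(abs(tt), 78, lower.tail = FALSE),
               tolerance = 1e-10)

  # and with covariates, against lm()
  cov1 <- rnorm(80); cov2 <- rnorm(80)
  fit2 <- fit_eqtl(x, y, cbind(cov1, cov2))
  lmfit <- summary(lm(y ~ x + cov1 + cov2))$coefficients
  expect_equal(fit2$beta, lmfit["x", 1], tolerance = 1e-10)
  expect_equal(fit2$se, lmfit["x", 2], tolerance = 1e-10)
  expect_equal(fit2$p_value, lmfit["x", 4], tolerance = 1e-10)
})

test_that("eQTL fit handles degenerate designs and missing data explicitly", {
  set.seed(31)
  y <- rnorm(30)
  expect_error(fit_eqtl(rep(1, 30), y), "constant dosage")
  x <- rbinom(30, 2, 0.4)
  dup <- cbind(c1 = x)   # same as dosage: rank deficient
  expect_error(fit_eqtl(x, y, dup), "rank-deficient|collinear")
  # perfect fit without noise
  fitp <- fit_eqtl(x, 2 * x)
  expect_equal(fitp$beta, 2, tolerance = 1e-12)
  expect_lt(fitp$p_value, 1e-12)
  # NA dosage drops that sample only
  x_na <- x; x_na[1] <- NA
  expect_equal(fit_eqtl(x_na, y)$n, 29)
})

test_that("per-feature FDR matches the BH oracle within each feature family", {
  one <- fdr_per_feature(data.frame(feature_id = "f", p_value = 0.04))
  expect_equal(one$fdr, 0.04)
  set.seed(33)
  res <- data.frame(feature_id = rep(c("a", "b", "c"), times = c(10, 5, 20)),
                    p_value = runif(35))
  out <- fdr_per_feature(res)
  for (f in c("a", "b", "c")) {
    expect_equal(out$fdr[out$feature_id == f],
                 oracle_bh(res$p_value[res$feature_id == f]))
  }
  glob <- fdr_per_feature(res, global = TRUE)
  expect_equal(glob$fdr, oracle_bh(res$p_value))
})

test_that("stepwise conditional analysis separates independent signals and stops on null", {
  set.seed(34)
  n <- 200
  dosage <- matrix(rbinom(n * 20, 2, 0.4), n, 20,
                   dimnames = list(NULL, paste0("s", 1:20)))
  y <- 1.0 * dosage[, 3] + 1.0 * dosage[, 11] + rnorm(n)
  sig <- stepwise_conditional("f", dosage, y)
  expect_setequal(sig$snp_id[1:2], c("s3", "s11"))
  expect_equal(sig$conditional_rank[1:2], c(0L, 1L))

  # single causal SNP: the second step finds nothing more than rarely
  y1 <- 1.0 * dosage[, 5] + rnorm(n)
  sig1 <- stepwise_conditional("f", dosage, y1)
  expect_equal(sig1$snp_id[1], "s5")

  # null features yield no signal in nearly all replicates (BH keeps the
  # per-feature any-discovery rate near the FDR level)
  zeros <- sum(replicate(30, {
    nrow(stepwise_conditional("f", dosage, rnorm(n))) == 0L
  }))
  expect_gte(zeros, 24)

  # perfectly correlated copies can never both be reported
  dosage2 <- cbind(dosage[, 1:5], twin = dosage[, 3])
  y2 <- 1.0 * dosage[, 3] + rnorm(n)
  sig2 <- stepwise_conditional("f", dosage2, y2)
  expect_false(all(c("s3", "twin") %in% sig2$snp_id))
})

test_that("eQTL replication fraction: identity, disjoint, planted sharing", {
  a <- data.frame(feature_id = "f", snp_id = paste0("s", 1:10),
                  significant = rep(c(TRUE, FALSE), 5))
  expect_equal(replicate_eqtl(a, a)$fraction, 1)
  b <- a
  b$significant <- !a$significant
  expect_equal(replicate_eqtl(a, b)$fraction, 0)
  # half the A hits replicate
  c_ <- a
  c_$significant <- c(TRUE, FALSE, TRUE, FALSE, FALSE,
                      FALSE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(replicate_eqtl(a, c_)$fraction, 0.6)
  expect_error(replicate_eqtl(a, data.frame(feature_id = "g", snp_id = "x",
                                            significant = TRUE)),
               "no shared")
})

test_that("residualization removes covariate structure", {
  set.seed(36)
  cov1 <- rnorm(50)
  expr <- rbind(f1 = 2 * cov1 + rnorm(50), f2 = rnorm(50))
  res <- residualize(expr, cbind(cov1))
  expect_lt(abs(cor(res["f1", ], cov1)), 1e-10)
  expect_equal(dim(res), dim(expr))
})
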