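# cis-eQTL mapping: genotype QC, expression filtering, cis-window pairing,
# covariate-adjusted OLS association, per-feature BH FDR and stepwise
# conditional analysis for independent signals.

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact two-sided p-value for deviation from Hardy-Weinberg proportions
#' given hard genotype counts, summing the probabilities of all heterozygote
#' counts no more likely than the observed one (conditional on allele
#' counts).
#'
#' @param n_het Heterozygote count.
#' @param n_hom1,n_hom2 Homozygote counts (either order).
#' @return Exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_het, n_hom1, n_hom2) {
  n <- n_het + n_hom1 + n_hom2
  if (n == 0) return(1)
  n_rare <- 2 * min(n_hom1, n_hom2) + n_het
  hs <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  logp <- vapply(hs, function(h) {
    n_aa <- (n_rare - h) / 2
    n_bb <- n - n_aa - h
    lgamma(n + 1) - lgamma(n_aa + 1) - lgamma(h + 1) - lgamma(n_bb + 1) +
      lgamma(n_rare + 1) + lgamma(2 * n - n_rare + 1) - lgamma(2 * n + 1) +
      h * log(2)
  }, 0)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[hs == n_het]
  min(1, sum(prob[prob <= obs * (1 + 1e-7)]))
}

#' Genotype quality control
#'
#' Removes monomorphic SNPs, SNPs below the MAF threshold, SNPs deviating
#' from Hardy-Weinberg equilibrium (exact test) and SNPs with too few
#' heterozygotes. The HWE and heterozygote-count filters need hard
#' genotype calls; with fractional dosages they are skipped with a warning.
#' An optional per-SNP imputation-quality column can be filtered too.
#'
#' @param g `genotype_matrix`.
#' @param maf_min Minimum minor allele frequency (inclusive).
#' @param hwe_p_min Minimum exact HWE p-value (inclusive).
#' @param min_het Minimum heterozygote count (inclusive).
#' @param r2_quality Optional numeric vector of per-SNP imputation quality
#'   aligned with `g$snps`; SNPs at or below `r2_quality_min` are removed.
#' @param r2_quality_min Quality threshold (strict), used only when
#'   `r2_quality` is given.
#' @return Filtered `genotype_matrix`; error when nothing survives.
#' @export
genotype_qc <- function(g, maf_min = 0.05, hwe_p_min = 1e-4, min_het = 2,
                        r2_quality = NULL, r2_quality_min = 0.5) {
  dos <- g$dosage
  afreq <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(afreq, 1 - afreq)
  mono <- apply(dos, 2, function(x) length(unique(x[!is.na(x)])) <= 1L)
  keep <- !mono & maf >= maf_min
  if (g$hard_calls) {
    hets <- colSums(dos == 1, na.rm = TRUE)
    hwe_p <- vapply(seq_len(ncol(dos)), function(j) {
      x <- dos[!is.na(dos[, j]), j]
      hwe_exact_test(sum(x == 1), sum(x == 0), sum(x == 2))
    }, 0)
    keep <- keep & hets >= min_het & hwe_p >= hwe_p_min
  } else {
    warning("fractional dosages: HWE and heterozygote-count filters skipped")
  }
  if (!is.null(r2_quality)) keep <- keep & r2_quality > r2_quality_min
  if (!any(keep)) stop("no SNPs pass genotype QC")
  out <- new_genotype_matrix(dos[, keep, drop = FALSE],
                             g$snps[keep, , drop = FALSE])
  out
}

#' Expression filter on RPKM scale
#'
#' Retains features whose RPKM exceeds `min_rpkm` in at least `min_frac`
#' of samples.
#'
#' @param expr_rpkm Matrix (features x samples) on RPKM scale.
#' @param min_rpkm Strict RPKM threshold.
#' @param min_frac Minimum fraction of samples (inclusive).
#' @return The retained rows of `expr_rpkm`.
#' @export
filter_features <- function(expr_rpkm, min_rpkm = 0.1, min_frac = 0.8) {
  keep <- rowMeans(expr_rpkm > min_rpkm) >= min_frac
  expr_rpkm[keep, , drop = FALSE]
}

#' Enumerate cis SNP-feature pairs
#'
#' A SNP is paired with a feature when the distance between the SNP
#' position and the feature's span is at most `window_bp` (inclusive
#' boundary); a SNP inside the span has distance 0.
#'
#' @param snps data.frame (`snp_id`, `chrom`, `pos`), 0-based positions.
#' @param features data.frame (`id` or `feature_id`, `chrom`, `start`,
#'   `end`), 0-based half-open.
#' @param window_bp Cis window half-width in bp.
#' @return data.frame (`snp_id`, `feature_id`, `distance_bp`).
#' @export
cis_pairs <- function(snps, features, window_bp = 1e6) {
  fid <- if (!is.null(features$feature_id)) features$feature_id else features$id
  out <- lapply(seq_len(nrow(features)), function(i) {
    same <- snps$chrom == features$chrom[i]
    # distance of base index pos to inclusive span [start, end-1]
    d <- pmax(0, features$start[i] - snps$pos,
              snps$pos - (features$end[i] - 1L))
    hit <- same & d <= window_bp
    if (!any(hit)) return(NULL)
    data.frame(snp_id = snps$snp_id[hit], feature_id = fid[i],
               distance_bp = d[hit], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(snp_id = character(), feature_id = character(),
                      distance_bp = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Covariate-adjusted eQTL linear model
#'
#' Ordinary least squares of expression on dosage plus covariates, with a
#' two-sided t-test on the dosage coefficient. Samples with a missing
#' dosage, expression or covariate value are dropped for this test only.
#'
#' @param dosage Numeric dosage vector.
#' @param expr Numeric expression vector, same length.
#' @param covariates Optional numeric matrix/data.frame of covariates.
#' @return list with `beta`, `se`, `p_value`, `n` (samples used).
#' @export
fit_eqtl <- function(dosage, expr, covariates = NULL) {
  X <- cbind(`(Intercept)` = 1, dosage = dosage)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates))) {
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    }
    X <- cbind(X, covariates)
  }
  ok <- stats::complete.cases(X) & !is.na(expr)
  X <- X[ok, , drop = FALSE]
  y <- expr[ok]
  n <- nrow(X)
  if (n < ncol(X) + 1L) stop("too few complete samples for the model")
  if (stats::var(X[, "dosage"]) == 0) stop("constant dosage: effect not estimable")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  beta_all <- qr.coef(qx, y)
  res <- y - X %*% beta_all
  df <- n - ncol(X)
  sigma2 <- sum(res^2) / df
  XtX_inv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  se <- sqrt(sigma2 * diag(XtX_inv))
  tstat <- beta_all / se
  j <- which(colnames(X) == "dosage")
  list(beta = unname(beta_all[j]), se = unname(se[j]),
       p_value = unname(2 * stats::pt(abs(tstat[j]), df, lower.tail = FALSE)),
       n = n)
}

#' BH FDR within each expression feature
#'
#' Adjusts p-values by Benjamini-Hochberg within each feature's family of
#' cis tests; a `global = TRUE` mode adjusts across all rows instead.
#'
#' @param results data.frame with `feature_id` and `p_value`.
#' @param fdr_level Significance level on the adjusted scale.
#' @param global Pool all features into one BH family.
#' @return `results` with `fdr` and `significant` columns.
#' @export
fdr_per_feature <- function(results, fdr_level = 0.05, global = FALSE) {
  if (global) {
    results$fdr <- stats::p.adjust(results$p_value, method = "BH")
  } else {
    results$fdr <- NA_real_
    for (f in unique(results$feature_id)) {
      idx <- results$feature_id == f
      results$fdr[idx] <- stats::p.adjust(results$p_value[idx], method = "BH")
    }
  }
  results$significant <- results$fdr < fdr_level
  results
}

#' Map cis-eQTLs across all features
#'
#' Runs [cis_pairs()], fits the covariate-adjusted model for every pair and
#' applies per-feature BH FDR. All returned signals have
#' `conditional_rank = 0` (primary pass); [stepwise_conditional()] finds
#' higher ranks.
#'
#' @param genotypes `genotype_matrix` (after [genotype_qc()]).
#' @param expr Matrix (features x samples), residualized expression.
#' @param features data.frame with feature coordinates.
#' @param covariates Optional covariate matrix (samples x covariates).
#' @param window_bp Cis window half-width.
#' @param fdr_level FDR level.
#' @return EQTL result data.frame: `feature_id`, `snp_id`, `beta`, `se`,
#'   `p_value`, `fdr`, `significant`, `conditional_rank`.
#' @export
map_cis_eqtl <- function(genotypes, expr, features, covariates = NULL,
                         window_bp = 1e6, fdr_level = 0.05) {
  pairs <- cis_pairs(genotypes$snps, features, window_bp)
  pairs <- pairs[pairs$feature_id %in% rownames(expr), , drop = FALSE]
  if (!nrow(pairs)) stop("no cis pairs to test")
  fits <- lapply(seq_len(nrow(pairs)), function(k) {
    fit_eqtl(genotypes$dosage[, pairs$snp_id[k]],
             expr[pairs$feature_id[k], ], covariates)
  })
  res <- data.frame(
    feature_id = pairs$feature_id, snp_id = pairs$snp_id,
    beta = vapply(fits, `[[`, 0, "beta"),
    se = vapply(fits, `[[`, 0, "se"),
    p_value = vapply(fits, `[[`, 0, "p_value"),
    stringsAsFactors = FALSE
  )
  res <- fdr_per_feature(res, fdr_level)
  res$conditional_rank <- 0L
  res
}

#' Stepwise conditional analysis for one feature
#'
#' Starting from the primary cis scan of one feature, iteratively adds the
#' lead SNP (smallest p-value) to the covariates, refits every remaining
#' cis SNP and re-applies BH within the feature, until no SNP passes
#' `fdr_level` or `max_steps` is reached. Each discovered signal carries
#' its discovery step as `conditional_rank` (0 = primary). A lead SNP
#' collinear with the current covariates is skipped with a warning.
#'
#' @param feature_id Feature to analyse.
#' @param dosage Matrix (samples x cis SNPs) of dosages for the feature's
#'   cis SNPs.
#' @param expr Expression vector for the feature.
#' @param covariates Optional covariate matrix.
#' @param fdr_level FDR level per step.
#' @param max_steps Cap on conditioning rounds.
#' @return data.frame of independent signals (possibly 0 rows):
#'   `feature_id`, `snp_id`, `beta`, `se`, `p_value`, `fdr`,
#'   `conditional_rank`.
#' @export
stepwise_conditional <- function(feature_id, dosage, expr, covariates = NULL,
                                 fdr_level = 0.05, max_steps = 5) {
  empty <- data.frame(feature_id = character(), snp_id = character(),
                      beta = numeric(), se = numeric(), p_value = numeric(),
                      fdr = numeric(), conditional_rank = integer(),
                      stringsAsFactors = FALSE)
  remaining <- colnames(dosage)
  conditioned <- NULL
  signals <- empty
  step <- 0L
  while (step < max_steps && length(remaining)) {
    cov_now <- covariates
    if (!is.null(conditioned)) {
      cov_now <- cbind(cov_now, dosage[, conditioned, drop = FALSE])
    }
    fits <- lapply(remaining, function(s) {
      tryCatch(fit_eqtl(dosage[, s], expr, cov_now),
               error = function(e) NULL)
    })
    ok <- !vapply(fits, is.null, TRUE)
    if (!any(ok)) break
    snp_ok <- remaining[ok]
    p <- vapply(fits[ok], `[[`, 0, "p_value")
    fdr <- stats::p.adjust(p, method = "BH")
    if (!any(fdr < fdr_level)) break
    lead <- which.min(p)
    lead_fit <- fits[ok][[lead]]
    signals <- rbind(signals, data.frame(
      feature_id = feature_id, snp_id = snp_ok[lead],
      beta = lead_fit$beta, se = lead_fit$se, p_value = p[lead],
      fdr = fdr[lead], conditional_rank = step,
      stringsAsFactors = FALSE
    ))
    # collinearity of the new lead with what is already conditioned on
    test_design <- cbind(1, cov_now, dosage[, snp_ok[lead]])
    if (qr(test_design[stats::complete.cases(test_design), ])$rank < ncol(test_design)) {
      warning("lead SNP ", snp_ok[lead], " collinear with covariates; stopping")
      break
    }
    conditioned <- c(conditioned, snp_ok[lead])
    remaining <- setdiff(remaining, snp_ok[lead])
    step <- step + 1L
  }
  rownames(signals) <- NULL
  signals
}

#' eQTL replication fraction between two result sets
#'
#' Among (SNP, feature) pairs significant in set A and testable (present)
#' in set B, the fraction also significant in B.
#'
#' @param set_a,set_b EQTL result data.frames with `feature_id`, `snp_id`,
#'   `significant`.
#' @return list with `fraction`, `n_tested`, `n_replicated`.
#' @export
replicate_eqtl <- function(set_a, set_b) {
  key_a <- paste(set_a$snp_id, set_a$feature_id)
  key_b <- paste(set_b$snp_id, set_b$feature_id)
  if (!length(intersect(key_a, key_b))) {
    stop("no shared SNP-feature pairs between the result sets")
  }
  sig_a <- key_a[set_a$significant]
  tested <- intersect(sig_a, key_b)
  if (!length(tested)) {
    return(list(fraction = NA_real_, n_tested = 0L, n_replicated = 0L))
  }
  sig_b <- key_b[set_b$significant]
  n_rep <- sum(tested %in% sig_b)
  list(fraction = n_rep / length(tested),
       n_tested = length(tested), n_replicated = n_rep)
}

#' Residualize expression on a covariate matrix
#'
#' Least-squares residuals of each feature on the covariates (plus
#' intercept) — the simple stand-in for upstream covariate removal when a
#' pre-residualized matrix is not supplied.
#'
#' @param expr Matrix (features x samples).
#' @param covariates Matrix (samples x covariates).
#' @return Residualized matrix, same shape as `expr`.
#' @export
residualize <- function(expr, covariates) {
  X <- cbind(1, as.matrix(covariates))
  t(apply(expr, 1, function(y) stats::lm.fit(X, y)$residuals))
}
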