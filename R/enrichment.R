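# Enrichment analyses: read-depth-matched randomization tests for GWAS
# signal and eQTL overlap among ASE sites, module eigengene / membership
# computation, and Fisher exact enrichment of cell-type labels and GWAS
# catalogue overlap.

# Shared randomization scaffold. Sites are binned by mean read depth
# (default: deciles of the pooled depth distribution); every iteration
# draws, with replacement and per bin, as many non-ASE sites as the ASE
# set has in that bin, and records the mean of `values` over the draw.
depth_matched_core <- function(ase_ids, non_ase_ids, depths, values,
                               n_iter, n_bins, seed,
                               degenerate = c("error", "sign"),
                               record_draws = FALSE) {
  degenerate <- match.arg(degenerate)
  if (!length(ase_ids)) stop("empty ASE set")
  if (!length(non_ase_ids)) stop("empty non-ASE set")
  set.seed(seed)
  pooled <- depths[c(ase_ids, non_ase_ids)]
  breaks <- unique(stats::quantile(pooled, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(breaks) < 2L) breaks <- c(breaks - 0.5, breaks + 0.5)
  bin_of <- function(d) cut(d, breaks = breaks, include.lowest = TRUE,
                            labels = FALSE)
  ase_bin <- bin_of(depths[ase_ids])
  non_bin <- bin_of(depths[non_ase_ids])
  ase_counts <- table(factor(ase_bin, levels = seq_len(length(breaks) - 1)))
  sums <- numeric(n_iter)
  draw_ids <- if (record_draws) list()
  for (b in which(ase_counts > 0)) {
    pool_ids <- non_ase_ids[non_bin == b]
    if (!length(pool_ids)) {
      stop(sprintf("ASE depth bin %d has no non-ASE counterpart", b))
    }
    n_b <- as.integer(ase_counts[b])
    picked <- sample.int(length(pool_ids), n_b * n_iter, replace = TRUE)
    draw <- matrix(values[pool_ids[picked]], nrow = n_iter)
    sums <- sums + rowSums(draw)
    if (record_draws) {
      draw_ids[[as.character(b)]] <- matrix(pool_ids[picked], nrow = n_iter)
    }
  }
  r <- sums / length(ase_ids)
  observed <- mean(values[ase_ids])
  null_mean <- mean(r)
  null_sd <- stats::sd(r)
  if (null_sd == 0) {
    if (degenerate == "error") {
      stop("null distribution has zero standard deviation (degenerate values)")
    }
    z <- if (observed == null_mean) 0 else sign(observed - null_mean) * Inf
  } else {
    z <- (observed - null_mean) / null_sd
  }
  structure(
    list(observed_stat = observed, null_mean = null_mean, null_sd = null_sd,
         z = z, p_value = stats::pnorm(z, lower.tail = FALSE),
         n_iter = n_iter, seed = seed, r = r,
         bin_breaks = breaks, ase_bin_counts = ase_counts,
         draw_ids = draw_ids),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "depth-matched randomization: observed %.4f, null %.4f (sd %.4f)\n  z = %.3f, one-sided p = %.3g (%d iterations, seed %d)\n",
    x$observed_stat, x$null_mean, x$null_sd, x$z, x$p_value,
    x$n_iter, x$seed))
  invisible(x)
}

#' Depth-matched randomization test for GWAS enrichment among ASEs
#'
#' Restricts ASE and non-ASE sites to SNPs present in the GWAS table (the
#' common set), bins the sites by mean read depth and repeatedly samples
#' depth-matched non-ASE sets with replacement; each iteration's statistic
#' r_i is the mean -log10 GWAS p over the sampled set. The z-score of the
#' observed ASE-set mean against the mean and SD of the r_i gives a
#' one-sided (enrichment) normal p-value; `two_sided = TRUE` doubles the
#' smaller tail.
#'
#' @param ase_depth Named numeric vector: mean read depth per ASE SNP.
#' @param non_ase_depth Named numeric vector: mean depth per non-ASE SNP.
#' @param gwas data.frame (`snp_id`, `p_value`).
#' @param n_iter Randomization iterations.
#' @param n_bins Depth bins (quantile-based).
#' @param seed Integer seed.
#' @param two_sided Report a two-sided p-value instead.
#' @return `enrichment_result`: `observed_stat`, `null_mean`, `null_sd`,
#'   `z`, `p_value`, `n_iter`, `seed`, and the r_i vector `r`.
#' @export
depth_matched_randomization <- function(ase_depth, non_ase_depth, gwas,
                                        n_iter = 1e5, n_bins = 10, seed = 1L,
                                        two_sided = FALSE) {
  if (length(unique(gwas$p_value)) < 2L) {
    stop("degenerate GWAS p distribution: all p-values identical")
  }
  values <- stats::setNames(-log10(gwas$p_value), gwas$snp_id)
  ase_ids <- intersect(names(ase_depth), gwas$snp_id)
  non_ids <- intersect(names(non_ase_depth), gwas$snp_id)
  if (!length(ase_ids)) stop("no ASE site is present in the GWAS table")
  if (!length(non_ids)) stop("no non-ASE site is present in the GWAS table")
  depths <- c(ase_depth[ase_ids], non_ase_depth[non_ids])
  res <- depth_matched_core(ase_ids, non_ids, depths, values,
                            n_iter, n_bins, seed, degenerate = "error")
  if (two_sided) {
    res$p_value <- 2 * min(stats::pnorm(res$z), stats::pnorm(res$z, lower.tail = FALSE))
  }
  res
}

#' Depth-matched randomization test for eQTL overlap among ASEs
#'
#' Same scaffold as [depth_matched_randomization()] with the per-set
#' statistic replaced by the fraction of sampled SNPs that are eQTLs.
#'
#' @param ase_depth,non_ase_depth Named mean-depth vectors.
#' @param eqtl_snp_set Character vector of eQTL SNP ids.
#' @param n_iter Iterations.
#' @param n_bins Depth bins.
#' @param seed Integer seed.
#' @return `enrichment_result` (z may be 0/Inf when the null is degenerate,
#'   e.g. an empty eQTL set).
#' @export
eqtl_ase_overlap_randomization <- function(ase_depth, non_ase_depth,
                                           eqtl_snp_set, n_iter = 1e5,
                                           n_bins = 10, seed = 1L) {
  ids <- c(names(ase_depth), names(non_ase_depth))
  values <- stats::setNames(as.numeric(ids %in% eqtl_snp_set), ids)
  depths <- c(ase_depth, non_ase_depth)
  depth_matched_core(names(ase_depth), names(non_ase_depth), depths, values,
                     n_iter, n_bins, seed, degenerate = "sign")
}

#' Module eigengene
#'
#' First principal component of the (standardized) member features,
#' returning one score per sample; the sign is oriented so that the mean
#' correlation of members with the eigengene is positive.
#'
#' @param expr Matrix (member features x samples), >= 2 members.
#' @return Numeric eigengene vector by sample, with attribute
#'   `var_explained`.
#' @export
module_eigengene <- function(expr) {
  if (nrow(expr) < 2L) stop("a module needs at least 2 member features")
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant feature(s) dropped from the module")
    expr <- expr[sds > 0, , drop = FALSE]
    if (nrow(expr) < 2L) stop("fewer than 2 non-constant member features")
  }
  pc <- stats::prcomp(t(expr), center = TRUE, scale. = TRUE)
  eg <- pc$x[, 1]
  orient <- mean(apply(expr, 1, function(f) stats::cor(f, eg)))
  if (orient < 0) eg <- -eg
  attr(eg, "var_explained") <- pc$sdev[1]^2 / sum(pc$sdev^2)
  eg
}

#' Module membership (kME)
#'
#' Pearson correlation of a feature's expression with a module eigengene;
#' the feature is assigned to the module when the membership reaches
#' `membership_min` (inclusive by default; `strict = TRUE` requires a
#' strictly greater value).
#'
#' @param feature_expr Numeric expression vector (>= 3 samples,
#'   non-constant).
#' @param eigengene Eigengene vector, same samples.
#' @param membership_min Assignment threshold.
#' @param strict Use a strict inequality.
#' @return list with `membership` and logical `assigned`.
#' @export
module_membership <- function(feature_expr, eigengene, membership_min = 0.3,
                              strict = FALSE) {
  if (length(feature_expr) < 3L) stop("need at least 3 samples")
  if (stats::sd(feature_expr) == 0 || stats::sd(eigengene) == 0) {
    stop("constant vector: correlation undefined")
  }
  m <- stats::cor(feature_expr, eigengene)
  list(membership = m,
       assigned = if (strict) m > membership_min else m >= membership_min)
}

#' Cell-type enrichment by Fisher's exact test
#'
#' For each cell type, a two-sided Fisher exact test on the 2x2 table of
#' (in class vs out of class) by (labelled with the cell type vs not),
#' BH-corrected across cell types. Cell types with a zero margin are
#' skipped with a warning.
#'
#' @param labels_in_class Cell-type labels of features in the class.
#' @param labels_out_class Cell-type labels of the background features.
#' @param cell_types Cell types to test (default: all observed).
#' @return data.frame: `cell_type`, `odds_ratio`, `p_value`, `fdr`,
#'   `significant` (p < 0.05 convention).
#' @export
celltype_enrichment <- function(labels_in_class, labels_out_class,
                                cell_types = NULL) {
  if (is.null(cell_types)) {
    cell_types <- sort(unique(c(labels_in_class, labels_out_class)))
  }
  rows <- lapply(cell_types, function(ct) {
    a <- sum(labels_in_class == ct)
    b <- sum(labels_in_class != ct)
    c_ <- sum(labels_out_class == ct)
    d <- sum(labels_out_class != ct)
    tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      warning("cell type ", ct, " has a zero margin; skipped")
      return(NULL)
    }
    ft <- stats::fisher.test(tab)
    data.frame(cell_type = ct, odds_ratio = unname(ft$estimate),
               p_value = ft$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable cell type (all margins zero)")
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value < 0.05
  rownames(out) <- NULL
  out
}

#' GWAS catalogue overlap enrichment for eQTL SNPs
#'
#' Fisher exact test asking whether, among SNPs overlapping any GWAS hit,
#' eQTL SNPs are enriched for brain-relevant associations relative to the
#' background set. Overlap is by exact SNP id.
#'
#' @param eqtl_snps Character set of eQTL SNP ids.
#' @param background_snps Character set of background SNP ids.
#' @param brain_gwas_snps SNPs with brain/behaviour-relevant GWAS hits.
#' @param other_gwas_snps SNPs with any other GWAS hit.
#' @return list with `odds_ratio`, `p_value` and the 2x2 `table`.
#' @export
gwas_overlap_fisher <- function(eqtl_snps, background_snps,
                                brain_gwas_snps, other_gwas_snps) {
  a <- length(intersect(eqtl_snps, brain_gwas_snps))
  b <- length(intersect(eqtl_snps, other_gwas_snps))
  c_ <- length(intersect(background_snps, brain_gwas_snps))
  d <- length(intersect(background_snps, other_gwas_snps))
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                dimnames = list(set = c("eqtl", "background"),
                                gwas = c("brain", "other")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero margin in the overlap table")
  }
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value, table = tab)
}
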