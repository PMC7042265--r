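# Beta-heterogeneity testing: is an eQTL's effect shared across a gene's
# expression features (exons, junctions, linked regions) or distinct?
# Single-slope vs multiple-slope linear mixed models (random intercepts for
# individual and feature), compared by likelihood ratio. Models are fitted
# by maximum likelihood, not REML: the two models differ in their fixed
# effects, and an LRT on fixed effects is invalid under REML.

check_long_frame <- function(data) {
  need <- c("individual_id", "feature_id", "dosage", "expression")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("long frame missing column(s): ",
                         paste(miss, collapse = ", "))
  if (length(unique(data$feature_id)) < 2L) {
    stop("need at least 2 distinct features (df would be 0)")
  }
  if (length(unique(data$individual_id)) < 10L) {
    stop("need at least 10 individuals")
  }
  if (anyDuplicated(data[, c("individual_id", "feature_id")])) {
    stop("an individual contributes more than one row to a feature")
  }
  invisible(data)
}

#' Assemble a long frame for heterogeneity testing
#'
#' Stacks per-feature expression against a shared dosage vector into the
#' (individual, feature, dosage, expression) long format the mixed models
#' consume.
#'
#' @param dosage Named (or ordered) dosage vector by individual.
#' @param expr Matrix (features x individuals), columns aligned to `dosage`.
#' @return Long data.frame with `individual_id`, `feature_id`, `dosage`,
#'   `expression`.
#' @export
make_long_frame <- function(dosage, expr) {
  ind <- colnames(expr)
  if (is.null(ind)) ind <- paste0("I", seq_len(ncol(expr)))
  data.frame(
    individual_id = rep(ind, each = nrow(expr)),
    feature_id = rep(rownames(expr), times = ncol(expr)),
    dosage = rep(dosage, each = nrow(expr)),
    expression = as.vector(expr),
    stringsAsFactors = FALSE
  )
}

fit_lmm <- function(formula, data) {
  one_fit <- function(optimizer) {
    suppressWarnings(withCallingHandlers(
      lme4::lmer(formula, data = data, REML = FALSE,
                 control = lme4::lmerControl(
                   optimizer = optimizer,
                   check.conv.singular = "ignore",
                   optCtrl = if (optimizer == "bobyqa") list(maxfun = 5e4)
                             else list())),
      message = function(m) invokeRestart("muffleMessage")
    ))
  }
  conv_code <- function(fit) {
    cc <- fit@optinfo$conv$lme4
    if (!is.null(cc$code)) cc$code else 0L
  }
  fit <- one_fit("nloptwrap")
  # marginal gradient-check failures are usually spurious; retry with a
  # derivative-free optimizer before declaring non-convergence
  if (conv_code(fit) < 0) fit <- one_fit("bobyqa")
  if (conv_code(fit) < 0) {
    stop("mixed model did not converge: ",
         paste(unlist(fit@optinfo$conv$lme4$messages), collapse = "; "))
  }
  fit
}

#' Fit the single-slope (non-heterogeneous) model
#'
#' Linear mixed model `expression ~ dosage + (1 | individual) +
#' (1 | feature)`: one common dosage slope, with random intercepts
#' absorbing within-individual and within-feature correlation. Fitted by
#' maximum likelihood. Variance components at the 0 boundary are permitted
#' and flagged, not treated as errors.
#'
#' @param data Long frame (see [make_long_frame()]).
#' @return list with `fit` (lmerMod), `logLik`, `slope`, `singular`.
#' @export
fit_single_slope <- function(data) {
  check_long_frame(data)
  fit <- fit_lmm(expression ~ dosage + (1 | individual_id) + (1 | feature_id),
                 data)
  list(fit = fit, logLik = as.numeric(stats::logLik(fit)),
       slope = unname(lme4::fixef(fit)["dosage"]),
       singular = lme4::isSingular(fit))
}

#' Fit the multiple-slope (heterogeneous) model
#'
#' The single-slope model plus a fixed dosage-by-feature interaction: one
#' extra slope per additional feature. Fitted by maximum likelihood.
#'
#' @param data Long frame.
#' @return list with `fit`, `logLik`, `slopes` (per-feature dosage slopes,
#'   reference feature first), `singular`.
#' @export
fit_multi_slope <- function(data) {
  check_long_frame(data)
  data$feature_id <- factor(data$feature_id)
  fit <- fit_lmm(
    expression ~ dosage + dosage:feature_id +
      (1 | individual_id) + (1 | feature_id), data)
  fx <- lme4::fixef(fit)
  base <- fx["dosage"]
  inter <- fx[grep("^dosage:feature_id", names(fx))]
  slopes <- c(base, base + inter)
  names(slopes) <- levels(data$feature_id)
  list(fit = fit, logLik = as.numeric(stats::logLik(fit)),
       slopes = slopes, singular = lme4::isSingular(fit))
}

#' Likelihood-ratio test for slope heterogeneity
#'
#' Compares the nested single- and multiple-slope fits:
#' statistic 2(ll1 - ll0) (clipped at 0), chi-square reference with
#' `n_features - 1` degrees of freedom. The random-effect structure is
#' identical in both models, so the usual variance-boundary mixture issue
#' does not arise for this contrast.
#'
#' @param fit0 Single-slope fit (from [fit_single_slope()]).
#' @param fit1 Multiple-slope fit (from [fit_multi_slope()]).
#' @param n_features Number of distinct features in the data.
#' @return list with `lrt_stat`, `df`, `p_value`.
#' @export
lrt_heterogeneity <- function(fit0, fit1, n_features) {
  stat <- 2 * (fit1$logLik - fit0$logLik)
  if (stat < -1e-6) {
    stop(sprintf(
      "larger model has lower likelihood (delta = %.3g): optimizer failure",
      stat))
  }
  stat <- max(0, stat)
  df <- n_features - 1L
  list(lrt_stat = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' One-call heterogeneity test
#'
#' Fits both models on a long frame and returns the LRT.
#'
#' @param data Long frame.
#' @return list with `lrt_stat`, `df`, `p_value`, `slope0` (common slope),
#'   `slopes1` (per-feature slopes), `singular` (either fit at boundary).
#' @export
test_heterogeneity <- function(data) {
  f0 <- fit_single_slope(data)
  f1 <- fit_multi_slope(data)
  lrt <- lrt_heterogeneity(f0, f1, length(unique(data$feature_id)))
  c(lrt, list(slope0 = f0$slope, slopes1 = f1$slopes,
              singular = f0$singular || f1$singular))
}

#' Classify eQTL signal sharing from heterogeneity p-values
#'
#' BH-adjusts heterogeneity p-values (within each `class_pair` when that
#' column is present) and labels each gene `distinct` when the adjusted
#' p-value is below `fdr_level`, else `shared`.
#'
#' @param results data.frame with `p_value` and optionally `class_pair`.
#' @param fdr_level FDR level.
#' @return `results` with `fdr` and `label` columns.
#' @export
classify_sharing <- function(results, fdr_level = 0.05) {
  if (!is.null(results$class_pair)) {
    results$fdr <- NA_real_
    for (cp in unique(results$class_pair)) {
      idx <- results$class_pair == cp
      results$fdr[idx] <- stats::p.adjust(results$p_value[idx], method = "BH")
    }
  } else {
    results$fdr <- stats::p.adjust(results$p_value, method = "BH")
  }
  results$label <- ifelse(results$fdr < fdr_level, "distinct", "shared")
  results
}

#' Select the comparator exon for an intergenic eQTL
#'
#' The known exon with the most evidence of association with the same SNP:
#' smallest association p-value, ties broken by the lower exon start
#' coordinate.
#'
#' @param ieqtl_snp SNP id of the intergenic eQTL.
#' @param gene_exons data.frame of the gene's exons (`exon_id`, `start`).
#' @param eqtl_results EQTL result data.frame (`feature_id`, `snp_id`,
#'   `p_value`), exon features keyed by `exon_id`.
#' @return The chosen `exon_id`; error when no exon of the gene was tested
#'   for this SNP.
#' @export
select_comparator_exon <- function(ieqtl_snp, gene_exons, eqtl_results) {
  hits <- eqtl_results[eqtl_results$snp_id == ieqtl_snp &
                         eqtl_results$feature_id %in% gene_exons$exon_id, ,
                       drop = FALSE]
  if (!nrow(hits)) {
    stop("no tested exon for SNP ", ieqtl_snp, ": gene excluded")
  }
  hits$start <- gene_exons$start[match(hits$feature_id, gene_exons$exon_id)]
  hits$feature_id[order(hits$p_value, hits$start)][1]
}
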