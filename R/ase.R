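# Allele-specific expression: exact binomial calling, per-sample FDR,
# and classification of sites by direction consistency, imprinting-like
# behaviour and mono-allelic (NMD) expression.

#' Filter allele counts to valid sites
#'
#' A site-sample pair is valid when the total read count C1 + C2 strictly
#' exceeds `min_total` (default: more than five reads).
#'
#' @param counts Allele count data.frame (see [read_allele_counts()]).
#' @param min_total Strict lower bound on C1 + C2.
#' @return The retained rows.
#' @export
filter_valid_sites <- function(counts, min_total = 5) {
  counts[counts$c1 + counts$c2 > min_total, , drop = FALSE]
}

#' Adjusted allelic ratio
#'
#' The ASE effect size (C1 + 0.5) / (C2 + 0.5); the half-count offset
#' reduces the small-sample bias of the raw ratio.
#'
#' @param c1,c2 Non-negative read counts (vectorized).
#' @return Numeric vector of adjusted ratios.
#' @export
adjusted_ratio <- function(c1, c2) {
  if (any(c1 < 0 | c2 < 0)) stop("counts must be non-negative")
  (c1 + 0.5) / (c2 + 0.5)
}

#' Exact binomial test for allelic imbalance
#'
#' Two-sided exact binomial p-value for departure from the balanced null
#' C1 = C2 (success probability 1/2). The default `"minlik"` method sums
#' P(X = k) over all k whose point probability does not exceed that of the
#' observed count (the minimum-likelihood definition used by
#' `stats::binom.test`); `"central"` doubles the smaller tail and caps
#' at 1.
#'
#' @param c1,c2 Non-negative counts (vectorized); c1 + c2 >= 1 per pair.
#' @param method `"minlik"` (default) or `"central"`.
#' @return p-values in (0, 1\].
#' @export
binomial_ase_test <- function(c1, c2, method = c("minlik", "central")) {
  method <- match.arg(method)
  if (any(c1 < 0 | c2 < 0)) stop("counts must be non-negative")
  n <- c1 + c2
  if (any(n < 1)) stop("c1 + c2 must be at least 1")
  p <- numeric(length(n))
  for (nn in unique(n)) {
    idx <- which(n == nn)
    d <- stats::dbinom(0:nn, nn, 0.5)
    if (method == "minlik") {
      # relative tolerance guards against rounding in dbinom when deciding
      # which outcomes are "as extreme" as the observed one
      p[idx] <- vapply(c1[idx], function(k) {
        sum(d[d <= d[k + 1] * (1 + 1e-7)])
      }, 0)
    } else {
      p[idx] <- vapply(c1[idx], function(k) {
        min(1, 2 * min(stats::pbinom(k, nn, 0.5),
                       stats::pbinom(k - 1, nn, 0.5, lower.tail = FALSE)))
      }, 0)
    }
  }
  pmin(p, 1)
}

#' Benjamini-Hochberg FDR within each sample
#'
#' P-values are BH-adjusted independently within every sample (the
#' multiplicity unit is the individual's own set of valid sites);
#' significance is adjusted p < `fdr_level`. A `pooled = TRUE` sensitivity
#' mode adjusts across all samples at once.
#'
#' @param calls data.frame with at least `sample_id` and `p_value`.
#' @param fdr_level Significance level on the adjusted scale.
#' @param pooled Adjust across samples instead of within.
#' @return `calls` with columns `fdr` and `significant` added.
#' @export
per_sample_fdr <- function(calls, fdr_level = 0.05, pooled = FALSE) {
  if (any(calls$p_value <= 0 | calls$p_value > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  if (pooled) {
    calls$fdr <- stats::p.adjust(calls$p_value, method = "BH")
  } else {
    calls$fdr <- NA_real_
    for (s in unique(calls$sample_id)) {
      idx <- calls$sample_id == s
      if (!any(idx)) {
        warning("sample ", s, " has no tests; skipped")
        next
      }
      calls$fdr[idx] <- stats::p.adjust(calls$p_value[idx], method = "BH")
    }
  }
  calls$significant <- calls$fdr < fdr_level
  calls
}

#' Mono-allelic expression flag
#'
#' TRUE when strictly more than `frac` (default 95%) of reads at the site
#' come from a single allele — the pattern expected under effective
#' nonsense-mediated decay.
#'
#' @param c1,c2 Counts (vectorized); c1 + c2 > 0.
#' @param frac Strict major-allele fraction threshold.
#' @return Logical vector.
#' @export
flag_monoallelic <- function(c1, c2, frac = 0.95) {
  if (any(c1 + c2 <= 0)) stop("c1 + c2 must be positive")
  pmax(c1, c2) / (c1 + c2) > frac
}

#' Call ASE across a full allele-count table
#'
#' Runs the complete per-sample calling pipeline: valid-site filter,
#' adjusted ratio, exact binomial test, per-sample BH FDR, direction
#' (1 if C1 > C2, 0 if C1 < C2, NA at ties) and the mono-allelic flag.
#'
#' @param counts Allele count data.frame.
#' @param fdr_level FDR significance level.
#' @param min_total Valid-site strict total-count bound.
#' @param monoallelic_frac Strict mono-allelic fraction.
#' @param pooled_fdr Pool FDR across samples (sensitivity mode).
#' @return ASE call data.frame: input columns plus `adjusted_ratio`,
#'   `p_value`, `fdr`, `significant`, `direction`, `monoallelic`.
#' @export
call_ase <- function(counts, fdr_level = 0.05, min_total = 5,
                     monoallelic_frac = 0.95, pooled_fdr = FALSE) {
  valid <- filter_valid_sites(counts, min_total)
  if (!nrow(valid)) stop("no valid sites after the total-count filter")
  valid$adjusted_ratio <- adjusted_ratio(valid$c1, valid$c2)
  valid$p_value <- binomial_ase_test(valid$c1, valid$c2)
  valid <- per_sample_fdr(valid, fdr_level)
  if (pooled_fdr) valid <- per_sample_fdr(valid, fdr_level, pooled = TRUE)
  valid$direction <- ifelse(valid$c1 > valid$c2, 1L,
                            ifelse(valid$c1 < valid$c2, 0L, NA_integer_))
  valid$monoallelic <- flag_monoallelic(valid$c1, valid$c2, monoallelic_frac)
  rownames(valid) <- NULL
  valid
}

#' Classify site-level direction consistency
#'
#' For each site, significant calls across individuals are summarized:
#' with at least `min_individuals` significant individuals the site is
#' `consistent` when every defined direction agrees (unidirectional) and
#' `inconsistent` otherwise (the imprinting-like pattern); fewer significant
#' individuals give `insufficient`. Ties (C1 = C2) carry no direction and
#' never break consistency.
#'
#' @param calls ASE call data.frame from [call_ase()].
#' @param min_individuals Minimum significant individuals for a verdict.
#' @param use_all_individuals Count all tested individuals (not only
#'   significant ones) against the threshold — alternative reading,
#'   off by default.
#' @return data.frame: `snp_id`, `n_significant_individuals`,
#'   `n_direction1`, `n_direction0`, `consistency`.
#' @export
classify_consistency <- function(calls, min_individuals = 10,
                                 use_all_individuals = FALSE) {
  out <- do.call(rbind, lapply(split(calls, calls$snp_id), function(d) {
    sig <- d[d$significant, , drop = FALSE]
    n1 <- sum(sig$direction == 1L, na.rm = TRUE)
    n0 <- sum(sig$direction == 0L, na.rm = TRUE)
    n_for_rule <- if (use_all_individuals) length(unique(d$sample_id)) else
      length(unique(sig$sample_id))
    consistency <- if (n_for_rule < min_individuals) "insufficient"
    else if (n1 == 0L || n0 == 0L) "consistent"
    else "inconsistent"
    data.frame(snp_id = d$snp_id[1],
               n_significant_individuals = length(unique(sig$sample_id)),
               n_direction1 = n1, n_direction0 = n0,
               consistency = consistency, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Expression-by-genotype dosage check
#'
#' Tests whether total expression differs by genotype group — a two-sided
#' t-test for two groups (e.g. carrier vs non-carrier of a truncating
#' variant) or a one-way ANOVA for three genotype classes. Used to confirm
#' the dosage reduction expected under nonsense-mediated decay.
#'
#' @param expression Numeric vector of expression values by sample.
#' @param genotype_class Factor-like vector of group labels, same length.
#' @return list with `p_value`, `group_means` (named), and `method`.
#' @export
dosage_effect_test <- function(expression, genotype_class) {
  genotype_class <- as.factor(genotype_class)
  tab <- table(genotype_class)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    stop("group(s) with fewer than 2 samples: ", paste(small, collapse = ", "))
  }
  means <- tapply(expression, genotype_class, mean)
  if (nlevels(genotype_class) == 2L) {
    p <- stats::t.test(expression ~ genotype_class)$p.value
    method <- "t-test"
  } else {
    p <- summary(stats::aov(expression ~ genotype_class))[[1]][["Pr(>F)"]][1]
    method <- "anova"
  }
  list(p_value = p, group_means = means, method = method)
}

#' ASE replication fraction between two call sets
#'
#' Among sites significant (in any sample) in set A and testable in set B,
#' the fraction that is also significant in B.
#'
#' @param calls_a,calls_b ASE call data.frames from [call_ase()].
#' @return list with `fraction`, `n_tested`, `n_replicated`.
#' @export
replicate_ase <- function(calls_a, calls_b) {
  shared <- intersect(unique(calls_a$snp_id), unique(calls_b$snp_id))
  if (!length(shared)) stop("no shared SNP ids between the call sets")
  sig_a <- unique(calls_a$snp_id[calls_a$significant])
  tested <- intersect(sig_a, unique(calls_b$snp_id))
  if (!length(tested)) {
    return(list(fraction = NA_real_, n_tested = 0L, n_replicated = 0L))
  }
  sig_b <- unique(calls_b$snp_id[calls_b$significant])
  n_rep <- sum(tested %in% sig_b)
  list(fraction = n_rep / length(tested),
       n_tested = length(tested), n_replicated = n_rep)
}
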