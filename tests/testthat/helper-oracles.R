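# Independent oracles used across the suite. Each is a direct, naive
# restatement of the definition it checks, kept free of the package's own
# code paths.

# two-sided exact binomial p at p = 0.5: sum of P(X = k) over all k whose
# point probability does not exceed that of the observed count. Mirror
# outcomes (k, n-k) are mathematically tied but dbinom can round them to
# values a few ulps apart at large n, so ties are detected with the same
# relative tolerance stats::binom.test uses.
oracle_binom_p <- function(c1, c2) {
  n <- c1 + c2
  d <- dbinom(0:n, n, 0.5)
  min(1, sum(d[d <= d[c1 + 1] * (1 + 1e-7)]))
}

# Benjamini-Hochberg from the definition: adj_(i) = min_{j >= i} m p_(j) / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# expressed-region tier rules, restated directly
oracle_er_tier <- function(n_junction_samples, max_r2, distance_bp,
                           min_split = 4, r2_min = 0.2, max_dist = 5000) {
  if (n_junction_samples >= min_split) return("strong")
  if (is.na(max_r2)) return("unclassified")
  if (max_r2 > r2_min && distance_bp < max_dist) return("moderate")
  "weak"
}

# two-sided Fisher exact p by full hypergeometric enumeration over all
# tables with the observed margins
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n_ <- c + d         # row 2 total
  k <- a + c          # col 1 total
  lo <- max(0, k - n_)
  hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n_, k)
  obs <- dhyper(a, m, n_, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# small long-frame generator for the mixed-model tests: per-feature slopes,
# random intercepts for individual and feature, iid noise
gen_het_data <- function(n_ind, slopes, ind_sd = 0.7, feat_sd = 0.7,
                         noise_sd = 1, maf = 0.3) {
  n_feat <- length(slopes)
  dosage <- rbinom(n_ind, 2, maf)
  ind_eff <- rnorm(n_ind, sd = ind_sd)
  feat_eff <- rnorm(n_feat, sd = feat_sd)
  expr <- outer(slopes, dosage) +
    matrix(rep(ind_eff, each = n_feat), nrow = n_feat) +
    matrix(rep(feat_eff, n_ind), nrow = n_feat) +
    matrix(rnorm(n_feat * n_ind, sd = noise_sd), nrow = n_feat)
  rownames(expr) <- paste0("f", seq_len(n_feat))
  colnames(expr) <- paste0("I", seq_len(n_ind))
  make_long_frame(dosage, expr)
}

# OLS likelihood-ratio statistic for the dosage x feature interaction
# (gaussian ML), the fixed-effects analogue of the mixed-model LRT
oracle_ols_interaction <- function(data) {
  data$feature_id <- factor(data$feature_id)
  fit0 <- lm(expression ~ dosage + feature_id, data = data)
  fit1 <- lm(expression ~ dosage + feature_id + dosage:feature_id, data = data)
  n <- nrow(data)
  stat <- n * log(sum(residuals(fit0)^2) / sum(residuals(fit1)^2))
  df <- nlevels(data$feature_id) - 1
  list(stat = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

# plain OLS interaction LRT with no individual or feature terms: the exact
# limit of the mixed-model LRT when every variance component sits at 0
oracle_ols_plain <- function(data) {
  data$feature_id <- factor(data$feature_id)
  fit0 <- lm(expression ~ dosage, data = data)
  fit1 <- lm(expression ~ dosage + dosage:feature_id, data = data)
  nrow(data) * log(sum(residuals(fit0)^2) / sum(residuals(fit1)^2))
}

# mixed-model LRT together with the maximum variance parameter (theta)
# across both fits, to detect boundary (variance = 0) solutions
het_lrt_with_theta <- function(data) {
  f0 <- fit_single_slope(data)
  f1 <- fit_multi_slope(data)
  lrt <- lrt_heterogeneity(f0, f1, length(unique(data$feature_id)))
  max_theta <- max(abs(lme4::getME(f0$fit, "theta")),
                   abs(lme4::getME(f1$fit, "theta")))
  c(lrt, list(max_theta = max_theta))
}
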