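# Synthetic data generators. Every input the pipeline consumes can be
# generated here with planted ground truth, so each downstream stage is
# testable without controlled-access data. Truth is emitted alongside the
# data, never embedded in it.

#' Simulate Hardy-Weinberg genotypes
#'
#' Each SNP gets a minor allele frequency drawn uniformly in
#' \[`maf_low`, `maf_high`\] and genotypes drawn under Hardy-Weinberg
#' equilibrium. SNPs are uniformly spaced along one synthetic chromosome so
#' that cis-window logic is exercised without a genome build.
#'
#' @param n_samples Number of individuals (>= 2).
#' @param n_snps Number of SNPs.
#' @param maf_low,maf_high MAF range, 0 < maf_low <= maf_high <= 0.5.
#' @param seed Integer seed.
#' @param chrom Chromosome name for all SNPs.
#' @param spacing_bp Distance between adjacent SNP positions.
#' @return `genotype_matrix` with an extra element `truth`
#'   (data.frame `snp_id`, `maf`).
#' @export
sim_genotypes <- function(n_samples, n_snps, maf_low = 0.05, maf_high = 0.5,
                          seed = 1L, chrom = "chrS", spacing_bp = 10000L) {
  if (n_samples < 2) stop("n_samples must be at least 2")
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5)) {
    stop("require 0 < maf_low <= maf_high <= 0.5")
  }
  set.seed(seed)
  maf <- stats::runif(n_snps, maf_low, maf_high)
  dosage <- vapply(maf, function(p) {
    stats::rbinom(n_samples, 2L, p)
  }, numeric(n_samples))
  dosage <- matrix(as.numeric(dosage), nrow = n_samples)
  rownames(dosage) <- sprintf("S%03d", seq_len(n_samples))
  snps <- data.frame(
    snp_id = sprintf("snp%04d", seq_len(n_snps)),
    chrom = chrom,
    pos = as.integer(seq_len(n_snps)) * as.integer(spacing_bp),
    stringsAsFactors = FALSE
  )
  g <- new_genotype_matrix(dosage, snps)
  g$truth <- data.frame(snp_id = snps$snp_id, maf = maf,
                        stringsAsFactors = FALSE)
  g
}

#' Simulate gene models on the synthetic chromosome
#'
#' Genes are placed left to right with `n_exons` equal-length exons each,
#' separated by introns; consecutive genes are separated by an intergenic
#' gap. All coordinates are 0-based half-open.
#'
#' @param n_genes Number of genes.
#' @param n_exons Exons per gene.
#' @param exon_len,intron_len,gap_len Lengths in bp.
#' @param chrom Chromosome name.
#' @param offset_bp Start coordinate of the first gene.
#' @return data.frame of exons: `gene_id`, `exon_id`, `chrom`, `start`, `end`.
#' @export
sim_gene_models <- function(n_genes, n_exons = 4L, exon_len = 200L,
                            intron_len = 800L, gap_len = 50000L,
                            chrom = "chrS", offset_bp = 1000L) {
  gene_span <- n_exons * exon_len + (n_exons - 1L) * intron_len
  out <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
    g_start <- offset_bp + (i - 1L) * (gene_span + gap_len)
    ex_start <- g_start + (seq_len(n_exons) - 1L) * (exon_len + intron_len)
    data.frame(
      gene_id = sprintf("gene%03d", i),
      exon_id = sprintf("gene%03d_ex%d", i, seq_len(n_exons)),
      chrom = chrom,
      start = as.integer(ex_start),
      end = as.integer(ex_start + exon_len),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Simulate expression with additive cis effects
#'
#' Each feature's expression is `beta * dosage` of its causal SNP(s) plus
#' Gaussian noise, with an optional shared per-individual random offset
#' (used to create the within-individual correlation the heterogeneity
#' mixed model accounts for). Features without a planted effect are pure
#' noise. The returned truth records the planted betas and, for genes with
#' several exon features, whether the effect is shared (all betas equal)
#' or distinct.
#'
#' @param genotypes `genotype_matrix`.
#' @param features data.frame with `feature_id` and optionally `gene_id`
#'   (used for shared/distinct bookkeeping).
#' @param effects data.frame with `feature_id`, `snp_id`, `beta`; a feature
#'   may appear several times (summed effects).
#' @param noise_sd Residual standard deviation (>= 0).
#' @param individual_sd SD of the shared per-individual offset (>= 0, 0 off).
#' @param seed Integer seed.
#' @return list with `expr` (features x samples matrix) and `truth`
#'   (list `effects`, `gene_sharing`).
#' @export
sim_expression <- function(genotypes, features, effects, noise_sd = 1,
                           individual_sd = 0, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (individual_sd < 0) stop("individual_sd must be non-negative")
  missing_snp <- setdiff(effects$snp_id, genotypes$snps$snp_id)
  if (length(missing_snp)) {
    stop("effect SNP(s) absent from genotypes: ",
         paste(missing_snp, collapse = ", "))
  }
  set.seed(seed)
  n_samp <- nrow(genotypes$dosage)
  expr <- matrix(stats::rnorm(nrow(features) * n_samp, sd = noise_sd),
                 nrow = nrow(features),
                 dimnames = list(features$feature_id, rownames(genotypes$dosage)))
  if (individual_sd > 0) {
    offset <- stats::rnorm(n_samp, sd = individual_sd)
    expr <- sweep(expr, 2L, offset, `+`)
  }
  for (k in seq_len(nrow(effects))) {
    f <- effects$feature_id[k]
    if (!f %in% rownames(expr)) stop("effect feature absent from features: ", f)
    expr[f, ] <- expr[f, ] + effects$beta[k] * genotypes$dosage[, effects$snp_id[k]]
  }
  gene_sharing <- NULL
  if (!is.null(features$gene_id)) {
    beta_of <- stats::setNames(rep(0, nrow(features)), features$feature_id)
    for (k in seq_len(nrow(effects))) {
      beta_of[effects$feature_id[k]] <- beta_of[effects$feature_id[k]] + effects$beta[k]
    }
    by_gene <- split(beta_of[features$feature_id], features$gene_id)
    multi <- by_gene[lengths(by_gene) > 1]
    if (length(multi)) {
      gene_sharing <- data.frame(
        gene_id = names(multi),
        shared = vapply(multi, function(b) length(unique(b)) == 1L, TRUE),
        stringsAsFactors = FALSE
      )
      rownames(gene_sharing) <- NULL
    }
  }
  list(expr = expr,
       truth = list(effects = effects, gene_sharing = gene_sharing))
}

#' Simulate allele counts at heterozygous sites
#'
#' Plants the four ASE site classes: `null` (balanced, p = 0.5), `cis`
#' (fixed alternative-allele fraction `p_alt`, same direction in every
#' individual), `imprinted` (direction flipped per individual with
#' probability 1/2, emulating random parent-of-origin silencing) and `nmd`
#' (near mono-allelic, `p_alt >= 0.95`, same direction everywhere). Read
#' depth per individual-site is drawn from a discretized log-normal
#' truncated at 1; counts C1 are Binomial(depth, p).
#'
#' @param n_individuals Individuals carrying every het site.
#' @param site_spec data.frame with `snp_id`, `class`
#'   (null/cis/imprinted/nmd) and `p_alt` (ignored for null; must be
#'   in (0,1); >= 0.95 for nmd).
#' @param seed Integer seed.
#' @param depth_meanlog,depth_sdlog Log-normal depth parameters
#'   (defaults give median 20).
#' @param chrom Chromosome name.
#' @param spacing_bp Distance between site positions.
#' @return list with `counts` (allele count data.frame) and `truth`
#'   (site_spec plus the per-individual direction convention:
#'   direction 1 means C1 > C2).
#' @export
sim_allele_counts <- function(n_individuals, site_spec, seed = 1L,
                              depth_meanlog = log(20), depth_sdlog = 0.8,
                              chrom = "chrS", spacing_bp = 10000L) {
  if (!nrow(site_spec)) stop("site_spec is empty")
  if (!all(site_spec$class %in% c("null", "cis", "imprinted", "nmd"))) {
    stop("site class must be one of null, cis, imprinted, nmd")
  }
  non_null <- site_spec$class != "null"
  if (any(non_null & (site_spec$p_alt <= 0 | site_spec$p_alt >= 1))) {
    stop("p_alt must lie strictly in (0, 1)")
  }
  nmd <- site_spec$class == "nmd"
  if (any(nmd & pmax(site_spec$p_alt, 1 - site_spec$p_alt) < 0.95)) {
    stop("nmd sites need p_alt >= 0.95 (or <= 0.05)")
  }
  set.seed(seed)
  n_sites <- nrow(site_spec)
  rows <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    cls <- site_spec$class[i]
    p <- switch(cls,
      null = rep(0.5, n_individuals),
      cis = rep(site_spec$p_alt[i], n_individuals),
      nmd = rep(site_spec$p_alt[i], n_individuals),
      imprinted = ifelse(stats::runif(n_individuals) < 0.5,
                         site_spec$p_alt[i], 1 - site_spec$p_alt[i])
    )
    depth <- pmax(1L, as.integer(round(stats::rlnorm(
      n_individuals, depth_meanlog, depth_sdlog))))
    c1 <- stats::rbinom(n_individuals, depth, p)
    rows[[i]] <- data.frame(
      sample_id = sprintf("I%03d", seq_len(n_individuals)),
      snp_id = site_spec$snp_id[i],
      chrom = chrom,
      pos = i * as.integer(spacing_bp),
      allele1 = "A", allele2 = "C",
      c1 = c1, c2 = depth - c1,
      stringsAsFactors = FALSE
    )
  }
  counts <- do.call(rbind, rows)
  rownames(counts) <- NULL
  list(counts = counts, truth = site_spec)
}

#' Simulate split reads linking regions to gene exons
#'
#' For each requested link, junction records are produced in exactly
#' `n_samples` distinct samples; each record has one block overlapping the
#' expressed region and the other overlapping the first exon of the linked
#' gene, ordered left-to-right with a gap between the blocks.
#'
#' @param regions data.frame of expressed regions (`chrom`, `start`, `end`,
#'   `id`).
#' @param gene_models Exon table from [sim_gene_models()].
#' @param links data.frame with `er_id`, `gene_id`, `n_samples`.
#' @param seed Integer seed (sample labels only; geometry is deterministic).
#' @return Split read data.frame (possibly 0 rows).
#' @export
sim_split_reads <- function(regions, gene_models, links, seed = 1L) {
  cols <- c("sample_id", "chrom", "left_start", "left_end",
            "right_start", "right_end")
  if (is.null(links) || !nrow(links)) {
    out <- data.frame(sample_id = character(), chrom = character(),
                      left_start = integer(), left_end = integer(),
                      right_start = integer(), right_end = integer(),
                      stringsAsFactors = FALSE)
    return(out[, cols])
  }
  set.seed(seed)
  rows <- vector("list", nrow(links))
  for (k in seq_len(nrow(links))) {
    er <- regions[regions$id == links$er_id[k], ]
    if (!nrow(er)) stop("unknown region in links: ", links$er_id[k])
    exons <- gene_models[gene_models$gene_id == links$gene_id[k], ]
    if (!nrow(exons)) stop("unknown gene in links: ", links$gene_id[k])
    if (er$chrom[1] != exons$chrom[1]) {
      stop(sprintf("region %s and gene %s are on different chromosomes",
                   links$er_id[k], links$gene_id[k]))
    }
    ex <- exons[1, ]
    blk_er <- c(er$start[1], min(er$end[1], er$start[1] + 50L))
    blk_ex <- c(ex$start, min(ex$end, ex$start + 50L))
    if (blk_er[1] <= blk_ex[1]) {
      left <- blk_er; right <- blk_ex
    } else {
      left <- blk_ex; right <- blk_er
    }
    if (left[2] >= right[1]) {
      stop(sprintf("region %s overlaps gene %s: no junction gap",
                   links$er_id[k], links$gene_id[k]))
    }
    n <- links$n_samples[k]
    rows[[k]] <- data.frame(
      sample_id = sprintf("S%03d", seq_len(n)),
      chrom = er$chrom[1],
      left_start = left[1], left_end = left[2],
      right_start = right[1], right_end = right[2],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, cols]
}

#' Simulate GWAS summary statistics with planted enrichment
#'
#' Background SNPs get -log10 p drawn from Exponential(ln 10), i.e.
#' p ~ Uniform(0, 1); SNPs in `enriched` have their -log10 p inflated by
#' `shift`.
#'
#' @param snp_ids Character vector of SNP ids.
#' @param enriched Subset of `snp_ids` to inflate.
#' @param shift Additive -log10 p inflation (>= 0).
#' @param seed Integer seed.
#' @return list with `gwas` (data.frame `snp_id`, `p_value`) and `truth`
#'   (the enriched set).
#' @export
sim_gwas <- function(snp_ids, enriched = character(), shift = 0, seed = 1L) {
  if (shift < 0) stop("shift must be non-negative")
  extra <- setdiff(enriched, snp_ids)
  if (length(extra)) stop("enriched SNPs not in snp_ids: ",
                          paste(extra, collapse = ", "))
  set.seed(seed)
  neglog <- stats::rexp(length(snp_ids), rate = log(10))
  neglog[snp_ids %in% enriched] <- neglog[snp_ids %in% enriched] + shift
  list(
    gwas = data.frame(snp_id = snp_ids, p_value = 10^(-neglog),
                      stringsAsFactors = FALSE),
    truth = list(enriched = enriched, shift = shift)
  )
}

#' Generate a complete synthetic study
#'
#' Produces every input the pipeline consumes — genotypes, gene models and
#' expression with planted cis effects (shared and distinct across exons),
#' allele counts with planted null/cis/imprinted/NMD sites, expressed
#' regions with split-read links, GWAS statistics with planted enrichment
#' — and writes them, together with a truth table, under `out_dir`.
#'
#' @param out_dir Output directory (created if needed).
#' @param config `aseqtl_config`; `config$seed` drives all randomness.
#' @param n_samples,n_snps,n_genes,n_individuals,n_ase_sites Study sizes.
#' @return Invisibly, a named list of the generated objects and the truth.
#' @export
simulate_study <- function(out_dir, config = run_config(),
                           n_samples = 100L, n_snps = 120L, n_genes = 12L,
                           n_individuals = 40L, n_ase_sites = 60L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  geno <- sim_genotypes(n_samples, n_snps, seed = seed)
  genes <- sim_gene_models(n_genes)

  # exon-level features; half of the effect genes shared, half distinct
  features <- data.frame(
    feature_id = genes$exon_id, gene_id = genes$gene_id,
    chrom = genes$chrom, start = genes$start, end = genes$end,
    stringsAsFactors = FALSE
  )
  eff_genes <- unique(genes$gene_id)[seq_len(min(6L, n_genes))]
  effects <- do.call(rbind, lapply(seq_along(eff_genes), function(i) {
    gid <- eff_genes[i]
    ex <- genes$exon_id[genes$gene_id == gid]
    snp <- nearest_snp_to(geno, min(genes$start[genes$gene_id == gid]))
    if (i %% 2 == 1) {
      data.frame(feature_id = ex, snp_id = snp, beta = 1.0)   # shared
    } else {
      data.frame(feature_id = ex, snp_id = snp,
                 beta = c(1.0, rep(0, length(ex) - 1L)))       # distinct
    }
  }))
  effects <- effects[effects$beta != 0, ]
  expr_sim <- sim_expression(geno, features, effects, noise_sd = 1,
                             individual_sd = 0.5, seed = seed + 1L)

  # ASE sites: 60% null, then cis / imprinted / nmd
  n_cis <- max(1L, round(0.2 * n_ase_sites))
  n_imp <- max(1L, round(0.1 * n_ase_sites))
  n_nmd <- max(1L, round(0.05 * n_ase_sites))
  n_null <- n_ase_sites - n_cis - n_imp - n_nmd
  site_spec <- data.frame(
    snp_id = sprintf("ase%04d", seq_len(n_ase_sites)),
    class = c(rep("null", n_null), rep("cis", n_cis),
              rep("imprinted", n_imp), rep("nmd", n_nmd)),
    p_alt = c(rep(0.5, n_null), rep(0.75, n_cis),
              rep(0.85, n_imp), rep(0.98, n_nmd)),
    stringsAsFactors = FALSE
  )
  ase_sim <- sim_allele_counts(n_individuals, site_spec, seed = seed + 2L)

  # expressed regions: one strongly linked, one moderate-candidate, one far
  span_end <- max(genes$end)
  regions <- data.frame(
    chrom = "chrS",
    start = c(genes$end[4] + 2000L, genes$end[8] + 3000L, span_end + 100000L),
    end = c(genes$end[4] + 2400L, genes$end[8] + 3400L, span_end + 100400L),
    id = c("ER1", "ER2", "ER3"),
    stringsAsFactors = FALSE
  )
  links <- data.frame(er_id = "ER1", gene_id = genes$gene_id[4],
                      n_samples = 5L, stringsAsFactors = FALSE)
  reads <- sim_split_reads(regions, genes, links, seed = seed + 3L)

  # region expression: ER2 co-expressed with its neighbouring gene's first
  # exon (moderate tier), ER1 and ER3 independent noise
  set.seed(seed + 5L)
  er_expr <- matrix(stats::rnorm(3L * n_samples, sd = 1),
                    nrow = 3L,
                    dimnames = list(regions$id, colnames(expr_sim$expr)))
  neighbour_exon <- genes$exon_id[genes$gene_id == genes$gene_id[8]][1]
  er_expr["ER2", ] <- 0.8 * expr_sim$expr[neighbour_exon, ] +
    stats::rnorm(n_samples, sd = 0.5)

  gwas_sim <- sim_gwas(site_spec$snp_id,
                       enriched = site_spec$snp_id[site_spec$class == "cis"],
                       shift = 1, seed = seed + 4L)

  write_genotypes_vcf(geno, file.path(out_dir, "genotypes.vcf"))
  write_expression(expr_sim$expr, file.path(out_dir, "expression.tsv"))
  feat_iv <- data.frame(chrom = features$chrom, start = features$start,
                        end = features$end, id = features$feature_id)
  write_intervals(feat_iv, file.path(out_dir, "features.bed"))
  write_intervals(regions, file.path(out_dir, "regions.bed"))
  utils::write.table(genes, file.path(out_dir, "gene_models.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_expression(er_expr, file.path(out_dir, "er_expression.tsv"))
  write_allele_counts(ase_sim$counts, file.path(out_dir, "allele_counts.tsv"))
  write_split_reads(reads, file.path(out_dir, "split_reads.tsv"))
  write_gwas(gwas_sim$gwas, file.path(out_dir, "gwas.tsv"))
  truth <- list(
    genotype_maf = geno$truth,
    expression = expr_sim$truth,
    ase_sites = ase_sim$truth,
    er_links = links,
    er_tiers = data.frame(er_id = c("ER1", "ER2", "ER3"),
                          tier = c("strong", "moderate", "weak"),
                          stringsAsFactors = FALSE),
    gwas = gwas_sim$truth
  )
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(list(genotypes = geno, gene_models = genes, features = features,
                 expression = expr_sim$expr, er_expression = er_expr,
                 allele_counts = ase_sim$counts,
                 regions = regions, split_reads = reads,
                 gwas = gwas_sim$gwas, truth = truth))
}

nearest_snp_to <- function(genotypes, pos) {
  i <- which.min(abs(genotypes$snps$pos - pos))
  genotypes$snps$snp_id[i]
}
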