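# Evidence-tier classification of unannotated expressed regions (ERs):
# strong (split-read junctions to a gene in enough samples), moderate
# (co-expressed with and close to the nearest gene), weak (neither),
# plus re-expression validation and enhancer-overlap statistics.
# Interval arithmetic is delegated to GenomicRanges/IRanges.

gene_spans <- function(genes) {
  sp <- do.call(rbind, lapply(split(genes, genes$gene_id), function(g) {
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
               start = min(g$start), end = max(g$end),
               stringsAsFactors = FALSE)
  }))
  rownames(sp) <- NULL
  sp
}

#' Link an expressed region to a gene via split reads
#'
#' A split read supports a link when one of its blocks overlaps the ER and
#' the other block overlaps an exon of the gene (same chromosome). The gene
#' supported by junctions in the most distinct samples is returned, provided
#' that count reaches `min_samples`; ties go to the nearest gene.
#'
#' @param er One-row data.frame (`chrom`, `start`, `end`, `id`).
#' @param reads Split read data.frame (see [read_split_reads()]).
#' @param genes Exon table (`gene_id`, `chrom`, `start`, `end`).
#' @param min_samples Distinct-sample support needed for a link.
#' @return list with `gene_id` (NA when no gene reaches `min_samples`) and
#'   `n_junction_samples` (best support observed, 0 when none).
#' @export
link_by_split_reads <- function(er, reads, genes, min_samples = 4) {
  no_link <- list(gene_id = NA_character_, n_junction_samples = 0L)
  reads <- reads[reads$chrom == er$chrom, , drop = FALSE]
  genes_c <- genes[genes$chrom == er$chrom, , drop = FALSE]
  if (!nrow(reads) || !nrow(genes_c)) return(no_link)
  # half-open interval overlap: a.start < b.end && a.end > b.start
  left_in_er <- reads$left_start < er$end & reads$left_end > er$start
  right_in_er <- reads$right_start < er$end & reads$right_end > er$start
  # the block NOT on the ER must land on an exon of the gene
  samples <- character(0)
  gene_of <- character(0)
  for (j in seq_len(nrow(genes_c))) {
    ex_s <- genes_c$start[j]
    ex_e <- genes_c$end[j]
    left_in_ex <- reads$left_start < ex_e & reads$left_end > ex_s
    right_in_ex <- reads$right_start < ex_e & reads$right_end > ex_s
    hit <- (left_in_er & right_in_ex) | (right_in_er & left_in_ex)
    if (any(hit)) {
      samples <- c(samples, reads$sample_id[hit])
      gene_of <- c(gene_of, rep(genes_c$gene_id[j], sum(hit)))
    }
  }
  if (!length(samples)) return(no_link)
  per_gene <- vapply(split(samples, gene_of),
                     function(s) length(unique(s)), 0L)
  best_n <- max(per_gene)
  cand <- names(per_gene)[per_gene == best_n]
  if (best_n < min_samples) {
    return(list(gene_id = NA_character_, n_junction_samples = as.integer(best_n)))
  }
  if (length(cand) > 1L) {
    # tie-break: nearest of the tied genes
    spans <- gene_spans(genes_c[genes_c$gene_id %in% cand, , drop = FALSE])
    d <- pmax(0L, pmax(spans$start - er$end, er$start - spans$end))
    cand <- spans$gene_id[order(d, spans$start)][1]
  }
  list(gene_id = cand[1], n_junction_samples = as.integer(best_n))
}

#' Nearest gene to an expressed region
#'
#' Distance is the gap between the closest boundaries of the ER and the
#' gene's merged exon span (0 when they overlap); ties are broken by the
#' lower gene start coordinate.
#'
#' @param er One-row data.frame (`chrom`, `start`, `end`).
#' @param genes Exon table.
#' @return list with `gene_id` and `distance_bp`, or NULL when no gene is
#'   on the ER's chromosome.
#' @export
nearest_gene <- function(er, genes) {
  spans <- gene_spans(genes[genes$chrom == er$chrom, , drop = FALSE])
  if (is.null(spans) || !nrow(spans)) return(NULL)
  d <- pmax(0L, pmax(spans$start - er$end, er$start - spans$end))
  pick <- order(d, spans$start)[1]
  list(gene_id = spans$gene_id[pick], distance_bp = as.integer(d[pick]))
}

#' Maximum exon r-squared with an expressed region
#'
#' Squared Pearson correlation between the ER's expression and each exon of
#' a gene; the maximum across exons is returned. Constant exon profiles are
#' dropped; a constant ER profile (or no usable exon) is an error.
#'
#' @param er_expr Numeric vector of ER expression by sample.
#' @param exon_expr Matrix (exons x samples) for the gene's exons, columns
#'   aligned with `er_expr`.
#' @return Maximum r-squared in \[0, 1\].
#' @export
max_exon_r2 <- function(er_expr, exon_expr) {
  if (length(er_expr) < 3) stop("need at least 3 shared samples")
  if (stats::sd(er_expr) == 0) stop("constant ER expression: correlation undefined")
  exon_expr <- matrix(exon_expr, ncol = length(er_expr))
  keep <- apply(exon_expr, 1, stats::sd) > 0
  if (!any(keep)) stop("all exon profiles constant: correlation undefined")
  max(apply(exon_expr[keep, , drop = FALSE], 1,
            function(e) stats::cor(er_expr, e)^2))
}

#' Classify one expressed region into an evidence tier
#'
#' Precedence: `strong` when split-read junctions link the ER to a gene in
#' at least `min_split_samples` distinct samples; otherwise `moderate` when
#' the maximum exon r-squared with the nearest gene exceeds `r2_min` AND the
#' ER lies closer than `max_distance_bp`; otherwise `weak`. With no gene on
#' the chromosome or an undefined correlation the tier is `unclassified`.
#'
#' @param er One-row ER data.frame (`chrom`, `start`, `end`, `id`).
#' @param reads Split read data.frame.
#' @param genes Exon table.
#' @param er_expr ER expression by sample (may be NULL: r2 unavailable).
#' @param exon_expr Exon expression matrix with rownames matching
#'   `genes$exon_id` (may be NULL).
#' @param thresholds Threshold list (see [default_thresholds()]).
#' @return One-row data.frame: `er_id`, `tier`, `linked_gene`, `max_r2`,
#'   `distance_bp`, `n_junction_samples`.
#' @export
classify_er <- function(er, reads, genes, er_expr = NULL, exon_expr = NULL,
                        thresholds = default_thresholds()) {
  link <- link_by_split_reads(er, reads, genes,
                              min_samples = thresholds$min_split_samples)
  near <- nearest_gene(er, genes)
  max_r2 <- NA_real_
  if (!is.null(near) && !is.null(er_expr) && !is.null(exon_expr)) {
    exons <- genes$exon_id[genes$gene_id == near$gene_id]
    exons <- intersect(exons, rownames(exon_expr))
    if (length(exons)) {
      max_r2 <- tryCatch(
        max_exon_r2(er_expr, exon_expr[exons, , drop = FALSE]),
        error = function(e) NA_real_
      )
    }
  }
  tier <- if (!is.na(link$gene_id)) {
    "strong"
  } else if (is.null(near)) {
    "unclassified"
  } else if (is.na(max_r2)) {
    "unclassified"
  } else if (max_r2 > thresholds$r2_min &&
             near$distance_bp < thresholds$max_distance_bp) {
    "moderate"
  } else {
    "weak"
  }
  linked <- if (tier == "strong") link$gene_id
  else if (tier %in% c("moderate", "weak")) near$gene_id
  else NA_character_
  data.frame(
    er_id = er$id, tier = tier, linked_gene = linked,
    max_r2 = max_r2,
    distance_bp = if (is.null(near)) NA_integer_ else near$distance_bp,
    n_junction_samples = link$n_junction_samples,
    stringsAsFactors = FALSE
  )
}

#' Classify a table of expressed regions
#'
#' Applies [classify_er()] to every region. Regions no longer than 100 bp
#' (which the upstream discovery step should have removed) are kept but
#' flagged with a warning.
#'
#' @param regions ER data.frame (`chrom`, `start`, `end`, `id`).
#' @param reads Split read data.frame.
#' @param genes Exon table.
#' @param er_expr Matrix (ERs x samples) with rownames matching region ids,
#'   or NULL.
#' @param exon_expr Exon expression matrix, or NULL.
#' @param thresholds Threshold list.
#' @return data.frame with one classification row per region, input order.
#' @export
classify_ers <- function(regions, reads, genes, er_expr = NULL,
                         exon_expr = NULL, thresholds = default_thresholds()) {
  short <- regions$end - regions$start <= 100L
  if (any(short)) {
    warning(sum(short), " region(s) are <= 100 bp; upstream discovery",
            " normally removes these")
  }
  out <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
    ev <- if (!is.null(er_expr) && regions$id[i] %in% rownames(er_expr)) {
      er_expr[regions$id[i], ]
    }
    classify_er(regions[i, ], reads, genes, ev, exon_expr, thresholds)
  }))
  rownames(out) <- NULL
  out
}

#' Re-expression validation of a region
#'
#' TRUE when the region's RPKM exceeds `min_rpkm` in at least `min_frac`
#' of samples (the independent-dataset validation rule).
#'
#' @param er_expr_rpkm RPKM values by sample (>= 1 sample).
#' @param min_rpkm Strict RPKM threshold.
#' @param min_frac Minimum fraction of samples (inclusive).
#' @return Logical flag.
#' @export
validate_expression <- function(er_expr_rpkm, min_rpkm = 0.1, min_frac = 0.8) {
  if (!length(er_expr_rpkm)) stop("need at least one sample")
  mean(er_expr_rpkm > min_rpkm) >= min_frac
}

#' Enhancer overlap statistics for two interval sets
#'
#' Each set is collapsed (self-overlaps merged) and intersected with the
#' merged enhancer set. For each set the percentage of its bases inside
#' enhancers is reported, along with the same percentage normalized per Mb
#' of set size (adjusting for annotation size) and the target/reference
#' fold change of the per-Mb values.
#'
#' @param targets,reference,enhancers Interval data.frames
#'   (`chrom`, `start`, `end`).
#' @return list: `pct_overlap_targets`, `pct_overlap_reference`,
#'   `pct_per_mb_targets`, `pct_per_mb_reference`, `fold` (NA with a
#'   warning when the reference has zero enhancer overlap).
#' @export
enhancer_overlap_stats <- function(targets, reference, enhancers) {
  measure <- function(set) {
    gr <- GenomicRanges::reduce(intervals_to_granges(set))
    total <- sum(BiocGenerics::width(gr))
    enh <- GenomicRanges::reduce(intervals_to_granges(enhancers))
    ov <- sum(BiocGenerics::width(GenomicRanges::intersect(gr, enh)))
    c(total = total, overlap = ov)
  }
  t_m <- measure(targets)
  r_m <- measure(reference)
  pct_t <- 100 * t_m["overlap"] / t_m["total"]
  pct_r <- 100 * r_m["overlap"] / r_m["total"]
  per_mb_t <- pct_t / (t_m["total"] / 1e6)
  per_mb_r <- pct_r / (r_m["total"] / 1e6)
  fold <- if (r_m["overlap"] == 0) {
    warning("reference has zero enhancer overlap; fold undefined")
    NA_real_
  } else unname(per_mb_t / per_mb_r)
  list(pct_overlap_targets = unname(pct_t),
       pct_overlap_reference = unname(pct_r),
       pct_per_mb_targets = unname(per_mb_t),
       pct_per_mb_reference = unname(per_mb_r),
       fold = fold)
}
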