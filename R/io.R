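# Readers/writers for every external table the pipeline touches.
# Internal coordinate convention: 0-based, half-open (BED) everywhere;
# 1-based inputs (VCF POS) are converted at the boundary.

fmt_num <- function(x) {
  # shortest representation that survives a write -> read round trip
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    s <- sprintf("%.15g", v)
    if (as.numeric(s) != v) s <- sprintf("%.17g", v)
    s
  }, "")
  out
}

#' Read a genotype matrix from a minimal VCF or a dosage TSV
#'
#' VCF input uses the GT field when present (hard genotypes 0/1/2 counted as
#' minor-allele, i.e. ALT, copies) or otherwise the DS dosage field. Dosage
#' TSV input has columns `snp_id`, `chrom`, `pos` (0-based) followed by one
#' column per sample. VCF POS (1-based) is converted to the internal 0-based
#' convention. Missing genotypes become `NA` and are never imputed.
#'
#' @param path Path to a `.vcf` file or a dosage TSV.
#' @return A `genotype_matrix`: list with `dosage` (samples x SNPs numeric
#'   matrix, values in \[0, 2\] or `NA`), `snps` (data.frame `snp_id`,
#'   `chrom`, `pos`), and logical `hard_calls` (TRUE when all non-missing
#'   dosages are 0/1/2).
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  first <- readLines(path, n = 1L)
  if (grepl("^##fileformat=VCF", first)) {
    read_genotypes_vcf(path)
  } else {
    read_genotypes_tsv(path)
  }
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n_snp <- nrow(fix)
  if (n_snp == 0L) stop("VCF contains no variant records: ", path)
  fmt_keys <- strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)
  use_gt <- all(vapply(fmt_keys, function(k) "GT" %in% k, TRUE))
  use_ds <- all(vapply(fmt_keys, function(k) "DS" %in% k, TRUE))
  if (use_gt) {
    gt <- vcfR::extract.gt(v, element = "GT")
    dos <- matrix(NA_real_, nrow = n_snp, ncol = ncol(gt))
    clean <- gsub("|", "/", gt, fixed = TRUE)
    dos[clean %in% c("0/0")] <- 0
    dos[clean %in% c("0/1", "1/0")] <- 1
    dos[clean %in% c("1/1")] <- 2
    bad <- !is.na(gt) & is.na(dos) & !clean %in% c("./.", ".")
    if (any(bad)) {
      i <- which(bad, arr.ind = TRUE)[1, ]
      stop(sprintf("malformed GT '%s' at variant %s", gt[i[1], i[2]], fix[i[1], "ID"]))
    }
    dimnames(dos) <- dimnames(gt)
  } else if (use_ds) {
    dos <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    stop("VCF has neither GT nor DS in FORMAT: ", path)
  }
  if (any(dos < 0 | dos > 2, na.rm = TRUE)) {
    bad <- which(dos < 0 | dos > 2, arr.ind = TRUE)[1, ]
    stop(sprintf("dosage outside [0,2] at variant %s", fix[bad[1], "ID"]))
  }
  new_genotype_matrix(
    dosage = t(dos),
    snps = data.frame(
      snp_id = fix[, "ID"],
      chrom = fix[, "CHROM"],
      pos = as.integer(fix[, "POS"]) - 1L,  # VCF is 1-based
      stringsAsFactors = FALSE
    )
  )
}

read_genotypes_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos")
  if (!all(need %in% names(d))) {
    stop("dosage TSV must have columns snp_id, chrom, pos: ", path)
  }
  sample_cols <- setdiff(names(d), need)
  if (!length(sample_cols)) stop("dosage TSV has no sample columns: ", path)
  dos <- as.matrix(d[, sample_cols, drop = FALSE])
  if (!is.numeric(dos)) {
    bad_row <- which(apply(d[, sample_cols, drop = FALSE], 1,
                           function(r) any(is.na(suppressWarnings(as.numeric(r))) & r != "NA")))[1]
    stop(sprintf("malformed dosage record at line %d of %s", bad_row + 1L, path))
  }
  out_of_range <- which(dos < 0 | dos > 2, arr.ind = TRUE)
  if (nrow(out_of_range)) {
    stop(sprintf("dosage outside [0,2] at line %d of %s",
                 out_of_range[1, 1] + 1L, path))
  }
  storage.mode(dos) <- "double"
  dos <- t(dos)
  colnames(dos) <- d$snp_id
  new_genotype_matrix(
    dosage = dos,
    snps = data.frame(snp_id = d$snp_id, chrom = d$chrom,
                      pos = as.integer(d$pos), stringsAsFactors = FALSE)
  )
}

new_genotype_matrix <- function(dosage, snps) {
  stopifnot(ncol(dosage) == nrow(snps))
  colnames(dosage) <- snps$snp_id
  vals <- dosage[!is.na(dosage)]
  structure(
    list(dosage = dosage, snps = snps,
         hard_calls = all(vals %in% c(0, 1, 2))),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%s)\n",
              nrow(x$dosage), ncol(x$dosage),
              if (x$hard_calls) "hard calls" else "dosages"))
  invisible(x)
}

#' Write a genotype matrix as a dosage TSV
#'
#' Inverse of [read_genotypes()] for the TSV representation; a write
#' followed by a read returns an identical matrix.
#'
#' @param g `genotype_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  samples <- rownames(g$dosage)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(g$dosage)))
  d <- data.frame(g$snps, t(g$dosage), check.names = FALSE,
                  stringsAsFactors = FALSE)
  names(d) <- c(names(g$snps), samples)
  for (s in samples) d[[s]] <- fmt_num(d[[s]])
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genotype matrix as a minimal VCF
#'
#' Hard-call matrices are written with GT fields (0/0, 0/1, 1/1), fractional
#' dosages with DS fields. Internal 0-based positions become 1-based VCF POS.
#' REF/ALT are placeholders (A/C) unless given in `g$snps`.
#'
#' @param g `genotype_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  samples <- rownames(g$dosage)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(g$dosage)))
  ref <- if (!is.null(g$snps$ref)) g$snps$ref else rep("A", nrow(g$snps))
  alt <- if (!is.null(g$snps$alt)) g$snps$alt else rep("C", nrow(g$snps))
  hdr <- c(
    "##fileformat=VCFv4.2",
    if (g$hard_calls) '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
    else '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Dosage">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(g$snps)), function(i) {
    dos <- g$dosage[, i]
    cells <- if (g$hard_calls) {
      c("0/0", "0/1", "1/1", "./.")[ifelse(is.na(dos), 4L, dos + 1L)]
    } else {
      ifelse(is.na(dos), ".", fmt_num(dos))
    }
    paste(c(g$snps$chrom[i], g$snps$pos[i] + 1L, g$snps$snp_id[i],
            ref[i], alt[i], ".", "PASS", ".",
            if (g$hard_calls) "GT" else "DS", cells), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read genomic intervals from a BED file
#'
#' BED3 or more columns; 0-based half-open coordinates are retained as-is.
#' Input order is preserved. A missing 4th column yields ids
#' `iv1, iv2, ...`.
#'
#' @param path BED file path.
#' @return data.frame with `chrom`, `start`, `end`, `id`.
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), id = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "[ \t]+")
  n_fields <- lengths(fields)
  if (any(n_fields < 3)) {
    stop(sprintf("BED line %d has fewer than 3 columns", which(n_fields < 3)[1]))
  }
  chrom <- vapply(fields, `[[`, "", 1)
  start_c <- vapply(fields, `[[`, "", 2)
  end_c <- vapply(fields, `[[`, "", 3)
  start <- suppressWarnings(as.integer(start_c))
  end <- suppressWarnings(as.integer(end_c))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop(sprintf("non-numeric coordinate at BED line %d", bad[1]))
  rev_iv <- which(start >= end)
  if (length(rev_iv)) {
    stop(sprintf("start >= end at BED line %d (%s:%s-%s)",
                 rev_iv[1], chrom[rev_iv[1]], start_c[rev_iv[1]], end_c[rev_iv[1]]))
  }
  id <- ifelse(n_fields >= 4, vapply(fields, function(f) f[min(4, length(f))], ""),
               paste0("iv", seq_along(fields)))
  data.frame(chrom = chrom, start = start, end = end, id = id,
             stringsAsFactors = FALSE)
}

#' Write genomic intervals as BED4
#'
#' @param intervals data.frame with `chrom`, `start`, `end`, `id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end", "id") %in% names(intervals)))
  utils::write.table(intervals[, c("chrom", "start", "end", "id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Convert an interval data.frame to GRanges
#'
#' Internal 0-based half-open intervals become the 1-based closed ranges
#' GRanges expects.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` and optional `id`.
#' @return `GRanges` with names taken from `id` if present.
#' @export
intervals_to_granges <- function(intervals) {
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L, end = intervals$end)
  )
  if (!is.null(intervals$id)) names(gr) <- intervals$id
  gr
}

#' Read GWAS summary statistics
#'
#' Expects a header row with a SNP id column (`snp_id`, `snp`, `SNP` or
#' `rsid`) and a p-value column (`p_value`, `p`, `pval` or `pvalue`).
#' Zero p-values are rejected (their -log10 transform is undefined), as are
#' duplicate SNP ids.
#'
#' @param path TSV file path.
#' @return data.frame with `snp_id`, `p_value`.
#' @export
read_gwas <- function(path) {
  if (!file.exists(path)) stop("GWAS file not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  id_col <- intersect(c("snp_id", "snp", "SNP", "rsid"), names(d))[1]
  p_col <- intersect(c("p_value", "p", "pval", "pvalue"), names(d))[1]
  if (is.na(id_col) || is.na(p_col)) {
    stop("GWAS table needs a SNP id column and a p-value column: ", path)
  }
  out <- data.frame(snp_id = as.character(d[[id_col]]),
                    p_value = as.numeric(d[[p_col]]),
                    stringsAsFactors = FALSE)
  if (anyNA(out$p_value)) {
    stop(sprintf("non-numeric p-value at line %d of %s",
                 which(is.na(out$p_value))[1] + 1L, path))
  }
  if (any(out$p_value <= 0)) {
    stop(sprintf("p-value <= 0 at line %d (-log10 undefined)",
                 which(out$p_value <= 0)[1] + 1L))
  }
  if (any(out$p_value > 1)) {
    stop(sprintf("p-value > 1 at line %d", which(out$p_value > 1)[1] + 1L))
  }
  dup <- duplicated(out$snp_id)
  if (any(dup)) stop("duplicate SNP id in GWAS table: ", out$snp_id[dup][1])
  out
}

#' Write GWAS summary statistics
#' @param gwas data.frame with `snp_id`, `p_value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gwas <- function(gwas, path) {
  out <- data.frame(snp_id = gwas$snp_id, p_value = fmt_num(gwas$p_value))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample allele count table
#'
#' Columns: `sample_id`, `snp_id`, `chrom`, `pos`, `allele1`, `allele2`,
#' `c1`, `c2`. Alleles must be ordered alphabetically (allele1 < allele2)
#' and counts non-negative.
#'
#' @param path TSV file path.
#' @return data.frame of allele counts.
#' @export
read_allele_counts <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "snp_id", "chrom", "pos", "allele1", "allele2", "c1", "c2")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("allele count table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(d$c1 < 0 | d$c2 < 0)) {
    stop(sprintf("negative count at line %d", which(d$c1 < 0 | d$c2 < 0)[1] + 1L))
  }
  if (any(d$allele1 >= d$allele2)) {
    stop(sprintf("alleles not in alphabetical order at line %d",
                 which(d$allele1 >= d$allele2)[1] + 1L))
  }
  d[, need]
}

#' Write a per-sample allele count table
#' @param counts Allele count data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_allele_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix (features x samples)
#'
#' First column `feature_id`, remaining columns one per sample.
#'
#' @param path TSV file path.
#' @return Numeric matrix with feature ids as rownames.
#' @export
read_expression <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(d)[1] != "feature_id") stop("first column must be feature_id: ", path)
  m <- as.matrix(d[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  rownames(m) <- d$feature_id
  m
}

#' Write an expression matrix (features x samples)
#' @param expr Numeric matrix, feature ids as rownames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  d <- data.frame(feature_id = rownames(expr), check.names = FALSE)
  for (j in seq_len(ncol(expr))) d[[colnames(expr)[j]]] <- fmt_num(expr[, j])
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a split-read junction table
#'
#' Columns: `sample_id`, `chrom`, `left_start`, `left_end`, `right_start`,
#' `right_end` (0-based half-open blocks). A gap must separate the blocks
#' (`left_end < right_start`).
#'
#' @param path TSV file path.
#' @return data.frame of split reads.
#' @export
read_split_reads <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "chrom", "left_start", "left_end",
            "right_start", "right_end")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("split read table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(d) && any(d$left_end >= d$right_start)) {
    stop(sprintf("split read without gap at line %d",
                 which(d$left_end >= d$right_start)[1] + 1L))
  }
  d[, need]
}

#' Write a split-read junction table
#' @param reads Split read data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_split_reads <- function(reads, path) {
  utils::write.table(reads, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
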