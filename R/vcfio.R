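#' Read a multi-sample VCF into a genotype matrix
#'
#' Loads all records of a VCF 4.x file (optionally gzip-compressed) in
#' file order, keeping only the GT field. Missing calls ("./." or ".")
#' are preserved as missing, never as reference. Records on the
#' mitochondrial contig, when one is named, are stored haploid:
#' homozygous-diploid calls are collapsed to a single allele copy and a
#' heterozygous mitochondrial call is rejected as a data inconsistency.
#'
#' @param path VCF file path.
#' @param mito_contig optional contig id to load as haploid (ploidy 1).
#' @param contig_lengths optional named vector of contig lengths,
#'   required only when the VCF header carries no `##contig` lines.
#' @return a [geno_matrix()].
#' @export
read_vcf <- function(path, mito_contig = NULL, contig_lengths = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(v@gt)[-1]
  if (nrow(fix) == 0) stop("VCF contains no records: ", path)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, samples))

  if (is.null(contig_lengths)) {
    meta <- v@meta[grepl("^##contig=", v@meta)]
    ids <- sub('.*[<,]ID=([^,>]+).*', "\\1", meta)
    lens <- suppressWarnings(as.numeric(sub('.*[<,]length=([0-9]+).*', "\\1", meta)))
    if (length(ids) == 0 || anyNA(lens)) {
      stop("VCF header has no usable ##contig lines; supply contig_lengths")
    }
    contig_lengths <- stats::setNames(lens, ids)
  }

  chrom <- unname(fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"])
  ref <- unname(fix[, "REF"])
  alt <- unname(fix[, "ALT"])
  alt[is.na(alt)] <- "."
  ref_len <- nchar(ref)
  alt_len <- vapply(strsplit(alt, ",", fixed = TRUE),
                    function(a) max(nchar(a)), integer(1))
  is_indel <- ref_len != 1L | (alt != "." & alt_len != 1L)

  n <- nrow(gt)
  m <- length(samples)
  a1 <- matrix(NA_integer_, n, m)
  a2 <- matrix(NA_integer_, n, m)
  gt_chr <- as.character(gt)
  gt_chr[is.na(gt_chr)] <- "."
  first <- sub("^([^/|]*).*$", "\\1", gt_chr)
  rest <- sub("^[^/|]*[/|]?", "", gt_chr)
  to_idx <- function(x) {
    x[x == "." | x == ""] <- NA_character_
    suppressWarnings(as.integer(x))
  }
  a1[] <- to_idx(first)
  a2[] <- to_idx(rest)   # haploid "1" has no separator: a2 stays NA

  ploidy <- rep(2L, n)
  if (!is.null(mito_contig)) {
    mi <- chrom == mito_contig
    ploidy[mi] <- 1L
    m1 <- a1[mi, , drop = FALSE]
    m2 <- a2[mi, , drop = FALSE]
    het <- !is.na(m1) & !is.na(m2) & m1 != m2
    if (any(het)) {
      w <- which(het, arr.ind = TRUE)[1, ]
      stop(sprintf(
        "heterozygous mitochondrial genotype for sample '%s' at %s:%d",
        samples[w[2]], mito_contig, pos[which(mi)[w[1]]]))
    }
    a2[mi, ] <- NA_integer_
  }

  n_alleles <- ifelse(alt == ".", 1L,
                      1L + lengths(strsplit(alt, ",", fixed = TRUE)))
  mx <- pmax(a1, a2, na.rm = TRUE)
  mx[is.na(a1) & is.na(a2)] <- 0L
  bad <- which(apply(mx, 1, max) >= n_alleles)
  if (length(bad) > 0) {
    stop(sprintf("allele index out of range at %s:%d",
                 chrom[bad[1]], pos[bad[1]]))
  }

  geno_matrix(chrom, pos, ref, alt, a1, a2, ploidy, is_indel,
              samples, contig_lengths)
}

#' Write a genotype matrix as an uncompressed VCF 4.2 file
#'
#' Emits contig header lines and GT-only genotype columns; haploid
#' sites are written with single-allele genotypes. Output is
#' deterministic: identical inputs produce byte-identical files.
#'
#' @param gm a [geno_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=fugupop",
    sprintf("##contig=<ID=%s,length=%d>",
            names(gm$contig_lengths), as.integer(gm$contig_lengths)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", gm$samples), collapse = "\t")
  ), con)
  if (n_sites(gm) == 0) return(invisible(path))
  f1 <- gm$a1
  f2 <- gm$a2
  g1 <- ifelse(is.na(f1), ".", as.character(f1))
  g2 <- ifelse(is.na(f2), ".", as.character(f2))
  gt <- matrix(paste(g1, g2, sep = "/"), nrow(g1), ncol(g1))
  hap <- gm$ploidy == 1L
  gt[hap, ] <- g1[hap, ]
  body <- paste(gm$chrom, gm$pos, ".", gm$ref, gm$alt, ".", "PASS", ".",
                "GT", sep = "\t")
  gt_str <- do.call(paste, c(split(gt, col(gt)), sep = "\t"))
  writeLines(paste(body, gt_str, sep = "\t"), con)
  invisible(path)
}

#' Filter sites the way VCFTOOLS does
#'
#' Reproduces the strict site filter
#' `-mac 2 -min-alleles 2 -max-missing-count 2`: a retained site is
#' biallelic (when `biallelic_only`), carries a minor allele count of at
#' least `min_mac` over non-missing calls, and has at most `max_missing`
#' missing genotype calls (individuals, not allele copies). Missing
#' genotypes are excluded from allele counts, never imputed as
#' reference. Multi-allelic sites are dropped, not split. Site order is
#' preserved and an empty result is allowed.
#'
#' @param gm a [geno_matrix()].
#' @param min_mac minimum minor allele count (default 2).
#' @param max_missing maximum missing genotype calls per site (default 2).
#' @param biallelic_only drop non-biallelic sites (default `TRUE`).
#' @return the filtered [geno_matrix()].
#' @export
filter_sites <- function(gm, min_mac = 2, max_missing = 2,
                         biallelic_only = TRUE) {
  stopifnot(min_mac >= 0, max_missing >= 0)
  if (n_sites(gm) == 0) return(gm)
  cnt <- .site_counts(gm, seq_len(n_samples(gm)))
  n_missing <- n_samples(gm) - cnt$n_ind

  n_alt_alleles <- ifelse(gm$alt == ".", 0L,
                          lengths(strsplit(gm$alt, ",", fixed = TRUE)))
  biallelic <- n_alt_alleles == 1L

  if (min_mac > 0) {
    # minor allele count = called copies minus the most frequent allele
    mac <- rep(NA_integer_, n_sites(gm))
    mac[biallelic] <- pmin(cnt$alt[biallelic],
                           cnt$n_copies[biallelic] - cnt$alt[biallelic])
    multi <- which(!biallelic & n_alt_alleles > 1L)
    for (i in multi) {
      a1 <- gm$a1[i, ]
      a2 <- if (gm$ploidy[i] == 2L) gm$a2[i, ] else NULL
      ok <- if (is.null(a2)) !is.na(a1) else !is.na(a1) & !is.na(a2)
      alleles <- c(a1[ok], a2[ok])
      mac[i] <- if (length(alleles) == 0) 0L else
        length(alleles) - max(tabulate(alleles + 1L, nbins = 1L + n_alt_alleles[i]))
    }
    mac[n_alt_alleles == 0L] <- 0L
  } else {
    mac <- rep(Inf, n_sites(gm))
  }

  keep <- n_missing <= max_missing & mac >= min_mac
  if (biallelic_only) keep <- keep & biallelic
  subset_geno(gm, sites = which(keep))
}

#' Write windowed statistics as TSV
#'
#' Coordinates are written 0-based half-open; missing statistics are
#' written as `NA`, mirroring the undefined entries of per-window
#' diversity-ratio tables.
#'
#' @param ws data.frame with columns `chrom`, `start`, `end`, `n_sites`
#'   and any number of statistic columns, sorted by (chrom, start).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_window_stats <- function(ws, path) {
  stopifnot(all(c("chrom", "start", "end", "n_sites") %in% names(ws)))
  if (nrow(ws) > 0) {
    # one contiguous block per contig, ascending starts inside it
    blocks <- rle(ws$chrom)$values
    same <- ws$chrom[-1] == ws$chrom[-nrow(ws)]
    if (anyDuplicated(blocks) || any(same & diff(ws$start) < 0)) {
      stop("windows must be sorted by (chrom, start)")
    }
  }
  utils::write.table(ws, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write intervals as BED
#'
#' @param bed data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `name`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(bed, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(bed))
  df <- bed[, cols, drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of regions
#' @param path BED path (first three columns used, optional fourth as name).
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open)
#'   and `name` when present.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  df$chrom <- as.character(df$chrom)
  if (ncol(df) >= 4) names(df)[4] <- "name"
  df[, seq_len(min(4, ncol(df))), drop = FALSE]
}
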