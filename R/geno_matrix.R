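#' Genotype matrix container
#'
#' The internal genotype model shared by every analysis in the package:
#' an ordered set of variant sites (autosomal diploid or mitochondrial
#' haploid) with per-sample allele indices, held as two integer matrices.
#'
#' @param chrom character vector of contig ids, one per site.
#' @param pos integer vector of 1-based positions (bp). Sites must be
#'   sorted non-decreasingly within each contig.
#' @param ref,alt character vectors of REF and ALT allele strings; a
#'   multi-allelic ALT is comma-separated, a monomorphic record is ".".
#' @param a1,a2 integer matrices (sites x samples) of allele indices
#'   (0 = REF, 1 = first ALT, ...). `NA` marks a missing call; for
#'   haploid sites `a2` is `NA` throughout.
#' @param ploidy integer vector per site, 2 (autosome) or 1 (mito).
#' @param is_indel logical vector per site.
#' @param samples character vector of sample ids (column order of
#'   `a1`/`a2`).
#' @param contig_lengths named numeric vector, contig id -> length (bp).
#'   Every contig occurring in `chrom` must be present.
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(chrom, pos, ref, alt, a1, a2, ploidy, is_indel,
                        samples, contig_lengths) {
  n <- length(pos)
  stopifnot(
    length(chrom) == n, length(ref) == n, length(alt) == n,
    length(ploidy) == n, length(is_indel) == n,
    is.matrix(a1), is.matrix(a2),
    nrow(a1) == n, nrow(a2) == n,
    ncol(a1) == length(samples), ncol(a2) == length(samples)
  )
  if (any(pos < 1L)) stop("positions must be >= 1")
  missing_contig <- setdiff(unique(chrom), names(contig_lengths))
  if (length(missing_contig) > 0) {
    stop("contig(s) absent from contig_lengths: ",
         paste(missing_contig, collapse = ", "))
  }
  if (n > 1) {
    same <- chrom[-1] == chrom[-n]
    if (any(same & diff(pos) < 0)) {
      stop("sites must be sorted non-decreasingly by position within contigs")
    }
  }
  dimnames(a1) <- dimnames(a2) <- list(NULL, samples)
  structure(
    list(chrom = as.character(chrom), pos = as.integer(pos),
         ref = as.character(ref), alt = as.character(alt),
         a1 = a1, a2 = a2,
         ploidy = as.integer(ploidy), is_indel = as.logical(is_indel),
         samples = as.character(samples),
         contig_lengths = contig_lengths),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d sites x %d samples on %d contig(s)\n",
              n_sites(x), n_samples(x), length(x$contig_lengths)))
  hap <- sum(x$ploidy == 1L)
  if (hap > 0) cat(sprintf("  %d haploid (mitochondrial) site(s)\n", hap))
  invisible(x)
}

#' Number of sites in a genotype matrix
#' @param gm a `geno_matrix`.
#' @return integer count.
#' @export
n_sites <- function(gm) length(gm$pos)

#' Number of samples in a genotype matrix
#' @param gm a `geno_matrix`.
#' @return integer count.
#' @export
n_samples <- function(gm) length(gm$samples)

#' Subset a genotype matrix by site index and/or sample
#'
#' @param gm a `geno_matrix`.
#' @param sites integer or logical index over sites (default: all).
#' @param samples character sample ids or index (default: all).
#' @return a `geno_matrix` restricted to the selection; contig lengths
#'   are kept in full so window coordinates stay valid.
#' @export
subset_geno <- function(gm, sites = NULL, samples = NULL) {
  si <- if (is.null(sites)) seq_len(n_sites(gm)) else seq_len(n_sites(gm))[sites]
  sj <- if (is.null(samples)) seq_len(n_samples(gm)) else {
    if (is.character(samples)) {
      j <- match(samples, gm$samples)
      if (anyNA(j)) stop("unknown sample(s): ",
                         paste(samples[is.na(j)], collapse = ", "))
      j
    } else seq_len(n_samples(gm))[samples]
  }
  geno_matrix(gm$chrom[si], gm$pos[si], gm$ref[si], gm$alt[si],
              gm$a1[si, sj, drop = FALSE], gm$a2[si, sj, drop = FALSE],
              gm$ploidy[si], gm$is_indel[si],
              gm$samples[sj], gm$contig_lengths)
}

#' Alternate-allele dosage matrix for biallelic sites
#'
#' @param gm a `geno_matrix`; every selected site must be biallelic.
#' @param sites optional site index.
#' @return integer matrix (sites x samples) of ALT-copy counts
#'   (0/1/2 diploid, 0/1 haploid), `NA` where the call is missing.
#' @export
dosage <- function(gm, sites = NULL) {
  si <- if (is.null(sites)) seq_len(n_sites(gm)) else seq_len(n_sites(gm))[sites]
  if (any(grepl(",", gm$alt[si], fixed = TRUE))) {
    stop("dosage() requires biallelic sites")
  }
  a1 <- gm$a1[si, , drop = FALSE]
  a2 <- gm$a2[si, , drop = FALSE]
  hap <- gm$ploidy[si] == 1L
  d <- a1
  dip <- which(!hap)
  d[dip, ] <- a1[dip, , drop = FALSE] + a2[dip, , drop = FALSE]
  d
}

# Per-site called allele-copy / ALT-copy / heterozygote counts over a
# sample column subset. A diploid individual with a half-missing call
# ("./1") is treated as missing entirely, matching dosage().
.site_counts <- function(gm, cols, sites = NULL) {
  si <- if (is.null(sites)) seq_len(n_sites(gm)) else seq_len(n_sites(gm))[sites]
  a1 <- gm$a1[si, cols, drop = FALSE]
  a2 <- gm$a2[si, cols, drop = FALSE]
  hap <- gm$ploidy[si] == 1L

  full <- !is.na(a1) & !is.na(a2)        # fully-called diploid calls
  full[hap, ] <- !is.na(a1[hap, , drop = FALSE])
  n_ind <- rowSums(full)
  n_copies <- ifelse(hap, n_ind, 2L * n_ind)

  alt1 <- (a1 > 0L) & full
  alt2 <- (a2 > 0L) & full
  alt2[hap, ] <- FALSE
  alt_count <- rowSums(alt1, na.rm = TRUE) + rowSums(alt2, na.rm = TRUE)

  het <- rowSums(full & (a1 != a2), na.rm = TRUE)
  het[hap] <- 0L

  list(n_copies = n_copies, alt = alt_count, n_het = het, n_ind = n_ind)
}
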