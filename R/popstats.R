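#' Per-site allele frequency in a sample group
#'
#' Counts are taken over non-missing calls only, respecting ploidy
#' (one copy per call at haploid mitochondrial sites).
#'
#' @param gm a [geno_matrix()].
#' @param group character vector of sample ids (non-empty).
#' @param sites optional site index (default: all sites).
#' @return data.frame with one row per site: `n_alleles_called`,
#'   `alt_count`, `freq` (ALT frequency; `NA` when every call in the
#'   group is missing).
#' @export
allele_freq <- function(gm, group, sites = NULL) {
  stopifnot(length(group) > 0)
  cols <- match(group, gm$samples)
  if (anyNA(cols)) stop("unknown sample(s): ",
                        paste(group[is.na(cols)], collapse = ", "))
  cnt <- .site_counts(gm, cols, sites)
  freq <- ifelse(cnt$n_copies > 0, cnt$alt / cnt$n_copies, NA_real_)
  data.frame(n_alleles_called = cnt$n_copies, alt_count = cnt$alt,
             freq = freq)
}

# Weir & Cockerham (1984) two-population variance components a, b, c
# for one biallelic diploid site, vectorised over sites.
# Inputs per group: n (called individuals), p (ALT freq), h (observed
# heterozygote proportion among called individuals).
.wc_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

# Hudson (1992) FST numerator/denominator from sample allele
# frequencies: num = (p1 - p2)^2, den = p1(1-p2) + p2(1-p1).
# Equals 1 - Hw/Hb; works for haploid or diploid data, is exactly 1
# iff the called data show a fixed difference, exactly 0 for equal
# frequencies, and never exceeds 1.
.hudson_components <- function(n1, p1, n2, p2) {
  list(num = (p1 - p2)^2,
       den = p1 * (1 - p2) + p2 * (1 - p1))
}

#' Per-site FST variance components between two groups
#'
#' Returns numerator and denominator separately so that windows can
#' combine sites as a ratio of sums; the per-site point estimate is
#' `num / den` where `den > 0` and undefined otherwise (for example at
#' sites monomorphic across both groups). Under the Weir-Cockerham
#' (1984) theta the numerator is the among-population component `a` and
#' the denominator `a + b + c`; the Weir-Cockerham estimator is defined
#' for diploid sites only. The Hudson (1992) estimator uses sample
#' allele frequencies (`num = (p1-p2)^2`,
#' `den = p1(1-p2) + p2(1-p1)`, i.e. `1 - Hw/Hb`) and accepts haploid
#' sites; its estimate is exactly 1 iff the called data show a fixed
#' difference, exactly 0 at equal frequencies, and never exceeds 1.
#'
#' @param gm a [geno_matrix()]; selected sites must be biallelic.
#' @param g1,g2 character vectors of sample ids (each with at least one
#'   called genotype at a site for that site's estimate to be defined).
#' @param estimator `"weir_cockerham"` (default) or `"hudson"`.
#' @param sites optional site index.
#' @return data.frame per site: `num`, `den`, `fst` (`num/den`, `NA`
#'   when undefined).
#' @export
fst_site <- function(gm, g1, g2, estimator = c("weir_cockerham", "hudson"),
                     sites = NULL) {
  estimator <- match.arg(estimator)
  si <- if (is.null(sites)) seq_len(n_sites(gm)) else seq_len(n_sites(gm))[sites]
  if (any(grepl(",", gm$alt[si], fixed = TRUE))) {
    stop("fst_site() requires biallelic sites")
  }
  c1 <- match(g1, gm$samples); c2 <- match(g2, gm$samples)
  if (anyNA(c1) || anyNA(c2)) stop("unknown sample(s) in group")
  s1 <- .site_counts(gm, c1, si)
  s2 <- .site_counts(gm, c2, si)
  if (estimator == "weir_cockerham") {
    if (any(gm$ploidy[si] == 1L)) {
      stop("Weir-Cockerham estimator requires diploid sites; use hudson")
    }
    ok <- s1$n_ind > 0 & s2$n_ind > 0
    p1 <- s1$alt / s1$n_copies; p2 <- s2$alt / s2$n_copies
    h1 <- s1$n_het / s1$n_ind;  h2 <- s2$n_het / s2$n_ind
    comp <- .wc_components(s1$n_ind, p1, h1, s2$n_ind, p2, h2)
    num <- comp$a
    den <- comp$a + comp$b + comp$c
  } else {
    ok <- s1$n_copies >= 1 & s2$n_copies >= 1
    p1 <- s1$alt / s1$n_copies; p2 <- s2$alt / s2$n_copies
    comp <- .hudson_components(s1$n_copies, p1, s2$n_copies, p2)
    num <- comp$num
    den <- comp$den
  }
  num[!ok] <- NA_real_
  den[!ok] <- NA_real_
  fst <- ifelse(!is.na(den) & den > 0, num / den, NA_real_)
  data.frame(num = num, den = den, fst = fst)
}

#' Per-site nucleotide diversity within a group
#'
#' Unbiased per-site heterozygosity `n_ref * n_alt / choose(n, 2)` over
#' the group's `n` called allele copies; undefined with fewer than two
#' called copies, 0 at monomorphic sites.
#'
#' @inheritParams allele_freq
#' @return numeric vector of per-site pi (NA where undefined).
#' @export
pi_site <- function(gm, group, sites = NULL) {
  cols <- match(group, gm$samples)
  if (anyNA(cols)) stop("unknown sample(s): ",
                        paste(group[is.na(cols)], collapse = ", "))
  cnt <- .site_counts(gm, cols, sites)
  n <- cnt$n_copies
  ifelse(n >= 2, (n - cnt$alt) * cnt$alt / choose(n, 2), NA_real_)
}

# Tajima (1989) constants for sample size n (allele copies)
.tajima_constants <- function(n) {
  stopifnot(n >= 3)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, e1 = e1, e2 = e2)
}

#' Tajima's D over a set of sites
#'
#' Standard Tajima (1989) statistic
#' `D = (pi_sum - S/a1) / sqrt(e1*S + e2*S*(S-1))` over the group's
#' segregating sites, with the usual a1..e2 constants for sample size n
#' in allele copies. Sites with different missingness are accepted; n
#' is taken as the median called-copy count across the supplied sites.
#'
#' @param gm a [geno_matrix()].
#' @param group character vector of sample ids.
#' @param sites optional site index defining the region.
#' @return scalar D; `NA` when the group has no segregating site among
#'   the supplied sites. Errors when fewer than 3 allele copies are
#'   called.
#' @export
tajima_d <- function(gm, group, sites = NULL) {
  cols <- match(group, gm$samples)
  if (anyNA(cols)) stop("unknown sample(s) in group")
  cnt <- .site_counts(gm, cols, sites)
  covered <- cnt$n_copies >= 2
  seg <- covered & cnt$alt > 0 & cnt$alt < cnt$n_copies
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  n <- stats::median(cnt$n_copies[covered])
  if (n < 3) stop("Tajima's D requires at least 3 called allele copies")
  pi_sum <- sum((cnt$n_copies[seg] - cnt$alt[seg]) * cnt$alt[seg] /
                  choose(cnt$n_copies[seg], 2))
  k <- .tajima_constants(n)
  (pi_sum - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Sliding windows over contigs
#'
#' Windows start at multiples of `step` and are clipped at the contig
#' end; every base pair of every contig is covered by at least one
#' window. A contig shorter than `size` yields the single clipped
#' window `[0, length)`.
#'
#' @param contig_lengths named numeric vector, contig -> length (bp).
#' @param size window size in bp.
#' @param step step in bp (`size >= step >= 1`).
#' @return data.frame `chrom`, `start`, `end` (0-based half-open),
#'   ordered by contig then start.
#' @export
sliding_windows <- function(contig_lengths, size, step = size) {
  stopifnot(size >= step, step >= 1)
  out <- lapply(names(contig_lengths), function(ch) {
    L <- contig_lengths[[ch]]
    n <- if (L <= size) 1L else as.integer(ceiling((L - size) / step)) + 1L
    start <- (seq_len(n) - 1L) * step
    data.frame(chrom = ch, start = start, end = pmin(start + size, L))
  })
  do.call(rbind, out)
}

# indices of sites falling in [start, end) per window, positions 1-based
.window_site_index <- function(gm, windows) {
  lapply(seq_len(nrow(windows)), function(i) {
    which(gm$chrom == windows$chrom[i] &
            gm$pos > windows$start[i] & gm$pos <= windows$end[i])
  })
}

#' Windowed population statistics
#'
#' Computes, per window, any subset of: `fst` (focal vs the pooled
#' complement, per-site variance components combined as a ratio of
#' sums), per-group nucleotide diversity (`pi_<group>`, the sum of
#' per-site pi divided by the window span in bp, so invariant positions
#' contribute zero), the diversity-ratio statistic
#' `pi_ratio_log2 = log2(mean over x in others of pi_x / pi_focal)`
#' (missing when the focal diversity is zero), and per-group Tajima's D
#' (`tajima_d_<group>`). Windows without sites report `n_sites = 0` and
#' missing statistics.
#'
#' @param gm a [geno_matrix()] of biallelic sites.
#' @param pm a [pop_map()].
#' @param windows data.frame from [sliding_windows()].
#' @param focal focal group label.
#' @param others character vector of complement group labels (disjoint
#'   from `focal`).
#' @param stats character subset of
#'   `c("fst", "pi", "pi_ratio_log2", "tajima_d")`.
#' @param estimator FST estimator passed to [fst_site()].
#' @return data.frame: window coordinates, `n_sites`, requested
#'   statistic columns.
#' @export
windowed_stats <- function(gm, pm, windows, focal, others,
                           stats = c("fst", "pi", "pi_ratio_log2"),
                           estimator = "weir_cockerham") {
  stopifnot(!(focal %in% others))
  stats <- match.arg(stats, c("fst", "pi", "pi_ratio_log2", "tajima_d"),
                     several.ok = TRUE)
  focal_samples <- group_samples(pm, focal)
  other_samples <- group_samples(pm, others)
  groups <- c(stats::setNames(list(focal_samples), focal),
              pm$groups[others])

  need_pi <- any(c("pi", "pi_ratio_log2") %in% stats)
  pi_mat <- if (need_pi) {
    matrix(unlist(lapply(groups, function(g) pi_site(gm, g))),
           nrow = n_sites(gm), ncol = length(groups),
           dimnames = list(NULL, names(groups)))
  } else NULL
  fst_comp <- if ("fst" %in% stats) {
    fst_site(gm, focal_samples, other_samples, estimator = estimator)
  } else NULL

  idx <- .window_site_index(gm, windows)
  out <- windows
  out$n_sites <- lengths(idx)

  if ("fst" %in% stats) {
    out$fst <- vapply(idx, function(ii) {
      num <- sum(fst_comp$num[ii], na.rm = TRUE)
      den <- sum(fst_comp$den[ii], na.rm = TRUE)
      if (length(ii) == 0 || den <= 0) NA_real_ else num / den
    }, numeric(1))
  }
  if (need_pi) {
    span <- out$end - out$start
    pi_by_group <- lapply(names(groups), function(gname) {
      vapply(seq_along(idx), function(i) {
        ii <- idx[[i]]
        if (length(ii) == 0) return(NA_real_)
        sum(pi_mat[ii, gname], na.rm = TRUE) / span[i]
      }, numeric(1))
    })
    names(pi_by_group) <- names(groups)
    if ("pi" %in% stats) {
      for (gname in names(groups)) {
        out[[paste0("pi_", gname)]] <- pi_by_group[[gname]]
      }
    }
    if ("pi_ratio_log2" %in% stats) {
      pf <- pi_by_group[[focal]]
      ratios <- vapply(others, function(x) pi_by_group[[x]], numeric(nrow(out)))
      if (is.null(dim(ratios))) ratios <- matrix(ratios, nrow = nrow(out))
      mean_ratio <- rowMeans(ratios, na.rm = FALSE) / pf
      # mean over species of (pi_x / pi_focal) = rowMeans(pi_x) / pi_focal
      out$pi_ratio_log2 <- ifelse(!is.na(pf) & pf > 0 & mean_ratio > 0,
                                  log2(mean_ratio), NA_real_)
    }
  }
  if ("tajima_d" %in% stats) {
    for (gname in names(groups)) {
      g <- groups[[gname]]
      out[[paste0("tajima_d_", gname)]] <- vapply(idx, function(ii) {
        if (length(ii) == 0) return(NA_real_)
        tryCatch(tajima_d(gm, g, sites = ii), error = function(e) NA_real_)
      }, numeric(1))
    }
  }
  out
}

#' LD decay curve from unphased genotype dosages
#'
#' For every intra-contig pair of biallelic diploid SNPs with pairwise
#' distance at most `max_dist` and both minor allele frequencies at
#' least `maf_min`, computes the Rogers-Huff style composite `r^2` as
#' the squared Pearson correlation of ALT-dosage vectors (complete
#' observations only), then bins pairs by distance and averages per
#' bin. Pairs where either site has zero dosage variance among the
#' jointly called samples are skipped.
#'
#' @param gm a [geno_matrix()] of biallelic sites.
#' @param group character vector of at least 4 sample ids.
#' @param max_dist maximum pair distance in bp (default 300000).
#' @param maf_min minor-allele-frequency floor (default 0.05).
#' @param bin_width distance bin width in bp (default 1000).
#' @return data.frame `distance_lo`, `distance_hi`, `mean_r2`,
#'   `n_pairs` over contiguous ascending bins (bins without pairs have
#'   `n_pairs = 0` and missing `mean_r2`).
#' @export
ld_decay <- function(gm, group, max_dist = 300000, maf_min = 0.05,
                     bin_width = 1000) {
  stopifnot(length(group) >= 4, maf_min >= 0, maf_min < 0.5)
  cols <- match(group, gm$samples)
  if (anyNA(cols)) stop("unknown sample(s) in group")

  use <- which(gm$ploidy == 2L & !grepl(",", gm$alt, fixed = TRUE) &
                 !gm$is_indel)
  cnt <- .site_counts(gm, cols, use)
  freq <- ifelse(cnt$n_copies > 0, cnt$alt / cnt$n_copies, NA_real_)
  maf <- pmin(freq, 1 - freq)
  use <- use[!is.na(maf) & maf >= maf_min]

  n_bins <- as.integer(ceiling(max_dist / bin_width))
  sum_r2 <- numeric(n_bins)
  n_pairs <- integer(n_bins)

  for (ch in unique(gm$chrom[use])) {
    si <- use[gm$chrom[use] == ch]
    if (length(si) < 2) next
    pos <- gm$pos[si]
    o <- order(pos)
    si <- si[o]; pos <- pos[o]
    D <- dosage(gm, si)[, cols, drop = FALSE]
    hi <- findInterval(pos + max_dist, pos)
    for (k in seq_along(si)) {
      if (hi[k] <= k) next
      j <- (k + 1):hi[k]
      d <- pos[j] - pos[k]
      r <- suppressWarnings(
        stats::cor(D[k, ], t(D[j, , drop = FALSE]),
                   use = "pairwise.complete.obs"))
      r2 <- as.numeric(r)^2
      ok <- !is.na(r2)
      if (!any(ok)) next
      b <- pmin(as.integer(ceiling(d[ok] / bin_width)), n_bins)
      add <- rowsum(r2[ok], b)
      bi <- as.integer(rownames(add))
      sum_r2[bi] <- sum_r2[bi] + add[, 1]
      n_pairs <- n_pairs + tabulate(b, n_bins)
    }
  }
  data.frame(
    distance_lo = (seq_len(n_bins) - 1L) * bin_width,
    distance_hi = pmin(seq_len(n_bins) * bin_width, max_dist),
    mean_r2 = ifelse(n_pairs > 0, sum_r2 / pmax(n_pairs, 1L), NA_real_),
    n_pairs = n_pairs
  )
}
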