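# Independent brute-force oracles, written scalar and straight from the
# published formulas, used to cross-check the vectorised implementations.

# Build a geno_matrix from a character matrix of GT strings
# ("0/0", "0/1", "./.", "1", ".", ...), sites in rows.
build_gm <- function(gt, chrom = NULL, pos = NULL, ref = NULL, alt = NULL,
                     ploidy = NULL, contig_lengths = NULL,
                     samples = NULL) {
  gt <- as.matrix(gt)
  n <- nrow(gt); m <- ncol(gt)
  if (is.null(chrom)) chrom <- rep("chr1", n)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  if (is.null(ref)) ref <- rep("A", n)
  if (is.null(alt)) alt <- rep("T", n)
  if (is.null(ploidy)) ploidy <- ifelse(grepl("[/|]", gt[, 1]), 2L, 1L)
  if (is.null(samples)) samples <- paste0("s", seq_len(m))
  if (is.null(contig_lengths)) {
    contig_lengths <- stats::setNames(
      tapply(pos, chrom, max) + 1000, sort(unique(chrom)))
    contig_lengths <- contig_lengths[unique(chrom)]
  }
  parse1 <- function(x) {
    p <- strsplit(x, "[/|]")[[1]]
    v <- suppressWarnings(as.integer(p))
    c(v, NA_integer_)[1:2]
  }
  a1 <- matrix(NA_integer_, n, m)
  a2 <- matrix(NA_integer_, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    v <- parse1(gt[i, j])
    a1[i, j] <- v[1]; a2[i, j] <- v[2]
  }
  geno_matrix(chrom, pos, ref, alt, a1, a2, ploidy,
              rep(FALSE, n), samples, contig_lengths)
}

# allele copies of one sample group at one site, NA-free
.called_copies <- function(gm, site, group) {
  j <- match(group, gm$samples)
  a1 <- gm$a1[site, j]; a2 <- gm$a2[site, j]
  if (gm$ploidy[site] == 1L) return(a1[!is.na(a1)])
  ok <- !is.na(a1) & !is.na(a2)
  c(a1[ok], a2[ok])
}

# Weir & Cockerham (1984) theta components for one biallelic diploid
# site and two populations, literal transcription with r = 2.
wc_oracle <- function(gm, site, g1, g2) {
  stats_for <- function(group) {
    j <- match(group, gm$samples)
    a1 <- gm$a1[site, j]; a2 <- gm$a2[site, j]
    ok <- !is.na(a1) & !is.na(a2)
    a1 <- a1[ok]; a2 <- a2[ok]
    n <- length(a1)
    p <- sum(a1 == 1) + sum(a2 == 1)
    list(n = n, p = p / (2 * n), h = sum(a1 != a2) / n)
  }
  s1 <- stats_for(g1); s2 <- stats_for(g2)
  if (s1$n == 0 || s2$n == 0) return(list(a = NA, b = NA, c = NA, theta = NA))
  r <- 2
  n_bar <- (s1$n + s2$n) / r
  n_c <- (r * n_bar - (s1$n^2 + s2$n^2) / (r * n_bar)) / (r - 1)
  p_bar <- (s1$n * s1$p + s2$n * s2$p) / (r * n_bar)
  s_sq <- (s1$n * (s1$p - p_bar)^2 + s2$n * (s2$p - p_bar)^2) /
    ((r - 1) * n_bar)
  h_bar <- (s1$n * s1$h + s2$n * s2$h) / (r * n_bar)
  a <- (n_bar / n_c) * (s_sq - (1 / (n_bar - 1)) *
        (p_bar * (1 - p_bar) - ((r - 1) / r) * s_sq - h_bar / 4))
  b <- (n_bar / (n_bar - 1)) * (p_bar * (1 - p_bar) -
        ((r - 1) / r) * s_sq - ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  cc <- h_bar / 2
  den <- a + b + cc
  list(a = a, b = b, c = cc,
       theta = if (!is.na(den) && den > 0) a / den else NA_real_)
}

# Hudson (1992) FST for one site via the 1 - Hw/Hb route: Hw is the
# average within-population heterozygosity, Hb the between-population
# heterozygosity. Algebraically equal to (p1-p2)^2 / (p1(1-p2)+p2(1-p1))
# but computed along a different path than the implementation.
hudson_oracle <- function(gm, site, g1, g2) {
  c1 <- .called_copies(gm, site, g1)
  c2 <- .called_copies(gm, site, g2)
  if (length(c1) < 1 || length(c2) < 1) {
    return(list(num = NA, den = NA, fst = NA))
  }
  p1 <- mean(c1 == 1); p2 <- mean(c2 == 1)
  hw <- p1 * (1 - p1) + p2 * (1 - p2)
  hb <- p1 * (1 - p2) + p2 * (1 - p1)
  list(num = unname(hb - hw), den = unname(hb),
       fst = if (hb > 0) unname(1 - hw / hb) else NA_real_)
}

# per-site pi as the literal average over all pairs of allele copies
pi_oracle <- function(gm, site, group) {
  cp <- .called_copies(gm, site, group)
  n <- length(cp)
  if (n < 2) return(NA_real_)
  diff <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) diff <- diff + (cp[i] != cp[j])
  unname(diff / choose(n, 2))
}

# Tajima (1989) D with constants recomputed from scratch for each call
tajima_oracle <- function(alt_counts, n) {
  seg <- alt_counts > 0 & alt_counts < n
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  pi_sum <- 0
  for (k in alt_counts[seg]) pi_sum <- pi_sum + 2 * k * (n - k) / (n * (n - 1))
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# random small two-group genotype configuration with fuzzed missingness
random_fst_config <- function() {
  n1 <- sample(2:10, 1); n2 <- sample(2:10, 1)
  draw <- function(n) {
    g <- replicate(n, sprintf("%d/%d", sample(0:1, 1), sample(0:1, 1)))
    miss <- runif(n) < 0.15
    g[miss] <- "./."
    g
  }
  repeat {
    g1 <- draw(n1); g2 <- draw(n2)
    gm <- build_gm(matrix(c(g1, g2), nrow = 1))
    grp1 <- gm$samples[seq_len(n1)]
    grp2 <- gm$samples[n1 + seq_len(n2)]
    cc1 <- .called_copies(gm, 1, grp1)
    cc2 <- .called_copies(gm, 1, grp2)
    if (length(cc1) >= 2 && length(cc2) >= 2) {
      return(list(gm = gm, g1 = grp1, g2 = grp2))
    }
  }
}

# the 5-site toy set exercising the three site-filter rules:
# a triallelic site, a singleton (mac = 1), a site with 3 missing
# calls, and two clean biallelic sites with mac >= 2
toy_filter_gm <- function() {
  gt <- rbind(
    c("0/1", "0/2", "0/0", "1/2", "0/0"),   # triallelic -> dropped
    c("0/0", "0/0", "0/0", "0/1", "0/0"),   # mac 1      -> dropped
    c("./.", "./.", "./.", "0/1", "0/1"),   # 3 missing  -> dropped
    c("0/1", "0/1", "0/0", "0/0", "./."),   # clean, mac 2, 1 missing
    c("1/1", "1/1", "0/0", "0/1", "0/0")    # clean, mac 5
  )
  alt <- c("T,G", "T", "T", "T", "T")
  build_gm(gt, pos = c(100L, 200L, 300L, 400L, 500L), alt = alt)
}

# write the same toy set as a VCF text file, returns the path
toy_filter_vcf <- function(path = tempfile(fileext = ".vcf")) {
  write_vcf(toy_filter_gm(), path)
  path
}

small_cfg <- function(seed = 1, ...) {
  sim_config(
    seed = seed,
    species = c(Tb = 4L, Tf = 4L, Tn = 4L, Tob = 4L),
    sister_pairs = list(c("Tb", "Tf"), c("Tn", "Tob")),
    contigs = c(chr1 = 5e5, chr2 = 5e5),
    mito_sites = 40L,
    ...
  )
}
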