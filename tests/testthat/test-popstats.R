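test_that("allele frequency counts non-missing copies and respects ploidy", {
  gm <- build_gm(rbind(c("0/0", "0/1", "1/1"),
                       c("0/0", "./.", "./.")))
  af <- allele_freq(gm, paste0("s", 1:3))
  # diploid {AA, Aa, aa} -> 3 of 6
  expect_equal(af$freq[1], 0.5)
  expect_equal(af$n_alleles_called[1], 6L)
  # {AA, ./., ./.} -> 2 called copies, freq 0
  expect_equal(af$n_alleles_called[2], 2L)
  expect_equal(af$freq[2], 0)

  hap <- build_gm(rbind(c("0", "1", "1")), ploidy = 1L)
  expect_equal(allele_freq(hap, paste0("s", 1:3))$freq, 2 / 3)

  all_missing <- build_gm(rbind(c("./.", "0/0")))
  expect_true(is.na(allele_freq(all_missing, "s1")$freq))
})

test_that("per-site FST matches fixed-difference and no-differentiation cases", {
  fixed <- build_gm(rbind(c("1/1", "1/1", "0/0", "0/0", "0/0")))
  g1 <- paste0("s", 1:2); g2 <- paste0("s", 3:5)
  expect_equal(fst_site(fixed, g1, g2, "weir_cockerham")$fst, 1)
  expect_equal(fst_site(fixed, g1, g2, "hudson")$fst, 1)

  same <- build_gm(rbind(rep(c("0/0", "0/1", "1/1"), 2)))
  ga <- paste0("s", 1:3); gb <- paste0("s", 4:6)
  expect_lte(fst_site(same, ga, gb, "weir_cockerham")$fst, 0)
  expect_equal(fst_site(same, ga, gb, "hudson")$fst, 0)

  mono <- build_gm(rbind(rep("0/0", 6)))
  res <- fst_site(mono, ga, gb, "weir_cockerham")
  expect_true(is.na(res$fst))
})

test_that("per-site FST equals the independent straight-from-formula value", {
  gm <- build_gm(matrix(c("0/0", "0/0", "0/1", "1/1", "1/1", "1/1"),
                        nrow = 1))
  g1 <- paste0("s", 1:3); g2 <- paste0("s", 4:6)
  expect_equal(fst_site(gm, g1, g2, "weir_cockerham")$fst, 0.8,
               tolerance = 1e-12)
  expect_equal(fst_site(gm, g1, g2, "hudson")$fst, 5 / 6,
               tolerance = 1e-12)
})

test_that("W-C and Hudson estimates agree with oracles on fuzzed configurations", {
  set.seed(42)
  for (rep in 1:200) {
    cf <- random_fst_config()
    wc <- fst_site(cf$gm, cf$g1, cf$g2, "weir_cockerham")
    orc <- wc_oracle(cf$gm, 1, cf$g1, cf$g2)
    if (!is.na(orc$theta)) {
      expect_equal(wc$fst, orc$theta, tolerance = 1e-12)
    }
    hu <- fst_site(cf$gm, cf$g1, cf$g2, "hudson")
    orh <- hudson_oracle(cf$gm, 1, cf$g1, cf$g2)
    expect_equal(hu$num, orh$num, tolerance = 1e-12)
    expect_equal(hu$den, orh$den, tolerance = 1e-12)
  }
})

test_that("Hudson estimate is 1 exactly iff a complete-data fixed difference, never above", {
  set.seed(99)
  hit_one <- FALSE
  for (rep in 1:300) {
    cf <- random_fst_config()
    fst <- fst_site(cf$gm, cf$g1, cf$g2, "hudson")$fst
    if (is.na(fst)) next
    expect_lte(fst, 1)
    cc1 <- fugupop:::.site_counts(cf$gm, match(cf$g1, cf$gm$samples))
    cc2 <- fugupop:::.site_counts(cf$gm, match(cf$g2, cf$gm$samples))
    fixed_diff <- (cc1$alt == 0 & cc2$alt == cc2$n_copies) |
      (cc1$alt == cc1$n_copies & cc2$alt == 0)
    if (fst == 1) {
      hit_one <- TRUE
      expect_true(fixed_diff)
    }
    if (fixed_diff) expect_equal(fst, 1)
  }
  expect_true(hit_one)   # the fuzz actually exercised the boundary
})

test_that("per-site pi matches the pairwise-difference definition", {
  gm <- build_gm(rbind(c("0/1", "0/1"),      # 2 ref + 2 alt copies
                       c("0/0", "0/0"),      # monomorphic
                       c("0",   "1")))       # one pair, one difference
  gm$ploidy[3] <- 1L
  grp <- c("s1", "s2")
  p <- pi_site(gm, grp)
  expect_equal(p[1], 4 / 6)
  expect_equal(p[2], 0)
  expect_equal(p[3], 1)

  set.seed(7)
  for (rep in 1:50) {
    cf <- random_fst_config()
    expect_equal(pi_site(cf$gm, cf$g1), pi_oracle(cf$gm, 1, cf$g1),
                 tolerance = 1e-12)
  }
})

test_that("Tajima's D agrees with the textbook-constant oracle", {
  # n = 6 copies, alt counts {1, 1, 2, 5}
  gt <- rbind(c("0/1", "0/0", "0/0"),
              c("0/0", "1/0", "0/0"),
              c("0/1", "0/0", "0/1"),
              c("1/1", "1/1", "0/1"))
  gm <- build_gm(gt)
  grp <- paste0("s", 1:3)
  expect_equal(tajima_d(gm, grp), -0.676126573150321, tolerance = 1e-10)
  expect_equal(tajima_d(gm, grp), tajima_oracle(c(1, 1, 2, 5), 6),
               tolerance = 1e-12)

  # no segregating site -> undefined, not 0
  mono <- build_gm(rbind(rep("0/0", 3), rep("1/1", 3)))
  expect_true(is.na(tajima_d(mono, paste0("s", 1:3))))

  # fewer than 3 called copies -> error
  tiny <- build_gm(rbind(c("0/1", "./.")))
  expect_error(tajima_d(tiny, c("s1", "s2")), "3 called")

  set.seed(123)
  for (rep in 1:30) {
    n_ind <- sample(3:8, 1)
    n <- 2 * n_ind
    counts <- sample(0:n, 12, replace = TRUE)
    gt <- t(vapply(counts, function(k) {
      copies <- sample(c(rep(1L, k), rep(0L, n - k)))
      paste(copies[seq(1, n, 2)], copies[seq(2, n, 2)], sep = "/")
    }, character(n_ind)))
    gm <- build_gm(gt)
    d_pkg <- tajima_d(gm, paste0("s", seq_len(n_ind)))
    d_orc <- tajima_oracle(counts, n)
    if (is.na(d_orc)) expect_true(is.na(d_pkg))
    else expect_equal(d_pkg, d_orc, tolerance = 1e-10)
  }
})

test_that("sliding windows cover every base with the expected count", {
  w <- sliding_windows(c(chr1 = 100000), 50000, 10000)
  expect_equal(w$start[1], 0)
  expect_equal(w$end[1], 50000)
  expect_lte(max(w$start), 90000)
  expect_equal(nrow(w), ceiling((100000 - 50000) / 10000) + 1)
  expect_equal(max(w$end), 100000)

  # size == step tiles without overlap
  t1 <- sliding_windows(c(chr1 = 100000), 20000, 20000)
  expect_equal(t1$start, seq(0, 80000, 20000))

  # contig shorter than the window: one clipped window
  short <- sliding_windows(c(chr1 = 30000), 50000, 10000)
  expect_equal(nrow(short), 1L)
  expect_equal(short$end, 30000)

  # coverage property on fuzzed geometries
  set.seed(5)
  for (rep in 1:20) {
    L <- sample(1000:100000, 1)
    size <- sample(100:5000, 1)
    step <- sample(seq_len(size), 1)
    w <- sliding_windows(c(c1 = L), size, step)
    expect_equal(w$start[1], 0)
    expect_equal(max(w$end), L)
    gaps <- w$start[-1] > w$end[-nrow(w)]
    expect_false(any(gaps))
  }
})

test_that("windowed diversity-ratio statistic follows its definition", {
  # focal polymorphic at 1 of 4 sites; each other group at all 4
  # -> every other group's window pi is 4x focal -> log2(mean 4) = 2
  het <- "0/1"; hom <- "0/0"
  gt <- rbind(c(het, het, het, het, het, het),
              c(hom, hom, het, het, het, het),
              c(hom, hom, het, het, het, het),
              c(hom, hom, het, het, het, het))
  gm <- build_gm(gt, pos = c(100L, 200L, 300L, 400L),
                 contig_lengths = c(chr1 = 1000))
  pm <- pop_map(c(s1 = "F", s2 = "F", s3 = "X", s4 = "X",
                  s5 = "Y", s6 = "Y"))
  w <- data.frame(chrom = "chr1", start = 0, end = 1000)
  ws <- windowed_stats(gm, pm, w, "F", c("X", "Y"),
                       stats = c("pi", "pi_ratio_log2"))
  expect_equal(ws$pi_ratio_log2, 2)
  expect_equal(ws$pi_X / ws$pi_F, 4)

  # identical diversity everywhere -> ratio statistic 0
  same <- build_gm(rbind(rep(het, 6)), contig_lengths = c(chr1 = 1000))
  ws0 <- windowed_stats(same, pm, w, "F", c("X", "Y"),
                        stats = c("pi", "pi_ratio_log2"))
  expect_equal(ws0$pi_ratio_log2, 0)

  # zero focal diversity -> missing ratio, never infinite
  gt2 <- rbind(c(hom, hom, het, het, het, het))
  gm2 <- build_gm(gt2, contig_lengths = c(chr1 = 1000))
  ws2 <- windowed_stats(gm2, pm, w, "F", c("X", "Y"),
                        stats = c("pi", "pi_ratio_log2"))
  expect_true(is.na(ws2$pi_ratio_log2))

  # a window with no sites reports n_sites 0 and missing stats
  w2 <- data.frame(chrom = "chr1", start = c(0, 500), end = c(500, 1000))
  ws3 <- windowed_stats(gm, pm, w2, "F", c("X", "Y"))
  expect_equal(ws3$n_sites[2], 0L)
  expect_true(is.na(ws3$fst[2]))
})

test_that("windowed FST is the ratio of summed per-site components", {
  sim <- simulate_cohort(small_cfg(seed = 21))
  gm <- subset_geno(sim$gm, sites = which(sim$gm$ploidy == 2L))
  w <- data.frame(chrom = "chr1", start = 0, end = 100000)
  ws <- windowed_stats(gm, sim$pm, w, "Tb", c("Tf", "Tn", "Tob"),
                       stats = "fst")
  focal <- group_samples(sim$pm, "Tb")
  rest <- group_samples(sim$pm, c("Tf", "Tn", "Tob"))
  ii <- which(gm$chrom == "chr1" & gm$pos >= 1 & gm$pos <= 100000)
  comp <- fst_site(gm, focal, rest, sites = ii)
  expect_equal(ws$fst,
               sum(comp$num, na.rm = TRUE) / sum(comp$den, na.rm = TRUE))
})

test_that("r2 is 1 for duplicated sites and symmetric under relabeling", {
  set.seed(31)
  col <- sample(c("0/0", "0/1", "1/1"), 8, replace = TRUE)
  swap <- chartr("01", "10", col)
  gm <- build_gm(rbind(col, col, swap), pos = c(100L, 600L, 1100L),
                 contig_lengths = c(chr1 = 10000))
  pmv <- paste0("s", 1:8)
  ld <- ld_decay(gm, pmv, max_dist = 2000, maf_min = 0.05,
                 bin_width = 500)
  # duplicated column at distance 500 and allele-swapped columns:
  # all three pairs are perfect LD (r2 invariant to ref/alt relabeling)
  expect_equal(sum(ld$n_pairs), 3L)
  expect_equal(ld$mean_r2[ld$n_pairs > 0], rep(1, 2))
})

test_that("r2 at unlinked sites matches the permutation-oracle baseline", {
  sim <- simulate_cohort(small_cfg(seed = 55, ld_block_mean = NULL))
  gm <- subset_geno(sim$gm, sites = which(sim$gm$ploidy == 2L))
  grp <- group_samples(sim$pm, "Tb")
  ld <- ld_decay(gm, grp, max_dist = 100000, maf_min = 0.1,
                 bin_width = 100000)

  # permutation oracle: break any linkage by shuffling each site's
  # genotypes independently, then recompute the same statistic
  set.seed(77)
  gmp <- gm
  for (i in seq_len(n_sites(gmp))) {
    o <- sample.int(n_samples(gmp))
    gmp$a1[i, ] <- gmp$a1[i, o]
    gmp$a2[i, ] <- gmp$a2[i, o]
  }
  ldp <- ld_decay(gmp, grp, max_dist = 100000, maf_min = 0.1,
                  bin_width = 100000)
  # both should sit near 1/(n-1) for n=4 samples; compare within
  # Monte-Carlo error of the permutation oracle
  se <- sqrt(2) / 3 / sqrt(min(ld$n_pairs, ldp$n_pairs))
  expect_lt(abs(ld$mean_r2 - ldp$mean_r2), 5 * se + 0.02)
})

test_that("mean r2 decays with distance on linked simulator output", {
  sim <- simulate_cohort(small_cfg(seed = 13, ld_block_mean = 20000))
  gm <- subset_geno(sim$gm, sites = which(sim$gm$ploidy == 2L))
  ld <- ld_decay(gm, group_samples(sim$pm, "Tn"), max_dist = 100000,
                 maf_min = 0.05, bin_width = 25000)
  # near-range LD clearly above far-range LD
  expect_gt(ld$mean_r2[1], ld$mean_r2[4] + 0.05)
  # non-increasing within a noise tolerance
  expect_true(all(diff(ld$mean_r2) < 0.03))
})
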