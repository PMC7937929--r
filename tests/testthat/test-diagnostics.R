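test_that("fixed-difference discovery includes and excludes the right sites", {
  # rows: fixed difference; focal not fixed; complement not fixed;
  # fixed same allele both sides (monomorphic)
  gt <- rbind(c("1/1", "1/1", "0/0", "0/0", "0/0"),
              c("1/1", "0/1", "0/0", "0/0", "0/0"),
              c("1/1", "1/1", "0/0", "0/1", "0/0"),
              c("0/0", "0/0", "0/0", "0/0", "0/0"))
  gm <- build_gm(gt)
  pm <- pop_map(c(s1 = "A", s2 = "A", s3 = "B", s4 = "B", s5 = "B"))
  panel <- find_diagnostic_sites(gm, pm, "A", "B")
  expect_equal(nrow(panel), 1L)
  expect_equal(panel$pos, 100L)
  expect_equal(panel$allele_a, "T")
  expect_equal(panel$allele_b, "A")
})

test_that("panel discovery is symmetric up to allele-side relabeling", {
  sim <- simulate_cohort(small_cfg(seed = 8))
  pab <- find_diagnostic_sites(sim$gm, sim$pm, "Tb", c("Tf", "Tn", "Tob"))
  pba <- find_diagnostic_sites(sim$gm, sim$pm, c("Tf", "Tn", "Tob"), "Tb")
  expect_equal(nrow(pab), nrow(pba))
  expect_equal(paste(pab$chrom, pab$pos), paste(pba$chrom, pba$pos))
  expect_equal(pab$allele_a, pba$allele_b)
  expect_equal(pab$allele_b, pba$allele_a)
})

test_that("simulator truth panel is recovered exactly, with Hudson FST 1 at every site", {
  cfg <- sim_config(seed = 14)
  sim <- simulate_cohort(cfg)
  labs <- names(cfg$species)
  for (sp in c("Tn", "Tb")) {
    panel <- find_diagnostic_sites(sim$gm, sim$pm, sp, setdiff(labs, sp))
    truth <- sim$truth$diagnostic_sites
    truth <- truth[truth$species == sp, ]
    expect_setequal(paste(panel$chrom, panel$pos),
                    paste(truth$chrom, truth$pos))
    expect_equal(nrow(panel), nrow(truth))   # no extras, nothing missed
  }
  # every panel site re-evaluated with Hudson FST gives exactly 1
  panel <- find_diagnostic_sites(sim$gm, sim$pm, "Tn", setdiff(labs, "Tn"))
  key <- paste(sim$gm$chrom, sim$gm$pos)
  si <- match(paste(panel$chrom, panel$pos), key)
  fst <- fst_site(sim$gm, group_samples(sim$pm, "Tn"),
                  group_samples(sim$pm, setdiff(labs, "Tn")),
                  estimator = "hudson", sites = si)$fst
  expect_true(all(fst == 1))
})

test_that("differentiated-site selection matches brute-force thresholding", {
  sim <- simulate_cohort(small_cfg(seed = 17))
  gm <- filter_sites(sim$gm, min_mac = 1, max_missing = 2)
  pm <- sim$pm
  panel <- find_differentiated_sites(gm, pm, "Tb", "Tf", fst_min = 0.8)

  ga <- group_samples(pm, "Tb"); gb <- group_samples(pm, "Tf")
  fa <- allele_freq(gm, ga)$freq
  fb <- allele_freq(gm, gb)$freq
  expected <- vapply(seq_len(n_sites(gm)), function(i) {
    orc <- wc_oracle(gm, i, ga, gb)
    !is.na(orc$theta) && orc$theta > 0.8 &&
      !is.na(fa[i]) && !is.na(fb[i]) &&
      ((fa[i] > 0.5) != (fb[i] > 0.5)) && fa[i] != 0.5 && fb[i] != 0.5
  }, logical(1))
  expect_setequal(paste(panel$chrom, panel$pos),
                  paste(gm$chrom[expected], gm$pos[expected]))

  # a fixed-difference panel is recovered at fst_min just below 1
  diag <- find_diagnostic_sites(gm, pm, "Tb", "Tf",
                                max_missing_per_group = n_samples(gm))
  near1 <- find_differentiated_sites(gm, pm, "Tb", "Tf",
                                     fst_min = 1 - 1e-9,
                                     estimator = "hudson",
                                     max_missing_per_group = n_samples(gm))
  expect_setequal(paste(near1$chrom, near1$pos),
                  paste(diag$chrom, diag$pos))
})

test_that("introgression ratio counts donor allele copies exactly", {
  # panel of 10 sites, side A = alt allele everywhere
  panel <- structure(
    data.frame(chrom = "chr1", pos = seq(100L, 1000L, 100L),
               allele_a = "T", allele_b = "A", is_indel = FALSE,
               stringsAsFactors = FALSE),
    pair = c("A", "B"), class = c("diag_panel", "data.frame"))

  # 8 homozygous recurrent (A side), 1 heterozygous, 1 homozygous donor
  gt <- matrix(c(rep("1/1", 8), "0/1", "0/0"), ncol = 1)
  gm <- build_gm(gt, pos = seq(100L, 1000L, 100L),
                 contig_lengths = c(chr1 = 10000))
  r <- introgression_ratio(gm, panel, "s1", direction = "B")
  expect_equal(r$introgression_ratio, 0.15)
  expect_equal(r$donor_allele_copies, 3L)
  expect_equal(r$n_sites_called, 10L)
  expect_equal(r$assigned_class, "admixed")

  # pure focal individual scores 0 and classes as pure
  pure <- build_gm(matrix(rep("1/1", 10), ncol = 1),
                   pos = seq(100L, 1000L, 100L),
                   contig_lengths = c(chr1 = 10000))
  rp <- introgression_ratio(pure, panel, "s1", direction = "B")
  expect_equal(rp$introgression_ratio, 0)
  expect_equal(rp$assigned_class, "pure")

  # zero called panel sites is an error naming the sample
  none <- build_gm(matrix(rep("./.", 10), ncol = 1),
                   pos = seq(100L, 1000L, 100L),
                   contig_lengths = c(chr1 = 10000))
  expect_error(introgression_ratio(none, panel, "s1"), "s1")
})

test_that("simulated F1 hybrids are heterozygous at every panel site with ratio 0.5", {
  hyb <- data.frame(sample = "H1", recurrent = "Tb", donor = "Tf",
                    generation = "F1", stringsAsFactors = FALSE)
  sim <- simulate_cohort(small_cfg(seed = 23, hybrids = hyb))
  panel <- truth_pair_panel(sim$truth, "Tb", "Tf", exclude_contig = "MT")
  r <- introgression_ratio(sim$gm, panel, "H1", direction = "B")
  expect_equal(r$introgression_ratio, 0.5)
  expect_true(all(r$per_site$donor_copies == 1L))
  expect_equal(sim$truth$hybrid_index$realized, 0.5)
})

test_that("mitochondrial lineage is the majority side with mismatches counted", {
  # 143 mito sites: 142 match side B (the maternal lineage), 1 side A
  n <- 143L
  gt <- matrix(c("1", rep("0", n - 1L)), ncol = 1)
  gm <- build_gm(gt, chrom = rep("MT", n), pos = seq_len(n) * 10L,
                 ploidy = rep(1L, n), contig_lengths = c(MT = 16500))
  panel <- structure(
    data.frame(chrom = "MT", pos = seq_len(n) * 10L, allele_a = "T",
               allele_b = "A", is_indel = FALSE, stringsAsFactors = FALSE),
    pair = c("Tb", "Tf"), class = c("diag_panel", "data.frame"))
  m <- mito_assign(gm, panel, "s1")
  expect_equal(m$assigned_lineage, "B")
  expect_equal(m$mismatch_count, 1L)
  expect_equal(m$matches_b, 142L)

  # all sites matching one side gives zero mismatches
  gt2 <- matrix(rep("1", n), ncol = 1)
  gm2 <- build_gm(gt2, chrom = rep("MT", n), pos = seq_len(n) * 10L,
                  ploidy = rep(1L, n), contig_lengths = c(MT = 16500))
  m2 <- mito_assign(gm2, panel, "s1")
  expect_equal(m2$assigned_lineage, "A")
  expect_equal(m2$mismatch_count, 0L)

  # heterozygous mito genotypes are a data inconsistency
  het <- build_gm(matrix("0/1", ncol = 1), chrom = "MT", pos = 10L,
                  ploidy = 2L, contig_lengths = c(MT = 16500))
  panel1 <- panel[1, ]
  attr(panel1, "pair") <- c("Tb", "Tf")
  class(panel1) <- c("diag_panel", "data.frame")
  expect_error(mito_assign(het, panel1, "s1"), "heterozygous")
})

test_that("maternal-donor hybrids carry donor mito regardless of autosomal ratio", {
  hyb <- data.frame(sample = c("H1", "H2"),
                    recurrent = "Tb", donor = "Tf",
                    generation = c("BC1", "BC2"),
                    maternal = "Tf", stringsAsFactors = FALSE)
  sim <- simulate_cohort(small_cfg(seed = 29, hybrids = hyb))
  mito_panel <- truth_pair_panel(sim$truth, "Tb", "Tf", contig = "MT")
  auto_panel <- truth_pair_panel(sim$truth, "Tb", "Tf",
                                 exclude_contig = "MT")
  for (h in c("H1", "H2")) {
    m <- mito_assign(sim$gm, mito_panel, h)
    expect_equal(m$assigned_lineage, "B")   # side B = Tf, the maternal side
    expect_equal(m$mismatch_count, 0L)
    r <- introgression_ratio(sim$gm, auto_panel, h, direction = "B")
    expect_lt(r$introgression_ratio, 0.5)   # autosomes mostly recurrent
  }
})

test_that("major-allele sourcing at polymorphic panel sites follows its definition", {
  panel <- structure(
    data.frame(chrom = "chr1", pos = c(100L, 200L, 300L, 400L),
               allele_a = "T", allele_b = "A", is_indel = FALSE,
               stringsAsFactors = FALSE),
    pair = c("A", "B"), class = c("diag_panel", "data.frame"))
  # query group of 5: freq of side A (alt) is 0.9, 0.9, 0.5, 0 by row
  gt <- rbind(c("1/1", "1/1", "1/1", "1/1", "1/0"),
              c("1/1", "1/1", "1/1", "1/1", "0/1"),
              c("1/1", "1/1", "0/1", "0/0", "0/0"),
              c("0/0", "0/0", "0/0", "0/0", "0/0"))
  gm <- build_gm(gt, pos = c(100L, 200L, 300L, 400L),
                 contig_lengths = c(chr1 = 10000))
  res <- het_major_allele_source(gm, panel, paste0("s", 1:5))
  # sites 1-2 polymorphic A-major; site 3 an exact tie; site 4 fixed
  expect_equal(res$fraction_a_major, 1.0)
  expect_equal(res$n_polymorphic, 2L)
  expect_equal(res$n_ties, 1L)

  # all ties -> undefined fraction
  tie <- build_gm(rbind(c("1/1", "0/0")), pos = 100L,
                  contig_lengths = c(chr1 = 10000))
  res2 <- het_major_allele_source(tie, panel[1, ], c("s1", "s2"))
  expect_true(is.na(res2$fraction_a_major))
  expect_equal(res2$n_ties, 1L)
})

test_that("two-pass discovery grows the panel after excluding hybrids", {
  hyb <- data.frame(sample = paste0("H", 1:2), recurrent = "Tb",
                    donor = "Tf", generation = c("BC1", "BC2"),
                    stringsAsFactors = FALSE)
  # panel of ~800 sites: the 0.01 admixture threshold is calibrated
  # for panels of several hundred sites, where a pure individual's
  # leave-one-out ratio sits well below it
  cfg <- sim_config(seed = 31,
                    species = c(Tb = 6L, Tf = 6L, Tn = 4L, Tob = 4L),
                    sister_pairs = list(c("Tb", "Tf"), c("Tn", "Tob")),
                    contigs = c(chr1 = 5e5, chr2 = 5e5),
                    mito_sites = 40L,
                    fixed_diff_density = 4e-4,
                    shared_poly_density = 1e-3,
                    recomb_tract_mean = 5e4,
                    hybrids = hyb)
  sim <- simulate_cohort(cfg)
  res <- two_pass_panel(sim$gm, sim$pm, "Tb", "Tf")

  # the hybrids are flagged (the BC2 via its discordant maternal
  # mitochondria when its diluted autosomal signal is ambiguous) and
  # no purebred is flagged with them
  expect_setequal(res$excluded, c("H1", "H2"))
  # hybrid heterozygosity suppresses the provisional panel; removing
  # the hybrids releases those sites: final panel is a strict superset
  k1 <- paste(res$provisional_panel$chrom, res$provisional_panel$pos)
  k2 <- paste(res$panel$chrom, res$panel$pos)
  expect_true(all(k1 %in% k2))
  expect_gt(nrow(res$panel), nrow(res$provisional_panel))
  # pass 2 recovers the full truth panel, mitochondrial sites included
  truth <- truth_pair_panel(sim$truth, "Tb", "Tf")
  expect_setequal(k2, paste(truth$chrom, truth$pos))
})

test_that("panel TSV round-trips through write_panel/read_panel", {
  sim <- simulate_cohort(small_cfg(seed = 5))
  panel <- find_diagnostic_sites(sim$gm, sim$pm, "Tb",
                                 c("Tf", "Tn", "Tob"))
  path <- tempfile(fileext = ".tsv")
  write_panel(panel, path)
  p2 <- read_panel(path, pair = attr(panel, "pair"))
  expect_equal(p2$pos, panel$pos)
  expect_equal(p2$allele_a, panel$allele_a)
  expect_equal(attr(p2, "pair"), attr(panel, "pair"))
})
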