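#' Simulation configuration for a multi-species resequencing cohort
#'
#' Defines the study conditions for the synthetic cohort generator:
#' species and sample sizes, contigs, planted species-specific fixed
#' differences, shared (possibly tree-discordant) polymorphism,
#' within-species diversity model, hybrid individuals with
#' recombination-delimited donor tracts, species-level homozygous donor
#' blocks, diversity-reduced sweep intervals and a haploid
#' mitochondrial contig.
#'
#' Defaults emulate a ten-species pufferfish cohort at desk scale: ten
#' species of five individuals on two 2 Mb autosomes plus a 16.5 kb
#' mitochondrial contig, one species-specific fixed difference per
#' 10 kb per species, and shared polymorphism dense enough
#' (one site per 100 bp) that per-species windowed diversity sits at
#' the realistic scale for this genus (about 5e-4 per bp in 50 kb
#' windows). The sister-pair topology (Tb-Tf, Tob-Tn, Tr-To, Tx-Toc,
#' Ta-Tp) governs concordant versus discordant allele sharing.
#'
#' @param seed integer seed driving all randomness.
#' @param species named integer vector, species label -> number of
#'   individuals.
#' @param sister_pairs list of character pairs defining the species
#'   tree's cherries; concordant shared polymorphism is confined to
#'   single species or a sister pair, discordant (ILS-like) sharing
#'   spans species from different pairs.
#' @param contigs named numeric vector of autosomal contig lengths (bp).
#' @param mito_contig,mito_length,mito_sites mitochondrial contig name,
#'   length (bp) and number of species-assigned haploid sites.
#' @param fixed_diff_density per-bp rate of species-specific fixed
#'   differences, per species.
#' @param shared_poly_density per-bp rate of shared polymorphic sites.
#' @param ils_fraction fraction of shared sites whose carrier set is
#'   tree-discordant.
#' @param diversity_model `"neutral"` (derived-copy count drawn with
#'   probability proportional to 1/i — the constant-size neutral site
#'   frequency spectrum) or `"beta"` (population frequency drawn from
#'   `Beta(diversity_beta[1], diversity_beta[2])`, genotypes
#'   Hardy-Weinberg).
#' @param diversity_beta length-2 numeric, the Beta shape parameters
#'   used when `diversity_model = "beta"`.
#' @param ld_block_mean mean length (bp) of within-species haplotype
#'   blocks: shared sites inside one block assign their derived copies
#'   through a shared slot permutation, so genotype correlation (and
#'   hence `r^2`) decays from high within-block values to the
#'   unlinked-sampling baseline `1/(n-1)` at this distance scale.
#'   `NULL` disables linkage (every site independent). Allele
#'   frequencies and per-site counts are unaffected, so diversity,
#'   Tajima's D and panel structure do not change.
#' @param indel_fraction fraction of planted sites emitted as 1 bp
#'   insertions rather than SNPs.
#' @param missing_rate per-genotype missing-call rate (default 0: the
#'   generator emulates a post-QC callset).
#' @param hybrids data.frame with columns `sample`, `recurrent`,
#'   `donor`, `generation` (`"F1"`, `"BC1"`, `"BC2"`, ... or a numeric
#'   donor fraction as character) and optionally `maternal` (defaults
#'   to the donor species, the maternal side of the emulated
#'   asymmetric cross).
#' @param recomb_tract_mean mean donor/recurrent tract length in bp
#'   (exponential tiling).
#' @param sweeps data.frame `species`, `chrom`, `start`, `end` (0-based
#'   half-open), `factor` (> 1): within the interval the species'
#'   shared-site heterozygosity is thinned so expected diversity drops
#'   by `factor`.
#' @param donor_blocks data.frame `species`, `donor`, `chrom`, `start`,
#'   `end`: inside the block every individual of `species` draws both
#'   allele copies from the donor's frequencies, planting a
#'   species-level homozygous introgression tract.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(
    seed = 1L,
    species = c(Tb = 5L, Tf = 5L, Tn = 5L, Tob = 5L, Tx = 5L,
                Toc = 5L, Tr = 5L, To = 5L, Ta = 5L, Tp = 5L),
    sister_pairs = list(c("Tb", "Tf"), c("Tob", "Tn"), c("Tr", "To"),
                        c("Tx", "Toc"), c("Ta", "Tp")),
    contigs = c(chr1 = 2e6, chr2 = 2e6),
    mito_contig = "MT", mito_length = 16500, mito_sites = 150L,
    fixed_diff_density = 1e-4,
    shared_poly_density = 1e-2,
    ils_fraction = 0.05,
    diversity_model = c("neutral", "beta"),
    diversity_beta = c(0.5, 0.5),
    ld_block_mean = 20000,
    indel_fraction = 0.1,
    missing_rate = 0,
    hybrids = NULL,
    recomb_tract_mean = 3e5,
    sweeps = NULL,
    donor_blocks = NULL) {
  diversity_model <- match.arg(diversity_model)
  stopifnot(fixed_diff_density >= 0, shared_poly_density >= 0,
            ils_fraction >= 0, ils_fraction <= 1,
            indel_fraction >= 0, indel_fraction <= 1,
            missing_rate >= 0, missing_rate < 1,
            recomb_tract_mean > 0, all(species >= 1))
  if (is.null(hybrids)) {
    hybrids <- data.frame(sample = character(), recurrent = character(),
                          donor = character(), generation = character(),
                          maternal = character(), stringsAsFactors = FALSE)
  }
  if (!"maternal" %in% names(hybrids)) hybrids$maternal <- hybrids$donor
  if (is.null(sweeps)) {
    sweeps <- data.frame(species = character(), chrom = character(),
                         start = numeric(), end = numeric(),
                         factor = numeric(), stringsAsFactors = FALSE)
  }
  if (is.null(donor_blocks)) {
    donor_blocks <- data.frame(species = character(), donor = character(),
                               chrom = character(), start = numeric(),
                               end = numeric(), stringsAsFactors = FALSE)
  }
  labs <- names(species)
  bad <- setdiff(c(hybrids$recurrent, hybrids$donor, hybrids$maternal,
                   sweeps$species, donor_blocks$species,
                   donor_blocks$donor), labs)
  if (length(bad) > 0) stop("unknown species referenced: ",
                            paste(unique(bad), collapse = ", "))
  if (nrow(sweeps) > 0) {
    stopifnot(all(sweeps$factor > 1),
              all(sweeps$chrom %in% names(contigs)),
              all(sweeps$start >= 0),
              all(sweeps$end <= contigs[sweeps$chrom]))
  }
  if (nrow(donor_blocks) > 0) {
    stopifnot(all(donor_blocks$chrom %in% names(contigs)),
              all(donor_blocks$start >= 0),
              all(donor_blocks$end <= contigs[donor_blocks$chrom]))
  }
  structure(list(
    seed = as.integer(seed), species = species,
    sister_pairs = sister_pairs, contigs = contigs,
    mito_contig = mito_contig, mito_length = mito_length,
    mito_sites = as.integer(mito_sites),
    fixed_diff_density = fixed_diff_density,
    shared_poly_density = shared_poly_density,
    ils_fraction = ils_fraction,
    diversity_model = diversity_model, diversity_beta = diversity_beta,
    ld_block_mean = ld_block_mean,
    indel_fraction = indel_fraction, missing_rate = missing_rate,
    hybrids = hybrids, recomb_tract_mean = recomb_tract_mean,
    sweeps = sweeps, donor_blocks = donor_blocks
  ), class = "sim_config")
}

# derived-copy count for one species at a segregating site
.draw_seg_counts <- function(n_draws, n_copies, model, beta_shape) {
  if (n_copies < 2) return(rep(0L, n_draws))
  if (model == "neutral") {
    i <- seq_len(n_copies - 1)
    sample(i, n_draws, replace = TRUE, prob = 1 / i)
  } else {
    p <- stats::rbeta(n_draws, beta_shape[1], beta_shape[2])
    stats::rbinom(n_draws, n_copies, p)
  }
}

# carrier-set draw: concordant = a clade (single species or sister
# pair); discordant = two species from different pairs (never a clade).
# Discordant sharing needs at least two pairs to draw from.
.draw_carriers <- function(n, labs, pairs, ils_fraction) {
  clades <- c(as.list(labs), pairs)
  if (length(pairs) < 2) ils_fraction <- 0
  discordant <- stats::runif(n) < ils_fraction
  lapply(seq_len(n), function(i) {
    if (!discordant[i] && length(clades) > 0) {
      clades[[sample.int(length(clades), 1)]]
    } else {
      pr <- sample.int(length(pairs), 2)
      c(sample(pairs[[pr[1]]], 1), sample(pairs[[pr[2]]], 1))
    }
  })
}

#' Simulate a multi-species cohort with known truth
#'
#' Generates the full synthetic dataset the downstream analyses run
#' on: per-species fixed differences (the focal species fixed for the
#' alternate allele, every other species fixed reference), shared
#' polymorphism with concordant or tree-discordant carrier sets,
#' Hardy-Weinberg genotypes within species, diversity-reduced sweep
#' intervals, hybrid individuals built from exponential recombination
#' tracts (F1 carries one full donor haplotype; a BC_k backcross
#' carries donor tracts on one haplotype with probability `2^-k`, for
#' an expected donor allele fraction of `2^-(k+1)`), species-level
#' homozygous donor blocks, and a haploid mitochondrial contig whose
#' hybrid haplotypes are copied from the maternal species. All
#' randomness derives from the single configured seed; the same
#' configuration always yields identical output.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `gm` ([geno_matrix()]), `pm`
#'   ([pop_map()]) and `truth`, where `truth` is a list:
#'   `diagnostic_sites` (data.frame `species`, `chrom`, `pos`, `ref`,
#'   `alt`, `is_indel` of planted species-specific sites still intact
#'   after donor blocks), `hybrid_index` (`sample`, `recurrent`,
#'   `donor`, `expected`, `realized`), `tracts` (donor tracts per
#'   hybrid, BED-style plus `sample`), `sweep_windows`,
#'   `species_tracts` (the donor blocks), `mito_lineage` (`sample`,
#'   `lineage`).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(cfg$seed)

  labs <- names(cfg$species)
  n_ind <- cfg$species
  purebred <- unlist(lapply(labs, function(s) {
    paste0(s, seq_len(n_ind[[s]]))
  }))
  pure_species <- rep(labs, n_ind)
  hyb <- cfg$hybrids
  samples <- c(purebred, hyb$sample)
  sample_species <- c(pure_species,
                      if (nrow(hyb) > 0) hyb$recurrent else character())

  ## ---- autosomal site table -------------------------------------------
  site_list <- lapply(names(cfg$contigs), function(ch) {
    L <- cfg$contigs[[ch]]
    n_fixed <- round(cfg$fixed_diff_density * L)
    n_shared <- round(cfg$shared_poly_density * L)
    total <- n_fixed * length(labs) + n_shared
    if (total > L) stop("site density exceeds contig length")
    pos <- sort(sample.int(L, total))
    owner <- sample(c(rep(labs, each = n_fixed),
                      rep(NA_character_, n_shared)))
    data.frame(chrom = ch, pos = pos, owner = owner,
               stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, site_list)
  n_auto <- nrow(sites)
  is_shared <- is.na(sites$owner)
  carriers <- vector("list", n_auto)
  carriers[is_shared] <- .draw_carriers(sum(is_shared), labs,
                                        cfg$sister_pairs, cfg$ils_fraction)

  ## ---- per-species allele-copy pools ----------------------------------
  # copies[[s]]: n_auto x 2n_s matrix of 0/1 derived-allele indicators
  copies <- list()
  for (s in labs) {
    nc <- 2L * n_ind[[s]]
    mat <- matrix(0L, n_auto, nc)
    mat[!is_shared & sites$owner == s, ] <- 1L
    carry <- which(is_shared & vapply(carriers, function(x)
      s %in% x, logical(1)))
    if (length(carry) > 0) {
      cnts <- .draw_seg_counts(length(carry), nc, cfg$diversity_model,
                               cfg$diversity_beta)
      # sweep thinning: survive with probability 1/factor
      sw <- cfg$sweeps[cfg$sweeps$species == s, , drop = FALSE]
      if (nrow(sw) > 0) {
        for (k in seq_len(nrow(sw))) {
          inside <- sites$chrom[carry] == sw$chrom[k] &
            sites$pos[carry] > sw$start[k] & sites$pos[carry] <= sw$end[k]
          thin <- inside & stats::runif(length(carry)) > 1 / sw$factor[k]
          cnts[thin] <- 0L
        }
      }
      if (is.null(cfg$ld_block_mean)) {
        for (u in seq_along(carry)) {
          if (cnts[u] > 0) {
            mat[carry[u], sample.int(nc, cnts[u])] <- 1L
          }
        }
      } else {
        # haplotype blocks: sites in one block share a slot permutation
        for (ch in unique(sites$chrom[carry])) {
          inch <- which(sites$chrom[carry] == ch)
          L <- cfg$contigs[[ch]]
          lens <- numeric(0)
          while (sum(lens) < L) {
            lens <- c(lens, stats::rexp(32, rate = 1 / cfg$ld_block_mean))
          }
          edges <- c(0, cumsum(lens))
          blk <- findInterval(sites$pos[carry[inch]] - 1L, edges)
          for (b in unique(blk)) {
            perm <- sample.int(nc)
            for (u in inch[blk == b]) {
              if (cnts[u] > 0) mat[carry[u], perm[seq_len(cnts[u])]] <- 1L
            }
          }
        }
      }
    }
    copies[[s]] <- mat
  }

  ## ---- species-level donor blocks -------------------------------------
  db <- cfg$donor_blocks
  if (nrow(db) > 0) {
    for (k in seq_len(nrow(db))) {
      s <- db$species[k]; d <- db$donor[k]
      inb <- which(sites$chrom == db$chrom[k] &
                     sites$pos > db$start[k] & sites$pos <= db$end[k])
      if (length(inb) == 0) next
      fd <- rowMeans(copies[[d]][inb, , drop = FALSE])
      nc <- ncol(copies[[s]])
      draw <- matrix(stats::rbinom(length(inb) * nc, 1L, rep(fd, nc)),
                     length(inb), nc)
      copies[[s]][inb, ] <- draw
    }
  }

  ## ---- purebred genotypes ---------------------------------------------
  m <- length(samples)
  a1 <- matrix(NA_integer_, n_auto, m)
  a2 <- matrix(NA_integer_, n_auto, m)
  col <- 1L
  for (s in labs) {
    for (i in seq_len(n_ind[[s]])) {
      a1[, col] <- copies[[s]][, 2L * i - 1L]
      a2[, col] <- copies[[s]][, 2L * i]
      col <- col + 1L
    }
  }

  ## ---- species population frequencies (for hybrid allele draws) -------
  freq <- vapply(labs, function(s) rowMeans(copies[[s]]),
                 numeric(n_auto))
  colnames(freq) <- labs

  ## ---- hybrids: recombination-tract mosaics ---------------------------
  tract_rows <- list()
  hybrid_index <- NULL
  if (nrow(hyb) > 0) {
    gen_prob <- function(g) {
      # donor probability per tract on the non-recurrent haplotype
      if (grepl("^F1$", g)) return(1)
      if (grepl("^BC[0-9]+$", g)) return(2^(-as.integer(sub("BC", "", g))))
      f <- suppressWarnings(as.numeric(g))
      if (is.na(f) || f < 0 || f > 0.5) {
        stop("generation must be F1, BC<k> or a donor fraction <= 0.5: ", g)
      }
      2 * f
    }
    expected_frac <- function(g) gen_prob(g) / 2
    hybrid_index <- data.frame(sample = hyb$sample,
                               recurrent = hyb$recurrent,
                               donor = hyb$donor,
                               expected = vapply(hyb$generation,
                                                 expected_frac, numeric(1)),
                               realized = NA_real_,
                               stringsAsFactors = FALSE)
    for (hrow in seq_len(nrow(hyb))) {
      hs <- hyb$sample[hrow]
      R <- hyb$recurrent[hrow]; D <- hyb$donor[hrow]
      pdon <- gen_prob(hyb$generation[hrow])
      jcol <- length(purebred) + hrow
      donor_origin2 <- logical(n_auto)   # per-site donor origin of hap2
      for (ch in names(cfg$contigs)) {
        L <- cfg$contigs[[ch]]
        # exponential tract tiling of the non-recurrent haplotype
        lens <- numeric(0)
        while (sum(lens) < L) {
          lens <- c(lens, stats::rexp(16, rate = 1 / cfg$recomb_tract_mean))
        }
        edges <- unique(c(pmin(cumsum(lens), L)))
        edges <- c(edges[edges < L], L)
        starts <- c(0, edges[-length(edges)])
        is_donor <- stats::runif(length(starts)) < pdon
        si <- which(sites$chrom == ch)
        if (length(si) > 0) {
          tract_of <- findInterval(sites$pos[si] - 1L, starts)
          donor_origin2[si] <- is_donor[tract_of]
        }
        if (any(is_donor)) {
          tract_rows[[length(tract_rows) + 1L]] <- data.frame(
            sample = hs, chrom = ch,
            start = starts[is_donor], end = edges[is_donor],
            origin = D, stringsAsFactors = FALSE)
        }
      }
      p_r <- freq[, R]; p_d <- freq[, D]
      a1[, jcol] <- stats::rbinom(n_auto, 1L, p_r)
      p2 <- ifelse(donor_origin2, p_d, p_r)
      a2[, jcol] <- stats::rbinom(n_auto, 1L, p2)
      # realized donor fraction over the recurrent/donor truth panel
      panel_sites <- which(!is_shared & sites$owner %in% c(R, D))
      if (length(panel_sites) > 0) {
        hybrid_index$realized[hrow] <-
          sum(donor_origin2[panel_sites]) / (2 * length(panel_sites))
      }
    }
  }

  ## ---- allele strings --------------------------------------------------
  indel <- stats::runif(n_auto) < cfg$indel_fraction
  ref <- rep("A", n_auto)
  alt <- ifelse(indel, "AT", "T")

  ## ---- mitochondrial contig -------------------------------------------
  mito_owner <- rep(labs, length.out = cfg$mito_sites)
  mito_pos <- sort(sample.int(cfg$mito_length, cfg$mito_sites))
  mito_owner <- sample(mito_owner)
  mito_lineage <- sample_species
  if (nrow(hyb) > 0) {
    mito_lineage[length(purebred) + seq_len(nrow(hyb))] <- hyb$maternal
  }
  m1 <- matrix(NA_integer_, cfg$mito_sites, m)
  for (j in seq_len(m)) {
    m1[, j] <- as.integer(mito_owner == mito_lineage[j])
  }
  m2 <- matrix(NA_integer_, cfg$mito_sites, m)

  ## ---- assemble geno_matrix -------------------------------------------
  chrom <- c(sites$chrom, rep(cfg$mito_contig, cfg$mito_sites))
  pos <- c(sites$pos, mito_pos)
  ref_all <- c(ref, rep("A", cfg$mito_sites))
  alt_all <- c(alt, rep("T", cfg$mito_sites))
  a1_all <- rbind(a1, m1)
  a2_all <- rbind(a2, m2)
  ploidy <- c(rep(2L, n_auto), rep(1L, cfg$mito_sites))
  is_indel <- c(indel, rep(FALSE, cfg$mito_sites))

  if (cfg$missing_rate > 0) {
    auto_idx <- seq_len(n_auto)
    drop <- matrix(stats::runif(n_auto * m) < cfg$missing_rate, n_auto, m)
    a1_all[auto_idx, ][drop] <- NA_integer_
    a2_all[auto_idx, ][drop] <- NA_integer_
  }

  contig_lengths <- c(cfg$contigs,
                      stats::setNames(cfg$mito_length, cfg$mito_contig))
  gm <- geno_matrix(chrom, pos, ref_all, alt_all, a1_all, a2_all,
                    ploidy, is_indel, samples, contig_lengths)
  pm <- pop_map(stats::setNames(sample_species, samples))

  ## ---- truth -----------------------------------------------------------
  fixed_idx <- which(!is_shared)
  intact <- rep(TRUE, length(fixed_idx))
  if (nrow(db) > 0) {
    for (k in seq_len(nrow(db))) {
      hit <- sites$chrom[fixed_idx] == db$chrom[k] &
        sites$pos[fixed_idx] > db$start[k] &
        sites$pos[fixed_idx] <= db$end[k] &
        (sites$owner[fixed_idx] %in% c(db$species[k], db$donor[k]))
      intact <- intact & !hit
    }
  }
  diag_auto <- data.frame(species = sites$owner[fixed_idx][intact],
                          chrom = sites$chrom[fixed_idx][intact],
                          pos = sites$pos[fixed_idx][intact],
                          ref = ref[fixed_idx][intact],
                          alt = alt[fixed_idx][intact],
                          is_indel = indel[fixed_idx][intact],
                          stringsAsFactors = FALSE)
  diag_mito <- data.frame(species = mito_owner, chrom = cfg$mito_contig,
                          pos = mito_pos, ref = "A", alt = "T",
                          is_indel = FALSE, stringsAsFactors = FALSE)
  truth <- list(
    diagnostic_sites = rbind(diag_auto, diag_mito),
    hybrid_index = hybrid_index,
    tracts = if (length(tract_rows) > 0) do.call(rbind, tract_rows) else
      data.frame(sample = character(), chrom = character(),
                 start = numeric(), end = numeric(),
                 origin = character(), stringsAsFactors = FALSE),
    sweep_windows = cfg$sweeps,
    species_tracts = cfg$donor_blocks,
    mito_lineage = data.frame(sample = samples, lineage = mito_lineage,
                              stringsAsFactors = FALSE)
  )
  list(gm = gm, pm = pm, truth = truth)
}

#' Extract the truth diagnostic panel for a species pair
#'
#' The planted fixed differences between species `a` and species `b`
#' are the union of `a`-specific and `b`-specific sites: at an
#' `a`-specific site, side A carries the alternate allele and side B
#' the reference; at a `b`-specific site the reverse.
#'
#' @param truth the `truth` element of [simulate_cohort()] output.
#' @param a,b species labels for side A and side B.
#' @param contig optional contig filter (e.g. the mitochondrial contig
#'   name, or its negation via `exclude_contig`).
#' @param exclude_contig optional contig to drop (e.g. restrict the
#'   panel to autosomes).
#' @return a `diag_panel` data.frame.
#' @export
truth_pair_panel <- function(truth, a, b, contig = NULL,
                             exclude_contig = NULL) {
  ds <- truth$diagnostic_sites
  ds <- ds[ds$species %in% c(a, b), , drop = FALSE]
  if (!is.null(contig)) ds <- ds[ds$chrom == contig, , drop = FALSE]
  if (!is.null(exclude_contig)) {
    ds <- ds[ds$chrom != exclude_contig, , drop = FALSE]
  }
  a_owned <- ds$species == a
  panel <- data.frame(chrom = ds$chrom, pos = ds$pos,
                      allele_a = ifelse(a_owned, ds$alt, ds$ref),
                      allele_b = ifelse(a_owned, ds$ref, ds$alt),
                      is_indel = ds$is_indel, stringsAsFactors = FALSE)
  panel <- panel[order(panel$chrom, panel$pos), , drop = FALSE]
  rownames(panel) <- NULL
  structure(panel, pair = c(a, b), class = c("diag_panel", "data.frame"))
}

#' Write simulator outputs to disk
#'
#' Emits the cohort VCF (uncompressed 4.2 with contig headers), the
#' population map TSV and every truth table (species-specific site
#' TSV, hybrid-index TSV, donor-tract BED, sweep BED, mitochondrial
#' lineage TSV).
#'
#' @param sim output of [simulate_cohort()].
#' @param outdir output directory (created if absent).
#' @return named character vector of written paths, invisibly.
#' @export
write_sim_outputs <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    vcf = file.path(outdir, "cohort.vcf"),
    popmap = file.path(outdir, "popmap.tsv"),
    diagnostic = file.path(outdir, "truth_diagnostic_sites.tsv"),
    hybrids = file.path(outdir, "truth_hybrid_index.tsv"),
    tracts = file.path(outdir, "truth_tracts.bed"),
    donor_blocks = file.path(outdir, "truth_donor_blocks.bed"),
    sweeps = file.path(outdir, "truth_sweeps.bed"),
    mito = file.path(outdir, "truth_mito_lineage.tsv")
  )
  write_vcf(sim$gm, paths[["vcf"]])
  write_popmap(sim$pm, paths[["popmap"]])
  utils::write.table(sim$truth$diagnostic_sites, paths[["diagnostic"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  hi <- sim$truth$hybrid_index
  if (is.null(hi)) {
    hi <- data.frame(sample = character(), recurrent = character(),
                     donor = character(), expected = numeric(),
                     realized = numeric())
  }
  utils::write.table(hi, paths[["hybrids"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tr <- sim$truth$tracts
  utils::write.table(
    data.frame(chrom = tr$chrom, start = tr$start, end = tr$end,
               name = paste(tr$sample, tr$origin, sep = ":")),
    paths[["tracts"]], sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  db <- sim$truth$species_tracts
  utils::write.table(
    data.frame(chrom = db$chrom, start = db$start, end = db$end,
               name = paste(db$species, db$donor, sep = "<-")),
    paths[["donor_blocks"]], sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  sw <- sim$truth$sweep_windows
  utils::write.table(
    data.frame(chrom = sw$chrom, start = sw$start, end = sw$end,
               name = sw$species),
    paths[["sweeps"]], sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$truth$mito_lineage, paths[["mito"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
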