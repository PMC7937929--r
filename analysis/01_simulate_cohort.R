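#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# Ten pufferfish species, five individuals each, on two 2 Mb autosomes
# plus a mitochondrial contig, with every feature the downstream
# analyses target planted at known positions:
#   * four hybrid individuals inside the Tb population (two BC1, one
#     BC2, one F1), all with Tf mothers — the asymmetric-hybridization
#     scenario the mito/autosome comparison should expose;
#   * six 50 kb selective sweeps in Tn on chr1 (8-fold diversity
#     reduction) for the composite sweep scan;
#   * two 300 kb species-level donor tracts in Tn on chr2 (one from
#     Tx, one from Tob) for the homozygote-ratio scan.
# Everything downstream reads the files this stage writes, so the whole
# workflow is reproducible from this one seed.

suppressMessages(library(fugupop))

seed <- 20260929L
outdir <- "results/sim"

hybrids <- data.frame(
  sample = c("TbH1", "TbH2", "TbH3", "TbH4"),
  recurrent = "Tb", donor = "Tf",
  generation = c("BC1", "BC1", "BC2", "F1"),
  maternal = "Tf", stringsAsFactors = FALSE)

sweep_starts <- seq(2e5, by = 3e5, length.out = 6)
sweeps <- data.frame(species = "Tn", chrom = "chr1",
                     start = sweep_starts, end = sweep_starts + 5e4,
                     factor = 8)

donor_blocks <- data.frame(
  species = "Tn", donor = c("Tx", "Tob"), chrom = "chr2",
  start = c(3e5, 1.2e6), end = c(6e5, 1.5e6), stringsAsFactors = FALSE)

cfg <- sim_config(seed = seed, hybrids = hybrids, sweeps = sweeps,
                  donor_blocks = donor_blocks)
sim <- simulate_cohort(cfg)
paths <- write_sim_outputs(sim, outdir)

cat(sprintf("cohort: %d sites x %d samples (%d mitochondrial sites)\n",
            n_sites(sim$gm), n_samples(sim$gm),
            sum(sim$gm$ploidy == 1L)))
cat(sprintf("planted: %d species-specific sites, %d hybrids, %d sweeps, %d donor tracts\n",
            nrow(sim$truth$diagnostic_sites), nrow(hybrids),
            nrow(sweeps), nrow(donor_blocks)))
cat("wrote:\n"); for (p in paths) cat(" ", p, "\n")
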