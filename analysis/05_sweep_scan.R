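#!/usr/bin/env Rscript
# Stage 5 — composite selective-sweep scan for Tn and fine mapping.
#
# Genome scan in 50 kb windows sliding by 10 kb: a window is a sweep
# candidate if its FST (Tn versus the pooled other species) reaches
# the dataset's own top-1% threshold OR the mean diversity ratio
# log2(mean_x pi_x / pi_Tn) exceeds 1.5 in absolute value. Selected
# windows merge into candidate regions, which are compared against
# the planted sweeps, and the strongest region is re-scanned at
# 1 kb / 500 bp with FST, per-group diversity and Tajima's D — the
# per-gene view in which a sweep appears as a focal diversity trough
# with negative focal Tajima's D.

suppressMessages(library(fugupop))

gm <- read_vcf("results/filtered.vcf", mito_contig = "MT")
pm <- read_popmap("results/sim/popmap.tsv")
species <- names(pm$groups)
others <- setdiff(species, "Tn")

ss <- sweep_scan(gm, pm, "Tn", others)
write_window_stats(ss$windows[, c("chrom", "start", "end", "n_sites",
                                  "fst", "pi_Tn", "pi_ratio_log2",
                                  "selected", "trigger")],
                   "results/sweep_windows.tsv")
utils::write.table(ss$regions, "results/sweep_regions.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE, na = "NA")
write_bed(ss$regions[, c("chrom", "start", "end")],
          "results/sweep_regions.bed")
cat(sprintf("FST threshold (top 1%%): %.3f\n", ss$fst_threshold))
cat(sprintf("%d of %d windows selected; %d merged regions spanning %.2f Mb\n",
            ss$n_selected_windows, nrow(ss$windows),
            nrow(ss$regions), ss$total_merged_bp / 1e6))

truth <- read_bed("results/sim/truth_sweeps.bed")
hit <- vapply(seq_len(nrow(truth)), function(i) {
  any(ss$regions$chrom == truth$chrom[i] &
        ss$regions$start < truth$end[i] &
        ss$regions$end > truth$start[i])
}, logical(1))
cat(sprintf("planted sweeps recovered: %d / %d\n", sum(hit), nrow(truth)))

top <- ss$regions[which.max(ss$regions$max_fst), ]
pad <- 2.5e4
region <- list(chrom = top$chrom,
               start = max(0, top$start - pad),
               end = min(gm$contig_lengths[[top$chrom]], top$end + pad))
cat(sprintf("fine-mapping %s:%d-%d\n", region$chrom, region$start,
            region$end))
fs <- fine_scan(gm, pm, region, "Tn", others)
write_window_stats(fs, "results/fine_scan_top_region.tsv")
trough <- fs[which.min(fs$pi_Tn), ]
cat(sprintf(
  "focal diversity trough at %s:%d-%d (pi_Tn %.2e vs residual %.2e, focal Tajima's D %.2f)\n",
  trough$chrom, trough$start, trough$end, trough$pi_Tn,
  trough$pi_residual, trough$tajima_d_Tn))
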