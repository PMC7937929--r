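#' Windowed homozygote-ratio introgression scan
#'
#' For a query group and a diagnostic panel between sides A and B,
#' counts per window the panel sites at which the query group is fixed
#' homozygous for the side-A allele (`n_a_hom`), fixed homozygous for
#' the side-B allele (`n_b_hom`), or neither (`n_other`), and reports
#' `log10_ratio = log10((n_a_hom + c) / (n_b_hom + c))` with
#' pseudocount `c`. A site counts as side-fixed when every counted
#' query genotype is homozygous and the side allele's frequency among
#' called query copies is at least `fix_threshold` (strict fixation by
#' default). Windows tile each contig non-overlapping at `window_size`
#' unless a smaller `step` is given.
#'
#' @param gm a [geno_matrix()].
#' @param panel a `diag_panel` between sides A and B.
#' @param pm a [pop_map()].
#' @param query_group query group label(s), disjoint from the panel's
#'   defining groups.
#' @param window_size window size in bp (default 100000).
#' @param step window step (default `window_size`: non-overlapping).
#' @param pseudocount additive constant `c > 0` (default 1).
#' @param fix_threshold frequency needed to call a site side-fixed
#'   (default 1.0).
#' @return data.frame per window: `chrom`, `start`, `end`, `n_sites`
#'   (panel sites in window), `n_a_hom`, `n_b_hom`, `n_other`,
#'   `log10_ratio` (missing for windows without panel sites).
#' @export
homozygote_ratio_scan <- function(gm, panel, pm, query_group,
                                  window_size = 100000,
                                  step = window_size,
                                  pseudocount = 1, fix_threshold = 1.0) {
  stopifnot(window_size >= 1, pseudocount > 0,
            fix_threshold > 0.5, fix_threshold <= 1)
  q <- group_samples(pm, query_group)
  cols <- match(q, gm$samples)
  if (anyNA(cols)) stop("unknown query sample(s)")

  ps <- .panel_sites(gm, panel)
  ok <- !is.na(ps$site) & !is.na(ps$a_allele_idx)
  si <- ps$site[ok]
  a_idx <- ps$a_allele_idx[ok]

  cnt <- .site_counts(gm, cols, si)
  freq_alt <- ifelse(cnt$n_copies > 0, cnt$alt / cnt$n_copies, NA_real_)
  freq_a <- ifelse(a_idx == 1L, freq_alt, 1 - freq_alt)
  all_hom <- cnt$n_het == 0 & cnt$n_ind > 0
  a_fixed <- all_hom & !is.na(freq_a) & freq_a >= fix_threshold
  b_fixed <- all_hom & !is.na(freq_a) & (1 - freq_a) >= fix_threshold

  contigs <- gm$contig_lengths[unique(gm$chrom[si])]
  windows <- sliding_windows(contigs, window_size, step)
  out <- windows
  n <- nrow(windows)
  out$n_sites <- integer(n)
  out$n_a_hom <- integer(n)
  out$n_b_hom <- integer(n)
  out$n_other <- integer(n)
  for (i in seq_len(n)) {
    inw <- gm$chrom[si] == windows$chrom[i] &
      gm$pos[si] > windows$start[i] & gm$pos[si] <= windows$end[i]
    out$n_sites[i] <- sum(inw)
    out$n_a_hom[i] <- sum(inw & a_fixed)
    out$n_b_hom[i] <- sum(inw & b_fixed)
    out$n_other[i] <- sum(inw) - out$n_a_hom[i] - out$n_b_hom[i]
  }
  out$log10_ratio <- ifelse(
    out$n_sites > 0,
    log10((out$n_a_hom + pseudocount) / (out$n_b_hom + pseudocount)),
    NA_real_)
  out
}

#' Detect candidate donor tracts from homozygote-ratio windows
#'
#' Scans the sorted window table for maximal runs of at least
#' `min_run` consecutive windows whose `log10_ratio` lies beyond
#' `side_threshold` on the same side; each run becomes one candidate
#' segment labeled by side (`"A"` for positive, `"B"` for negative).
#' Windows with a missing ratio break runs.
#'
#' @param windows data.frame from [homozygote_ratio_scan()], sorted by
#'   (chrom, start).
#' @param side_threshold absolute `log10_ratio` cutoff (default 1).
#' @param min_run minimum consecutive windows (default 2).
#' @return data.frame BED-style: `chrom`, `start`, `end`, `name`
#'   (side), `n_windows`.
#' @export
detect_tracts <- function(windows, side_threshold = 1, min_run = 2) {
  stopifnot(min_run >= 1, side_threshold > 0)
  side <- ifelse(is.na(windows$log10_ratio), 0L,
                 ifelse(windows$log10_ratio >= side_threshold, 1L,
                        ifelse(windows$log10_ratio <= -side_threshold,
                               -1L, 0L)))
  out <- list()
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    r <- rle(side[wi])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- which(r$values != 0L & r$lengths >= min_run)
    for (k in sel) {
      rows <- wi[starts[k]:ends[k]]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch,
        start = min(windows$start[rows]),
        end = max(windows$end[rows]),
        name = if (r$values[k] > 0) "A" else "B",
        n_windows = length(rows), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(),
                      n_windows = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# merge overlapping or book-ended intervals within each chrom
.merge_intervals <- function(df) {
  if (nrow(df) == 0) return(df)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  out <- list()
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, , drop = FALSE]
    s <- d$start[1]; e <- d$end[1]; n <- 1L
    for (i in seq_len(nrow(d))[-1]) {
      if (d$start[i] <= e) {       # overlapping or book-ended
        e <- max(e, d$end[i]); n <- n + 1L
      } else {
        out[[length(out) + 1L]] <- data.frame(chrom = ch, start = s,
                                              end = e, n_windows = n)
        s <- d$start[i]; e <- d$end[i]; n <- 1L
      }
    }
    out[[length(out) + 1L]] <- data.frame(chrom = ch, start = s,
                                          end = e, n_windows = n)
  }
  do.call(rbind, out)
}

#' Composite selective-sweep scan
#'
#' Windows the genome (default 50 kb sliding by 10 kb), computes
#' windowed FST between the focal group and the pooled complement plus
#' the diversity-ratio statistic `log2(mean over x of pi_x/pi_focal)`,
#' and selects a window if its FST reaches the empirical
#' `fst_quantile` threshold (top 1% by default; the threshold is the
#' dataset's own 99th percentile, linearly interpolated) OR the
#' absolute diversity-ratio statistic exceeds `pi_ratio_log2_min`.
#' Overlapping or book-ended selected windows are merged into candidate
#' sweep regions.
#'
#' @param gm a [geno_matrix()] of biallelic diploid sites.
#' @param pm a [pop_map()].
#' @param focal focal group label.
#' @param others complement group labels (at least 2 for the average
#'   ratio).
#' @param size,step window size and step in bp (defaults 50000, 10000).
#' @param fst_quantile empirical quantile for the FST arm (default 0.99).
#' @param pi_ratio_log2_min absolute log2 diversity-ratio cutoff
#'   (default 1.5).
#' @param estimator FST estimator, see [fst_site()].
#' @return list: `windows` (window table with `fst`, per-group pi,
#'   `pi_ratio_log2`, `selected`, `trigger`), `regions` (merged
#'   data.frame `chrom`, `start`, `end`, `n_windows_merged`, `max_fst`,
#'   `min_pi_ratio_log2`, `max_pi_ratio_log2`, `trigger`),
#'   `fst_threshold` (the empirical quantile used), `total_merged_bp`.
#' @export
sweep_scan <- function(gm, pm, focal, others, size = 50000, step = 10000,
                       fst_quantile = 0.99, pi_ratio_log2_min = 1.5,
                       estimator = "weir_cockerham") {
  stopifnot(length(others) >= 1)
  gm <- subset_geno(gm, sites = which(gm$ploidy == 2L))
  contigs <- gm$contig_lengths[names(gm$contig_lengths) %in%
                                 unique(gm$chrom)]
  windows <- sliding_windows(contigs, size, step)
  ws <- windowed_stats(gm, pm, windows, focal, others,
                       stats = c("fst", "pi", "pi_ratio_log2"),
                       estimator = estimator)
  thr <- stats::quantile(ws$fst, fst_quantile, na.rm = TRUE, names = FALSE)
  fst_arm <- !is.na(ws$fst) & ws$fst >= thr
  pi_arm <- !is.na(ws$pi_ratio_log2) &
    abs(ws$pi_ratio_log2) > pi_ratio_log2_min
  ws$selected <- fst_arm | pi_arm
  ws$trigger <- ifelse(fst_arm & pi_arm, "both",
                       ifelse(fst_arm, "fst",
                              ifelse(pi_arm, "pi_ratio", NA_character_)))

  sel <- ws[ws$selected, , drop = FALSE]
  regions <- .merge_intervals(sel[, c("chrom", "start", "end")])
  if (nrow(regions) > 0) {
    names(regions)[names(regions) == "n_windows"] <- "n_windows_merged"
    regions$max_fst <- NA_real_
    regions$min_pi_ratio_log2 <- NA_real_
    regions$max_pi_ratio_log2 <- NA_real_
    regions$trigger <- NA_character_
    for (i in seq_len(nrow(regions))) {
      inr <- sel$chrom == regions$chrom[i] &
        sel$start < regions$end[i] & sel$end > regions$start[i]
      regions$max_fst[i] <- suppressWarnings(max(sel$fst[inr], na.rm = TRUE))
      pr <- sel$pi_ratio_log2[inr]
      if (any(!is.na(pr))) {
        regions$min_pi_ratio_log2[i] <- min(pr, na.rm = TRUE)
        regions$max_pi_ratio_log2[i] <- max(pr, na.rm = TRUE)
      }
      tr <- unique(sel$trigger[inr])
      regions$trigger[i] <- if (length(tr) == 1) tr else "both"
    }
    regions$max_fst[!is.finite(regions$max_fst)] <- NA_real_
  } else {
    regions <- data.frame(chrom = character(), start = numeric(),
                          end = numeric(), n_windows_merged = integer(),
                          max_fst = numeric(), min_pi_ratio_log2 = numeric(),
                          max_pi_ratio_log2 = numeric(),
                          trigger = character(), stringsAsFactors = FALSE)
  }
  list(windows = ws, regions = regions, fst_threshold = thr,
       n_selected_windows = sum(ws$selected),
       total_merged_bp = sum(regions$end - regions$start))
}

#' Fine-resolution scan of a candidate region
#'
#' Recomputes FST, nucleotide diversity and Tajima's D at fine
#' resolution (1 kb windows sliding by 500 bp by default) within one
#' region, with the complement groups pooled into a single residual
#' group — the per-gene view used to localise sweep signals. Window
#' starts are offset from the region start and clipped at the region
#' end.
#'
#' @param gm a [geno_matrix()].
#' @param pm a [pop_map()].
#' @param region list or one-row data.frame with `chrom`, `start`,
#'   `end` (0-based half-open, within one contig).
#' @param focal focal group label.
#' @param others complement group labels (pooled).
#' @param size,step fine window size and step (defaults 1000, 500).
#' @param estimator FST estimator.
#' @return window table with `fst`, `pi_<focal>`, `pi_residual`,
#'   `tajima_d_<focal>`, `tajima_d_residual`; empty (zero rows) when
#'   the region contains no window.
#' @export
fine_scan <- function(gm, pm, region, focal, others, size = 1000,
                      step = 500, estimator = "weir_cockerham") {
  chrom <- as.character(region$chrom)
  L <- region$end - region$start
  stopifnot(L > 0, chrom %in% names(gm$contig_lengths))
  w <- sliding_windows(stats::setNames(L, chrom), size, step)
  w$start <- w$start + region$start
  w$end <- w$end + region$start

  residual <- unlist(pm$groups[others], use.names = FALSE)
  pm2 <- pop_map(stats::setNames(
    c(rep(focal, length(pm$groups[[focal]])), rep("residual", length(residual))),
    c(pm$groups[[focal]], residual)))
  in_gm <- gm$samples %in% names(pm2$assignments)
  keep_sites <- which(gm$ploidy == 2L & gm$chrom == chrom)
  gm2 <- subset_geno(gm, sites = keep_sites, samples = which(in_gm))
  windowed_stats(gm2, pm2, w, focal, "residual",
                 stats = c("fst", "pi", "pi_ratio_log2", "tajima_d"),
                 estimator = estimator)
}

#' Interval Jaccard index between two BED-style tables
#'
#' Length of the intersection of the two interval unions divided by
#' the length of their union; used to compare detected tracts or sweep
#' regions with simulator truth.
#'
#' @param a,b data.frames with `chrom`, `start`, `end`.
#' @return scalar in `[0, 1]` (1 when both are empty).
#' @export
interval_jaccard <- function(a, b) {
  cover <- function(df, chroms) {
    lapply(chroms, function(ch) {
      d <- df[df$chrom == ch, , drop = FALSE]
      if (nrow(d) == 0) return(cbind(numeric(0), numeric(0)))
      m <- .merge_intervals(d[, c("chrom", "start", "end")])
      cbind(m$start, m$end)
    })
  }
  chroms <- union(unique(a$chrom), unique(b$chrom))
  if (length(chroms) == 0) return(1)
  ia <- cover(a, chroms); ib <- cover(b, chroms)
  inter <- 0; uni <- 0
  for (k in seq_along(chroms)) {
    A <- ia[[k]]; B <- ib[[k]]
    la <- sum(A[, 2] - A[, 1]); lb <- sum(B[, 2] - B[, 1])
    ov <- 0
    if (nrow(A) > 0 && nrow(B) > 0) {
      for (i in seq_len(nrow(A))) {
        ov <- ov + sum(pmax(0, pmin(A[i, 2], B[, 2]) - pmax(A[i, 1], B[, 1])))
      }
    }
    inter <- inter + ov
    uni <- uni + la + lb - ov
  }
  if (uni == 0) 1 else inter / uni
}
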