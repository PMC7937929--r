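#' Species-diagnostic fixed-difference marker panel
#'
#' A site enters the panel iff it is biallelic, every called allele
#' copy in the focal side carries one allele, every called copy in the
#' complement side carries the other, and each side has at most
#' `max_missing_per_group` missing genotype calls. On called data this
#' is exactly the set of sites with Hudson FST = 1 between the sides.
#' Both SNPs and indels qualify; each site records the allele carried
#' by each side.
#'
#' @param gm a [geno_matrix()].
#' @param pm a [pop_map()].
#' @param focal focal group label (side A).
#' @param complement character vector of complement group labels
#'   (side B), disjoint from `focal`.
#' @param max_missing_per_group maximum missing calls per side at a
#'   retained site (default 2, mirroring the global site filter).
#' @return an object of class `diag_panel`: a data.frame with columns
#'   `chrom`, `pos` (1-based), `allele_a`, `allele_b`, `is_indel`, and
#'   attributes `pair = c(A, B)` and `max_missing_per_group`.
#' @export
find_diagnostic_sites <- function(gm, pm, focal, complement,
                                  max_missing_per_group = 2) {
  stopifnot(length(intersect(focal, complement)) == 0)
  ga <- group_samples(pm, focal)
  gb <- group_samples(pm, complement)
  ca <- match(ga, gm$samples); cb <- match(gb, gm$samples)
  if (anyNA(ca) || anyNA(cb)) stop("population map sample absent from genotypes")

  biallelic <- !grepl(",", gm$alt, fixed = TRUE) & gm$alt != "."
  sa <- .site_counts(gm, ca)
  sb <- .site_counts(gm, cb)
  miss_a <- length(ca) - sa$n_ind
  miss_b <- length(cb) - sb$n_ind

  a_fixed_alt <- sa$n_copies > 0 & sa$alt == sa$n_copies
  a_fixed_ref <- sa$n_copies > 0 & sa$alt == 0
  b_fixed_alt <- sb$n_copies > 0 & sb$alt == sb$n_copies
  b_fixed_ref <- sb$n_copies > 0 & sb$alt == 0

  keep <- biallelic &
    miss_a <= max_missing_per_group & miss_b <= max_missing_per_group &
    ((a_fixed_alt & b_fixed_ref) | (a_fixed_ref & b_fixed_alt))

  i <- which(keep)
  allele_a <- ifelse(a_fixed_alt[i], gm$alt[i], gm$ref[i])
  allele_b <- ifelse(a_fixed_alt[i], gm$ref[i], gm$alt[i])
  panel <- data.frame(chrom = gm$chrom[i], pos = gm$pos[i],
                      allele_a = allele_a, allele_b = allele_b,
                      is_indel = gm$is_indel[i],
                      stringsAsFactors = FALSE)
  structure(panel,
            pair = c(paste(focal, collapse = "+"),
                     paste(complement, collapse = "+")),
            max_missing_per_group = max_missing_per_group,
            class = c("diag_panel", "data.frame"))
}

#' Highly differentiated (but not necessarily fixed) marker panel
#'
#' Selects sites whose per-site FST estimate exceeds `fst_min` and
#' records, per side, the group-major allele as that side's allele.
#' Sites where the same allele is major in both groups are excluded,
#' since they cannot source an allele copy to either side.
#'
#' @inheritParams find_diagnostic_sites
#' @param g1,g2 group labels for side A and side B.
#' @param fst_min FST threshold in `[0, 1]` (default 0.8); sites with
#'   `fst > fst_min` are retained.
#' @param estimator FST estimator, see [fst_site()].
#' @return a `diag_panel` (same schema as [find_diagnostic_sites()])
#'   with an extra column `fst`.
#' @export
find_differentiated_sites <- function(gm, pm, g1, g2, fst_min = 0.8,
                                      estimator = "weir_cockerham",
                                      max_missing_per_group = 2) {
  stopifnot(fst_min >= 0, fst_min <= 1)
  ga <- group_samples(pm, g1)
  gb <- group_samples(pm, g2)
  biallelic <- !grepl(",", gm$alt, fixed = TRUE) & gm$alt != "."
  if (estimator == "weir_cockerham") biallelic <- biallelic & gm$ploidy == 2L
  cand <- which(biallelic)
  fst <- rep(NA_real_, n_sites(gm))
  fst[cand] <- fst_site(gm, ga, gb, estimator = estimator, sites = cand)$fst

  fa <- allele_freq(gm, ga)$freq
  fb <- allele_freq(gm, gb)$freq
  ca <- match(ga, gm$samples); cb <- match(gb, gm$samples)
  sa <- .site_counts(gm, ca); sb <- .site_counts(gm, cb)
  miss_ok <- (length(ca) - sa$n_ind) <= max_missing_per_group &
    (length(cb) - sb$n_ind) <= max_missing_per_group

  keep <- !is.na(fst) & fst > fst_min & miss_ok &
    !is.na(fa) & !is.na(fb) &
    ((fa > 0.5) != (fb > 0.5)) & fa != 0.5 & fb != 0.5

  i <- which(keep)
  a_is_alt <- fa[i] > 0.5
  panel <- data.frame(chrom = gm$chrom[i], pos = gm$pos[i],
                      allele_a = ifelse(a_is_alt, gm$alt[i], gm$ref[i]),
                      allele_b = ifelse(a_is_alt, gm$ref[i], gm$alt[i]),
                      is_indel = gm$is_indel[i],
                      fst = fst[i],
                      stringsAsFactors = FALSE)
  structure(panel, pair = c(g1, g2),
            max_missing_per_group = max_missing_per_group,
            class = c("diag_panel", "data.frame"))
}

# match panel rows to gm site indices; returns index (NA where absent)
# plus, per matched site, which allele index (0/1) is side A.
.panel_sites <- function(gm, panel) {
  key_gm <- paste(gm$chrom, gm$pos, sep = ":")
  key_p <- paste(panel$chrom, panel$pos, sep = ":")
  i <- match(key_p, key_gm)
  ok <- !is.na(i)
  a_idx <- rep(NA_integer_, length(i))
  a_idx[ok] <- ifelse(panel$allele_a[ok] == gm$ref[i[ok]], 0L,
                      ifelse(panel$allele_a[ok] == gm$alt[i[ok]], 1L,
                             NA_integer_))
  list(site = i, a_allele_idx = a_idx)
}

#' Per-individual introgression ratio over a diagnostic panel
#'
#' The deterministic diagnostic-allele fraction: the proportion of the
#' individual's called allele copies at panel sites that carry the
#' donor side's allele. On a fixed-difference panel this equals the
#' individual's expected ancestry proportion from the donor (an F1
#' hybrid scores exactly 0.5, a pure recurrent individual 0).
#'
#' @param gm a [geno_matrix()].
#' @param panel a `diag_panel`.
#' @param sample sample id present in `gm`.
#' @param direction donor side, `"A"` or `"B"` of the panel pair.
#' @param threshold admixture call threshold on the ratio
#'   (default 0.01).
#' @return list of class `introgression_report`: `sample`, `pair`,
#'   `direction`, `n_sites_called`, `donor_allele_copies`,
#'   `introgression_ratio`, `assigned_class` (`"pure"`/`"admixed"`),
#'   and `per_site` (data.frame chrom, pos, donor_copies, ploidy).
#'   Errors when no panel site is called in the sample.
#' @export
introgression_ratio <- function(gm, panel, sample, direction = c("B", "A"),
                                threshold = 0.01) {
  direction <- match.arg(direction)
  j <- match(sample, gm$samples)
  if (is.na(j)) stop("unknown sample: ", sample)
  ps <- .panel_sites(gm, panel)
  ok <- !is.na(ps$site) & !is.na(ps$a_allele_idx)
  si <- ps$site[ok]
  a_idx <- ps$a_allele_idx[ok]
  donor_idx <- if (direction == "A") a_idx else 1L - a_idx

  a1 <- gm$a1[si, j]
  a2 <- gm$a2[si, j]
  hap <- gm$ploidy[si] == 1L
  called <- ifelse(hap, !is.na(a1), !is.na(a1) & !is.na(a2))
  copies <- ifelse(hap, 1L, 2L)[called]
  dc <- (as.integer(a1 == donor_idx) +
           ifelse(hap, 0L, as.integer(a2 == donor_idx)))[called]
  n_called <- sum(called)
  if (n_called == 0) stop("no called panel sites for sample ", sample)
  total <- sum(copies)
  ratio <- sum(dc) / total
  structure(list(
    sample = sample,
    pair = attr(panel, "pair"),
    direction = direction,
    n_sites_called = n_called,
    donor_allele_copies = sum(dc),
    total_allele_copies = total,
    introgression_ratio = ratio,
    assigned_class = if (ratio >= threshold) "admixed" else "pure",
    per_site = data.frame(chrom = gm$chrom[si][called],
                          pos = gm$pos[si][called],
                          donor_copies = dc,
                          ploidy = gm$ploidy[si][called])
  ), class = "introgression_report")
}

#' @export
print.introgression_report <- function(x, ...) {
  cat(sprintf(
    "%s: %d/%d donor allele copies at %d panel sites -> ratio %.4f (%s)\n",
    x$sample, x$donor_allele_copies, x$total_allele_copies,
    x$n_sites_called, x$introgression_ratio, x$assigned_class))
  invisible(x)
}

#' Introgression ratios for many samples
#'
#' @inheritParams introgression_ratio
#' @param samples character vector of sample ids.
#' @return data.frame: `sample`, `n_sites_called`, `donor_copies`,
#'   `total_copies`, `ratio`, `class`.
#' @export
introgression_table <- function(gm, panel, samples, direction = "B",
                                threshold = 0.01) {
  rows <- lapply(samples, function(s) {
    r <- introgression_ratio(gm, panel, s, direction, threshold)
    data.frame(sample = s, n_sites_called = r$n_sites_called,
               donor_copies = r$donor_allele_copies,
               total_copies = r$total_allele_copies,
               ratio = r$introgression_ratio,
               class = r$assigned_class, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mitochondrial lineage assignment from a diagnostic panel
#'
#' Tallies, per mitochondrial panel site, whether the sample's
#' haplotype matches side A or side B; the assigned lineage is the
#' majority side and `mismatch_count` the number of sites matching the
#' minority side. Mitochondrial calls must be haploid or
#' homozygous-diploid; a heterozygous call is a data inconsistency and
#' raises an error.
#'
#' @param gm a [geno_matrix()].
#' @param panel a `diag_panel` restricted to the mitochondrial contig.
#' @param sample sample id.
#' @return list of class `mito_assignment`: `sample`, `n_sites`,
#'   `matches_a`, `matches_b`, `assigned_lineage` (`"A"`/`"B"`),
#'   `mismatch_count`.
#' @export
mito_assign <- function(gm, panel, sample) {
  j <- match(sample, gm$samples)
  if (is.na(j)) stop("unknown sample: ", sample)
  ps <- .panel_sites(gm, panel)
  ok <- !is.na(ps$site) & !is.na(ps$a_allele_idx)
  si <- ps$site[ok]
  a_idx <- ps$a_allele_idx[ok]
  a1 <- gm$a1[si, j]
  a2 <- gm$a2[si, j]
  dip <- gm$ploidy[si] == 2L
  het <- dip & !is.na(a1) & !is.na(a2) & a1 != a2
  if (any(het)) {
    w <- which(het)[1]
    stop(sprintf("heterozygous mitochondrial genotype for %s at %s:%d",
                 sample, gm$chrom[si[w]], gm$pos[si[w]]))
  }
  called <- !is.na(a1)
  matches_a <- sum(a1[called] == a_idx[called])
  matches_b <- sum(a1[called] == (1L - a_idx[called]))
  lineage <- if (matches_a >= matches_b) "A" else "B"
  structure(list(
    sample = sample,
    pair = attr(panel, "pair"),
    n_sites = sum(called),
    matches_a = matches_a,
    matches_b = matches_b,
    assigned_lineage = lineage,
    mismatch_count = min(matches_a, matches_b)
  ), class = "mito_assignment")
}

#' @export
print.mito_assignment <- function(x, ...) {
  cat(sprintf("%s: mito lineage %s (%s) — %d/%d sites, %d mismatch(es)\n",
              x$sample, x$assigned_lineage,
              x$pair[match(x$assigned_lineage, c("A", "B"))],
              max(x$matches_a, x$matches_b), x$n_sites, x$mismatch_count))
  invisible(x)
}

#' Major-allele source at polymorphic panel sites in a third group
#'
#' Over the panel sites that are polymorphic within the query group
#' (side-A allele frequency strictly between 0 and 1), reports the
#' fraction whose query-group major allele is the side-A allele.
#' Exact-tie sites (frequency 0.5) are unresolved and excluded from
#' both numerator and denominator, reported separately.
#'
#' @param gm a [geno_matrix()].
#' @param panel a `diag_panel` between two groups the query group does
#'   not belong to.
#' @param query_group character vector of sample ids.
#' @return list: `fraction_a_major` (`NA` when no resolvable
#'   polymorphic site), `n_polymorphic`, `n_a_major`, `n_ties`.
#' @export
het_major_allele_source <- function(gm, panel, query_group) {
  ps <- .panel_sites(gm, panel)
  ok <- !is.na(ps$site) & !is.na(ps$a_allele_idx)
  si <- ps$site[ok]
  a_idx <- ps$a_allele_idx[ok]
  af <- allele_freq(gm, query_group, sites = si)
  freq_a <- ifelse(a_idx == 1L, af$freq, 1 - af$freq)
  poly <- !is.na(freq_a) & freq_a > 0 & freq_a < 1
  ties <- poly & freq_a == 0.5
  resolv <- poly & !ties
  n_a_major <- sum(freq_a[resolv] > 0.5)
  list(
    fraction_a_major = if (sum(resolv) == 0) NA_real_ else
      n_a_major / sum(resolv),
    n_polymorphic = sum(resolv),
    n_a_major = n_a_major,
    n_ties = sum(ties)
  )
}

#' Two-pass diagnostic panel discovery with hybrid removal
#'
#' Pass 1 flags admixed individuals, pass 2 rediscovers the
#' fixed-difference panel on the remaining "purebred" individuals
#' only. A hybrid's introgressed copies hide exactly the fixed
#' differences it contaminates, so the sites that survive discovery
#' with the hybrid included are ones where it looks purebred — its
#' ratio over that panel is near zero and cannot expose it. Flagging
#' is therefore leave-one-out: for each individual the panel is
#' rediscovered with that individual excluded, which releases the
#' sites its own copies suppressed, and the individual's
#' opposite-side diagnostic-allele fraction over that panel is
#' compared with `threshold`. A pure individual never suppresses a
#' fixed difference, so its leave-one-out ratio stays at the binomial
#' noise floor raised only by ILS-like shared polymorphism: sites
#' where the left-out individual holds the last minority copies of a
#' nearly fixed ancestral variant enter its leave-one-out panel and
#' mimic introgression, so under realistic polymorphism density the
#' pure autosomal baseline sits at a few percent, not at zero. The
#' autosomal flag threshold therefore defaults to 0.1 — above that
#' floor, below the F1/BC1 signals (0.5/0.25) — and a second,
#' deterministic arm flags any individual whose mitochondrial
#' haplotype matches the opposite side on the leave-one-out
#' mitochondrial panel: the maternal line is untouched by backcross
#' dilution, so this arm exposes maternal-donor hybrids of any
#' generation that the autosomal arm can no longer separate from the
#' ILS floor. One strongly admixed individual (an F1 suppresses
#' every site) can empty everyone else's leave-one-out panel, so
#' flagging iterates to a fixed point: flagged individuals are
#' removed and the remaining ones re-examined, and no flag is issued
#' from a panel smaller than `min_flag_panel` sites (too few markers
#' to estimate an ancestry fraction). Removing flagged individuals
#' can only release sites, so the final panel is a superset of the
#' provisional (everyone-included) one.
#'
#' @inheritParams find_diagnostic_sites
#' @param threshold admixture flag threshold on the autosomal
#'   leave-one-out ratio (default 0.1; see above — the per-individual
#'   reporting threshold of [introgression_ratio()] stays at 0.01).
#' @param min_flag_panel smallest leave-one-out panel a flag may be
#'   based on (default 50 sites).
#' @param min_mito_sites smallest leave-one-out mitochondrial panel
#'   the mito-discordance arm may act on (default 5 sites).
#' @return list: `panel` (pass-2 `diag_panel`),
#'   `provisional_panel` (the everyone-included panel), `excluded`
#'   (character vector of flagged samples, in flagging order),
#'   `pass1_ratios` (data.frame: per-sample leave-one-out panel size,
#'   autosomal ratio, mito lineage concordance and class from the
#'   last round the sample was examined, with the round number).
#' @export
two_pass_panel <- function(gm, pm, focal, complement,
                           max_missing_per_group = 2, threshold = 0.1,
                           min_flag_panel = 50, min_mito_sites = 5) {
  p1 <- find_diagnostic_sites(gm, pm, focal, complement,
                              max_missing_per_group)
  side_a <- group_samples(pm, focal)
  side_b <- group_samples(pm, complement)
  mito_chroms <- unique(gm$chrom[gm$ploidy == 1L])

  excluded <- character(0)
  ratio_log <- list()
  round <- 0L
  repeat {
    round <- round + 1L
    kept_all <- setdiff(gm$samples, excluded)
    loo_row <- function(s, direction) {
      keep <- setdiff(kept_all, s)
      pm_s <- pop_map(pm$assignments[names(pm$assignments) %in% keep])
      panel_s <- find_diagnostic_sites(subset_geno(gm, samples = keep),
                                       pm_s, focal, complement,
                                       max_missing_per_group)
      auto_s <- panel_s[!(panel_s$chrom %in% mito_chroms), , drop = FALSE]
      r <- tryCatch(
        introgression_ratio(gm, auto_s, s, direction, threshold),
        error = function(e) NULL)
      ratio <- if (is.null(r)) NA_real_ else r$introgression_ratio
      auto_flag <- nrow(auto_s) >= min_flag_panel && !is.na(ratio) &&
        ratio >= threshold

      mito_s <- panel_s[panel_s$chrom %in% mito_chroms, , drop = FALSE]
      mito_lineage <- NA_character_
      mito_flag <- FALSE
      if (nrow(mito_s) >= min_mito_sites) {
        m <- tryCatch(mito_assign(gm, mito_s, s), error = function(e) NULL)
        if (!is.null(m) && m$n_sites >= min_mito_sites) {
          mito_lineage <- m$assigned_lineage
          own_side <- if (direction == "B") "A" else "B"
          mito_flag <- mito_lineage != own_side
        }
      }
      data.frame(sample = s, round = round,
                 n_panel_sites = nrow(auto_s), ratio = ratio,
                 mito_discordant = mito_flag,
                 class = if (auto_flag || mito_flag) "admixed" else "pure",
                 stringsAsFactors = FALSE)
    }
    cur <- rbind(
      do.call(rbind, lapply(intersect(side_a, kept_all), loo_row, "B")),
      do.call(rbind, lapply(intersect(side_b, kept_all), loo_row, "A")))
    ratio_log[[round]] <- cur
    new_flags <- cur$sample[cur$class == "admixed"]
    # never empty a side: keep at least one individual on each
    for (side in list(side_a, side_b)) {
      left <- setdiff(intersect(side, kept_all), new_flags)
      if (length(left) == 0 && length(new_flags) > 0) {
        spare <- intersect(side, kept_all)[1]
        new_flags <- setdiff(new_flags, spare)
      }
    }
    if (length(new_flags) == 0) break
    excluded <- c(excluded, new_flags)
  }
  all_rounds <- do.call(rbind, ratio_log)
  all_rounds <- all_rounds[order(all_rounds$round), ]
  ratios <- all_rounds[!duplicated(all_rounds$sample, fromLast = TRUE), ]
  ratios <- ratios[order(match(ratios$sample, gm$samples)), ]
  rownames(ratios) <- NULL

  keep <- setdiff(gm$samples, excluded)
  pm2 <- pop_map(pm$assignments[names(pm$assignments) %in% keep])
  gm2 <- subset_geno(gm, samples = keep)
  p2 <- find_diagnostic_sites(gm2, pm2, focal, complement,
                              max_missing_per_group)
  list(panel = p2, provisional_panel = p1, excluded = excluded,
       pass1_ratios = ratios)
}

#' Write a diagnostic panel as TSV
#' @param panel a `diag_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  utils::write.table(as.data.frame(panel), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a diagnostic panel TSV
#' @param path panel TSV path (columns chrom, pos, allele_a, allele_b,
#'   is_indel).
#' @param pair optional character pair of side labels.
#' @return a `diag_panel`.
#' @export
read_panel <- function(path, pair = c("A", "B")) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  structure(df, pair = pair, class = c("diag_panel", "data.frame"))
}
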