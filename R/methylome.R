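#' Combine CpG calls from both strands
#'
#' The reverse-strand cytosine of a CpG sits one base after the
#' forward-strand one; counts of the two strands are summed at the
#' forward-strand position. Non-CpG (CHH) records pass through unchanged.
#'
#' @param calls Methylation call tibble (`chrom`, `pos`, `strand`,
#'   `context`, `meth`, `total`).
#' @return Calls with CpG records strand-collapsed (strand set to `"+"`).
#' @export
combine_cpg_strands <- function(calls) {
  cpg <- calls[calls$context == "CpG", , drop = FALSE]
  other <- calls[calls$context != "CpG", , drop = FALSE]
  if (nrow(cpg) == 0) return(calls)
  dup <- cpg |>
    group_by(chrom, strand, pos) |>
    summarise(n = n(), .groups = "drop")
  if (any(dup$n > 1)) {
    stopf("duplicate CpG record(s) at the same position and strand")
  }
  fwd_pos <- ifelse(cpg$strand == "-", cpg$pos - 1, cpg$pos)
  comb <- cpg |>
    mutate(pos = fwd_pos) |>
    group_by(chrom, pos) |>
    summarise(meth = sum(meth), total = sum(total), .groups = "drop") |>
    mutate(strand = "+", context = "CpG") |>
    select(chrom, pos, strand, context, meth, total)
  arrange(bind_rows(comb, other), chrom, pos)
}

viterbi_two_state <- function(sym, p_stay = 0.99,
                              em_ordered = c(0.35, 0.05, 0.60),
                              em_disordered = c(0.15, 0.70, 0.15)) {
  # states: 1 = ordered (FMR/LMR-like), 2 = disordered (PMD-like)
  n <- length(sym)
  le1 <- log(em_ordered)[sym]
  le2 <- log(em_disordered)[sym]
  lstay <- log(p_stay); lsw <- log(1 - p_stay)
  ptr1 <- integer(n); ptr2 <- integer(n)
  v1 <- log(0.5) + le1[1]
  v2 <- log(0.5) + le2[1]
  if (n > 1) {
    for (i in 2:n) {
      a <- v1 + lstay; b <- v2 + lsw
      if (a >= b) { ptr1[i] <- 1L; n1 <- a } else { ptr1[i] <- 2L; n1 <- b }
      a <- v1 + lsw; b <- v2 + lstay
      if (a >= b) { ptr2[i] <- 1L; n2 <- a } else { ptr2[i] <- 2L; n2 <- b }
      v1 <- n1 + le1[i]
      v2 <- n2 + le2[i]
    }
  }
  path <- integer(n)
  path[n] <- if (v1 >= v2) 1L else 2L
  if (n > 1) {
    for (i in (n - 1):1) {
      path[i] <- if (path[i + 1] == 1L) ptr1[i + 1] else ptr2[i + 1]
    }
  }
  path
}

running_mean <- function(x, k = 3) {
  n <- length(x)
  half <- (k - 1) %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Segment a CpG methylome into UMR/LMR/FMR/PMD classes
#'
#' Three passes over coverage-filtered, strand-combined CpG levels:
#'
#' 1. **PMDs** — a two-state segmentation (ordered vs disordered) over
#'    levels discretized to low (< 0.3), mid (0.3–0.7) and high (> 0.7);
#'    maximal disordered runs become PMD candidates and candidates shorter
#'    than `pmd_min_length` (100 kb) are discarded (reported separately in
#'    the `short_pmds` attribute for inspection).
#' 2. **UMRs/LMRs** — outside PMDs, levels are smoothed with a running
#'    mean over `smooth_k` CpGs; maximal runs with smoothed level below
#'    `hypo_max` and at least `hypo_min_cpgs` CpGs are hypomethylated
#'    segments, split into UMR (>= `umr_min_cpgs` CpGs) and LMR.
#' 3. **FMRs** — remaining stretches with mean level >= `fmr_min_mean`
#'    (0.85) and at least `fmr_min_cpgs` CpGs; anything else is
#'    `unclassified`.
#'
#' @param calls Strand-combined CpG calls.
#' @param min_coverage Per-CpG minimum coverage (default 4).
#' @param pmd_min_length Minimum PMD length in bp (default 1e5).
#' @param smooth_k Running-mean window in CpGs (default 3).
#' @param hypo_max Smoothed-level cutoff for hypomethylated segments
#'   (default 0.5).
#' @param hypo_min_cpgs Minimum CpGs for a hypomethylated segment
#'   (default 4).
#' @param umr_min_cpgs CpG count at or above which a hypomethylated
#'   segment is a UMR rather than an LMR (default 30).
#' @param fmr_min_mean Minimum mean methylation of an FMR (default 0.85).
#' @param fmr_min_cpgs Minimum CpGs of an FMR (default 5).
#' @return Tibble of non-overlapping segments sorted by position:
#'   `chrom`, `start`, `end`, `class`, `n_cpg`, `mean_meth`.
#' @export
segment_methylome <- function(calls, min_coverage = 4, pmd_min_length = 1e5,
                              smooth_k = 3, hypo_max = 0.5,
                              hypo_min_cpgs = 4, umr_min_cpgs = 30,
                              fmr_min_mean = 0.85, fmr_min_cpgs = 5) {
  cpg <- calls[calls$context == "CpG" & calls$total >= min_coverage, ,
               drop = FALSE]
  if (nrow(cpg) == 0) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  class = character(), n_cpg = integer(),
                  mean_meth = double()))
  }
  cpg <- arrange(cpg, chrom, pos)
  segs <- list()
  shorts <- list()
  for (ch in unique(cpg$chrom)) {
    d <- cpg[cpg$chrom == ch, , drop = FALSE]
    pos <- d$pos
    lev <- d$meth / d$total
    n <- length(lev)
    sym <- ifelse(lev < 0.3, 1L, ifelse(lev > 0.7, 3L, 2L))
    state <- if (n >= 2) viterbi_two_state(sym) else rep(1L, n)
    cls <- rep(NA_character_, n)  # per-CpG assigned class
    # pass 1: PMDs
    pruns <- true_runs(state == 2L)
    for (r in seq_len(nrow(pruns))) {
      i0 <- pruns$start[r]; i1 <- pruns$end[r]
      len <- pos[i1] + 1 - pos[i0]
      if (len >= pmd_min_length) {
        cls[i0:i1] <- "PMD"
      } else {
        shorts[[length(shorts) + 1]] <-
          tibble(chrom = ch, start = pos[i0], end = pos[i1] + 1,
                 n_cpg = i1 - i0 + 1L, mean_meth = mean(lev[i0:i1]))
      }
    }
    # pass 2: UMR/LMR outside PMDs (smoothing within each non-PMD stretch)
    nonpmd <- true_runs(is.na(cls))
    for (r in seq_len(nrow(nonpmd))) {
      i0 <- nonpmd$start[r]; i1 <- nonpmd$end[r]
      sm <- running_mean(lev[i0:i1], smooth_k)
      hyp <- true_runs(sm < hypo_max)
      for (h in seq_len(nrow(hyp))) {
        j0 <- i0 + hyp$start[h] - 1L; j1 <- i0 + hyp$end[h] - 1L
        ncp <- j1 - j0 + 1L
        if (ncp >= hypo_min_cpgs) {
          cls[j0:j1] <- if (ncp >= umr_min_cpgs) "UMR" else "LMR"
        }
      }
    }
    # pass 3: FMR / unclassified on what remains
    rem <- true_runs(is.na(cls))
    for (r in seq_len(nrow(rem))) {
      i0 <- rem$start[r]; i1 <- rem$end[r]
      ncp <- i1 - i0 + 1L
      cls[i0:i1] <- if (mean(lev[i0:i1]) >= fmr_min_mean &&
                        ncp >= fmr_min_cpgs) "FMR" else "unclassified"
    }
    cruns <- rle(cls)
    ends <- cumsum(cruns$lengths)
    starts <- ends - cruns$lengths + 1L
    segs[[ch]] <- tibble(
      chrom = ch,
      start = pos[starts],
      end = pos[ends] + 1,
      class = cruns$values,
      n_cpg = cruns$lengths,
      mean_meth = vapply(seq_along(starts),
                         function(i) mean(lev[starts[i]:ends[i]]),
                         numeric(1))
    )
  }
  out <- arrange(bind_rows(segs), chrom, start)
  attr(out, "short_pmds") <- if (length(shorts)) bind_rows(shorts) else
    tibble(chrom = character(), start = double(), end = double(),
           n_cpg = integer(), mean_meth = double())
  out
}

#' Pool CHH methylation into 1-kb bins
#'
#' Methylated and total CHH counts are summed per bin; the bin level is the
#' pooled ratio (sum of methylated over sum of total), not the mean of
#' per-site ratios. Bins with no CHH record are masked.
#'
#' @param calls Methylation calls (only CHH records are consumed).
#' @param genome A [cm_genome()].
#' @param bin_size Bin size in bp (default 1000).
#' @return A [bin_track()] on 1-kb bins with extra columns `meth` and
#'   `total`; `value` is the pooled methylation level.
#' @export
bin_chh <- function(calls, genome, bin_size = 1000) {
  bins <- cm_bins(genome, bin_size)
  chh <- calls[calls$context == "CHH", , drop = FALSE]
  meth <- rep(0, nrow(bins)); total <- rep(0, nrow(bins))
  if (nrow(chh) > 0) {
    idx <- pos_to_bin(bins, chh$chrom, chh$pos)
    ok <- !is.na(idx)
    meth <- meth + as.vector(tapply_sum(idx[ok], chh$meth[ok], nrow(bins)))
    total <- total + as.vector(tapply_sum(idx[ok], chh$total[ok], nrow(bins)))
  }
  out <- bin_track(bins, ifelse(total > 0, meth / total, NA_real_))
  out$meth <- meth
  out$total <- total
  out
}

tapply_sum <- function(idx, val, n) {
  out <- numeric(n)
  agg <- rowsum(val, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Coverage-weighted mean methylation inside regions
#'
#' @param calls Strand-combined CpG calls.
#' @param regions Tibble of intervals.
#' @param min_coverage Per-CpG minimum coverage (default 4).
#' @return Pooled methylation level (total methylated / total counts) of
#'   qualifying CpGs inside the regions; `NA` if none qualify.
#' @export
mean_methylation_in <- function(calls, regions, min_coverage = 4) {
  cpg <- calls[calls$context == "CpG" & calls$total >= min_coverage, ,
               drop = FALSE]
  if (nrow(cpg) == 0 || nrow(regions) == 0) return(NA_real_)
  keep <- in_regions(cpg$chrom, cpg$pos, regions)
  if (!any(keep)) return(NA_real_)
  sum(cpg$meth[keep]) / sum(cpg$total[keep])
}

# membership of positions in a set of intervals (per chromosome findInterval
# over merged interval starts/ends)
in_regions <- function(chrom, pos, regions) {
  regions <- merge_intervals(regions)
  out <- rep(FALSE, length(pos))
  for (ch in unique(chrom)) {
    rg <- regions[regions$chrom == ch, , drop = FALSE]
    if (nrow(rg) == 0) next
    sel <- chrom == ch
    i <- findInterval(pos[sel], rg$start)
    out[sel] <- i >= 1 & pos[sel] < rg$end[pmax(i, 1)]
  }
  out
}
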