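#' Call A/B compartments from a balanced contact matrix
#'
#' Per chromosome, the O/E correlation matrix is decomposed into its
#' leading eigenvectors. Among the first `n_candidates` components the one
#' with the largest absolute Pearson correlation with the activity track is
#' taken as the compartment eigenvector (a reproducible surrogate for
#' manual curation of chromosomes where a later component carries the
#' checkerboard), scaled by the square root of its eigenvalue, and oriented
#' so that its correlation with activity is non-negative. Bins with a
#' positive value are labelled `A`, negative `B`; exactly zero or masked
#' bins stay unassigned.
#'
#' @param x A balanced `cm_contacts` (see [ice_balance()]).
#' @param activity A [bin_track()] on the same bins marking active
#'   chromatin (gene density, expression, or any active-chromatin proxy);
#'   used only for component selection and sign orientation.
#' @param n_candidates Number of leading components considered (default 3).
#' @param scale_eigen Scale the eigenvector by `sqrt(eigenvalue)` (default
#'   `TRUE`) so magnitudes are comparable across chromosomes.
#' @param reliable_min_cor Absolute activity correlation below which the
#'   chromosome is flagged unreliable in the selection table (default 0.2).
#' @return A tibble (class `cm_compartments`) with bin columns plus `pc1`
#'   and `label` (`"A"`, `"B"` or `NA`); attribute `pc_selection` records,
#'   per chromosome, the chosen component, its activity correlation and a
#'   reliability flag.
#' @export
call_compartments <- function(x, activity, n_candidates = 3,
                              scale_eigen = TRUE, reliable_min_cor = 0.2) {
  if (!x$balanced) stopf("call_compartments() needs a balanced matrix")
  if (!same_bins(x$bins, activity)) stopf("activity track is on different bins")
  g <- bins_genome(x$bins)
  cors <- oe_correlation(x)
  pc1 <- rep(NA_real_, nrow(x$bins))
  sel <- list()
  for (ch in g$chrom) {
    rows <- which(x$bins$chrom == ch)
    cc <- cors[[ch]]
    ok <- which(apply(cc, 1, function(r) any(is.finite(r))))
    # short terminal bins never enter the PCA
    ok <- setdiff(ok, which(x$bins$short[rows]))
    if (length(ok) < 3) {
      warnf("degenerate correlation matrix on %s; bins unassigned", ch)
      sel[[ch]] <- tibble(chrom = ch, component = NA_integer_,
                          activity_cor = NA_real_, reliable = FALSE)
      next
    }
    sub <- cc[ok, ok, drop = FALSE]
    sub[!is.finite(sub)] <- 0
    sub <- (sub + t(sub)) / 2
    eg <- eigen(sub, symmetric = TRUE)
    k <- min(n_candidates, ncol(eg$vectors))
    act <- activity$value[rows][ok]
    comp_cor <- vapply(seq_len(k), function(i) {
      r <- cor_pairwise(eg$vectors[, i], act)
      if (is.na(r)) 0 else r
    }, numeric(1))
    best <- which.max(abs(comp_cor))
    v <- eg$vectors[, best]
    if (scale_eigen) v <- v * sqrt(max(eg$values[best], 0))
    if (comp_cor[best] < 0) v <- -v
    pc1[rows[ok]] <- v
    sel[[ch]] <- tibble(chrom = ch, component = best,
                        activity_cor = abs(comp_cor[best]),
                        reliable = abs(comp_cor[best]) >= reliable_min_cor)
  }
  out <- bin_track(x$bins, pc1)
  names(out)[names(out) == "value"] <- "pc1"
  out$label <- dplyr::case_when(out$pc1 > 0 ~ "A", out$pc1 < 0 ~ "B",
                                TRUE ~ NA_character_)
  attr(out, "pc_selection") <- bind_rows(sel)
  class(out) <- c("cm_compartments", class(out))
  out
}

#' @export
glance.cm_compartments <- function(x, ...) {
  sel <- attr(x, "pc_selection")
  tibble(
    n_bins = nrow(x),
    n_assigned = sum(!is.na(x$label)),
    frac_a = compartment_fraction(x),
    min_activity_cor = min(sel$activity_cor, na.rm = TRUE),
    all_reliable = all(sel$reliable)
  )
}

std_pc1 <- function(track) {
  track |>
    group_by(chrom) |>
    mutate(pc1 = pc1 / sd(pc1[is.finite(pc1)])) |>
    ungroup()
}

#' Differential A/B compartments between two samples
#'
#' A bin is differential when its eigenvector values have opposite signs in
#' the two samples and differ by at least `delta`; a region is reported for
#' every maximal run of at least `min_bins` consecutive differential bins
#' of the same direction. Masked or exactly-zero bins never qualify. By
#' default tracks are variance-standardized per chromosome first so the
#' `delta = 1` threshold acts on a declared, comparable scale.
#'
#' @param a,b `cm_compartments` tracks on the same bins.
#' @param delta Minimum per-bin difference (default 1).
#' @param min_bins Minimum consecutive qualifying bins (default 2).
#' @param standardize Divide each chromosome's values by their standard
#'   deviation before applying `delta` (default `TRUE`).
#' @return Tibble of regions: `chrom`, `start`, `end`, `direction`
#'   (`"A->B"` / `"B->A"`, sample `a` relative to `b`), `n_bins`,
#'   `mean_delta`, and list-column `delta_pc1` of per-bin differences.
#' @export
differential_compartments <- function(a, b, delta = 1, min_bins = 2,
                                      standardize = TRUE) {
  if (!same_bins(a, b)) stopf("tracks are on different bin tables")
  if (standardize) {
    a <- std_pc1(a)
    b <- std_pc1(b)
  }
  pa <- a$pc1; pb <- b$pc1
  qual <- is.finite(pa) & is.finite(pb) & pa != 0 & pb != 0 &
    (sign(pa) != sign(pb)) & (abs(pa - pb) >= delta)
  dir <- ifelse(pa > 0, "A->B", "B->A")
  out <- list()
  for (ch in unique(a$chrom)) {
    rows <- which(a$chrom == ch)
    q <- qual[rows]
    runs <- true_runs(q)
    for (r in seq_len(nrow(runs))) {
      idx <- rows[runs$start[r]:runs$end[r]]
      # split runs of mixed direction
      dsplit <- true_runs(dir[idx] == "A->B")
      pieces <- list()
      taken <- rep(FALSE, length(idx))
      for (p in seq_len(nrow(dsplit))) {
        pieces <- c(pieces, list(idx[dsplit$start[p]:dsplit$end[p]]))
        taken[dsplit$start[p]:dsplit$end[p]] <- TRUE
      }
      bsplit <- true_runs(!taken)
      for (p in seq_len(nrow(bsplit))) {
        pieces <- c(pieces, list(idx[bsplit$start[p]:bsplit$end[p]]))
      }
      for (piece in pieces) {
        if (length(piece) < min_bins) next
        out <- c(out, list(tibble(
          chrom = ch,
          start = min(a$start[piece]),
          end = max(a$end[piece]),
          direction = dir[piece[1]],
          n_bins = length(piece),
          mean_delta = mean(pa[piece] - pb[piece]),
          delta_pc1 = list(pa[piece] - pb[piece])
        )))
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  direction = character(), n_bins = integer(),
                  mean_delta = double(), delta_pc1 = list()))
  }
  arrange(bind_rows(out), chrom, start)
}

#' Compartment status shared across a cohort
#'
#' @param tracks List of >= 2 `cm_compartments` tracks on the same bins.
#' @return A bin table with a `status` column: `common-A` (positive in
#'   every track), `common-B` (negative in every track), `unassigned` (any
#'   masked/zero bin), else `dynamic`.
#' @export
common_compartments <- function(tracks) {
  if (length(tracks) < 2) stopf("common_compartments() needs >= 2 tracks")
  ref <- tracks[[1]]
  for (t in tracks[-1]) {
    if (!same_bins(ref, t)) stopf("tracks are on different bin tables")
  }
  pcs <- vapply(tracks, function(t) t$pc1, numeric(nrow(ref)))
  any_na <- apply(pcs, 1, function(v) any(!is.finite(v) | v == 0))
  all_pos <- apply(pcs, 1, function(v) all(v > 0))
  all_neg <- apply(pcs, 1, function(v) all(v < 0))
  status <- dplyr::case_when(
    any_na ~ "unassigned",
    all_pos ~ "common-A",
    all_neg ~ "common-B",
    TRUE ~ "dynamic"
  )
  out <- as_tibble(ref[, c("bin", "chrom", "start", "end", "short")])
  out$status <- status
  attr(out, "bin_size") <- attr(ref, "bin_size")
  attr(out, "genome") <- attr(ref, "genome")
  out
}

# Rebin a per-bin value vector to a coarser bin size by the mean of
# constituent unmasked bins; a coarse bin with > 50% masked constituents is
# masked.
rebin_mean <- function(track, value_col, bin_size) {
  s <- bins_size(track)
  if (bin_size < s || bin_size %% s != 0) {
    stopf("target bin size must be a multiple of the native bin size")
  }
  track |>
    mutate(.grp = floor(start / bin_size)) |>
    group_by(chrom, .grp) |>
    summarise(
      value = if (mean(is.na(.data[[value_col]])) > 0.5) NA_real_ else
        mean(.data[[value_col]], na.rm = TRUE),
      .groups = "drop"
    ) |>
    arrange(match(chrom, unique(track$chrom)), .grp)
}

#' Genome-wide correlation of two compartment eigenvector tracks
#'
#' Tracks are rebinned to `bin_size` by the mean of constituent unmasked
#' bins (a coarse bin with more than half of its constituents masked is
#' masked), then Pearson-correlated over jointly unmasked bins.
#'
#' @param a,b `cm_compartments` tracks on the same bins.
#' @param bin_size Correlation bin size in bp; defaults to the native bin
#'   size (use 5e5 for biological replicates).
#' @return One-row tibble with `r`, `r_squared` and `n_bins`.
#' @export
pc1_correlation <- function(a, b, bin_size = NULL) {
  if (!same_bins(a, b)) stopf("tracks are on different bin tables")
  bin_size <- bin_size %||% bins_size(a)
  va <- rebin_mean(a, "pc1", bin_size)$value
  vb <- rebin_mean(b, "pc1", bin_size)$value
  ok <- is.finite(va) & is.finite(vb)
  if (sum(ok) < 3) stopf("fewer than 3 jointly unmasked bins")
  r <- cor(va[ok], vb[ok])
  tibble(r = r, r_squared = r^2, n_bins = sum(ok))
}

#' Fraction of the assigned genome in A compartments
#'
#' @param track A `cm_compartments` track.
#' @return Sum of A-bin widths divided by the sum of assigned (A or B) bin
#'   widths.
#' @export
compartment_fraction <- function(track) {
  w <- track$end - track$start
  assigned <- !is.na(track$label)
  if (!any(assigned)) stopf("no assigned bins")
  sum(w[assigned & track$label == "A"]) / sum(w[assigned])
}
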